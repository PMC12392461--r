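compound,assay,ec10,emax_pct,role
estradiol,ERalpha,1.98e-11,100,reference_agonist
rosiglitazone,PPARgamma,3.0e-11,100,reference_agonist
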