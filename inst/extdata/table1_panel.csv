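compound,alpha_neutral_pct,log_kow,log_dlipw,ic10_median,ec10_eralpha,ec10_pparg,ec10_ahr,ec_ir15_are,ec10_mmp,ec10_noi,emax_eralpha,emax_pparg,sigma_sr_score
TCBPA,29,6.36,6.10,7.84e-5,3.44e-6,1.55e-5,,,1.48e-5,3.22e-4,33,32,1.83
TBBPA,5,5.91,5.24,9.28e-5,,8.48e-8,,,2.83e-5,,0,52,1.22
TMBPF,95,4.37,4.53,1.27e-5,,3.29e-7,,,,4.28e-6,0,18,1.10
BPPH,99,6.67,6.85,8.02e-6,,5.55e-7,9.54e-6,,1.96e-6,,0,12,1.28
BPG,100,6.01,6.19,7.84e-6,9.02e-7,1.17e-7,,,3.12e-6,,19,22,2.04
BADGE,100,3.62,3.78,3.85e-5,,,,,,3.81e-5,,,0.03
BPP,100,6.09,6.27,1.91e-5,4.78e-7,,,,1.78e-6,,13,,2.00
Pergafast,0.089,4.11,3.27,1.91e-5,,6.71e-7,2.29e-5,,,1.25e-5,,16,1.99
BTUM,0.0007,4.82,3.99,3.10e-5,,2.56e-7,,,,6.48e-5,,47,1.02
BPT,96,3.29,3.42,9.51e-5,7.27e-7,9.61e-7,,,1.83e-5,,80,20,3.00
BPF,99,2.71,2.85,4.09e-4,9.95e-7,,,,1.65e-4,,60,,1.14
BPZ,99,4.64,4.80,5.28e-5,4.43e-8,,8.04e-5,,2.21e-5,3.05e-5,21,,1.13
BzPB,99,3.30,3.45,1.32e-4,3.02e-6,2.04e-6,,1.94e-5,2.44e-5,,53,16,3.40
Bz,71,2.06,2.07,3.73e-4,1.06e-6,,6.20e-5,,,,32,,1.04
BPAP,95,5.06,5.22,3.31e-5,1.94e-7,,,,,5.12e-5,24,,1.05
BPAF,96,4.72,4.87,2.28e-5,2.44e-8,,,,5.32e-6,1.62e-5,40,,1.82
BP-MIBK,100,4.47,4.63,3.26e-5,1.43e-8,,,,1.14e-5,,30,,1.10
BPB,99,3.72,3.87,3.62e-5,1.35e-7,,,,1.64e-5,2.80e-5,24,,1.78
BPA,100,4.25,3.65,7.00e-5,3.70e-7,,2.64e-4,,2.80e-5,5.08e-5,38,,1.54
BPE,98,4.05,4.20,7.91e-5,4.01e-7,,6.19e-5,,3.21e-5,1.14e-4,52,,1.17
BPS-MPE,68,4.28,4.30,1.12e-4,,2.35e-7,,,5.59e-6,2.47e-4,,25,2.01
BPS-MAE,80,2.85,2.91,1.90e-4,1.41e-5,5.57e-7,,,7.85e-5,2.52e-5,28,22,3.59
D8,61,2.87,2.83,3.37e-4,1.12e-5,,,1.22e-3,5.20e-5,1.91e-4,18,,2.12
BPS,39,1.97,1.77,5.61e-4,1.43e-6,,,,1.17e-4,,66,,2.00
"2,4-BPS",43,1.90,1.72,4.63e-4,1.98e-5,,,,5.90e-5,,19,,2.00
t-TMCD,100,1.30,1.43,8.94e-3,3.03e-3,,,,1.85e-2,4.15e-3,,,0.02
r-TMCD,100,1.30,1.43,8.29e-3,1.29e-2,,,,,5.99e-3,,,0.01
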