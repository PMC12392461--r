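#' Morgan (ECFP4-style) circular fingerprint from SMILES
#'
#' Computes an extended-connectivity fingerprint of radius 2 (ECFP4) as a
#' fixed-length binary vector. The SMILES is first canonicalized with
#' OpenBabel (via \pkg{ChemmineOB}), so different notations of the same
#' molecule give identical fingerprints, then parsed into a molecular graph
#' with \pkg{ChemmineR}. Initial atom invariants are (atomic number, heavy
#' degree, implicit+explicit hydrogen count, formal charge, ring
#' membership); neighborhoods are iteratively hashed out to the requested
#' radius and folded onto `n_bits` bits. Stereochemistry is not encoded.
#'
#' @param smiles A single SMILES string.
#' @param radius Neighborhood radius (2 for ECFP4).
#' @param n_bits Folded fingerprint length (default 1024).
#' @return Integer vector of 0/1 of length `n_bits`.
#' @export
morgan_fingerprint <- function(smiles, radius = 2, n_bits = 1024) {
  mol <- parse_molecule(smiles)
  ids <- atom_invariants(mol)
  all_ids <- ids
  if (nrow(mol$bonds) > 0 && radius > 0) {
    nb <- neighbor_table(mol)
    for (r in seq_len(radius)) {
      new_ids <- vapply(seq_along(ids), function(a) {
        nbs <- nb[[a]]
        if (!length(nbs$atom)) return(hash_ints(c(r, ids[a])))
        ord <- order(nbs$order, ids[nbs$atom])
        hash_ints(c(r, ids[a],
                    as.vector(rbind(nbs$order[ord], ids[nbs$atom][ord]))))
      }, numeric(1))
      ids <- new_ids
      all_ids <- c(all_ids, ids)
    }
  }
  bits <- integer(n_bits)
  bits[unique(all_ids %% n_bits) + 1L] <- 1L
  bits
}

#' Fingerprint a set of compounds
#'
#' @param ids Character vector of unique compound ids.
#' @param smiles SMILES strings, same length as `ids`.
#' @inheritParams morgan_fingerprint
#' @return Binary matrix with one row per compound (rownames = ids).
#' @export
fingerprint_set <- function(ids, smiles, radius = 2, n_bits = 1024) {
  stopifnot(length(ids) == length(smiles), !anyDuplicated(ids))
  fps <- matrix(0L, nrow = length(ids), ncol = n_bits,
                dimnames = list(ids, NULL))
  for (i in seq_along(ids)) {
    fp <- tryCatch(morgan_fingerprint(smiles[i], radius, n_bits),
                   error = function(e) {
                     stop("cannot fingerprint compound '", ids[i], "': ",
                          conditionMessage(e), call. = FALSE)
                   })
    fps[i, ] <- fp
  }
  fps
}

#' Tanimoto distance matrix of a fingerprint set
#'
#' \eqn{d = 1 - |A \cap B| / |A \cup B|} on the set bits. Two identical
#' all-zero fingerprints get distance 0; an empty fingerprint is at distance
#' 1 from any non-identical vector (with a warning).
#'
#' @param fps Binary fingerprint matrix from [fingerprint_set()] (rows =
#'   compounds).
#' @return Symmetric distance matrix in `[0, 1]` with zero diagonal.
#' @export
tanimoto_distance_matrix <- function(fps) {
  stopifnot(is.matrix(fps), nrow(fps) >= 2)
  fps <- fps != 0
  counts <- rowSums(fps)
  if (any(counts == 0)) {
    warning("fingerprint(s) with no set bits: ",
            paste(rownames(fps)[counts == 0], collapse = ", "),
            "; distance to any non-identical vector is 1")
  }
  inter <- tcrossprod(fps * 1)
  union <- outer(counts, counts, "+") - inter
  d <- 1 - inter / union
  d[union == 0] <- 0   # two empty fingerprints are identical
  diag(d) <- 0
  dimnames(d) <- list(rownames(fps), rownames(fps))
  d
}

#' Hierarchical similarity grouping
#'
#' Agglomerative clustering of the Tanimoto distance matrix, cut into `k`
#' groups. Average linkage by default (complete and Ward's D2 available).
#' Labels are arbitrary but deterministic; compare partitions up to label
#' permutation with [same_partition()].
#'
#' @param dm Square symmetric distance matrix (e.g. from
#'   [tanimoto_distance_matrix()]).
#' @param k Number of groups, `1 <= k <= nrow(dm)`.
#' @param linkage `"average"`, `"complete"` or `"ward"`.
#' @return Named integer vector of group labels.
#' @export
hierarchical_groups <- function(dm, k = 5,
                                linkage = c("average", "complete", "ward")) {
  linkage <- match.arg(linkage)
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  if (k < 1 || k > nrow(dm)) {
    stop("`k` must lie between 1 and the number of compounds (", nrow(dm),
         ")", call. = FALSE)
  }
  method <- c(average = "average", complete = "complete",
              ward = "ward.D2")[[linkage]]
  hc <- stats::hclust(stats::as.dist(dm), method = method)
  stats::cutree(hc, k = k)
}

#' Are two clusterings the same partition?
#'
#' Label-permutation-invariant comparison of two group assignments over the
#' same items.
#'
#' @param a,b Group label vectors of equal length.
#' @return `TRUE` if they induce identical partitions.
#' @export
same_partition <- function(a, b) {
  stopifnot(length(a) == length(b))
  co_a <- outer(a, a, "==")
  co_b <- outer(b, b, "==")
  all(co_a == co_b)
}

#' Read a SMILES file
#'
#' Plain-text file with one compound per line: `id<TAB>smiles` (a header
#' line `id\tsmiles` is allowed and skipped).
#'
#' @param path File path.
#' @return Tibble with columns `id`, `smiles`.
#' @export
read_smiles_file <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          col.names = c("id", "smiles"),
                          stringsAsFactors = FALSE)
  if (nrow(df) && identical(tolower(df$id[1]), "id")) df <- df[-1, ]
  tibble::as_tibble(df)
}

## ---- internal molecular-graph machinery -------------------------------

ATOMIC_NUMBERS <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15, S = 16,
  Cl = 17, Br = 35, I = 53
)

# default valences for implicit-H assignment (smallest valence >= bond sum)
ALLOWED_VALENCES <- list(
  H = 1, B = 3, C = 4, N = c(3, 5), O = 2, Si = 4, P = c(3, 5),
  S = c(2, 4, 6), F = 1, Cl = 1, Br = 1, I = 1
)

# Canonicalize (OpenBabel) and parse a SMILES into an atom/bond graph.
parse_molecule <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, !is.na(smiles))
  can <- tryCatch(
    trimws(ChemmineOB::convertFormat("SMI", "CAN", smiles)),
    error = function(e) ""
  )
  can <- sub("\t.*$", "", can)
  if (!nzchar(can)) {
    stop("unparseable SMILES: '", smiles, "'", call. = FALSE)
  }
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(can))[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_[0-9]+$", "", rownames(ab))
  unknown <- setdiff(unique(elements), names(ATOMIC_NUMBERS))
  if (length(unknown)) {
    stop("unsupported element(s) in '", smiles, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0) {
    matrix(integer(0), ncol = 3)
  } else {
    cbind(as.integer(bb[, 1]), as.integer(bb[, 2]), as.integer(bb[, 3]))
  }
  # drop explicit hydrogens into the heavy atoms' H counts
  heavy <- which(elements != "H")
  h_explicit <- integer(length(elements))
  if (length(heavy) < length(elements) && nrow(bonds)) {
    is_h <- elements == "H"
    keep <- !(is_h[bonds[, 1]] | is_h[bonds[, 2]])
    for (i in which(!keep)) {
      hv <- bonds[i, 1:2][!is_h[bonds[i, 1:2]]]
      if (length(hv)) h_explicit[hv] <- h_explicit[hv] + 1L
    }
    idx_map <- match(seq_along(elements), heavy)
    bonds <- bonds[keep, , drop = FALSE]
    bonds[, 1] <- idx_map[bonds[, 1]]
    bonds[, 2] <- idx_map[bonds[, 2]]
  }
  list(elements = elements[heavy], bonds = bonds,
       h_explicit = h_explicit[heavy],
       charges = integer(length(heavy)))
}

# per-atom neighbor lists with bond orders
neighbor_table <- function(mol) {
  n <- length(mol$elements)
  nb <- replicate(n, list(atom = integer(0), order = integer(0)),
                  simplify = FALSE)
  b <- mol$bonds
  for (i in seq_len(nrow(b))) {
    a1 <- b[i, 1]; a2 <- b[i, 2]; o <- b[i, 3]
    nb[[a1]]$atom <- c(nb[[a1]]$atom, a2)
    nb[[a1]]$order <- c(nb[[a1]]$order, o)
    nb[[a2]]$atom <- c(nb[[a2]]$atom, a1)
    nb[[a2]]$order <- c(nb[[a2]]$order, o)
  }
  nb
}

# initial Morgan invariants: hash of (Z, heavy degree, H count, charge, ring)
atom_invariants <- function(mol) {
  n <- length(mol$elements)
  z <- ATOMIC_NUMBERS[mol$elements]
  degree <- integer(n)
  bond_sum <- integer(n)
  b <- mol$bonds
  for (i in seq_len(nrow(b))) {
    degree[b[i, 1:2]] <- degree[b[i, 1:2]] + 1L
    bond_sum[b[i, 1:2]] <- bond_sum[b[i, 1:2]] + b[i, 3]
  }
  n_h <- vapply(seq_len(n), function(a) {
    allowed <- ALLOWED_VALENCES[[mol$elements[a]]]
    total <- bond_sum[a] + mol$h_explicit[a] + abs(mol$charges[a])
    v <- allowed[allowed >= total]
    v <- if (length(v)) min(v) else total
    as.integer(v - total) + mol$h_explicit[a]
  }, integer(1))
  in_ring <- ring_atoms(mol)
  vapply(seq_len(n), function(a) {
    hash_ints(c(z[a], degree[a], n_h[a], mol$charges[a], in_ring[a]))
  }, numeric(1))
}

# atoms incident to a cycle edge (edges that are not bridges)
ring_atoms <- function(mol) {
  n <- length(mol$elements)
  if (nrow(mol$bonds) == 0) return(integer(n))
  g <- igraph::graph_from_edgelist(mol$bonds[, 1:2, drop = FALSE],
                                   directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  bridge_idx <- igraph::bridges(g)
  ring_edges <- setdiff(seq_len(nrow(mol$bonds)), as.integer(bridge_idx))
  out <- integer(n)
  out[unique(as.vector(mol$bonds[ring_edges, 1:2]))] <- 1L
  out
}

# deterministic polynomial hash of an integer vector, mod 2^31 - 1
hash_ints <- function(x) {
  p <- 2147483647
  h <- 2166136261 %% p
  for (v in x) {
    h <- (h * 31 + (v %% p)) %% p
  }
  h
}
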