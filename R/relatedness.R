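#' Genomic relationship matrix
#'
#' Standard variance-normalised estimator: entry (i, i') is the mean over
#' SNPs of `(g_ij - 2 p_j)(g_i'j - 2 p_j) / (2 p_j (1 - p_j))`, with allele
#' frequencies `p_j` computed on the included samples and missing calls
#' mean-imputed (zero after standardisation). Variants below the MAF floor
#' or monomorphic are excluded. Self-pairs sit near `1 + F` (inbreeding F),
#' duplicates near 1, parent-offspring near 0.5.
#'
#' @param x a `genotype_matrix`.
#' @param maf_floor exclude variants with MAF below this (default 0.05, the
#'   filter the framework applies before relatedness screening).
#' @param sample_ids optional subset.
#' @return a `relatedness_matrix`: list with `ids` and symmetric `matrix`.
#' @export
grm <- function(x, maf_floor = 0.05, sample_ids = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (!is.null(sample_ids)) x <- gm_subset(x, sample_ids = sample_ids)
  af <- allele_frequency(x)
  use <- !is.na(af$maf) & af$maf >= maf_floor & af$maf > 0
  if (!any(use)) stop("no usable SNPs after MAF filter")
  g <- x$calls[, use, drop = FALSE]
  p <- af$f[use]
  z <- sweep(g, 2, 2 * p)
  z[is.na(g)] <- 0                                  # mean imputation
  z <- sweep(z, 2, sqrt(2 * p * (1 - p)), "/")
  m <- tcrossprod(z) / sum(use)
  structure(list(ids = x$samples$id, matrix = m),
            class = "relatedness_matrix")
}

#' Supra-threshold related pairs
#'
#' @param rel a `relatedness_matrix` from [grm()].
#' @param cutoff relatedness value above which a pair is reported
#'   (default 0.025, PLINK's `--rel-cutoff` default, a value applied
#'   analyses rarely state explicitly).
#' @return data.frame: `id1`, `id2`, `value`, one row per off-diagonal
#'   pair with `value > cutoff`.
#' @export
related_pairs <- function(rel, cutoff = 0.025) {
  stopifnot(inherits(rel, "relatedness_matrix"))
  m <- rel$matrix
  idx <- which(upper.tri(m) & m > cutoff, arr.ind = TRUE)
  data.frame(id1 = rel$ids[idx[, 1]], id2 = rel$ids[idx[, 2]],
             value = m[idx], stringsAsFactors = FALSE)
}

#' Greedy unrelated-subset selection
#'
#' Iteratively removes the individual participating in the most remaining
#' related pairs (ties broken by removing the lexicographically larger id)
#' until no pairs remain. Greedy, so not guaranteed maximum; the kept set
#' is certified to induce zero pairs from the input list.
#'
#' @param pairs data.frame with `id1`, `id2` (from [related_pairs()]).
#' @param all_ids character vector of every candidate id.
#' @return list with `keep` and `drop` (character vectors; `keep` preserves
#'   the order of `all_ids`).
#' @export
greedy_unrelated <- function(pairs, all_ids) {
  if (nrow(pairs)) {
    unknown <- setdiff(c(pairs$id1, pairs$id2), all_ids)
    if (length(unknown)) stop("pairs reference unknown id(s): ",
                              paste(utils::head(unknown, 3), collapse = ", "))
  }
  drop <- character()
  p1 <- pairs$id1; p2 <- pairs$id2
  active <- rep(TRUE, length(p1))
  while (any(active)) {
    deg <- table(c(p1[active], p2[active]))
    worst <- names(deg)[deg == max(deg)]
    victim <- max(worst)                             # lexicographic tie-break
    drop <- c(drop, victim)
    active <- active & p1 != victim & p2 != victim
  }
  list(keep = setdiff(all_ids, drop), drop = drop)
}
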