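#' Per-SNP Hudson Fst components
#'
#' For sample alt frequencies `p1`, `p2` from `n1`, `n2` diploids:
#' numerator `(p1 - p2)^2 - p1(1-p1)/(2 n1 - 1) - p2(1-p2)/(2 n2 - 1)`
#' (the finite-sample-corrected between-population term) and denominator
#' `p1(1-p2) + p2(1-p1)`. Combined across SNPs as a ratio of averages by
#' [pairwise_fst()], the form recommended under ascertained SNP panels.
#'
#' @param p1,p2 numeric vectors of alt-allele sample frequencies.
#' @param n1,n2 diploid sample counts per SNP (scalars or vectors,
#'   `>= 2`).
#' @return list with `numerator` and `denominator` vectors.
#' @export
hudson_components <- function(p1, n1, p2, n2) {
  stopifnot(length(p1) == length(p2))
  if (any(n1 < 2, na.rm = TRUE) || any(n2 < 2, na.rm = TRUE))
    stop("need at least 2 diploids per population")
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (2 * n1 - 1) -
    p2 * (1 - p2) / (2 * n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  list(numerator = num, denominator = den)
}

#' Pairwise Hudson Fst between labelled groups
#'
#' Ratio-of-averages per pair: `sum_j num_j / sum_j den_j` over SNPs where
#' both groups have at least 2 non-missing diploids and the denominator is
#' positive. Groups with fewer than 2 samples are excluded with a warning.
#' Negative per-pair estimates (sampling noise around 0) are kept raw in
#' `fst_raw` and clamped to `[0, 1]` in `fst`.
#'
#' @param x a `genotype_matrix`.
#' @param group_labels character vector, one label per sample (NA =
#'   ungrouped, excluded).
#' @return an `fst_matrix`: list with `groups`, `fst` (clamped symmetric
#'   matrix, zero diagonal), `fst_raw`, `n_snps` (usable SNPs per pair).
#' @export
pairwise_fst <- function(x, group_labels) {
  stopifnot(inherits(x, "genotype_matrix"),
            length(group_labels) == nrow(x$calls))
  groups <- split(x$samples$id, group_labels)
  sizes <- vapply(groups, length, 0L)
  if (any(sizes < 2)) {
    warning("excluding group(s) with < 2 samples: ",
            paste(names(groups)[sizes < 2], collapse = ", "))
    groups <- groups[sizes >= 2]
  }
  if (length(groups) < 2) stop("need at least 2 groups of size >= 2")
  K <- length(groups)
  M <- ncol(x$calls)
  p <- matrix(NA_real_, K, M)
  nn <- matrix(NA_real_, K, M)
  for (k in seq_len(K)) {
    af <- allele_frequency(x, groups[[k]])
    p[k, ] <- af$f
    nn[k, ] <- af$n_obs
  }
  fst_raw <- matrix(0, K, K, dimnames = list(names(groups), names(groups)))
  n_snps <- matrix(NA_integer_, K, K,
                   dimnames = list(names(groups), names(groups)))
  for (a in seq_len(K - 1)) for (b in (a + 1):K) {
    ok <- !is.na(p[a, ]) & !is.na(p[b, ]) & nn[a, ] >= 2 & nn[b, ] >= 2
    hc <- hudson_components(p[a, ok], nn[a, ok], p[b, ok], nn[b, ok])
    use <- hc$denominator > 0
    est <- sum(hc$numerator[use]) / sum(hc$denominator[use])
    fst_raw[a, b] <- fst_raw[b, a] <- est
    n_snps[a, b] <- n_snps[b, a] <- sum(use)
  }
  fst <- pmin(pmax(fst_raw, 0), 1)
  diag(fst) <- 0
  structure(list(groups = names(groups), fst = fst, fst_raw = fst_raw,
                 n_snps = n_snps),
            class = "fst_matrix")
}

#' Min/mean/max over pairwise Fst values
#'
#' Summaries over the strictly-upper-triangle entries of the clamped
#' matrix (the conventional three-number summary of group differentiation).
#'
#' @param fm an `fst_matrix` (or a bare symmetric matrix).
#' @return named numeric vector `c(min, mean, max)`.
#' @export
summarize_pairs <- function(fm) {
  m <- if (inherits(fm, "fst_matrix")) fm$fst else as.matrix(fm)
  vals <- m[upper.tri(m)]
  if (!length(vals)) stop("no pairs to summarise")
  c(min = min(vals), mean = mean(vals), max = max(vals))
}

#' Write a phylip-format distance matrix of mean Fst values
#'
#' Square phylip layout: a count line, then one line per group with the
#' name padded to 10 characters and its row of values. Names longer than
#' 10 characters switch to relaxed phylip (name + two spaces) with a
#' warning.
#'
#' @param fm an `fst_matrix`.
#' @param path output path.
#' @export
write_phylip <- function(fm, path) {
  stopifnot(inherits(fm, "fst_matrix"))
  m <- fm$fst
  nms <- fm$groups
  relaxed <- any(nchar(nms) > 10)
  if (relaxed)
    warning("group name(s) longer than 10 characters; writing relaxed phylip")
  lines <- format(nrow(m))
  for (i in seq_len(nrow(m))) {
    nm <- if (relaxed) paste0(nms[i], "  ") else
      formatC(nms[i], width = -10)
    lines <- c(lines, paste0(nm, paste(sprintf("%.6f", m[i, ]),
                                       collapse = " ")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a square phylip distance matrix
#'
#' Counterpart of [write_phylip()] (strict or relaxed dialect).
#'
#' @param path phylip file.
#' @return list with `groups` and `matrix`.
#' @export
read_phylip <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  nms <- character(n)
  m <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[1 + i]), "[ \t]+")[[1]]
    nms[i] <- f[1]
    m[i, ] <- as.numeric(f[-1])
  }
  dimnames(m) <- list(nms, nms)
  list(groups = nms, matrix = m)
}

#' Write the long-format pair table
#'
#' @param fm an `fst_matrix`.
#' @param path TSV path; columns group1, group2, fst, fst_raw, n_snps.
#' @export
write_fst_pairs <- function(fm, path) {
  stopifnot(inherits(fm, "fst_matrix"))
  K <- length(fm$groups)
  rows <- list()
  for (a in seq_len(K - 1)) for (b in (a + 1):K)
    rows[[length(rows) + 1L]] <- data.frame(
      group1 = fm$groups[a], group2 = fm$groups[b],
      fst = fm$fst[a, b], fst_raw = fm$fst_raw[a, b],
      n_snps = fm$n_snps[a, b], stringsAsFactors = FALSE)
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
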