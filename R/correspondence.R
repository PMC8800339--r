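#' Build a filtered contingency table
#'
#' Cross-tabulates paired labels (e.g. K-means cluster vs region of
#' birth) after dropping samples with a missing label on either side.
#' Birth categories (columns) with fewer than `min_count` observations are
#' excluded — "fewer than 10" means a category with exactly 10 is kept —
#' and rows left empty are dropped. The filter applies to columns only:
#' clusters are never dropped for rarity; the filter concerns sparse birth
#' categories only.
#'
#' @param labels_a row labels per sample (clusters).
#' @param labels_b column labels per sample (regions or countries).
#' @param min_count column total below which a category is dropped
#'   (default 10).
#' @return integer matrix of counts with dimnames.
#' @export
build_contingency <- function(labels_a, labels_b, min_count = 10) {
  stopifnot(length(labels_a) == length(labels_b))
  ok <- !is.na(labels_a) & !is.na(labels_b)
  if (!any(ok)) stop("no samples with both labels present")
  tab <- table(labels_a[ok], labels_b[ok])
  tab <- tab[, colSums(tab) >= min_count, drop = FALSE]
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  if (nrow(tab) == 0 || ncol(tab) == 0)
    stop("contingency table empty after the minimum-count filter")
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  m
}

#' Pearson chi-square test of independence
#'
#' `X^2 = sum (O - E)^2 / E` with expected counts from the row/column
#' margins; no continuity correction; `dof = (R - 1)(C - 1)`.
#'
#' @param tab count matrix (no zero margins).
#' @return list with `statistic`, `dof`, `p_value`.
#' @export
chi_square <- function(tab) {
  tab <- as.matrix(tab)
  r <- rowSums(tab); cs <- colSums(tab)
  if (any(r == 0) || any(cs == 0)) stop("zero row/column margin")
  n <- sum(tab)
  E <- outer(r, cs) / n
  stat <- sum((tab - E)^2 / E)
  dof <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = stat, dof = dof,
       p_value = stats::pchisq(stat, dof, lower.tail = FALSE))
}

#' Correspondence analysis of a contingency table
#'
#' Standard CA: with correspondence matrix `P = tab/n`, row and column
#' masses `r`, `c`, the standardised residuals
#' `S = D_r^{-1/2} (P - r c') D_c^{-1/2}` are decomposed by SVD. Principal
#' coordinates (mass-scaled, the symmetric-map convention) and standard
#' coordinates are both returned. Per-dimension inertia is
#' `sigma_d^2 / sum sigma^2`; total inertia equals Pearson `X^2 / n`
#' exactly. An independence table has zero inertia and zero coordinates
#' (no error). Because figure-style reports often quote Dim1/Dim2
#' percentages renormalised over the first two dimensions, both the raw
#' and the 2-D-renormalised fractions are reported.
#'
#' @param tab count matrix, e.g. from [build_contingency()].
#' @return a `ca_result`: list with `row_coords`, `col_coords` (principal
#'   coordinates), `row_standard`, `col_standard`, `singular_values`,
#'   `inertia_fractions`, `inertia_fractions_dim12` (first two
#'   renormalised), `total_inertia`, `chi_square`, `dof`, `n`.
#' @export
ca_fit <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  if (n == 0) stop("empty table")
  chi <- chi_square(tab)
  P <- tab / n
  r <- rowSums(P); cs <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - outer(r, cs)) %*% diag(1 / sqrt(cs))
  sv <- svd(S)
  ndim <- min(nrow(tab), ncol(tab)) - 1
  sigma <- sv$d[seq_len(ndim)]
  sigma[sigma < 1e-12] <- 0
  U <- sv$u[, seq_len(ndim), drop = FALSE]
  V <- sv$v[, seq_len(ndim), drop = FALSE]
  # deterministic sign: largest-|u| entry positive
  for (d in seq_len(ndim)) {
    j <- which.max(abs(U[, d]))
    if (U[j, d] < 0) { U[, d] <- -U[, d]; V[, d] <- -V[, d] }
  }
  row_std <- diag(1 / sqrt(r)) %*% U
  col_std <- diag(1 / sqrt(cs)) %*% V
  row_pc <- row_std %*% diag(sigma, ndim)
  col_pc <- col_std %*% diag(sigma, ndim)
  dn <- paste0("Dim", seq_len(ndim))
  dimnames(row_pc) <- dimnames(row_std) <- list(rownames(tab), dn)
  dimnames(col_pc) <- dimnames(col_std) <- list(colnames(tab), dn)
  tot <- sum(sigma^2)
  fr <- if (tot > 0) sigma^2 / tot else rep(0, ndim)
  fr12 <- if (ndim >= 2 && sum(fr[1:2]) > 0) fr[1:2] / sum(fr[1:2]) else
    fr[seq_len(min(ndim, 2))]
  structure(list(row_coords = row_pc, col_coords = col_pc,
                 row_standard = row_std, col_standard = col_std,
                 singular_values = sigma, inertia_fractions = fr,
                 inertia_fractions_dim12 = fr12, total_inertia = tot,
                 chi_square = chi$statistic, dof = chi$dof, n = n),
            class = "ca_result")
}

#' Read a country-to-region mapping
#'
#' CSV with columns `country`, `region` (a UN-geoscheme-style lookup; the
#' package ships a small synthetic example under `extdata`).
#'
#' @param path CSV path.
#' @return named character vector: region per country.
#' @export
read_region_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("country", "region") %in% names(df)))
    stop("region map needs 'country' and 'region' columns")
  stats::setNames(df$region, df$country)
}

#' Map countries of birth to regions
#'
#' @param countries character vector of birth countries (NA allowed).
#' @param region_map named vector from [read_region_map()].
#' @return character vector of regions (NA where the country is missing or
#'   unmapped, with a warning for unmapped countries).
#' @export
map_countries_to_regions <- function(countries, region_map) {
  out <- unname(region_map[countries])
  unmapped <- unique(countries[!is.na(countries) & is.na(out)])
  if (length(unmapped))
    warning("unmapped countries: ", paste(utils::head(unmapped, 5),
                                          collapse = ", "))
  out
}
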