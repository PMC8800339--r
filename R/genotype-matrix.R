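#' Genotype matrix container
#'
#' A `genotype_matrix` holds biallelic SNP calls for a cohort as a samples x
#' variants integer matrix of alt-allele counts (0, 1, 2 or `NA` for
#' missing), together with per-sample and per-variant metadata. It is the
#' common currency of every stage in the package: simulation, IO, QC,
#' admixture, PCA and Fst all consume and produce it.
#'
#' @param calls integer matrix, samples x variants, values in
#'   \{0, 1, 2, NA\}. Row and column names, if absent, are taken from the
#'   metadata tables.
#' @param samples data.frame with at least column `id` (unique, non-empty);
#'   optional columns `population_label`, `birth_country`, `birth_region`
#'   (NA where unknown).
#' @param variants data.frame with columns `id` (unique, non-empty),
#'   `chrom`, `pos` (1-based), `ref`, `alt` (single bases, `ref != alt`).
#' @return an object of class `genotype_matrix`: a list with elements
#'   `calls`, `samples`, `variants`.
#' @export
genotype_matrix <- function(calls, samples, variants) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  if (!"id" %in% names(samples)) stop("samples table needs an 'id' column")
  for (col in c("population_label", "birth_country", "birth_region")) {
    if (!col %in% names(samples))
      samples[[col]] <- rep(NA_character_, nrow(samples))
  }
  need <- c("id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(variants))
  if (length(miss)) stop("variants table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(calls) != nrow(samples) || ncol(calls) != nrow(variants)) {
    stop("calls dimensions (", nrow(calls), " x ", ncol(calls),
         ") do not match metadata (", nrow(samples), " samples, ",
         nrow(variants), " variants)")
  }
  if (anyDuplicated(samples$id)) stop("duplicate sample ids")
  if (any(!nzchar(variants$id))) stop("empty variant id")
  if (any(variants$pos < 1)) stop("variant pos must be >= 1")
  if (any(variants$ref == variants$alt)) stop("ref allele equals alt allele")
  bad <- calls[!is.na(calls) & !(calls %in% 0:2)]
  if (length(bad)) stop("calls must be 0, 1, 2 or NA")
  rownames(calls) <- samples$id
  colnames(calls) <- variants$id
  structure(list(calls = calls, samples = samples, variants = variants),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$calls), "samples x", ncol(x$calls),
      "variants\n")
  n_ref <- sum(!is.na(x$samples$population_label))
  if (n_ref) cat("  reference-labelled samples:", n_ref, "\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing call rate: %.4f\n", miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix
#'
#' @param x a `genotype_matrix`.
#' @param sample_ids,variant_ids character vectors of ids to keep (order is
#'   respected); `NULL` keeps all.
#' @return a `genotype_matrix`.
#' @export
gm_subset <- function(x, sample_ids = NULL, variant_ids = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  si <- if (is.null(sample_ids)) seq_len(nrow(x$calls)) else
    match(sample_ids, x$samples$id)
  vi <- if (is.null(variant_ids)) seq_len(ncol(x$calls)) else
    match(variant_ids, x$variants$id)
  if (anyNA(si)) stop("unknown sample id(s): ",
                      paste(sample_ids[is.na(si)][1:min(3, sum(is.na(si)))],
                            collapse = ", "))
  if (anyNA(vi)) stop("unknown variant id(s)")
  genotype_matrix(x$calls[si, vi, drop = FALSE],
                  x$samples[si, , drop = FALSE],
                  x$variants[vi, , drop = FALSE])
}

#' Bind two cohorts that share an identical variant set
#'
#' Sample-wise concatenation; variants must agree in id, position and
#' alleles. Used after [merge_by_id()] has reconciled the variant sets.
#'
#' @param a,b `genotype_matrix` objects with identical variant tables.
#' @return a `genotype_matrix` containing the samples of `a` then `b`.
#' @export
gm_rbind <- function(a, b) {
  stopifnot(inherits(a, "genotype_matrix"), inherits(b, "genotype_matrix"))
  if (!identical(a$variants$id, b$variants$id))
    stop("variant sets differ; run merge_by_id() first")
  if (length(intersect(a$samples$id, b$samples$id)))
    stop("sample ids overlap between cohorts")
  genotype_matrix(rbind(a$calls, b$calls),
                  rbind(a$samples[names(a$samples)],
                        b$samples[names(a$samples)]),
                  a$variants)
}

# internal: order variants by (chrom, pos) and return the reordered cohort
gm_sort_variants <- function(x) {
  o <- order(x$variants$chrom, x$variants$pos)
  gm_subset(x, variant_ids = x$variants$id[o])
}
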