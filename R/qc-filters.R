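#' LD pruning parameters
#'
#' Defaults mirror the settings in common use for ancestry panels: a 50 kb window
#' advanced in 10 kb steps with an r-squared threshold of 0.025 (PLINK
#' dialect `--indep-pairwise 50 10 0.025`, read with kilobase window
#' semantics). `window_unit = "snp"` switches to SNP-count windows for
#' users who want PLINK's plain-number behaviour.
#'
#' @param window_kb,step_kb window width and step, kilobases (or SNP counts
#'   when `window_unit = "snp"`); `window_kb >= step_kb > 0`.
#' @param r2_threshold genotypic r-squared above which one of a pair is
#'   removed, in `[0, 1]`.
#' @param maf minor-allele-frequency floor applied before pruning (0
#'   disables).
#' @param exclude_regions data.frame (`chrom`, `start`, `end`; 1-based
#'   inclusive) of regions to drop before pruning, e.g. long-range LD
#'   regions; see [read_regions_bed()].
#' @param reference_sample_ids optional sample subset on which r-squared
#'   (and the removal tie-break MAF) is computed, e.g. an unrelated
#'   reference population; `NULL` uses all samples.
#' @param window_unit `"kb"` (default: kilobase window semantics) or
#'   `"snp"`.
#' @return a `prune_params` list.
#' @export
prune_params <- function(window_kb = 50, step_kb = 10, r2_threshold = 0.025,
                         maf = 0, exclude_regions = NULL,
                         reference_sample_ids = NULL,
                         window_unit = c("kb", "snp")) {
  window_unit <- match.arg(window_unit)
  stopifnot(window_kb >= step_kb, step_kb > 0,
            r2_threshold >= 0, r2_threshold <= 1, maf >= 0, maf <= 1)
  structure(list(window_kb = window_kb, step_kb = step_kb,
                 r2_threshold = r2_threshold, maf = maf,
                 exclude_regions = exclude_regions,
                 reference_sample_ids = reference_sample_ids,
                 window_unit = window_unit),
            class = "prune_params")
}

#' Per-variant alt-allele frequency and MAF
#'
#' Frequency is alt-allele count over `2 x` non-missing samples; variants
#' with zero non-missing calls get `NA`.
#'
#' @param x a `genotype_matrix`.
#' @param sample_ids optional subset of samples to count over.
#' @return data.frame: `id`, `f` (alt frequency), `maf`, `n_obs`
#'   (non-missing samples).
#' @export
allele_frequency <- function(x, sample_ids = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  g <- x$calls
  if (!is.null(sample_ids)) {
    i <- match(sample_ids, x$samples$id)
    if (anyNA(i)) stop("unknown sample id(s) in subset")
    g <- g[i, , drop = FALSE]
  }
  n_obs <- colSums(!is.na(g))
  f <- colSums(g, na.rm = TRUE) / (2 * n_obs)
  f[n_obs == 0] <- NA_real_
  data.frame(id = x$variants$id, f = unname(f),
             maf = unname(pmin(f, 1 - f)), n_obs = unname(n_obs),
             stringsAsFactors = FALSE)
}

#' Remove variants inside exclusion regions
#'
#' Regions are 1-based inclusive intervals; a variant is removed when its
#' chromosome matches and `start <= pos <= end`.
#'
#' @param x a `genotype_matrix`.
#' @param regions data.frame with `chrom`, `start`, `end`.
#' @return the filtered `genotype_matrix`.
#' @export
exclude_regions <- function(x, regions) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (is.null(regions) || nrow(regions) == 0) return(x)
  drop <- rep(FALSE, nrow(x$variants))
  for (r in seq_len(nrow(regions))) {
    drop <- drop | (x$variants$chrom == as.character(regions$chrom[r]) &
                    x$variants$pos >= regions$start[r] &
                    x$variants$pos <= regions$end[r])
  }
  gm_subset(x, variant_ids = x$variants$id[!drop])
}

#' Read exclusion regions from BED
#'
#' BED is 0-based half-open; intervals are converted to the package's
#' 1-based inclusive convention (`start + 1`, `end`).
#'
#' @param path BED path (first three columns used; comment/track lines
#'   skipped).
#' @return data.frame: `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_regions_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  if (!length(lines))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t| +")
  data.frame(chrom = vapply(f, `[[`, "", 1),
             start = as.integer(vapply(f, `[[`, "", 2)) + 1L,
             end = as.integer(vapply(f, `[[`, "", 3)),
             stringsAsFactors = FALSE)
}

#' Genotypic r-squared between two call vectors
#'
#' Squared Pearson correlation of alt-allele counts over pairwise-complete
#' samples (the composite/genotypic r-squared; phase is not used). Returns
#' 0 when either vector is constant on the complete pairs.
#'
#' @param g1,g2 integer vectors of calls (0/1/2/NA), equal length.
#' @return r-squared in `[0, 1]`.
#' @export
ld_r2 <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 2) stop("fewer than 2 pairwise-complete samples")
  a <- g1[ok]; b <- g2[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) return(0)
  stats::cor(a, b)^2
}

#' Greedy windowed LD pruning
#'
#' Variants must be sorted by (chrom, pos). Within each window (width
#' `window_kb`, advanced by `step_kb`), while any retained pair has
#' r-squared above the threshold the member with the lower MAF is removed
#' (tie: the larger position). r-squared and MAF are computed on
#' `reference_sample_ids` when given. After pruning, no retained pair
#' within a window exceeds the threshold on that subset.
#'
#' @param x a `genotype_matrix` with variants sorted by (chrom, pos).
#' @param params a [prune_params()].
#' @return character vector of retained variant ids (in input order).
#' @export
ld_prune <- function(x, params = prune_params()) {
  stopifnot(inherits(x, "genotype_matrix"), inherits(params, "prune_params"))
  v <- x$variants
  o <- order(v$chrom, v$pos)
  if (!identical(o, seq_len(nrow(v))))
    stop("variants must be sorted by (chrom, pos); see gm_sort_variants()")
  if (!is.null(params$exclude_regions))
    x <- exclude_regions(x, params$exclude_regions)
  ref_ids <- params$reference_sample_ids
  af <- allele_frequency(x, ref_ids)
  keep_maf <- !is.na(af$maf) & af$maf >= params$maf
  x <- gm_subset(x, variant_ids = x$variants$id[keep_maf])
  af <- af[keep_maf, ]
  g <- x$calls
  if (!is.null(ref_ids)) g <- g[match(ref_ids, x$samples$id), , drop = FALSE]
  v <- x$variants
  maf <- af$maf
  kept <- rep(TRUE, nrow(v))
  for (cc in unique(v$chrom)) {
    jc <- which(v$chrom == cc)
    pos <- v$pos[jc]
    if (params$window_unit == "kb") {
      w <- params$window_kb * 1000
      s <- params$step_kb * 1000
      # grid windows give the stepped greedy sweep; windows anchored at
      # each variant then guarantee the post-condition, since a stepped
      # grid alone can miss pairs separated by more than window - step
      starts <- seq(min(pos), max(pos), by = s)
      windows <- c(lapply(starts, function(st)
                     jc[pos >= st & pos <= st + w]),
                   lapply(pos, function(st)
                     jc[pos >= st & pos <= st + w]))
    } else {
      w <- round(params$window_kb); s <- round(params$step_kb)
      starts <- seq(1, length(jc), by = s)
      windows <- lapply(starts, function(st)
        jc[st:min(st + w - 1, length(jc))])
    }
    for (win in windows) {
      win <- win[kept[win]]
      if (length(win) < 2) next
      repeat {
        act <- win[kept[win]]
        if (length(act) < 2) break
        r2 <- suppressWarnings(stats::cor(g[, act, drop = FALSE],
                                          use = "pairwise.complete.obs")^2)
        r2[is.na(r2)] <- 0
        diag(r2) <- 0
        over <- which(r2 > params$r2_threshold, arr.ind = TRUE)
        if (!nrow(over)) break
        over <- over[over[, 1] < over[, 2], , drop = FALSE]
        i1 <- act[over[1, 1]]; i2 <- act[over[1, 2]]
        drop_j <- if (maf[i1] < maf[i2]) i1
          else if (maf[i2] < maf[i1]) i2
          else if (v$pos[i1] > v$pos[i2]) i1 else i2
        kept[drop_j] <- FALSE
      }
    }
  }
  v$id[kept]
}

#' Write a kept-variant list (PLINK extract-file dialect)
#'
#' @param ids character vector of variant ids.
#' @param path output path; one id per line.
#' @export
write_keep_list <- function(ids, path) {
  writeLines(ids, path)
  invisible(path)
}
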