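#' Read genotypes from VCF, PED/MAP or BED/BIM/FAM
#'
#' Dispatches on `format`. The VCF path handles the GT-only subset of
#' VCF 4.x: diploid GT fields (phased or unphased, treated identically) are
#' mapped to alt-allele counts; `./.` and half-calls become missing (half
#' calls with a warning); multi-allelic records are dropped with a warning.
#' PLINK binary BED is read-only ([write_genotypes()] targets VCF and text
#' PED/MAP).
#'
#' @param path file path. For `"ped"` give the `.ped` file (the `.map` is
#'   found alongside); for `"bed"` give the `.bed` (with `.bim`/`.fam`
#'   alongside).
#' @param format one of `"vcf"`, `"ped"`, `"bed"`.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("vcf", "ped", "bed"), ...) {
  format <- match.arg(format)
  switch(format,
         vcf = read_vcf(path),
         ped = read_ped(path, ...),
         bed = read_bed(path))
}

#' Write genotypes to VCF or PED/MAP
#'
#' Inverse of [read_genotypes()] on the supported subset: alt-allele counts
#' become unphased GT (`0/0`, `0/1`, `1/1`, `./.`) or PED allele pairs
#' (missing as `0 0`).
#'
#' @param x a `genotype_matrix`.
#' @param path output path (for `"ped"`, the `.ped` path; a `.map` is
#'   written alongside).
#' @param format `"vcf"` or `"ped"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(x, path, format = c("vcf", "ped")) {
  format <- match.arg(format)
  switch(format, vcf = write_vcf(x, path), ped = write_ped(x, path))
  invisible(path)
}

read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  body_at <- which(!startsWith(lines, "##"))
  if (!length(body_at) || !startsWith(lines[body_at[1]], "#CHROM"))
    stop("not a VCF: missing #CHROM header line in ", path)
  hdr <- strsplit(lines[body_at[1]], "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 10) stop("VCF has no sample columns: ", path)
  sample_ids <- hdr[-(1:9)]
  data_lines <- lines[body_at[-1]]
  data_lines <- data_lines[nzchar(data_lines)]
  n_var <- length(data_lines)
  n_smp <- length(sample_ids)
  calls <- matrix(NA_integer_, n_smp, n_var)
  vid <- character(n_var); chrom <- character(n_var)
  pos <- integer(n_var); ref <- character(n_var); alt <- character(n_var)
  keep <- rep(TRUE, n_var)
  n_multi <- 0L; n_half <- 0L
  gt_map <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
              "0|0" = 0L, "0|1" = 1L, "1|0" = 1L, "1|1" = 2L,
              "./." = NA_integer_, ".|." = NA_integer_, "." = NA_integer_)
  for (i in seq_len(n_var)) {
    f <- strsplit(data_lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(hdr))
      stop("malformed VCF record at data line ", i, " of ", path,
           " (", length(f), " fields, expected ", length(hdr), ")")
    if (grepl(",", f[5], fixed = TRUE)) {           # multi-allelic: flag+drop
      n_multi <- n_multi + 1L; keep[i] <- FALSE; next
    }
    chrom[i] <- f[1]; pos[i] <- as.integer(f[2]); vid[i] <- f[3]
    ref[i] <- f[4]; alt[i] <- f[5]
    gt <- sub(":.*$", "", f[-(1:9)])
    g <- gt_map[gt]
    unknown <- is.na(g) & !(gt %in% c("./.", ".|.", "."))
    if (any(unknown)) {
      u <- gt[unknown][1]
      if (grepl("^[0-9.]([/|][0-9.])?$", u) && grepl("\\.", u)) {
        n_half <- n_half + sum(unknown)             # half-calls -> missing
      } else if (!grepl("[/|]", u)) {
        stop("non-diploid GT '", u, "' at data line ", i, " of ", path)
      } else {
        stop("unparseable GT '", u, "' at data line ", i, " of ", path)
      }
    }
    calls[, i] <- unname(g)
  }
  if (n_multi) warning(n_multi, " multi-allelic record(s) dropped")
  if (n_half) warning(n_half, " half-call(s) set to missing")
  calls <- calls[, keep, drop = FALSE]
  variants <- data.frame(id = vid[keep], chrom = chrom[keep],
                         pos = pos[keep], ref = ref[keep], alt = alt[keep],
                         stringsAsFactors = FALSE)
  samples <- data.frame(id = sample_ids, stringsAsFactors = FALSE)
  genotype_matrix(calls, samples, variants)
}

write_vcf <- function(x, path) {
  stopifnot(inherits(x, "genotype_matrix"))
  gt_str <- c("0/0", "0/1", "1/1")
  g <- x$calls                                       # samples x variants
  txt <- matrix("./.", nrow(g), ncol(g))
  ok <- !is.na(g)
  txt[ok] <- gt_str[g[ok] + 1L]
  v <- x$variants
  rows <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", ".", ".", "GT",
                sep = "\t")
  if (nrow(g) > 0 && ncol(g) > 0) {
    body <- apply(txt, 2, paste, collapse = "\t")
    rows <- paste(rows, body, sep = "\t")
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", x$samples$id), collapse = "\t"))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

# PED carries no ref/alt orientation; by default alt = minor allele (ties
# broken alphabetically). Pass alt_alleles (named by variant id) to pin the
# orientation, e.g. for an exact round-trip of a cohort written by write_ped.
read_ped <- function(path, alt_alleles = NULL) {
  map_path <- sub("\\.ped$", ".map", path)
  if (identical(map_path, path)) map_path <- paste0(path, ".map")
  if (!file.exists(path)) stop("no such file: ", path)
  if (!file.exists(map_path)) stop("no .map alongside ", path)
  map <- utils::read.table(map_path, stringsAsFactors = FALSE)
  if (ncol(map) != 4) stop("malformed .map: expected 4 columns")
  names(map) <- c("chrom", "id", "cm", "pos")
  ped <- utils::read.table(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  n_var <- nrow(map)
  if (ncol(ped) != 6 + 2 * n_var)
    stop("malformed .ped: expected ", 6 + 2 * n_var, " columns, got ",
         ncol(ped))
  a1 <- as.matrix(ped[, 6 + 2 * seq_len(n_var) - 1, drop = FALSE])
  a2 <- as.matrix(ped[, 6 + 2 * seq_len(n_var), drop = FALSE])
  # allele coding: first-seen non-zero allele pair per variant defines
  # ref/alt from the accompanying .ref file if present, else ref = major
  ref <- character(n_var); alt <- character(n_var)
  calls <- matrix(NA_integer_, nrow(ped), n_var)
  for (j in seq_len(n_var)) {
    al <- c(a1[, j], a2[, j])
    obs <- setdiff(unique(al), "0")
    if (length(obs) > 2) stop("more than 2 alleles at variant ", map$id[j])
    counts <- table(factor(al[al != "0"], levels = obs))
    pinned <- if (!is.null(alt_alleles)) alt_alleles[map$id[j]] else NA
    if (!is.na(pinned)) {
      alt[j] <- pinned
      obs_ref <- setdiff(obs, pinned)
      ref[j] <- if (length(obs_ref)) obs_ref[1] else
        setdiff(c("A", "C", "G", "T", "B"), pinned)[1]
    } else if (length(obs) == 0) { ref[j] <- "A"; alt[j] <- "B" }
    else if (length(obs) == 1) {
      ref[j] <- obs
      alt[j] <- setdiff(c("A", "C", "G", "T", "B"), obs)[1]
    } else {
      o <- order(-as.integer(counts), names(counts))   # major first, tie: abc
      ref[j] <- names(counts)[o[1]]; alt[j] <- names(counts)[o[2]]
    }
    miss <- a1[, j] == "0" | a2[, j] == "0"
    cnt <- (a1[, j] == alt[j]) + (a2[, j] == alt[j])
    cnt[miss] <- NA_integer_
    calls[, j] <- cnt
  }
  samples <- data.frame(id = ped[, 2], stringsAsFactors = FALSE)
  variants <- data.frame(id = map$id, chrom = as.character(map$chrom),
                         pos = as.integer(map$pos), ref = ref, alt = alt,
                         stringsAsFactors = FALSE)
  genotype_matrix(calls, samples, variants)
}

write_ped <- function(x, path) {
  stopifnot(inherits(x, "genotype_matrix"))
  map_path <- sub("\\.ped$", ".map", path)
  if (identical(map_path, path)) map_path <- paste0(path, ".map")
  v <- x$variants
  utils::write.table(data.frame(v$chrom, v$id, 0, v$pos),
                     map_path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  g <- x$calls
  n <- nrow(g); m <- ncol(g)
  out <- character(n)
  for (i in seq_len(n)) {
    gi <- g[i, ]
    a1 <- ifelse(is.na(gi), "0", ifelse(gi >= 1, v$alt, v$ref))
    a2 <- ifelse(is.na(gi), "0", ifelse(gi == 2, v$alt, v$ref))
    al <- character(2 * m)
    al[c(TRUE, FALSE)] <- a1; al[c(FALSE, TRUE)] <- a2
    out[i] <- paste(c(x$samples$id[i], x$samples$id[i], "0", "0", "0", "-9",
                      al), collapse = " ")
  }
  writeLines(out, path)
  invisible(path)
}

# PLINK binary BED (SNP-major), read-only. Alt allele = A1 (.bim column 5),
# matching PLINK's convention that 0b00 codes the A1/A1 homozygote.
read_bed <- function(path) {
  bim_path <- sub("\\.bed$", ".bim", path)
  fam_path <- sub("\\.bed$", ".fam", path)
  if (!file.exists(path)) stop("no such file: ", path)
  if (!file.exists(bim_path) || !file.exists(fam_path))
    stop(".bim/.fam not found alongside ", path)
  bim <- utils::read.table(bim_path, stringsAsFactors = FALSE)
  names(bim) <- c("chrom", "id", "cm", "pos", "a1", "a2")
  fam <- utils::read.table(fam_path, stringsAsFactors = FALSE,
                           colClasses = "character")
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK BED file: ", path)
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major BED files are supported")
  bpv <- ceiling(n / 4)                              # bytes per variant
  if (length(raw) != 3 + bpv * m)
    stop("BED size inconsistent with .bim/.fam dimensions")
  # decode 2-bit codes: 00 hom A1 -> 2, 10 het -> 1, 11 hom A2 -> 0, 01 -> NA
  code_map <- c(`0` = 2L, `1` = NA_integer_, `2` = 1L, `3` = 0L)
  calls <- matrix(NA_integer_, n, m)
  body <- as.integer(raw[-(1:3)])
  shifts <- c(1L, 4L, 16L, 64L)
  for (j in seq_len(m)) {
    bytes <- body[(j - 1) * bpv + seq_len(bpv)]
    codes <- integer(4 * bpv)
    for (s in 1:4) codes[seq(s, by = 4, length.out = bpv)] <-
        (bytes %/% shifts[s]) %% 4L
    calls[, j] <- code_map[as.character(codes[seq_len(n)])]
  }
  samples <- data.frame(id = fam[, 2], stringsAsFactors = FALSE)
  variants <- data.frame(id = bim$id, chrom = as.character(bim$chrom),
                         pos = as.integer(bim$pos), ref = bim$a2,
                         alt = bim$a1, stringsAsFactors = FALSE)
  genotype_matrix(calls, samples, variants)
}

#' Merge two cohorts on shared variant identifiers
#'
#' Variant matching is by id only (never by position). Ids duplicated
#' within either input are dropped, as are shared ids whose allele pairs
#' cannot be reconciled. When ref/alt are exactly swapped between inputs,
#' the second cohort's calls at that variant are recoded `0 <-> 2`.
#' Strand-ambiguous SNPs (A/T, C/G) are kept when the alleles match
#' literally, with a warning. Sample sets must be disjoint.
#'
#' @param a,b `genotype_matrix` cohorts.
#' @return a list with `merged` (a `genotype_matrix`, variants ordered by
#'   chrom/pos as in `a`) and `report` (counts: `n_shared`, `n_dup_a`,
#'   `n_dup_b`, `n_swapped`, `n_mismatch`, `n_kept`).
#' @export
merge_by_id <- function(a, b) {
  stopifnot(inherits(a, "genotype_matrix"), inherits(b, "genotype_matrix"))
  dup_a <- unique(a$variants$id[duplicated(a$variants$id)])
  dup_b <- unique(b$variants$id[duplicated(b$variants$id)])
  ids_a <- setdiff(a$variants$id, dup_a)
  ids_b <- setdiff(b$variants$id, dup_b)
  shared <- intersect(ids_a, ids_b)
  if (!length(shared)) stop("zero overlapping variant ids")
  va <- a$variants[match(shared, a$variants$id), ]
  vb <- b$variants[match(shared, b$variants$id), ]
  same <- va$ref == vb$ref & va$alt == vb$alt
  swap <- va$ref == vb$alt & va$alt == vb$ref & !same
  keep <- same | swap
  ambig <- same & ((va$ref == "A" & va$alt == "T") |
                   (va$ref == "T" & va$alt == "A") |
                   (va$ref == "C" & va$alt == "G") |
                   (va$ref == "G" & va$alt == "C"))
  if (any(ambig))
    warning(sum(ambig), " strand-ambiguous SNP(s) kept on literal match")
  kept_ids <- shared[keep]
  sa <- gm_subset(a, variant_ids = kept_ids)
  sb <- gm_subset(b, variant_ids = kept_ids)
  swap_ids <- shared[swap]
  if (length(swap_ids)) {
    j <- match(swap_ids, sb$variants$id)
    sb$calls[, j] <- 2L - sb$calls[, j]
    sb$variants$ref[j] <- sa$variants$ref[j]
    sb$variants$alt[j] <- sa$variants$alt[j]
  }
  merged <- gm_sort_variants(gm_rbind(sa, sb))
  report <- list(n_shared = length(shared),
                 n_dup_a = length(dup_a), n_dup_b = length(dup_b),
                 n_swapped = sum(swap), n_mismatch = sum(!keep),
                 n_kept = length(kept_ids))
  list(merged = merged, report = report)
}

#' Read or write a sample-metadata table
#'
#' Tab-separated with columns `id`, `population_label`, `birth_country`,
#' `birth_region`; empty fields are missing.
#'
#' @param path TSV path.
#' @return `read_sample_metadata`: a data.frame.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if (!"id" %in% names(df)) stop("metadata needs an 'id' column")
  df
}

#' @rdname read_sample_metadata
#' @param df data.frame with an `id` column.
#' @export
write_sample_metadata <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Attach sample metadata to a cohort
#'
#' @param x a `genotype_matrix`.
#' @param meta data.frame with `id` plus any of `population_label`,
#'   `birth_country`, `birth_region`; rows are matched by id, samples
#'   absent from `meta` keep their current values.
#' @return the updated `genotype_matrix`.
#' @export
attach_metadata <- function(x, meta) {
  stopifnot(inherits(x, "genotype_matrix"))
  i <- match(x$samples$id, meta$id)
  for (col in intersect(c("population_label", "birth_country",
                          "birth_region"), names(meta))) {
    hit <- !is.na(i)
    x$samples[[col]][hit] <- meta[[col]][i[hit]]
  }
  x
}
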