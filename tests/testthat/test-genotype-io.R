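vcf_lines <- c(
  "##fileformat=VCFv4.2",
  "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
  paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
        "FORMAT", "S1", "S2", "S3", sep = "\t"),
  paste("1", "100", "rs1", "A", "G", ".", ".", ".", "GT",
        "0/1", "1|1", "./.", sep = "\t"),
  paste("2", "200", "rs2", "C", "T", ".", ".", ".", "GT",
        "0/0", "1/0", "0|1", sep = "\t"))

test_that("VCF read: hand-transcribed 3x2 matrix, GT conventions", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf_lines, f)
  gm <- read_genotypes(f, "vcf")
  # transcribed by hand: 0/1->1, 1|1->2, ./.->NA; 0/0->0, 1/0->1, 0|1->1
  expect_equal(unname(gm$calls),
               matrix(c(1L, 2L, NA, 0L, 1L, 1L), nrow = 3))
  expect_equal(gm$samples$id, c("S1", "S2", "S3"))
  expect_equal(gm$variants$pos, c(100L, 200L))
  expect_equal(gm$variants$ref, c("A", "C"))
})

test_that("VCF read: multi-allelic dropped, half-call missing, malformed errors", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(vcf_lines,
               paste("3", "300", "rs3", "A", "G,T", ".", ".", ".", "GT",
                     "0/1", "0/0", "0/0", sep = "\t")), f)
  expect_warning(gm <- read_genotypes(f, "vcf"), "multi-allelic")
  expect_equal(ncol(gm$calls), 2)

  writeLines(c(vcf_lines[1:4],
               paste("2", "200", "rs2", "C", "T", ".", ".", ".", "GT",
                     "./1", "0/0", "0/0", sep = "\t")), f)
  expect_warning(gm <- read_genotypes(f, "vcf"), "half-call")
  expect_true(is.na(gm$calls["S1", "rs2"]))

  writeLines(c(vcf_lines, "1\t5\tbroken"), f)
  expect_error(read_genotypes(f, "vcf"), "malformed VCF record")

  writeLines(c(vcf_lines[1:4],
               paste("2", "200", "rs2", "C", "T", ".", ".", ".", "GT",
                     "0/1/1", "0/0", "0/0", sep = "\t")), f)
  expect_error(read_genotypes(f, "vcf"), "GT")
})

test_that("VCF and PED round-trips preserve the cohort", {
  spec <- flat_spec(K = 2, F = 0.1, n = 8, n_snps = 40, seed = 31)
  gm <- simulate_cohort(spec)$genotypes
  gm$calls[2, 5] <- NA                               # planted missing call
  f <- withr::local_tempfile(fileext = ".vcf")
  write_genotypes(gm, f, "vcf")
  back <- read_genotypes(f, "vcf")
  expect_identical(back$calls, gm$calls)
  expect_identical(back$variants[c("id", "chrom", "pos", "ref", "alt")],
                   gm$variants[c("id", "chrom", "pos", "ref", "alt")])

  p <- withr::local_tempfile(fileext = ".ped")
  write_genotypes(gm, p, "ped")
  alt <- setNames(gm$variants$alt, gm$variants$id)
  back2 <- read_genotypes(p, "ped", alt_alleles = alt)
  expect_identical(back2$calls, gm$calls)
  expect_equal(back2$variants$pos, gm$variants$pos)
})

test_that("missing calls serialize as ./. and 0 0; empty cohort writes a header", {
  gm <- gm_from_calls(matrix(c(NA, 1L), 1, 2))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_genotypes(gm, f, "vcf")
  expect_match(grep("^1\t1000", readLines(f), value = TRUE), "\\./\\.")
  p <- withr::local_tempfile(fileext = ".ped")
  write_genotypes(gm, p, "ped")
  expect_match(readLines(p), " 0 0 ")

  empty <- genotype_matrix(matrix(integer(), 0, 0),
                           data.frame(id = character()),
                           data.frame(id = character(), chrom = character(),
                                      pos = integer(), ref = character(),
                                      alt = character()))
  write_genotypes(empty, f, "vcf")
  expect_true(any(startsWith(readLines(f), "#CHROM")))
})

test_that("PLINK BED decodes against a hand-packed fixture", {
  # 3 samples x 2 variants, SNP-major. Codes per variant (sample order):
  # v1: hom-A1 (00), het (10), hom-A2 (11) -> byte 0b00110100? packed
  # little-endian 2-bit pairs: sample1 bits 0-1, sample2 bits 2-3, ...
  b1 <- as.raw(0x00 + 0x02 * 4 + 0x03 * 16)          # 00, 10, 11
  b2 <- as.raw(0x01 + 0x00 * 4 + 0x02 * 16)          # 01(miss), 00, 10
  dir <- withr::local_tempdir()
  bed <- file.path(dir, "toy.bed")
  writeBin(c(as.raw(c(0x6c, 0x1b, 0x01)), b1, b2), bed)
  writeLines(c("1\trs1\t0\t100\tA\tG", "1\trs2\t0\t200\tC\tT"),
             file.path(dir, "toy.bim"))
  writeLines(c("F1 I1 0 0 0 -9", "F2 I2 0 0 0 -9", "F3 I3 0 0 0 -9"),
             file.path(dir, "toy.fam"))
  gm <- read_genotypes(bed, "bed")
  # alt = A1: 00 -> 2, 10 -> 1, 11 -> 0, 01 -> NA
  expect_equal(unname(gm$calls), matrix(c(2L, 1L, 0L, NA, 2L, 1L), 3))
  expect_equal(gm$variants$alt, c("A", "C"))
})

test_that("merge_by_id: duplicates, mismatches, swaps, symmetry", {
  ca <- matrix(c(0L, 1L, 2L, 1L, 0L, 2L, 1L, 1L, 0L, 2L, 1L, 0L), 2, 6)
  a <- genotype_matrix(ca, data.frame(id = c("A1", "A2")),
                       data.frame(id = c("r1", "r2", "r3", "r4", "r5", "r4"),
                                  chrom = "1", pos = c(1:6) * 100L,
                                  ref = c("A", "A", "C", "G", "T", "G"),
                                  alt = c("G", "C", "T", "A", "C", "A")))
  cb <- matrix(c(2L, 0L, 1L, 1L, 0L, 0L, 2L, 2L, 1L, 2L), 2, 5)
  b <- genotype_matrix(cb, data.frame(id = c("B1", "B2")),
                       data.frame(id = c("r1", "r2", "r3", "r5", "r9"),
                                  chrom = "1", pos = c(1:5) * 100L,
                                  ref = c("A", "A", "C", "C", "A"),
                                  alt = c("G", "G", "T", "T", "G")))
  # shared ids r1..r5 minus duplicate r4 in a -> 4 shared; r2 alleles A/C
  # vs A/G are irreconcilable -> dropped; r5 T/C vs C/T is a swap
  res <- merge_by_id(a, b)
  expect_equal(res$report$n_dup_a, 1)
  expect_equal(res$report$n_mismatch, 1)
  expect_equal(res$report$n_swapped, 1)
  expect_setequal(res$merged$variants$id, c("r1", "r3", "r5"))
  # swap recodes b 0<->2 so allele frequencies line up
  i5 <- match("r5", res$merged$variants$id)
  expect_equal(unname(res$merged$calls[c("B1", "B2"), i5]),
               2L - cb[, 4])
  # symmetric variant membership
  res2 <- merge_by_id(b, a)
  expect_setequal(res2$merged$variants$id, res$merged$variants$id)

  # identical inputs (disjoint samples): all kept, all-zero removals
  a2 <- a; a2$samples$id <- c("X1", "X2"); rownames(a2$calls) <- a2$samples$id
  a_nodup <- gm_subset(a, variant_ids = c("r1", "r2", "r3", "r5"))
  a2_nodup <- gm_subset(a2, variant_ids = c("r1", "r2", "r3", "r5"))
  res3 <- merge_by_id(a_nodup, a2_nodup)
  expect_equal(res3$report$n_mismatch, 0)
  expect_equal(res3$report$n_kept, 4)
  expect_identical(res3$merged$calls[c("A1", "A2"), ],
                   a_nodup$calls[c("A1", "A2"), ])
})

test_that("merge errors on zero overlap; strand-ambiguous kept with warning", {
  a <- gm_from_calls(matrix(0:1, 2, 1))
  b <- gm_from_calls(matrix(1:2, 2, 1))
  b$variants$id <- "other"
  b$samples$id <- c("T1", "T2"); rownames(b$calls) <- b$samples$id
  expect_error(merge_by_id(a, b), "zero overlapping")

  at <- gm_from_calls(matrix(0:1, 2, 1)); at$variants$ref <- "A"
  at$variants$alt <- "T"
  bt <- at; bt$samples$id <- c("T1", "T2"); rownames(bt$calls) <- bt$samples$id
  expect_warning(merge_by_id(at, bt), "strand-ambiguous")
})

test_that("sample metadata round-trips and attaches", {
  df <- data.frame(id = c("S001", "S002"),
                   population_label = c("YRI", NA),
                   birth_country = c(NA, "Spain"),
                   birth_region = c(NA, "Southern Europe"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_sample_metadata(df, f)
  back <- read_sample_metadata(f)
  expect_equal(back$birth_country, df$birth_country)
  gm <- gm_from_calls(matrix(0L, 2, 2))
  gm$samples$id <- c("S001", "S002"); rownames(gm$calls) <- gm$samples$id
  gm2 <- attach_metadata(gm, back)
  expect_equal(gm2$samples$population_label, c("YRI", NA))
  expect_equal(gm2$samples$birth_country, c(NA, "Spain"))
})
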