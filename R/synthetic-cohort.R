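#' Specify a structured synthetic cohort
#'
#' Describes a hierarchical Balding-Nichols world: a global ancestral
#' allele-frequency vector, continental groups diverged from it by drift
#' parameter `F_c`, and subpopulations diverged from their continent by
#' `F_s`. Expected pairwise Hudson Fst between two populations diverged by
#' `F1` and `F2` from a common ancestor is `(F1 + F2)/2` (and for two
#' subpopulations of different continents with continental divergence `F_c`,
#' approximately `F_c + (F_s1 + F_s2)(1 - F_c)/2`), which is the truth the
#' downstream estimators are tested against.
#'
#' @param continents list; each element a list with `name`, `F` (divergence
#'   from the global ancestor, in `[0, 1)`), and `subpops`: a list of lists
#'   with `name`, `F` (divergence from the continent), `n` (sample count),
#'   `region` (birth-region label), `countries` (named numeric vector of
#'   birth-country mixing weights), and optional `reference = TRUE` to mark
#'   the subpopulation as that continent's reference panel (its samples get
#'   `population_label = <continent name>`).
#' @param n_snps number of independent SNPs.
#' @param maf_range ancestral allele frequencies are drawn Uniform over this
#'   interval (both ends in `(0, 0.5]` by convention, a point mass when
#'   equal).
#' @param admixed_blocks list of lists with `n` and `alpha` (Dirichlet
#'   concentration vector over continents, all `> 0`); these samples draw
#'   each allele copy from continent k with probability `q_k`.
#' @param relative_pairs number of parent-offspring trios to append (one
#'   offspring per trio; see [add_relatives()]).
#' @param label_concordance probability in `[0, 1]` that a sample's recorded
#'   birth region/country matches its true subpopulation's.
#' @param missing_label_fraction fraction of samples whose birth labels are
#'   set missing.
#' @param ld_tag_fraction,ld_flip_prob optional LD-block mode: this fraction
#'   of SNPs is duplicated 500 bp away with per-allele-copy flip probability
#'   `ld_flip_prob`, giving the LD pruner correlated pairs to remove.
#'   Default off (independent SNPs).
#' @param n_chrom,spacing_bp variants are laid out round-robin over
#'   `n_chrom` chromosomes at `spacing_bp` intervals.
#' @param seed integer seed; all randomness flows from one generator stream.
#' @return a `population_spec` list, validated.
#' @export
population_spec <- function(continents, n_snps = 5000,
                            maf_range = c(0.05, 0.5),
                            admixed_blocks = list(), relative_pairs = 0,
                            label_concordance = 1,
                            missing_label_fraction = 0,
                            ld_tag_fraction = 0, ld_flip_prob = 0.05,
                            n_chrom = 22, spacing_bp = 3000, seed = 1) {
  stopifnot(is.list(continents), length(continents) >= 1)
  for (co in continents) {
    stopifnot(is.character(co$name), co$F >= 0, co$F < 1,
              is.list(co$subpops), length(co$subpops) >= 1)
    for (sp in co$subpops) {
      stopifnot(is.character(sp$name), sp$F >= 0, sp$F < 1, sp$n >= 0)
      if (!is.null(sp$countries)) stopifnot(all(sp$countries > 0))
    }
  }
  stopifnot(n_snps >= 1, length(maf_range) == 2,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            label_concordance >= 0, label_concordance <= 1,
            missing_label_fraction >= 0, missing_label_fraction <= 1,
            relative_pairs >= 0, ld_tag_fraction >= 0, ld_tag_fraction <= 1,
            ld_flip_prob >= 0, ld_flip_prob <= 1)
  K <- length(continents)
  for (blk in admixed_blocks)
    stopifnot(blk$n >= 0, length(blk$alpha) == K, all(blk$alpha > 0))
  structure(list(continents = continents, n_snps = as.integer(n_snps),
                 maf_range = maf_range, admixed_blocks = admixed_blocks,
                 relative_pairs = as.integer(relative_pairs),
                 label_concordance = label_concordance,
                 missing_label_fraction = missing_label_fraction,
                 ld_tag_fraction = ld_tag_fraction,
                 ld_flip_prob = ld_flip_prob,
                 n_chrom = as.integer(n_chrom),
                 spacing_bp = as.integer(spacing_bp),
                 seed = as.integer(seed)),
            class = "population_spec")
}

# Beta draw around p with drift F: Beta(p(1-F)/F, (1-p)(1-F)/F).
# F = 0 is the degenerate copy. Frequencies clamped to [1e-6, 1 - 1e-6].
bn_draw <- function(p, F) {
  if (F == 0) return(p)
  out <- stats::rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
  pmin(pmax(out, 1e-6), 1 - 1e-6)
}

#' Draw hierarchical Balding-Nichols allele frequencies
#'
#' Ancestral frequencies are Uniform over `maf_range`; each continent's
#' frequencies are Beta-distributed around the ancestral value with its
#' `F_c`; each subpopulation's around its continent's with its `F_s`.
#'
#' @param spec a [population_spec()]. Uses the spec's seed unless the
#'   caller has already seeded the stream (`use_seed = FALSE` inside
#'   [simulate_cohort()]).
#' @param use_seed set the RNG from `spec$seed` first (default `TRUE`).
#' @return list with `ancestral` (length-M vector), `continent` (K x M
#'   matrix, rownames = continent names), `subpop` (S x M matrix, rownames =
#'   subpopulation names), and `subpop_continent` (named character map).
#' @export
draw_hierarchical_frequencies <- function(spec, use_seed = TRUE) {
  stopifnot(inherits(spec, "population_spec"))
  if (use_seed) set.seed(spec$seed)
  M <- spec$n_snps
  p0 <- stats::runif(M, spec$maf_range[1], spec$maf_range[2])
  cn <- vapply(spec$continents, `[[`, "", "name")
  cont <- matrix(NA_real_, length(cn), M, dimnames = list(cn, NULL))
  sub <- NULL; sub_names <- character(); sub_cont <- character()
  for (co in spec$continents) {
    pc <- bn_draw(p0, co$F)
    cont[co$name, ] <- pc
    for (sp in co$subpops) {
      sub <- rbind(sub, bn_draw(pc, sp$F))
      sub_names <- c(sub_names, sp$name)
      sub_cont <- c(sub_cont, co$name)
    }
  }
  rownames(sub) <- sub_names
  names(sub_cont) <- sub_names
  list(ancestral = p0, continent = cont, subpop = sub,
       subpop_continent = sub_cont)
}

#' Simulate genotypes for a specified cohort
#'
#' Unadmixed samples in subpopulation s draw `g ~ Binomial(2, p_sj)`.
#' Admixed samples draw, per allele copy and SNP, a continent with
#' probability `q_k` and then a Bernoulli allele at that continent's
#' frequency. Truth tables (per-sample continental proportions `q`,
#' subpopulation, region/country of the subpopulation) are attached.
#'
#' @param freqs output of [draw_hierarchical_frequencies()].
#' @param spec the matching [population_spec()].
#' @return a `simulated_cohort`: list with `genotypes` (a
#'   [genotype_matrix()]), `truth` (data.frame: `sample_id`, `subpop`,
#'   `continent`, `region`, `country`, and `q.<continent>` columns),
#'   `truth_relative_pairs` (empty here; see [add_relatives()]), `freqs`
#'   and `spec`.
#' @export
simulate_genotypes <- function(freqs, spec) {
  stopifnot(inherits(spec, "population_spec"))
  K <- length(spec$continents)
  cn <- rownames(freqs$continent)
  M0 <- spec$n_snps
  rows <- list(); truth <- list(); idx <- 0L
  add_block <- function(g, subpop, continent, region, country, q,
                        poplab) {
    idx <<- idx + 1L
    rows[[idx]] <<- list(g = g, poplab = poplab)
    truth[[idx]] <<- data.frame(subpop = subpop, continent = continent,
                                region = region, country = country,
                                stringsAsFactors = FALSE)
    truth[[idx]] <<- cbind(truth[[idx]],
                           as.data.frame(q, col.names = paste0("q.", cn)))
  }
  for (co in spec$continents) {
    for (sp in co$subpops) {
      if (sp$n == 0) next
      p <- freqs$subpop[sp$name, ]
      g <- matrix(stats::rbinom(sp$n * M0, 2L, rep(p, each = sp$n)),
                  nrow = sp$n)
      q <- matrix(0, sp$n, K, dimnames = list(NULL, paste0("q.", cn)))
      q[, paste0("q.", co$name)] <- 1
      ctries <- if (is.null(sp$countries))
        stats::setNames(1, paste0(sp$name, "_country")) else sp$countries
      country <- sample(names(ctries), sp$n, replace = TRUE,
                        prob = ctries / sum(ctries))
      region <- if (is.null(sp$region)) paste0(co$name, "_region") else
        sp$region
      poplab <- if (isTRUE(sp$reference)) co$name else NA_character_
      add_block(g, sp$name, co$name, region, country, q, poplab)
    }
  }
  for (bi in seq_along(spec$admixed_blocks)) {
    blk <- spec$admixed_blocks[[bi]]
    if (blk$n == 0) next
    gam <- matrix(stats::rgamma(blk$n * K, shape = rep(blk$alpha,
                                                       each = blk$n)),
                  nrow = blk$n)
    qm <- gam / rowSums(gam)
    g <- matrix(NA_integer_, blk$n, M0)
    for (i in seq_len(blk$n)) {
      c1 <- sample.int(K, M0, replace = TRUE, prob = qm[i, ])
      c2 <- sample.int(K, M0, replace = TRUE, prob = qm[i, ])
      a1 <- stats::rbinom(M0, 1L, freqs$continent[cbind(c1, seq_len(M0))])
      a2 <- stats::rbinom(M0, 1L, freqs$continent[cbind(c2, seq_len(M0))])
      g[i, ] <- a1 + a2
    }
    colnames(qm) <- paste0("q.", cn)
    add_block(g, paste0("ADMIX", bi), NA_character_, NA_character_,
              NA_character_, qm, NA_character_)
  }
  g_all <- do.call(rbind, lapply(rows, `[[`, "g"))
  truth_df <- do.call(rbind, truth)
  n <- nrow(g_all)
  ids <- sprintf("S%05d", seq_len(n))
  truth_df <- cbind(data.frame(sample_id = ids, stringsAsFactors = FALSE),
                    truth_df)
  # variant layout: round-robin chromosomes, fixed spacing
  variants <- synth_variant_table(M0, spec)
  samples <- data.frame(
    id = ids,
    population_label = unlist(lapply(seq_along(rows), function(i)
      rep(rows[[i]]$poplab, nrow(truth[[i]])))),
    birth_country = NA_character_, birth_region = NA_character_,
    stringsAsFactors = FALSE)
  gm <- genotype_matrix(g_all, samples, variants)
  cohort <- structure(list(genotypes = gm, truth = truth_df,
                           truth_relative_pairs =
                             data.frame(id1 = character(),
                                        id2 = character(),
                                        stringsAsFactors = FALSE),
                           freqs = freqs, spec = spec),
                      class = "simulated_cohort")
  if (spec$ld_tag_fraction > 0) cohort <- add_ld_duplicates(cohort)
  cohort
}

synth_variant_table <- function(M, spec) {
  chrom <- as.character(rep_len(seq_len(spec$n_chrom), M))
  pos <- integer(M)
  for (cc in unique(chrom)) {
    j <- which(chrom == cc)
    pos[j] <- 1L + (seq_along(j) - 1L) * spec$spacing_bp
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, M, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  data.frame(id = sprintf("rs%06d", seq_len(M)), chrom = chrom, pos = pos,
             ref = ref, alt = unname(alt), stringsAsFactors = FALSE)
}

# LD-block mode: duplicate a fraction of SNPs 500 bp downstream, each allele
# copy flipped with probability eps, so r2 between tag and duplicate is
# about (1 - 2*eps)^2.
add_ld_duplicates <- function(cohort) {
  spec <- cohort$spec
  gm <- cohort$genotypes
  M <- ncol(gm$calls)
  n_tag <- round(spec$ld_tag_fraction * M)
  if (n_tag == 0) return(cohort)
  tags <- sort(sample.int(M, n_tag))
  eps <- spec$ld_flip_prob
  g <- gm$calls[, tags, drop = FALSE]
  flip_alt <- matrix(stats::rbinom(length(g), ifelse(is.na(g), 0L, g),
                                   1 - eps), nrow = nrow(g))
  flip_ref <- matrix(stats::rbinom(length(g),
                                   ifelse(is.na(g), 0L, 2L - g), eps),
                     nrow = nrow(g))
  gdup <- flip_alt + flip_ref
  gdup[is.na(g)] <- NA_integer_
  vdup <- gm$variants[tags, ]
  vdup$id <- paste0(vdup$id, "_dup")
  vdup$pos <- vdup$pos + 500L
  calls <- cbind(gm$calls, gdup)
  variants <- rbind(gm$variants, vdup)
  gm2 <- genotype_matrix(calls, gm$samples, variants)
  cohort$genotypes <- gm_sort_variants(gm2)
  cohort
}

#' Append parent-offspring relatives to a simulated cohort
#'
#' Each appended offspring receives one allele per SNP from each of two
#' distinct, randomly chosen parents from the same subpopulation (Mendelian
#' transmission: a parent with genotype g transmits an alt allele with
#' probability g/2). Both parent-offspring pairs are recorded in
#' `truth_relative_pairs`.
#'
#' @param cohort a `simulated_cohort`.
#' @param n_pairs number of offspring to append; requires at least
#'   `2 * n_pairs` unadmixed founders.
#' @return the augmented `simulated_cohort`.
#' @export
add_relatives <- function(cohort, n_pairs) {
  stopifnot(inherits(cohort, "simulated_cohort"), n_pairs >= 0)
  if (n_pairs == 0) return(cohort)
  founders <- cohort$truth$sample_id[!is.na(cohort$truth$subpop) &
                                     !grepl("^ADMIX", cohort$truth$subpop)]
  if (length(founders) < 2 * n_pairs)
    stop("need at least ", 2 * n_pairs, " founders, have ",
         length(founders))
  gm <- cohort$genotypes
  tr <- cohort$truth
  M <- ncol(gm$calls)
  new_g <- matrix(NA_integer_, n_pairs, M)
  new_truth <- list(); pairs <- list()
  used <- character()
  for (i in seq_len(n_pairs)) {
    pool <- setdiff(founders, used)
    sp_tab <- table(tr$subpop[match(pool, tr$sample_id)])
    sp_ok <- names(sp_tab)[sp_tab >= 2]
    if (!length(sp_ok)) stop("no subpopulation with 2 unused founders left")
    sp <- sample(sp_ok, 1)
    cand <- pool[tr$subpop[match(pool, tr$sample_id)] == sp]
    par <- sample(cand, 2)
    used <- c(used, par)
    g1 <- gm$calls[par[1], ]; g2 <- gm$calls[par[2], ]
    a1 <- stats::rbinom(M, 1L, ifelse(is.na(g1), 0.5, g1 / 2))
    a2 <- stats::rbinom(M, 1L, ifelse(is.na(g2), 0.5, g2 / 2))
    new_g[i, ] <- a1 + a2
    child <- sprintf("R%05d", i)
    t1 <- tr[match(par[1], tr$sample_id), ]
    t2 <- tr[match(par[2], tr$sample_id), ]
    tc <- t1
    tc$sample_id <- child
    qcols <- grep("^q\\.", names(tr))
    tc[qcols] <- (t1[qcols] + t2[qcols]) / 2
    new_truth[[i]] <- tc
    pairs[[length(pairs) + 1L]] <- data.frame(id1 = child, id2 = par[1],
                                              stringsAsFactors = FALSE)
    pairs[[length(pairs) + 1L]] <- data.frame(id1 = child, id2 = par[2],
                                              stringsAsFactors = FALSE)
  }
  new_truth <- do.call(rbind, new_truth)
  new_samples <- data.frame(id = new_truth$sample_id,
                            population_label = NA_character_,
                            birth_country = NA_character_,
                            birth_region = NA_character_,
                            stringsAsFactors = FALSE)
  gm2 <- genotype_matrix(rbind(gm$calls, new_g),
                         rbind(gm$samples, new_samples),
                         gm$variants)
  cohort$genotypes <- gm2
  cohort$truth <- rbind(tr, new_truth)
  cohort$truth_relative_pairs <- rbind(cohort$truth_relative_pairs,
                                       do.call(rbind, pairs))
  cohort
}

#' Assign (noisy) birth-place labels to a simulated cohort
#'
#' With probability `label_concordance` a sample receives its true
#' subpopulation's region and a country drawn from that subpopulation's
#' country weights; otherwise a region drawn uniformly from the other
#' regions (with a country of that region). A `missing_label_fraction` of
#' samples gets missing labels. Admixed samples (no subpopulation truth)
#' always draw uniformly.
#'
#' @param cohort a `simulated_cohort`.
#' @return the cohort with `birth_region`/`birth_country` filled in both
#'   the sample metadata and the truth table (`obs_region`, `obs_country`).
#' @export
assign_birth_labels <- function(cohort) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  spec <- cohort$spec
  # region -> country weights lookup from the spec
  reg_countries <- list()
  for (co in spec$continents) for (sp in co$subpops) {
    reg <- if (is.null(sp$region)) paste0(co$name, "_region") else sp$region
    ctries <- if (is.null(sp$countries))
      stats::setNames(1, paste0(sp$name, "_country")) else sp$countries
    have <- reg_countries[[reg]]
    reg_countries[[reg]] <- if (is.null(have)) ctries else {
      merged <- c(have, ctries[setdiff(names(ctries), names(have))])
      merged
    }
  }
  regions <- names(reg_countries)
  tr <- cohort$truth
  n <- nrow(tr)
  obs_region <- character(n); obs_country <- character(n)
  for (i in seq_len(n)) {
    true_reg <- tr$region[i]
    concordant <- !is.na(true_reg) &&
      stats::runif(1) < spec$label_concordance
    reg <- if (concordant) true_reg else {
      others <- setdiff(regions, true_reg)
      if (!length(others)) true_reg else sample(others, 1)
    }
    w <- reg_countries[[reg]]
    obs_region[i] <- reg
    obs_country[i] <- if (concordant && !is.na(tr$country[i]))
      tr$country[i] else sample(names(w), 1, prob = w / sum(w))
  }
  if (spec$missing_label_fraction > 0) {
    nm <- stats::runif(n) < spec$missing_label_fraction
    obs_region[nm] <- NA_character_
    obs_country[nm] <- NA_character_
  }
  cohort$truth$obs_region <- obs_region
  cohort$truth$obs_country <- obs_country
  i <- match(cohort$genotypes$samples$id, tr$sample_id)
  cohort$genotypes$samples$birth_region <- obs_region[i]
  cohort$genotypes$samples$birth_country <- obs_country[i]
  cohort
}

#' Simulate a full structured cohort
#'
#' Runs [draw_hierarchical_frequencies()], [simulate_genotypes()],
#' [add_relatives()] and [assign_birth_labels()] under the spec's single
#' seed, in that order, so the whole cohort is reproducible byte-for-byte.
#'
#' @param spec a [population_spec()].
#' @return a `simulated_cohort`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(spec$seed)
  freqs <- draw_hierarchical_frequencies(spec, use_seed = FALSE)
  cohort <- simulate_genotypes(freqs, spec)
  cohort <- add_relatives(cohort, spec$relative_pairs)
  assign_birth_labels(cohort)
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat("simulated_cohort:", nrow(x$genotypes$calls), "samples,",
      ncol(x$genotypes$calls), "variants,",
      nrow(x$truth_relative_pairs), "recorded relative pairs\n")
  invisible(x)
}

#' Write a simulated cohort's truth tables
#'
#' @param cohort a `simulated_cohort`.
#' @param dir output directory (created if needed). Writes
#'   `truth.tsv` and `truth_relative_pairs.tsv`.
#' @return `dir`, invisibly.
#' @export
write_truth_tables <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(cohort$truth_relative_pairs,
                     file.path(dir, "truth_relative_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(dir)
}
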