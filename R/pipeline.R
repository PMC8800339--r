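#' Pipeline configuration
#'
#' Collects every stage parameter with this workflow's conventional defaults:
#' assignment threshold 0.8; LD pruning 50 kb / 10 kb / r2 0.025; MAF 0.05
#' before relatedness screening and 0.01 before per-group pruning; outlier
#' removal with 10 PCs, 6 SD, 5 iterations; k scanned 2..20; contingency
#' minimum count 10; relatedness cutoff 0.025.
#'
#' @param spec a [population_spec()] for synthetic mode, or `NULL` when
#'   `target_path`/`reference_path` point at genotype files.
#' @param target_path,reference_path,metadata_path,region_map_path input
#'   files for real-data mode (VCF/PED; TSV metadata; CSV country-region
#'   map). Ignored in synthetic mode.
#' @param format genotype file format for real-data mode.
#' @param threshold CAG assignment threshold.
#' @param prune_window_kb,prune_step_kb,prune_r2 global and per-group LD
#'   pruning parameters.
#' @param maf_rel MAF floor before relatedness screening.
#' @param maf_prune MAF floor for per-group pruning.
#' @param rel_cutoff relatedness cutoff for [related_pairs()].
#' @param outlier_pcs,outlier_sigma,outlier_iter PCA outlier-removal rule.
#' @param n_pcs components computed per group.
#' @param top_pcs_override per-group named list (or single integer) pinning
#'   the top-PC count; `NULL` uses the scree elbow.
#' @param kmin,kmax,restarts K-means scan range and restarts.
#' @param k_override per-group named list (or single integer) pinning k.
#' @param min_count contingency minimum category count.
#' @param min_cag_size groups with fewer assigned target samples are
#'   skipped in the per-group stages.
#' @param exclude_regions data.frame of high-LD regions to drop before
#'   pruning ([read_regions_bed()]), or `NULL`.
#' @param prune_reference_group reference population whose samples supply
#'   the r2 estimates for the global prune (default: first reference
#'   group, mirroring the use of a single unrelated reference panel).
#' @param seed integer seed driving every stochastic stage.
#' @param out_dir output directory for per-stage artifacts.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(spec = NULL, target_path = NULL,
                            reference_path = NULL, metadata_path = NULL,
                            region_map_path = NULL,
                            format = c("vcf", "ped", "bed"),
                            threshold = 0.8, prune_window_kb = 50,
                            prune_step_kb = 10, prune_r2 = 0.025,
                            maf_rel = 0.05, maf_prune = 0.01,
                            rel_cutoff = 0.025, outlier_pcs = 10,
                            outlier_sigma = 6, outlier_iter = 5,
                            n_pcs = 20, top_pcs_override = NULL,
                            kmin = 2, kmax = 20, restarts = 25,
                            k_override = NULL, min_count = 10,
                            min_cag_size = 30, exclude_regions = NULL,
                            prune_reference_group = NULL, seed = NULL,
                            out_dir = tempfile("cag_run_")) {
  format <- match.arg(format)
  if (is.null(seed)) stop("a seed is required")
  if (is.null(spec) && is.null(target_path))
    stop("give either a population_spec or input paths")
  stopifnot(threshold > 0, threshold <= 1,
            prune_r2 >= 0, prune_r2 <= 1,
            maf_rel >= 0, maf_rel <= 0.5, maf_prune >= 0, maf_prune <= 0.5,
            rel_cutoff >= 0, outlier_pcs >= 1, outlier_sigma > 0,
            outlier_iter >= 1, n_pcs >= 3, kmin >= 2, kmax >= kmin,
            restarts >= 1, min_count >= 0)
  structure(list(spec = spec, target_path = target_path,
                 reference_path = reference_path,
                 metadata_path = metadata_path,
                 region_map_path = region_map_path, format = format,
                 threshold = threshold, prune_window_kb = prune_window_kb,
                 prune_step_kb = prune_step_kb, prune_r2 = prune_r2,
                 maf_rel = maf_rel, maf_prune = maf_prune,
                 rel_cutoff = rel_cutoff, outlier_pcs = outlier_pcs,
                 outlier_sigma = outlier_sigma, outlier_iter = outlier_iter,
                 n_pcs = n_pcs, top_pcs_override = top_pcs_override,
                 kmin = kmin, kmax = kmax, restarts = restarts,
                 k_override = k_override, min_count = min_count,
                 min_cag_size = min_cag_size,
                 exclude_regions = exclude_regions,
                 prune_reference_group = prune_reference_group,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' The JSON object may carry any [pipeline_config()] argument; a `spec`
#' sub-object is rebuilt into a [population_spec()].
#'
#' @param path JSON file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  unl <- function(x) if (is.list(x)) unlist(x) else x
  if (!is.null(raw$spec)) {
    sp <- raw$spec
    conts <- lapply(sp$continents, function(co) {
      co$F <- unl(co$F)
      co$subpops <- lapply(co$subpops, function(s) {
        for (fld in c("F", "n", "region", "reference")) {
          if (!is.null(s[[fld]])) s[[fld]] <- unl(s[[fld]])
        }
        if (!is.null(s$countries)) s$countries <- unlist(s$countries)
        s
      })
      co
    })
    args <- lapply(sp[setdiff(names(sp), c("continents",
                                           "admixed_blocks"))], unl)
    if (!is.null(sp$admixed_blocks)) {
      args$admixed_blocks <- lapply(sp$admixed_blocks, function(b)
        list(n = unl(b$n), alpha = unlist(b$alpha)))
    }
    raw$spec <- do.call(population_spec, c(list(continents = conts), args))
  }
  top <- lapply(raw[setdiff(names(raw), c("spec", "exclude_regions"))], unl)
  if (!is.null(raw$exclude_regions)) {
    top$exclude_regions <- do.call(rbind, lapply(raw$exclude_regions,
                                                 as.data.frame))
  }
  do.call(pipeline_config, c(list(spec = raw$spec), top))
}

# per-group override values may be a single number or a named list/vector
pick_override <- function(ov, cag) {
  if (is.null(ov)) return(NULL)
  if (length(ov) > 1 || !is.null(names(ov))) {
    v <- tryCatch(ov[[cag]], error = function(e) NULL)
    if (is.null(v) || is.na(v)) return(NULL)
    return(v)
  }
  ov
}

manifest_row <- function(stage, name, n_samples_in, n_samples_out,
                         n_variants_in, n_variants_out, params = "",
                         outputs = "") {
  data.frame(stage = stage, name = name,
             n_samples_in = n_samples_in, n_samples_out = n_samples_out,
             n_variants_in = n_variants_in, n_variants_out = n_variants_out,
             params = params, outputs = outputs, stringsAsFactors = FALSE)
}

#' Run the full continental-ancestry framework
#'
#' Stages, in the workflow's canonical order: (1) merge target and reference cohorts
#' by variant id; (2) global LD prune with r2 on the reference subset;
#' (3) supervised admixture against reference frequencies; (4) CAG
#' assignment at the threshold; then per group (5) unrelated-subset
#' selection, (6) per-group LD prune, (7) PCA with outlier removal and
#' projection of related and reference samples, (8) variance explained and
#' top-PC selection, (9) K-means with silhouette k selection, (10)
#' correspondence analysis of clusters against birth regions, (11)
#' pairwise Fst between clusters. Reference samples donate allele
#' frequencies and are projected onto PCs but never enter clustering or
#' CA. Every stage's sample/variant counts are logged to a manifest; a
#' rerun under the same config and seed is bit-identical.
#'
#' @param config a [pipeline_config()].
#' @return a `run_result`: list with `manifest` (data.frame), `cags`
#'   (per-group results: pca model, scores, clusters, ca, fst, outliers,
#'   unrelated sets), `admixture` (`ancestry_fit`), `assignments`,
#'   `cohort` (the merged `genotype_matrix`), `truth` (synthetic mode
#'   only), `out_dir`.
#' @export
run_framework <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(...) {
    cat(sprintf(...), "\n", sep = "", file = log_path, append = TRUE)
  }
  cat("", file = log_path)                           # truncate
  truth <- NULL; rel_truth <- NULL
  if (!is.null(config$spec)) {
    sim <- simulate_cohort(config$spec)
    truth <- sim$truth
    rel_truth <- sim$truth_relative_pairs
    gm_all <- sim$genotypes
    is_ref <- !is.na(gm_all$samples$population_label)
    target <- gm_subset(gm_all, sample_ids = gm_all$samples$id[!is_ref])
    reference <- gm_subset(gm_all, sample_ids = gm_all$samples$id[is_ref])
  } else {
    target <- read_genotypes(config$target_path, config$format)
    reference <- read_genotypes(config$reference_path, config$format)
    if (!is.null(config$metadata_path)) {
      meta <- read_sample_metadata(config$metadata_path)
      target <- attach_metadata(target, meta)
      reference <- attach_metadata(reference, meta)
    }
    if (!is.null(config$region_map_path)) {
      rmap <- read_region_map(config$region_map_path)
      target$samples$birth_region <-
        map_countries_to_regions(target$samples$birth_country, rmap)
    }
  }
  manifest <- list()
  # --- stage 1: merge ------------------------------------------------------
  mg <- merge_by_id(target, reference)
  cohort <- mg$merged
  logf("stage 1 merge: %d + %d samples, %d shared variants kept (%d dup, %d mismatch)",
       nrow(target$calls), nrow(reference$calls), mg$report$n_kept,
       mg$report$n_dup_a + mg$report$n_dup_b, mg$report$n_mismatch)
  manifest[[1]] <- manifest_row(1, "merge",
                                nrow(target$calls) + nrow(reference$calls),
                                nrow(cohort$calls),
                                ncol(target$calls), ncol(cohort$calls),
                                params = jsonlite::toJSON(mg$report,
                                                          auto_unbox = TRUE))
  ref_ids_all <- cohort$samples$id[!is.na(cohort$samples$population_label)]
  target_ids <- setdiff(cohort$samples$id, ref_ids_all)
  # --- stage 2: global LD prune -------------------------------------------
  ref_groups <- split(ref_ids_all,
                      cohort$samples$population_label[
                        match(ref_ids_all, cohort$samples$id)])
  prg <- config$prune_reference_group
  if (is.null(prg)) prg <- names(ref_groups)[1]
  pp <- prune_params(config$prune_window_kb, config$prune_step_kb,
                     config$prune_r2, maf = 0,
                     exclude_regions = config$exclude_regions,
                     reference_sample_ids = ref_groups[[prg]])
  kept <- ld_prune(cohort, pp)
  pruned <- gm_subset(cohort, variant_ids = kept)
  logf("stage 2 global prune (r2 on %s): %d -> %d variants", prg,
       ncol(cohort$calls), length(kept))
  manifest[[2]] <- manifest_row(2, "ld_prune_global", nrow(cohort$calls),
                                nrow(cohort$calls), ncol(cohort$calls),
                                length(kept),
                                params = sprintf("window=%gkb step=%gkb r2=%g ref=%s",
                                                 config$prune_window_kb,
                                                 config$prune_step_kb,
                                                 config$prune_r2, prg))
  # --- stage 3: supervised admixture --------------------------------------
  model <- reference_frequencies(pruned)
  fit <- fit_admixture(pruned, model, sample_ids = target_ids)
  q_path <- file.path(config$out_dir, "admixture.Q.tsv")
  write_q_table(fit, q_path, config$threshold)
  logf("stage 3 admixture: %d samples x %d SNPs, %d EM iterations, ll=%.2f",
       length(target_ids), length(kept), fit$iterations,
       utils::tail(fit$loglik, 1))
  manifest[[3]] <- manifest_row(3, "supervised_admixture",
                                length(target_ids), length(target_ids),
                                length(kept), length(kept),
                                params = sprintf("K=%d tol=1e-6",
                                                 length(model$populations)),
                                outputs = "admixture.Q.tsv")
  # --- stage 4: CAG assignment --------------------------------------------
  assignments <- assign_cag(fit, config$threshold)
  tab <- table(assignments)
  logf("stage 4 assignment at %.2f: %s", config$threshold,
       paste(names(tab), as.integer(tab), sep = "=", collapse = " "))
  manifest[[4]] <- manifest_row(4, "cag_assignment", length(target_ids),
                                sum(assignments != "unassigned"),
                                length(kept), length(kept),
                                params = sprintf("threshold=%g",
                                                 config$threshold))
  # --- stages 5-11 per CAG -------------------------------------------------
  cags <- list()
  for (cag in model$populations) {
    cag_targets <- names(assignments)[assignments == cag]
    if (length(cag_targets) < config$min_cag_size) {
      logf("skipping CAG %s: only %d assigned targets", cag,
           length(cag_targets))
      next
    }
    cag_refs <- ref_groups[[cag]]
    cag_ids <- c(cag_targets, cag_refs)
    sub <- gm_subset(cohort, sample_ids = cag_ids)
    # stage 5: unrelated selection (MAF 0.05, GRM, greedy)
    rel <- grm(sub, maf_floor = config$maf_rel)
    pairs <- related_pairs(rel, config$rel_cutoff)
    sel <- greedy_unrelated(pairs, cag_ids)
    unrelated <- sel$keep
    unrelated_targets <- intersect(unrelated, cag_targets)
    # stage 6: per-CAG prune (MAF 0.01) on unrelated samples
    ppc <- prune_params(config$prune_window_kb, config$prune_step_kb,
                        config$prune_r2, maf = config$maf_prune,
                        exclude_regions = config$exclude_regions,
                        reference_sample_ids = unrelated)
    kept_c <- ld_prune(sub, ppc)
    sub_p <- gm_subset(sub, variant_ids = kept_c)
    # stage 7: PCA on unrelated targets, outliers removed, others projected
    outl <- remove_outliers(sub_p, fit_sample_ids = unrelated_targets,
                            n_pcs = config$n_pcs,
                            n_outlier_pcs = config$outlier_pcs,
                            sigma = config$outlier_sigma,
                            iterations = config$outlier_iter)
    pca <- outl$model
    fit_ids <- pca$fit_sample_ids
    projected_ids <- setdiff(cag_ids, fit_ids)
    proj <- if (length(projected_ids))
      project_samples(sub_p, pca, projected_ids) else
      matrix(0, 0, ncol(pca$scores))
    # stage 8: variance explained, top-PC selection
    ve <- variance_explained(pca)
    ov <- pick_override(config$top_pcs_override, cag)
    top <- select_top_pcs(ve, override = ov)
    top <- min(top, ncol(pca$scores))
    # stage 9: K-means + silhouette on fit-sample top PCs
    kov <- pick_override(config$k_override, cag)
    clus <- select_k(pca$scores[, seq_len(top), drop = FALSE],
                     kmin = config$kmin,
                     kmax = min(config$kmax, length(fit_ids) - 1),
                     restarts = config$restarts,
                     seed = config$seed + match(cag, model$populations),
                     override = kov)
    # stage 10: correspondence analysis vs birth region
    regions <- sub$samples$birth_region[match(fit_ids, sub$samples$id)]
    ca <- tryCatch({
      ct <- build_contingency(paste0("K", clus$labels), regions,
                              config$min_count)
      ca_fit(ct)
    }, error = function(e) {
      logf("CAG %s: CA skipped (%s)", cag, conditionMessage(e))
      NULL
    })
    # stage 11: pairwise Fst between clusters
    cl_labels <- rep(NA_character_, nrow(sub_p$calls))
    cl_labels[match(fit_ids, sub_p$samples$id)] <-
      paste0("K", clus$labels)
    fst <- tryCatch(pairwise_fst(sub_p, cl_labels),
                    error = function(e) {
                      logf("CAG %s: Fst skipped (%s)", cag,
                           conditionMessage(e))
                      NULL
                    })
    # artifacts
    pre <- file.path(config$out_dir, paste0("cag_", cag))
    sc_all <- rbind(pca$scores, proj)
    write_evec(sc_all, paste0(pre, ".evec.tsv"),
               labels = ifelse(rownames(sc_all) %in% cag_refs, cag,
                               ifelse(rownames(sc_all) %in% fit_ids,
                                      "target", "projected")))
    utils::write.table(clus$silhouette, paste0(pre, ".silhouette.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(id = names(clus$labels),
                                  cluster = clus$labels),
                       paste0(pre, ".clusters.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(ca)) {
      ca_df <- rbind(
        data.frame(label = rownames(ca$row_coords), side = "cluster",
                   ca$row_coords, stringsAsFactors = FALSE),
        data.frame(label = rownames(ca$col_coords), side = "birth",
                   ca$col_coords, stringsAsFactors = FALSE))
      ca_df$inertia_fraction <- c(ca$inertia_fractions,
                                  rep(NA, nrow(ca_df) -
                                        length(ca$inertia_fractions)))
      utils::write.table(ca_df, paste0(pre, ".ca.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE, na = "")
    }
    if (!is.null(fst)) write_phylip(fst, paste0(pre, ".fst.phylip"))
    logf("CAG %s: %d targets (%d unrelated fit, %d outliers), %d SNPs, top %d PCs, k=%d",
         cag, length(cag_targets), length(fit_ids),
         length(outl$outliers), length(kept_c), top, clus$chosen_k)
    manifest[[length(manifest) + 1L]] <-
      rbind(manifest_row(5, paste0("unrelated_", cag), length(cag_ids),
                         length(unrelated), ncol(sub$calls),
                         ncol(sub$calls),
                         params = sprintf("cutoff=%g maf=%g",
                                          config$rel_cutoff,
                                          config$maf_rel)),
            manifest_row(6, paste0("prune_", cag), length(unrelated),
                         length(unrelated), ncol(sub$calls),
                         length(kept_c),
                         params = sprintf("maf=%g", config$maf_prune)),
            manifest_row(7, paste0("pca_", cag), length(unrelated_targets),
                         length(fit_ids), length(kept_c),
                         length(pca$variant_ids),
                         params = sprintf("outlier %d PCs/%g sd/%d iter",
                                          config$outlier_pcs,
                                          config$outlier_sigma,
                                          config$outlier_iter),
                         outputs = basename(paste0(pre, ".evec.tsv"))),
            manifest_row(8, paste0("top_pcs_", cag), length(fit_ids),
                         length(fit_ids), length(pca$variant_ids),
                         length(pca$variant_ids),
                         params = sprintf("top=%d", top)),
            manifest_row(9, paste0("kmeans_", cag), length(fit_ids),
                         length(fit_ids), top, top,
                         params = sprintf("k=%d", clus$chosen_k),
                         outputs = basename(paste0(pre, ".clusters.tsv"))),
            manifest_row(10, paste0("ca_", cag), length(fit_ids),
                         if (is.null(ca)) 0L else ca$n, top, top,
                         params = if (is.null(ca)) "skipped" else
                           sprintf("X2=%.3f dof=%d", ca$chi_square,
                                   ca$dof)),
            manifest_row(11, paste0("fst_", cag), length(fit_ids),
                         length(fit_ids), length(pca$variant_ids),
                         length(pca$variant_ids),
                         params = if (is.null(fst)) "skipped" else
                           sprintf("pairs=%d",
                                   sum(upper.tri(fst$fst))),
                         outputs = if (is.null(fst)) "" else
                           basename(paste0(pre, ".fst.phylip"))))
    cags[[cag]] <- list(targets = cag_targets, references = cag_refs,
                        unrelated = unrelated, related_pairs = pairs,
                        pruned_variants = kept_c, pca = pca,
                        projected_scores = proj, outliers = outl$outliers,
                        variance_explained = ve, top_pcs = top,
                        clusters = clus, ca = ca, fst = fst)
  }
  manifest <- do.call(rbind, manifest)
  utils::write.table(manifest, file.path(config$out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  structure(list(manifest = manifest, cags = cags, admixture = fit,
                 assignments = assignments, cohort = cohort, truth = truth,
                 truth_relative_pairs = rel_truth,
                 out_dir = config$out_dir, config = config),
            class = "run_result")
}

#' Check manifest count-flow conservation
#'
#' Within each stage chain the output counts of one stage must match the
#' input counts of the next; no samples may appear from nowhere.
#'
#' @param manifest a manifest data.frame from [run_framework()].
#' @return `TRUE` (invisibly) or an error describing the first violation.
#' @export
check_manifest <- function(manifest) {
  global <- manifest[manifest$stage %in% 1:4, ]
  for (i in seq_len(nrow(global) - 1)) {
    if (global$n_variants_out[i] != global$n_variants_in[i + 1])
      stop("variant count mismatch between stages ", global$stage[i],
           " and ", global$stage[i + 1])
  }
  if (global$n_samples_out[1] != global$n_samples_in[2])
    stop("sample count mismatch after merge")
  # per-CAG chains: unrelated -> prune -> pca sample flow
  cags <- unique(sub("^[a-z_]*_", "", manifest$name[manifest$stage == 5]))
  for (cg in cags) {
    m5 <- manifest[manifest$name == paste0("unrelated_", cg), ]
    m6 <- manifest[manifest$name == paste0("prune_", cg), ]
    m7 <- manifest[manifest$name == paste0("pca_", cg), ]
    if (m5$n_samples_out != m6$n_samples_in)
      stop("sample flow broken between stages 5 and 6 for ", cg)
    if (m6$n_variants_out != m7$n_variants_in)
      stop("variant flow broken between stages 6 and 7 for ", cg)
  }
  invisible(TRUE)
}

#' Synthetic end-to-end rehearsal with truth-based evaluation
#'
#' Runs [run_framework()] on a synthetic spec and scores the results
#' against the generator's truth: admixture recovery (mean absolute error
#' of q), assignment accuracy for near-pure samples and unassignment of
#' strongly admixed ones, adjusted Rand index of the K-means clusters
#' against true subpopulations per group, CA Dim1+Dim2 inertia, Hudson
#' Fst recovery against the Balding-Nichols expectations, and PCA outlier
#' counts.
#'
#' @param config a [pipeline_config()] with a `spec` (synthetic mode).
#' @return an `evaluation_report` list; see fields in the source or the
#'   package vignette. Includes the underlying `run_result`.
#' @export
rehearse <- function(config) {
  stopifnot(inherits(config, "pipeline_config"), !is.null(config$spec))
  run <- run_framework(config)
  truth <- run$truth
  fit <- run$admixture
  qhat <- fit$q
  qcols <- paste0("q.", fit$populations)
  ti <- match(rownames(qhat), truth$sample_id)
  qtrue <- as.matrix(truth[ti, qcols])
  colnames(qtrue) <- fit$populations
  q_mae <- mean(abs(qhat - qtrue))
  qmax <- apply(qtrue, 1, max)
  true_top <- fit$populations[max.col(qtrue, ties.method = "first")]
  assigned <- run$assignments[rownames(qhat)]
  pure <- qmax >= 0.9
  acc_pure <- if (any(pure))
    mean(assigned[pure] == true_top[pure]) else NA_real_
  mixed <- qmax <= 0.7
  unassigned_mixed <- if (any(mixed))
    mean(assigned[mixed] == "unassigned") else NA_real_
  # expected pairwise Fst between subpopulations under the generating model
  spec <- config$spec
  Fc <- stats::setNames(vapply(spec$continents, `[[`, 0, "F"),
                        vapply(spec$continents, `[[`, "", "name"))
  Fs <- list()
  for (co in spec$continents) for (sp in co$subpops)
    Fs[[sp$name]] <- c(F = sp$F, cont = co$name)
  cag_reports <- list()
  for (cag in names(run$cags)) {
    cg <- run$cags[[cag]]
    fit_ids <- rownames(cg$pca$scores)
    tr_sub <- truth$subpop[match(fit_ids, truth$sample_id)]
    # ARI scored on samples with a true subpopulation; admixed samples have
    # no subpopulation truth to recover
    has_sub <- !is.na(tr_sub) & !grepl("^ADMIX", tr_sub)
    ari <- if (sum(has_sub) >= 2)
      adjusted_rand_index(cg$clusters$labels[has_sub], tr_sub[has_sub])
    else NA_real_
    dim12 <- if (!is.null(cg$ca))
      sum(cg$ca$inertia_fractions[seq_len(min(2,
        length(cg$ca$inertia_fractions)))]) else NA_real_
    # Fst recovery on true subpopulation labels within this group
    sub <- gm_subset(run$cohort, sample_ids = fit_ids,
                     variant_ids = cg$pruned_variants)
    est <- tryCatch(pairwise_fst(sub, tr_sub), error = function(e) NULL)
    fst_err <- NA_real_
    if (!is.null(est)) {
      errs <- c()
      gps <- est$groups
      for (a in seq_along(gps)) for (b in seq_along(gps)) {
        if (a >= b) next
        fa <- Fs[[gps[a]]]; fb <- Fs[[gps[b]]]
        if (is.null(fa) || is.null(fb)) next
        expected <- if (fa["cont"] == fb["cont"])
          (as.numeric(fa["F"]) + as.numeric(fb["F"])) / 2
        else {
          fc <- mean(Fc[c(fa["cont"], fb["cont"])])
          NA_real_                                  # cross-continent pairs
        }                                           # not expected in a CAG
        if (!is.na(expected))
          errs <- c(errs, abs(est$fst_raw[a, b] - expected))
      }
      if (length(errs)) fst_err <- max(errs)
    }
    cag_reports[[cag]] <- list(ari = ari, dim12_inertia = dim12,
                               max_fst_error = fst_err,
                               n_outliers = length(cg$outliers),
                               chosen_k = cg$clusters$chosen_k)
  }
  # continental-level Fst recovery on unadmixed founder samples
  founders <- truth$sample_id[!is.na(truth$continent) &
                              !grepl("^ADMIX", truth$subpop) &
                              !truth$sample_id %in%
                                run$truth_relative_pairs$id1]
  cont_lab <- truth$continent[match(run$cohort$samples$id,
                                    truth$sample_id)]
  cont_lab[!run$cohort$samples$id %in% founders] <- NA
  cont_fst <- tryCatch(pairwise_fst(run$cohort, cont_lab),
                       error = function(e) NULL)
  cont_fst_err <- NA_real_
  if (!is.null(cont_fst)) {
    errs <- c()
    gps <- cont_fst$groups
    for (a in seq_along(gps)) for (b in seq_along(gps)) {
      if (a >= b) next
      # pooled subpops: expected about Fc + mean within-continent drift
      expA <- Fc[gps[a]]; expB <- Fc[gps[b]]
      expected <- (expA + expB) / 2
      errs <- c(errs, abs(cont_fst$fst_raw[a, b] - expected))
    }
    cont_fst_err <- max(errs)
  }
  structure(list(q_mae = q_mae, assignment_accuracy_pure = acc_pure,
                 unassigned_rate_admixed = unassigned_mixed,
                 cags = cag_reports,
                 continental_fst_max_error = cont_fst_err,
                 run = run),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("rehearsal evaluation:\n")
  cat(sprintf("  admixture q MAE:                 %.4f\n", x$q_mae))
  cat(sprintf("  assignment accuracy (qmax>=0.9): %.4f\n",
              x$assignment_accuracy_pure))
  cat(sprintf("  unassigned rate    (qmax<=0.7):  %.4f\n",
              x$unassigned_rate_admixed))
  cat(sprintf("  continental Fst max |error|:     %.4f\n",
              x$continental_fst_max_error))
  for (cag in names(x$cags)) {
    r <- x$cags[[cag]]
    cat(sprintf("  %s: k=%d ARI=%.3f Dim1+2=%.3f max Fst err=%.4f outliers=%d\n",
                cag, r$chosen_k, r$ari,
                ifelse(is.na(r$dim12_inertia), NaN, r$dim12_inertia),
                ifelse(is.na(r$max_fst_error), NaN, r$max_fst_error),
                r$n_outliers))
  }
  invisible(x)
}

#' A default synthetic world echoing a multi-ancestry biobank cohort
#'
#' Four continental groups at pairwise Fst 0.1 (each diverged 0.1 from the
#' global ancestor), three subpopulations per continent with
#' within-continent pairwise Fst inside the 0.003-0.015 range typical of
#' within-group differentiation on European-ascertained arrays (ordered
#' AFR < EUR < SAS < EAS, sized toward the upper half of the range so
#' structure is detectable at desk-scale sample counts), one reference panel per
#' continent, a Dirichlet(0.3) admixed block, parent-offspring pairs, and
#' 90% birth-label concordance.
#'
#' @param n_snps SNP count (default 20000).
#' @param n_per_subpop samples per subpopulation (default 60).
#' @param n_reference reference-panel size per continent (default 100,
#'   about the size of a 1000-Genomes population sample).
#' @param n_admixed admixed samples (default 60).
#' @param relative_pairs parent-offspring offspring count (default 10).
#' @param seed integer seed.
#' @return a [population_spec()].
#' @export
default_rehearsal_spec <- function(n_snps = 20000, n_per_subpop = 60,
                                   n_reference = 100, n_admixed = 60,
                                   relative_pairs = 10, seed = 1) {
  mk_cont <- function(name, Fsub, regions) {
    subs <- list(list(name = paste0(name, "_REF"), F = 0,
                      n = n_reference, region = regions[1],
                      countries = stats::setNames(1,
                        paste0(name, "_REF_country")),
                      reference = TRUE))
    for (i in 1:3) {
      subs[[i + 1]] <- list(
        name = paste0(name, "_P", i), F = Fsub, n = n_per_subpop,
        region = regions[i + 1],
        countries = stats::setNames(c(0.7, 0.3),
                                    paste0(name, "_P", i,
                                           c("_countryA", "_countryB"))))
    }
    list(name = name, F = 0.1, subpops = subs)
  }
  continents <- list(
    mk_cont("AFR", 0.008, paste0("AFR_R", 0:3)),
    mk_cont("EUR", 0.009, paste0("EUR_R", 0:3)),
    mk_cont("SAS", 0.010, paste0("SAS_R", 0:3)),
    mk_cont("EAS", 0.013, paste0("EAS_R", 0:3)))
  population_spec(continents = continents, n_snps = n_snps,
                  admixed_blocks = list(list(n = n_admixed,
                                             alpha = rep(0.3, 4))),
                  relative_pairs = relative_pairs,
                  label_concordance = 0.9,
                  missing_label_fraction = 0.02, seed = seed)
}
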