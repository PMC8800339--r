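#' Reference-population allele frequencies
#'
#' Builds the fixed frequency table `f` (K populations x M variants) for
#' supervised ancestry estimation from labelled reference samples.
#' Frequencies are clamped to `[1e-6, 1 - 1e-6]` so the likelihood is
#' finite; a SNP with no non-missing calls in a group gets 0.5 with a
#' warning.
#'
#' @param x a `genotype_matrix`.
#' @param groups named list mapping population name to sample ids, or
#'   `NULL` to use the non-missing `population_label` column (each group
#'   needs at least 2 samples).
#' @return an `ancestry_model`: list with `populations`, `f` (K x M),
#'   `variant_ids`.
#' @export
reference_frequencies <- function(x, groups = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (is.null(groups)) {
    lab <- x$samples$population_label
    groups <- split(x$samples$id[!is.na(lab)], lab[!is.na(lab)])
  }
  if (!length(groups)) stop("no reference groups")
  sizes <- vapply(groups, length, 0L)
  if (any(sizes < 2)) stop("reference group(s) with fewer than 2 samples: ",
                           paste(names(groups)[sizes < 2], collapse = ", "))
  K <- length(groups)
  M <- ncol(x$calls)
  f <- matrix(NA_real_, K, M, dimnames = list(names(groups),
                                              x$variants$id))
  n_allmiss <- 0L
  for (k in seq_len(K)) {
    af <- allele_frequency(x, groups[[k]])
    miss <- is.na(af$f)
    n_allmiss <- n_allmiss + sum(miss)
    fk <- af$f
    fk[miss] <- 0.5
    f[k, ] <- pmin(pmax(fk, 1e-6), 1 - 1e-6)
  }
  if (n_allmiss) warning(n_allmiss,
                         " all-missing group/SNP frequencies set to 0.5")
  structure(list(populations = names(groups), f = f,
                 variant_ids = x$variants$id),
            class = "ancestry_model")
}

#' Supervised admixture proportions by per-individual EM
#'
#' With reference frequencies `f` held fixed, each individual's ancestry
#' vector `q` maximises the binomial likelihood
#' `sum_j [ g_j log(sum_k q_k f_kj) + (2 - g_j) log(sum_k q_k (1 - f_kj)) ]`
#' over the simplex, missing genotypes omitted. The EM update allocates
#' each allele copy to source populations proportionally to `q_k f_kj`
#' (alt) or `q_k (1 - f_kj)` (ref) and renormalises; the log-likelihood is
#' non-decreasing and each row of `q` sums to 1 after every step.
#' Individuals are independent, so all are updated in one vectorised sweep.
#'
#' @param x a `genotype_matrix` sharing variants with `model`.
#' @param model an `ancestry_model` from [reference_frequencies()].
#' @param sample_ids optional subset of samples to fit.
#' @param tol convergence tolerance on `max |q_new - q_old|`
#'   (default 1e-6).
#' @param max_iter iteration cap (default 1000).
#' @return an `ancestry_fit`: list with `q` (samples x K, rows on the
#'   simplex), `loglik` (per-iteration total log-likelihood trace),
#'   `iterations`, `converged`, `populations`.
#' @export
fit_admixture <- function(x, model, sample_ids = NULL, tol = 1e-6,
                          max_iter = 1000) {
  stopifnot(inherits(x, "genotype_matrix"), inherits(model, "ancestry_model"))
  if (!identical(x$variants$id, model$variant_ids))
    stop("cohort and model must share the same variants (same ids, order)")
  if (!is.null(sample_ids)) x <- gm_subset(x, sample_ids = sample_ids)
  g <- x$calls
  n <- nrow(g); K <- nrow(model$f)
  ga <- g; ga[is.na(g)] <- 0L                         # alt copies
  gr <- 2L - g; gr[is.na(g)] <- 0L                    # ref copies
  storage.mode(ga) <- "double"; storage.mode(gr) <- "double"
  m_obs <- rowSums(!is.na(g))
  if (any(m_obs == 0)) stop("sample(s) with zero non-missing genotypes")
  fa <- model$f                                      # K x M
  fr <- 1 - fa
  q <- matrix(1 / K, n, K, dimnames = list(x$samples$id,
                                           model$populations))
  # individuals are independent, so rows whose q has converged are frozen
  # and dropped from later sweeps; the trace records each row's
  # log-likelihood at the start of its last evaluated iteration, so the
  # total remains non-decreasing across iterations
  active <- rep(TRUE, n)
  ll_row <- rep(NA_real_, n)
  loglik <- numeric(0)
  iter <- 0L; converged <- FALSE
  tfa <- t(fa); tfr <- t(fr)
  while (iter < max_iter) {
    iter <- iter + 1L
    idx <- which(active)
    da <- q[idx, , drop = FALSE] %*% fa               # active x M mixtures
    dr <- q[idx, , drop = FALSE] %*% fr
    ll_row[idx] <- rowSums(ga[idx, , drop = FALSE] * log(da) +
                           gr[idx, , drop = FALSE] * log(dr))
    ll <- sum(ll_row)
    if (!is.finite(ll)) stop("non-finite log-likelihood at iteration ", iter)
    loglik <- c(loglik, ll)
    alt_assign <- (ga[idx, , drop = FALSE] / da) %*% tfa *
      q[idx, , drop = FALSE]                          # allele-copy counts
    ref_assign <- (gr[idx, , drop = FALSE] / dr) %*% tfr *
      q[idx, , drop = FALSE]
    q_new <- (alt_assign + ref_assign) / (2 * m_obs[idx])
    q_new <- q_new / rowSums(q_new)                   # guard rounding drift
    d_row <- apply(abs(q_new - q[idx, , drop = FALSE]), 1, max)
    q[idx, ] <- q_new
    active[idx[d_row < tol]] <- FALSE
    if (!any(active)) { converged <- TRUE; break }
  }
  structure(list(q = q, loglik = loglik, iterations = iter,
                 converged = converged, populations = model$populations),
            class = "ancestry_fit")
}

#' Assign continental ancestry groups at a proportion threshold
#'
#' A sample is labelled with its highest-proportion population when that
#' proportion is at least `threshold` (inclusive, "at least 80%"),
#' otherwise `"unassigned"`.
#'
#' @param fit an `ancestry_fit` (or a bare q matrix with population column
#'   names).
#' @param threshold assignment threshold (default 0.8).
#' @return character vector of labels, named by sample id.
#' @export
assign_cag <- function(fit, threshold = 0.8) {
  q <- if (inherits(fit, "ancestry_fit")) fit$q else as.matrix(fit)
  stopifnot(threshold >= 0, threshold <= 1)
  top <- max.col(q, ties.method = "first")
  lab <- colnames(q)[top]
  qmax <- q[cbind(seq_len(nrow(q)), top)]
  lab[qmax < threshold] <- "unassigned"
  stats::setNames(lab, rownames(q))
}

#' Pairwise Fst among reference populations
#'
#' Delegates to [pairwise_fst()] on the labelled reference samples and
#' reports the mean over the K(K-1)/2 pairs (the framework reports 0.1055
#' for its four continental reference panels).
#'
#' @param x a `genotype_matrix` containing the reference samples.
#' @param groups as in [reference_frequencies()].
#' @return list with `fst` (an `fst_matrix`) and `mean` (mean over pairs).
#' @export
reference_pairwise_fst <- function(x, groups = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (is.null(groups)) {
    lab <- x$samples$population_label
    groups <- split(x$samples$id[!is.na(lab)], lab[!is.na(lab)])
  }
  if (length(groups) < 2) stop("need at least 2 reference groups")
  labels <- rep(NA_character_, nrow(x$samples))
  for (nm in names(groups))
    labels[x$samples$id %in% groups[[nm]]] <- nm
  fm <- pairwise_fst(x, labels)
  list(fst = fm, mean = summarize_pairs(fm)["mean"])
}

#' Write admixture proportions as a .Q-style table
#'
#' One row per sample: id, K proportion columns (named `q.<population>`),
#' and the assigned group label.
#'
#' @param fit an `ancestry_fit`.
#' @param path TSV output path.
#' @param threshold passed to [assign_cag()].
#' @export
write_q_table <- function(fit, path, threshold = 0.8) {
  stopifnot(inherits(fit, "ancestry_fit"))
  df <- data.frame(id = rownames(fit$q), stringsAsFactors = FALSE)
  qd <- as.data.frame(fit$q)
  names(qd) <- paste0("q.", fit$populations)
  df <- cbind(df, qd, cag = unname(assign_cag(fit, threshold)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
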