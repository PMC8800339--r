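#' Patterson normalisation of a genotype matrix
#'
#' Centers each variant by its mean call and scales by
#' `sqrt(p (1 - p))` with `p = mean/2`, both computed on the fit samples
#' only; missing calls become 0 after centering; variants monomorphic on
#' the fit samples are dropped. This is the normalisation under which
#' genotype PCA eigenvalues follow the usual population-genetic theory.
#'
#' @param x a `genotype_matrix`.
#' @param fit_sample_ids samples on which centre/scale are estimated
#'   (default: all).
#' @return list with `X` (fit samples x kept variants, normalised),
#'   `center`, `scale` (per kept variant), `variant_ids` (kept),
#'   `fit_sample_ids`.
#' @export
patterson_normalize <- function(x, fit_sample_ids = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (is.null(fit_sample_ids)) fit_sample_ids <- x$samples$id
  xf <- gm_subset(x, sample_ids = fit_sample_ids)
  mu <- colMeans(xf$calls, na.rm = TRUE)
  p <- mu / 2
  sc <- sqrt(p * (1 - p))
  keep <- !is.na(sc) & sc > 0
  if (!any(keep)) stop("all variants monomorphic on the fit samples")
  g <- xf$calls[, keep, drop = FALSE]
  X <- sweep(g, 2, mu[keep])
  X[is.na(g)] <- 0
  X <- sweep(X, 2, sc[keep], "/")
  list(X = X, center = mu[keep], scale = sc[keep],
       variant_ids = xf$variants$id[keep], fit_sample_ids = fit_sample_ids)
}

#' Fit principal components on normalised genotypes
#'
#' Eigen-decomposition of the fit samples' covariance (computed via the
#' n x n cross-product, so biobank-width variant counts stay cheap).
#' Scores are the fit samples' projections; sample score variance along PC
#' p equals the eigenvalue `lambda_p`. Signs are fixed so each PC's
#' largest-magnitude loading is positive. If the data have rank below
#' `n_pcs`, fewer PCs are returned with a warning.
#'
#' @param norm output of [patterson_normalize()].
#' @param n_pcs how many components to keep (default 20).
#' @return a `pca_model`: list with `eigenvalues` (all positive ones, for
#'   variance-explained), `loadings` (variants x n_pcs, orthonormal
#'   columns), `scores` (fit samples x n_pcs), `center`, `scale`,
#'   `variant_ids`, `fit_sample_ids`.
#' @export
fit_pcs <- function(norm, n_pcs = 20) {
  X <- norm$X
  n <- nrow(X)
  if (n < 2) stop("need at least 2 fit samples")
  ee <- eigen(tcrossprod(X), symmetric = TRUE)
  tol <- max(ee$values[1], 0) * n * .Machine$double.eps
  pos <- which(ee$values > max(tol, 1e-12))
  lambda <- ee$values[pos] / (n - 1)
  rank <- length(pos)
  p_keep <- min(n_pcs, rank)
  if (p_keep < n_pcs)
    warning("rank ", rank, " < requested ", n_pcs, " PCs; returning ",
            p_keep)
  if (p_keep == 0) {
    return(structure(list(eigenvalues = numeric(0),
                          loadings = matrix(0, ncol(X), 0),
                          scores = matrix(0, n, 0),
                          center = norm$center, scale = norm$scale,
                          variant_ids = norm$variant_ids,
                          fit_sample_ids = norm$fit_sample_ids),
                     class = "pca_model"))
  }
  U <- ee$vectors[, pos[seq_len(p_keep)], drop = FALSE]
  d <- sqrt(ee$values[pos[seq_len(p_keep)]])
  V <- crossprod(X, U) %*% diag(1 / d, p_keep)        # variants x p
  # deterministic sign: largest-|loading| entry positive per PC
  for (p in seq_len(p_keep)) {
    j <- which.max(abs(V[, p]))
    if (V[j, p] < 0) { V[, p] <- -V[, p]; U[, p] <- -U[, p] }
  }
  scores <- U %*% diag(d, p_keep)
  rownames(scores) <- rownames(X)
  colnames(scores) <- paste0("PC", seq_len(p_keep))
  colnames(V) <- paste0("PC", seq_len(p_keep))
  rownames(V) <- norm$variant_ids
  structure(list(eigenvalues = lambda, loadings = V, scores = scores,
                 center = norm$center, scale = norm$scale,
                 variant_ids = norm$variant_ids,
                 fit_sample_ids = norm$fit_sample_ids),
            class = "pca_model")
}

#' Project samples onto fitted principal components
#'
#' Held-out samples are normalised with the fit samples' centre and scale
#' (never their own) and multiplied by the loadings, the standard
#' projection that avoids shrinkage toward the projected samples' own
#' structure. Projecting a fit sample reproduces its fitted score.
#'
#' @param x a `genotype_matrix` containing the samples to project (must
#'   contain the model's variants).
#' @param model a `pca_model`.
#' @param sample_ids samples to project (default: all in `x`).
#' @return matrix of scores (samples x PCs).
#' @export
project_samples <- function(x, model, sample_ids = NULL) {
  stopifnot(inherits(x, "genotype_matrix"), inherits(model, "pca_model"))
  if (is.null(sample_ids)) sample_ids <- x$samples$id
  xs <- gm_subset(x, sample_ids = sample_ids,
                  variant_ids = model$variant_ids)
  g <- xs$calls
  Xn <- sweep(g, 2, model$center)
  Xn[is.na(g)] <- 0
  Xn <- sweep(Xn, 2, model$scale, "/")
  sc <- Xn %*% model$loadings
  rownames(sc) <- sample_ids
  sc
}

#' Iterative PCA outlier removal
#'
#' smartpca-style: fit PCs on the current fit set; flag any fit sample
#' whose score on any of the top `n_outlier_pcs` components lies more than
#' `sigma` standard deviations from that component's mean (mean and SD
#' over fit-sample scores); drop flagged samples and refit. Stops early
#' when an iteration flags nothing; always refits once at the end.
#' Defaults (10 PCs, 6 SD, 5 iterations) are smartpca's standard settings.
#'
#' @param x a `genotype_matrix`.
#' @param fit_sample_ids starting fit set (default: all samples).
#' @param n_pcs components computed per fit (default 20).
#' @param n_outlier_pcs components screened for outliers (default 10).
#' @param sigma SD threshold (default 6; `Inf` disables removal).
#' @param iterations maximum removal iterations (default 5).
#' @return list with `model` (final `pca_model`), `outliers` (character
#'   vector of removed ids), `outliers_by_iteration` (list).
#' @export
remove_outliers <- function(x, fit_sample_ids = NULL, n_pcs = 20,
                            n_outlier_pcs = 10, sigma = 6, iterations = 5) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (is.null(fit_sample_ids)) fit_sample_ids <- x$samples$id
  fit_ids <- fit_sample_ids
  by_iter <- list()
  for (it in seq_len(iterations)) {
    model <- suppressWarnings(
      fit_pcs(patterson_normalize(x, fit_ids), n_pcs))
    sc <- model$scores
    p_use <- min(n_outlier_pcs, ncol(sc))
    if (p_use == 0) break
    mu <- colMeans(sc[, seq_len(p_use), drop = FALSE])
    sd_ <- apply(sc[, seq_len(p_use), drop = FALSE], 2, stats::sd)
    sd_[sd_ == 0] <- Inf
    z <- abs(sweep(sweep(sc[, seq_len(p_use), drop = FALSE], 2, mu), 2,
                   sd_, "/"))
    flagged <- rownames(sc)[apply(z > sigma, 1, any)]
    by_iter[[it]] <- flagged
    if (!length(flagged)) break
    fit_ids <- setdiff(fit_ids, flagged)
    if (!length(fit_ids)) stop("all fit samples flagged as outliers")
  }
  model <- suppressWarnings(fit_pcs(patterson_normalize(x, fit_ids), n_pcs))
  list(model = model, outliers = setdiff(fit_sample_ids, fit_ids),
       outliers_by_iteration = by_iter)
}

#' Variance explained per principal component
#'
#' Each eigenvalue divided by the sum of all computed eigenvalues.
#'
#' @param model a `pca_model` (or a numeric eigenvalue vector).
#' @return numeric vector of fractions summing to 1.
#' @export
variance_explained <- function(model) {
  ev <- if (inherits(model, "pca_model")) model$eigenvalues else
    as.numeric(model)
  if (!length(ev)) return(numeric(0))
  ev / sum(ev)
}

#' Select the number of top PCs from a scree spectrum
#'
#' Automated elbow: the index maximising the second forward difference of
#' the descending variance-explained fractions (the sharpest flattening).
#' Analysts usually pick the elbow by eye, so `override` lets a
#' config pin the count. A flat spectrum returns the minimum of 2 with a
#' warning.
#'
#' @param fractions variance-explained fractions, descending (at least 3).
#' @param override integer to force, bypassing the elbow rule.
#' @return integer count of top PCs.
#' @export
select_top_pcs <- function(fractions, override = NULL) {
  if (!is.null(override)) {
    stopifnot(override >= 1)
    return(as.integer(override))
  }
  stopifnot(length(fractions) >= 3)
  f <- sort(fractions, decreasing = TRUE)
  d2 <- f[-(1:2)] - 2 * f[-c(1, length(f))] + f[-((length(f) - 1):length(f))]
  if (max(d2) <= 1e-12) {
    warning("flat scree spectrum; defaulting to 2 PCs")
    return(2L)
  }
  max(2L, as.integer(which.max(d2)))
}

#' Write scores in an evec-like layout
#'
#' Tab-separated: sample id, one column per PC, then a group label column
#' (the EIGENSOFT .evec convention).
#'
#' @param scores samples x PCs matrix with rownames.
#' @param path output path.
#' @param labels optional character vector of group labels (recycled "???"
#'   when absent).
#' @export
write_evec <- function(scores, path, labels = NULL) {
  if (is.null(labels)) labels <- rep("???", nrow(scores))
  df <- data.frame(id = rownames(scores), scores, label = labels,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
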