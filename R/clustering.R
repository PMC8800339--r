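#' K-means on top principal components
#'
#' Lloyd's algorithm with k-means++-style seeding, run `restarts` times
#' and keeping the solution with the lowest within-cluster sum of squares.
#' PCs are equally weighted (plain Euclidean distance). An empty cluster
#' arising during an update is re-seeded from the point farthest from its
#' assigned centroid. Deterministic under `seed`.
#'
#' @param scores numeric matrix, samples x top PCs (rownames = sample ids).
#' @param k number of clusters, `1 <= k <= n`.
#' @param restarts independent seedings (default 25).
#' @param seed integer seed (`NULL` leaves the RNG stream untouched).
#' @param max_iter Lloyd iteration cap per restart.
#' @return list with `labels` (integer vector in `1..k`, named), `centers`,
#'   `withinss` (per cluster), `tot_withinss`, `betweenss`, `totss`.
#' @export
kmeans_fit <- function(scores, k, restarts = 25, seed = NULL,
                       max_iter = 100) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  stopifnot(k >= 1, k <= n)
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    res <- kmeans_once(scores, k, max_iter)
    if (is.null(best) || res$tot_withinss < best$tot_withinss) best <- res
  }
  center_means <- colMeans(scores)
  totss <- sum(sweep(scores, 2, center_means)^2)
  best$totss <- totss
  best$betweenss <- totss - best$tot_withinss
  names(best$labels) <- rownames(scores)
  best
}

# one k-means++ seeding + Lloyd run
kmeans_once <- function(X, k, max_iter) {
  n <- nrow(X)
  # k-means++ seeding
  centers <- X[sample.int(n, 1), , drop = FALSE]
  if (k > 1) {
    d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
    for (j in 2:k) {
      probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      pick <- sample.int(n, 1, prob = probs)
      centers <- rbind(centers, X[pick, , drop = FALSE])
      d2 <- pmin(d2, rowSums(sweep(X, 2, X[pick, ])^2))
    }
  }
  labels <- integer(n)
  for (it in seq_len(max_iter)) {
    dmat <- point_center_dist2(X, centers)
    new_labels <- max.col(-dmat, ties.method = "first")
    # empty-cluster repair: reseed from the farthest point
    repeat {
      sizes <- tabulate(new_labels, k)
      empty <- which(sizes == 0)
      if (!length(empty)) break
      cur_d <- dmat[cbind(seq_len(n), new_labels)]
      far <- which.max(cur_d)
      centers[empty[1], ] <- X[far, ]
      dmat[, empty[1]] <- rowSums(sweep(X, 2, centers[empty[1], ])^2)
      new_labels <- max.col(-dmat, ties.method = "first")
    }
    if (identical(new_labels, labels)) break
    labels <- new_labels
    for (j in seq_len(k))
      centers[j, ] <- colMeans(X[labels == j, , drop = FALSE])
  }
  withinss <- vapply(seq_len(k), function(j) {
    pts <- X[labels == j, , drop = FALSE]
    sum(sweep(pts, 2, colMeans(pts))^2)
  }, 0)
  list(labels = labels, centers = centers, withinss = withinss,
       tot_withinss = sum(withinss))
}

point_center_dist2 <- function(X, centers) {
  cross <- X %*% t(centers)
  xx <- rowSums(X^2)
  cc <- rowSums(centers^2)
  outer(xx, cc, "+") - 2 * cross
}

#' Average silhouette width of a partition
#'
#' Standard silhouette with Euclidean distance on the supplied scores:
#' `s(i) = (b - a) / max(a, b)` with `a` the mean distance to the sample's
#' own cluster (excluding itself) and `b` the smallest mean distance to
#' another cluster; members of singleton clusters score 0.
#'
#' @param scores samples x PCs matrix.
#' @param labels integer/character cluster labels, at least 2 clusters.
#' @return average silhouette width in `[-1, 1]`.
#' @export
silhouette_width <- function(scores, labels) {
  scores <- as.matrix(scores)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2) stop("silhouette needs at least 2 clusters")
  d <- as.matrix(stats::dist(scores))
  n <- nrow(scores)
  s <- numeric(n)
  sizes <- tabulate(labels, k)
  for (i in seq_len(n)) {
    li <- labels[i]
    if (sizes[li] == 1) { s[i] <- 0; next }
    a <- sum(d[i, labels == li]) / (sizes[li] - 1)
    b <- min(vapply(setdiff(seq_len(k), li), function(j)
      mean(d[i, labels == j]), 0))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Silhouette-guided choice of k for K-means
#'
#' Fits K-means for every k in `kmin:kmax`, scores each partition by
#' average silhouette width, and picks the k with the largest (ties to the
#' smaller k). The full silhouette-vs-k table is returned so a deliberate
#' override — e.g. an analyst deliberately taking the second-best k for
#' one group — stays an explicit, recorded choice.
#'
#' @param scores samples x top-PC matrix.
#' @param kmin,kmax scan range (defaults 2 and 20); `kmax < n`.
#' @param restarts,seed passed to [kmeans_fit()]; per-k seeds are derived
#'   from `seed` so the table is reproducible.
#' @param override integer k to force; silhouettes are still computed and
#'   reported.
#' @return a `cluster_result`: list with `chosen_k`, `labels` (for the
#'   chosen k), `silhouette` (data.frame k / avg_silhouette),
#'   `tot_withinss`, `betweenss`, `totss`, `seed`, `restarts`, `override`.
#' @export
select_k <- function(scores, kmin = 2, kmax = 20, restarts = 25, seed = 1,
                     override = NULL) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  stopifnot(kmin >= 2, kmax >= kmin)
  kmax <- min(kmax, n - 1)
  fits <- list(); sil <- rep(NA_real_, kmax - kmin + 1)
  ks <- kmin:kmax
  for (i in seq_along(ks)) {
    fit <- kmeans_fit(scores, ks[i], restarts = restarts,
                      seed = seed + ks[i])
    fits[[i]] <- fit
    sil[i] <- silhouette_width(scores, fit$labels)
  }
  tab <- data.frame(k = ks, avg_silhouette = sil)
  chosen <- if (!is.null(override)) as.integer(override) else
    ks[which.max(sil)]
  fit <- if (chosen %in% ks) fits[[match(chosen, ks)]] else
    kmeans_fit(scores, chosen, restarts = restarts, seed = seed + chosen)
  structure(list(chosen_k = chosen, labels = fit$labels, silhouette = tab,
                 tot_withinss = fit$tot_withinss,
                 betweenss = fit$betweenss, totss = fit$totss,
                 seed = seed, restarts = restarts, override = override),
            class = "cluster_result")
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement; 1 for identical partitions (up to label
#' permutation), about 0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return numeric ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(a))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (max_idx - expected)
}
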