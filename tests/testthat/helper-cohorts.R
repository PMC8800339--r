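# Shared fixture builders and independent oracles. Everything is generated
# in code; no binary fixtures.

# a flat spec: K continents, one subpopulation each, no admixture
flat_spec <- function(K = 2, F = 0.1, n = 50, n_snps = 2000, seed = 1,
                      ...) {
  conts <- lapply(seq_len(K), function(k)
    list(name = paste0("C", k), F = F,
         subpops = list(list(name = paste0("P", k), F = 0, n = n,
                             region = paste0("R", k)))))
  population_spec(conts, n_snps = n_snps, seed = seed, ...)
}

# one continent, several subpopulations diverged F_s each
subpop_spec <- function(n_sub = 3, F_s = 0.01, n = 100, n_snps = 20000,
                        seed = 1, ...) {
  subs <- lapply(seq_len(n_sub), function(s)
    list(name = paste0("P", s), F = F_s, n = n, region = paste0("R", s)))
  population_spec(list(list(name = "C1", F = 0, subpops = subs)),
                  n_snps = n_snps, seed = seed, ...)
}

# small genotype_matrix straight from a call matrix
gm_from_calls <- function(calls, chrom = NULL, pos = NULL) {
  n <- nrow(calls); m <- ncol(calls)
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  genotype_matrix(
    calls,
    data.frame(id = sprintf("S%03d", seq_len(n))),
    data.frame(id = sprintf("v%03d", seq_len(m)), chrom = chrom, pos = pos,
               ref = rep("A", m), alt = rep("G", m)))
}

# brute-force maximum independent set size for small related-pair graphs
mis_size <- function(pairs, ids) {
  n <- length(ids)
  best <- 0L
  for (mask in 0:(2^n - 1)) {
    sel <- ids[bitwAnd(bitwShiftR(mask, seq_len(n) - 1L), 1L) == 1L]
    ok <- TRUE
    if (nrow(pairs)) {
      for (r in seq_len(nrow(pairs))) {
        if (pairs$id1[r] %in% sel && pairs$id2[r] %in% sel) {
          ok <- FALSE; break
        }
      }
    }
    if (ok) best <- max(best, length(sel))
  }
  best
}

# exhaustive post-prune LD certificate: TRUE when no retained pair within
# window_bp (same chromosome) exceeds the threshold
prune_certificate <- function(gm, kept_ids, window_bp = 50000,
                              threshold = 0.025, sample_ids = NULL) {
  sub <- gm_subset(gm, sample_ids = sample_ids, variant_ids = kept_ids)
  v <- sub$variants
  for (cc in unique(v$chrom)) {
    j <- which(v$chrom == cc)
    for (a in seq_along(j)) {
      for (b in seq_along(j)) {
        if (a >= b) next
        if (abs(v$pos[j[a]] - v$pos[j[b]]) > window_bp) next
        if (ld_r2(sub$calls[, j[a]], sub$calls[, j[b]]) > threshold)
          return(FALSE)
      }
    }
  }
  TRUE
}

# independent silhouette evaluation, straight from the formula
silhouette_oracle <- function(scores, labels) {
  scores <- as.matrix(scores)
  d <- as.matrix(dist(scores))
  labs <- as.character(labels)
  u <- unique(labs)
  s <- numeric(nrow(scores))
  for (i in seq_len(nrow(scores))) {
    own <- which(labs == labs[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(setdiff(u, labs[i]), function(l)
      mean(d[i, labs == l]), 0))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
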