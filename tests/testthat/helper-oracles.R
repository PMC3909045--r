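# Brute-force reference implementations, kept deliberately naive and
# independent of the package code paths they check.

# UPGMA by direct agglomeration: at every step merge the pair of clusters
# with the smallest mean pairwise inter-cluster distance, recomputed from
# the full distance matrix each time. Returns sorted merge heights.
oracle_upgma_heights <- function(x) {
  d <- as.matrix(dist(x))
  clusters <- as.list(seq_len(nrow(x)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      h <- mean(d[clusters[[i]], clusters[[j]]])
      if (h < best_h) { best_h <- h; best <- c(i, j) }
    }
    heights <- c(heights, best_h)
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
  }
  heights
}

# AUC as the exhaustive pairwise win fraction (ties count half)
oracle_auc_pairwise <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  wins <- 0
  for (p in pos) for (q in neg)
    wins <- wins + (p > q) + 0.5 * (p == q)
  wins / (length(pos) * length(neg))
}

# Kruskal-Wallis H from first principles: mid-ranks, tie correction
oracle_kruskal_h <- function(groups) {
  values <- unlist(groups)
  r <- rank(values)
  n <- length(values)
  idx <- rep(seq_along(groups), lengths(groups))
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, idx, function(ri) length(ri) * (mean(ri) - (n + 1) / 2)^2))
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Spearman rho as the Pearson correlation of mid-ranks, computed longhand
oracle_spearman_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) / sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# PCA scores via eigendecomposition of the covariance matrix of the
# scaled data (the package uses the SVD route)
oracle_pca_scores <- function(x, k, scale = TRUE) {
  xs <- base::scale(x, center = TRUE, scale = scale)
  ev <- eigen(stats::cov(xs) * (nrow(x) - 1) / (nrow(x) - 1), symmetric = TRUE)
  v <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) v[, j] <- -v[, j]
  }
  xs %*% v
}
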