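# Independent oracles and small fixture builders used across the suite.

# Brute-force per-voxel accumulation of region means.
oracle_region_means <- function(map, atlas) {
  p <- atlas$pairs
  one <- function(label) {
    tot <- 0; n <- 0
    for (i in seq_len(dim(map)[1])) for (j in seq_len(dim(map)[2]))
      for (k in seq_len(dim(map)[3]))
        if (atlas$label_grid[i, j, k] == label) {
          tot <- tot + map[i, j, k]; n <- n + 1
        }
    tot / n
  }
  data.frame(pair_id = p$pair_id,
             left_value = vapply(p$left_label, one, 0),
             right_value = vapply(p$right_label, one, 0))
}

# Normal-equations least squares residuals.
oracle_ls_residuals <- function(Y, X) {
  beta <- solve(t(X) %*% X, t(X) %*% Y)
  Y - X %*% beta
}

# Naive O(n^3) agglomerative clustering with average linkage on a
# dissimilarity matrix; returns the merge heights and the member sets formed.
oracle_average_linkage <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  active <- rep(TRUE, n)
  D <- as.matrix(D); diag(D) <- Inf
  heights <- numeric(0)
  sets <- list()
  while (sum(active) > 1) {
    idx <- which(active)
    best <- c(NA, NA); bestd <- Inf
    for (a in idx) for (b in idx) if (a < b) {
      # average linkage: mean pairwise dissimilarity between member sets
      d <- mean(outer(clusters[[a]], clusters[[b]],
                      Vectorize(function(x, y) D[x, y])))
      if (d < bestd) { bestd <- d; best <- c(a, b) }
    }
    heights <- c(heights, bestd)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[1]]] <- merged
    active[best[2]] <- FALSE
    sets[[length(sets) + 1L]] <- sort(merged)
  }
  list(heights = heights, sets = sets)
}

# Independent probit refit of the multiscale-bootstrap AU model from a BP
# table: weighted regression of qnorm(1-bp) on sqrt(rho) and 1/sqrt(rho).
oracle_au_refit <- function(bp, rho, B) {
  use <- bp > 0 & bp < 1
  y <- qnorm(1 - bp[use])
  d <- data.frame(y = y, x1 = sqrt(rho[use]), x2 = 1 / sqrt(rho[use]))
  w <- B * dnorm(y)^2 / (bp[use] * (1 - bp[use]))
  fit <- lm(y ~ 0 + x1 + x2, data = d, weights = w)
  v <- coef(fit)[["x1"]]; cc <- coef(fit)[["x2"]]
  list(v = v, c = cc, au = 1 - pnorm(v - cc))
}

# One-sided sign-test p by direct binomial pmf summation.
oracle_sign_p <- function(k, n) {
  sum(vapply(k:n, function(j) choose(n, j) * 0.5^n, 0))
}

# Small planted-truth builder shared by several tests.
small_truth <- function(n_pairs = 12, left = 1:3, right = 4:5, ...) {
  cohort_truth(n_pairs = n_pairs, planted_left = left, planted_right = right,
               ...)
}
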