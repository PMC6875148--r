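#' Agglomerative clustering of the intrinsic-connectivity matrix
#'
#' Hierarchical clustering on the dissimilarity `d = 1 - r` derived from the
#' group mean correlation matrix. Average linkage (UPGMA) is the default;
#' Ward and complete linkage are available. Deterministic given its input and
#' invariant under region relabeling (up to label permutation).
#'
#' @param group_mean_r symmetric correlation matrix with unit diagonal,
#'   dimnames giving region ids.
#' @param linkage `"average"`, `"complete"` or `"ward.D2"`.
#' @return an `hclust` object.
#' @export
hierarchical_cluster <- function(group_mean_r,
                                 linkage = c("average", "complete", "ward.D2")) {
  linkage <- match.arg(linkage)
  if (!isSymmetric(unname(group_mean_r), tol = 1e-8))
    stop("group_mean_r must be symmetric")
  d <- as.dist(1 - group_mean_r)
  hclust(d, method = linkage)
}

# Leaf-label membership of every internal node, as sorted character keys.
node_member_keys <- function(hc) {
  n <- length(hc$labels %||% seq_len(nrow(hc$merge) + 1L))
  labs <- hc$labels %||% as.character(seq_len(n))
  members <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    m <- hc$merge[i, ]
    take <- function(j) if (j < 0) labs[-j] else members[[j]]
    members[[i]] <- c(take(m[1]), take(m[2]))
  }
  vapply(members, function(v) paste(sort(v), collapse = "|"), "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Multiscale-bootstrap AU support for dendrogram nodes
#'
#' Resamples participants with replacement at several sample-size ratios,
#' recomputes the Fisher-z-averaged group matrix and its dendrogram at each
#' resample, and records per reference node the fraction of resamples in
#' which the node's exact member set reappears (the bootstrap proportion
#' BP(rho)). The approximately unbiased (AU) p value extrapolates these
#' proportions through the signed-distance/curvature probit model
#' `qnorm(1 - BP(rho)) = v*sqrt(rho) + c/sqrt(rho)` fit by weighted least
#' squares; `AU = 1 - pnorm(v - c)`. BP is reported at `rho = 1`.
#'
#' A node recovered in every resample at every scale has AU = BP = 1; a node
#' never recovered has AU = 0 (flagged); a non-finite fit falls back to BP
#' with a warning.
#'
#' @param cstack a `connectivity_stack` (per-subject matrices; group means
#'   are recomputed internally per resample).
#' @param scales resample-size ratios spanning values below and above 1.
#' @param B bootstrap replicates per scale (>= 100).
#' @param seed RNG seed; AU values are reproducible given (seed, scales, B).
#' @param linkage linkage method passed to [hierarchical_cluster()].
#' @return object of class `au_dendrogram`: list with `hclust` (reference
#'   dendrogram from the full group matrix), `nodes` (per internal node:
#'   members, height, `bp`, `au`, fit coefficients `v`, `c`, `flag`),
#'   `scales`, `B`, `seed`.
#' @export
multiscale_bootstrap_au <- function(cstack, scales = seq(0.5, 1.4, by = 0.1),
                                    B = 1000, seed = 1L,
                                    linkage = "average") {
  stopifnot(inherits(cstack, "connectivity_stack"))
  if (B < 100) stop("B must be >= 100")
  if (!any(scales < 1) || !any(scales >= 1))
    stop("scales must span values below and above 1")
  cstack <- group_connectivity(cstack)
  hc <- hierarchical_cluster(cstack$group_mean_r, linkage = linkage)
  ref_keys <- node_member_keys(hc)
  n_nodes <- length(ref_keys)
  n_sub <- dim(cstack$cor)[3]
  zt <- atanh(pmin(pmax(cstack$cor, -1 + 1e-15), 1 - 1e-15))
  for (k in seq_len(dim(zt)[1])) zt[k, k, ] <- 0
  labs <- dimnames(cstack$cor)[[1]]
  n_r <- length(labs)
  counts <- matrix(0L, n_nodes, length(scales))
  m_used <- integer(length(scales))
  withr_seed(seed, {
    for (si in seq_along(scales)) {
      m <- max(2L, as.integer(ceiling(scales[si] * n_sub)))
      m_used[si] <- m
      for (b in seq_len(B)) {
        idx <- sample.int(n_sub, m, replace = TRUE)
        mz <- rowMeans(zt[, , idx, drop = FALSE], dims = 2)
        r <- tanh(mz)
        diag(r) <- 1
        bh <- hclust(as.dist(1 - r), method = linkage)
        bh$labels <- labs
        keys <- node_member_keys(bh)
        hit <- ref_keys %in% keys
        counts[hit, si] <- counts[hit, si] + 1L
      }
    }
  })
  rho <- m_used / n_sub
  bp_mat <- counts / B
  fit <- fit_au_model(bp_mat, rho, B)
  heights <- hc$height
  nodes <- data.frame(node = seq_len(n_nodes), members = ref_keys,
                      size = lengths(strsplit(ref_keys, "|", fixed = TRUE)),
                      height = heights, bp = fit$bp1, au = fit$au,
                      v = fit$v, c = fit$c, flag = fit$flag)
  structure(list(hclust = hc, nodes = nodes, bp_table = bp_mat,
                 scales = rho, B = B, seed = seed, linkage = linkage,
                 group_mean_r = cstack$group_mean_r),
            class = "au_dendrogram")
}

# Probit-model fit of AU from a node x scale BP table.
# Exposed internally so tests can refit independently of the bootstrap loop.
fit_au_model <- function(bp_mat, rho, B) {
  n_nodes <- nrow(bp_mat)
  au <- v <- cc <- numeric(n_nodes)
  flag <- character(n_nodes)
  near1 <- which.min(abs(rho - 1))
  for (i in seq_len(n_nodes)) {
    bp <- bp_mat[i, ]
    if (all(bp == 1)) { au[i] <- 1; v[i] <- NA; cc[i] <- NA; flag[i] <- "certain"; next }
    if (all(bp == 0)) { au[i] <- 0; v[i] <- NA; cc[i] <- NA; flag[i] <- "never_recovered"; next }
    use <- bp > 0 & bp < 1
    if (sum(use) < 2) {
      au[i] <- bp[near1]; v[i] <- NA; cc[i] <- NA; flag[i] <- "fallback_bp"
      next
    }
    y <- qnorm(1 - bp[use])
    x1 <- sqrt(rho[use]); x2 <- 1 / sqrt(rho[use])
    w <- B * dnorm(y)^2 / (bp[use] * (1 - bp[use]))
    X <- cbind(x1, x2)
    cf <- tryCatch(solve(crossprod(X * sqrt(w)), crossprod(X, w * y)),
                   error = function(e) NULL)
    if (is.null(cf) || !all(is.finite(cf))) {
      warning("non-finite AU fit for node ", i, "; falling back to BP")
      au[i] <- bp[near1]; v[i] <- NA; cc[i] <- NA; flag[i] <- "fallback_bp"
      next
    }
    v[i] <- cf[1]; cc[i] <- cf[2]
    au[i] <- 1 - pnorm(cf[1] - cf[2])
    flag[i] <- "ok"
  }
  list(au = au, v = v, c = cc, bp1 = bp_mat[, near1], flag = flag)
}

#' Cut a dendrogram into networks
#'
#' Either cuts to a fixed number of clusters (`rule = list(fixed_k = k)`), or
#' returns the maximal AU-supported clusters covering all regions
#' (`rule = list(au_threshold = p)`): the largest non-root nodes with
#' `AU >= p`, chosen greedily and disjointly, remaining regions becoming
#' singleton networks. Networks are labeled 1..K in decreasing size.
#'
#' @param dend an `hclust` (fixed_k only) or `au_dendrogram`.
#' @param rule a one-element list, `fixed_k` or `au_threshold`.
#' @return object of class `network_partition`: `assignment` (named integer
#'   vector, region id to network), `n_networks`, `dendrogram`, `nodes` (AU
#'   table when available).
#' @export
cut_partition <- function(dend, rule = list(fixed_k = 2)) {
  hc <- if (inherits(dend, "au_dendrogram")) dend$hclust else dend
  n <- length(hc$labels %||% seq_len(nrow(hc$merge) + 1L))
  if (!is.null(rule$fixed_k)) {
    k <- rule$fixed_k
    if (k > n) stop("k exceeds the number of regions")
    asg <- cutree(hc, k = k)
  } else if (!is.null(rule$au_threshold)) {
    if (!inherits(dend, "au_dendrogram"))
      stop("au_threshold rule requires an au_dendrogram")
    nodes <- dend$nodes
    root <- which.max(nodes$size)  # root spans all regions
    cand <- nodes[nodes$node != nodes$node[root] &
                    nodes$au >= rule$au_threshold, , drop = FALSE]
    cand <- cand[order(-cand$size), , drop = FALSE]
    labs <- hc$labels %||% as.character(seq_len(n))
    asg <- setNames(rep(NA_integer_, n), labs)
    net <- 0L
    for (i in seq_len(nrow(cand))) {
      mem <- strsplit(cand$members[i], "|", fixed = TRUE)[[1]]
      if (all(is.na(asg[mem]))) {
        net <- net + 1L
        asg[mem] <- net
      }
    }
    for (l in labs[is.na(asg)]) {
      net <- net + 1L
      asg[l] <- net
    }
  } else stop("rule must specify fixed_k or au_threshold")
  # relabel by decreasing size, ties by first appearance
  sizes <- table(asg)
  newlab <- setNames(seq_along(sizes), names(sort(sizes, decreasing = TRUE)))
  asg <- setNames(as.integer(newlab[as.character(asg)]), names(asg))
  structure(list(assignment = asg, n_networks = length(unique(asg)),
                 dendrogram = dend,
                 nodes = if (inherits(dend, "au_dendrogram")) dend$nodes),
            class = "network_partition")
}

#' @export
print.network_partition <- function(x, ...) {
  cat(sprintf("Network partition: %d networks over %d regions\n",
              x$n_networks, length(x$assignment)))
  for (k in sort(unique(x$assignment)))
    cat(sprintf("  network %d (%d): %s\n", k, sum(x$assignment == k),
                paste(names(x$assignment)[x$assignment == k], collapse = ", ")))
  invisible(x)
}

#' Export a dendrogram as Newick text
#'
#' @param dend an `hclust` or `au_dendrogram`.
#' @return a single Newick string (also usable with [ape::read.tree()]).
#' @export
dendrogram_newick <- function(dend) {
  hc <- if (inherits(dend, "au_dendrogram")) dend$hclust else dend
  phy <- ape::as.phylo(hc)
  ape::write.tree(phy)
}

#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie adjusted Rand index; 1 for identical partitions (up to
#' label permutation), ~0 for independent ones.
#'
#' @param a,b cluster label vectors of equal length (names ignored).
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / ch2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
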