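# Build a small preprocessed-flagged stack from raw matrices.
stack_from <- function(mats, tr = 2) {
  s <- region_series_stack(mats, tr = tr)
  s$nuisance_regressed <- TRUE
  s$filtered <- TRUE
  s
}

test_that("subject correlations match the covariance definition", {
  set.seed(1)
  Y <- matrix(rnorm(200 * 4), 200, 4,
              dimnames = list(NULL, c("L1", "L2", "R3", "R4")))
  cs <- subject_correlations(stack_from(list(Y)))
  want <- cov(Y) / outer(apply(Y, 2, sd), apply(Y, 2, sd))
  expect_equal(unname(cs$cor[, , 1]), unname(want), tolerance = 1e-12)
  # anti-phase sinusoids correlate at -1; duplicated region at +1
  t <- 1:100
  Z <- cbind(L1 = sin(t / 5), L2 = -sin(t / 5), R9 = sin(t / 5))
  cz <- subject_correlations(stack_from(list(Z)))$cor[, , 1]
  expect_equal(cz["L1", "L2"], -1, tolerance = 1e-12)
  expect_equal(cz["L1", "R9"], 1, tolerance = 1e-12)
  # constant series named in the error
  bad <- cbind(L1 = rnorm(50), L7 = rep(1, 50))
  expect_error(subject_correlations(stack_from(list(bad))), "L7")
})

test_that("unpreprocessed stacks are flagged", {
  Y <- matrix(rnorm(100 * 2), 100, 2, dimnames = list(NULL, c("L1", "L2")))
  raw <- region_series_stack(list(Y), tr = 2)
  expect_warning(subject_correlations(raw), "preprocessed")
})

test_that("Fisher z is atanh with its inverse, monotone and odd", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.62), 0.7250, tolerance = 1e-4)
  expect_equal(fisher_z(-0.3), -fisher_z(0.3), tolerance = 1e-14)
  expect_equal(fisher_z_inverse(fisher_z(0.3)), 0.3, tolerance = 1e-14)
  r <- seq(-0.9, 0.9, by = 0.1)
  expect_true(all(diff(fisher_z(r)) > 0))
  expect_error(fisher_z(1), "domain")
})

test_that("group averaging happens on the z scale, not the r scale", {
  # two subjects with skewed correlations: tanh(mean z) != mean r
  mk <- function(r) {
    m <- matrix(c(1, r, r, 1), 2, 2, dimnames = list(c("L1", "L2"),
                                                     c("L1", "L2")))
    m
  }
  cs <- structure(list(cor = array(c(mk(0.95), mk(0.1)), dim = c(2, 2, 2),
                                   dimnames = list(c("L1", "L2"),
                                                   c("L1", "L2"), NULL))),
                  class = "connectivity_stack")
  g <- group_connectivity(cs)
  z_way <- tanh(mean(atanh(c(0.95, 0.1))))
  r_way <- mean(c(0.95, 0.1))
  expect_equal(g$group_mean_r["L1", "L2"], z_way, tolerance = 1e-12)
  expect_gt(abs(g$group_mean_r["L1", "L2"] - r_way), 0.05)
  expect_equal(g$group_mean_r, tanh(g$group_mean_z), ignore_attr = TRUE)
})

test_that("average-linkage merges match a naive O(n^3) oracle", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 8
    R <- cov2cor(crossprod(matrix(rnorm(n * n * 3), n * 3, n)))
    dimnames(R) <- list(paste0("L", 1:n), paste0("L", 1:n))
    hc <- hierarchical_cluster(R)
    orc <- oracle_average_linkage(1 - R)
    expect_equal(hc$height, orc$heights, tolerance = 1e-12)
    got_sets <- lapply(seq_len(nrow(hc$merge)), function(i) {
      km <- latnet:::node_member_keys(hc)[i]
      sort(match(strsplit(km, "|", fixed = TRUE)[[1]], rownames(R)))
    })
    expect_equal(got_sets, orc$sets)
  }
})

test_that("two exact blocks separate at the first cut, invariant to ordering", {
  R <- matrix(0, 6, 6)
  R[1:3, 1:3] <- 0.9; R[4:6, 4:6] <- 0.9; diag(R) <- 1
  ids <- c("L1", "L2", "L3", "R4", "R5", "R6")
  dimnames(R) <- list(ids, ids)
  hc <- hierarchical_cluster(R)
  k2 <- cutree(hc, 2)
  expect_equal(unname(k2), c(1, 1, 1, 2, 2, 2))
  perm <- c(4, 1, 6, 2, 5, 3)
  hp <- hierarchical_cluster(R[perm, perm])
  expect_equal(adjusted_rand_index(cutree(hp, 2)[ids], k2), 1)
  expect_error(hierarchical_cluster(matrix(c(1, 0.2, 0.5, 1), 2, 2)),
               "symmetric")
})

# A two-block connectivity stack with clear structure, used for AU tests.
two_block_stack <- function(n_sub = 30, seed = 5) {
  truth <- small_truth(8, left = 1:5, right = 6:8, within_network_r = 0.6,
                       between_network_r = 0)
  rest <- simulate_resting_series(1:8, truth, n_subjects = n_sub,
                                  n_volumes = 240, tr = 2, drift_sd = 0,
                                  nuisance_scale = 0, seed = seed)
  s <- as_region_series_stack(rest)
  s$nuisance_regressed <- TRUE; s$filtered <- TRUE
  subject_correlations(s)
}

test_that("AU supports well-separated planted clusters", {
  cs <- two_block_stack()
  au <- multiscale_bootstrap_au(cs, B = 200, seed = 9)
  nodes <- au$nodes
  left_key <- paste(sort(paste0("L", 1:5)), collapse = "|")
  right_key <- paste(sort(paste0("R", 6:8)), collapse = "|")
  expect_gte(nodes$au[nodes$members == left_key], 0.95)
  expect_gte(nodes$au[nodes$members == right_key], 0.95)
  # AU >= BP near certainty under positive curvature
  hi <- nodes$bp > 0.9 & nodes$flag == "ok" & nodes$c > 0
  expect_true(all(nodes$au[hi] >= nodes$bp[hi] - 0.02))
  # reproducible given (seed, scales, B)
  au2 <- multiscale_bootstrap_au(cs, B = 200, seed = 9)
  expect_equal(au2$nodes$au, nodes$au)
})

test_that("a node recovered always has AU = BP = 1; probit fit matches a refit", {
  bp_tab <- rbind(rep(1, 10),
                  c(0.62, 0.68, 0.74, 0.78, 0.82, 0.85, 0.88, 0.90, 0.92, 0.93))
  rho <- seq(0.5, 1.4, by = 0.1)
  fit <- latnet:::fit_au_model(bp_tab, rho, B = 1000)
  expect_equal(fit$au[1], 1)
  expect_equal(fit$flag[1], "certain")
  orc <- oracle_au_refit(bp_tab[2, ], rho, B = 1000)
  expect_equal(fit$v[2], orc$v, tolerance = 1e-8)
  expect_equal(fit$c[2], orc$c, tolerance = 1e-8)
  expect_equal(fit$au[2], orc$au, tolerance = 1e-8)
  # never-recovered node flagged at AU 0
  gone <- latnet:::fit_au_model(rbind(rep(0, 10)), rho, B = 1000)
  expect_equal(gone$au, 0)
  expect_equal(gone$flag, "never_recovered")
})

test_that("AU is invariant to region ordering", {
  cs <- two_block_stack()
  perm <- sample(8)
  cs_perm <- cs
  cs_perm$cor <- cs$cor[perm, perm, , drop = FALSE]
  au1 <- multiscale_bootstrap_au(cs, B = 150, seed = 4)
  au2 <- multiscale_bootstrap_au(cs_perm, B = 150, seed = 4)
  n1 <- au1$nodes[order(au1$nodes$members), ]
  n2 <- au2$nodes[order(au2$nodes$members), ]
  expect_equal(n1$members, n2$members)
  expect_equal(n1$au, n2$au, tolerance = 0.12)  # resampling noise only
})

test_that("partition cutting honours fixed_k and au_threshold rules", {
  cs <- two_block_stack()
  au <- multiscale_bootstrap_au(cs, B = 150, seed = 2)
  truth_lab <- c(rep(1, 5), rep(2, 3))
  p2 <- cut_partition(au, list(fixed_k = 2))
  expect_equal(adjusted_rand_index(p2$assignment, truth_lab), 1)
  expect_equal(p2$n_networks, 2)
  pn <- cut_partition(au$hclust, list(fixed_k = 8))
  expect_equal(pn$n_networks, 8)
  expect_error(cut_partition(au, list(fixed_k = 9)), "exceeds")
  # au_threshold = 0 returns the two children of the root
  p0 <- cut_partition(au, list(au_threshold = 0))
  expect_equal(adjusted_rand_index(p0$assignment, truth_lab), 1)
  expect_error(cut_partition(au$hclust, list(au_threshold = 0.9)),
               "au_dendrogram")
  expect_error(cut_partition(au, list()), "rule")
})

test_that("bootstrap argument contracts are enforced", {
  cs <- two_block_stack(n_sub = 10)
  expect_error(multiscale_bootstrap_au(cs, B = 50), "B must be")
  expect_error(multiscale_bootstrap_au(cs, scales = c(1, 1.2), B = 200),
               "span")
})

test_that("Newick export round-trips through ape with the right tips", {
  cs <- two_block_stack()
  au <- multiscale_bootstrap_au(cs, B = 150, seed = 3)
  nwk <- dendrogram_newick(au)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, dimnames(cs$cor)[[1]])
})

test_that("adjusted Rand index agrees with mclust and scores the extremes", {
  a <- c(1, 1, 2, 2, 3, 3)
  b <- c(2, 2, 3, 3, 1, 1)
  expect_equal(adjusted_rand_index(a, b), 1)
  set.seed(8)
  x <- sample(1:3, 40, TRUE); y <- sample(1:3, 40, TRUE)
  skip_if_not_installed("mclust")
  expect_equal(adjusted_rand_index(x, y), mclust::adjustedRandIndex(x, y),
               tolerance = 1e-12)
})
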