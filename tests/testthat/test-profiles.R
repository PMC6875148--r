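test_that("single-region two-task F equals the squared paired t", {
  set.seed(55)
  n <- 24
  d <- data.frame(subject_id = rep(1:n, 2),
                  pair_id = 1,
                  task = rep(c("PROD", "LISN"), each = n),
                  left_value = rnorm(2 * n, c(rep(0.4, n), rep(0.1, n)), 0.3),
                  right_value = rnorm(2 * n, 0, 0.3))
  tab <- compute_asymmetries(d)
  eff <- suppressWarnings(fit_mixed_model(tab, "asymmetry"))
  a <- tab$asymmetry[tab$task == "PROD"] - tab$asymmetry[tab$task == "LISN"]
  tt <- t.test(a)
  expect_equal(eff$F[eff$term == "Task"], unname(tt$statistic)^2,
               tolerance = 1e-8)
  expect_equal(eff$p[eff$term == "Task"], tt$p.value, tolerance = 1e-6)
})

test_that("fitted marginal task means reproduce cell means on balanced data", {
  truth <- small_truth(4, left = 1:2, right = 3:4)
  tab <- simulate_task_table(truth, n_subjects = 30, seed = 66)
  long <- rbind(
    data.frame(subject = tab$subject_id, roi = tab$pair_id, task = tab$task,
               side = "left", value = tab$left_value),
    data.frame(subject = tab$subject_id, roi = tab$pair_id, task = tab$task,
               side = "right", value = tab$right_value))
  fit <- lmerTest::lmer(value ~ factor(task) * factor(roi) * factor(side) +
                          (1 | subject), data = long)
  pred <- predict(fit, re.form = NA)
  cellhat <- tapply(pred, interaction(long$task, long$roi, long$side), mean)
  cellobs <- tapply(long$value, interaction(long$task, long$roi, long$side), mean)
  expect_equal(as.numeric(cellhat), as.numeric(cellobs), tolerance = 1e-6)
})

test_that("a planted Task effect is detected with high power", {
  ps <- vapply(1:10, function(s) {
    truth <- cohort_truth(n_pairs = 2, planted_left = 1:2,
                          planted_right = integer())
    # PROD/READ high, LISN low, both sides
    truth$effect_means[, "LISN", ] <- 0.2
    truth$effect_means[, c("PROD", "READ"), ] <- 0.5
    tab <- simulate_task_table(truth, n_subjects = 80, seed = 700 + s)
    eff <- fit_mixed_model(tab, "activation")
    eff$p[eff$term == "Task"]
  }, 0)
  expect_gte(mean(ps < 0.001), 0.95)
})

test_that("mixed-model terms are calibrated on null cohorts", {
  # asymmetry response, 2 ROIs x 3 tasks, no planted effects
  rejections <- vapply(1:150, function(s) {
    truth <- cohort_truth(n_pairs = 2, planted_left = integer(),
                          planted_right = integer())
    tab <- simulate_task_table(truth, n_subjects = 20, seed = 3000 + s)
    eff <- suppressWarnings(fit_mixed_model(tab, "asymmetry"))
    eff$p[eff$term == "Task"] < 0.05
  }, TRUE)
  rate <- mean(rejections)
  se3 <- 3 * sqrt(0.05 * 0.95 / 150)
  expect_lt(abs(rate - 0.05), se3 + 1e-9)
})

test_that("all expected terms are present with valid df and p", {
  truth <- small_truth(4, left = 1:2, right = 3:4)
  tab <- simulate_task_table(truth, n_subjects = 25, seed = 8)
  act <- suppressWarnings(fit_mixed_model(tab, "activation"))
  expect_setequal(act$term, c("Task", "ROI", "Side", "Task x ROI",
                              "Task x Side", "ROI x Side",
                              "Task x ROI x Side"))
  expect_true(all(act$p >= 0 & act$p <= 1))
  expect_true(all(act$df1 > 0 & act$df2 > 0))
  asym <- suppressWarnings(fit_mixed_model(tab, "asymmetry"))
  expect_setequal(asym$term, c("Task", "ROI", "Task x ROI"))
  # deterministic and row-order invariant
  act2 <- suppressWarnings(fit_mixed_model(tab[sample(nrow(tab)), ],
                                           "activation"))
  expect_equal(act2$F, act$F, tolerance = 1e-8)
})

test_that("Tukey reduces to the paired t test with two tasks", {
  set.seed(77)
  n <- 18
  d <- data.frame(subject_id = rep(1:n, 2), pair_id = 1,
                  task = rep(c("PROD", "LISN"), each = n),
                  left_value = rnorm(2 * n, 0.3, 0.4),
                  right_value = rnorm(2 * n, 0.1, 0.4))
  tab <- compute_asymmetries(d)
  tk <- tukey_pairwise(tab, "activation", "left")
  v <- tab$left_value
  tt <- t.test(v[tab$task == "PROD"], v[tab$task == "LISN"], paired = TRUE)
  expect_equal(tk$p_adj, tt$p.value, tolerance = 1e-10)
  expect_equal(abs(tk$diff), abs(unname(tt$estimate)), tolerance = 1e-12)
})

test_that("Tukey flags a planted task difference and is null-calibrated", {
  truth <- cohort_truth(n_pairs = 1, planted_left = 1,
                        planted_right = integer())
  truth$effect_means[, "PROD", "left"] <- 0.8
  truth$effect_means[, c("LISN", "READ"), "left"] <- 0.2
  tab <- simulate_task_table(truth, n_subjects = 60, seed = 19)
  tk <- tukey_pairwise(tab, "activation", "left")
  prod_lisn <- tk[(tk$task_a == "PROD" & tk$task_b == "LISN") |
                    (tk$task_a == "LISN" & tk$task_b == "PROD"), ]
  expect_true(prod_lisn$significant)
  # three identical task distributions: few false families
  fams <- vapply(1:100, function(s) {
    nulltab <- simulate_task_table(
      cohort_truth(n_pairs = 1, planted_left = integer(),
                   planted_right = integer()),
      n_subjects = 20, seed = 5000 + s)
    any(tukey_pairwise(nulltab, "activation", "left")$significant)
  }, TRUE)
  expect_gte(mean(!fams), 0.93)
})

test_that("adjusted p values never fall below the unadjusted model contrast", {
  truth <- small_truth(3, left = 1:2, right = 3)
  tab <- simulate_task_table(truth, n_subjects = 25, seed = 31)
  tk <- tukey_pairwise(tab, "asymmetry")
  for (i in seq_len(nrow(tk))) {
    r <- tk[i, ]
    d <- tab[tab$pair_id == r$pair_id, ]
    fit <- lm(asymmetry ~ factor(task) + factor(subject_id), data = d)
    mse <- sum(residuals(fit)^2) / fit$df.residual
    se_diff <- sqrt(2 * mse / 25)
    p_unadj <- 2 * pt(-abs(r$diff) / se_diff, fit$df.residual)
    expect_gte(r$p_adj, p_unadj - 1e-10)
  }
  # all three task pairs covered per region
  expect_equal(as.integer(table(tk$pair_id)), rep(3L, 3))
})
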