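test_that("one-sample t matches hand arithmetic on a worked set", {
  res <- one_sample_test(c(1, 2, 3, 4, 5))
  expect_equal(res$mean, 3)
  expect_equal(res$t, 3 / (sd(1:5) / sqrt(5)), tolerance = 1e-12)
  expect_equal(res$t, 4.242640687, tolerance = 1e-8)
  expect_equal(res$p, 2 * pt(-res$t, 4), tolerance = 1e-12)
  expect_true(res$sign_ok)
})

test_that("degenerate inputs follow the zero-mean convention", {
  z <- one_sample_test(rep(0, 10))
  expect_equal(z$t, 0)
  expect_equal(z$p, 1)
  expect_error(one_sample_test(rep(2, 10)), "degenerate")
  expect_error(one_sample_test(1), "at least 2")
})

test_that("conjunction thresholds reproduce the nominal products", {
  expect_equal(conjunction_threshold(0.05, 3), 1.25e-4)
  expect_equal(signif(conjunction_threshold(conjunction_threshold(0.05, 3), 2), 3),
               1.56e-8)
  expect_equal(conjunction_threshold(1, 3), 1)
  expect_error(conjunction_threshold(1.2, 3), "alpha")
  expect_error(conjunction_threshold(0.05, 0), "positive integer")
})

test_that("joint selection recovers planted sets and stores thresholds", {
  truth <- small_truth(20, left = 1:5, right = 6:8)
  tab <- simulate_task_table(truth, n_subjects = 144, seed = 41)
  left <- select_joint_hrois(tab, "left")
  right <- select_joint_hrois(tab, "right")
  expect_equal(left$selected, 1:5)
  expect_equal(right$selected, 6:8)
  expect_equal(left$nominal_conjunction_threshold, 1.25e-4)
  expect_equal(left$nominal_overall_threshold, 1.5625e-8)
  # a pair cannot be jointly leftward and rightward
  expect_length(intersect(left$selected, right$selected), 0)
  # selected = joint activation AND joint asymmetry
  pp <- left$per_pair
  expect_equal(pp$selected_flag,
               pp$joint_activation_flag & pp$joint_asymmetry_flag)
})

test_that("alpha = 1 selects every correctly signed region; shrinking alpha is monotone", {
  truth <- small_truth(10, left = 1:3, right = 4:5)
  tab <- simulate_task_table(truth, n_subjects = 60, seed = 7)
  all_in <- select_joint_hrois(tab, "left", alpha_per_test = 1)
  pt <- all_in$per_task
  signs_ok <- tapply(pt$activation_mean > 0 & pt$asymmetry_mean > 0,
                     pt$pair_id, all)
  expect_equal(all_in$selected, as.integer(names(signs_ok))[signs_ok])
  a1 <- select_joint_hrois(tab, "left", alpha_per_test = 0.05)$selected
  a2 <- select_joint_hrois(tab, "left", alpha_per_test = 0.025)$selected
  expect_true(all(a2 %in% a1))
})

test_that("selection statistics agree with per-vector tests and ignore subject order", {
  truth <- small_truth(6, left = 1:2, right = 3:4)
  tab <- simulate_task_table(truth, n_subjects = 30, seed = 13)
  res <- select_joint_hrois(tab, "left")
  # spot-check per_task rows against the scalar test
  for (pid in c(1, 5)) for (tk in c("PROD", "READ")) {
    v <- tab$left_value[tab$pair_id == pid & tab$task == tk]
    row <- res$per_task[res$per_task$pair_id == pid & res$per_task$task == tk, ]
    ot <- one_sample_test(v)
    expect_equal(row$activation_t, ot$t, tolerance = 1e-12)
    expect_equal(row$activation_p, ot$p, tolerance = 1e-12)
  }
  # permuting subject labels changes nothing
  perm <- tab
  remap <- setNames(sample(unique(tab$subject_id)), unique(tab$subject_id))
  perm$subject_id <- remap[as.character(perm$subject_id)]
  res2 <- select_joint_hrois(task_signal_table(perm), "left")
  expect_equal(res2$per_task, res$per_task)
})

test_that("count tables obey the set-inclusion orderings", {
  truth <- small_truth(15, left = 1:4, right = 5:7)
  tab <- simulate_task_table(truth, n_subjects = 144, seed = 23)
  for (hemi in c("left", "right")) {
    ct <- count_selection_steps(tab, hemi)
    per_task <- ct[ct$contrast != "conjunction", ]
    conj <- ct[ct$contrast == "conjunction", ]
    expect_true(all(per_task$both <= pmin(per_task$activation,
                                          per_task$asymmetry)))
    expect_true(all(conj$activation <= per_task$activation))
    expect_true(all(conj$asymmetry <= per_task$asymmetry))
    expect_true(all(conj$both <= per_task$both))
  }
  # planted cohort: conjunction 'both' equals the planted count
  ct <- count_selection_steps(tab, "left")
  expect_equal(ct$both[ct$contrast == "conjunction"], 4)
})

test_that("null cohorts yield (near) empty conjunctions", {
  truth <- cohort_truth(n_pairs = 185, planted_left = integer(),
                        planted_right = integer())
  tab <- simulate_task_table(truth, n_subjects = 40, seed = 3)
  ct <- count_selection_steps(tab, "left")
  # expected 3-task joint count is 185 * (0.05/2)^3 ~ 0.003
  expect_lte(ct$both[ct$contrast == "conjunction"], 1)
})

test_that("named threshold schemes carry the documented alphas", {
  expect_equal(threshold_scheme("methods")$alpha_per_test, 0.05)
  expect_equal(threshold_scheme("table1")$alpha_per_test, 0.05 / 184)
  expect_equal(threshold_scheme(0.01)$alpha_per_test, 0.01)
})

test_that("selection masks keep only the selected side's labels", {
  truth <- small_truth(6, left = 1:2, right = 3:4)
  atlas <- make_toy_atlas(6, grid_shape = c(10, 6, 3), seed = 2)
  tab <- simulate_task_table(truth, n_subjects = 100, seed = 5)
  res <- select_joint_hrois(tab, "left")
  f <- tempfile(fileext = ".nii.gz")
  write_selection_mask(res, atlas, f)
  m <- as.array(RNifti::readNifti(f))
  kept <- setdiff(unique(as.vector(m)), 0)
  expect_setequal(kept, atlas$pairs$left_label[match(res$selected,
                                                     atlas$pairs$pair_id)])
})
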