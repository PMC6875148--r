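#' One-sample t test with a sign requirement
#'
#' Two-sided one-sample t test of the mean against zero, plus a flag for
#' whether the sample mean has the hypothesized direction. Used per (pair,
#' task) on region activations and asymmetries; requiring `p < alpha` AND the
#' correct sign behaves like a one-sided test at `alpha/2`.
#'
#' A zero-variance sample with zero mean returns `t = 0, p = 1`; a
#' zero-variance sample with nonzero mean is a degenerate input (t undefined)
#' and errors.
#'
#' @param values numeric vector, one value per subject (n >= 2).
#' @param direction `"positive"` or `"negative"`: the hypothesized sign of
#'   the mean.
#' @return list with `mean`, `t`, `p` (two-sided), `sign_ok`, `n`.
#' @export
one_sample_test <- function(values, direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  if (length(values) < 2) stop("need at least 2 values")
  if (!all(is.finite(values))) stop("non-finite values")
  m <- mean(values)
  s <- sd(values)
  n <- length(values)
  if (s == 0) {
    if (m == 0) return(list(mean = 0, t = 0, p = 1, sign_ok = FALSE, n = n))
    stop("degenerate input: zero variance with nonzero mean")
  }
  t <- m / (s / sqrt(n))
  p <- 2 * pt(-abs(t), df = n - 1)
  list(mean = m, t = t, p = p,
       sign_ok = if (direction == "positive") m > 0 else m < 0, n = n)
}

#' Nominal conjunction significance threshold
#'
#' Joint significance of k independent tests each at level `alpha`:
#' `alpha^k`. At `alpha = 0.05` and `k = 3` tasks this is 1.25e-4; squaring it
#' for the conjunction of the activation and asymmetry criteria gives
#' 1.5625e-8 (reported to three significant digits as 1.56e-8).
#'
#' @param alpha per-test significance level in (0, 1).
#' @param k number of conjoined tests, >= 1.
#' @return `alpha^k`.
#' @export
conjunction_threshold <- function(alpha, k) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1)
    stop("alpha must be in (0, 1]")
  if (k < 1 || k != round(k)) stop("k must be a positive integer")
  alpha^k
}

# Vectorized one-sample t over matrix columns (subjects in rows).
col_t_tests <- function(X) {
  n <- nrow(X)
  m <- colMeans(X)
  s <- sqrt(colSums(sweep(X, 2, m)^2) / (n - 1))
  t <- ifelse(s == 0, 0, m / (s / sqrt(n)))
  p <- ifelse(s == 0 & m == 0, 1, 2 * pt(-abs(t), df = n - 1))
  if (any(s == 0 & m != 0))
    stop("degenerate input: zero variance with nonzero mean")
  list(mean = m, t = t, p = p, n = n)
}

#' Select hROIs jointly activated and asymmetric in every task
#'
#' Implements the per-hemisphere conjunction: a pair is selected when its
#' (hemisphere-side) activation is significant with the right sign in all
#' tasks AND its left-minus-right asymmetry is significant with the right
#' sign in all tasks, each test at `p < alpha_per_test` (two-sided) with a
#' sign requirement. For the left hemisphere both signs are positive; for the
#' right hemisphere the right-side activation must be positive and the
#' asymmetry negative. Shrinking `alpha_per_test` can only remove regions.
#'
#' @param table a `task_signal_table` covering all tasks for every pair.
#' @param hemisphere `"left"` or `"right"`.
#' @param alpha_per_test per-test significance level (default 0.05).
#' @return object of class `selection_result`: list with `per_task` (one row
#'   per pair x task with activation and asymmetry statistics), `per_pair`
#'   (joint flags and `selected_flag`), `selected` (pair_ids), `hemisphere`,
#'   `alpha_per_test`, `nominal_conjunction_threshold` (`alpha^3`) and
#'   `nominal_overall_threshold` (`alpha^6`).
#' @export
select_joint_hrois <- function(table, hemisphere = c("left", "right"),
                               alpha_per_test = 0.05) {
  hemisphere <- match.arg(hemisphere)
  if (!inherits(table, "task_signal_table")) table <- task_signal_table(table)
  tasks <- sort(unique(table$task))
  pairs <- sort(unique(table$pair_id))
  subs <- sort(unique(table$subject_id))
  ord <- order(table$task, table$pair_id, table$subject_id)
  tb <- table[ord, ]
  n_s <- length(subs); n_p <- length(pairs); n_t <- length(tasks)
  act_col <- if (hemisphere == "left") tb$left_value else tb$right_value
  act_dir <- "positive"
  asym_dir <- if (hemisphere == "left") "positive" else "negative"
  A <- matrix(act_col, nrow = n_s)            # columns: pair within task
  S <- matrix(tb$asymmetry, nrow = n_s)
  ta <- col_t_tests(A)
  ts <- col_t_tests(S)
  sgn <- function(m, dir) if (dir == "positive") m > 0 else m < 0
  per_task <- data.frame(
    pair_id = rep(pairs, times = n_t),
    task = rep(tasks, each = n_p),
    activation_mean = ta$mean, activation_t = ta$t, activation_p = ta$p,
    asymmetry_mean = ts$mean, asymmetry_t = ts$t, asymmetry_p = ts$p)
  act_pass <- matrix(ta$p < alpha_per_test & sgn(ta$mean, act_dir), nrow = n_p)
  asy_pass <- matrix(ts$p < alpha_per_test & sgn(ts$mean, asym_dir), nrow = n_p)
  joint_act <- rowSums(act_pass) == n_t
  joint_asy <- rowSums(asy_pass) == n_t
  per_pair <- data.frame(pair_id = pairs,
                         joint_activation_flag = joint_act,
                         joint_asymmetry_flag = joint_asy,
                         selected_flag = joint_act & joint_asy)
  structure(
    list(per_task = per_task, per_pair = per_pair,
         selected = pairs[per_pair$selected_flag],
         hemisphere = hemisphere, alpha_per_test = alpha_per_test,
         nominal_conjunction_threshold = conjunction_threshold(alpha_per_test, n_t),
         nominal_overall_threshold = conjunction_threshold(alpha_per_test, n_t)^2,
         tasks = tasks, n_subjects = n_s),
    class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "Conjunction selection (%s hemisphere, alpha = %g/test over %d tasks):\n",
    x$hemisphere, x$alpha_per_test, length(x$tasks)))
  cat(sprintf("  %d of %d pairs selected; nominal joint threshold %.3g, overall %.3g\n",
              length(x$selected), nrow(x$per_pair),
              x$nominal_conjunction_threshold, x$nominal_overall_threshold))
  invisible(x)
}

#' Threshold schemes for selection-step counting
#'
#' Named per-test alpha schemes: `"methods"` is p < 0.05 per contrast (the
#' operational rule whose nominal three-task conjunction level is 1.25e-4);
#' `"table1"` is the Bonferroni-corrected per-contrast 0.05/184 = 0.00027
#' variant; `"uncorrected"` is an alias of 0.05 kept for count tables that
#' report both.
#'
#' @param scheme scheme name, or a numeric per-test alpha.
#' @return list with `name` and `alpha_per_test`.
#' @export
threshold_scheme <- function(scheme = c("methods", "table1", "uncorrected")) {
  if (is.numeric(scheme))
    return(list(name = sprintf("alpha=%g", scheme), alpha_per_test = scheme))
  scheme <- match.arg(scheme)
  alpha <- switch(scheme, methods = 0.05, table1 = 0.05 / 184,
                  uncorrected = 0.05)
  list(name = scheme, alpha_per_test = alpha)
}

#' Count pairs passing each selection step
#'
#' Per task and per criterion (activation, asymmetry, both) and for the
#' three-task conjunction, mirroring selection-step count tables. Counts obey
#' `both <= min(activation, asymmetry)` and conjunction <= every single-task
#' count.
#'
#' @param table a `task_signal_table`.
#' @param hemisphere `"left"` or `"right"`.
#' @param scheme a [threshold_scheme()] (or name / numeric alpha).
#' @return data.frame of class `count_table` with columns `contrast`
#'   (task name or `"conjunction"`), `activation`, `asymmetry`, `both`.
#' @export
count_selection_steps <- function(table, hemisphere = c("left", "right"),
                                  scheme = "methods") {
  hemisphere <- match.arg(hemisphere)
  if (!is.list(scheme)) scheme <- threshold_scheme(scheme)
  res <- select_joint_hrois(table, hemisphere, scheme$alpha_per_test)
  pt <- res$per_task
  alpha <- scheme$alpha_per_test
  sgn_act <- pt$activation_mean > 0
  sgn_asy <- if (hemisphere == "left") pt$asymmetry_mean > 0 else
    pt$asymmetry_mean < 0
  act <- pt$activation_p < alpha & sgn_act
  asy <- pt$asymmetry_p < alpha & sgn_asy
  tasks <- res$tasks
  rows <- lapply(tasks, function(tk) {
    i <- pt$task == tk
    data.frame(contrast = tk, activation = sum(act[i]),
               asymmetry = sum(asy[i]), both = sum(act[i] & asy[i]))
  })
  conj <- data.frame(
    contrast = "conjunction",
    activation = sum(res$per_pair$joint_activation_flag),
    asymmetry = sum(res$per_pair$joint_asymmetry_flag),
    both = sum(res$per_pair$selected_flag))
  out <- rbind(do.call(rbind, rows), conj)
  attr(out, "scheme") <- scheme$name
  attr(out, "hemisphere") <- hemisphere
  class(out) <- c("count_table", "data.frame")
  out
}

#' Export selected regions as a NIfTI label volume
#'
#' Writes a label volume keeping only the selected side of each selected pair
#' (left labels for a left-hemisphere selection), the package's analogue of a
#' downloadable selection atlas.
#'
#' @param result a `selection_result`.
#' @param atlas the `homotopic_atlas` the signals came from.
#' @param path output .nii/.nii.gz path.
#' @return the path, invisibly.
#' @export
write_selection_mask <- function(result, atlas, path) {
  p <- atlas$pairs
  i <- match(result$selected, p$pair_id)
  keep <- if (result$hemisphere == "left") p$left_label[i] else p$right_label[i]
  grid <- atlas$label_grid
  grid[!(grid %in% keep)] <- 0L
  img <- RNifti::asNifti(grid, datatype = "int32")
  img <- RNifti::`sform<-`(img, structure(atlas$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
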