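#' Repeated-measures mixed model over selected regions
#'
#' Fits a linear mixed-effects model to the selected regions' signals with
#' Subject as a random intercept and all interactions among the applicable
#' fixed factors. For `response = "activation"` the factors are Task, ROI and
#' Side (both members of each pair enter); for `response = "asymmetry"` the
#' Side factor is dropped, as the asymmetry is already the side contrast.
#' Factors with a single level (e.g. one region, or one task) are omitted
#' automatically. F tests use Satterthwaite denominator degrees of freedom.
#' A singular random-effects fit triggers a warning and a fixed-effects
#' refit (the simplified structure), whose ANOVA is returned instead.
#'
#' @param table a `task_signal_table`.
#' @param response `"activation"` or `"asymmetry"`.
#' @param hemisphere the hemisphere whose selection is being profiled (used
#'   for bookkeeping; the activation model always includes both sides).
#' @param selected pair_ids to include (e.g. `selection_result$selected`);
#'   default all pairs in the table.
#' @return data.frame of class `effects_table`: one row per model term with
#'   `term`, `F`, `df1`, `df2`, `p`; attributes `response`, `hemisphere`,
#'   `n_subjects`.
#' @export
fit_mixed_model <- function(table, response = c("activation", "asymmetry"),
                            hemisphere = c("left", "right"),
                            selected = NULL) {
  response <- match.arg(response)
  hemisphere <- match.arg(hemisphere)
  if (!inherits(table, "task_signal_table")) table <- task_signal_table(table)
  if (!is.null(selected)) table <- table[table$pair_id %in% selected, ]
  if (response == "activation") {
    long <- rbind(
      data.frame(subject = table$subject_id, roi = table$pair_id,
                 task = table$task, side = "left", value = table$left_value),
      data.frame(subject = table$subject_id, roi = table$pair_id,
                 task = table$task, side = "right", value = table$right_value))
  } else {
    long <- data.frame(subject = table$subject_id, roi = table$pair_id,
                       task = table$task, side = "asym",
                       value = table$asymmetry)
  }
  long$subject <- factor(long$subject)
  long$Task <- factor(long$task)
  long$ROI <- factor(long$roi)
  long$Side <- factor(long$side)
  fixed <- c("Task", "ROI", if (response == "activation") "Side")
  fixed <- fixed[vapply(fixed, function(f) nlevels(long[[f]]) > 1, TRUE)]
  if (!length(fixed)) stop("no fixed factor with more than one level")
  rhs <- paste(fixed, collapse = " * ")
  fml <- stats::as.formula(paste("value ~", rhs, "+ (1 | subject)"))
  fit <- lmerTest::lmer(fml, data = long,
                        control = lme4::lmerControl(calc.derivs = FALSE))
  if (lme4::isSingular(fit)) {
    warning("singular random-effects fit; refitting without the random intercept")
    lmfit <- stats::lm(stats::as.formula(paste("value ~", rhs)), data = long)
    a <- stats::anova(lmfit)
    terms <- setdiff(rownames(a), "Residuals")
    eff <- data.frame(term = gsub(":", " x ", terms),
                      F = a[terms, "F value"], df1 = a[terms, "Df"],
                      df2 = a["Residuals", "Df"], p = a[terms, "Pr(>F)"])
  } else {
    a <- stats::anova(fit, type = 3, ddf = "Satterthwaite")
    eff <- data.frame(term = gsub(":", " x ", rownames(a)),
                      F = a[["F value"]], df1 = a[["NumDF"]],
                      df2 = a[["DenDF"]], p = a[["Pr(>F)"]])
  }
  rownames(eff) <- NULL
  attr(eff, "response") <- response
  attr(eff, "hemisphere") <- hemisphere
  attr(eff, "n_subjects") <- nlevels(long$subject)
  class(eff) <- c("effects_table", "data.frame")
  eff
}

#' Tukey range tests among task means, per region
#'
#' Two-sided studentized-range (Tukey) comparisons of the task means of each
#' region, on either the selected-side activation or the asymmetry. Each
#' region is fit as a randomized block (subject) design and the three task
#' means are compared with the studentized-range distribution; the family is
#' the set of task means within one region. With two tasks the test reduces
#' to the paired two-sided t test. An optional Bonferroni factor across
#' regions is available.
#'
#' @param table a `task_signal_table`.
#' @param response `"activation"` or `"asymmetry"`.
#' @param hemisphere for activation, which side's value is profiled.
#' @param selected pair_ids to include; default all.
#' @param bonferroni_regions if TRUE, adjusted p values are additionally
#'   multiplied by the number of regions (capped at 1).
#' @param alpha significance level for the `significant` flag.
#' @return data.frame of class `pairwise_table`: `pair_id`, `task_a`,
#'   `task_b`, `diff` (mean a - mean b), `p_adj`, `significant`.
#' @export
tukey_pairwise <- function(table, response = c("activation", "asymmetry"),
                           hemisphere = c("left", "right"), selected = NULL,
                           bonferroni_regions = FALSE, alpha = 0.05) {
  response <- match.arg(response)
  hemisphere <- match.arg(hemisphere)
  if (!inherits(table, "task_signal_table")) table <- task_signal_table(table)
  if (!is.null(selected)) table <- table[table$pair_id %in% selected, ]
  value <- switch(response,
                  activation = if (hemisphere == "left") table$left_value
                               else table$right_value,
                  asymmetry = table$asymmetry)
  df <- data.frame(pair_id = table$pair_id, subject = factor(table$subject_id),
                   task = factor(table$task), value = value)
  tasks <- levels(df$task)
  k <- length(tasks)
  if (k < 2) stop("need at least 2 tasks for pairwise comparisons")
  pairs_idx <- utils::combn(k, 2)
  regions <- sort(unique(df$pair_id))
  out <- lapply(regions, function(r) {
    d <- df[df$pair_id == r, ]
    if (min(table(d$task)) < 2)
      stop("degenerate input: fewer than 2 observations per task cell")
    fit <- stats::lm(value ~ task + subject, data = d)
    mse <- sum(stats::residuals(fit)^2) / fit$df.residual
    n_per <- nrow(d) / k
    means <- tapply(d$value, d$task, mean)
    se <- sqrt(mse / n_per)
    diffs <- means[pairs_idx[1, ]] - means[pairs_idx[2, ]]
    q <- abs(diffs) / se
    p <- ptukey(q, nmeans = k, df = fit$df.residual, lower.tail = FALSE)
    data.frame(pair_id = r, task_a = tasks[pairs_idx[1, ]],
               task_b = tasks[pairs_idx[2, ]], diff = as.numeric(diffs),
               p_adj = as.numeric(p))
  })
  out <- do.call(rbind, out)
  if (bonferroni_regions)
    out$p_adj <- pmin(1, out$p_adj * length(regions))
  out$significant <- out$p_adj < alpha
  rownames(out) <- NULL
  attr(out, "response") <- response
  class(out) <- c("pairwise_table", "data.frame")
  out
}
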