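#' Task signal table
#'
#' Long-format table of region-mean BOLD contrast values: one row per
#' (subject, homotopic pair, task) with the left and right region means and
#' the left-minus-right asymmetry. The complete subject x pair x task grid is
#' required, all values finite.
#'
#' @param df data.frame with columns `subject_id`, `pair_id`, `task`,
#'   `left_value`, `right_value` and optionally `asymmetry`.
#' @return object of class `task_signal_table` (a data.frame).
#' @export
task_signal_table <- function(df) {
  req <- c("subject_id", "pair_id", "task", "left_value", "right_value")
  if (!all(req %in% names(df)))
    stop("task signal table needs columns ", paste(req, collapse = ", "))
  df <- as.data.frame(df)
  if (!all(is.finite(df$left_value)) || !all(is.finite(df$right_value)))
    stop("non-finite values in task signal table")
  tab <- table(df$subject_id, df$pair_id, df$task)
  if (any(tab != 1L))
    stop("completeness error: subject x pair x task grid is incomplete or duplicated")
  class(df) <- c("task_signal_table", "data.frame")
  df
}

#' Fill (or refresh) the asymmetry column
#'
#' Asymmetry is defined as left minus right, for both hemispheres' analyses;
#' rightward asymmetries are therefore negative. Antisymmetric under side
#' swap.
#'
#' @param table a `task_signal_table` or compatible data.frame.
#' @return the table with `asymmetry = left_value - right_value`.
#' @export
compute_asymmetries <- function(table) {
  if (!all(c("left_value", "right_value") %in% names(table)))
    stop("completeness error: both sides required to compute asymmetry")
  table$asymmetry <- table$left_value - table$right_value
  if (!inherits(table, "task_signal_table")) table <- task_signal_table(table)
  table
}

#' Region mean signal per homotopic pair
#'
#' Arithmetic mean of the contrast map over every voxel of each region (no
#' intensity thresholding), for the left and right member of every pair.
#' Independent of voxel enumeration order.
#'
#' @param contrast_map 3-D numeric array aligned to the atlas grid.
#' @param atlas a `homotopic_atlas`.
#' @return data.frame with `pair_id`, `left_value`, `right_value`.
#' @export
extract_region_means <- function(contrast_map, atlas) {
  if (!identical(dim(contrast_map), dim(atlas$label_grid)))
    stop(sprintf("alignment error: map dim %s does not match atlas grid %s",
                 paste(dim(contrast_map), collapse = "x"),
                 paste(dim(atlas$label_grid), collapse = "x")))
  lab <- as.vector(atlas$label_grid)
  keep <- lab != 0L
  means <- tapply(as.vector(contrast_map)[keep], lab[keep], mean)
  p <- atlas$pairs
  data.frame(pair_id = p$pair_id,
             left_value = as.numeric(means[as.character(p$left_label)]),
             right_value = as.numeric(means[as.character(p$right_label)]))
}

#' Region time-series stack
#'
#' Per-subject (volumes x regions) matrices with the sampling interval and
#' preprocessing provenance flags. The band is attached when filtering is
#' applied.
#'
#' @param series list of numeric matrices (volumes x regions), identical
#'   column sets.
#' @param tr sampling interval, seconds.
#' @param regions optional region table (`pair_id`, `hemisphere`,
#'   `region_id`).
#' @return object of class `region_series_stack`.
#' @export
region_series_stack <- function(series, tr, regions = NULL) {
  stopifnot(is.list(series), length(series) >= 1, tr > 0)
  nt <- vapply(series, nrow, 0L)
  if (length(unique(nt)) != 1L)
    stop("all subjects must have the same number of volumes")
  structure(list(series = series, tr = tr, regions = regions,
                 band = NULL, nuisance_regressed = FALSE, filtered = FALSE),
            class = "region_series_stack")
}

#' @export
print.region_series_stack <- function(x, ...) {
  cat(sprintf(
    "Region series stack: %d subjects, %d regions x %d volumes, TR %gs\n",
    length(x$series), ncol(x$series[[1]]), nrow(x$series[[1]]), x$tr))
  cat(sprintf("  nuisance_regressed: %s, filtered: %s%s\n",
              x$nuisance_regressed, x$filtered,
              if (!is.null(x$band)) sprintf(" (%g-%g Hz)", x$band[1], x$band[2])
              else ""))
  invisible(x)
}

#' @rdname region_series_stack
#' @param cohort a `rest_cohort` from [simulate_resting_series()].
#' @export
as_region_series_stack <- function(cohort) {
  stopifnot(inherits(cohort, "rest_cohort"))
  region_series_stack(cohort$series, tr = cohort$tr, regions = cohort$regions)
}

#' Remove nuisance series and linear trend by regression
#'
#' Ordinary least squares of every region series on an intercept, a linear
#' ramp, and the supplied nuisance series (e.g. white-matter and CSF mean
#' series); the residuals are returned. Residuals are orthogonal to every
#' regressor to numerical precision. A rank-deficient design triggers a
#' warning and a minimum-norm (pseudoinverse) fit.
#'
#' @param stack a `region_series_stack`.
#' @param nuisance list (one element per subject) of (volumes x k) matrices,
#'   or NULL for detrending only.
#' @return the stack with residual series and `nuisance_regressed = TRUE`.
#' @export
regress_nuisance <- function(stack, nuisance = NULL) {
  stopifnot(inherits(stack, "region_series_stack"))
  n <- nrow(stack$series[[1]])
  ramp <- seq_len(n)
  out <- stack
  for (s in seq_along(stack$series)) {
    X <- cbind(intercept = 1, trend = ramp)
    if (!is.null(nuisance)) {
      nu <- as.matrix(nuisance[[s]])
      if (nrow(nu) != n)
        stop("nuisance series length does not match data")
      X <- cbind(X, nu)
    }
    qr_x <- qr(X)
    if (qr_x$rank < ncol(X)) {
      warning("rank-deficient nuisance design; using pseudoinverse fit")
      sv <- svd(X)
      pos <- sv$d > max(sv$d) * 1e-10
      beta <- sv$v[, pos, drop = FALSE] %*%
        (t(sv$u[, pos, drop = FALSE]) %*% stack$series[[s]] / sv$d[pos])
      out$series[[s]] <- stack$series[[s]] - X %*% beta
    } else {
      out$series[[s]] <- qr.resid(qr_x, stack$series[[s]])
    }
  }
  out$nuisance_regressed <- TRUE
  out
}
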