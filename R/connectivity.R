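#' Per-subject correlation matrices over selected regions
#'
#' Pearson correlation between every pair of region time series, per subject.
#' The stack should be preprocessed (nuisance regressed, then bandpass
#' filtered) first; a warning is raised otherwise.
#'
#' @param stack a `region_series_stack`.
#' @param selected optional character vector of region ids (columns) to use;
#'   default all.
#' @return object of class `connectivity_stack`: 3-D array `cor`
#'   (region x region x subject) with dimnames, plus `regions` metadata.
#' @export
subject_correlations <- function(stack, selected = NULL) {
  stopifnot(inherits(stack, "region_series_stack"))
  if (!isTRUE(stack$nuisance_regressed) || !isTRUE(stack$filtered))
    warning("series are not fully preprocessed (nuisance_regressed/filtered)")
  first <- stack$series[[1]]
  ids <- colnames(first)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(first)))
  if (is.null(selected)) selected <- ids
  n_r <- length(selected)
  n_s <- length(stack$series)
  out <- array(NA_real_, dim = c(n_r, n_r, n_s),
               dimnames = list(selected, selected, NULL))
  for (s in seq_len(n_s)) {
    Y <- stack$series[[s]]
    colnames(Y) <- ids
    Y <- Y[, selected, drop = FALSE]
    sds <- apply(Y, 2, sd)
    if (any(sds == 0))
      stop("undefined correlation: constant series for region(s) ",
           paste(selected[sds == 0], collapse = ", "))
    out[, , s] <- cor(Y)
  }
  regions <- stack$regions
  if (!is.null(regions)) regions <- regions[regions$region_id %in% selected, ]
  structure(list(cor = out, subject_ids = seq_len(n_s), regions = regions),
            class = "connectivity_stack")
}

#' Fisher z-transform and its inverse
#'
#' `z = atanh(r)`, the variance-stabilizing transform applied per subject
#' before averaging correlations across subjects; odd and strictly
#' increasing. `fisher_z_inverse` is `tanh`.
#'
#' @param r correlation(s), `|r| < 1`.
#' @return transformed value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stop("domain error: |r| must be < 1")
  atanh(r)
}

#' @rdname fisher_z
#' @param z Fisher-z value(s).
#' @export
fisher_z_inverse <- function(z) tanh(z)

#' Group intrinsic-connectivity matrix
#'
#' Averages the Fisher-z-transformed per-subject correlation matrices across
#' subjects and back-transforms elementwise: `group_mean_r =
#' tanh(mean(atanh(r_subject)))`. The order (transform, average, then
#' back-transform) is fixed; averaging raw correlations gives a different,
#' biased matrix on skewed inputs.
#'
#' @param cstack a `connectivity_stack`.
#' @return the stack with `group_mean_z` and `group_mean_r` matrices added.
#' @export
group_connectivity <- function(cstack) {
  stopifnot(inherits(cstack, "connectivity_stack"))
  z <- cstack$cor
  zt <- atanh(pmin(pmax(z, -1 + 1e-15), 1 - 1e-15))
  mz <- apply(zt, c(1, 2), mean)
  diag(mz) <- Inf
  cstack$group_mean_z <- mz
  r <- tanh(mz)
  diag(r) <- 1
  cstack$group_mean_r <- r
  cstack
}
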