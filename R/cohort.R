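#' Ground truth for a synthetic cohort
#'
#' Encodes what the generators plant: which pairs are jointly activated and
#' leftward-asymmetric (or rightward) in all tasks, the per-(pair, task, side)
#' effect means in BOLD % units, the network partition used for resting-state
#' block covariance, and the noise model.
#'
#' Default effect sizes follow the scale of group hROI analyses of word-list
#' tasks: an activated side around 0.4 BOLD %, the contralateral side around
#' 0.15 (asymmetry 0.25), voxel noise SD 0.35 so that across-subject SDs of
#' region means land near 0.35-0.45. The default partition puts the planted
#' left set in network 1 and the planted right set in network 2, with
#' within-network correlation 0.5 and between-network correlation -0.05.
#'
#' @param n_pairs number of homotopic pairs in the atlas.
#' @param planted_left,planted_right disjoint sets of pair_ids carrying joint
#'   activation + asymmetry effects (leftward resp. rightward).
#' @param tasks character vector of task names.
#' @param effect_active effect mean (BOLD %) on the activated side of a planted
#'   pair, every task.
#' @param effect_contra effect mean on the opposite side of a planted pair.
#' @param effect_means optional full array `n_pairs x n_tasks x 2` (sides
#'   left, right) overriding the two scalars.
#' @param noise_sd i.i.d. voxel noise SD.
#' @param intercept_sd SD of the per-subject random intercept added to all
#'   region voxels (induces the repeated-measures structure); default half the
#'   voxel noise SD.
#' @param planted_partition named integer vector mapping pair_id to network
#'   label for the resting-state model; default networks 1 and 2 for the
#'   planted left and right sets.
#' @param within_network_r,between_network_r resting-state correlations inside
#'   and across planted networks; must satisfy
#'   `abs(within_network_r) > abs(between_network_r)` and yield a positive
#'   definite covariance.
#' @param ar_rho AR(1) coefficient of the resting-state temporal noise.
#' @return an object of class `cohort_truth`.
#' @export
cohort_truth <- function(n_pairs = 185,
                         planted_left = 1:14,
                         planted_right = 15:21,
                         tasks = c("PROD", "LISN", "READ"),
                         effect_active = 0.40,
                         effect_contra = 0.15,
                         effect_means = NULL,
                         noise_sd = 0.35,
                         intercept_sd = noise_sd / 2,
                         planted_partition = NULL,
                         within_network_r = 0.5,
                         between_network_r = -0.05,
                         ar_rho = 0.3) {
  if (length(intersect(planted_left, planted_right)))
    stop("planted left and right sets must be disjoint")
  if (max(c(planted_left, planted_right, 0)) > n_pairs)
    stop("planted pair ids exceed n_pairs")
  if (abs(within_network_r) <= abs(between_network_r))
    stop("|within_network_r| must exceed |between_network_r|")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  nt <- length(tasks)
  if (is.null(effect_means)) {
    effect_means <- array(0, dim = c(n_pairs, nt, 2),
                          dimnames = list(NULL, tasks, c("left", "right")))
    effect_means[planted_left, , "left"] <- effect_active
    effect_means[planted_left, , "right"] <- effect_contra
    effect_means[planted_right, , "right"] <- effect_active
    effect_means[planted_right, , "left"] <- effect_contra
  } else {
    stopifnot(all(dim(effect_means) == c(n_pairs, nt, 2)))
    dimnames(effect_means) <- list(NULL, tasks, c("left", "right"))
  }
  if (is.null(planted_partition)) {
    planted_partition <- c(rep(1L, length(planted_left)),
                           rep(2L, length(planted_right)))
    names(planted_partition) <- c(planted_left, planted_right)
  }
  structure(
    list(n_pairs = n_pairs, planted_left = as.integer(planted_left),
         planted_right = as.integer(planted_right), tasks = tasks,
         effect_means = effect_means, noise_sd = noise_sd,
         intercept_sd = intercept_sd, planted_partition = planted_partition,
         within_network_r = within_network_r,
         between_network_r = between_network_r, ar_rho = ar_rho),
    class = "cohort_truth")
}

#' Build a mirror-symmetric toy atlas
#'
#' Places `n_pairs` left-hemisphere regions at random voxel sites in the x < 0
#' half of the grid and mirrors them exactly across the mid-sagittal plane, so
#' left and right volumes are equal by construction. Left labels are
#' `1..n_pairs`, right labels `n_pairs+1..2*n_pairs`.
#'
#' @param n_pairs number of homotopic pairs (>= 2).
#' @param grid_shape integer length-3; the first dimension must be even so no
#'   voxel sits on the midline.
#' @param voxels_per_region voxels per region; scalar or per-pair vector.
#' @param voxel_size voxel edge lengths, mm.
#' @param seed RNG seed; same seed gives an identical atlas.
#' @return a validated [homotopic_atlas()].
#' @export
make_toy_atlas <- function(n_pairs, grid_shape = c(24, 24, 18),
                           voxels_per_region = 1, voxel_size = c(2, 2, 2),
                           seed = 1L) {
  stopifnot(n_pairs >= 2)
  if (grid_shape[1] %% 2L != 0L)
    stop("grid_shape[1] must be even (mirror symmetry about the midline)")
  vpr <- rep_len(voxels_per_region, n_pairs)
  half <- grid_shape
  half[1] <- grid_shape[1] %/% 2L
  capacity <- prod(half)
  if (sum(vpr) > capacity)
    stop(sprintf("capacity error: %d voxels requested but left half-grid holds %d",
                 sum(vpr), capacity))
  grid <- array(0L, dim = grid_shape)
  withr_seed(seed, {
    slots <- sample.int(capacity, sum(vpr))
  })
  ijk <- arrayInd(slots, .dim = half)           # 1-based, left half
  lab <- rep.int(seq_len(n_pairs), vpr)
  grid[cbind(ijk[, 1], ijk[, 2], ijk[, 3])] <- lab
  mirror_i <- grid_shape[1] + 1L - ijk[, 1]     # exact x reflection
  grid[cbind(mirror_i, ijk[, 2], ijk[, 3])] <- lab + n_pairs
  pairs <- data.frame(
    pair_id = seq_len(n_pairs),
    name = sprintf("region_%03d", seq_len(n_pairs)),
    abbreviation = sprintf("r%d", seq_len(n_pairs)),
    left_label = seq_len(n_pairs),
    right_label = seq_len(n_pairs) + n_pairs)
  homotopic_atlas(grid, pairs, voxel_size = voxel_size)
}

# Run code under a temporary RNG state.
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}

#' Simulate per-subject task contrast maps
#'
#' Each voxel of a region receives the planted (pair, task, side) effect mean
#' plus a per-subject random intercept (shared across regions and tasks) plus
#' i.i.d. Gaussian voxel noise; background voxels are pure noise. Region
#' empirical means therefore converge to the planted effects as the number of
#' subjects grows.
#'
#' @param atlas a `homotopic_atlas`.
#' @param truth a [cohort_truth()] with `n_pairs` matching the atlas.
#' @param n_subjects positive integer.
#' @param seed RNG seed.
#' @return an object of class `task_cohort`: list with `atlas`, `truth`,
#'   `n_subjects`, and `maps[[subject]][[task]]` 3-D arrays.
#' @export
simulate_task_maps <- function(atlas, truth, n_subjects, seed = 1L) {
  if (n_subjects < 1) stop("n_subjects must be positive")
  if (truth$n_pairs != nrow(atlas$pairs))
    stop("truth$n_pairs does not match the atlas")
  dims <- dim(atlas$label_grid)
  lab <- as.vector(atlas$label_grid)
  in_region <- lab != 0L
  np <- truth$n_pairs
  # voxel -> (pair, side): left labels 1..np are pair_id; right are pair_id+np
  vox_pair <- ifelse(lab[in_region] > np, lab[in_region] - np, lab[in_region])
  vox_side <- ifelse(lab[in_region] > np, 2L, 1L)
  maps <- vector("list", n_subjects)
  withr_seed(seed, {
    intercepts <- rnorm(n_subjects, 0, truth$intercept_sd)
    for (s in seq_len(n_subjects)) {
      subj <- vector("list", length(truth$tasks))
      names(subj) <- truth$tasks
      for (t in seq_along(truth$tasks)) {
        v <- rnorm(length(lab), 0, truth$noise_sd)
        eff <- truth$effect_means[cbind(vox_pair, t, vox_side)]
        v[in_region] <- v[in_region] + eff + intercepts[s]
        subj[[t]] <- array(v, dim = dims)
      }
      maps[[s]] <- subj
    }
  })
  structure(list(atlas = atlas, truth = truth, n_subjects = n_subjects,
                 maps = maps, seed = seed),
            class = "task_cohort")
}

#' Simulate resting-state region time series with planted network structure
#'
#' Draws, per subject, region series from a block-structured correlation
#' matrix (within- vs between-network correlation from the truth object) with
#' AR(1) temporal innovations, then adds a per-region linear drift and scaled
#' white-matter-like / CSF-like nuisance components. The added drift and
#' nuisance are exactly the terms [regress_nuisance()] removes; the correlated
#' signal content survives [bandpass_fir()] because identical linear filtering
#' of all regions preserves cross-correlation.
#'
#' @param selected region table: data.frame with `pair_id` and `hemisphere`
#'   (`"left"`/`"right"`), or a vector of pair_ids (hemisphere taken from the
#'   truth's planted sets).
#' @param truth a [cohort_truth()].
#' @param n_subjects,n_volumes,tr cohort geometry; defaults 138 subjects, 240
#'   volumes, TR 2 s (8 min).
#' @param drift_sd SD of the per-region linear drift amplitude (signal units
#'   over the scan); 0 disables drift.
#' @param nuisance_scale SD of per-region loadings on the two nuisance series;
#'   0 disables.
#' @param seed RNG seed.
#' @return object of class `rest_cohort`: `series[[subject]]` (volumes x
#'   regions), `nuisance[[subject]]` (volumes x 2), `regions`, `tr`, `truth`.
#' @export
simulate_resting_series <- function(selected, truth, n_subjects = 138,
                                    n_volumes = 240, tr = 2,
                                    drift_sd = 0.5, nuisance_scale = 0.3,
                                    seed = 1L) {
  regions <- as_region_table(selected, truth)
  R <- nrow(regions)
  Sigma <- planted_block_correlation(regions$pair_id, truth)
  ch <- tryCatch(chol(Sigma), error = function(e)
    stop(sprintf(paste0("target covariance not positive definite for ",
                        "within_network_r = %g, between_network_r = %g"),
                 truth$within_network_r, truth$between_network_r)))
  rho <- truth$ar_rho
  tcen <- seq(-0.5, 0.5, length.out = n_volumes)
  series <- vector("list", n_subjects)
  nuis <- vector("list", n_subjects)
  withr_seed(seed, {
    for (s in seq_len(n_subjects)) {
      E <- matrix(rnorm(n_volumes * R), n_volumes, R)
      if (rho != 0)  # AR(1) over time, unit marginal variance
        E <- apply(E, 2, function(e)
          as.numeric(stats::filter(e * sqrt(1 - rho^2), rho,
                                   method = "recursive",
                                   init = e[1] / sqrt(1 - rho^2) * 0)))
      Y <- E %*% ch
      nu <- cbind(wm = ar1_series(n_volumes, 0.9),
                  csf = ar1_series(n_volumes, 0.9))
      if (nuisance_scale > 0)
        Y <- Y + nu %*% matrix(rnorm(2 * R, 0, nuisance_scale), 2, R)
      if (drift_sd > 0)
        Y <- Y + tcen %*% t(rnorm(R, 0, drift_sd))
      colnames(Y) <- regions$region_id
      series[[s]] <- Y
      nuis[[s]] <- nu
    }
  })
  structure(list(series = series, nuisance = nuis, regions = regions,
                 tr = tr, n_volumes = n_volumes, truth = truth, seed = seed),
            class = "rest_cohort")
}

ar1_series <- function(n, rho) {
  as.numeric(stats::filter(rnorm(n, 0, sqrt(1 - rho^2)), rho,
                           method = "recursive"))
}

# Normalize a selection spec into a region table with stable region_ids.
as_region_table <- function(selected, truth = NULL) {
  if (is.data.frame(selected)) {
    stopifnot(all(c("pair_id", "hemisphere") %in% names(selected)))
    rt <- selected[, c("pair_id", "hemisphere")]
  } else {
    if (is.null(truth)) stop("a bare pair_id vector needs a truth object")
    hemi <- ifelse(selected %in% truth$planted_right, "right", "left")
    rt <- data.frame(pair_id = as.integer(selected), hemisphere = hemi)
  }
  rt$region_id <- paste0(ifelse(rt$hemisphere == "left", "L", "R"), rt$pair_id)
  rt
}

# Block correlation matrix from the planted partition.
planted_block_correlation <- function(pair_ids, truth) {
  net <- truth$planted_partition[as.character(pair_ids)]
  net[is.na(net)] <- seq_len(sum(is.na(net))) + max(truth$planted_partition)
  same <- outer(net, net, "==")
  Sigma <- ifelse(same, truth$within_network_r, truth$between_network_r)
  diag(Sigma) <- 1
  unname(Sigma)
}

#' Extract a task signal table from a simulated (or real) task cohort
#'
#' Applies [extract_region_means()] to every subject x task map and assembles
#' the long-format subject x pair x task table of left/right region means and
#' left-minus-right asymmetries.
#'
#' @param cohort a `task_cohort` from [simulate_task_maps()].
#' @return a `task_signal_table` (see [task_signal_table()]).
#' @export
extract_task_table <- function(cohort) {
  stopifnot(inherits(cohort, "task_cohort"))
  np <- nrow(cohort$atlas$pairs)
  tasks <- names(cohort$maps[[1]])
  out <- vector("list", cohort$n_subjects * length(tasks))
  k <- 0L
  for (s in seq_len(cohort$n_subjects)) {
    for (tk in tasks) {
      m <- extract_region_means(cohort$maps[[s]][[tk]], cohort$atlas)
      k <- k + 1L
      out[[k]] <- data.frame(subject_id = s, pair_id = m$pair_id, task = tk,
                             left_value = m$left_value,
                             right_value = m$right_value)
    }
  }
  compute_asymmetries(do.call(rbind, out))
}

#' Simulate a task signal table directly at region level
#'
#' Equivalent in distribution to [simulate_task_maps()] followed by
#' [extract_task_table()] when each region holds `voxels_per_region` voxels:
#' the region mean of i.i.d. voxel noise is Gaussian with SD
#' `noise_sd/sqrt(voxels_per_region)`. Used where voxel grids are not needed.
#'
#' @inheritParams simulate_task_maps
#' @param voxels_per_region effective voxels averaged per region.
#' @return a `task_signal_table`.
#' @export
simulate_task_table <- function(truth, n_subjects, voxels_per_region = 1,
                                seed = 1L) {
  np <- truth$n_pairs
  tasks <- truth$tasks
  sdm <- truth$noise_sd / sqrt(voxels_per_region)
  grid <- expand.grid(pair_id = seq_len(np), task = tasks,
                      subject_id = seq_len(n_subjects),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  withr_seed(seed, {
    intercepts <- rnorm(n_subjects, 0, truth$intercept_sd)
    ti <- match(grid$task, tasks)
    grid$left_value <- truth$effect_means[cbind(grid$pair_id, ti, 1L)] +
      intercepts[grid$subject_id] + rnorm(nrow(grid), 0, sdm)
    grid$right_value <- truth$effect_means[cbind(grid$pair_id, ti, 2L)] +
      intercepts[grid$subject_id] + rnorm(nrow(grid), 0, sdm)
  })
  compute_asymmetries(grid[, c("subject_id", "pair_id", "task",
                               "left_value", "right_value")])
}
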