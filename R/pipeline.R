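#' Pipeline configuration
#'
#' Collects every tunable of the two-part analysis with study-scale defaults:
#' 144 task subjects, 138 resting subjects, three tasks, 185 homotopic pairs,
#' 240 volumes at TR 2 s, per-test alpha 0.05, 0.01-0.1 Hz band with a 65-tap
#' filter, average linkage, fixed_k = 2 networks, bootstrap scales
#' 0.5..1.4 with B replicates per scale.
#'
#' @param mode `"simulate"` (generate a synthetic cohort) or `"load"` (read a
#'   task signal table and resting series from `paths`).
#' @param paths named list of input paths for `mode = "load"`: `signal_table`
#'   (TSV), optionally `atlas_volume` + `atlas_pairs`.
#' @param n_pairs,n_subjects_task,n_subjects_rest,n_volumes,tr cohort scale.
#' @param planted_left,planted_right planted pair sets for simulation.
#' @param alpha_per_test per-test significance level.
#' @param scheme threshold scheme name for count tables.
#' @param band,n_taps bandpass edges (Hz) and FIR length.
#' @param linkage,clustering_rule clustering choices.
#' @param scales,B bootstrap configuration; `B = 0` skips AU computation.
#' @param profile if TRUE, fit the mixed models and Tukey tables.
#' @param seed master seed; stage seeds are derived from it.
#' @param output_dir optional directory for TSV/JSON outputs.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "load"), paths = list(),
                            n_pairs = 185, n_subjects_task = 144,
                            n_subjects_rest = 138, n_volumes = 240, tr = 2,
                            planted_left = 1:14, planted_right = 15:21,
                            alpha_per_test = 0.05, scheme = "methods",
                            band = c(0.01, 0.1), n_taps = 65,
                            linkage = "average",
                            clustering_rule = list(fixed_k = 2),
                            scales = seq(0.5, 1.4, by = 0.1), B = 1000,
                            profile = FALSE, seed = 1L, output_dir = NULL) {
  mode <- match.arg(mode)
  cfg <- list(mode = mode, paths = paths, n_pairs = n_pairs,
              n_subjects_task = n_subjects_task,
              n_subjects_rest = n_subjects_rest, n_volumes = n_volumes,
              tr = tr, planted_left = planted_left,
              planted_right = planted_right, alpha_per_test = alpha_per_test,
              scheme = scheme, band = band, n_taps = n_taps,
              linkage = linkage, clustering_rule = clustering_rule,
              scales = scales, B = B, profile = profile, seed = seed,
              output_dir = output_dir)
  if (mode == "load") {
    if (is.null(paths$signal_table))
      stop("config error: mode 'load' requires paths$signal_table")
    absent <- unlist(paths)[!file.exists(unlist(paths))]
    if (length(absent))
      stop("config error: missing input path(s): ",
           paste(absent, collapse = ", "))
  }
  stopifnot(band[1] < band[2], band[2] < 1 / (2 * tr))
  structure(cfg, class = "pipeline_config")
}

# Derived stage seeds, kept below 2^31.
stage_seed <- function(seed, stage) (as.integer(seed) * 101L + stage) %% 2000000000L

#' Run the full two-part pipeline
#'
#' Part 1: obtain the task signal table (simulated or loaded), run the
#' per-hemisphere conjunction selection and selection-step counts, and
#' optionally the mixed-model/Tukey task profiles of the selected regions.
#' Part 2: simulate (or load) resting-state series for the selected regions,
#' regress nuisance series and linear trend, bandpass filter, compute
#' per-subject correlations, Fisher-z average, cluster, attach AU support,
#' cut the partition and summarize the networks. Deterministic stages are
#' bit-identical across reruns with the same config and seed.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result` with elements `atlas`, `table`,
#'   `selection` (per hemisphere), `counts`, `regions`, `profiles` (optional),
#'   `connectivity`, `au`, `partition`, `summary`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  log_stage <- function(name) message(sprintf("[latnet] %s (%.1fs elapsed)",
                                              name,
                                              as.numeric(Sys.time() - t0, units = "secs")))
  truth <- NULL
  if (config$mode == "simulate") {
    log_stage("simulate: atlas + task cohort")
    truth <- cohort_truth(n_pairs = config$n_pairs,
                          planted_left = config$planted_left,
                          planted_right = config$planted_right)
    atlas <- make_toy_atlas(config$n_pairs,
                            grid_shape = toy_grid_for(config$n_pairs),
                            voxels_per_region = 1,
                            seed = stage_seed(config$seed, 1L))
    cohort <- simulate_task_maps(atlas, truth, config$n_subjects_task,
                                 seed = stage_seed(config$seed, 2L))
    table <- extract_task_table(cohort)
  } else {
    log_stage("load: signal table")
    atlas <- if (!is.null(config$paths$atlas_volume))
      load_atlas(config$paths$atlas_volume, config$paths$atlas_pairs)
    table <- task_signal_table(read.delim(config$paths$signal_table))
    table <- compute_asymmetries(table)
  }
  log_stage("select: conjunction per hemisphere")
  sel_left <- select_joint_hrois(table, "left", config$alpha_per_test)
  sel_right <- select_joint_hrois(table, "right", config$alpha_per_test)
  counts <- list(left = count_selection_steps(table, "left", config$scheme),
                 right = count_selection_steps(table, "right", config$scheme))
  regions <- rbind(
    data.frame(pair_id = sel_left$selected, hemisphere = "left"),
    data.frame(pair_id = sel_right$selected, hemisphere = "right"))
  if (nrow(regions) < 2)
    stop("stage 'select': fewer than 2 regions selected; cannot cluster")
  regions <- as_region_table(regions)
  profiles <- NULL
  if (isTRUE(config$profile)) {
    log_stage("profile: mixed models + Tukey")
    profiles <- list(
      activation_left = fit_mixed_model(table, "activation", "left",
                                        selected = sel_left$selected),
      asymmetry_left = fit_mixed_model(table, "asymmetry", "left",
                                       selected = sel_left$selected),
      tukey_left = tukey_pairwise(table, "activation", "left",
                                  selected = sel_left$selected))
  }
  log_stage("rest: simulate + preprocess")
  if (config$mode == "simulate") {
    rest <- simulate_resting_series(regions, truth,
                                    n_subjects = config$n_subjects_rest,
                                    n_volumes = config$n_volumes,
                                    tr = config$tr,
                                    seed = stage_seed(config$seed, 3L))
    stack <- as_region_series_stack(rest)
    stack <- regress_nuisance(stack, rest$nuisance)
  } else {
    stop("stage 'rest': loading resting series from disk requires ",
         "paths$rest_series; only simulate mode ships a generator")
  }
  stack <- bandpass_fir(stack, config$band[1], config$band[2], config$n_taps)
  log_stage("cluster: correlations + dendrogram + AU")
  cstack <- subject_correlations(stack)
  cstack <- group_connectivity(cstack)
  au <- NULL
  if (config$B > 0) {
    au <- multiscale_bootstrap_au(cstack, scales = config$scales,
                                  B = config$B,
                                  seed = stage_seed(config$seed, 4L),
                                  linkage = config$linkage)
    dend <- au
  } else {
    dend <- hierarchical_cluster(cstack$group_mean_r, config$linkage)
  }
  partition <- cut_partition(dend, config$clustering_rule)
  summary <- network_summary(partition, cstack, atlas, regions)
  manifest <- list(
    package_version = as.character(packageVersion("latnet")),
    seed = config$seed,
    config_hash = config_hash(config),
    n_selected = nrow(regions),
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S"))
  res <- structure(
    list(atlas = atlas, truth = truth, table = table,
         selection = list(left = sel_left, right = sel_right),
         counts = counts, regions = regions, profiles = profiles,
         connectivity = cstack, au = au, partition = partition,
         summary = summary, manifest = manifest, config = config),
    class = "pipeline_result")
  if (!is.null(config$output_dir)) write_pipeline_outputs(res, config$output_dir)
  log_stage("done")
  res
}

# A grid just big enough for n_pairs single-voxel mirrored regions.
toy_grid_for <- function(n_pairs) {
  half <- ceiling(sqrt(n_pairs))
  c(2L * half, half + 1L, max(2L, ceiling(n_pairs / (half * (half + 1L)))) + 1L)
}

# md5 of the canonical JSON of the config (paths and output_dir excluded).
config_hash <- function(config) {
  c2 <- config[setdiff(names(config), c("output_dir", "paths"))]
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(c2, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

#' Write pipeline outputs as TSV/JSON
#'
#' Selection tables, counts, the group connectivity matrix, the Newick
#' dendrogram, the partition and network summaries, and a JSON manifest
#' (package version, seed, config hash).
#'
#' @param res a `pipeline_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, name) write.table(x, file.path(dir, name), sep = "\t",
                                       quote = FALSE, row.names = FALSE)
  tsv(res$table, "signal_table.tsv")
  tsv(res$selection$left$per_task, "selection_left_per_task.tsv")
  tsv(res$selection$left$per_pair, "selection_left_per_pair.tsv")
  tsv(res$selection$right$per_task, "selection_right_per_task.tsv")
  tsv(res$selection$right$per_pair, "selection_right_per_pair.tsv")
  tsv(res$counts$left, "counts_left.tsv")
  tsv(res$counts$right, "counts_right.tsv")
  tsv(res$regions, "selected_regions.tsv")
  if (!is.null(res$profiles)) {
    tsv(res$profiles$activation_left, "effects_activation_left.tsv")
    tsv(res$profiles$asymmetry_left, "effects_asymmetry_left.tsv")
    tsv(res$profiles$tukey_left, "tukey_activation_left.tsv")
  }
  gm <- res$connectivity$group_mean_r
  tsv(data.frame(region_id = rownames(gm), gm, check.names = FALSE),
      "group_mean_r.tsv")
  writeLines(dendrogram_newick(if (!is.null(res$au)) res$au else
    hierarchical_cluster(gm)), file.path(dir, "dendrogram.newick"))
  if (!is.null(res$au)) tsv(res$au$nodes, "au_nodes.tsv")
  jsonlite::write_json(
    list(assignment = as.list(res$partition$assignment),
         n_networks = res$partition$n_networks),
    file.path(dir, "partition.json"), auto_unbox = TRUE, digits = NA)
  tsv(res$summary$networks, "networks.tsv")
  if (!is.null(res$summary$network_pairs))
    tsv(res$summary$network_pairs, "network_pairs.tsv")
  jsonlite::write_json(res$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("latnet pipeline result\n")
  cat(sprintf("  selected: %d left + %d right regions\n",
              length(x$selection$left$selected),
              length(x$selection$right$selected)))
  cat(sprintf("  networks: %d\n", x$partition$n_networks))
  invisible(x)
}
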