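#' Homotopic-pair ROI atlas
#'
#' A homotopic atlas is a 3-D integer label grid (0 = background) together with
#' a pair table mapping left- and right-hemisphere labels to named homotopic
#' pairs, a voxel size in mm, and a 4x4 affine taking 0-based voxel indices to
#' world mm coordinates. Hemisphere membership is defined by the sign of the
#' world x coordinate of each region's voxel centroid (x < 0 is left, the
#' radiological/MNI convention).
#'
#' @param label_grid 3-D integer array of region labels, 0 for background.
#' @param pairs data.frame with columns `pair_id`, `name`, `abbreviation`,
#'   `left_label`, `right_label`.
#' @param voxel_size numeric length-3, voxel edge lengths in mm.
#' @param affine 4x4 numeric matrix mapping homogeneous 0-based voxel indices
#'   to world mm. Defaults to a diagonal affine centred on the grid.
#' @return An object of class `homotopic_atlas`.
#' @seealso [load_atlas()], [make_toy_atlas()], [region_volume()]
#' @export
homotopic_atlas <- function(label_grid, pairs, voxel_size = c(2, 2, 2),
                            affine = NULL) {
  if (length(dim(label_grid)) != 3L)
    stop("`label_grid` must be a 3-D array")
  if (any(label_grid != round(label_grid)))
    stop("format error: `label_grid` contains non-integer labels")
  storage.mode(label_grid) <- "integer"
  if (!all(voxel_size > 0) || length(voxel_size) != 3L)
    stop("`voxel_size` must be three positive lengths (mm)")
  if (is.null(affine))
    affine <- centered_affine(dim(label_grid), voxel_size)
  req <- c("pair_id", "name", "abbreviation", "left_label", "right_label")
  if (!all(req %in% names(pairs)))
    stop("pair table must have columns ", paste(req, collapse = ", "))
  pairs <- as.data.frame(pairs)[, req]
  atlas <- structure(
    list(label_grid = label_grid, voxel_size = as.numeric(voxel_size),
         affine = affine, pairs = pairs),
    class = "homotopic_atlas")
  validate_atlas(atlas)
  atlas
}

# Diagonal affine placing the grid centre at world origin (0-based indices).
centered_affine <- function(grid_dim, voxel_size) {
  rbind(cbind(diag(voxel_size), -voxel_size * (grid_dim - 1) / 2),
        c(0, 0, 0, 1))
}

#' Validate a homotopic atlas
#'
#' Checks the structural invariants: every nonzero grid label belongs to
#' exactly one pair and one side, left and right label sets are disjoint, each
#' region has at least one voxel, and left (right) region centroids fall at
#' world x < 0 (x > 0). Validation is side-effect free.
#'
#' @param atlas a `homotopic_atlas`.
#' @return `TRUE`, invisibly; otherwise an error describing every violation.
#' @export
validate_atlas <- function(atlas) {
  p <- atlas$pairs
  errs <- character()
  if (anyDuplicated(p$pair_id))
    errs <- c(errs, "duplicate pair_id values")
  ll <- p$left_label; rl <- p$right_label
  if (any(ll == rl))
    errs <- c(errs, "pairs with identical left and right labels")
  all_lab <- c(ll, rl)
  if (anyDuplicated(all_lab))
    errs <- c(errs, sprintf("labels used more than once: %s",
                            paste(unique(all_lab[duplicated(all_lab)]), collapse = ", ")))
  grid_lab <- sort(unique(as.vector(atlas$label_grid)))
  grid_lab <- grid_lab[grid_lab != 0L]
  missing <- setdiff(all_lab, grid_lab)
  if (length(missing))
    errs <- c(errs, sprintf("labels in pair table absent from grid: %s",
                            paste(missing, collapse = ", ")))
  extra <- setdiff(grid_lab, all_lab)
  if (length(extra))
    errs <- c(errs, sprintf("grid labels not in any pair: %s",
                            paste(extra, collapse = ", ")))
  if (!length(errs)) {
    cx <- label_centroid_x(atlas)
    bad_l <- p$pair_id[cx[as.character(ll)] >= 0]
    bad_r <- p$pair_id[cx[as.character(rl)] <= 0]
    if (length(bad_l))
      errs <- c(errs, sprintf("left regions with centroid x >= 0 for pairs: %s",
                              paste(bad_l, collapse = ", ")))
    if (length(bad_r))
      errs <- c(errs, sprintf("right regions with centroid x <= 0 for pairs: %s",
                              paste(bad_r, collapse = ", ")))
  }
  if (length(errs))
    stop("atlas validation failed: ", paste(errs, collapse = "; "))
  invisible(TRUE)
}

# World-x centroid per label, named by label.
label_centroid_x <- function(atlas) {
  idx <- which(atlas$label_grid != 0L, arr.ind = TRUE) - 1  # 0-based
  lab <- atlas$label_grid[atlas$label_grid != 0L]
  a <- atlas$affine
  wx <- idx %*% a[1, 1:3] + a[1, 4]
  tapply(as.vector(wx), lab, mean)
}

#' Load a homotopic atlas from a NIfTI label volume and a pair table
#'
#' @param label_volume_path path to a NIfTI-1 (.nii/.nii.gz) integer label
#'   image.
#' @param pair_table_path path to a TSV with header
#'   `pair_id,name,abbreviation,left_label,right_label`.
#' @return a validated [homotopic_atlas()].
#' @export
load_atlas <- function(label_volume_path, pair_table_path) {
  img <- RNifti::readNifti(label_volume_path)
  arr <- array(as.vector(img), dim = dim(img))
  if (any(arr != round(arr)))
    stop("format error: label volume is not integer-valued")
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = dim(aff))
  vox <- abs(c(aff[1, 1], aff[2, 2], aff[3, 3]))
  if (any(vox == 0)) vox <- RNifti::pixdim(img)[1:3]
  pairs <- read.delim(pair_table_path, sep = "\t", stringsAsFactors = FALSE)
  homotopic_atlas(arr, pairs, voxel_size = vox, affine = aff)
}

#' Write a homotopic atlas to disk
#'
#' Writes the label grid as NIfTI-1 (int32, sform set from the atlas affine)
#' and the pair table as TSV.
#'
#' @param atlas a `homotopic_atlas`.
#' @param label_volume_path output .nii or .nii.gz path.
#' @param pair_table_path output TSV path.
#' @return the two paths, invisibly.
#' @export
write_atlas <- function(atlas, label_volume_path, pair_table_path) {
  img <- RNifti::asNifti(atlas$label_grid, datatype = "int32")
  img <- RNifti::`sform<-`(img, structure(atlas$affine, code = 2L))
  RNifti::writeNifti(img, label_volume_path)
  write.table(atlas$pairs, pair_table_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(label_volume_path, pair_table_path))
}

#' Region volume in mm^3
#'
#' Volume of one side of a homotopic pair: voxel count times voxel volume.
#' Additive over disjoint regions.
#'
#' @param atlas a `homotopic_atlas`.
#' @param pair_id pair identifier (scalar or vector).
#' @param side `"left"` or `"right"`.
#' @return numeric volume(s), mm^3.
#' @export
region_volume <- function(atlas, pair_id, side = c("left", "right")) {
  side <- match.arg(side)
  i <- match(pair_id, atlas$pairs$pair_id)
  if (anyNA(i))
    stop("unknown pair_id: ", paste(pair_id[is.na(i)], collapse = ", "))
  lab <- if (side == "left") atlas$pairs$left_label[i] else atlas$pairs$right_label[i]
  counts <- tabulate(atlas$label_grid, nbins = max(atlas$label_grid))
  counts[lab] * prod(atlas$voxel_size)
}

#' @export
print.homotopic_atlas <- function(x, ...) {
  cat(sprintf("Homotopic atlas: %d pairs (%d labels), grid %s, voxel %s mm\n",
              nrow(x$pairs), 2L * nrow(x$pairs),
              paste(dim(x$label_grid), collapse = "x"),
              paste(signif(x$voxel_size, 3), collapse = "x")))
  invisible(x)
}
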