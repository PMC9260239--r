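#' Scalar brain map
#'
#' One real value per voxel on a [volume_grid()] — used for CBF maps
#' (mL/100 g/min), VMHC maps (Fisher z), CBF/VMHC ratio maps, z-score maps
#' and statistic (t, p) maps. `NaN`/`NA` marks voxels outside the validity
#' mask of whatever produced the map.
#'
#' @param values numeric 3D array matching `grid$shape`.
#' @param grid a [volume_grid()].
#' @param units free-text unit label.
#' @return An object of class `scalar_map`.
#' @export
scalar_map <- function(values, grid, units = "") {
  values <- as.array(values)
  if (!identical(dim(values), as.integer(grid$shape)))
    nvc_grid_error("map values do not match the grid shape")
  storage.mode(values) <- "double"
  structure(list(values = values, grid = grid, units = units),
            class = "scalar_map")
}

#' @export
print.scalar_map <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("<scalar_map %s on %dx%dx%d grid; %d finite voxels, range [%.4g, %.4g]>\n",
              if (nzchar(x$units)) x$units else "(unitless)",
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3],
              length(v),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' BOLD time series volume
#'
#' A 4D resting-state series: one time series per voxel on a shared grid.
#'
#' @param data numeric 4D array, dimensions `c(grid$shape, n_timepoints)`.
#' @param grid a [volume_grid()].
#' @param tr_seconds repetition time in seconds (> 0).
#' @return An object of class `bold_series`.
#' @export
bold_series <- function(data, grid, tr_seconds) {
  data <- as.array(data)
  if (length(dim(data)) != 4L)
    nvc_format_error("BOLD data must be a 4D array")
  if (!identical(dim(data)[1:3], as.integer(grid$shape)))
    nvc_grid_error("BOLD data do not match the grid shape")
  if (dim(data)[4] < 2L)
    nvc_data_error("a BOLD series needs at least 2 timepoints")
  if (!is.finite(tr_seconds) || tr_seconds <= 0)
    nvc_config_error("'tr_seconds' must be > 0")
  storage.mode(data) <- "double"
  structure(list(data = data, grid = grid, n_timepoints = dim(data)[4],
                 tr_seconds = as.numeric(tr_seconds)),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  cat(sprintf("<bold_series %dx%dx%d x %d volumes, TR = %g s>\n",
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3],
              x$n_timepoints, x$tr_seconds))
  invisible(x)
}

## Voxels-by-time matrix view (voxel linear index fastest, so this is a
## plain reshape).
series_matrix <- function(series) {
  matrix(series$data, nrow = prod(series$grid$shape),
         ncol = series$n_timepoints)
}

#' Binary brain mask
#'
#' @param values array of 0/1 (or logical) matching the grid shape.
#' @param grid a [volume_grid()].
#' @param kind one of `"analysis"`, `"gray_matter"`, `"lesion"`. Gray-matter
#'   masks must contain at least one voxel; lesion masks may be empty
#'   (controls carry empty lesion masks).
#' @return An object of class `brain_mask`.
#' @export
brain_mask <- function(values, grid,
                       kind = c("analysis", "gray_matter", "lesion")) {
  kind <- match.arg(kind)
  values <- as.array(values)
  if (is.logical(values)) values <- values * 1L
  if (!identical(dim(values), as.integer(grid$shape)))
    nvc_grid_error("mask does not match the grid shape")
  if (any(is.na(values)) || !all(values %in% c(0, 1)))
    nvc_data_error("mask values must be 0 or 1")
  if (kind == "gray_matter" && sum(values) == 0)
    nvc_data_error("a gray-matter mask must contain at least one voxel")
  storage.mode(values) <- "integer"
  structure(list(values = values, grid = grid, kind = kind),
            class = "brain_mask")
}

#' @export
print.brain_mask <- function(x, ...) {
  cat(sprintf("<brain_mask [%s] %d/%d voxels>\n", x$kind,
              sum(x$values), prod(x$grid$shape)))
  invisible(x)
}

mask_logical <- function(mask) mask$values > 0L

#' Atlas label volume
#'
#' Integer region labels per voxel; 0 is background. Every nonzero label
#' present in the volume must have an entry in `names`. An optional
#' `homotopic_pairs` table records left/right label pairings.
#'
#' @param labels non-negative integer array matching the grid shape.
#' @param grid a [volume_grid()].
#' @param names named character vector mapping label (as name) to region
#'   name, e.g. `c("1" = "pSTS_L", "2" = "pSTS_R")`.
#' @param homotopic_pairs optional two-column matrix/data.frame of paired
#'   left/right labels.
#' @return An object of class `atlas_labels`.
#' @export
atlas_labels <- function(labels, grid, names, homotopic_pairs = NULL) {
  labels <- as.array(labels)
  if (!identical(dim(labels), as.integer(grid$shape)))
    nvc_grid_error("atlas labels do not match the grid shape")
  if (any(is.na(labels)) || any(labels < 0) || any(labels != round(labels)))
    nvc_data_error("atlas labels must be non-negative integers")
  storage.mode(labels) <- "integer"
  present <- sort(unique(labels[labels > 0L]))
  missing <- setdiff(as.character(present), base::names(names))
  if (length(missing))
    nvc_label_error(paste0("labels without a name entry: ",
                           paste(missing, collapse = ", ")))
  structure(list(labels = labels, grid = grid, names = names,
                 homotopic_pairs = homotopic_pairs),
            class = "atlas_labels")
}

#' Lesion volume in mL
#'
#' Counts nonzero voxels and converts to millilitres using the grid's voxel
#' volume (1 mL = 1000 mm^3), mirroring the usual mask volumetrics of
#' command-line neuroimaging tools.
#'
#' @param lesion a lesion [brain_mask()].
#' @return Volume in mL.
#' @export
lesion_volume_ml <- function(lesion) {
  stopifnot(inherits(lesion, "brain_mask"))
  if (lesion$kind != "lesion")
    nvc_data_error("lesion_volume_ml expects a mask of kind 'lesion'")
  sum(lesion$values) * voxel_volume_mm3(lesion$grid) / 1000
}

#' Lesion overlap map
#'
#' Voxel-wise sum of binary lesion masks: the value at a voxel is the number
#' of subjects with a lesion there.
#'
#' @param lesions list of lesion [brain_mask()] objects on one shared grid.
#' @return A [scalar_map()] of overlap counts.
#' @export
lesion_overlap_map <- function(lesions) {
  stopifnot(length(lesions) >= 1L)
  grid <- lesions[[1L]]$grid
  acc <- array(0, dim = grid$shape)
  for (m in lesions) {
    stopifnot_same_grid(grid, m$grid, "lesion masks")
    acc <- acc + m$values
  }
  scalar_map(acc, grid, units = "subjects")
}
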