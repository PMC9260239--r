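#' Z-score a map within a mask
#'
#' Subtracts the within-mask mean and divides by the within-mask population
#' (divide-by-n) standard deviation. Voxels outside the mask (or non-finite)
#' are NaN. A zero-SD (constant) map yields all zeros with a warning rather
#' than dividing by zero.
#'
#' @param map a [scalar_map()].
#' @param mask [brain_mask()] defining the normalization population.
#' @return A z-scored [scalar_map()].
#' @export
zscore_map <- function(map, mask) {
  stopifnot_same_grid(map$grid, mask$grid, "map/mask")
  sel <- mask_logical(mask) & is.finite(map$values)
  v <- map$values[sel]
  if (!length(v)) nvc_data_error("no finite in-mask voxels to z-score")
  mu <- mean(v)
  sd_ <- sqrt(mean((v - mu)^2))
  out <- array(NaN, dim = map$grid$shape)
  if (sd_ == 0) {
    warning("zero within-mask SD; z-score map set to 0")
    out[sel] <- 0
  } else {
    out[sel] <- (map$values[sel] - mu) / sd_
  }
  scalar_map(out, map$grid, units = "z")
}

#' Spatial CBF-VMHC coupling
#'
#' Pearson correlation across voxels between a subject's CBF map and VMHC
#' map over the jointly valid in-mask voxels: the whole-gray-matter
#' neurovascular coupling index. Being a Pearson correlation, it is
#' invariant to affine rescaling of either map, so raw and z-scored maps
#' give the same value.
#'
#' @param cbf CBF [scalar_map()].
#' @param vmhc VMHC map ([compute_vmhc()] output or any [scalar_map()]).
#' @param mask [brain_mask()], typically gray matter (minus the subject's
#'   lesion).
#' @param subject_id optional id carried into the result.
#' @return A `coupling_result`: list with `subject_id`, `spatial_r`,
#'   `n_voxels`.
#' @export
spatial_coupling <- function(cbf, vmhc, mask, subject_id = NA_character_) {
  stopifnot_same_grid(cbf$grid, vmhc$grid, "CBF/VMHC")
  stopifnot_same_grid(cbf$grid, mask$grid, "CBF/mask")
  sel <- mask_logical(mask) & is.finite(cbf$values) & is.finite(vmhc$values)
  if (!is.null(vmhc$valid)) sel <- sel & mask_logical(vmhc$valid)
  x <- cbf$values[sel]
  y <- vmhc$values[sel]
  if (length(x) < 3L)
    nvc_data_error("spatial coupling needs at least 3 jointly valid voxels")
  r <- if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance in a coupling input; spatial_r is NaN")
    NaN
  } else {
    stats::cor(x, y)
  }
  structure(list(subject_id = subject_id, spatial_r = r,
                 n_voxels = length(x)),
            class = "coupling_result")
}

#' @export
print.coupling_result <- function(x, ...) {
  cat(sprintf("<coupling_result %s: spatial r = %.3f over %d voxels>\n",
              x$subject_id, x$spatial_r, x$n_voxels))
  invisible(x)
}

#' CBF/VMHC ratio map
#'
#' Voxel-wise ratio of CBF to VMHC — the blood supply per unit of homotopic
#' connectivity strength. The ratio uses the *original* (pre-z-score) map
#' values: standardized CBF units over Fisher-z VMHC. Voxels with VMHC at or
#' below `vmhc_floor` (in particular the sub-threshold voxels floored to 0
#' by [compute_vmhc()]) are invalid, which keeps the denominator away from
#' zero. The z-scored ratio map used for group statistics is obtained by
#' composing with [zscore_map()].
#'
#' @param cbf CBF [scalar_map()].
#' @param vmhc VMHC map.
#' @param mask [brain_mask()] limiting the valid region.
#' @param vmhc_floor minimum VMHC for a valid ratio (default 0.05).
#' @return A `ratio_map` [scalar_map()] with a `valid` [brain_mask()].
#' @export
coupling_ratio <- function(cbf, vmhc, mask, vmhc_floor = 0.05) {
  stopifnot_same_grid(cbf$grid, vmhc$grid, "CBF/VMHC")
  stopifnot_same_grid(cbf$grid, mask$grid, "CBF/mask")
  sel <- mask_logical(mask) & is.finite(cbf$values) &
    is.finite(vmhc$values) & vmhc$values > vmhc_floor
  if (!is.null(vmhc$valid)) sel <- sel & mask_logical(vmhc$valid)
  out <- array(NaN, dim = cbf$grid$shape)
  out[sel] <- cbf$values[sel] / vmhc$values[sel]
  res <- scalar_map(out, cbf$grid, units = "CBF / Fisher z")
  res$valid <- brain_mask(array(sel, dim = cbf$grid$shape), cbf$grid,
                          "analysis")
  class(res) <- c("ratio_map", class(res))
  res
}
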