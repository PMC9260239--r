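#' Mirror-average a volume
#'
#' Averages a volume with its left-right mirrored counterpart, yielding an
#' exactly mirror-symmetric volume — the construction used to build
#' symmetric templates from anatomical images.
#'
#' @param volume a [scalar_map()] on an even grid.
#' @return A mirror-symmetric [scalar_map()].
#' @export
mirror_average <- function(volume) {
  stopifnot(inherits(volume, "scalar_map"))
  perm <- mirror_perm(volume$grid)
  out <- (volume$values + volume$values[perm]) / 2
  scalar_map(array(out, dim = volume$grid$shape), volume$grid,
             units = volume$units)
}

#' Voxel-mirrored homotopic connectivity (VMHC)
#'
#' For every voxel v inside the analysis mask whose mirror is also inside
#' the mask, computes the Pearson correlation r between the time series at v
#' and at mirror(v). Correlations below `threshold_r` (including all
#' negative r) are floored to 0 to suppress weak, noise-driven correlations;
#' the voxel stays valid. Surviving correlations are Fisher r-to-z
#' transformed (z = atanh(r), with r clipped to 1 - 1e-7 so z stays
#' finite). The same value is assigned to v and mirror(v), making the map
#' exactly mirror-symmetric. Voxels with a zero-variance series on either
#' side, or outside the mask pairing, are invalid (NaN).
#'
#' @param series preprocessed [bold_series()].
#' @param analysis_mask [brain_mask()]; a voxel is valid only if both it and
#'   its mirror are inside.
#' @param threshold_r correlation floor (default 0.2), applied on the r
#'   scale before the Fisher transform.
#' @return A `vmhc_map`: a [scalar_map()] of Fisher-z values with fields
#'   `threshold_r` and `valid` (a [brain_mask()]).
#' @export
compute_vmhc <- function(series, analysis_mask, threshold_r = 0.2) {
  stopifnot(inherits(series, "bold_series"))
  stopifnot_same_grid(series$grid, analysis_mask$grid, "BOLD/analysis mask")
  grid <- series$grid
  perm <- as.vector(mirror_perm(grid))
  inmask <- as.vector(mask_logical(analysis_mask))
  paired <- inmask & inmask[perm]

  m <- series_matrix(series)
  mu <- rowMeans(m)
  a <- m - mu
  ss <- rowSums(a * a)
  ok <- paired & ss > 0
  ok <- ok & ok[perm]

  r <- rep(NaN, length(perm))
  if (any(ok)) {
    i <- which(ok)
    num <- rowSums(a[i, , drop = FALSE] * a[perm[i], , drop = FALSE])
    r[i] <- num / sqrt(ss[i] * ss[perm[i]])
  } else {
    warning("no valid mirrored voxel pair inside the analysis mask; all-NaN VMHC map")
  }
  z <- r
  z[ok & r < threshold_r] <- 0
  keep <- ok & r >= threshold_r
  z[keep] <- atanh(pmin(pmax(r[keep], -1 + 1e-7), 1 - 1e-7))

  out <- scalar_map(array(z, dim = grid$shape), grid, units = "Fisher z")
  out$threshold_r <- threshold_r
  out$valid <- brain_mask(array(ok, dim = grid$shape), grid, "analysis")
  class(out) <- c("vmhc_map", class(out))
  out
}

#' @export
print.vmhc_map <- function(x, ...) {
  v <- x$values[mask_logical(x$valid)]
  cat(sprintf("<vmhc_map: %d valid voxels, threshold r = %g, mean z = %.3f>\n",
              length(v), x$threshold_r, mean(v)))
  invisible(x)
}

#' Per-subject whole-mask VMHC means
#'
#' Mean Fisher-z VMHC over the (valid, in-mask) voxels of each subject's
#' map; the per-subject summary used for whole-gray-matter group
#' comparisons.
#'
#' @param maps list of `vmhc_map`s.
#' @param mask [brain_mask()] over which to average (e.g. gray matter).
#' @return Named numeric vector of per-subject means.
#' @export
vmhc_group_mean <- function(maps, mask) {
  if (sum(mask$values) == 0) nvc_data_error("empty averaging mask")
  vapply(maps, function(m) {
    stopifnot_same_grid(m$grid, mask$grid, "VMHC/mask")
    sel <- mask_logical(mask) & is.finite(m$values)
    if (!is.null(m$valid)) sel <- sel & mask_logical(m$valid)
    mean(m$values[sel])
  }, numeric(1))
}
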