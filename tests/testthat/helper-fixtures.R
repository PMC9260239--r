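# Small in-code fixtures shared across the suite.

tiny_grid <- function(shape = c(6, 6, 4), voxel_size = c(3, 3, 3)) {
  volume_grid(shape, voxel_size)
}

full_mask <- function(grid, kind = "gray_matter") {
  brain_mask(array(1L, dim = grid$shape), grid, kind)
}

mask_at <- function(grid, voxels, kind = "lesion") {
  v <- array(0L, dim = grid$shape)
  for (i in seq_len(nrow(voxels))) v[voxels[i, 1], voxels[i, 2], voxels[i, 3]] <- 1L
  brain_mask(v, grid, kind)
}

random_map <- function(grid, seed = 1) {
  set.seed(seed)
  scalar_map(array(rnorm(prod(grid$shape)), dim = grid$shape), grid)
}

random_series <- function(grid, nt = 20, tr = 2, seed = 1) {
  set.seed(seed)
  bold_series(array(rnorm(prod(grid$shape) * nt), dim = c(grid$shape, nt)),
              grid, tr)
}

# gray-matter mask minus a subject's lesion
gm_minus <- function(gm, lesion) {
  brain_mask(gm$values > 0 & lesion$values == 0, gm$grid, "analysis")
}
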