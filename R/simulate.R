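#' Simulation configuration
#'
#' Defines the synthetic two-group cohort: 19 left-hemisphere stroke
#' patients and 22 controls with planted homotopic correlations, CBF-VMHC
#' spatial coupling, lesions, motion and behavior. The defaults encode the
#' study conditions the package's analyses are modelled on: 180 volumes at
#' TR = 2 s on a 3 mm grid; whole-gray-matter mean homotopic connectivity of
#' 0.53 (controls) vs 0.40 (patients) on the Fisher-z scale; spatial
#' CBF-VMHC coupling 0.51 vs 0.44; gray-matter CBF around 45.8 vs 43.8
#' mL/100 g/min; mean lesion volume around 61 mL (not attainable on very
#' small grids — scale `lesion_radius_mm` with the grid); cohort mean
#' framewise displacement around 0.096 mm; and a planted ROI-VMHC to
#' behavior partial correlation of 0.75.
#'
#' Homotopic-correlation truth maps are drawn per mirror pair on the
#' Fisher-z scale (`rho_z_mean_*`, `rho_z_sd`, clipped to `rho_z_range`) and
#' mapped through tanh, giving per-voxel targets in `[0, 1)`. The spatial
#' spread (`rho_z_sd = 0.4`) reflects the wide range of homotopic
#' correlation seen across gray matter in real resting-state maps
#' (r roughly 0 to 0.9).
#'
#' @param shape,voxel_size,lr_axis grid geometry (see [volume_grid()]).
#' @param n_patients,n_controls group sizes.
#' @param n_timepoints acquired BOLD volumes (before any trimming).
#' @param tr_seconds repetition time, s.
#' @param band analysis frequency band (Hz); simulated series are
#'   band-limited to it so that filtering preserves the planted structure.
#' @param rho_z_mean_control,rho_z_mean_patient group means of the
#'   homotopic-correlation truth maps, Fisher-z scale.
#' @param rho_z_sd,rho_z_range spatial SD and clipping range of the truth
#'   maps, Fisher-z scale.
#' @param subject_z_sd_control,subject_z_sd_patient between-subject SD of a
#'   global Fisher-z offset applied to each subject's truth map, matched to
#'   the reference cohort's between-subject spread of whole-gray-matter
#'   VMHC (0.04 controls, 0.10 patients).
#' @param roi_z_sd extra between-subject Fisher-z SD planted in the
#'   behavior ROI of patients: the true connectivity variation that carries
#'   the brain-behavior effect (it must dominate measurement noise for the
#'   effect to be recoverable, as it does in real cohorts).
#' @param coupling_r_control,coupling_r_patient target across-voxel
#'   CBF-VMHC Pearson correlations, in (-1, 1).
#' @param cbf_mean_control,cbf_mean_patient gray-matter mean CBF,
#'   mL/100 g/min.
#' @param cbf_spatial_sd across-voxel SD of simulated CBF.
#' @param behavior_effect_r planted partial correlation between the target
#'   ROI's VMHC and the total comprehension score, |r| < 1.
#' @param behavior_roi name of the atlas region carrying the behavior
#'   effect.
#' @param lesion_n_range min/max spherical lesions per patient.
#' @param lesion_radius_mm min/max lesion sphere radius, mm.
#' @param motion_step_mm,motion_step_rad random-walk step SDs of the motion
#'   traces.
#' @param noise_sd unit noise scale of the BOLD components.
#' @param seed integer RNG seed; a fixed seed makes every generated
#'   artifact bit-reproducible.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(shape = c(36, 40, 36), voxel_size = c(3, 3, 3),
                       lr_axis = 1L,
                       n_patients = 19L, n_controls = 22L,
                       n_timepoints = 180L, tr_seconds = 2,
                       band = c(0.01, 0.08),
                       rho_z_mean_control = 0.53, rho_z_mean_patient = 0.40,
                       rho_z_sd = 0.40, rho_z_range = c(0.02, 1.8),
                       subject_z_sd_control = 0.04,
                       subject_z_sd_patient = 0.10, roi_z_sd = 0.15,
                       coupling_r_control = 0.51, coupling_r_patient = 0.44,
                       cbf_mean_control = 45.8, cbf_mean_patient = 43.8,
                       cbf_spatial_sd = 12,
                       behavior_effect_r = 0.75, behavior_roi = "pSTS_L",
                       lesion_n_range = c(1L, 1L),
                       lesion_radius_mm = c(20, 26),
                       motion_step_mm = 0.02, motion_step_rad = 4e-4,
                       noise_sd = 1, seed = 1L) {
  grid <- volume_grid(shape, voxel_size, lr_axis)
  for (r in c(coupling_r_control, coupling_r_patient))
    if (!is.finite(r) || abs(r) >= 1)
      nvc_config_error("coupling targets must lie strictly inside (-1, 1)")
  if (abs(behavior_effect_r) >= 1)
    nvc_config_error("behavior_effect_r must satisfy |r| < 1")
  if (rho_z_range[1] < 0)
    nvc_config_error("homotopic-correlation targets must be >= 0")
  if (n_timepoints < 2L) nvc_config_error("n_timepoints must be >= 2")
  cfg <- list(grid = grid, n_patients = as.integer(n_patients),
              n_controls = as.integer(n_controls),
              n_timepoints = as.integer(n_timepoints),
              tr_seconds = tr_seconds, band = band,
              rho_z_mean_control = rho_z_mean_control,
              rho_z_mean_patient = rho_z_mean_patient,
              rho_z_sd = rho_z_sd, rho_z_range = rho_z_range,
              subject_z_sd_control = subject_z_sd_control,
              subject_z_sd_patient = subject_z_sd_patient,
              roi_z_sd = roi_z_sd,
              coupling_r_control = coupling_r_control,
              coupling_r_patient = coupling_r_patient,
              cbf_mean_control = cbf_mean_control,
              cbf_mean_patient = cbf_mean_patient,
              cbf_spatial_sd = cbf_spatial_sd,
              behavior_effect_r = behavior_effect_r,
              behavior_roi = behavior_roi,
              lesion_n_range = as.integer(lesion_n_range),
              lesion_radius_mm = lesion_radius_mm,
              motion_step_mm = motion_step_mm,
              motion_step_rad = motion_step_rad,
              noise_sd = noise_sd, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Read a simulation configuration from YAML
#'
#' The YAML keys mirror the [sim_config()] arguments field-for-field.
#'
#' @param path YAML file path.
#' @return A `sim_config`.
#' @export
sim_config_from_yaml <- function(path) {
  do.call(sim_config, yaml::read_yaml(path))
}

group_field <- function(config, prefix, group) {
  config[[paste0(prefix, "_", group)]]
}

#' Ellipsoidal gray-matter mask
#'
#' A mirror-symmetric ellipsoid centred in the grid with semi-axes at 45%
#' of each extent: a stand-in gray-matter compartment for simulated
#' cohorts.
#'
#' @param grid a [volume_grid()].
#' @return A gray-matter [brain_mask()].
#' @export
sim_gray_matter <- function(grid) {
  n <- grid$shape
  ctr <- (n + 1) / 2
  semi <- 0.45 * n
  d2 <- outer(((seq_len(n[1]) - ctr[1]) / semi[1])^2,
              ((seq_len(n[2]) - ctr[2]) / semi[2])^2, "+")
  d3 <- outer(as.vector(d2), ((seq_len(n[3]) - ctr[3]) / semi[3])^2, "+")
  brain_mask(array(d3 <= 1, dim = n), grid, "gray_matter")
}

#' Symmetric synthetic atlas
#'
#' Four pairs of mirror-symmetric cubic regions inside the gray-matter
#' compartment, named after the temporoparietal/cingulate parcels whose
#' roles the synthetic behavior effects emulate (pSTS, A39rv, A40c, A23v;
#' `_L`/`_R` for hemisphere). Odd labels are left, the following even label
#' is the right-hemisphere mirror.
#'
#' @param grid a [volume_grid()].
#' @return An [atlas_labels()] with `homotopic_pairs`.
#' @export
sim_atlas <- function(grid) {
  n <- grid$shape
  base <- c("pSTS", "A39rv", "A40c", "A23v")
  centers <- rbind(c(0.28, 0.35, 0.50),
                   c(0.30, 0.62, 0.58),
                   c(0.26, 0.50, 0.38),
                   c(0.36, 0.46, 0.66))
  hw <- pmax(1L, round(n / 14))
  labs <- array(0L, dim = n)
  perm <- mirror_perm(grid)
  for (k in seq_along(base)) {
    ctr <- round(centers[k, ] * n)
    rng <- lapply(1:3, function(a)
      max(1L, ctr[a] - hw[a]):min(n[a], ctr[a] + hw[a]))
    labs[rng[[1]], rng[[2]], rng[[3]]] <- 2L * k - 1L
  }
  right <- array(labs[perm], dim = n)
  labs[right > 0L] <- right[right > 0L] + 1L
  names <- stats::setNames(paste0(rep(base, each = 2), c("_L", "_R")),
                           seq_len(2L * length(base)))
  atlas_labels(labs, grid, names,
               homotopic_pairs = cbind(left = 2L * seq_along(base) - 1L,
                                       right = 2L * seq_along(base)))
}

#' Homotopic-correlation truth map
#'
#' Draws one target correlation per mirror pair — Gaussian on the Fisher-z
#' scale, clipped, then mapped through tanh — and assigns it to both
#' members, yielding a mirror-symmetric per-voxel map of target homotopic
#' correlations in `[0, 1)`.
#'
#' @param config a [sim_config()].
#' @param group `"control"` or `"patient"`.
#' @param seed RNG seed (default: from config).
#' @return A [scalar_map()] of target correlations (units `"rho"`).
#' @export
simulate_rho_map <- function(config, group = c("control", "patient"),
                             seed = config$seed) {
  group <- match.arg(group)
  if (!is.null(seed)) set.seed(seed)
  grid <- config$grid
  left <- left_half_indices(grid)
  perm <- mirror_perm(grid)
  z <- stats::rnorm(length(left), group_field(config, "rho_z_mean", group),
                    config$rho_z_sd)
  z <- pmin(pmax(z, config$rho_z_range[1]), config$rho_z_range[2])
  vals <- numeric(n_voxels(grid))
  vals[left] <- tanh(z)
  vals[perm[left]] <- tanh(z)
  scalar_map(array(vals, dim = grid$shape), grid, units = "rho")
}

## Per-subject truth map: group map plus a global Fisher-z offset (true
## between-subject variation) and, for patients, an extra offset on the
## behavior ROI's pairs (the variation that carries the behavior effect).
## Offsets are applied symmetrically and the result re-clipped.
subject_rho_map <- function(config, base_rho, group, roi_voxels = NULL) {
  z <- atanh(base_rho$values)
  z <- z + stats::rnorm(1, 0, group_field(config, "subject_z_sd", group))
  if (!is.null(roi_voxels) && length(roi_voxels) && config$roi_z_sd > 0) {
    perm <- mirror_perm(base_rho$grid)
    hit <- union(roi_voxels, perm[roi_voxels])
    z[hit] <- z[hit] + stats::rnorm(1, 0, config$roi_z_sd)
  }
  z <- pmin(pmax(z, config$rho_z_range[1]), config$rho_z_range[2])
  scalar_map(array(tanh(z), dim = base_rho$grid$shape), base_rho$grid,
             units = "rho")
}

## Zero out the target correlation of every mirror pair touching a lesion:
## homotopic connectivity collapses when either member is infarcted.
lesion_aware_rho <- function(rho_map, lesion) {
  if (is.null(lesion) || sum(lesion$values) == 0) return(rho_map)
  perm <- mirror_perm(rho_map$grid)
  les <- as.vector(mask_logical(lesion))
  hit <- les | les[perm]
  vals <- as.vector(rho_map$values)
  vals[hit] <- 0
  scalar_map(array(vals, dim = rho_map$grid$shape), rho_map$grid,
             units = rho_map$units)
}

## Band-limited unit-variance noise matrix (nt x k): white noise passed
## through the ideal analysis-band filter, each column rescaled to SD 1.
bandlimited_noise <- function(nt, k, tr, band) {
  x <- matrix(stats::rnorm(nt * k), nt, k)
  x <- detrend_bandpass_matrix(x, tr, band[1], band[2])
  sc <- sqrt(colMeans(x^2))
  sweep(x, 2, pmax(sc, 1e-12), "/")
}

#' Simulate a BOLD series with planted homotopic correlation
#'
#' Each mirror pair with target correlation rho gets
#' `left = sqrt(rho) g + sqrt(1 - rho) e_L` and
#' `right = sqrt(rho) g + sqrt(1 - rho) e_R`, where g, e_L, e_R are
#' independent unit-variance noise series band-limited to the analysis
#' band, so the expected Pearson correlation of the pair is exactly rho and
#' band-pass filtering does not destroy the planted structure. Voxels
#' inside a lesion are replaced by near-zero signal plus low-amplitude
#' noise (infarct dropout), and their pairs' targets are forced to 0.
#'
#' @param config a [sim_config()].
#' @param group `"control"` or `"patient"`.
#' @param rho_map optional truth [scalar_map()] (defaults to
#'   [simulate_rho_map()] for the group).
#' @param lesion optional lesion [brain_mask()].
#' @param seed RNG seed (default: from config).
#' @return A [bold_series()] with attribute-free planted structure; the
#'   truth map used is attached as field `rho_truth`.
#' @export
simulate_bold <- function(config, group = c("control", "patient"),
                          rho_map = NULL, lesion = NULL,
                          seed = config$seed) {
  group <- match.arg(group)
  if (!is.null(seed)) set.seed(seed)
  grid <- config$grid
  if (is.null(rho_map)) rho_map <- simulate_rho_map(config, group, seed = NULL)
  stopifnot_same_grid(grid, rho_map$grid, "rho map")
  rho_map <- lesion_aware_rho(rho_map, lesion)
  rho <- as.vector(rho_map$values)
  if (any(!is.finite(rho)) || any(rho < 0) || any(rho >= 1))
    nvc_config_error("homotopic-correlation targets must lie in [0, 1)")

  left <- left_half_indices(grid)
  perm <- mirror_perm(grid)
  p <- length(left)
  nt <- config$n_timepoints
  rl <- rho[left]
  noise <- config$noise_sd *
    bandlimited_noise(nt, 3L * p, config$tr_seconds, config$band)
  g  <- noise[, seq_len(p), drop = FALSE]
  eL <- noise[, p + seq_len(p), drop = FALSE]
  eR <- noise[, 2L * p + seq_len(p), drop = FALSE]
  sr <- sqrt(rl); sq <- sqrt(1 - rl)
  mat <- matrix(0, n_voxels(grid), nt)
  mat[left, ]       <- t(sweep(g, 2, sr, "*") + sweep(eL, 2, sq, "*"))
  mat[perm[left], ] <- t(sweep(g, 2, sr, "*") + sweep(eR, 2, sq, "*"))
  mat <- mat + 100                            # baseline signal level
  if (!is.null(lesion) && sum(lesion$values) > 0) {
    les <- which(as.vector(mask_logical(lesion)))
    mat[les, ] <- 0.05 * stats::rnorm(length(les) * nt)
  }
  out <- bold_series(array(mat, dim = c(grid$shape, nt)), grid,
                     config$tr_seconds)
  out$rho_truth <- rho_map
  out
}

#' Simulate a CBF map coupled to a VMHC truth map
#'
#' `CBF = mean + spread * (b s + sqrt(1 - b^2) eps)` where s is the
#' standardized (mean 0, SD 1 within the mask) truth map, b the group's
#' coupling target and eps unit Gaussian noise, so the expected
#' across-voxel Pearson correlation with the truth map equals the target.
#' Gray-matter mean lands on the group's CBF level. Voxels outside the mask
#' get low background perfusion; lesioned voxels get near-zero perfusion
#' plus noise.
#'
#' @param config a [sim_config()].
#' @param vmhc_truth truth [scalar_map()] on the Fisher-z scale (e.g.
#'   `atanh` of a rho map).
#' @param group `"control"` or `"patient"`.
#' @param gm gray-matter [brain_mask()] (default: [sim_gray_matter()]).
#' @param lesion optional lesion [brain_mask()]; excluded from the
#'   standardization population and overwritten with near-zero perfusion.
#' @param seed RNG seed (default: from config).
#' @return A CBF [scalar_map()] in mL/100 g/min.
#' @export
simulate_cbf <- function(config, vmhc_truth, group = c("control", "patient"),
                         gm = NULL, lesion = NULL, seed = config$seed) {
  group <- match.arg(group)
  if (!is.null(seed)) set.seed(seed)
  grid <- config$grid
  stopifnot_same_grid(grid, vmhc_truth$grid, "vmhc truth")
  if (is.null(gm)) gm <- sim_gray_matter(grid)
  b <- group_field(config, "coupling_r", group)
  if (abs(b) >= 1) nvc_config_error("coupling target must be inside (-1, 1)")
  mu <- group_field(config, "cbf_mean", group)
  sel <- as.vector(mask_logical(gm))
  if (!is.null(lesion)) sel <- sel & !as.vector(mask_logical(lesion))
  tv <- as.vector(vmhc_truth$values)
  s <- (tv - mean(tv[sel])) / pop_sd(tv[sel])
  eps <- stats::rnorm(n_voxels(grid))
  cbf <- mu + config$cbf_spatial_sd * (b * s + sqrt(1 - b^2) * eps)
  outside <- !as.vector(mask_logical(gm))
  cbf[outside] <- 0.6 * mu +
    0.5 * config$cbf_spatial_sd * stats::rnorm(sum(outside))
  if (!is.null(lesion)) {
    les <- as.vector(mask_logical(lesion))
    cbf[les] <- abs(stats::rnorm(sum(les), 2, 1))
  }
  scalar_map(array(cbf, dim = grid$shape), grid, units = "mL/100g/min")
}

#' Simulate left-hemisphere spherical lesions
#'
#' Each patient gets 1 or more spheres drawn from the configured radius
#' range, placed entirely within the left half of the grid; controls get
#' empty masks. With the default grid and radii (20-26 mm on a 36-voxel,
#' 3 mm left-right extent) voxelized lesion volumes average near the
#' reference cohort's 61 mL scale.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed (default: from config).
#' @return List of lesion [brain_mask()]s, patients first, then (empty)
#'   control masks.
#' @export
simulate_lesions <- function(config, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  grid <- config$grid
  n <- grid$shape
  vs <- grid$voxel_size
  a <- grid$lr_axis
  half_mm <- (n[a] / 2) * vs[a]
  rmax <- config$lesion_radius_mm[2]
  if (2 * rmax > half_mm || any(2 * rmax > n[-a] * vs[-a]))
    nvc_config_error(sprintf(
      "lesion radius %g mm cannot fit inside the left hemisphere (%g mm); scale lesion_radius_mm with the grid",
      rmax, half_mm))
  coords_mm <- lapply(1:3, function(ax) (seq_len(n[ax]) - 0.5) * vs[ax])
  masks <- vector("list", config$n_patients + config$n_controls)
  for (i in seq_len(config$n_patients)) {
    vol <- array(FALSE, dim = n)
    k <- if (config$lesion_n_range[1] == config$lesion_n_range[2])
      config$lesion_n_range[1]
    else sample(config$lesion_n_range[1]:config$lesion_n_range[2], 1L)
    for (s in seq_len(k)) {
      r <- stats::runif(1, config$lesion_radius_mm[1], rmax)
      ctr <- numeric(3)
      for (ax in 1:3) {
        hi <- if (ax == a) half_mm - r else n[ax] * vs[ax] - r
        ctr[ax] <- stats::runif(1, r, hi)
      }
      d2 <- outer((coords_mm[[1]] - ctr[1])^2,
                  (coords_mm[[2]] - ctr[2])^2, "+")
      d3 <- outer(as.vector(d2), (coords_mm[[3]] - ctr[3])^2, "+")
      vol <- vol | array(d3 <= r^2, dim = n)
    }
    masks[[i]] <- brain_mask(vol, grid, "lesion")
  }
  empty <- brain_mask(array(0L, dim = n), grid, "lesion")
  for (i in config$n_patients + seq_len(config$n_controls))
    masks[[i]] <- empty
  masks
}

#' Simulate 6-parameter motion traces
#'
#' Gaussian random walks for three translations (mm) and three rotations
#' (rad), with a per-subject amplitude factor, calibrated so the cohort
#' mean framewise displacement lands near 0.096 mm at the default steps
#' (mean FD scales linearly with the step sizes).
#'
#' @param config a [sim_config()].
#' @param n_subjects number of traces to generate (default: whole cohort).
#' @param seed RNG seed (default: from config).
#' @return List of `n_timepoints` x 6 matrices.
#' @export
simulate_motion <- function(config,
                            n_subjects = config$n_patients + config$n_controls,
                            seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  nt <- config$n_timepoints
  lapply(seq_len(n_subjects), function(i) {
    amp <- stats::runif(1, 0.6, 1.4)
    steps <- cbind(matrix(stats::rnorm(3 * nt, 0, config$motion_step_mm),
                          nt, 3),
                   matrix(stats::rnorm(3 * nt, 0, config$motion_step_rad),
                          nt, 3)) * amp
    steps[1, ] <- 0
    m <- apply(steps, 2, cumsum)
    colnames(m) <- c("tx", "ty", "tz", "rx", "ry", "rz")
    m
  })
}

#' Simulate behavior scores from ROI homotopic connectivity
#'
#' Patient comprehension scores on a 0-100 scale: a linear function of the
#' subject's ROI VMHC plus age and education terms plus noise, with the
#' noise amplitude solved so that the expected partial correlation between
#' score and ROI VMHC (controlling age and education) equals
#' `behavior_effect_r`. Word- and sentence-level subscores and the aphasia
#' quotient are derived from the total with extra noise. All scores are
#' clipped to `[0, 100]`.
#'
#' @param config a [sim_config()].
#' @param roi_vmhc numeric vector of per-subject ROI VMHC values (patients
#'   only).
#' @param age,education optional covariate vectors; drawn from the
#'   reference cohort's distributions when omitted.
#' @param seed RNG seed (default: from config).
#' @return data.frame with `comp_total`, `comp_word`, `comp_sentence`,
#'   `aq`, `age`, `education`.
#' @export
simulate_behavior <- function(config, roi_vmhc, age = NULL, education = NULL,
                              seed = config$seed) {
  if (abs(config$behavior_effect_r) >= 1)
    nvc_config_error("behavior_effect_r must satisfy |r| < 1")
  if (!is.null(seed)) set.seed(seed)
  n <- length(roi_vmhc)
  if (n < 3L) nvc_data_error("need at least 3 subjects to simulate behavior")
  if (is.null(age)) age <- round(pmin(pmax(stats::rnorm(n, 60.1, 13.1),
                                           25), 80))
  if (is.null(education)) education <- round(pmin(pmax(
    stats::rnorm(n, 9.9, 3.7), 6), 20))
  std <- function(v) if (stats::sd(v) == 0) v * 0 else
    (v - mean(v)) / stats::sd(v)
  r <- config$behavior_effect_r
  amp <- 15                                   # score points per SD
  clip <- function(v) pmin(pmax(v, 0), 100)
  total <- 55 + 5 * std(education) - 5 * std(age) +
    amp * (r * std(roi_vmhc) + sqrt(1 - r^2) * stats::rnorm(n))
  total <- clip(total)
  data.frame(
    comp_total = total,
    comp_word = clip(total + stats::rnorm(n, 0, 8)),
    comp_sentence = clip(total + stats::rnorm(n, 0, 8)),
    aq = clip(0.8 * total - 8 + stats::rnorm(n, 0, 10)),
    age = age, education = education)
}

#' Simulate a full cohort study
#'
#' Assembles grid, gray matter, atlas, lesions, per-subject BOLD, CBF and
#' motion, and patient behavior into a [cohort_study()] with known ground
#' truth. Patients' homotopic-correlation truth maps are lesion-aware
#' (pairs touching the subject's lesion are set to 0), and each patient's
#' CBF is planted against their own truth map, so the group coupling
#' targets hold over the lesion-masked gray matter. Behavior is generated
#' for patients only, from their *measured* ROI VMHC (computed from the
#' simulated series), so the planted brain-behavior partial correlation
#' refers to the quantity the pipeline actually recovers.
#'
#' @param config a [sim_config()].
#' @return A `cohort_study` with extra fields `config` and `truth`
#'   (group rho maps and per-patient measured ROI VMHC).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  grid <- config$grid
  gm <- sim_gray_matter(grid)
  atlas <- sim_atlas(grid)
  n_pat <- config$n_patients; n_con <- config$n_controls
  ids <- c(sprintf("pat%02d", seq_len(n_pat)),
           sprintf("con%02d", seq_len(n_con)))
  groups <- rep(c("patient", "control"), c(n_pat, n_con))

  lesions <- simulate_lesions(config, seed = next_seed())
  names(lesions) <- ids
  rho_con <- simulate_rho_map(config, "control", seed = next_seed())
  rho_pat <- simulate_rho_map(config, "patient", seed = next_seed())
  motion <- simulate_motion(config, seed = next_seed())
  names(motion) <- ids

  roi_label <- as.integer(names(atlas$names)[atlas$names ==
                                               config$behavior_roi])
  if (!length(roi_label))
    nvc_config_error(sprintf("behavior_roi '%s' is not an atlas region",
                             config$behavior_roi))
  bold <- list(); cbf <- list()
  roi_vmhc <- numeric(0)
  for (i in seq_along(ids)) {
    grp <- groups[i]
    les <- if (grp == "patient") lesions[[i]] else NULL
    rho <- if (grp == "patient") rho_pat else rho_con
    roi_vox <- if (grp == "patient") which(atlas$labels == roi_label) else NULL
    rho_i <- subject_rho_map(config, rho, grp, roi_voxels = roi_vox)
    rho_i <- lesion_aware_rho(rho_i, les)
    b <- simulate_bold(config, grp, rho_map = rho_i, lesion = les,
                       seed = next_seed())
    truth_z <- scalar_map(atanh(rho_i$values), grid, units = "Fisher z")
    cbf[[ids[i]]] <- simulate_cbf(config, truth_z, grp, gm = gm,
                                  lesion = les, seed = next_seed())
    bold[[ids[i]]] <- b
    if (grp == "patient") {
      vm <- compute_vmhc(b, gm)
      sel <- atlas$labels == roi_label & mask_logical(vm$valid)
      roi_vmhc <- c(roi_vmhc, mean(vm$values[sel]))
    }
  }

  behavior <- simulate_behavior(config, roi_vmhc, seed = next_seed())
  sex <- c(sample(rep(c("F", "M"), c(5, n_pat - min(5, n_pat)))[seq_len(n_pat)]),
           sample(rep(c("F", "M"), c(10, max(n_con - 10, 0)))[seq_len(n_con)]))
  phenotype <- data.frame(
    subject_id = ids, group = groups,
    age = c(behavior$age,
            round(pmin(pmax(stats::rnorm(n_con, 54.3, 13.7), 25), 80))),
    sex = sex,
    education = c(behavior$education,
                  round(pmin(pmax(stats::rnorm(n_con, 10.4, 4.5), 6), 20))),
    lesion_volume = vapply(lesions, lesion_volume_ml, numeric(1)),
    stringsAsFactors = FALSE)
  for (b in c("comp_total", "comp_word", "comp_sentence", "aq"))
    phenotype[[b]] <- c(behavior[[b]], rep(NA_real_, n_con))

  study <- cohort_study(phenotype, bold, cbf, lesions, gm, atlas,
                        motion = motion)
  study$config <- config
  study$truth <- list(rho_control = rho_con, rho_patient = rho_pat,
                      roi_vmhc = roi_vmhc, roi_label = roi_label)
  study
}

#' Write a simulated cohort to disk
#'
#' NIfTI volumes (BOLD, CBF, lesion masks, gray matter, atlas), one motion
#' table per subject, and the phenotype CSV — the on-disk layout the CLI
#' `simulate` subcommand produces.
#'
#' @param study a `cohort_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in study$phenotype$subject_id) {
    write_volume(study$bold[[id]], file.path(dir, paste0(id, "_bold.nii.gz")))
    write_volume(study$cbf[[id]], file.path(dir, paste0(id, "_cbf.nii.gz")))
    write_volume(study$lesions[[id]],
                 file.path(dir, paste0(id, "_lesion.nii.gz")))
    if (!is.null(study$motion))
      write_motion(study$motion[[id]],
                   file.path(dir, paste0(id, "_motion.txt")))
  }
  write_volume(study$gray_matter, file.path(dir, "gray_matter.nii.gz"))
  write_volume(study$atlas, file.path(dir, "atlas.nii.gz"))
  utils::write.csv(study$phenotype, file.path(dir, "phenotype.csv"),
                   row.names = FALSE)
  invisible(dir)
}
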