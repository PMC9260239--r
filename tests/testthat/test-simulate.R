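test_that("simulated BOLD carries the planted homotopic correlation", {
  cfg <- sim_config(shape = c(4, 4, 2), n_timepoints = 10000, seed = 1,
                    lesion_radius_mm = c(2, 3))
  g <- cfg$grid
  pair_r <- function(series) {
    perm <- nvcoupling:::mirror_perm(g)
    left <- nvcoupling:::left_half_indices(g)
    m <- nvcoupling:::series_matrix(series)
    vapply(left, function(i) cor(m[i, ], m[perm[i], ]), numeric(1))
  }
  null_map <- scalar_map(array(0, g$shape), g)
  b0 <- simulate_bold(cfg, "control", rho_map = null_map, seed = 2)
  expect_lt(abs(mean(pair_r(b0))), 0.03)

  hi_map <- scalar_map(array(0.81, g$shape), g)
  b1 <- simulate_bold(cfg, "control", rho_map = hi_map, seed = 3)
  expect_lt(abs(mean(pair_r(b1)) - 0.81), 0.02)

  # determinism: same seed, same series
  b2 <- simulate_bold(cfg, "control", rho_map = hi_map, seed = 3)
  expect_identical(b1$data, b2$data)

  bad <- scalar_map(array(1, g$shape), g)
  expect_error(simulate_bold(cfg, "control", rho_map = bad, seed = 4),
               class = "nvc_config_error")
})

test_that("simulated BOLD is band-limited so filtering preserves the structure", {
  cfg <- sim_config(shape = c(4, 4, 2), n_timepoints = 200, seed = 5,
                    lesion_radius_mm = c(2, 3))
  b <- simulate_bold(cfg, "control", seed = 6)
  # no spectral energy outside the analysis band (beyond DC/baseline)
  m <- t(nvcoupling:::series_matrix(b))
  m <- sweep(m, 2, colMeans(m))
  sp <- Mod(stats::mvfft(m))^2
  freq <- (0:(200 - 1)) / (200 * cfg$tr_seconds)
  freq <- pmin(freq, 1 / cfg$tr_seconds - freq)
  out_band <- freq > 0 & (freq < 0.01 - 1e-9 | freq > 0.08 + 1e-9)
  expect_lt(sum(sp[out_band, ]) / sum(sp), 1e-3)
  # the planted pair correlations survive detrending + band-pass filtering
  bf <- detrend_bandpass(b)
  perm <- nvcoupling:::mirror_perm(cfg$grid)
  left <- nvcoupling:::left_half_indices(cfg$grid)
  pr <- function(series) {
    sm <- nvcoupling:::series_matrix(series)
    vapply(left, function(i) cor(sm[i, ], sm[perm[i], ]), numeric(1))
  }
  expect_lt(max(abs(pr(b) - pr(bf))), 0.02)
})

test_that("simulated CBF hits its coupling target and gray-matter level", {
  cfg_hi <- sim_config(shape = c(26, 26, 18), coupling_r_control = 0.99,
                       lesion_radius_mm = c(5, 8), seed = 7)
  g <- cfg_hi$grid
  gm_all <- full_mask(g)                            # >= 10^4 voxels
  truth <- random_map(g, seed = 8)
  cb <- simulate_cbf(cfg_hi, truth, "control", gm = gm_all, seed = 9)
  expect_gte(cor(as.vector(cb$values), as.vector(truth$values)), 0.95)

  cfg0 <- sim_config(shape = c(26, 26, 18), coupling_r_control = 0,
                     lesion_radius_mm = c(5, 8), seed = 10)
  cb0 <- simulate_cbf(cfg0, truth, "control", gm = gm_all, seed = 11)
  expect_lte(abs(cor(as.vector(cb0$values), as.vector(truth$values))), 0.05)

  cfg <- sim_config(shape = c(26, 26, 18), lesion_radius_mm = c(5, 8),
                    seed = 12)
  gm <- sim_gray_matter(g)
  cbg <- simulate_cbf(cfg, truth, "control", gm = gm, seed = 13)
  expect_equal(mean(cbg$values[gm$values > 0]), 45.8, tolerance = 2)

  expect_error(sim_config(coupling_r_control = 1),
               class = "nvc_config_error")
})

test_that("simulated lesions stay in the left hemisphere at the reference scale", {
  cfg <- sim_config(seed = 14)                      # default 36x40x36 grid
  les <- simulate_lesions(cfg, seed = 15)
  right <- (cfg$grid$shape[1] / 2 + 1):cfg$grid$shape[1]
  for (i in seq_len(cfg$n_patients))
    expect_equal(sum(les[[i]]$values[right, , ]), 0)
  for (i in cfg$n_patients + seq_len(cfg$n_controls))
    expect_equal(sum(les[[i]]$values), 0)
  vols <- vapply(les[seq_len(cfg$n_patients)], lesion_volume_ml, numeric(1))
  expect_true(all(vols > 0))
  expect_equal(mean(vols), 61, tolerance = 0.3)     # within 30% of 61 mL

  small <- sim_config(shape = c(10, 10, 10), seed = 16)    # radii do not fit
  expect_error(simulate_lesions(small), class = "nvc_config_error")
})

test_that("simulated motion calibrates mean framewise displacement", {
  cfg <- sim_config(shape = c(6, 6, 4), lesion_radius_mm = c(2, 3), seed = 17)
  zero <- sim_config(shape = c(6, 6, 4), lesion_radius_mm = c(2, 3),
                     motion_step_mm = 0, motion_step_rad = 0, seed = 17)
  mz <- simulate_motion(zero, n_subjects = 2, seed = 18)
  expect_true(all(framewise_displacement(mz[[1]])$fd == 0))

  mots <- simulate_motion(cfg, seed = 19)
  fds <- vapply(mots, function(m) framewise_displacement(m)$mean_fd,
                numeric(1))
  expect_gt(mean(fds), 0.05)
  expect_lt(mean(fds), 0.15)

  # doubling both step sizes doubles FD exactly under the same seed
  dbl <- sim_config(shape = c(6, 6, 4), lesion_radius_mm = c(2, 3),
                    motion_step_mm = 0.04, motion_step_rad = 8e-4, seed = 17)
  m1 <- simulate_motion(cfg, n_subjects = 3, seed = 20)
  m2 <- simulate_motion(dbl, n_subjects = 3, seed = 20)
  expect_equal(framewise_displacement(m2[[2]])$mean_fd,
               2 * framewise_displacement(m1[[2]])$mean_fd, tolerance = 1e-12)
})

test_that("simulated behavior plants the requested partial correlation", {
  cfg0 <- sim_config(shape = c(6, 6, 4), lesion_radius_mm = c(2, 3),
                     behavior_effect_r = 0, seed = 21)
  set.seed(22)
  roi <- rnorm(200, 0.45, 0.12)
  b0 <- simulate_behavior(cfg0, roi, seed = 23)
  pc0 <- partial_correlation(roi, b0$comp_total, cbind(b0$age, b0$education))
  expect_lt(abs(pc0$r), 0.15)

  cfg75 <- sim_config(shape = c(6, 6, 4), lesion_radius_mm = c(2, 3),
                      behavior_effect_r = 0.75, seed = 24)
  b75 <- simulate_behavior(cfg75, roi, seed = 25)
  pc75 <- partial_correlation(roi, b75$comp_total,
                              cbind(b75$age, b75$education))
  expect_gt(pc75$r, 0.6)
  expect_lt(pc75$r, 0.85)

  for (col in c("comp_total", "comp_word", "comp_sentence", "aq")) {
    expect_true(all(b75[[col]] >= 0 & b75[[col]] <= 100))
  }
  expect_error(sim_config(behavior_effect_r = 1), class = "nvc_config_error")
})

test_that("rho truth maps are symmetric, in range, and subject maps vary", {
  cfg <- sim_config(shape = c(8, 8, 6), lesion_radius_mm = c(3, 5), seed = 26)
  rho <- simulate_rho_map(cfg, "control", seed = 27)
  perm <- nvcoupling:::mirror_perm(cfg$grid)
  expect_identical(rho$values, array(rho$values[perm], cfg$grid$shape))
  expect_true(all(rho$values >= 0 & rho$values < 1))

  les <- mask_at(cfg$grid, rbind(c(1, 1, 1)), kind = "lesion")
  aware <- nvcoupling:::lesion_aware_rho(rho, les)
  expect_equal(aware$values[1, 1, 1], 0)
  expect_equal(aware$values[8, 1, 1], 0)            # mirror of the lesion
  expect_equal(aware$values[2, , ], rho$values[2, , ])
})

test_that("cohort simulation is bit-reproducible under a fixed seed", {
  cfg <- sim_config(shape = c(8, 8, 6), n_patients = 4, n_controls = 4,
                    n_timepoints = 30, lesion_radius_mm = c(3, 5), seed = 28)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$bold[["pat01"]]$data, s2$bold[["pat01"]]$data)
  expect_identical(s1$cbf[["con02"]]$values, s2$cbf[["con02"]]$values)
  expect_identical(s1$phenotype, s2$phenotype)
  expect_identical(s1$motion[["pat03"]], s2$motion[["pat03"]])
  # patients carry behavior scores in [0, 100]; controls carry none
  pat <- s1$phenotype$group == "patient"
  expect_true(all(s1$phenotype$comp_total[pat] >= 0 &
                    s1$phenotype$comp_total[pat] <= 100))
  expect_true(all(is.na(s1$phenotype$comp_total[!pat])))
  expect_true(all(s1$phenotype$lesion_volume[!pat] == 0))
  expect_true(all(s1$phenotype$lesion_volume[pat] > 0))
})
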