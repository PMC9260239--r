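test_that("analysis mask excludes voxels lesioned in over half the sample", {
  g <- tiny_grid()
  gm <- full_mask(g)
  expect_identical(build_analysis_mask(gm, list(brain_mask(array(0L, g$shape),
                                                           g, "lesion")),
                                       n_total = 41)$values, gm$values)
  # voxel A lesioned in 21/41 subjects (51.2%) -> excluded;
  # voxel B in 20/41 (48.8%) -> retained
  A <- rbind(c(1, 1, 1)); B <- rbind(c(2, 2, 2))
  lesions <- c(lapply(1:21, function(i) mask_at(g, A)),
               lapply(1:20, function(i) mask_at(g, B)))
  am <- build_analysis_mask(gm, lesions, n_total = 41)
  expect_identical(am$values[1, 1, 1], 0L)
  expect_identical(am$values[2, 2, 2], 1L)
  # patients-only denominator changes the fraction
  am2 <- build_analysis_mask(gm, lesions[1:21], n_total = 21)
  expect_identical(am2$values[1, 1, 1], 0L)
  expect_error(build_analysis_mask(gm, lesions, max_lesion_fraction = -1),
               class = "nvc_data_error")
})

test_that("design matrix coding and rank checks work", {
  ph <- data.frame(subject_id = paste0("s", 1:6),
                   group = rep(c("patient", "control"), 3),
                   age = c(60, 55, 70, 50, 65, 58),
                   sex = c("F", "M", "M", "F", "M", "M"),
                   education = c(9, 12, 8, 16, 10, 11),
                   lesion_volume = c(30, 0, 50, 0, 12, 0))
  X <- build_design(ph)
  expect_identical(colnames(X), c("intercept", "group", "age", "sex",
                                  "education", "lesion_volume"))
  expect_equal(unname(X[, "group"]), rep(c(1, 0), 3))
  expect_equal(unname(X[, "sex"]), c(1, 0, 0, 1, 0, 0))
  ph2 <- ph; ph2$age <- 60                # constant column dropped, not fatal
  expect_warning(X2 <- build_design(ph2, covariates = "age"), "constant")
  expect_identical(colnames(X2), c("intercept", "group"))
  ph3 <- ph; ph3$education <- ph3$age               # collinear
  expect_error(build_design(ph3, covariates = c("age", "education")),
               class = "nvc_data_error")
})

test_that("voxelwise GLM reduces to the pooled two-sample t without covariates", {
  g <- volume_grid(c(4, 4, 2), c(3, 3, 3))
  set.seed(31)
  ph <- data.frame(subject_id = paste0("s", 1:20),
                   group = rep(c("patient", "control"), each = 10),
                   age = rnorm(20, 55, 10), sex = rep(c("F", "M"), 10),
                   education = rnorm(20, 10, 3))
  maps <- lapply(1:20, function(i) random_map(g, seed = 100 + i))
  X <- build_design(ph, covariates = character(0))
  res <- voxelwise_group_glm(maps, X, q = 0.05)
  Y <- sapply(maps, function(m) m$values[2, 3, 1])
  st <- summary_two_sample_t(mean(Y[1:10]), sd(Y[1:10]), 10,
                             mean(Y[11:20]), sd(Y[11:20]), 10)
  expect_equal(res$t$values[2, 3, 1], st$t, tolerance = 1e-8)
  expect_equal(res$p$values[2, 3, 1], st$p, tolerance = 1e-8)
  expect_identical(res$df, 18L)
})

test_that("voxelwise GLM with covariates matches explicit normal equations", {
  g <- volume_grid(c(2, 2, 2), c(3, 3, 3))
  set.seed(32)
  ph <- data.frame(subject_id = paste0("s", 1:20),
                   group = rep(c("patient", "control"), each = 10),
                   age = rnorm(20, 55, 10), sex = rep(c("F", "M"), 10),
                   education = rnorm(20, 10, 3),
                   lesion_volume = c(runif(10, 5, 90), rep(0, 10)))
  maps <- lapply(1:20, function(i) random_map(g, seed = 200 + i))
  X <- build_design(ph)
  res <- voxelwise_group_glm(maps, X, q = 0.05)
  y <- sapply(maps, function(m) m$values[1, 2, 2])
  XtXi <- solve(t(X) %*% X)
  beta <- XtXi %*% t(X) %*% y
  resid <- y - X %*% beta
  df <- 20 - ncol(X)
  se <- sqrt(sum(resid^2) / df * XtXi[2, 2])
  expect_equal(res$t$values[1, 2, 2], unname(beta[2] / se), tolerance = 1e-10)

  # duplicated group column -> rank error naming it
  Xdup <- cbind(X, group2 = X[, "group"])
  expect_error(voxelwise_group_glm(maps, Xdup), class = "nvc_data_error")
  expect_error(voxelwise_group_glm(maps, Xdup), "group2")
})

test_that("voxelwise GLM handles per-subject missing voxels by listwise deletion", {
  g <- volume_grid(c(2, 2, 2), c(3, 3, 3))
  set.seed(33)
  ph <- data.frame(subject_id = paste0("s", 1:12),
                   group = rep(c("patient", "control"), each = 6),
                   age = rnorm(12, 55, 10), sex = rep("M", 12),
                   education = rnorm(12, 10, 2))
  maps <- lapply(1:12, function(i) random_map(g, seed = 300 + i))
  # voxel (1,1,1): NaN for 3 patients -> 3 remain, still fitted
  for (i in 1:3) maps[[i]]$values[1, 1, 1] <- NaN
  # voxel (2,1,1): NaN for 4 patients -> below min_per_group, NaN result
  for (i in 1:4) maps[[i]]$values[2, 1, 1] <- NaN
  X <- build_design(ph, covariates = character(0))
  res <- voxelwise_group_glm(maps, X, min_per_group = 3L)
  expect_true(is.finite(res$t$values[1, 1, 1]))
  expect_true(is.nan(res$t$values[2, 1, 1]))
  y <- sapply(maps[4:12], function(m) m$values[1, 1, 1])
  st <- summary_two_sample_t(mean(y[1:3]), sd(y[1:3]), 3,
                             mean(y[4:9]), sd(y[4:9]), 6)
  expect_equal(res$t$values[1, 1, 1], st$t, tolerance = 1e-8)
})

test_that("BH step-up flags match hand enumeration and stay monotone", {
  expect_identical(fdr_bh(c(0.01, 0.02, 0.03, 0.04), q = 0.05),
                   rep(TRUE, 4))                    # p_(4) = 0.04 <= 0.05
  expect_identical(fdr_bh(rep(1, 5)), rep(FALSE, 5))
  expect_identical(fdr_bh(0.04, q = 0.05), TRUE)    # m = 1, threshold 0.05

  # independent oracle: literal step-up enumeration
  bh_oracle <- function(p, q) {
    m <- length(p); o <- order(p); ps <- p[o]
    k <- which(ps <= seq_len(m) * q / m)
    flags <- rep(FALSE, m)
    if (length(k)) flags[p <= ps[max(k)]] <- TRUE
    flags
  }
  set.seed(41)
  for (i in 1:20) {
    p <- runif(50)^2
    expect_identical(fdr_bh(p, 0.05), bh_oracle(p, 0.05))
  }

  # monotonicity: lowering a flagged p keeps it flagged; larger q nests
  p <- runif(40)
  f05 <- fdr_bh(p, 0.05); f10 <- fdr_bh(p, 0.10)
  expect_true(all(!f05 | f10))
  if (any(f05)) {
    p2 <- p; p2[which(f05)[1]] <- p2[which(f05)[1]] / 2
    expect_true(fdr_bh(p2, 0.05)[which(f05)[1]])
  }
  expect_warning(fdr_bh(c(0.01, NaN)), "non-finite")
  expect_error(fdr_bh(c(0.5, 1.2)), class = "nvc_data_error")
})

test_that("ROI means summarise valid voxels per region", {
  g <- tiny_grid()
  labs <- array(0L, g$shape)
  labs[1:2, 1, 1] <- 1L; labs[3:4, 1, 1] <- 2L
  at <- atlas_labels(labs, g, c("1" = "left", "2" = "right"))

  const <- scalar_map(array(7, g$shape), g)
  expect_equal(roi_means(const, at)$mean, c(7, 7))

  vals <- array(NaN, g$shape); vals[1:4, 1, 1] <- c(1, 1, 5, 5)
  two <- roi_means(scalar_map(vals, g), at)
  expect_equal(two$mean, c(1, 5))
  expect_identical(two$name, c("left", "right"))

  lesioned <- mask_at(g, rbind(c(1, 1, 1), c(2, 1, 1)))
  valid <- brain_mask(1L - lesioned$values, g, "analysis")
  masked <- roi_means(scalar_map(vals, g), at, valid = valid)
  expect_true(is.nan(masked$mean[1]))               # region fully lesioned
  expect_equal(masked$mean[2], 5)

  expect_error(atlas_labels(labs, g, c("1" = "left")),
               class = "nvc_label_error")
})

test_that("partial correlation matches residual-regression oracle and cor.test", {
  set.seed(42)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  pc <- partial_correlation(x, y)
  ct <- cor.test(x, y)
  expect_equal(pc$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(pc$p, ct$p.value, tolerance = 1e-12)

  z <- rnorm(30)
  expect_equal(partial_correlation(x, x, cbind(z))$r, 1, tolerance = 1e-12)

  # n = 10 oracle via explicit lm residuals
  x10 <- rnorm(10); z10 <- rnorm(10)
  y10 <- 0.4 * x10 + 0.7 * z10 + rnorm(10)
  rx <- resid(lm(x10 ~ z10)); ry <- resid(lm(y10 ~ z10))
  pc10 <- partial_correlation(x10, y10, cbind(z10))
  expect_equal(pc10$r, cor(rx, ry), tolerance = 1e-10)
  tref <- cor(rx, ry) * sqrt(7 / (1 - cor(rx, ry)^2))
  expect_equal(pc10$p, 2 * pt(-abs(tref), 7), tolerance = 1e-10)

  expect_error(partial_correlation(x10[1:4], y10[1:4], cbind(z10[1:4], 1:4)),
               class = "nvc_data_error")
})

test_that("partial correlation recovers a planted effect within its standard error", {
  set.seed(43)
  n <- 200; r_true <- 0.6
  covs <- cbind(rnorm(n), rnorm(n))
  x <- rnorm(n)
  y <- r_true * scale(x) + sqrt(1 - r_true^2) * rnorm(n) +
    0.5 * covs[, 1] - 0.3 * covs[, 2]
  pc <- partial_correlation(x, as.vector(y), covs)
  se <- (1 - r_true^2) / sqrt(n - 3)
  expect_lt(abs(pc$r - r_true), 3 * se)
})

test_that("summary two-sample t and 2x2 chi-square follow the closed forms", {
  expect_equal(summary_two_sample_t(5, 1, 10, 5, 2, 12)$t, 0)
  st <- summary_two_sample_t(10, 1, 5, 8, 1, 5)
  expect_equal(st$t, 2 / (1 * sqrt(2 / 5)), tolerance = 1e-12)  # 3.1623
  expect_identical(st$df, 8)
  # agrees with t.test on raw data having those exact summaries
  a <- c(9, 10, 11); b <- c(7, 8, 9)
  tt <- t.test(a, b, var.equal = TRUE)
  st2 <- summary_two_sample_t(mean(a), sd(a), 3, mean(b), sd(b), 3)
  expect_equal(st2$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(st2$p, tt$p.value, tolerance = 1e-12)
  expect_error(summary_two_sample_t(1, 0, 5, 2, 0, 5),
               class = "nvc_data_error")
  expect_equal(summary_two_sample_t(1, 0, 5, 1, 0, 5)$t, 0)

  expect_equal(chi_square_2x2(2, 2, 3, 3)$chi2, 0)
  expect_equal(chi_square_2x2(10, 0, 0, 10)$chi2, 20)
  expect_error(chi_square_2x2(1, 0, 2, 0), class = "nvc_data_error")
  # cross-check against the closed formula on a random table
  ch <- chi_square_2x2(7, 13, 11, 9)
  N <- 40
  expect_equal(ch$chi2, N * (7 * 9 - 13 * 11)^2 / (20 * 20 * 18 * 22),
               tolerance = 1e-12)
})

test_that("BH family-level false positives stay controlled on null GLM simulations", {
  set.seed(44)
  n <- 20; m <- 200
  X <- cbind(intercept = 1, group = rep(c(1, 0), each = 10))
  qx <- qr(X)
  XtXi_g <- chol2inv(qr.R(qx))[2, 2]
  any_flag <- vapply(1:500, function(i) {
    Y <- matrix(rnorm(n * m), n, m)
    beta <- qr.coef(qx, Y)
    res <- Y - X %*% beta
    se <- sqrt(colSums(res^2) / (n - 2) * XtXi_g)
    p <- 2 * pt(-abs(beta[2, ] / se), n - 2)
    any(fdr_bh(p, 0.05))
  }, logical(1))
  expect_lte(mean(any_flag), 0.10)
})
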