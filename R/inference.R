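#' Group design matrix
#'
#' Builds the per-subject design for voxel-wise and ROI-level group models:
#' intercept, group indicator (patient = 1, control = 0) and the nuisance
#' covariates. Sex is coded F = 1, M = 0. Controls contribute
#' `lesion_volume = 0`. The matrix must be full rank; collinear columns are
#' reported by name.
#'
#' @param phenotype validated phenotype data.frame (see [read_phenotype()]).
#' @param covariates covariate columns to include beside the group
#'   indicator.
#' @return Numeric design matrix, one row per subject.
#' @export
build_design <- function(phenotype,
                         covariates = c("age", "sex", "education",
                                        "lesion_volume")) {
  phenotype <- validate_phenotype(phenotype)
  X <- cbind(intercept = 1,
             group = as.numeric(phenotype$group == "patient"))
  for (cv in covariates) {
    col <- switch(cv,
      group = nvc_data_error("'group' is always included; do not list it as a covariate"),
      sex = as.numeric(phenotype$sex == "F"),
      lesion_volume = {
        lv <- phenotype$lesion_volume %||% rep(0, nrow(phenotype))
        lv[is.na(lv)] <- 0
        lv
      },
      {
        if (is.null(phenotype[[cv]]))
          nvc_data_error(sprintf("phenotype lacks covariate '%s'", cv))
        phenotype[[cv]]
      })
    if (length(unique(col)) == 1L) {
      warning(sprintf("dropping constant covariate '%s'", cv))
      next
    }
    X <- cbind(X, col)
    colnames(X)[ncol(X)] <- cv
  }
  assert_full_rank(X)
  rownames(X) <- phenotype$subject_id
  X
}

assert_full_rank <- function(X) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    nvc_data_error(paste0("design matrix is rank deficient; collinear column(s): ",
                          paste(bad, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Group-level analysis mask
#'
#' Gray matter minus the voxels lesioned in more than `max_lesion_fraction`
#' of the sample, so voxel-wise statistics are only computed where most
#' subjects contribute intact tissue. Per-subject lesion exclusion (each
#' subject's own lesioned voxels) is applied separately, at fit time, via
#' the per-subject validity of the input maps.
#'
#' @param gm gray-matter [brain_mask()].
#' @param lesions list of per-subject lesion masks. Pass the full sample
#'   (controls included, with empty masks) for the default whole-sample
#'   denominator; pass patients only for the patients-only reading.
#' @param max_lesion_fraction voxels with lesion fraction strictly greater
#'   than this are excluded (default 0.5).
#' @param n_total denominator of the fraction; defaults to
#'   `length(lesions)`.
#' @return An analysis [brain_mask()].
#' @export
build_analysis_mask <- function(gm, lesions, max_lesion_fraction = 0.5,
                                n_total = length(lesions)) {
  overlap <- lesion_overlap_map(lesions)
  stopifnot_same_grid(gm$grid, overlap$grid, "gray matter/lesions")
  keep <- mask_logical(gm) & (overlap$values / n_total <= max_lesion_fraction)
  if (!any(keep))
    nvc_data_error("analysis mask is empty after lesion exclusion")
  brain_mask(keep, gm$grid, "analysis")
}

#' Voxel-wise group general linear model
#'
#' Fits, at every voxel, an OLS regression of the metric on the design
#' matrix and tests the group coefficient (two-sided t, df = n_used -
#' rank(design)). Voxels are fitted by listwise deletion: subjects with a
#' non-finite value at a voxel (their own lesion) are dropped there, and a
#' voxel is only fitted if at least `min_per_group` subjects per group
#' remain. With an intercept-plus-group design (no covariates) the t
#' statistic reduces to the classic pooled-variance two-sample t.
#'
#' @param maps list of per-subject [scalar_map()]s, in design row order.
#' @param design design matrix from [build_design()]; must contain a
#'   `group` column.
#' @param analysis_mask optional [brain_mask()] restricting fitted voxels.
#' @param q FDR level for the significance mask (default 0.05).
#' @param min_per_group minimum finite subjects per group at a voxel.
#' @return A `voxel_stat_result`: list with `t`, `p` ([scalar_map()]s),
#'   `significant` ([brain_mask()] after BH-FDR at level `q`), `q`, `mask`,
#'   `df`.
#' @export
voxelwise_group_glm <- function(maps, design, analysis_mask = NULL,
                                q = 0.05, min_per_group = 3L) {
  design <- as.matrix(design)
  if (!"group" %in% colnames(design))
    nvc_data_error("design must contain a 'group' column")
  n <- nrow(design)
  if (length(maps) != n)
    nvc_data_error("number of maps must equal design rows")
  grid <- maps[[1]]$grid
  for (m in maps) stopifnot_same_grid(grid, m$grid, "metric maps")
  assert_full_rank(design)
  gi <- which(colnames(design) == "group")
  grp <- design[, gi]
  n_pat <- sum(grp == 1); n_con <- sum(grp == 0)
  if (n_pat < 2 || n_con < 2)
    nvc_data_error("need at least 2 subjects per group")

  Y <- vapply(maps, function(m) as.vector(m$values), numeric(prod(grid$shape)))
  Y <- t(Y)                                   # subjects x voxels
  sel <- rep(TRUE, ncol(Y))
  if (!is.null(analysis_mask)) {
    stopifnot_same_grid(grid, analysis_mask$grid, "metric/analysis mask")
    sel <- as.vector(mask_logical(analysis_mask))
  }
  tval <- rep(NaN, ncol(Y)); pval <- rep(NaN, ncol(Y))

  fin <- is.finite(Y)
  ## Fit voxels sharing the same subject-validity pattern in one batch.
  pat_key <- apply(fin, 2, function(z) paste(which(!z), collapse = ","))
  pat_key[!sel] <- NA
  for (key in unique(pat_key[!is.na(pat_key)])) {
    vox <- which(!is.na(pat_key) & pat_key == key)
    rows <- if (key == "") seq_len(n) else
      setdiff(seq_len(n), as.integer(strsplit(key, ",")[[1]]))
    if (sum(grp[rows] == 1) < min_per_group ||
        sum(grp[rows] == 0) < min_per_group) next
    X <- design[rows, , drop = FALSE]
    qx <- qr(X)
    if (qx$rank < ncol(X)) next               # degenerate after deletion
    Ys <- Y[rows, vox, drop = FALSE]
    beta <- qr.coef(qx, Ys)
    res <- Ys - X %*% beta
    df <- length(rows) - ncol(X)
    if (df < 1) next
    sigma2 <- colSums(res^2) / df
    xtxinv_g <- chol2inv(qr.R(qx))[gi, gi]
    se <- sqrt(sigma2 * xtxinv_g)
    tv <- beta[gi, ] / se
    tv[se == 0] <- NaN
    tval[vox] <- tv
    pval[vox] <- 2 * stats::pt(-abs(tv), df)
  }

  flags <- rep(FALSE, ncol(Y))
  fit_ok <- is.finite(pval)
  if (any(fit_ok)) flags[fit_ok] <- fdr_bh(pval[fit_ok], q = q)
  structure(list(
    t = scalar_map(array(tval, grid$shape), grid, units = "t"),
    p = scalar_map(array(pval, grid$shape), grid, units = "p"),
    significant = brain_mask(array(flags, grid$shape), grid, "analysis"),
    q = q,
    mask = analysis_mask,
    df = n - ncol(design)),
    class = "voxel_stat_result")
}

#' Benjamini-Hochberg FDR flags
#'
#' Step-up procedure: sort the m p-values ascending, find the largest k with
#' p_(k) <= k q / m, and flag every p at or below p_(k). Non-finite
#' p-values are excluded from m (with a warning) and never flagged.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return Logical vector of significance flags, same length as input.
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  ok <- is.finite(p_values)
  if (!all(ok)) warning(sprintf("%d non-finite p-value(s) excluded from FDR",
                                sum(!ok)))
  p <- p_values[ok]
  if (any(p < 0 | p > 1)) nvc_data_error("p-values must lie in [0, 1]")
  flags <- rep(FALSE, length(p_values))
  if (length(p)) flags[ok] <- stats::p.adjust(p, method = "BH") <= q
  flags
}

#' Region-of-interest means
#'
#' Mean metric value per atlas region over the valid voxels; regions with
#' no valid voxel (e.g. fully inside a subject's lesion) get NaN.
#'
#' @param map a [scalar_map()].
#' @param atlas an [atlas_labels()].
#' @param valid optional [brain_mask()] of valid voxels (non-finite map
#'   values are always excluded).
#' @return data.frame with columns `label`, `name`, `mean`.
#' @export
roi_means <- function(map, atlas, valid = NULL) {
  stopifnot_same_grid(map$grid, atlas$grid, "map/atlas")
  sel <- is.finite(map$values)
  if (!is.null(valid)) {
    stopifnot_same_grid(map$grid, valid$grid, "map/valid mask")
    sel <- sel & mask_logical(valid)
  }
  labs <- sort(unique(atlas$labels[atlas$labels > 0L]))
  means <- vapply(labs, function(l) {
    v <- map$values[atlas$labels == l & sel]
    if (length(v)) mean(v) else NaN
  }, numeric(1))
  data.frame(label = labs,
             name = unname(atlas$names[as.character(labs)]),
             mean = means, stringsAsFactors = FALSE)
}

#' Per-subject ROI table
#'
#' Applies [roi_means()] to each subject's map and assembles a region x
#' subject table of mean metric values.
#'
#' @param maps named list of per-subject [scalar_map()]s.
#' @param atlas an [atlas_labels()].
#' @param valid optional named list of per-subject validity masks.
#' @return data.frame with `label`, `name`, then one column per subject.
#' @export
cohort_roi_table <- function(maps, atlas, valid = NULL) {
  ids <- names(maps) %||% paste0("subj", seq_along(maps))
  base <- NULL
  for (i in seq_along(maps)) {
    rm_ <- roi_means(maps[[i]], atlas,
                     valid = if (is.null(valid)) NULL else valid[[ids[i]]])
    if (is.null(base)) base <- rm_[, c("label", "name")]
    base[[ids[i]]] <- rm_$mean
  }
  base
}

#' Pearson partial correlation
#'
#' Correlation between x and y after residualizing both on the covariates
#' (plus an intercept). The two-sided p-value uses
#' t = r sqrt((n - 2 - k) / (1 - r^2)) with df = n - 2 - k, k = number of
#' covariates. With no covariates this is the plain Pearson correlation
#' test.
#'
#' @param x,y numeric vectors.
#' @param covariates optional numeric matrix/data.frame of covariates.
#' @return List with `r`, `p`, `df`, `n`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) nvc_data_error("x and y must have equal length")
  Z <- if (is.null(covariates)) matrix(1, n, 1)
       else cbind(1, as.matrix(covariates))
  k <- ncol(Z) - 1L
  if (n <= k + 2L)
    nvc_data_error("too few observations for the requested covariates")
  qz <- qr(Z)
  rx <- qr.resid(qz, x)
  ry <- qr.resid(qz, y)
  r <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  df <- n - 2L - k
  tstat <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), df), df = df, n = n)
}

#' Two-sample pooled t from printed summaries
#'
#' Pooled-variance two-sample t-test computed from group means, SDs and
#' sizes — the form needed to reproduce statistics from a published
#' demographics table when only summaries are available.
#'
#' @param mean1,sd1,n1 first group summary.
#' @param mean2,sd2,n2 second group summary.
#' @return List with `t`, `df`, `p`.
#' @export
summary_two_sample_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) nvc_data_error("need n >= 2 per group")
  if (sd1 < 0 || sd2 < 0) nvc_data_error("SDs must be >= 0")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  if (sp2 == 0) {
    if (mean1 == mean2) return(list(t = 0, df = df, p = 1))
    nvc_data_error("zero pooled variance with unequal means: t is infinite")
  }
  tstat <- (mean1 - mean2) / (sqrt(sp2) * sqrt(1 / n1 + 1 / n2))
  list(t = unname(tstat), df = unname(df),
       p = unname(2 * stats::pt(-abs(tstat), df)))
}

#' Uncorrected 2x2 chi-square
#'
#' Pearson chi-square on a 2x2 table without Yates continuity correction:
#' the convention that reproduces published sex-distribution statistics
#' computed from counts.
#'
#' @param a,b first row (e.g. patient F, patient M).
#' @param c,d second row (e.g. control F, control M).
#' @return List with `chi2`, `df` (= 1), `p`.
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    nvc_data_error("cells must be non-negative integers")
  tab <- matrix(cells, nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    nvc_data_error("all margins of the 2x2 table must be positive")
  # the small-expected-count approximation warning is irrelevant here: the
  # statistic itself is the published convention being reproduced
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value))
}
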