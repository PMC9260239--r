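#' Cohort study container
#'
#' Bundles the per-subject volumes with the shared masks and atlas: the unit
#' the pipeline consumes. All volumes must live on a single shared grid
#' (resampling/registration is upstream of this package).
#'
#' @param phenotype data.frame as validated by [read_phenotype()]; row order
#'   defines subject order.
#' @param bold named list of [bold_series()], one per subject_id.
#' @param cbf named list of CBF [scalar_map()]s, one per subject_id.
#' @param lesions named list of lesion [brain_mask()]s, one per subject_id
#'   (empty masks for controls).
#' @param gray_matter shared gray-matter [brain_mask()].
#' @param atlas shared [atlas_labels()].
#' @param motion optional named list of 6-column motion matrices.
#' @return An object of class `cohort_study`.
#' @export
cohort_study <- function(phenotype, bold, cbf, lesions, gray_matter, atlas,
                         motion = NULL) {
  phenotype <- validate_phenotype(phenotype)
  ids <- phenotype$subject_id
  for (nm in c("bold", "cbf", "lesions")) {
    lst <- get(nm)
    if (!all(ids %in% names(lst)))
      nvc_data_error(sprintf("'%s' is missing subjects: %s", nm,
                             paste(setdiff(ids, names(lst)), collapse = ", ")))
  }
  grid <- gray_matter$grid
  for (id in ids) {
    stopifnot_same_grid(grid, bold[[id]]$grid, paste("BOLD of", id))
    stopifnot_same_grid(grid, cbf[[id]]$grid, paste("CBF of", id))
    stopifnot_same_grid(grid, lesions[[id]]$grid, paste("lesion of", id))
  }
  stopifnot_same_grid(grid, atlas$grid, "atlas")
  structure(list(phenotype = phenotype, bold = bold[ids], cbf = cbf[ids],
                 lesions = lesions[ids], gray_matter = gray_matter,
                 atlas = atlas, motion = motion, grid = grid),
            class = "cohort_study")
}

#' @export
print.cohort_study <- function(x, ...) {
  cat(sprintf("<cohort_study: %d patients, %d controls on %dx%dx%d grid>\n",
              sum(x$phenotype$group == "patient"),
              sum(x$phenotype$group == "control"),
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3]))
  invisible(x)
}

#' Reference cohort summary statistics
#'
#' Printed demographic/clinical summaries of the post-stroke-aphasia
#' reference cohort (19 left-hemisphere stroke patients with aphasia, 22
#' healthy controls) that this package's analyses are modelled on. These
#' summaries are the inputs for the summary-level statistics reproduced by
#' [summary_two_sample_t()] and [chi_square_2x2()]; the raw MRI data behind
#' them are not public, which is why the package ships a synthetic-cohort
#' generator instead.
#'
#' @format A list with elements:
#' \describe{
#'   \item{sex_counts}{2x2 counts: rows patient/control, columns F/M.}
#'   \item{age, icv, education, mean_fd}{per-group mean/sd/n (years, cm^3,
#'     years, mm).}
#'   \item{lesion_volume_ml, post_stroke_days}{patient-only mean/sd.}
#'   \item{behavior}{patient-only means/sds of aphasia quotient and speech
#'     comprehension percentages (0-100 scales).}
#'   \item{gm_vmhc, gm_cbf, gm_coupling}{whole-gray-matter group summaries
#'     of VMHC (Fisher z), CBF (mL/100 g/min) and the CBF-VMHC spatial
#'     correlation.}
#' }
#' @export
reference_cohort <- list(
  n_patients = 19L, n_controls = 22L,
  sex_counts = matrix(c(5L, 14L, 10L, 12L), nrow = 2, byrow = TRUE,
                      dimnames = list(c("patient", "control"), c("F", "M"))),
  age        = list(patient = c(mean = 60.1, sd = 13.1, n = 19),
                    control = c(mean = 54.3, sd = 13.7, n = 22)),
  education  = list(patient = c(mean = 9.9, sd = 3.7, n = 19),
                    control = c(mean = 10.4, sd = 4.5, n = 22)),
  icv        = list(patient = c(mean = 1559.3, sd = 149.3, n = 19),
                    control = c(mean = 1473.8, sd = 157.3, n = 22)),
  mean_fd    = list(patient = c(mean = 0.096, sd = 0.036, n = 19),
                    control = c(mean = 0.097, sd = 0.062, n = 22)),
  lesion_volume_ml = c(mean = 61.0, sd = 56.7),
  post_stroke_days = c(mean = 11.5, sd = 5.7),
  behavior = list(aq            = c(mean = 38.8, sd = 23.1),
                  comp_total    = c(mean = 55.4, sd = 23.8),
                  comp_word     = c(mean = 54.2, sd = 27.3),
                  comp_sentence = c(mean = 55.1, sd = 21.7)),
  gm_vmhc     = list(patient = c(mean = 0.39, sd = 0.10),
                     control = c(mean = 0.53, sd = 0.04)),
  gm_cbf      = list(patient = c(mean = 43.8, sd = 14.8),
                     control = c(mean = 45.8, sd = 10.0)),
  gm_coupling = list(patient = c(mean = 0.44, sd = 0.06),
                     control = c(mean = 0.51, sd = 0.09))
)

#' Summary statistics of a cohort table
#'
#' Reproduces the standard demographics table from printed group summaries:
#' uncorrected Pearson chi-square for sex and pooled two-sample t-tests for
#' age and intracranial volume.
#'
#' @param ref a list shaped like [reference_cohort] (the default).
#' @return A list with `sex` (chi2, df, p), `age` and `icv` (t, df, p).
#' @export
cohort_table_stats <- function(ref = reference_cohort) {
  sex <- chi_square_2x2(ref$sex_counts[1, 1], ref$sex_counts[1, 2],
                        ref$sex_counts[2, 1], ref$sex_counts[2, 2])
  tt <- function(s) summary_two_sample_t(
    s$patient["mean"], s$patient["sd"], s$patient["n"],
    s$control["mean"], s$control["sd"], s$control["n"])
  list(sex = sex, age = tt(ref$age), icv = tt(ref$icv))
}
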