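#' Pipeline configuration
#'
#' Bundles every stage's parameters: the simulation config (or input
#' directory), preprocessing keys, the VMHC threshold, the ratio floor and
#' the statistics keys. Re-running with the same config reproduces all
#' outputs bit-exactly.
#'
#' @param simulation a [sim_config()] used when no input directory is
#'   given.
#' @param input_dir optional directory in the [write_cohort()] layout to
#'   analyze instead of simulating.
#' @param trim_volumes leading BOLD volumes (and motion rows) to discard.
#' @param band temporal filter band, Hz.
#' @param fwhm_mm spatial smoothing FWHM, mm (applied to BOLD and CBF).
#' @param head_radius_mm framewise-displacement rotation radius.
#' @param vmhc_threshold correlation floor of [compute_vmhc()].
#' @param vmhc_floor denominator floor of [coupling_ratio()].
#' @param q FDR level for voxel-wise and ROI-level inference.
#' @param covariates nuisance covariates of the group design.
#' @param lesion_denominator `"sample"` (lesion fraction over all subjects)
#'   or `"patients"`.
#' @param max_lesion_fraction group-level lesion exclusion threshold.
#' @param behavior_scores behavior columns tested against ROI metrics.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = sim_config(), input_dir = NULL,
                            trim_volumes = 10L, band = c(0.01, 0.08),
                            fwhm_mm = 6, head_radius_mm = 50,
                            vmhc_threshold = 0.2, vmhc_floor = 0.05,
                            q = 0.05,
                            covariates = c("age", "sex", "education",
                                           "lesion_volume"),
                            lesion_denominator = c("sample", "patients"),
                            max_lesion_fraction = 0.5,
                            behavior_scores = c("comp_total", "comp_word",
                                                "comp_sentence")) {
  structure(list(simulation = simulation, input_dir = input_dir,
                 trim_volumes = as.integer(trim_volumes), band = band,
                 fwhm_mm = fwhm_mm, head_radius_mm = head_radius_mm,
                 vmhc_threshold = vmhc_threshold, vmhc_floor = vmhc_floor,
                 q = q, covariates = covariates,
                 lesion_denominator = match.arg(lesion_denominator),
                 max_lesion_fraction = max_lesion_fraction,
                 behavior_scores = behavior_scores),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror [pipeline_config()]; a `simulation` block mirrors
#' [sim_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulation)) y$simulation <- do.call(sim_config, y$simulation)
  do.call(pipeline_config, y)
}

#' Load a cohort study from a directory
#'
#' Reads the [write_cohort()] layout: per-subject BOLD/CBF/lesion volumes,
#' motion tables, shared gray matter and atlas, and the phenotype CSV.
#'
#' @param dir directory path.
#' @param tr_seconds TR override for BOLD files lacking one.
#' @return A `cohort_study`.
#' @export
load_cohort <- function(dir, tr_seconds = NULL) {
  phenotype <- read_phenotype(file.path(dir, "phenotype.csv"))
  gm <- read_mask(file.path(dir, "gray_matter.nii.gz"), "gray_matter")
  atlas <- read_atlas(file.path(dir, "atlas.nii.gz"), grid = gm$grid)
  bold <- list(); cbf <- list(); lesions <- list(); motion <- list()
  for (id in phenotype$subject_id) {
    bold[[id]] <- read_volume(file.path(dir, paste0(id, "_bold.nii.gz")),
                              grid = gm$grid, tr_seconds = tr_seconds)
    cbf[[id]] <- read_volume(file.path(dir, paste0(id, "_cbf.nii.gz")),
                             grid = gm$grid, units = "mL/100g/min")
    lesions[[id]] <- read_mask(file.path(dir, paste0(id, "_lesion.nii.gz")),
                               "lesion", grid = gm$grid)
    mp <- file.path(dir, paste0(id, "_motion.txt"))
    if (file.exists(mp)) motion[[id]] <- read_motion(mp)
  }
  cohort_study(phenotype, bold, cbf, lesions, gm, atlas,
               motion = if (length(motion)) motion else NULL)
}

mask_minus_lesion <- function(gm, lesion) {
  brain_mask(mask_logical(gm) & !mask_logical(lesion), gm$grid, "analysis")
}

## NaN out a subject's own lesioned voxels in a metric map.
apply_subject_validity <- function(map, lesion) {
  v <- map$values
  v[mask_logical(lesion)] <- NaN
  out <- scalar_map(v, map$grid, units = map$units)
  out
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> preprocess -> VMHC -> CBF standardization ->
#' coupling -> lesion-aware group inference -> ROI brain-behavior
#' correlations. Every stage is a pure function of its inputs and the
#' config, so a rerun with the same config reproduces all outputs.
#'
#' Stage error handling: any failure is re-raised with the stage name (and
#' subject id where applicable) prefixed to the message.
#'
#' @param config a [pipeline_config()].
#' @param study optional pre-built `cohort_study` (overrides simulation /
#'   input_dir).
#' @param out_dir optional output directory; when given, writes stat maps
#'   (NIfTI), per-subject VMHC/ratio maps, ROI tables (CSV), coupling and
#'   cohort summaries (JSON) and a parameter log.
#' @return A list of results: `subjects` (per-subject mean FD, gm VMHC
#'   mean, gm CBF mean, coupling r), `group_stats` (per-metric
#'   `voxel_stat_result`), `summaries` (group-level means/tests),
#'   `roi_vmhc` (ROI x subject table), `behavior` (partial-correlation
#'   table with ROI-level FDR), `analysis_mask`, `study`.
#' @export
run_pipeline <- function(config, study = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(errorCondition(sprintf("[stage %s] %s", name, conditionMessage(e)),
                          class = class(e)[class(e) != "simpleError"]))
    })
  }
  if (is.null(study)) {
    study <- if (!is.null(config$input_dir))
      stage("load", load_cohort(config$input_dir))
    else stage("simulate", simulate_cohort(config$simulation))
  }
  gm <- study$gray_matter
  ids <- study$phenotype$subject_id
  is_patient <- study$phenotype$group == "patient"

  vmhc_maps <- list(); ratio_maps <- list(); cbf_maps <- list()
  coupling <- list(); mean_fd <- numeric(length(ids))
  names(mean_fd) <- ids
  for (i in seq_along(ids)) {
    id <- ids[i]
    stage(paste0("preprocess:", id), {
      mot <- study$motion[[id]] %||%
        matrix(0, study$bold[[id]]$n_timepoints, 6)
      pre <- preprocess_bold(study$bold[[id]], mot,
                             trim_volumes = config$trim_volumes,
                             band = config$band, fwhm_mm = config$fwhm_mm,
                             head_radius_mm = config$head_radius_mm)
      mean_fd[id] <- pre$mean_fd
      vmhc_maps[[id]] <- compute_vmhc(pre$series, gm,
                                       threshold_r = config$vmhc_threshold)
    })
    stage(paste0("cbf:", id), {
      std <- standardize_cbf(study$cbf[[id]], gm)
      cbf_maps[[id]] <- if (config$fwhm_mm > 0)
        smooth_gaussian(std, config$fwhm_mm) else std
    })
    stage(paste0("coupling:", id), {
      valid <- mask_minus_lesion(gm, study$lesions[[id]])
      coupling[[id]] <- spatial_coupling(cbf_maps[[id]], vmhc_maps[[id]],
                                          valid, subject_id = id)
      ratio_maps[[id]] <- coupling_ratio(cbf_maps[[id]], vmhc_maps[[id]],
                                          valid,
                                          vmhc_floor = config$vmhc_floor)
    })
  }

  analysis_mask <- stage("analysis_mask", {
    les <- if (config$lesion_denominator == "sample") study$lesions
           else study$lesions[is_patient]
    build_analysis_mask(gm, les,
                        max_lesion_fraction = config$max_lesion_fraction)
  })
  design <- stage("design", build_design(study$phenotype,
                                         covariates = config$covariates))

  zscore_and_mask <- function(maps) {
    out <- list()
    for (id in ids)
      out[[id]] <- apply_subject_validity(zscore_map(maps[[id]], gm),
                                          study$lesions[[id]])
    out
  }
  metric_maps <- list(vmhc = vmhc_maps, cbf = cbf_maps, ratio = ratio_maps)
  group_stats <- list()
  for (metric in names(metric_maps)) {
    group_stats[[metric]] <- stage(paste0("glm:", metric),
      voxelwise_group_glm(zscore_and_mask(metric_maps[[metric]]), design,
                          analysis_mask = analysis_mask, q = config$q))
  }

  gm_vmhc <- vmhc_group_mean(vmhc_maps, gm)
  gm_cbf <- vapply(ids, function(id) {
    v <- study$cbf[[id]]$values[mask_logical(gm)]
    mean(v[is.finite(v)])
  }, numeric(1))
  coupling_r <- vapply(coupling, function(x) x$spatial_r, numeric(1))
  subjects <- data.frame(subject_id = ids,
                         group = study$phenotype$group,
                         mean_fd = unname(mean_fd),
                         gm_vmhc = unname(gm_vmhc),
                         gm_cbf = unname(gm_cbf),
                         coupling_r = unname(coupling_r),
                         stringsAsFactors = FALSE)

  two_group <- function(v) {
    tt <- stats::t.test(v[is_patient], v[!is_patient], var.equal = TRUE)
    list(patient_mean = mean(v[is_patient]), patient_sd = stats::sd(v[is_patient]),
         control_mean = mean(v[!is_patient]), control_sd = stats::sd(v[!is_patient]),
         t = unname(tt$statistic), p = tt$p.value)
  }
  summaries <- list(gm_vmhc = two_group(gm_vmhc),
                    gm_cbf = two_group(gm_cbf),
                    coupling = two_group(coupling_r),
                    mean_fd = two_group(mean_fd))

  valid_masks <- lapply(ids, function(id)
    mask_minus_lesion(gm, study$lesions[[id]]))
  names(valid_masks) <- ids
  roi_vmhc <- stage("roi", cohort_roi_table(vmhc_maps, study$atlas,
                                            valid = valid_masks))

  behavior <- stage("behavior", {
    pheno_pat <- study$phenotype[is_patient, , drop = FALSE]
    covs <- cbind(age = pheno_pat$age,
                  sex = as.numeric(pheno_pat$sex == "F"),
                  education = pheno_pat$education,
                  lesion_volume = pheno_pat$lesion_volume)
    rows <- list()
    scores <- intersect(config$behavior_scores, names(pheno_pat))
    for (sc in scores) {
      y <- pheno_pat[[sc]]
      for (k in seq_len(nrow(roi_vmhc))) {
        x <- as.numeric(roi_vmhc[k, ids[is_patient]])
        if (any(!is.finite(x)) || any(!is.finite(y))) next
        pc <- partial_correlation(x, y, covs)
        rows[[length(rows) + 1]] <- data.frame(
          score = sc, label = roi_vmhc$label[k], name = roi_vmhc$name[k],
          r = pc$r, p = pc$p, n = pc$n, stringsAsFactors = FALSE)
      }
    }
    tab <- do.call(rbind, rows)
    if (!is.null(tab) && nrow(tab)) {
      tab$significant <- FALSE
      for (sc in unique(tab$score)) {      # FDR family per score, per metric
        sel <- tab$score == sc
        tab$significant[sel] <- fdr_bh(tab$p[sel], q = config$q)
      }
    }
    tab
  })

  results <- list(subjects = subjects, group_stats = group_stats,
                  summaries = summaries, roi_vmhc = roi_vmhc,
                  behavior = behavior, analysis_mask = analysis_mask,
                  vmhc_maps = vmhc_maps, cbf_maps = cbf_maps,
                  ratio_maps = ratio_maps, study = study, config = config)
  if (!is.null(out_dir)) stage("write", write_results(results, out_dir))
  results
}

write_results <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- results$config
  for (metric in names(results$group_stats)) {
    gs <- results$group_stats[[metric]]
    write_volume(gs$t, file.path(out_dir, paste0(metric, "_t.nii.gz")))
    write_volume(gs$p, file.path(out_dir, paste0(metric, "_p.nii.gz")))
    write_volume(gs$significant,
                 file.path(out_dir, paste0(metric, "_sig.nii.gz")))
  }
  for (id in results$subjects$subject_id) {
    write_volume(results$vmhc_maps[[id]],
                 file.path(out_dir, paste0(id, "_vmhc.nii.gz")))
    write_volume(results$ratio_maps[[id]],
                 file.path(out_dir, paste0(id, "_ratio.nii.gz")))
  }
  utils::write.csv(results$roi_vmhc, file.path(out_dir, "roi_vmhc.csv"),
                   row.names = FALSE)
  if (!is.null(results$behavior))
    utils::write.csv(results$behavior,
                     file.path(out_dir, "behavior_correlations.csv"),
                     row.names = FALSE)
  utils::write.csv(results$subjects, file.path(out_dir, "subjects.csv"),
                   row.names = FALSE)
  jsonlite::write_json(results$summaries,
                       file.path(out_dir, "group_summaries.json"),
                       auto_unbox = TRUE, digits = NA)
  log <- list(vmhc_threshold = cfg$vmhc_threshold, band = cfg$band,
              fwhm_mm = cfg$fwhm_mm, q = cfg$q,
              trim_volumes = cfg$trim_volumes,
              head_radius_mm = cfg$head_radius_mm,
              vmhc_floor = cfg$vmhc_floor, covariates = cfg$covariates,
              lesion_denominator = cfg$lesion_denominator,
              seed = if (!is.null(cfg$simulation)) cfg$simulation$seed)
  jsonlite::write_json(log, file.path(out_dir, "parameters.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
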