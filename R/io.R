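#' Read a NIfTI volume as a scalar map or BOLD series
#'
#' 3D files become [scalar_map()]s, 4D files become [bold_series()]. Voxel
#' sizes are taken from the NIfTI pixdim; the repetition time of a 4D series
#' is taken from the 4th pixdim entry unless overridden.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param grid optional expected [volume_grid()]; shape or voxel-size
#'   mismatch raises a grid error.
#' @param tr_seconds repetition time override for 4D input.
#' @param lr_axis left-right axis to record on the grid (default 1, the MNI
#'   x axis).
#' @param units unit label attached to 3D maps.
#' @return A [scalar_map()] or [bold_series()].
#' @export
read_volume <- function(path, grid = NULL, tr_seconds = NULL, lr_axis = 1L,
                        units = "") {
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) nvc_format_error(
                    sprintf("not a readable NIfTI file: %s (%s)",
                            path, conditionMessage(e))))
  dm <- dim(img)
  pd <- RNifti::pixdim(img)
  if (!length(dm) %in% c(3L, 4L))
    nvc_format_error(sprintf("expected a 3D or 4D NIfTI, got %dD", length(dm)))
  file_grid <- volume_grid(dm[1:3], voxel_size = pd[1:3], lr_axis = lr_axis)
  if (!is.null(grid)) stopifnot_same_grid(grid, file_grid, basename(path))
  if (length(dm) == 3L) {
    scalar_map(array(as.numeric(img), dim = dm), file_grid, units = units)
  } else {
    tr <- if (!is.null(tr_seconds)) tr_seconds
          else if (length(pd) >= 4L && is.finite(pd[4]) && pd[4] > 0) pd[4]
          else nvc_format_error("4D file has no usable TR; pass tr_seconds")
    bold_series(array(as.numeric(img), dim = dm), file_grid, tr_seconds = tr)
  }
}

#' Read a 3D NIfTI volume as a binary mask
#'
#' @inheritParams read_volume
#' @param kind mask kind, see [brain_mask()].
#' @export
read_mask <- function(path, kind = "analysis", grid = NULL, lr_axis = 1L) {
  m <- read_volume(path, grid = grid, lr_axis = lr_axis)
  if (!inherits(m, "scalar_map"))
    nvc_format_error("mask file must be 3D")
  brain_mask(m$values != 0, m$grid, kind = kind)
}

#' Read a 3D NIfTI label volume as an atlas
#'
#' @inheritParams read_volume
#' @param names named character vector mapping labels to region names; if
#'   omitted, regions are named `region_<label>`.
#' @export
read_atlas <- function(path, names = NULL, grid = NULL, lr_axis = 1L) {
  m <- read_volume(path, grid = grid, lr_axis = lr_axis)
  labs <- round(m$values)
  if (is.null(names)) {
    present <- sort(unique(labs[labs > 0]))
    names <- stats::setNames(paste0("region_", present), present)
  }
  atlas_labels(labs, m$grid, names = names)
}

#' Write a volume to NIfTI-1
#'
#' Scalar maps and BOLD series are written as 32-bit float, masks as uint8
#' and atlas labels as uint16. Round-tripping preserves shape, voxel size
#' and values to 32-bit float precision.
#'
#' @param x a [scalar_map()], [bold_series()], [brain_mask()] or
#'   [atlas_labels()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "bold_series")) {
    img <- RNifti::asNifti(x$data)
    RNifti::pixdim(img) <- c(x$grid$voxel_size, x$tr_seconds)
    dtype <- "float"
  } else if (inherits(x, "brain_mask")) {
    img <- RNifti::asNifti(x$values)
    RNifti::pixdim(img) <- x$grid$voxel_size
    dtype <- "uint8"
  } else if (inherits(x, "atlas_labels")) {
    img <- RNifti::asNifti(x$labels)
    RNifti::pixdim(img) <- x$grid$voxel_size
    dtype <- "uint16"
  } else if (inherits(x, "scalar_map")) {
    img <- RNifti::asNifti(x$values)
    RNifti::pixdim(img) <- x$grid$voxel_size
    dtype <- "float"
  } else {
    nvc_format_error("write_volume: unsupported object")
  }
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

#' Read a 6-parameter rigid-body motion table
#'
#' Whitespace- or comma-delimited text with one row per volume and six
#' columns: three translations (mm) and three rotations (rad). The SPM
#' convention puts translations first; set `order = "rotations_first"` for
#' tables in the FSL dialect.
#'
#' @param path text file path.
#' @param order column order dialect.
#' @return Numeric matrix with columns `tx, ty, tz, rx, ry, rz`.
#' @export
read_motion <- function(path, order = c("translations_first",
                                        "rotations_first")) {
  order <- match.arg(order)
  txt <- gsub(",", " ", readLines(path))
  txt <- txt[nzchar(trimws(txt))]
  m <- tryCatch(
    as.matrix(utils::read.table(text = txt, header = FALSE)),
    error = function(e) nvc_format_error(
      sprintf("cannot parse motion table %s: %s", path, conditionMessage(e))))
  if (ncol(m) != 6L)
    nvc_format_error(sprintf(
      "motion table must have 6 columns (3 translations mm + 3 rotations rad); got %d",
      ncol(m)))
  if (order == "rotations_first") m <- m[, c(4:6, 1:3), drop = FALSE]
  colnames(m) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  m
}

#' Write a motion table (translations first, whitespace-delimited)
#' @param trace 6-column motion matrix.
#' @param path output path.
#' @export
write_motion <- function(trace, path) {
  utils::write.table(trace, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

PHENOTYPE_REQUIRED <- c("subject_id", "group", "age", "sex", "education")
BEHAVIOR_COLUMNS   <- c("aq", "comp_total", "comp_word", "comp_sentence")

#' Read a per-subject phenotype table
#'
#' CSV with columns `subject_id, group, age, sex, education`, optionally
#' `lesion_volume` (mL) and behavior columns (`aq`, `comp_total`,
#' `comp_word`, `comp_sentence`; 0-100 scales, patients only).
#'
#' @param path CSV path.
#' @return A validated data.frame.
#' @export
read_phenotype <- function(path) {
  # sex must stay character: an all-female column would otherwise be
  # parsed as logical ("F" -> FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character",
                                       group = "character",
                                       sex = "character"))
  validate_phenotype(df)
}

validate_phenotype <- function(df) {
  missing <- setdiff(PHENOTYPE_REQUIRED, names(df))
  if (length(missing))
    nvc_format_error(paste0("phenotype table lacks columns: ",
                            paste(missing, collapse = ", ")))
  if (!all(df$group %in% c("patient", "control")))
    nvc_data_error("group must be 'patient' or 'control'")
  if (!all(df$sex %in% c("F", "M")))
    nvc_data_error("sex must be 'F' or 'M'")
  if (!is.null(df$lesion_volume)) {
    if (any(df$lesion_volume < 0, na.rm = TRUE))
      nvc_data_error("lesion_volume must be >= 0")
    if (any(df$group == "control" & !is.na(df$lesion_volume) &
            df$lesion_volume > 0))
      nvc_data_error("controls must have lesion_volume 0")
  }
  for (b in intersect(BEHAVIOR_COLUMNS, names(df))) {
    v <- df[[b]]
    if (any(is.finite(v) & (v < 0 | v > 100)))
      nvc_data_error(sprintf("behavior column '%s' outside [0, 100]", b))
  }
  df
}
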