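# NIfTI-1 and sidecar I/O for image series, maps and masks.

#' Write an inversion-recovery series as NIfTI + JSON sidecar
#'
#' Writes the 4D magnitude stack as NIfTI-1 (`<prefix>.nii.gz`) and the
#' acquisition metadata (inversion times, TR_img, flip angle, voxel size)
#' as `<prefix>.json`.
#'
#' @param series An [ir_series()] with 4D data.
#' @param prefix Output path prefix (without extension).
#' @return The NIfTI path, invisibly.
#' @export
write_ir_series <- function(series, prefix) {
  stopifnot(inherits(series, "ir_series"))
  if (length(dim(series$data)) != 4L)
    abort("Only 4D series can be written as NIfTI.")
  nii <- RNifti::asNifti(series$data,
                         pixdim = c(series$voxel_mm, 1))
  path <- paste0(prefix, ".nii.gz")
  RNifti::writeNifti(nii, path)
  jsonlite::write_json(
    list(inversion_times_s = series$ti, tr_img_s = series$tr_img,
         flip_angle_deg = series$flip_deg, voxel_mm = series$voxel_mm),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read an inversion-recovery series from NIfTI + JSON sidecar
#'
#' @param prefix Path prefix as used by [write_ir_series()], or the path
#'   to the `.nii`/`.nii.gz` file itself (the sidecar is found by swapping
#'   the extension).
#' @return An [ir_series()].
#' @export
read_ir_series <- function(prefix) {
  nii_path <- if (grepl("\\.nii(\\.gz)?$", prefix)) prefix else
    paste0(prefix, ".nii.gz")
  json_path <- sub("\\.nii(\\.gz)?$", ".json", nii_path)
  if (!file.exists(json_path))
    abort(sprintf("Sidecar `%s` not found.", json_path))
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  img <- RNifti::readNifti(nii_path)
  ir_series(array(as.numeric(img), dim = dim(img)),
            ti = meta$inversion_times_s, tr_img = meta$tr_img_s,
            flip_deg = meta$flip_angle_deg, voxel_mm = meta$voxel_mm)
}

#' Write a relaxation map (T1 and R1) as NIfTI
#'
#' @param map A [correct_t1()] result with array fields.
#' @param prefix Output path prefix; writes `<prefix>_t1.nii.gz`,
#'   `<prefix>_r1.nii.gz` and `<prefix>_mask.nii.gz`.
#' @return The T1 path, invisibly.
#' @export
write_relaxation_map <- function(map, prefix) {
  stopifnot(inherits(map, "relaxation_map"))
  if (is.null(dim(map$t1))) abort("Map has no grid; nothing to write.")
  pd <- c(map$voxel_mm %||% c(1, 1, 1))
  t1 <- map$t1; t1[is.na(t1)] <- 0
  RNifti::writeNifti(RNifti::asNifti(t1, pixdim = pd),
                     paste0(prefix, "_t1.nii.gz"))
  r1 <- map$r1; r1[is.na(r1)] <- 0
  RNifti::writeNifti(RNifti::asNifti(r1, pixdim = pd),
                     paste0(prefix, "_r1.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(map$mask),
                                           dim = dim(map$mask)),
                                     pixdim = pd),
                     paste0(prefix, "_mask.nii.gz"))
  invisible(paste0(prefix, "_t1.nii.gz"))
}

#' Read a relaxivity calibration table from CSV
#'
#' Expects columns `concentration_mM` (or `concentration_mg_per_ml` plus a
#' molecular weight) and `T1_s`, with an optional `medium` column.
#'
#' @param path CSV path.
#' @param mw_kda Molecular weight used to derive mM from mg/mL when only
#'   the latter is present.
#' @return Tibble with `conc_mM`, `T1_s` and `medium` columns, ready for
#'   [compute_relaxivity()].
#' @export
read_calibration_csv <- function(path, mw_kda = 74) {
  if (!file.exists(path))
    abort(sprintf("Calibration table `%s` not found.", path))
  d <- as_tibble(utils::read.csv(path))
  if (!"concentration_mM" %in% names(d)) {
    if (!"concentration_mg_per_ml" %in% names(d))
      abort("Calibration CSV needs `concentration_mM` or `concentration_mg_per_ml`.")
    d$concentration_mM <- convert_units(d$concentration_mg_per_ml,
                                        "mg_ml", mw_kda)
  }
  if (!"T1_s" %in% names(d)) abort("Calibration CSV needs a `T1_s` column.")
  tibble(conc_mM = d$concentration_mM, T1_s = d$T1_s,
         medium = d$medium %||% NA_character_)
}
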