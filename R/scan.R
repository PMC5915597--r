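#' Subject scan
#'
#' A masked voxel-by-time matrix for one subject. Rows follow the atlas
#' brain-mask enumeration exactly, so row `v` of every subject is the same
#' anatomical voxel.
#'
#' @param data Numeric matrix, voxels (rows, mask enumeration order) by
#'   timepoints (columns).
#' @param subject_id Character scalar.
#' @return An object of class `subject_scan`.
#' @export
subject_scan <- function(data, subject_id) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("`data` must be a numeric voxel x time matrix", call. = FALSE)
  }
  if (anyNA(data)) stop("scan contains missing values", call. = FALSE)
  if (ncol(data) < 3L) {
    stop("need at least 3 timepoints for a defined correlation", call. = FALSE)
  }
  structure(
    list(data = data, n_timepoints = ncol(data),
         subject_id = as.character(subject_id)),
    class = "subject_scan"
  )
}

#' @export
print.subject_scan <- function(x, ...) {
  cat("<subject_scan> ", x$subject_id, ": ", nrow(x$data), " voxels x ",
      x$n_timepoints, " timepoints\n", sep = "")
  invisible(x)
}

#' Load a 4D BOLD scan and mask it against an atlas
#'
#' The 4D volume must live on the same grid as the atlas (identical 3D
#' dimensions and affine); its voxels inside the brain mask are extracted in
#' the fixed enumeration order. Constant (zero-variance) voxels are accepted
#' here; they are flagged and excluded when connectivity is computed.
#'
#' @param path Path to a 4D NIfTI file.
#' @param atlas An [fc_atlas()].
#' @param subject_id Subject identifier; defaults to the file stem.
#' @return A [subject_scan()].
#' @export
load_scan <- function(path, atlas, subject_id = NULL) {
  if (is.null(subject_id)) {
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  }
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L) stop("expected a 4D volume", call. = FALSE)
  if (!all(dim(arr)[1:3] == dim(atlas$labels))) {
    stop("scan grid ", paste(dim(arr)[1:3], collapse = "x"),
         " does not match atlas grid ",
         paste(dim(atlas$labels), collapse = "x"), call. = FALSE)
  }
  if (max(abs(voxel_affine(img) - atlas$affine)) > 1e-3) {
    stop("scan affine does not match atlas affine", call. = FALSE)
  }
  nt <- dim(arr)[4]
  mat <- matrix(arr, nrow = prod(dim(arr)[1:3]), ncol = nt)[atlas$mask_idx, , drop = FALSE]
  if (anyNA(mat)) stop("scan has missing values inside the brain mask", call. = FALSE)
  subject_scan(mat, subject_id)
}

#' Write a subject scan as a 4D NIfTI on the atlas grid
#'
#' Voxels outside the brain mask are written as 0.
#'
#' @param scan A [subject_scan()].
#' @param atlas The atlas whose mask enumeration the scan rows follow.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return Invisibly, `path`.
#' @export
write_scan <- function(scan, atlas, path) {
  dims <- dim(atlas$labels)
  nt <- scan$n_timepoints
  arr <- array(0, dim = c(dims, nt))
  flat <- matrix(0, prod(dims), nt)
  flat[atlas$mask_idx, ] <- scan$data
  arr[] <- flat
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(atlas$affine, code = 4L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

phenotype_cols <- c("subject_id", "site", "group", "age", "sex", "education",
                    "mean_fd", "medicated", "hamd", "bdi", "illness_duration")

#' Read a phenotype table
#'
#' Expects a TSV with one row per subject: `subject_id`, `site`, `group`
#' (`control`/`patient`), `age` (years), `sex` (0/1), `education` (years),
#' `mean_fd` (mean framewise displacement, mm), `medicated` (0/1, NA for
#' controls), `hamd`, `bdi`, `illness_duration` (months, patients only).
#'
#' @param path TSV path.
#' @return A tibble with validated columns.
#' @export
read_phenotypes <- function(path) {
  ph <- readr::read_tsv(path, show_col_types = FALSE)
  validate_phenotypes(ph)
}

#' Validate a phenotype table
#' @param ph Data frame of subject phenotypes.
#' @return The table as a tibble, with `group` and `site` as character.
#' @export
validate_phenotypes <- function(ph) {
  ph <- tibble::as_tibble(ph)
  miss <- setdiff(phenotype_cols, names(ph))
  if (length(miss)) {
    stop("phenotype table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ph$site <- as.character(ph$site)
  ph$group <- as.character(ph$group)
  if (!all(ph$group %in% c("control", "patient"))) {
    stop("`group` must be 'control' or 'patient'", call. = FALSE)
  }
  if (anyDuplicated(ph$subject_id)) {
    stop("duplicate subject_id in phenotype table", call. = FALSE)
  }
  ph
}

#' Write a phenotype table as TSV
#' @param ph Phenotype tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_phenotypes <- function(ph, path) {
  readr::write_tsv(ph, path)
  invisible(path)
}
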