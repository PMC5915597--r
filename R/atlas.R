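#' Parcellation atlas
#'
#' An `fc_atlas` bundles an integer-labelled 3D parcellation volume, its
#' voxel-to-world affine, and a region-name table. Label 0 is background;
#' every voxel with a positive label belongs to the brain mask. All
#' downstream voxel bookkeeping (the brain-mask enumeration, the seed/brain
#' voxel-pair universe, world coordinates of peaks) derives from this object.
#'
#' The brain-mask enumeration is the ascending linear index of the label
#' array in column-major order (x fastest, then y, then z) and is the single
#' voxel ordering used everywhere: scan rows, pair indices and per-voxel
#' summaries all refer to positions in this enumeration.
#'
#' @param labels 3D integer array of region labels (0 = background).
#' @param affine 4x4 numeric matrix mapping 0-based voxel indices `(i,j,k,1)`
#'   to world (mm) coordinates. For an atlas in MNI space this yields MNI
#'   coordinates.
#' @param region_names data frame with columns `region_id` (unique positive
#'   integers covering every label present) and `region_name`.
#' @return An object of class `fc_atlas`.
#' @export
fc_atlas <- function(labels, affine, region_names) {
  if (length(dim(labels)) != 3L) {
    stop("`labels` must be a 3D array", call. = FALSE)
  }
  lab <- as.vector(labels)
  if (any(is.na(lab)) || any(lab != round(lab)) || any(lab < 0)) {
    stop("`labels` must contain non-negative integers with no missing values",
         call. = FALSE)
  }
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)) ||
      !all(abs(affine[4, ] - c(0, 0, 0, 1)) < 1e-8)) {
    stop("`affine` must be a 4x4 matrix with last row (0,0,0,1)", call. = FALSE)
  }
  region_names <- tibble::as_tibble(region_names)
  if (!all(c("region_id", "region_name") %in% names(region_names))) {
    stop("`region_names` needs columns region_id and region_name", call. = FALSE)
  }
  if (anyDuplicated(region_names$region_id)) {
    stop("duplicate region_id in region name table", call. = FALSE)
  }
  present <- sort(unique(lab[lab > 0]))
  missing_ids <- setdiff(present, region_names$region_id)
  if (length(missing_ids)) {
    stop("labels present in volume but absent from name table: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  labels <- array(as.integer(round(labels)), dim = dim(labels))  # plain array
  mask_idx <- which(labels > 0L)  # column-major scan: x fastest
  structure(
    list(
      labels = labels,
      affine = affine,
      region_names = dplyr::arrange(region_names, .data$region_id),
      mask_idx = mask_idx,
      mask_labels = as.integer(labels[mask_idx])
    ),
    class = "fc_atlas"
  )
}

#' @export
print.fc_atlas <- function(x, ...) {
  cat("<fc_atlas> ", paste(dim(x$labels), collapse = " x "),
      " grid, ", length(x$mask_idx), " brain voxels, ",
      nrow(x$region_names), " regions\n", sep = "")
  invisible(x)
}

#' Number of brain-mask voxels
#' @param atlas An `fc_atlas`.
#' @return Integer count of voxels with a positive label.
#' @export
n_brain_voxels <- function(atlas) length(atlas$mask_idx)

#' Load an atlas from a NIfTI label volume and a TSV of region names
#'
#' @param label_volume_path Path to a NIfTI-1 volume (`.nii`/`.nii.gz`) with
#'   integer region labels.
#' @param names_path Path to a TSV with columns `region_id` and `region_name`.
#' @return An [fc_atlas()].
#' @export
load_atlas <- function(label_volume_path, names_path) {
  img <- RNifti::readNifti(label_volume_path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) dim(arr) <- dim(arr)[1:3]
  if (any(abs(arr - round(arr)) > 1e-6)) {
    stop("label volume is not integer-valued", call. = FALSE)
  }
  nm <- readr::read_tsv(names_path, show_col_types = FALSE,
                        col_types = readr::cols(
                          region_id = readr::col_integer(),
                          region_name = readr::col_character()
                        ))
  fc_atlas(round(arr), voxel_affine(img), nm)
}

# 4x4 voxel->world matrix of an RNifti image (0-based voxel convention)
voxel_affine <- function(img) {
  aff <- try(structure(RNifti::xform(img), class = NULL), silent = TRUE)
  if (inherits(aff, "try-error")) stop("image carries no usable xform", call. = FALSE)
  m <- matrix(as.numeric(aff), 4L, 4L)
  dimnames(m) <- NULL
  m
}

#' Write an atlas to disk
#'
#' Writes the label volume as NIfTI (carrying the affine in the sform) and
#' the region names as TSV, the formats [load_atlas()] reads back.
#'
#' @param atlas An `fc_atlas`.
#' @param label_volume_path,names_path Output paths.
#' @return Invisibly, the atlas.
#' @export
write_atlas <- function(atlas, label_volume_path, names_path) {
  img <- RNifti::asNifti(atlas$labels)
  img <- RNifti::`sform<-`(img, structure(atlas$affine, code = 4L))
  RNifti::writeNifti(img, label_volume_path, datatype = "int32")
  readr::write_tsv(atlas$region_names[, c("region_id", "region_name")], names_path)
  invisible(atlas)
}

#' Brain-mask voxel indices of one region
#'
#' Positions of a region's voxels in the brain-mask enumeration. The order
#' is the fixed column-major scan order and is stable across calls, so it
#' can index scan rows and pair endpoints directly.
#'
#' @param atlas An `fc_atlas`.
#' @param region_id Positive integer label present in the atlas.
#' @return Integer vector of 1-based positions in the mask enumeration.
#' @export
voxel_indices <- function(atlas, region_id) {
  if (length(region_id) != 1L || is.na(region_id) || region_id <= 0) {
    stop("`region_id` must be a single positive label (0 is background)",
         call. = FALSE)
  }
  if (!region_id %in% atlas$region_names$region_id) {
    stop("unknown region_id: ", region_id, call. = FALSE)
  }
  which(atlas$mask_labels == as.integer(region_id))
}

#' World (mm) coordinates of brain-mask voxels
#'
#' Applies the atlas affine to the 0-based voxel coordinates of positions in
#' the brain-mask enumeration. With an MNI-space atlas these are MNI
#' coordinates.
#'
#' @param atlas An `fc_atlas`.
#' @param index Integer vector of mask-enumeration positions.
#' @return Numeric matrix with one `(x, y, z)` row per index.
#' @export
voxel_to_world <- function(atlas, index) {
  n <- length(atlas$mask_idx)
  if (any(index < 1L | index > n | is.na(index))) {
    stop("voxel index out of range 1..", n, call. = FALSE)
  }
  ijk <- arrayInd(atlas$mask_idx[index], dim(atlas$labels)) - 1L  # 0-based
  xyz <- cbind(ijk, 1) %*% t(atlas$affine)
  xyz[, 1:3, drop = FALSE]
}

#' Map world coordinates back to mask positions
#'
#' Inverse of [voxel_to_world()]: rounds to the nearest voxel and returns its
#' position in the brain-mask enumeration (NA when the voxel is background or
#' outside the grid).
#'
#' @param atlas An `fc_atlas`.
#' @param xyz Numeric matrix of world coordinates, one row per point.
#' @return Integer vector of mask positions (NA where unmapped).
#' @export
world_to_voxel <- function(atlas, xyz) {
  xyz <- rbind(NULL, xyz)
  ijk <- round(cbind(xyz, 1) %*% t(solve(atlas$affine)))[, 1:3, drop = FALSE] + 1L
  dims <- dim(atlas$labels)
  ok <- ijk[, 1] >= 1 & ijk[, 1] <= dims[1] &
    ijk[, 2] >= 1 & ijk[, 2] <= dims[2] &
    ijk[, 3] >= 1 & ijk[, 3] <= dims[3]
  lin <- rep(NA_integer_, nrow(ijk))
  lin[ok] <- as.integer((ijk[ok, 3] - 1) * dims[1] * dims[2] +
                          (ijk[ok, 2] - 1) * dims[1] + ijk[ok, 1])
  match(lin, atlas$mask_idx)
}

#' Region labels and names at mask positions
#' @param atlas An `fc_atlas`.
#' @param index Mask-enumeration positions.
#' @return Tibble with `voxel`, `region_id`, `region_name`.
#' @export
voxel_regions <- function(atlas, index) {
  ids <- atlas$mask_labels[index]
  tibble::tibble(
    voxel = as.integer(index),
    region_id = ids,
    region_name = atlas$region_names$region_name[match(ids, atlas$region_names$region_id)]
  )
}

#' Write a per-voxel statistic as a NIfTI map
#'
#' Places one value per brain-mask voxel back into the atlas grid
#' (background = 0) and writes it with the atlas affine.
#'
#' @param values Numeric vector, one value per mask voxel.
#' @param atlas An `fc_atlas`.
#' @param path Output NIfTI path.
#' @return Invisibly, `path`.
#' @export
write_voxel_map <- function(values, atlas, path) {
  stopifnot(length(values) == length(atlas$mask_idx))
  vol <- array(0, dim = dim(atlas$labels))
  vol[atlas$mask_idx] <- values
  img <- RNifti::asNifti(vol)
  img <- RNifti::`sform<-`(img, structure(atlas$affine, code = 4L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
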