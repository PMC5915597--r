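#' Enumerate seed-to-brain voxel pairs
#'
#' Builds the voxel-pair universe of the analysis: every unordered pair
#' (seed-ROI voxel, brain voxel), each listed exactly once. Within-ROI pairs
#' appear once (no duplication), giving
#' `|ROI| * (|brain| - |ROI|) + |ROI| * (|ROI| - 1) / 2` pairs. Order is
#' deterministic given the atlas: outer loop over ROI voxels ascending, inner
#' loop over partner voxels ascending.
#'
#' @param atlas An [fc_atlas()].
#' @param roi_id Region id of the seed ROI (needs at least 2 voxels).
#' @return A `pair_index`: integer matrix with columns `i` (ROI voxel) and
#'   `j` (partner voxel), both as brain-mask enumeration positions, with
#'   attributes `roi_id`, `roi_voxels` and `n_voxels`.
#' @export
enumerate_pairs <- function(atlas, roi_id) {
  roi <- voxel_indices(atlas, roi_id)
  if (length(roi) < 2L) {
    stop("seed ROI must have at least 2 voxels", call. = FALSE)
  }
  nv <- n_brain_voxels(atlas)
  in_roi <- logical(nv)
  in_roi[roi] <- TRUE
  nonroi <- which(!in_roi)
  blocks <- lapply(roi, function(i) {
    js <- sort(c(nonroi, roi[roi > i]))
    cbind(i = rep.int(i, length(js)), j = js)
  })
  pairs <- do.call(rbind, blocks)
  structure(pairs, roi_id = as.integer(roi_id), roi_voxels = roi,
            n_voxels = nv, class = c("pair_index", class(pairs)))
}

#' @export
print.pair_index <- function(x, ...) {
  cat("<pair_index> ", nrow(x), " voxel pairs: ROI region ",
      attr(x, "roi_id"), " (", length(attr(x, "roi_voxels")),
      " voxels) vs ", attr(x, "n_voxels"), " brain voxels\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.pair_index <- function(x, ...) {
  tibble::tibble(pair = seq_len(nrow(x)), i = x[, 1], j = x[, 2])
}

#' Pearson correlation of two time series
#'
#' The per-subject functional-connectivity measure. Constant input yields a
#' missing-value sentinel (`NA`), not an error; such voxels are recorded in
#' the zero-variance registry when computed store-wide.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return Correlation in `[-1, 1]`, or `NA` for constant input.
#' @export
pearson_fc <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("time series must have equal length >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Fisher z-transform
#'
#' `z = arctanh(r)`, the variance-stabilising transform applied to every
#' correlation before group testing. Odd and strictly increasing. With
#' `clip = FALSE` (default), `|r| >= 1` returns the `NA` sentinel; with
#' `clip = TRUE`, numerically degenerate `|r| >= 1` (duplicate series) is
#' clipped to `1 - 1e-12` in magnitude so the result stays finite.
#'
#' @param r Numeric vector of correlations.
#' @param clip Guard `|r| >= 1` by clipping instead of returning `NA`.
#' @return Fisher-z values.
#' @export
fisher_z <- function(r, clip = FALSE) {
  z <- r
  bad <- !is.na(r) & abs(r) >= 1
  if (clip) {
    z[bad] <- sign(r[bad]) * (1 - 1e-12)
  } else {
    z[bad] <- NA_real_
  }
  atanh(z)
}

# rows scaled so that tcrossprod of two rows is their Pearson r;
# zero-variance rows become NA and are reported
standardize_rows <- function(mat) {
  mu <- rowMeans(mat)
  xc <- mat - mu
  ss <- sqrt(rowSums(xc^2))
  zero <- which(ss == 0)
  ss[ss == 0] <- NA_real_
  list(x = xc / ss, zero_variance = zero)
}

#' Fisher-z connectivity of one subject over a pair index
#'
#' Computes, for every enumerated voxel pair, the Pearson correlation of the
#' two voxels' time series followed by the Fisher z-transform. Work proceeds
#' in chunks of pairs; `chunk_size` is purely a memory knob (peak additional
#' memory is O(chunk_size x timepoints)) and never changes the result —
#' any chunking yields bit-identical values.
#'
#' Voxels with constant time series are registered as zero-variance; every
#' pair touching one gets `NA`. Numerically degenerate correlations
#' (`|r| >= 1`, e.g. duplicated series) are clipped to `+/-(1 - 1e-12)`
#' before `arctanh` so the z stays finite.
#'
#' @param scan A [subject_scan()] whose rows cover all voxels in `pairs`.
#' @param pairs A [enumerate_pairs()] index.
#' @param chunk_size Pairs per chunk (default 65536).
#' @return List with `z` (numeric vector, one per pair) and `zero_variance`
#'   (mask positions of constant voxels).
#' @export
subject_pair_fc <- function(scan, pairs, chunk_size = 65536L) {
  if (nrow(scan$data) < attr(pairs, "n_voxels")) {
    stop("scan has fewer rows than the pair index's voxel universe",
         call. = FALSE)
  }
  std <- standardize_rows(scan$data)
  n <- nrow(pairs)
  z <- numeric(n)
  starts <- seq.int(1L, n, by = as.integer(chunk_size))
  for (s in starts) {
    e <- min(s + chunk_size - 1L, n)
    idx <- s:e
    r <- rowSums(std$x[pairs[idx, 1], , drop = FALSE] *
                   std$x[pairs[idx, 2], , drop = FALSE])
    z[idx] <- fisher_z(r, clip = TRUE)
  }
  list(z = z, zero_variance = std$zero_variance)
}

#' Build the subjects-by-pairs Fisher-z store
#'
#' The pipeline's central matrix: one row per subject, one column per
#' enumerated voxel pair, holding Fisher-z connectivity. Pairs touching a
#' subject's zero-variance voxels are `NA` and are excluded from all
#' downstream tests (the exclusion count is reported by `print()`).
#'
#' @param scans List of [subject_scan()]s.
#' @param pairs A [enumerate_pairs()] index.
#' @param chunk_size Passed to [subject_pair_fc()].
#' @return An `fc_store`: list with `z` (subjects x pairs matrix), `pairs`,
#'   `subjects` (ids in row order) and `zero_variance` (named list of mask
#'   positions per affected subject).
#' @export
compute_fc_store <- function(scans, pairs, chunk_size = 65536L) {
  ids <- vapply(scans, function(s) s$subject_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate subject ids in scans", call. = FALSE)
  z <- matrix(NA_real_, nrow = length(scans), ncol = nrow(pairs),
              dimnames = list(ids, NULL))
  zv <- list()
  for (k in seq_along(scans)) {
    res <- subject_pair_fc(scans[[k]], pairs, chunk_size)
    z[k, ] <- res$z
    if (length(res$zero_variance)) zv[[ids[k]]] <- res$zero_variance
  }
  new_fc_store(z, pairs, ids, zv)
}

new_fc_store <- function(z, pairs, subjects, zero_variance) {
  structure(list(z = z, pairs = pairs, subjects = subjects,
                 zero_variance = zero_variance),
            class = "fc_store")
}

#' @export
print.fc_store <- function(x, ...) {
  n_na <- sum(is.na(x$z))
  cat("<fc_store> ", nrow(x$z), " subjects x ", ncol(x$z),
      " voxel pairs (Fisher z)\n", sep = "")
  if (n_na) {
    cat("  ", n_na, " missing entries from ",
        length(x$zero_variance), " subject(s) with zero-variance voxels\n",
        sep = "")
  }
  invisible(x)
}

#' Write / read the Fisher-z store as HDF5
#'
#' Layout: datasets `/z` (pairs x subjects, float32 on disk), `/pairs`
#' (pairs x 2 mask positions), `/subjects` (ids), `/zero_variance`
#' (two-column table subject-row / voxel), plus the ROI bookkeeping needed
#' to reconstruct the pair index. Values are stored as float64 so the
#' round-trip is exact.
#'
#' @param store An `fc_store`.
#' @param path HDF5 file path (overwritten).
#' @return Invisibly, `path`.
#' @export
write_fc_store <- function(store, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(t(store$z), path, "z")
  rhdf5::h5write(unclass(store$pairs)[, , drop = FALSE], path, "pairs")
  rhdf5::h5write(store$subjects, path, "subjects")
  zv <- if (length(store$zero_variance)) {
    do.call(rbind, lapply(names(store$zero_variance), function(id) {
      cbind(match(id, store$subjects), store$zero_variance[[id]])
    }))
  } else matrix(integer(0), 0, 2)
  rhdf5::h5write(zv, path, "zero_variance")
  rhdf5::h5write(attr(store$pairs, "roi_id"), path, "roi_id")
  rhdf5::h5write(attr(store$pairs, "roi_voxels"), path, "roi_voxels")
  rhdf5::h5write(attr(store$pairs, "n_voxels"), path, "n_voxels")
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname write_fc_store
#' @param path HDF5 file written by [write_fc_store()].
#' @return `read_fc_store()`: the `fc_store`.
#' @export
read_fc_store <- function(path) {
  z <- t(rhdf5::h5read(path, "z"))
  pairs <- rhdf5::h5read(path, "pairs")
  storage.mode(pairs) <- "integer"
  colnames(pairs) <- c("i", "j")
  subjects <- as.character(rhdf5::h5read(path, "subjects"))
  zvm <- rhdf5::h5read(path, "zero_variance")
  zv <- list()
  if (length(zvm)) {
    sp <- split(as.integer(zvm[, 2]), as.integer(zvm[, 1]))
    zv <- stats::setNames(sp, subjects[as.integer(names(sp))])
  }
  pairs <- structure(pairs,
                     roi_id = as.integer(rhdf5::h5read(path, "roi_id")),
                     roi_voxels = as.integer(rhdf5::h5read(path, "roi_voxels")),
                     n_voxels = as.integer(rhdf5::h5read(path, "n_voxels")),
                     class = c("pair_index", "matrix", "array"))
  rownames(z) <- subjects
  rhdf5::h5closeAll()
  new_fc_store(z, pairs, subjects, zv)
}

#' Subset a store to a set of subjects
#' @param store An `fc_store`.
#' @param subject_ids Character vector of ids to keep (order respected).
#' @return An `fc_store` with the selected rows.
#' @export
subset_fc_store <- function(store, subject_ids) {
  miss <- setdiff(subject_ids, store$subjects)
  if (length(miss)) stop("unknown subjects: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  rows <- match(subject_ids, store$subjects)
  new_fc_store(store$z[rows, , drop = FALSE], store$pairs,
               store$subjects[rows],
               store$zero_variance[intersect(names(store$zero_variance), subject_ids)])
}
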