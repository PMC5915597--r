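#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an association result
#'
#' One row per voxel pair with the combined statistics, or per voxel with
#' the MA / signed-sum summaries when `level = "voxel"`.
#'
#' @param x An [associate()] result.
#' @param level `"pair"` or `"voxel"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.association_result <- function(x, level = c("pair", "voxel"), ...) {
  level <- match.arg(level)
  if (level == "pair") x$links else x$voxels
}

#' One-row summary of an association result
#' @param x An [associate()] result.
#' @param ... Unused.
#' @return Tibble with pair counts, the threshold mode and attained cutoff,
#'   significant-link and cluster counts.
#' @export
glance.association_result <- function(x, ...) {
  tibble::tibble(
    n_sites = length(x$sites),
    n_pairs = nrow(x$links),
    mode = format(x$mode),
    threshold_attained = x$threshold,
    n_significant = sum(x$links$significant),
    n_clusters = nrow(x$clusters)
  )
}

#' Tidy per-site link statistics
#' @param x A [site_link_test()] result.
#' @param ... Unused.
#' @return The underlying tibble with `site` and `n` columns added.
#' @export
tidy.site_link_stats <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::mutate(site = attr(x, "site"), n = attr(x, "n"),
                  .before = 1)
}

#' Tidy clinical correlations
#' @param x A [clinical_correlates()] result.
#' @param ... Unused.
#' @return A plain tibble.
#' @export
tidy.clinical_correlation <- function(x, ...) tibble::as_tibble(x)

#' Axial-slice map of the per-voxel signed association summary
#'
#' Tiles the signed sum-of-|Z| statistic over chosen axial (z) slices:
#' red-positive / blue-negative, the display convention of signed
#' connectivity-difference maps.
#'
#' @param object An [associate()] result.
#' @param atlas The atlas the result was computed on.
#' @param slices Grid z-indices to show (default: every slice containing a
#'   nonzero value, capped at 6).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.association_result <- function(object, atlas, slices = NULL, ...) {
  vals <- object$voxels$s * ifelse(object$voxels$sign < 0, -1, 1)
  ijk <- arrayInd(atlas$mask_idx, dim(atlas$labels))
  df <- tibble::tibble(x = ijk[, 1], y = ijk[, 2], z = ijk[, 3], value = vals)
  if (is.null(slices)) {
    nz <- sort(unique(df$z[df$value != 0]))
    slices <- if (length(nz)) utils::head(nz, 6) else
      unique(round(stats::quantile(df$z, c(0.25, 0.5, 0.75))))
  }
  df <- df[df$z %in% slices, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~z, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "grey95",
                                  high = "red", name = "signed sum |Z|") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (voxels)", y = "y (voxels)",
                  title = paste("Signed association map:",
                                object$contrast[1], "vs", object$contrast[2]))
}

#' Forest-style plot of clinical correlations
#'
#' Per-site partial correlations (points sized by site n) per cluster and
#' clinical score, with the Liptak-Stouffer combined two-tailed p annotated
#' by asterisks (* < 0.05, ** < 0.01).
#'
#' @param object A [clinical_correlates()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.clinical_correlation <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$label <- ifelse(df$combined_p < 0.01, "**",
                     ifelse(df$combined_p < 0.05, "*", ""))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r,
                                   y = factor(.data$cluster),
                                   colour = .data$site,
                                   size = .data$n)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), x = Inf,
                       hjust = 1.2, colour = "black", size = 4,
                       show.legend = FALSE) +
    ggplot2::facet_wrap(~score) +
    ggplot2::scale_size_continuous(range = c(2, 5)) +
    ggplot2::labs(x = "partial correlation r", y = "cluster",
                  title = "Clinical correlates of cluster-wise connectivity")
}
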