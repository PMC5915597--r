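#' ROI-wise mean connectivity profiles
#'
#' For each row of the association cluster table, averages each subject's
#' Fisher-z connectivity over that cluster's significant links (the links
#' whose endpoints touch the cluster, under the primary significance mask).
#' These region-set means are the per-subject connectivity summaries that
#' enter the clinical correlations. A subject with all of a cluster's links
#' missing gets `NA` for that cluster; a cluster whose link set is empty is
#' dropped with a warning.
#'
#' @param store The `fc_store` the association was run on.
#' @param result An [associate()] result (supplies mask and cluster table).
#' @return Long tibble: `subject_id`, `cluster`, `regions`, `mean_z`.
#' @export
roiwise_mean_fc <- function(store, result) {
  mask <- result$links$significant
  pairs <- store$pairs
  sig <- which(mask)
  out <- purrr::map_dfr(seq_len(nrow(result$clusters)), function(k) {
    vox <- result$clusters$voxels[[k]]
    links <- sig[pairs[sig, 1] %in% vox | pairs[sig, 2] %in% vox]
    if (!length(links)) {
      warning("cluster ", k, " has no significant links; dropped")
      return(NULL)
    }
    zsub <- store$z[, links, drop = FALSE]
    tibble::tibble(subject_id = store$subjects,
                   cluster = result$clusters$cluster[k],
                   regions = result$clusters$regions[k],
                   mean_z = unname(rowMeans(zsub, na.rm = TRUE)))
  })
  out$mean_z[is.nan(out$mean_z)] <- NA_real_
  out
}

#' Partial correlation with covariate adjustment
#'
#' Pearson correlation of the residuals of `x` and `y` after linear
#' regression of each on the covariates (plus intercept). The two-tailed p
#' uses `t = r * sqrt((n - k - 2) / (1 - r^2))` on `n - k - 2` degrees of
#' freedom, with `k` covariates.
#'
#' @param x,y Numeric vectors.
#' @param covariates Numeric matrix (or NULL for a plain correlation).
#' @return List with `r`, `p`, `n`, `df`.
#' @export
partial_corr <- function(x, y, covariates = NULL) {
  keep <- stats::complete.cases(x, y, covariates)
  x <- x[keep]; y <- y[keep]
  C <- if (is.null(covariates)) matrix(numeric(0), length(x), 0) else
    as.matrix(covariates)[keep, , drop = FALSE]
  n <- length(x); k <- ncol(C)
  if (n < k + 3L) stop("need n > #covariates + 2", call. = FALSE)
  X <- cbind(1, C)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient covariate matrix", call. = FALSE)
  rx <- stats::lm.fit(X, x)$residuals
  ry <- stats::lm.fit(X, y)$residuals
  # a variable fully explained by the covariates has no residual signal
  if (stats::sd(rx) <= 1e-10 * (stats::sd(x) + 1e-300) ||
      stats::sd(ry) <= 1e-10 * (stats::sd(y) + 1e-300)) {
    return(list(r = 0, p = 1, n = n, df = n - k - 2L))
  }
  r <- stats::cor(rx, ry)
  df <- n - k - 2L
  tval <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tval), df), n = n, df = df)
}

#' Combine per-site correlations with the Liptak-Stouffer method
#'
#' Each site's `(r, p)` becomes the signed score
#' `z = sign(r) * qnorm(1 - p/2)`; scores are combined with weights
#' `sqrt(n)` exactly as for the link statistics. A single site returns its
#' own p.
#'
#' @param r,p,n Per-site correlation, two-tailed p and sample size.
#' @return List with `Z` and two-tailed `p`.
#' @export
combine_correlation_sites <- function(r, p, n) {
  stopifnot(length(r) == length(p), length(p) == length(n), length(r) >= 1)
  z <- p_to_signed_z(p, r)
  comb <- liptak_combine(matrix(z, nrow = 1), weights = sqrt(n))
  list(Z = comb$Z, p = comb$p)
}

#' Clinical correlates of the significant connectivity clusters
#'
#' Within patients, correlates each cluster's ROI-wise mean connectivity
#' with each clinical score by partial correlation (adjusting for head
#' motion, education, sex, age and medication by default), separately per
#' site, then combines sites with the sqrt-n-weighted Liptak-Stouffer
#' method. Covariates constant within a site (e.g. medication at an
#' all-medicated site) are dropped for that site with a message.
#'
#' @param profile Output of [roiwise_mean_fc()].
#' @param phenotypes Phenotype tibble.
#' @param scores Clinical score columns to correlate.
#' @param covariates Adjustment covariates.
#' @param min_site_n Minimum patients per site to attempt a correlation.
#' @return A `clinical_correlation` tibble: one row per cluster x score x
#'   site with `r`, `p`, `n`, plus the combined `combined_Z`, `combined_p`
#'   repeated across that cluster/score's site rows.
#' @export
clinical_correlates <- function(profile, phenotypes,
                                scores = c("hamd", "bdi", "illness_duration"),
                                covariates = c("mean_fd", "education", "sex",
                                               "age", "medicated"),
                                min_site_n = 8L) {
  ph <- validate_phenotypes(phenotypes)
  ph <- ph[ph$group == "patient", , drop = FALSE]
  dat <- dplyr::inner_join(profile, ph, by = "subject_id")
  combos <- tidyr::expand_grid(
    cluster = unique(profile$cluster), score = scores)
  rows <- purrr::pmap_dfr(combos, function(cluster, score) {
    dd <- dat[dat$cluster == cluster, , drop = FALSE]
    site_rows <- purrr::map_dfr(unique(dd$site), function(s) {
      ds <- dd[dd$site == s, , drop = FALSE]
      cv <- list()
      for (nm in covariates) {
        v <- ds[[nm]]
        if (length(unique(v[!is.na(v)])) < 2L) {
          message("site '", s, "': covariate '", nm,
                  "' constant among patients; dropped")
          next
        }
        cv[[nm]] <- v
      }
      C <- if (length(cv)) do.call(cbind, cv) else NULL
      keep <- stats::complete.cases(ds$mean_z, ds[[score]], C)
      if (sum(keep) < max(min_site_n, length(cv) + 3L)) return(NULL)
      pc <- partial_corr(ds$mean_z, ds[[score]], C)
      tibble::tibble(cluster = cluster,
                     regions = ds$regions[1], score = score, site = s,
                     n = pc$n, r = pc$r, p = pc$p)
    })
    if (!nrow(site_rows)) return(NULL)
    comb <- combine_correlation_sites(site_rows$r, site_rows$p, site_rows$n)
    site_rows$combined_Z <- comb$Z
    site_rows$combined_p <- comb$p
    site_rows
  })
  structure(rows, class = c("clinical_correlation", class(rows)))
}

#' Write the clinical correlation table as TSV
#' @param cc A [clinical_correlates()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_clinical_correlates <- function(cc, path) {
  readr::write_tsv(as.data.frame(cc), path)
  invisible(path)
}
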