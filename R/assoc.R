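#' Per-site covariate-adjusted link tests
#'
#' For one imaging site, fits per voxel pair the linear model
#' `z ~ intercept + group + covariates` on that site's subjects and returns
#' the group coefficient's estimate, t statistic (Student reference with
#' `df = n - p` where `p` is the number of model parameters) and two-tailed
#' p, together with the signed normal-quantile z used by the
#' Liptak-Stouffer combination. With no covariates this reduces exactly to
#' the pooled-variance two-sample t-test. The group regressor is 1 for
#' `contrast[1]` and 0 for `contrast[2]`, so positive t means
#' `contrast[1] > contrast[2]`.
#'
#' Covariates that are constant within the site are dropped (with a
#' message), mirroring the rank-deficiency rule used for all-medicated
#' sites; any remaining rank deficiency (e.g. a covariate collinear with the
#' group indicator) is an error. Pairs with missing z for any retained
#' subject get `NA` statistics and are dropped later by the combination.
#'
#' @param store An `fc_store` (or a subset of one) for the site's subjects.
#' @param phenotypes Phenotype tibble covering the store's subjects.
#' @param site Site label to analyse.
#' @param contrast Character vector of two group labels, tested as
#'   `contrast[1] - contrast[2]`. Labels are matched against `group` unless
#'   both are in `c("medicated", "unmedicated")`, which contrast patient
#'   subgroups by medication status.
#' @param covariates Phenotype columns to adjust for (default the nuisance
#'   set: age, sex, mean framewise displacement, education).
#' @return A `site_link_stats` tibble with columns `pair`, `estimate`, `t`,
#'   `p`, `z` and attributes `site`, `n` (subjects used) and
#'   `weight = sqrt(n)`.
#' @export
site_link_test <- function(store, phenotypes, site,
                           contrast = c("patient", "control"),
                           covariates = c("age", "sex", "mean_fd", "education")) {
  ph <- validate_phenotypes(phenotypes)
  ph <- ph[ph$site == site & ph$subject_id %in% store$subjects, , drop = FALSE]
  if (!nrow(ph)) stop("site '", site, "': no subjects in store", call. = FALSE)
  memb <- contrast_membership(ph, contrast)
  ph <- ph[!is.na(memb), , drop = FALSE]
  g <- memb[!is.na(memb)]
  if (sum(g == 1) < 2L || sum(g == 0) < 2L) {
    stop("site '", site, "': need >= 2 subjects per contrast group",
         call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1, group = g)
  for (cv in covariates) {
    if (!cv %in% names(ph)) stop("missing covariate column: ", cv, call. = FALSE)
    v <- ph[[cv]]
    if (anyNA(v)) stop("site '", site, "': covariate '", cv,
                       "' has missing values", call. = FALSE)
    if (stats::sd(v) == 0) {
      message("site '", site, "': covariate '", cv,
              "' is constant and was dropped")
      next
    }
    X <- cbind(X, stats::setNames(list(v), cv)[[1]])
    colnames(X)[ncol(X)] <- cv
  }
  if (qr(X)$rank < ncol(X)) {
    stop("site '", site, "': rank-deficient design (collinear covariates)",
         call. = FALSE)
  }
  Y <- store$z[match(ph$subject_id, store$subjects), , drop = FALSE]
  fit <- fit_group_glm(X, Y, term = "group")
  out <- tibble::tibble(pair = seq_len(ncol(Y)),
                        estimate = fit$estimate, t = fit$t, p = fit$p,
                        z = p_to_signed_z(fit$p, fit$t))
  structure(out, site = site, n = nrow(X), weight = sqrt(nrow(X)),
            contrast = contrast, class = c("site_link_stats", class(out)))
}

contrast_membership <- function(ph, contrast) {
  stopifnot(length(contrast) == 2L)
  med_levels <- c("medicated", "unmedicated")
  if (all(contrast %in% med_levels)) {
    lev <- ifelse(ph$group == "patient",
                  ifelse(ph$medicated == 1, "medicated", "unmedicated"),
                  NA_character_)
  } else {
    lev <- ph$group
  }
  out <- rep(NA_real_, nrow(ph))
  out[!is.na(lev) & lev == contrast[1]] <- 1
  out[!is.na(lev) & lev == contrast[2]] <- 0
  out
}

# Vectorised OLS across response columns; t and two-tailed p for one term.
fit_group_glm <- function(X, Y, term) {
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("more model parameters than subjects", call. = FALSE)
  XtXinv <- chol2inv(chol(crossprod(X)))
  coefs <- XtXinv %*% crossprod(X, Y)            # p x m
  resid <- Y - X %*% coefs
  sigma2 <- colSums(resid^2) / (n - p)
  gi <- match(term, colnames(X))
  se <- sqrt(sigma2 * XtXinv[gi, gi])
  tt <- coefs[gi, ] / se
  tt[se == 0] <- NA_real_
  list(estimate = coefs[gi, ], t = tt,
       p = 2 * stats::pt(-abs(tt), df = n - p), df = n - p)
}

#' Signed normal-quantile z from a two-tailed p
#'
#' Converts a site's two-tailed p-value into the signed standard-normal
#' score fed to the Liptak-Stouffer combination:
#' `z = sign(t) * qnorm(1 - p/2)`. `p = 1` maps to 0 regardless of sign.
#' p is floored at 1e-300 so the result stays finite.
#'
#' @param p Two-tailed p-values in `(0, 1]`.
#' @param t Test statistics supplying the signs (only the sign is used).
#' @return Signed z-scores (NA propagated).
#' @export
p_to_signed_z <- function(p, t) {
  ok <- !is.na(p)
  if (any(p[ok] <= 0 | p[ok] > 1)) stop("p must lie in (0, 1]", call. = FALSE)
  p <- pmax(p, 1e-300)
  s <- sign(t)
  s[!is.na(s) & s == 0] <- 1
  s * stats::qnorm(p / 2, lower.tail = FALSE)
}

#' Liptak-Stouffer combination across sites
#'
#' Combines per-site signed z-scores into `Z = sum(w_k z_k) / sqrt(sum(w_k^2))`
#' with weights `w_k = sqrt(n_k)`, standard normal under the null, and the
#' two-tailed `p = 2 * (1 - Phi(|Z|))`. Sites with a missing z for a pair are
#' dropped from both numerator and denominator for that pair; a pair missing
#' everywhere stays `NA`. A single site returns its z unchanged for any
#' weight.
#'
#' @param z Matrix of signed z-scores, pairs x sites (a vector is treated as
#'   a single pair), or a list of `site_link_stats`.
#' @param weights Per-site weights (`sqrt` of the site sample sizes). Taken
#'   from the objects when `z` is a list of `site_link_stats`.
#' @return Tibble with `pair`, `Z`, `p`.
#' @export
liptak_combine <- function(z, weights = NULL) {
  if (is.list(z) && !is.data.frame(z) && !is.matrix(z)) {
    weights <- vapply(z, function(s) attr(s, "weight"), numeric(1))
    z <- do.call(cbind, lapply(z, function(s) s$z))
  }
  if (!is.matrix(z)) z <- matrix(z, nrow = 1)
  if (is.null(weights) || length(weights) != ncol(z) || any(weights <= 0)) {
    stop("need one positive weight per site", call. = FALSE)
  }
  W <- matrix(weights, nrow(z), ncol(z), byrow = TRUE)
  W[is.na(z)] <- NA_real_
  num <- rowSums(W * z, na.rm = TRUE)
  den <- sqrt(rowSums(W^2, na.rm = TRUE))
  Z <- ifelse(rowSums(!is.na(z)) == 0, NA_real_, num / den)
  tibble::tibble(pair = seq_len(nrow(z)), Z = Z,
                 p = 2 * stats::pnorm(-abs(Z)))
}

#' Benjamini-Hochberg step-up over the voxel-pair family
#'
#' Standard BH: sort p ascending, find the largest k with
#' `p_(k) <= k * q / m`, reject every p at or below that threshold
#' (ties included, deterministic). Missing p-values are excluded from `m`
#' and never rejected.
#'
#' @param p P-values (NA allowed).
#' @param q Target false discovery rate in `(0, 1)`.
#' @return List with `threshold` (the attained p cutoff `p*`, 0 when nothing
#'   is rejected) and `mask` (logical rejections, FALSE where p is NA).
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)", call. = FALSE)
  ok <- !is.na(p)
  if (!any(ok)) stop("no finite p-values", call. = FALSE)
  padj <- stats::p.adjust(p[ok], method = "BH")
  rej <- padj <= q
  mask <- logical(length(p))
  mask[ok][rej] <- TRUE
  threshold <- if (any(rej)) max(p[ok][rej]) else 0
  list(threshold = threshold, mask = mask)
}

#' Per-voxel measure of association (MA)
#'
#' `MA_v` is the number of significant links incident to voxel `v` at the
#' chosen threshold — defined for seed-ROI and non-ROI voxels alike.
#'
#' @param mask Logical significance mask over pairs.
#' @param pairs The [enumerate_pairs()] index the mask aligns to.
#' @return Integer vector, one count per brain-mask voxel.
#' @export
ma_score <- function(mask, pairs) {
  check_mask(mask, pairs)
  nv <- attr(pairs, "n_voxels")
  sig <- which(mask)
  tabulate(c(pairs[sig, 1], pairs[sig, 2]), nbins = nv)
}

#' Per-voxel signed sum-of-|Z| summary
#'
#' For each voxel, `S_v` is the sum of `|Z|` over its significant links, and
#' `sign_v` is the sign of the sum of the signed `Z` over the same links
#' (0 with no significant links). This is the per-voxel map used to display
#' where connectivity differs and in which net direction.
#'
#' @param Z Combined z-scores per pair.
#' @param mask Logical significance mask over pairs.
#' @param pairs The pair index.
#' @return Tibble with `voxel`, `s` (sum of |Z|), `sign` (-1, 0, +1).
#' @export
voxel_signed_summary <- function(Z, mask, pairs) {
  check_mask(mask, pairs)
  nv <- attr(pairs, "n_voxels")
  sig <- which(mask & !is.na(Z))
  vox <- c(pairs[sig, 1], pairs[sig, 2])
  acc <- function(vals) {
    out <- numeric(nv)
    if (length(vox)) {
      t <- rowsum(vals, vox)
      out[as.integer(rownames(t))] <- t
    }
    out
  }
  s <- acc(rep(abs(Z[sig]), 2))
  signed <- acc(rep(Z[sig], 2))
  tibble::tibble(voxel = seq_len(nv), s = s, sign = sign(signed))
}

check_mask <- function(mask, pairs) {
  if (!is.logical(mask) || length(mask) != nrow(pairs)) {
    stop("mask must be a logical vector aligned to the pair index",
         call. = FALSE)
  }
}

# 26-connected components of a set of brain-mask voxel positions.
# Returns an integer component label per input voxel.
connected_components_26 <- function(voxels, atlas) {
  if (!length(voxels)) return(integer(0))
  dims <- dim(atlas$labels)
  lin <- atlas$mask_idx[voxels]
  memb <- array(0L, dims)
  memb[lin] <- seq_along(voxels)
  ijk <- arrayInd(lin, dims)
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, , drop = FALSE]
  # half the offsets suffice: each undirected adjacency found once
  offsets <- offsets[seq_len(13), , drop = FALSE]
  edges <- list()
  for (o in seq_len(nrow(offsets))) {
    nb <- sweep(ijk, 2, offsets[o, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
      nb[, 2] >= 1 & nb[, 2] <= dims[2] &
      nb[, 3] >= 1 & nb[, 3] <= dims[3]
    if (!any(ok)) next
    nb_lin <- (nb[ok, 3] - 1) * dims[1] * dims[2] +
      (nb[ok, 2] - 1) * dims[1] + nb[ok, 1]
    hit <- memb[nb_lin]
    keep <- hit > 0L
    if (any(keep)) {
      edges[[length(edges) + 1L]] <-
        cbind(which(ok)[keep], hit[keep])
    }
  }
  g <- igraph::make_empty_graph(n = length(voxels), directed = FALSE)
  if (length(edges)) {
    em <- do.call(rbind, edges)
    g <- igraph::add_edges(g, t(em))
  }
  igraph::components(g)$membership
}

#' Cluster-extent filtering of a significance mask
#'
#' Voxels carrying at least one significant link are grouped into
#' 26-connected components; components with `min_cluster_voxels` voxels or
#' fewer have all their incident links removed from the mask (i.e. only
#' clusters strictly larger than the minimum survive, matching the
#' "cluster size > k" convention).
#'
#' @param mask Logical significance mask over pairs.
#' @param pairs The pair index.
#' @param atlas The atlas supplying voxel geometry.
#' @param min_cluster_voxels Extent threshold.
#' @return Filtered logical mask.
#' @export
cluster_filter <- function(mask, pairs, atlas, min_cluster_voxels) {
  check_mask(mask, pairs)
  active <- sort(unique(c(pairs[mask, 1], pairs[mask, 2])))
  if (!length(active)) return(mask)
  comp <- connected_components_26(active, atlas)
  sizes <- tabulate(comp)
  small <- active[sizes[comp] <= min_cluster_voxels]
  if (!length(small)) return(mask)
  drop <- mask & (pairs[, 1] %in% small | pairs[, 2] %in% small)
  mask & !drop
}

#' Region cluster table
#'
#' Groups every voxel incident to a significant link (seed side included, so
#' the seed region itself appears as a cluster when its voxels carry
#' significant links) into 26-connected components and reports one row per
#' surviving component: the set of atlas region names its voxels occupy, the
#' voxel count, the sum over all incident significant links of `|Z|` (a link
#' joining two components contributes to both), and the world coordinate of
#' the peak voxel (largest per-voxel sum of |Z|). Components with
#' `min_cluster_voxels` voxels or fewer are suppressed ("more than 10"
#' by default). Rows are ordered by decreasing sum of |Z|.
#'
#' @param mask Logical significance mask over pairs.
#' @param Z Combined z-scores per pair.
#' @param atlas The atlas.
#' @param pairs The pair index.
#' @param min_cluster_voxels Suppress components at or below this size.
#' @return Tibble with columns `cluster`, `regions`, `n_voxels`,
#'   `sum_abs_z`, `peak_x`, `peak_y`, `peak_z`, plus a `voxels` list-column
#'   of mask positions (used by the clinical stage).
#' @export
region_cluster_table <- function(mask, Z, atlas, pairs,
                                 min_cluster_voxels = 10L) {
  check_mask(mask, pairs)
  active <- sort(unique(c(pairs[mask, 1], pairs[mask, 2])))
  empty <- tibble::tibble(cluster = integer(), regions = character(),
                          n_voxels = integer(), sum_abs_z = numeric(),
                          peak_x = numeric(), peak_y = numeric(),
                          peak_z = numeric(), voxels = list())
  if (!length(active)) return(empty)
  comp <- connected_components_26(active, atlas)
  svox <- voxel_signed_summary(Z, mask, pairs)
  sig <- which(mask & !is.na(Z))
  comp_of <- integer(attr(pairs, "n_voxels"))
  comp_of[active] <- comp
  rows <- lapply(seq_len(max(comp)), function(k) {
    vox <- active[comp == k]
    if (length(vox) <= min_cluster_voxels) return(NULL)
    touches <- comp_of[pairs[sig, 1]] == k | comp_of[pairs[sig, 2]] == k
    region_ids <- sort(unique(atlas$mask_labels[vox]))
    nms <- atlas$region_names$region_name[
      match(region_ids, atlas$region_names$region_id)]
    peak <- vox[which.max(svox$s[vox])]
    xyz <- voxel_to_world(atlas, peak)
    tibble::tibble(regions = paste(nms, collapse = ", "),
                   n_voxels = length(vox),
                   sum_abs_z = sum(abs(Z[sig][touches])),
                   peak_x = xyz[1], peak_y = xyz[2], peak_z = xyz[3],
                   voxels = list(vox))
  })
  rows <- dplyr::bind_rows(rows)
  if (!nrow(rows)) return(empty)
  rows <- dplyr::arrange(rows, dplyr::desc(.data$sum_abs_z))
  dplyr::bind_cols(tibble::tibble(cluster = seq_len(nrow(rows))), rows)
}

#' Significance threshold modes
#'
#' The three reporting modes used for the association maps: `"fdr"`
#' (Benjamini-Hochberg at rate `q` over all pairs), `"unc"` (uncorrected
#' `p < alpha`) and `"unc_cluster"` (uncorrected `p < alpha` plus a
#' cluster-extent filter keeping components larger than
#' `min_cluster_voxels`). A compact string form is accepted everywhere a
#' mode is: `"fdr:0.05"`, `"unc:1e-4"`, `"unc-cluster:1e-3:20"`.
#'
#' @param mode `"fdr"`, `"unc"` or `"unc_cluster"`.
#' @param q FDR rate (fdr mode).
#' @param alpha Uncorrected level (unc modes).
#' @param min_cluster_voxels Extent threshold (unc_cluster mode).
#' @return A `threshold_mode` object.
#' @export
threshold_mode <- function(mode = c("fdr", "unc", "unc_cluster"),
                           q = 0.05, alpha = 1e-4, min_cluster_voxels = 20L) {
  mode <- match.arg(mode)
  if (mode == "fdr" && (q <= 0 || q >= 1)) stop("q in (0,1)", call. = FALSE)
  if (mode != "fdr" && (alpha <= 0 || alpha >= 1)) stop("alpha in (0,1)", call. = FALSE)
  if (mode == "unc_cluster" && min_cluster_voxels < 1) {
    stop("min_cluster_voxels >= 1", call. = FALSE)
  }
  structure(list(mode = mode, q = q, alpha = alpha,
                 min_cluster_voxels = as.integer(min_cluster_voxels)),
            class = "threshold_mode")
}

#' @rdname threshold_mode
#' @param x A string such as `"fdr:0.05"` or `"unc-cluster:1e-3:20"`, or a
#'   `threshold_mode` (returned unchanged).
#' @export
parse_threshold_mode <- function(x) {
  if (inherits(x, "threshold_mode")) return(x)
  parts <- strsplit(x, ":", fixed = TRUE)[[1]]
  switch(gsub("-", "_", parts[1]),
         fdr = threshold_mode("fdr", q = as.numeric(parts[2])),
         unc = threshold_mode("unc", alpha = as.numeric(parts[2])),
         unc_cluster = threshold_mode("unc_cluster",
                                      alpha = as.numeric(parts[2]),
                                      min_cluster_voxels = as.integer(parts[3])),
         stop("unknown threshold mode: ", x, call. = FALSE))
}

#' @export
format.threshold_mode <- function(x, ...) {
  switch(x$mode,
         fdr = sprintf("fdr:%g", x$q),
         unc = sprintf("unc:%g", x$alpha),
         unc_cluster = sprintf("unc-cluster:%g:%d", x$alpha,
                               x$min_cluster_voxels))
}

#' @export
print.threshold_mode <- function(x, ...) {
  cat("<threshold_mode>", format(x), "\n"); invisible(x)
}

#' Multi-site voxel-pair association analysis
#'
#' The full association stage: per-site covariate-adjusted link tests,
#' signed-z conversion, sqrt-n-weighted Liptak-Stouffer combination across
#' sites (a single site passes through via the identity), thresholding in
#' the requested mode, and the per-voxel and cluster summaries.
#'
#' @param store An `fc_store` over all subjects.
#' @param phenotypes Phenotype tibble.
#' @param atlas The atlas the store was built on.
#' @param contrast Two group labels, tested as `contrast[1] - contrast[2]`
#'   (see [site_link_test()]).
#' @param covariates Nuisance covariates adjusted per site.
#' @param mode A [threshold_mode()] or its string form.
#' @param sites Sites to include (default: all sites with subjects in both
#'   contrast groups after phenotype subsetting).
#' @param min_table_cluster_voxels Suppression size for the cluster table.
#' @return An `association_result` with elements `links` (tibble: pair, i,
#'   j, Z, p, significant), `site_stats`, `threshold` (attained p cutoff),
#'   `mode`, `voxels` (tibble: voxel, ma, s, sign), `clusters` (region
#'   cluster table) and `pairs`.
#' @export
associate <- function(store, phenotypes, atlas,
                      contrast = c("patient", "control"),
                      covariates = c("age", "sex", "mean_fd", "education"),
                      mode = threshold_mode("fdr", q = 0.05),
                      sites = NULL,
                      min_table_cluster_voxels = 10L) {
  mode <- parse_threshold_mode(mode)
  ph <- validate_phenotypes(phenotypes)
  ph <- ph[ph$subject_id %in% store$subjects, , drop = FALSE]
  if (is.null(sites)) {
    memb <- contrast_membership(ph, contrast)
    tab <- table(ph$site[!is.na(memb)], memb[!is.na(memb)])
    sites <- rownames(tab)[apply(tab >= 2, 1, all)]
  }
  if (!length(sites)) stop("no site has both contrast groups", call. = FALSE)
  site_stats <- lapply(sites, function(s) {
    ids <- ph$subject_id[ph$site == s]
    site_link_test(subset_fc_store(store, ids), ph, s, contrast, covariates)
  })
  names(site_stats) <- sites
  comb <- liptak_combine(site_stats)
  mask <- switch(mode$mode,
                 fdr = {
                   bh <- bh_fdr(comb$p, mode$q)
                   threshold <- bh$threshold
                   bh$mask
                 },
                 unc = {
                   threshold <- mode$alpha
                   !is.na(comb$p) & comb$p < mode$alpha
                 },
                 unc_cluster = {
                   threshold <- mode$alpha
                   m0 <- !is.na(comb$p) & comb$p < mode$alpha
                   cluster_filter(m0, store$pairs, atlas,
                                  mode$min_cluster_voxels)
                 })
  svox <- voxel_signed_summary(comb$Z, mask, store$pairs)
  voxels <- tibble::tibble(voxel = svox$voxel,
                           ma = ma_score(mask, store$pairs),
                           s = svox$s, sign = svox$sign)
  clusters <- region_cluster_table(mask, comb$Z, atlas, store$pairs,
                                   min_cluster_voxels = min_table_cluster_voxels)
  links <- tibble::tibble(pair = comb$pair,
                          i = store$pairs[, 1], j = store$pairs[, 2],
                          Z = comb$Z, p = comb$p, significant = mask)
  structure(list(links = links, site_stats = site_stats,
                 threshold = threshold, mode = mode, voxels = voxels,
                 clusters = clusters, pairs = store$pairs,
                 contrast = contrast, sites = sites),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat("<association_result> ", x$contrast[1], " vs ", x$contrast[2],
      ", ", length(x$sites), " site(s), mode ", format(x$mode), "\n",
      "  ", nrow(x$links), " voxel pairs, ",
      sum(x$links$significant), " significant (attained p cutoff ",
      format(x$threshold, digits = 3), ")\n",
      "  ", nrow(x$clusters), " reported cluster(s)\n", sep = "")
  invisible(x)
}
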