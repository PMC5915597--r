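# Independent brute-force oracles. Deliberately naive (double loops,
# textbook formulas) and kept free of any package internals so they can
# arbitrate the vectorised implementations.

oracle_pairs <- function(roi, n_voxels) {
  out <- NULL
  for (i in sort(roi)) {
    for (j in seq_len(n_voxels)) {
      if (j == i) next
      if (j %in% roi && j < i) next  # within-ROI pair kept once, from the low side
      out <- rbind(out, c(i, j))
    }
  }
  out
}

oracle_pair_z <- function(data, pairs) {
  z <- numeric(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    x <- data[pairs[k, 1], ]; y <- data[pairs[k, 2], ]
    if (sd(x) == 0 || sd(y) == 0) { z[k] <- NA_real_; next }
    r <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    if (abs(r) >= 1) r <- sign(r) * (1 - 1e-12)
    z[k] <- atanh(r)
  }
  z
}

oracle_bh <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  ks <- which(ps <= seq_len(m) * q / m)
  if (!length(ks)) return(list(threshold = 0, mask = rep(FALSE, m)))
  thr <- ps[max(ks)]
  list(threshold = thr, mask = p <= thr)
}

oracle_ma <- function(mask, pairs, n_voxels) {
  ma <- integer(n_voxels)
  for (v in seq_len(n_voxels)) {
    ma[v] <- sum(mask & (pairs[, 1] == v | pairs[, 2] == v))
  }
  ma
}

oracle_signed <- function(Z, mask, pairs, n_voxels) {
  s <- numeric(n_voxels); sgn <- numeric(n_voxels)
  for (v in seq_len(n_voxels)) {
    inc <- which(mask & (pairs[, 1] == v | pairs[, 2] == v))
    s[v] <- sum(abs(Z[inc]))
    sgn[v] <- sign(sum(Z[inc]))
  }
  list(s = s, sign = sgn)
}

# flood-fill 26-connected components over mask-voxel coordinates
oracle_components <- function(coords) {
  n <- nrow(coords)
  comp <- integer(n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (comp[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (u in seq_len(n)) {
        if (comp[u] == 0L && all(abs(coords[u, ] - coords[v, ]) <= 1)) {
          comp[u] <- cur
          queue <- c(queue, u)
        }
      }
    }
  }
  comp
}

oracle_cluster_filter <- function(mask, pairs, atlas, min_vox) {
  active <- sort(unique(c(pairs[mask, 1], pairs[mask, 2])))
  if (!length(active)) return(mask)
  coords <- arrayInd(atlas$mask_idx[active], dim(atlas$labels))
  comp <- oracle_components(coords)
  keep_vox <- active[tabulate(comp)[comp] > min_vox]
  out <- mask
  for (k in which(mask)) {
    if (!(pairs[k, 1] %in% keep_vox) || !(pairs[k, 2] %in% keep_vox)) {
      out[k] <- FALSE
    }
  }
  out
}

# partial correlation through the inverse of the correlation matrix
oracle_partial_corr <- function(x, y, C) {
  R <- cor(cbind(x, y, C))
  P <- solve(R)
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

# small fixtures ------------------------------------------------------------

tiny_atlas <- function() {
  labels <- array(0L, c(6, 6, 6))
  labels[1:2, 1:2, 1] <- 1L   # 4-voxel seed
  labels[4:6, 1:2, 1] <- 2L   # 6 voxels
  labels[1:2, 4:5, 2] <- 3L   # 4 voxels
  fc_atlas(labels, diag(4),
           data.frame(region_id = 1:3,
                      region_name = c("seed", "target", "other")))
}

random_scan <- function(n_voxels, n_timepoints, seed, id = "s1") {
  withr::local_seed(seed)
  subject_scan(matrix(rnorm(n_voxels * n_timepoints), n_voxels), id)
}

# two-group phenotype table for hand-built stores
toy_phenotypes <- function(n_per_group, site = "siteA", seed = 1) {
  withr::local_seed(seed)
  n <- 2 * n_per_group
  tibble::tibble(
    subject_id = sprintf("%s_%02d", site, seq_len(n)),
    site = site,
    group = rep(c("control", "patient"), each = n_per_group),
    age = runif(n, 20, 60), sex = rbinom(n, 1, 0.5),
    education = runif(n, 8, 18), mean_fd = rlnorm(n, log(0.15), 0.3),
    medicated = ifelse(rep(c(FALSE, TRUE), each = n_per_group),
                       rbinom(n, 1, 0.5), NA_integer_),
    hamd = ifelse(rep(c(FALSE, TRUE), each = n_per_group),
                  pmax(round(rnorm(n, 22, 4)), 8), round(runif(n, 0, 4))),
    bdi = ifelse(rep(c(FALSE, TRUE), each = n_per_group),
                 pmax(round(rnorm(n, 25, 6)), 5), round(runif(n, 0, 6))),
    illness_duration = ifelse(rep(c(FALSE, TRUE), each = n_per_group),
                              round(rlnorm(n, log(24), 0.8)), NA_real_)
  )
}

# hand-built fc_store from an explicit z matrix
manual_store <- function(z, pairs, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("s%02d", seq_len(nrow(z)))
  rownames(z) <- ids
  structure(list(z = z, pairs = pairs, subjects = ids,
                 zero_variance = list()),
            class = "fc_store")
}
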