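#' Build a toy parcellation atlas on a regular grid
#'
#' Lays out non-overlapping cuboid regions in a 3D grid (identity-scaled
#' affine with configurable voxel size and origin). Optionally the unlabeled
#' remainder of the grid is filled with one extra "background brain" region
#' so every grid voxel is inside the brain mask.
#'
#' @param grid_dims Integer vector of 3 grid dimensions.
#' @param region_layout Data frame with one row per cuboid region: columns
#'   `region_id`, `region_name`, `x0`, `y0`, `z0` (1-based corner) and `dx`,
#'   `dy`, `dz` (extents).
#' @param fill_region Optional list `list(region_id =, region_name =)`; when
#'   given, all remaining voxels get this label.
#' @param voxel_size Edge length in mm for the affine (default 3, the
#'   typical resampled fMRI resolution).
#' @param origin World coordinate of voxel (0,0,0).
#' @return An [fc_atlas()].
#' @export
make_toy_atlas <- function(grid_dims, region_layout, fill_region = NULL,
                           voxel_size = 3, origin = c(0, 0, 0)) {
  stopifnot(length(grid_dims) == 3L)
  layout <- tibble::as_tibble(region_layout)
  labels <- array(0L, dim = grid_dims)
  for (r in seq_len(nrow(layout))) {
    xs <- layout$x0[r] + seq_len(layout$dx[r]) - 1L
    ys <- layout$y0[r] + seq_len(layout$dy[r]) - 1L
    zs <- layout$z0[r] + seq_len(layout$dz[r]) - 1L
    if (max(xs) > grid_dims[1] || max(ys) > grid_dims[2] ||
        max(zs) > grid_dims[3] || min(xs) < 1 || min(ys) < 1 || min(zs) < 1) {
      stop("region ", layout$region_id[r], " does not fit in the grid",
           call. = FALSE)
    }
    if (any(labels[xs, ys, zs] != 0L)) {
      stop("region ", layout$region_id[r], " overlaps another region",
           call. = FALSE)
    }
    labels[xs, ys, zs] <- as.integer(layout$region_id[r])
  }
  names_tbl <- layout[, c("region_id", "region_name")]
  if (!is.null(fill_region)) {
    labels[labels == 0L] <- as.integer(fill_region$region_id)
    names_tbl <- dplyr::bind_rows(
      names_tbl,
      tibble::tibble(region_id = as.integer(fill_region$region_id),
                     region_name = fill_region$region_name))
  }
  affine <- diag(c(rep(voxel_size, 3), 1))
  affine[1:3, 4] <- origin
  fc_atlas(labels, affine, names_tbl)
}

#' Site specification for the cohort simulator
#'
#' @param name Site label.
#' @param n_controls,n_patients Subjects per group.
#' @param noise_scale Amplitude multiplier applied to the whole BOLD signal
#'   of the site's scans (scanner gain); correlations are unaffected.
#' @param coupling_offset Additive site effect on the coupling parameter
#'   zeta of every injected effect (a site effect on FC itself).
#' @param all_medicated If TRUE every patient at the site is medicated
#'   (emulating a site where medication cannot be contrasted).
#' @return A `site_spec` list.
#' @export
site_spec <- function(name, n_controls, n_patients, noise_scale = 1,
                      coupling_offset = 0, all_medicated = FALSE) {
  stopifnot(n_controls >= 0, n_patients >= 0, noise_scale > 0)
  structure(list(name = as.character(name), n_controls = n_controls,
                 n_patients = n_patients, noise_scale = noise_scale,
                 coupling_offset = coupling_offset,
                 all_medicated = all_medicated),
            class = "site_spec")
}

#' Injected connectivity effect
#'
#' One seed-to-target coupling: between the seed region and `region_b`, the
#' expected voxel-pair correlation is `tanh(zeta)` with
#' `zeta = zeta_base + site coupling_offset + delta_z * [patient]
#'  + sum(beta_cov * standardized covariate) + subject noise`.
#' `delta_z` is therefore the patient-minus-control group difference on the
#' Fisher-z scale — the scale the pipeline tests on.
#'
#' @param region_b Target region id.
#' @param delta_z Signed Fisher-z group difference.
#' @param zeta_base Baseline coupling (control, covariates at their means).
#' @param region_a Seed-side region id; defaults to the configured seed.
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(region_b, delta_z, zeta_base = 0.2, region_a = NULL) {
  stopifnot(is.finite(delta_z), is.finite(zeta_base))
  structure(list(region_a = region_a, region_b = region_b,
                 delta_z = delta_z, zeta_base = zeta_base),
            class = "effect_spec")
}

#' Simulation configuration for a multi-site case-control cohort
#'
#' Defines the generative model for synthetic BOLD data. Each region `r`
#' carries a latent AR(1) Gaussian signal `u_r(t)` (unit variance,
#' autocorrelation `ar`); voxel `i` of region `r` observes
#' `x_i(t) = sqrt(c) u_r(t) + sqrt(1 - c) eps_i(t)` with white Gaussian
#' `eps` and within-region coherence `c = coherence`. For each
#' [effect_spec()] the target's latent is
#' `u_b = rho u_a + sqrt(1 - rho^2) v_b` with independent AR(1) `v_b`, so
#' `u_b` is again a unit-variance AR(1) process and the expected voxel-pair
#' correlation across the two regions is `c * rho`. Setting
#' `rho = tanh(zeta) / c` makes that expected correlation `tanh(zeta)`,
#' i.e. expected Fisher-z FC equal to `zeta` (up to the small finite-T bias
#' of the sample correlation). `|tanh(zeta)| >= c` is an error: the
#' requested coupling is infeasible at the given coherence.
#'
#' @param seed Master seed; drives phenotype draws and per-subject streams.
#' @param sites List of [site_spec()]s.
#' @param atlas An [fc_atlas()], e.g. from [make_toy_atlas()].
#' @param seed_region_id Region id of the seed ROI.
#' @param effects List of [effect_spec()]s (targets must be distinct).
#' @param n_timepoints Scan length (default 230, about 8 min at TR 2 s).
#' @param ar Temporal autocorrelation of the latents in `[0, 1)`.
#' @param coherence Within-region coherence `c` in `(0, 1]`.
#' @param covariate_betas Named numeric: slopes on zeta per standardized
#'   phenotype covariate (names must be phenotype columns).
#' @param subject_zeta_sd SD of the per-subject, per-effect coupling noise.
#' @return A `simulation_config`.
#' @export
simulation_config <- function(seed, sites, atlas, seed_region_id, effects = list(),
                              n_timepoints = 230L, ar = 0.4, coherence = 0.8,
                              covariate_betas = numeric(0),
                              subject_zeta_sd = 0.1) {
  if (n_timepoints < 30L) stop("n_timepoints must be >= 30", call. = FALSE)
  if (ar < 0 || ar >= 1) stop("ar must be in [0, 1)", call. = FALSE)
  if (coherence <= 0 || coherence > 1) stop("coherence in (0, 1]", call. = FALSE)
  if (inherits(sites, "site_spec")) sites <- list(sites)
  if (inherits(effects, "effect_spec")) effects <- list(effects)
  effects <- lapply(effects, function(e) {
    if (is.null(e$region_a)) e$region_a <- seed_region_id
    e
  })
  tgt <- vapply(effects, function(e) e$region_b, numeric(1))
  if (anyDuplicated(tgt)) {
    stop("each region may be the target of at most one effect", call. = FALSE)
  }
  if (any(vapply(effects, function(e) e$region_a == e$region_b, logical(1)))) {
    stop("an effect cannot couple a region to itself", call. = FALSE)
  }
  for (e in effects) {
    for (rid in c(e$region_a, e$region_b)) {
      if (!rid %in% atlas$region_names$region_id) {
        stop("effect references unknown region ", rid, call. = FALSE)
      }
    }
  }
  if (length(voxel_indices(atlas, seed_region_id)) < 2L) {
    stop("seed region needs >= 2 voxels", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), sites = sites, atlas = atlas,
                 seed_region_id = seed_region_id, effects = effects,
                 n_timepoints = as.integer(n_timepoints), ar = ar,
                 coherence = coherence, covariate_betas = covariate_betas,
                 subject_zeta_sd = subject_zeta_sd),
            class = "simulation_config")
}

# stationary AR(1), unit variance: x_t = phi x_{t-1} + sqrt(1-phi^2) e_t
ar1_series <- function(n, phi) {
  e <- stats::rnorm(n)
  if (phi == 0) return(e)
  as.numeric(stats::filter(c(e[1], sqrt(1 - phi^2) * e[-1]), phi,
                           method = "recursive"))
}

# zeta -> inter-latent correlation rho; infeasible couplings error out
zeta_to_rho <- function(zeta, coherence) {
  rho <- tanh(zeta) / coherence
  if (any(abs(rho) >= 1)) {
    stop("requested coupling tanh(zeta) = ", signif(max(abs(tanh(zeta))), 4),
         " is not achievable at coherence ", coherence, call. = FALSE)
  }
  rho
}

# per-subject coupling parameters zeta for every effect, given phenotype row
subject_zetas <- function(config, phenotype_row, cov_center, cov_scale,
                          noise = NULL) {
  site_of <- vapply(config$sites, function(s) s$name, character(1))
  sp <- config$sites[[match(phenotype_row$site, site_of)]]
  shift <- 0
  betas <- config$covariate_betas
  for (nm in names(betas)) {
    v <- phenotype_row[[nm]]
    vstd <- if (is.na(v)) 0 else (v - cov_center[[nm]]) / cov_scale[[nm]]
    shift <- shift + betas[[nm]] * vstd
  }
  vapply(seq_along(config$effects), function(k) {
    e <- config$effects[[k]]
    e$zeta_base + sp$coupling_offset +
      e$delta_z * (phenotype_row$group == "patient") + shift +
      (if (is.null(noise)) 0 else noise[k])
  }, numeric(1))
}

#' Generate one subject's BOLD scan
#'
#' Draws the region latents and voxel noise for one subject under the
#' generative model of [simulation_config()] and returns the masked
#' voxel-by-time scan. The realized coupling parameters are attached as
#' attribute `"zeta"` (one per effect).
#'
#' @param config A [simulation_config()].
#' @param phenotype_row One-row phenotype tibble for the subject.
#' @param seed Integer seed for this subject's private RNG stream.
#' @param cov_center,cov_scale Named centering/scaling constants for the
#'   covariates entering zeta (as computed cohort-wide by
#'   [generate_cohort()]); defaults standardize nothing.
#' @return A [subject_scan()].
#' @export
generate_subject <- function(config, phenotype_row, seed,
                             cov_center = NULL, cov_scale = NULL) {
  if (is.null(cov_center)) {
    cov_center <- stats::setNames(
      rep(0, length(config$covariate_betas)), names(config$covariate_betas))
    cov_scale <- stats::setNames(
      rep(1, length(config$covariate_betas)), names(config$covariate_betas))
  }
  atlas <- config$atlas
  nt <- config$n_timepoints
  withr::local_seed(seed)
  noise <- stats::rnorm(length(config$effects), 0, config$subject_zeta_sd)
  zetas <- subject_zetas(config, phenotype_row, cov_center, cov_scale, noise)
  rho <- if (length(zetas)) zeta_to_rho(zetas, config$coherence) else numeric(0)

  region_ids <- atlas$region_names$region_id
  latents <- matrix(NA_real_, length(region_ids), nt)
  rownames(latents) <- as.character(region_ids)
  a_of <- vapply(config$effects, function(e) e$region_a, numeric(1))
  b_of <- vapply(config$effects, function(e) e$region_b, numeric(1))
  # independent AR(1) latents first (fixed region order for determinism),
  # then effect targets rebuilt as correlated mixtures of the seed latent
  for (rid in region_ids) {
    latents[as.character(rid), ] <- ar1_series(nt, config$ar)
  }
  for (k in seq_along(config$effects)) {
    ua <- latents[as.character(a_of[k]), ]
    vb <- ar1_series(nt, config$ar)
    latents[as.character(b_of[k]), ] <- rho[k] * ua + sqrt(1 - rho[k]^2) * vb
  }

  site_of <- vapply(config$sites, function(s) s$name, character(1))
  amp <- config$sites[[match(phenotype_row$site, site_of)]]$noise_scale
  cc <- config$coherence
  nv <- n_brain_voxels(atlas)
  eps <- matrix(stats::rnorm(nv * nt), nv, nt)
  data <- amp * (sqrt(cc) * latents[as.character(atlas$mask_labels), , drop = FALSE] +
                   sqrt(1 - cc) * eps)
  scan <- subject_scan(data, phenotype_row$subject_id)
  attr(scan, "zeta") <- zetas
  scan
}

generate_phenotypes <- function(config) {
  rows <- list()
  for (sp in config$sites) {
    n <- sp$n_controls + sp$n_patients
    grp <- rep(c("control", "patient"), c(sp$n_controls, sp$n_patients))
    is_pat <- grp == "patient"
    medicated <- ifelse(is_pat,
                        if (sp$all_medicated) 1L else stats::rbinom(n, 1, 0.5),
                        NA_integer_)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      subject_id = sprintf("%s_%03d", sp$name, seq_len(n)),
      site = sp$name,
      group = grp,
      age = stats::runif(n, 18, 60),
      sex = stats::rbinom(n, 1, 0.5),
      education = stats::runif(n, 6, 20),
      mean_fd = stats::rlnorm(n, log(0.15), 0.35),
      medicated = medicated,
      hamd = ifelse(is_pat, pmax(round(stats::rnorm(n, 22, 4)), 8),
                    pmax(round(stats::rnorm(n, 2, 1.5)), 0)),
      bdi = ifelse(is_pat, pmax(round(stats::rnorm(n, 25, 6)), 5),
                   pmax(round(stats::rnorm(n, 3, 2)), 0)),
      illness_duration = ifelse(is_pat, round(stats::rlnorm(n, log(24), 0.8)),
                                NA_real_)
    )
  }
  dplyr::bind_rows(rows)
}

#' Generate a full multi-site cohort with ground truth
#'
#' Draws phenotypes, then one scan per subject from a private RNG stream
#' derived from the master seed, so the cohort is bit-reproducible and each
#' subject's scan is independent of the others' generation order. Covariate
#' slopes on the coupling act on cohort-standardized covariate values
#' (missing values, e.g. medication for controls, enter at the mean).
#'
#' @param config A [simulation_config()].
#' @return List with `atlas`, `scans` (list of [subject_scan()]),
#'   `phenotypes` (tibble) and `ground_truth` (see details). `ground_truth`
#'   holds `expected_fc` — per effect, site and group the expected Fisher-z
#'   FC at covariate means — and `subject_zeta`, the realized per-subject
#'   coupling parameters.
#' @export
generate_cohort <- function(config) {
  withr::local_seed(config$seed)
  ph <- generate_phenotypes(config)
  subj_seeds <- sample.int(.Machine$integer.max - 1L, nrow(ph))
  betas <- config$covariate_betas
  cov_center <- list(); cov_scale <- list()
  for (nm in names(betas)) {
    v <- ph[[nm]]
    cov_center[[nm]] <- mean(v, na.rm = TRUE)
    s <- stats::sd(v, na.rm = TRUE)
    cov_scale[[nm]] <- if (is.na(s) || s == 0) 1 else s
  }
  scans <- vector("list", nrow(ph))
  zt <- vector("list", nrow(ph))
  for (k in seq_len(nrow(ph))) {
    scan <- generate_subject(config, ph[k, ], subj_seeds[k],
                             cov_center, cov_scale)
    zt[[k]] <- attr(scan, "zeta")
    attr(scan, "zeta") <- NULL
    scans[[k]] <- scan
  }
  effects_tbl <- purrr::map_dfr(config$effects, function(e) {
    tibble::tibble(region_a = e$region_a, region_b = e$region_b,
                   delta_z = e$delta_z, zeta_base = e$zeta_base)
  })
  expected <- purrr::map_dfr(config$sites, function(sp) {
    purrr::map_dfr(config$effects, function(e) {
      tibble::tibble(
        site = sp$name, region_a = e$region_a, region_b = e$region_b,
        expected_z_control = e$zeta_base + sp$coupling_offset,
        expected_z_patient = e$zeta_base + sp$coupling_offset + e$delta_z)
    })
  })
  subject_zeta <- if (length(config$effects)) {
    purrr::map_dfr(seq_len(nrow(ph)), function(k) {
      tibble::tibble(subject_id = ph$subject_id[k],
                     region_a = effects_tbl$region_a,
                     region_b = effects_tbl$region_b,
                     zeta = zt[[k]])
    })
  } else {
    tibble::tibble(subject_id = character(), region_a = numeric(),
                   region_b = numeric(), zeta = numeric())
  }
  list(atlas = config$atlas, scans = scans, phenotypes = ph,
       ground_truth = list(effects = effects_tbl, expected_fc = expected,
                           subject_zeta = subject_zeta))
}

#' Which pairs carry a true group difference
#'
#' Flags every enumerated voxel pair joining the two regions of an injected
#' effect with nonzero `delta_z` — the ground-truth non-null set used to
#' score false discoveries.
#'
#' @param config The [simulation_config()] that generated the cohort.
#' @param pairs A [enumerate_pairs()] index on the same atlas.
#' @return Logical vector over pairs.
#' @export
true_effect_pairs <- function(config, pairs) {
  atlas <- config$atlas
  out <- logical(nrow(pairs))
  for (e in config$effects) {
    if (e$delta_z == 0) next
    va <- voxel_indices(atlas, e$region_a)
    vb <- voxel_indices(atlas, e$region_b)
    out <- out |
      (pairs[, 1] %in% va & pairs[, 2] %in% vb) |
      (pairs[, 1] %in% vb & pairs[, 2] %in% va)
  }
  out
}

#' Default two-site demonstration atlas and configuration
#'
#' A 10x10x10 grid (1000 brain voxels) with a 27-voxel seed region
#' ("PCC-like"), two targets with elevated patient coupling ("lOFC-like",
#' "IFG-like"), one with reduced patient coupling ("ACC-like"), and the
#' remaining voxels as background brain. Two sites emulate the study's
#' structure: both case-control, the second with a site-level coupling
#' offset, amplitude difference, and optionally all patients medicated.
#'
#' @param seed Master seed.
#' @param n_controls,n_patients Per-site group sizes.
#' @param n_timepoints Scan length.
#' @param delta_z Fisher-z effect for the elevated targets (the reduced
#'   target gets `-delta_z`; set 0 for a global null).
#' @param single_effect If TRUE only the "lOFC-like" target carries an
#'   effect (used for false-discovery scoring with one non-null block).
#' @param covariate_betas Passed through to [simulation_config()].
#' @param coherence,ar,subject_zeta_sd Passed through.
#' @param site2_all_medicated All patients medicated at site 2.
#' @return A [simulation_config()].
#' @export
demo_config <- function(seed, n_controls = 20, n_patients = 20,
                        n_timepoints = 120L, delta_z = 0.25,
                        single_effect = FALSE,
                        covariate_betas = numeric(0), coherence = 0.8,
                        ar = 0.4, subject_zeta_sd = 0.1,
                        site2_all_medicated = FALSE) {
  layout <- tibble::tribble(
    ~region_id, ~region_name, ~x0, ~y0, ~z0, ~dx, ~dy, ~dz,
    1L, "PCC-like",  2L, 2L, 2L, 3L, 3L, 3L,
    2L, "lOFC-like", 7L, 2L, 2L, 3L, 3L, 3L,
    3L, "IFG-like",  2L, 7L, 2L, 3L, 3L, 3L,
    4L, "ACC-like",  7L, 7L, 2L, 3L, 3L, 3L)
  atlas <- make_toy_atlas(c(10L, 10L, 10L), layout,
                          fill_region = list(region_id = 5L,
                                             region_name = "Other-brain"))
  effects <- list(effect_spec(2L, delta_z))
  if (!single_effect) {
    effects <- c(effects, list(effect_spec(3L, delta_z),
                               effect_spec(4L, -delta_z)))
  }
  sites <- list(
    site_spec("siteA", n_controls, n_patients),
    site_spec("siteB", n_controls, n_patients, noise_scale = 1.15,
              coupling_offset = 0.03, all_medicated = site2_all_medicated))
  simulation_config(seed = seed, sites = sites, atlas = atlas,
                    seed_region_id = 1L, effects = effects,
                    n_timepoints = n_timepoints, ar = ar,
                    coherence = coherence, covariate_betas = covariate_betas,
                    subject_zeta_sd = subject_zeta_sd)
}
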