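test_that("make_toy_atlas lays out cuboid regions and rejects overlap", {
  g <- expand.grid(x0 = c(1, 5, 9), y0 = c(1, 5), z0 = 1)
  layout <- tibble::tibble(region_id = 1:6,
                           region_name = sprintf("r%d", 1:6),
                           x0 = g$x0, y0 = g$y0, z0 = g$z0,
                           dx = 3L, dy = 3L, dz = 3L)
  atl <- make_toy_atlas(c(12L, 12L, 12L), layout)
  expect_equal(nrow(atl$region_names), 6)
  for (rid in 1:6) expect_length(voxel_indices(atl, rid), 27)
  expect_equal(n_brain_voxels(atl), 6 * 27)

  bad <- layout; bad$x0[2] <- 2  # collides with region 1
  expect_error(make_toy_atlas(c(12L, 12L, 12L), bad), "overlaps")
  off <- layout; off$x0[3] <- 11
  expect_error(make_toy_atlas(c(12L, 12L, 12L), off), "does not fit")

  single <- tibble::tibble(region_id = 1L, region_name = "dot",
                           x0 = 2L, y0 = 2L, z0 = 2L, dx = 1L, dy = 1L, dz = 1L)
  atl1 <- make_toy_atlas(c(4L, 4L, 4L), single)
  expect_length(voxel_indices(atl1, 1L), 1)

  filled <- make_toy_atlas(c(4L, 4L, 4L), single,
                           fill_region = list(region_id = 9L,
                                              region_name = "rest"))
  expect_equal(n_brain_voxels(filled), 64)
  expect_length(voxel_indices(filled, 9L), 63)
})

test_that("identical seeds give bit-identical cohorts, regardless of call site", {
  cfg <- demo_config(seed = 123, n_controls = 3, n_patients = 3,
                     n_timepoints = 40L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(lapply(a$scans, `[[`, "data"),
                   lapply(b$scans, `[[`, "data"))
  expect_identical(a$ground_truth, b$ground_truth)
  # different seed, different data
  c2 <- generate_cohort(demo_config(seed = 124, n_controls = 3,
                                    n_patients = 3, n_timepoints = 40L))
  expect_false(identical(a$scans[[1]]$data, c2$scans[[1]]$data))
})

test_that("cohort size and phenotype schema follow the site specs", {
  cfg <- demo_config(seed = 5, n_controls = 20, n_patients = 20,
                     n_timepoints = 40L, site2_all_medicated = TRUE)
  cohort <- generate_cohort(cfg)
  expect_length(cohort$scans, 80)
  expect_equal(nrow(cohort$phenotypes), 80)
  expect_silent(validate_phenotypes(cohort$phenotypes))
  ph <- cohort$phenotypes
  expect_equal(unname(table(ph$site)), c(40L, 40L), ignore_attr = TRUE)
  expect_true(all(is.na(ph$medicated[ph$group == "control"])))
  expect_true(all(ph$medicated[ph$group == "patient" & ph$site == "siteB"] == 1))
  expect_true(all(is.na(ph$illness_duration[ph$group == "control"])))
  expect_true(all(ph$age >= 18 & ph$age <= 60))
  expect_true(all(ph$mean_fd > 0))
})

test_that("a null configuration injects no group difference", {
  cfg <- demo_config(seed = 77, n_controls = 4, n_patients = 4,
                     n_timepoints = 40L, delta_z = 0)
  gt <- generate_cohort(cfg)$ground_truth
  expect_true(all(gt$expected_fc$expected_z_control ==
                    gt$expected_fc$expected_z_patient))
})

test_that("infeasible couplings (|rho| >= 1) are rejected", {
  layout <- tibble::tibble(region_id = 1:2, region_name = c("a", "b"),
                           x0 = c(1L, 4L), y0 = 1L, z0 = 1L,
                           dx = 2L, dy = 2L, dz = 1L)
  atl <- make_toy_atlas(c(6L, 2L, 1L), layout)
  cfg <- simulation_config(seed = 1, sites = list(site_spec("s", 1, 1)),
                           atlas = atl, seed_region_id = 1L,
                           effects = list(effect_spec(2L, delta_z = 0,
                                                      zeta_base = atanh(0.95))),
                           n_timepoints = 40L, coherence = 0.5,
                           subject_zeta_sd = 0)
  row <- toy_phenotypes(1, site = "s")[1, ]
  expect_error(generate_subject(cfg, row, seed = 1),
               "not achievable at coherence")
})

test_that("near-perfect coupling at full coherence drives sample r toward 1", {
  layout <- tibble::tibble(region_id = 1:2, region_name = c("a", "b"),
                           x0 = c(1L, 4L), y0 = 1L, z0 = 1L,
                           dx = 2L, dy = 2L, dz = 1L)
  atl <- make_toy_atlas(c(6L, 2L, 1L), layout)
  rho <- 0.9999
  cfg <- simulation_config(seed = 2, sites = list(site_spec("s", 1, 0)),
                           atlas = atl, seed_region_id = 1L,
                           effects = list(effect_spec(2L, delta_z = 0,
                                                      zeta_base = atanh(rho))),
                           n_timepoints = 2000L, ar = 0, coherence = 1,
                           subject_zeta_sd = 0)
  cohort <- generate_cohort(cfg)
  x <- cohort$scans[[1]]$data
  r <- cor(x[voxel_indices(atl, 1L)[1], ], x[voxel_indices(atl, 2L)[1], ])
  expect_gt(r, 0.999)
})

test_that("the injected Fisher-z group difference is realized in sample FC", {
  # Monte-Carlo oracle for the coupling construction: zeta_base = 0.2,
  # delta_z = 0.15 should appear as the patient-minus-control mean of
  # sample Fisher-z FC across many subjects
  layout <- tibble::tibble(region_id = 1:2, region_name = c("a", "b"),
                           x0 = c(1L, 4L), y0 = 1L, z0 = 1L,
                           dx = 2L, dy = 2L, dz = 1L)
  atl <- make_toy_atlas(c(6L, 2L, 1L), layout)
  delta <- 0.15
  cfg <- simulation_config(
    seed = 31, sites = list(site_spec("s", 200, 200)), atlas = atl,
    seed_region_id = 1L,
    effects = list(effect_spec(2L, delta_z = delta, zeta_base = 0.2)),
    n_timepoints = 200L, ar = 0, coherence = 0.8, subject_zeta_sd = 0.05)
  cohort <- generate_cohort(cfg)
  pairs <- enumerate_pairs(atl, 1L)
  store <- compute_fc_store(cohort$scans, pairs)
  cross <- pairs[, 2] %in% voxel_indices(atl, 2L)
  mz <- rowMeans(store$z[, cross])
  pat <- cohort$phenotypes$group == "patient"
  est <- mean(mz[pat]) - mean(mz[!pat])
  # Monte-Carlo SE of the group difference of per-subject means
  se <- sqrt(var(mz[pat]) / sum(pat) + var(mz[!pat]) / sum(!pat))
  expect_lt(abs(est - delta), 3 * se)
  # and the per-site expected values in the ground truth agree
  gt <- cohort$ground_truth$expected_fc
  expect_equal(gt$expected_z_patient - gt$expected_z_control, delta)
  # realized per-subject couplings average to the group expectations
  sz <- dplyr::left_join(cohort$ground_truth$subject_zeta,
                         cohort$phenotypes[, c("subject_id", "group")],
                         by = "subject_id")
  mean_zeta <- tapply(sz$zeta, sz$group, mean)
  expect_lt(abs((mean_zeta[["patient"]] - mean_zeta[["control"]]) - delta),
            3 * 0.05 * sqrt(2 / 200))
})

test_that("latent temporal autocorrelation matches the configured AR(1) coefficient", {
  layout <- tibble::tibble(region_id = 1L, region_name = "a",
                           x0 = 1L, y0 = 1L, z0 = 1L, dx = 2L, dy = 1L, dz = 1L)
  atl <- make_toy_atlas(c(2L, 1L, 1L), layout)
  for (phi in c(0, 0.4, 0.7)) {
    cfg <- simulation_config(seed = 40 + round(10 * phi),
                             sites = list(site_spec("s", 1, 0)), atlas = atl,
                             seed_region_id = 1L, n_timepoints = 4000L,
                             ar = phi, coherence = 1)
    cohort <- generate_cohort(cfg)
    u <- cohort$scans[[1]]$data[1, ]  # coherence 1: the voxel IS the latent
    a1 <- acf(u, plot = FALSE, lag.max = 1)$acf[2]
    expect_lt(abs(a1 - phi), 3 / sqrt(4000))
  }
})

test_that("true_effect_pairs flags exactly the seed-target block", {
  cfg <- demo_config(seed = 1, single_effect = TRUE)
  pairs <- enumerate_pairs(cfg$atlas, 1L)
  truth <- true_effect_pairs(cfg, pairs)
  va <- voxel_indices(cfg$atlas, 1L)
  vb <- voxel_indices(cfg$atlas, 2L)
  expect_equal(sum(truth), length(va) * length(vb))
  expect_true(all(pairs[truth, 2] %in% vb))
  null_cfg <- demo_config(seed = 1, delta_z = 0)
  expect_equal(sum(true_effect_pairs(null_cfg, pairs)), 0)
})
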