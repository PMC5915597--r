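# small helper: a hand-built store with iid normal z for n subjects x m pairs
null_store <- function(n, pairs, seed, sd = 1) {
  withr::local_seed(seed)
  manual_store(matrix(rnorm(n * nrow(pairs), sd = sd), n), pairs)
}

test_that("with no covariates the link test equals the pooled-variance two-sample t", {
  atl <- tiny_atlas()
  pairs <- enumerate_pairs(atl, 1L)
  ph <- toy_phenotypes(8)
  store <- null_store(16, pairs, seed = 21)
  rownames(store$z) <- store$subjects <- ph$subject_id
  stats <- site_link_test(store, ph, "siteA", covariates = character(0))
  grp <- ph$group == "patient"
  for (k in c(1, 5, nrow(pairs))) {
    tt <- t.test(store$z[grp, k], store$z[!grp, k], var.equal = TRUE)
    expect_equal(stats$t[k], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(stats$p[k], tt$p.value, tolerance = 1e-12)
    expect_equal(stats$estimate[k], unname(diff(rev(tt$estimate))),
                 tolerance = 1e-12)
  }
})

test_that("under a permuted-null cohort the link-test p-values are uniform", {
  atl <- tiny_atlas()
  pairs <- enumerate_pairs(atl, 1L)
  ph <- toy_phenotypes(10, seed = 4)
  withr::local_seed(8)
  ph$group <- sample(ph$group)  # break any group structure
  store <- null_store(20, pairs, seed = 22)
  rownames(store$z) <- store$subjects <- ph$subject_id
  stats <- site_link_test(store, ph, "siteA")
  ks <- suppressWarnings(ks.test(stats$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("degenerate designs are rejected; constant covariates are dropped", {
  atl <- tiny_atlas()
  pairs <- enumerate_pairs(atl, 1L)
  ph <- toy_phenotypes(5)
  store <- null_store(10, pairs, seed = 23)
  rownames(store$z) <- store$subjects <- ph$subject_id
  # covariate perfectly collinear with the group indicator
  ph$age <- ifelse(ph$group == "patient", 50, 30)
  expect_error(site_link_test(store, ph, "siteA", covariates = "age"),
               "rank-deficient")
  ph$education <- 12
  expect_message(
    out <- site_link_test(store, ph, "siteA", covariates = "education"),
    "constant and was dropped")
  no_cov <- site_link_test(store, ph, "siteA", covariates = character(0))
  expect_equal(out$t, no_cov$t)
  # a group missing from the site
  ph2 <- toy_phenotypes(3)
  ph2$group <- "control"
  expect_error(site_link_test(store, ph2, "siteA"), ">= 2 subjects")
})

test_that("signed z conversion: sign carried, p = 1 maps to 0, floor keeps z finite", {
  expect_equal(p_to_signed_z(1, 3.2), 0)
  expect_equal(p_to_signed_z(1, -3.2), 0)
  expect_equal(round(p_to_signed_z(0.05, 2), 5), 1.95996)
  expect_equal(round(p_to_signed_z(0.05, -2), 5), -1.95996)
  expect_equal(p_to_signed_z(0.05, 2), -p_to_signed_z(0.05, -2))
  expect_true(is.finite(p_to_signed_z(1e-320, 1)))
  expect_error(p_to_signed_z(0, 1), "0, 1")
  expect_error(p_to_signed_z(1.2, 1), "0, 1")
})

test_that("Liptak-Stouffer combination: identity, closed form, cancellation, NA policy", {
  # single site returns its z for any weight
  one <- liptak_combine(matrix(c(1.7, -0.3), 2, 1), weights = 5)
  expect_equal(one$Z, c(1.7, -0.3))
  # z' = (2, 1), n = (100, 400): Z = (10*2 + 20*1)/sqrt(500)
  two <- liptak_combine(matrix(c(2, 1), 1, 2), weights = c(10, 20))
  expect_equal(two$Z, 40 / sqrt(500))
  expect_equal(round(two$Z, 5), 1.78885)
  expect_equal(two$p, 2 * pnorm(-40 / sqrt(500)))
  # opposite signs, equal weights cancel
  expect_equal(liptak_combine(matrix(c(2.4, -2.4), 1, 2),
                              weights = c(3, 3))$Z, 0)
  # a missing site drops out of numerator and denominator
  na_case <- liptak_combine(matrix(c(2, NA), 1, 2), weights = c(10, 20))
  expect_equal(na_case$Z, 2)
  all_na <- liptak_combine(matrix(NA_real_, 1, 2), weights = c(1, 1))
  expect_true(is.na(all_na$Z))
  expect_error(liptak_combine(matrix(1, 1, 2), weights = 1), "one positive weight")
})

test_that("the combined Z is strictly increasing in every site's z-score", {
  withr::local_seed(31)
  for (rep in 1:50) {
    z <- rnorm(3)
    w <- runif(3, 0.5, 3)
    k <- sample(3, 1)
    z_up <- z; z_up[k] <- z_up[k] + runif(1, 0.1, 2)
    Z0 <- liptak_combine(matrix(z, 1), weights = w)$Z
    Z1 <- liptak_combine(matrix(z_up, 1), weights = w)$Z
    expect_gt(Z1, Z0)
  }
  # in particular a same-sign site at least as strong as the current
  # combination reinforces it
  for (rep in 1:50) {
    z2 <- abs(rnorm(2))
    Z2 <- liptak_combine(matrix(z2, 1), weights = c(1, 1))$Z
    z3 <- c(z2, Z2 + abs(rnorm(1)))
    Z3 <- liptak_combine(matrix(z3, 1), weights = c(1, 1, 1))$Z
    expect_gte(abs(Z3), abs(Z2))
  }
})

test_that("BH step-up matches its definition oracle and handles edge cases", {
  got <- bh_fdr(c(0.001, 0.01, 0.02, 0.04, 0.2), q = 0.05)
  expect_equal(got$mask, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(got$threshold, 0.04)
  expect_equal(bh_fdr(rep(1, 10), 0.05)$mask, rep(FALSE, 10))
  expect_equal(bh_fdr(rep(1, 10), 0.05)$threshold, 0)
  expect_true(bh_fdr(0.04, 0.05)$mask)
  withr::local_seed(32)
  for (rep in 1:20) {
    p <- c(runif(60)^2, rep(NA, 3))
    q <- runif(1, 0.01, 0.2)
    got <- bh_fdr(p, q)
    ora <- oracle_bh(p[!is.na(p)], q)
    expect_equal(got$mask[!is.na(p)], ora$mask)
    expect_equal(got$threshold, ora$threshold)
    expect_false(any(got$mask[is.na(p)]))
  }
  expect_error(bh_fdr(rep(NA_real_, 3), 0.05), "no finite")
  expect_error(bh_fdr(0.5, 1.5), "q must be")
})

test_that("MA and signed voxel summaries match brute force on random masks", {
  atl <- tiny_atlas()
  pairs <- enumerate_pairs(atl, 1L)
  nv <- n_brain_voxels(atl)
  expect_equal(ma_score(rep(FALSE, nrow(pairs)), pairs), rep(0L, nv))
  withr::local_seed(33)
  for (rep in 1:10) {
    mask <- runif(nrow(pairs)) < 0.25
    Z <- rnorm(nrow(pairs))
    expect_equal(ma_score(mask, pairs), oracle_ma(mask, pairs, nv))
    got <- voxel_signed_summary(Z, mask, pairs)
    ora <- oracle_signed(Z, mask, pairs, nv)
    expect_equal(got$s, ora$s, tolerance = 1e-12)
    expect_equal(got$sign, ora$sign)
  }
  # three significant links at one voxel count 3; |Z| sums with net sign
  v <- voxel_indices(atl, 1L)[1]
  inc <- which(pairs[, 1] == v)[1:3]
  mask <- rep(FALSE, nrow(pairs)); mask[inc] <- TRUE
  Z <- rep(0, nrow(pairs)); Z[inc] <- c(3, -2, 0.5)
  expect_equal(ma_score(mask, pairs)[v], 3L)
  got <- voxel_signed_summary(Z, mask, pairs)
  expect_equal(got$s[v], 5.5)
  expect_equal(got$sign[v], 1)
})

test_that("cluster-extent filtering keeps only components larger than the minimum", {
  labels <- array(1L, c(12, 12, 3))
  atl <- fc_atlas(labels, diag(4),
                  data.frame(region_id = 1L, region_name = "brain"))
  pairs <- enumerate_pairs(atl, 1L)  # whole volume is the "ROI"

  # a single isolated significant voxel is removed at min 20
  v_iso <- world_to_voxel(atl, cbind(11, 11, 2))
  mask <- pairs[, 1] == v_iso | pairs[, 2] == v_iso
  partner_far <- world_to_voxel(atl, cbind(0, 0, 0))
  mask <- mask & (pairs[, 1] == partner_far | pairs[, 2] == partner_far)
  expect_true(sum(mask) == 1)
  expect_equal(sum(cluster_filter(mask, pairs, atl, 20)), 0)

  # a 27-voxel cuboid survives min 20 (paired against one far voxel the
  # filter removes as its own singleton component -> links die with it)
  cub <- as.matrix(expand.grid(x = 3:5, y = 3:5, z = 0:2))
  cub_vox <- world_to_voxel(atl, cub)
  mask27 <- (pairs[, 1] %in% cub_vox & pairs[, 2] %in% cub_vox)
  expect_gt(sum(mask27), 0)
  kept <- cluster_filter(mask27, pairs, atl, 20)
  expect_equal(kept, mask27)
})

test_that("of two components (15 and 25 voxels) only the larger survives min 20", {
  labels <- array(1L, c(20, 6, 3))
  atl <- fc_atlas(labels, diag(4),
                  data.frame(region_id = 1L, region_name = "brain"))
  pairs <- enumerate_pairs(atl, 1L)
  blob15 <- world_to_voxel(atl, as.matrix(expand.grid(x = 0:4, y = 0:2, z = 0)))
  blob25 <- world_to_voxel(atl, as.matrix(expand.grid(x = 14:18, y = 0:4, z = 0)))
  mask <- (pairs[, 1] %in% blob15 & pairs[, 2] %in% blob15) |
    (pairs[, 1] %in% blob25 & pairs[, 2] %in% blob25)
  got <- cluster_filter(mask, pairs, atl, 20)
  expect_identical(got, oracle_cluster_filter(mask, pairs, atl, 20))
  kept_vox <- unique(c(pairs[got, 1], pairs[got, 2]))
  expect_setequal(kept_vox, blob25)
})

test_that("cluster filtering equals the flood-fill oracle on random masks", {
  atl <- tiny_atlas()
  pairs <- enumerate_pairs(atl, 1L)
  withr::local_seed(34)
  for (rep in 1:8) {
    mask <- runif(nrow(pairs)) < 0.1
    for (mv in c(1, 3, 6)) {
      expect_identical(cluster_filter(mask, pairs, atl, mv),
                       oracle_cluster_filter(mask, pairs, atl, mv))
    }
  }
})

test_that("region cluster table: suppression boundary and brute-force sum of |Z|", {
  labels <- array(1L, c(15, 5, 3))
  labels[1:2, 1:2, 1] <- 2L
  atl <- fc_atlas(labels, diag(4),
                  data.frame(region_id = 1:2, region_name = c("far", "seed")))
  pairs <- enumerate_pairs(atl, 2L)
  # an 11-voxel blob and a 10-voxel blob, both far from the 4-voxel seed
  blob11 <- world_to_voxel(atl, as.matrix(expand.grid(x = 8:10, y = 0:3, z = 0))[1:11, ])
  blob10 <- world_to_voxel(atl, as.matrix(expand.grid(x = 13:14, y = 0:4, z = 2)))
  withr::local_seed(35)
  Z <- rnorm(nrow(pairs), 0, 2)
  mask <- (pairs[, 2] %in% c(blob11, blob10))
  tab <- region_cluster_table(mask, Z, atl, pairs, min_cluster_voxels = 10L)
  # the 10-voxel component is suppressed ("more than 10"), the seed (4 voxels) too
  expect_equal(nrow(tab), 1)
  expect_equal(tab$n_voxels, 11)
  expect_equal(tab$regions, "far")
  sig <- which(mask)
  in11 <- pairs[sig, 2] %in% blob11
  expect_equal(tab$sum_abs_z, sum(abs(Z[sig][in11])), tolerance = 1e-12)
  # peak voxel = maximal per-voxel sum of |Z| inside the component
  sv <- voxel_signed_summary(Z, mask, pairs)
  peak <- blob11[which.max(sv$s[blob11])]
  expect_equal(unname(c(tab$peak_x, tab$peak_y, tab$peak_z)),
               as.numeric(voxel_to_world(atl, peak)))
  # at min 9 both blobs are reported
  tab9 <- region_cluster_table(mask, Z, atl, pairs, min_cluster_voxels = 9L)
  expect_equal(sort(tab9$n_voxels), c(10, 11))
})

test_that("threshold modes parse, print and validate", {
  expect_equal(parse_threshold_mode("fdr:0.05")$q, 0.05)
  expect_equal(parse_threshold_mode("unc:1e-4")$alpha, 1e-4)
  m <- parse_threshold_mode("unc-cluster:1e-3:20")
  expect_equal(m$alpha, 1e-3)
  expect_equal(m$min_cluster_voxels, 20L)
  expect_equal(format(m), "unc-cluster:0.001:20")
  expect_error(parse_threshold_mode("bonferroni:0.05"), "unknown threshold mode")
  expect_error(threshold_mode("fdr", q = 1.2), "q in")
})

test_that("associate combines sites and modes coherently on a constructed cohort", {
  atl <- tiny_atlas()
  pairs <- enumerate_pairs(atl, 1L)
  phA <- toy_phenotypes(10, site = "siteA", seed = 41)
  phB <- toy_phenotypes(10, site = "siteB", seed = 42)
  ph <- dplyr::bind_rows(phA, phB)
  withr::local_seed(43)
  z <- matrix(rnorm(40 * nrow(pairs), sd = 0.3), 40)
  # inject a patient shift on all seed-target links
  tgt <- which(pairs[, 2] %in% voxel_indices(atl, 2L))
  z[ph$group == "patient", tgt] <- z[ph$group == "patient", tgt] + 0.6
  store <- manual_store(z, pairs, ph$subject_id)
  res <- associate(store, ph, atl, mode = "fdr:0.05",
                   min_table_cluster_voxels = 2L)
  expect_setequal(res$sites, c("siteA", "siteB"))
  expect_true(all(tgt %in% which(res$links$significant)))
  expect_true("target" %in% unlist(strsplit(res$clusters$regions, ", ")))
  # Z really is the weighted combination of the per-site signed scores
  zs <- sapply(res$site_stats, function(s) s$z[tgt[1]])
  w <- sapply(res$site_stats, attr, "n")
  expect_equal(res$links$Z[tgt[1]],
               sum(sqrt(w) * zs) / sqrt(sum(w)), tolerance = 1e-12)
  # uncorrected mode at the attained FDR cutoff rejects a superset
  res_unc <- associate(store, ph, atl,
                       mode = threshold_mode("unc", alpha = 0.05))
  expect_true(all(res$links$significant <= res_unc$links$significant))
  g <- glance(res)
  expect_equal(g$n_pairs, nrow(pairs))
  expect_equal(g$n_significant, sum(res$links$significant))
  td <- tidy(res)
  expect_equal(nrow(td), nrow(pairs))
})
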