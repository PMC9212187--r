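# Synthetic cohort generators: reproducibility, calibration, and the
# planted connectivity contrast.

test_that("feature cohorts are bit-reproducible and sized as specified", {
  a <- generate_feature_cohort(seed = 5)
  b <- generate_feature_cohort(seed = 5)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(ground_truth(a), ground_truth(b))
  expect_equal(sum(a$group == 0), 72) # default two-arm cohort sizes
  expect_equal(sum(a$group == 1), 68)
  c <- generate_feature_cohort(seed = 6)
  expect_false(identical(feature_matrix(a), feature_matrix(c)))
})

test_that("null cohorts are calibrated: ~5% of Welch tests reject at 0.05", {
  tab <- generate_feature_cohort(n_group0 = 50, n_group1 = 50,
                                 n_features = 200, n_informative = 0,
                                 effect = 0, seed = 77)
  tt <- welch_t_table(tab)
  n_sig <- sum(tt$p_value < 0.05)
  ci <- stats::qbinom(c(0.005, 0.995), 200, 0.05)
  expect_gte(n_sig, ci[1])
  expect_lte(n_sig, ci[2])
})

test_that("planted features carry the requested standardized shift", {
  tab <- generate_feature_cohort(n_group0 = 300, n_group1 = 300,
                                 n_features = 20, n_informative = 5,
                                 effect = 1.5, noise_sd = 2, seed = 10)
  gt <- ground_truth(tab)
  X <- feature_matrix(tab)
  shifts <- colMeans(X[tab$group == 1, gt$informative, drop = FALSE]) -
    colMeans(X[tab$group == 0, gt$informative, drop = FALSE])
  # each planted shift = effect * noise_sd = 3, SE ~ 2 * sqrt(2/300)
  expect_true(all(abs(shifts - 3) < 4 * 2 * sqrt(2 / 300)))
  noise_idx <- setdiff(seq_len(20), gt$informative)
  noise_shift <- colMeans(X[tab$group == 1, noise_idx]) -
    colMeans(X[tab$group == 0, noise_idx])
  expect_true(all(abs(noise_shift) < 4 * 2 * sqrt(2 / 300)))
})

test_that("planted informative features dominate the t-test ranking", {
  wins <- vapply(1:10, function(s) {
    tab <- generate_feature_cohort(n_group0 = 70, n_group1 = 70,
                                   n_features = 200, n_informative = 10,
                                   effect = 2, seed = 500 + s)
    sel <- ttest_select(tab, k = 15)
    all(ground_truth(tab)$informative %in% sel$best_subset)
  }, logical(1))
  expect_gte(sum(wins), 9)
})

test_that("time-series cohorts reproduce and respect their dimensions", {
  a <- generate_timeseries_cohort(n_group0 = 3, n_group1 = 3, n_roi = 6,
                                  t_points = 50, seed = 4, block_size = 3)
  b <- generate_timeseries_cohort(n_group0 = 3, n_group1 = 3, n_roi = 6,
                                  t_points = 50, seed = 4, block_size = 3)
  expect_identical(a$series[[1]]$data, b$series[[1]]$data)
  expect_equal(dim(a$series[[1]]$data), c(50, 6))
  expect_equal(a$series[[1]]$dt, 3)
  gt <- ground_truth(a)
  expect_equal(gt$block_rois, sprintf("ROI%03d", 1:3))
  expect_error(
    generate_timeseries_cohort(rho0 = 0.5, delta_rho = 0.6),
    "below 1")
})

test_that("the planted block shows the expected Fisher-z group contrast", {
  rho0 <- 0.2; drho <- 0.4
  coh <- generate_timeseries_cohort(n_group0 = 50, n_group1 = 50,
                                    n_roi = 8, t_points = 140,
                                    block_size = 4, rho0 = rho0,
                                    delta_rho = drho, seed = 31)
  block <- seq_len(4)
  mean_block_z <- vapply(coh$series, function(ts) {
    z <- fisher_z(roi_correlation(ts))$values[block, block]
    mean(z[upper.tri(z)])
  }, numeric(1))
  z0 <- mean_block_z[coh$group == 0]
  z1 <- mean_block_z[coh$group == 1]
  diff_obs <- mean(z1) - mean(z0)
  expected <- atanh(rho0 + drho) - atanh(rho0)
  se <- sqrt(var(z0) / length(z0) + var(z1) / length(z1))
  expect_lt(abs(diff_obs - expected), 2 * se + 0.01)
})

test_that("a null connectivity contrast stays within sampling noise", {
  coh <- generate_timeseries_cohort(n_group0 = 50, n_group1 = 50,
                                    n_roi = 8, t_points = 140,
                                    block_size = 4, rho0 = 0.2,
                                    delta_rho = 0, seed = 13)
  block <- seq_len(4)
  mz <- vapply(coh$series, function(ts) {
    z <- fisher_z(roi_correlation(ts))$values[block, block]
    mean(z[upper.tri(z)])
  }, numeric(1))
  d <- mean(mz[coh$group == 1]) - mean(mz[coh$group == 0])
  se <- sqrt(var(mz[coh$group == 0]) / 50 + var(mz[coh$group == 1]) / 50)
  expect_lt(abs(d), 2 * se + 0.01)
})

test_that("time-series cohorts round-trip through manifest + TSVs", {
  coh <- generate_timeseries_cohort(n_group0 = 2, n_group1 = 2, n_roi = 4,
                                    t_points = 30, seed = 8, block_size = 2)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(back$subject_id, coh$subject_id)
  expect_equal(back$group, coh$group)
  expect_equal(back$series[[3]]$data, coh$series[[3]]$data,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(attr(back, "ground_truth")$rho0, 0.2)
})

test_that("the full extraction chain recovers planted-block features", {
  # strong contrast so the graph itself differs between groups
  coh <- generate_timeseries_cohort(n_group0 = 20, n_group1 = 20,
                                    n_roi = 10, t_points = 140,
                                    block_size = 4, rho0 = 0.1,
                                    delta_rho = 0.6, seed = 91)
  atlas <- atlas_config(sprintf("ROI%03d", 1:10), character(0),
                        include_global = FALSE)
  tab <- extract_features(coh, atlas, band = NULL)
  expect_equal(ncol(feature_matrix(tab)), 70)
  sel <- ttest_select(tab, k = 10)
  block_nodes <- ground_truth(coh)$block_rois
  node_of <- sub("::.*$", "", sel$best_feature_names)
  frac_block <- mean(node_of %in% block_nodes)
  expect_gte(frac_block, 2 * (4 / 10)) # >= 2x the uniform node rate
})
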