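test_that("network maps are labeled, normalized, separable and deterministic", {
  nets <- make_network_maps(c(16, 16, 16), 7, seed = 1)
  expect_identical(names(nets$maps), network_labels())
  peaks <- vapply(nets$maps, max, numeric(1))
  expect_equal(unname(peaks), rep(1, 7))
  cc <- cor(sapply(nets$maps, as.vector))
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.5)
  nets2 <- make_network_maps(c(16, 16, 16), 7, seed = 1)
  expect_identical(nets$maps, nets2$maps)
  expect_false(identical(nets$maps,
                         make_network_maps(c(16, 16, 16), 7, seed = 2)$maps))
  expect_error(make_network_maps(c(8, 8, 8)), "grid too small")
})

test_that("ground_truth validates covariance, stability and amplitudes", {
  expect_s3_class(default_ground_truth("null"), "ground_truth")
  bad <- baseline_correlation(); bad[1, 2] <- 0.9  # asymmetric
  expect_error(ground_truth(bad), "not symmetric")
  notpsd <- diag(7); notpsd[1, 2] <- notpsd[2, 1] <- 1.5
  expect_error(ground_truth(notpsd), "not PSD")
  unstable <- data.frame(source = "SN", target = "SN", lag = 1, coef = 1.2)
  expect_error(ground_truth(diag(7), lag_couplings = unstable), "unstable")
  badlag <- data.frame(source = "SN", target = "aDMN", lag = 5, coef = 0.1)
  expect_error(ground_truth(diag(7), lag_couplings = badlag), "lags")
})

test_that("simulated time courses carry the planted covariance", {
  I7 <- diag(7); dimnames(I7) <- list(network_labels(), network_labels())
  # identity covariance, no lags: all |r| below sampling error at n_t = 5000
  tc <- simulate_timecourses(5000, 2, I7, seed = 21)
  r <- cor(t(tc))
  expect_lt(max(abs(r[upper.tri(r)])), 3 / sqrt(5000) * 1.5)
  # planted r = 0.3 recovered within +/- 0.05
  S <- I7; S["aDMN", "SN"] <- S["SN", "aDMN"] <- 0.3
  tc2 <- simulate_timecourses(5000, 2, S, seed = 22)
  expect_lt(abs(cor(tc2["aDMN", ], tc2["SN", ]) - 0.3), 0.05)
  # rows standardized
  expect_lt(max(abs(rowMeans(tc))), 1e-12)
  expect_equal(unname(apply(tc, 1, sd)), rep(1, 7))
  # determinism
  expect_identical(tc, simulate_timecourses(5000, 2, I7, seed = 21))
})

test_that("lagged coupling peaks at the planted lag", {
  I7 <- diag(7); dimnames(I7) <- list(network_labels(), network_labels())
  lc <- data.frame(source = "SN", target = "ipDMN", lag = 1, coef = 0.6)
  tc <- simulate_timecourses(5000, 2, I7, lag_couplings = lc, seed = 23)
  n <- ncol(tc)
  r_at <- function(k) cor(tc["SN", 1:(n - k)], tc["ipDMN", (1 + k):n])
  expect_gt(r_at(1), r_at(2))
  expect_gt(r_at(2), r_at(3))
  expect_gt(r_at(1), 0.3)
})

test_that("generate_cohort yields the published group sizes and structure", {
  truth <- default_ground_truth("null", seed = 7, noise_sd = 0.1)
  cohort <- generate_cohort(truth, grid_shape = c(12, 12, 12), n_t = 40)
  expect_identical(length(cohort$runs), 61L)
  expect_identical(nrow(cohort$subjects), 61L)
  expect_identical(
    as.integer(table(cohort$subjects$group)[c("HC", "NHE", "MHE")]),
    c(18L, 23L, 20L))
  expect_true(all(vapply(cohort$runs, function(r)
    identical(dim(r$data), c(12L, 12L, 12L, 40L)), logical(1))))
  # MHE PHES mean within 1 SD of the published -7.80
  mhe <- cohort$subjects$phes_composite[cohort$subjects$group == "MHE"]
  expect_lt(abs(mean(mhe) - (-7.80)), 2.28)
  expect_true(all(cohort$subjects$phes_composite >= -15 &
                    cohort$subjects$phes_composite <= 5))
})

test_that("noise-free single-subject data have rank <= number of components", {
  truth <- default_ground_truth("null", n_per_group = c(1, 0, 0),
                                noise_sd = 0, subject_sd = 0, seed = 9)
  cohort <- generate_cohort(truth, grid_shape = c(12, 12, 12), n_t = 60)
  m <- to_matrix(cohort$runs[[1]], cohort$mask)
  sv <- svd(m, nu = 0, nv = 0)$d
  expect_lt(sv[8] / sv[1], 1e-10)
  expect_gt(sv[7] / sv[1], 1e-10)
})

test_that("planted subject-level Fisher-Z matches the group targets", {
  truth <- default_ground_truth("mhe", seed = 13)
  cohort <- generate_cohort(truth, grid_shape = c(12, 12, 12), n_t = 20,
                            volumes = FALSE, keep_tcs = FALSE)
  z <- cohort$truth$subject_z
  grp <- cohort$subjects$group
  z_mhe <- mean(z[grp == "MHE", "aDMN", "SN"])
  z_hc <- mean(z[grp == "HC", "aDMN", "SN"])
  # planted shift 0.3, subject jitter 0.15 -> SE ~ 0.15/sqrt(n)
  expect_lt(abs((z_mhe - z_hc) - 0.3), 0.15)
  expect_lt(abs(mean(z[grp == "HC", "ipDMN", "SN"]) - atanh(-0.4)), 0.12)
})
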