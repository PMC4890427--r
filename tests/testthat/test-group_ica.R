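test_that("two_step_pca retains variance and rejects excessive orders", {
  cohort <- tiny_cohort()
  mats <- lapply(cohort$runs[1:3], function(r) to_matrix(r, cohort$mask))
  red <- two_step_pca(mats, k_group = 8)
  expect_identical(dim(red$whitened), c(8L, cohort$mask$n_voxels))
  # whitened: zero-mean rows, identity covariance
  expect_lt(max(abs(rowMeans(red$whitened))), 1e-10)
  C <- tcrossprod(red$whitened) / ncol(red$whitened)
  expect_lt(max(abs(C - diag(8))), 1e-8)
  expect_error(two_step_pca(mats, k_group = 8, k_subject = 5000), "exceeds")
})

test_that("noise-free rank-7 subject gives lossless step-1 reduction", {
  truth <- default_ground_truth("null", n_per_group = c(1, 0, 0),
                                noise_sd = 0, subject_sd = 0, seed = 2)
  cohort <- generate_cohort(truth, grid_shape = c(12, 12, 12), n_t = 60)
  m <- to_matrix(cohort$runs[[1]], cohort$mask)
  red <- two_step_pca(list(s = m), k_group = 7, k_subject = 7)
  expect_gte(red$variance_retained["step1"], 0.999)
})

test_that("infomax recovers independent sources (Amari oracle)", {
  set.seed(9)
  n <- 10000
  A <- matrix(c(1, 0.6, 0.4, 1), 2, 2)
  # uniform (sub-Gaussian) sources need the extended update
  S_u <- rbind(runif(n, -sqrt(3), sqrt(3)), runif(n, -sqrt(3), sqrt(3)))
  wu <- whiten_rows(A %*% S_u)
  fit_u <- infomax(wu$X, seed = 4, extended = TRUE)
  expect_lt(amari_index(fit_u$W %*% wu$W0 %*% A), 0.05)
  # sparse super-Gaussian sources with the default logistic update
  S_l <- rbind(rexp(n) - 1, rexp(n) - 1)
  wl <- whiten_rows(A %*% S_l)
  fit_l <- infomax(wl$X, seed = 4)
  expect_lt(amari_index(fit_l$W %*% wl$W0 %*% A), 0.05)
})

test_that("infomax is deterministic, scales sources, validates input", {
  set.seed(10)
  X <- whiten_rows(rbind(rexp(4000) - 1, rexp(4000) - 1, rexp(4000) - 1))$X
  f1 <- infomax(X, seed = 5)
  f2 <- infomax(X, seed = 5)
  expect_identical(f1$W, f2$W)
  expect_equal(unname(apply(f1$S, 1, sd)), rep(1, 3))
  # already-independent whitened input: W close to a signed permutation
  expect_lt(amari_index(f1$W %*% solve(f1$W)), 1e-12)
  raw <- rbind(rexp(4000), rexp(4000))
  expect_error(infomax(raw), "zero-mean|whitened")
})

test_that("icasso clusters stable problems tightly", {
  set.seed(12)
  n <- 2000
  S <- matrix(rexp(5 * n) - 1, 5)
  A <- diag(5) + matrix(runif(25, -0.3, 0.3), 5)
  w <- whiten_rows(A %*% S)
  res <- icasso(w$X, n_runs = 20, seed = 3)
  expect_true(all(res$iq > 0.9))
  expect_identical(length(res$iq), 5L)
  # duplicate runs: every cluster has one member per run, similarity 1
  res2 <- icasso(w$X, n_runs = 2, seeds = c(77L, 77L))
  expect_true(all(table(res2$cluster) == 2))
  expect_true(all(res2$iq > 0.9))
  expect_error(icasso(w$X, n_runs = 1), "n_runs >= 2")
})

test_that("icasso quality drops for pure-noise input", {
  set.seed(13)
  iq_noise <- replicate(3, {
    X <- whiten_rows(matrix(rnorm(5 * 800), 5))$X
    mean(icasso(X, n_runs = 5, seed = sample.int(1000, 1), max_iter = 128)$iq)
  })
  iq_signal <- replicate(3, {
    S <- matrix(rexp(5 * 800) - 1, 5)
    A <- diag(5) + matrix(runif(25, -0.3, 0.3), 5)
    X <- whiten_rows(A %*% S)$X
    mean(icasso(X, n_runs = 5, seed = sample.int(1000, 1), max_iter = 128)$iq)
  })
  expect_lt(mean(iq_noise), mean(iq_signal))
})

test_that("back-reconstruction matches direct ICA for a lossless single subject", {
  cohort <- tiny_cohort()
  m1 <- to_matrix(cohort$runs[[1]], cohort$mask)
  red <- two_step_pca(list(s1 = m1), k_group = 7, k_subject = 7)
  fit <- infomax(red$whitened, seed = 2)
  br <- back_reconstruct(fit$W, red)
  cc <- abs(cor(t(br$subject_maps[[1]]), t(fit$S)))
  expect_gt(min(apply(cc, 1, max)), 0.99)
  # Z-scaling of subject maps
  expect_lt(max(abs(rowMeans(br$subject_maps[[1]]))), 1e-8)
  expect_equal(unname(apply(br$subject_maps[[1]], 1, sd)), rep(1, 7),
               tolerance = 1e-8)
})

test_that("group ICA recovers planted maps and respects the sign convention", {
  cohort <- tiny_cohort()
  mats <- lapply(cohort$runs, function(r) to_matrix(r, cohort$mask))
  decomp <- run_group_ica(mats, n_components = 9, seed = 11)
  tmpl <- sapply(cohort$templates, as.vector)
  cc <- abs(cor(t(decomp$group_maps), tmpl))
  expect_gt(min(apply(cc, 2, max)), 0.9)
  # orientation: peak positive
  expect_true(all(apply(decomp$group_maps, 1, max) >=
                    abs(apply(decomp$group_maps, 1, min))))
  # subject map recovery for a noise-bearing subject
  sm <- decomp$subject_maps[[1]]
  best <- apply(abs(cor(t(sm), tmpl)), 2, max)
  expect_gt(min(best), 0.9)
})
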