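test_that("ancova group F matches the base-R sequential oracle", {
  subjects <- random_subjects(c(8, 8, 8), seed = 41)
  set.seed(42)
  y <- rnorm(24) + 0.5 * (subjects$group == "MHE") + 0.02 * subjects$age
  res <- ancova_anova(y, subjects)
  # oracle: sequential ANOVA with covariates entered first; the group line
  # is then the partial (Type III) test for the only factor
  g <- factor(subjects$group, levels = c("HC", "NHE", "MHE"))
  fit <- lm(y ~ age + sex + education_years + gm_score + g, data = subjects)
  tab <- anova(fit)
  expect_equal(res$F, tab["g", "F value"], tolerance = 1e-10)
  expect_equal(res$p, tab["g", "Pr(>F)"], tolerance = 1e-10)
  expect_identical(unname(res$df), c(2, 24 - 7))
  # post-hoc contrast equals coefficient t-test
  sm <- summary(fit)$coefficients
  expect_equal(res$posthoc$t[res$posthoc$contrast == "MHE-HC"],
               sm["gMHE", "t value"], tolerance = 1e-10)
  # adjusted means differ by the dummy coefficients
  expect_equal(unname(res$adjusted_means["MHE"] - res$adjusted_means["HC"]),
               unname(coef(fit)["gMHE"]), tolerance = 1e-10)
})

test_that("ancova reduces to one-way ANOVA when covariates are orthogonal", {
  subjects <- random_subjects(c(10, 10, 10), seed = 43)
  g <- factor(subjects$group, levels = c("HC", "NHE", "MHE"))
  set.seed(44)
  y0 <- rnorm(30) + (g == "NHE")
  # orthogonalize covariates against [1 | dummies | y]
  base_mat <- cbind(1, g == "NHE", g == "MHE", y0)
  for (cv in c("age", "sex", "education_years", "gm_score")) {
    subjects[[cv]] <- residuals(lm(subjects[[cv]] ~ base_mat))
  }
  res <- ancova_anova(y0, subjects)
  oneway <- anova(lm(y0 ~ g))
  # same sums of squares; F ratios differ only through the error df
  expect_equal(res$F * (30 - 3) / (30 - 7), oneway["g", "F value"],
               tolerance = 1e-6)
  expect_error(
    ancova_anova(y0, transform(subjects, gm_score = age)),
    "collinear")
})

test_that("ancova p-values are uniform under the null", {
  subjects <- random_subjects(c(10, 10, 10), seed = 45)
  design <- covariate_design(subjects)
  set.seed(46)
  pvals <- replicate(500, ancova_anova(rnorm(30), design)$p)
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("fdr_bh matches p.adjust and the step-up rule", {
  p <- c(0.01, 0.02, 0.03, 0.04, 0.05)
  res <- fdr_bh(p, 0.05)
  expect_true(all(res$reject))   # p(i) <= i q / m holds at i = 5
  expect_equal(res$p_adjusted, p.adjust(p, "BH"))
  expect_identical(fdr_bh(0.001, 0.05)$reject, TRUE)
  expect_equal(fdr_bh(0.001, 0.05)$p_adjusted, 0.001)
  set.seed(47)
  for (i in 1:20) {
    pv <- runif(21)^sample(c(1, 2, 3), 1)
    expect_equal(fdr_bh(pv, 0.05)$p_adjusted, p.adjust(pv, "BH"))
  }
  expect_identical(fdr_bh(numeric(0))$reject, logical(0))
})

test_that("fdr_bh rejections sit between Bonferroni and unadjusted", {
  set.seed(48)
  for (i in 1:20) {
    pv <- runif(30)^3
    n_bh <- sum(fdr_bh(pv, 0.05)$reject)
    expect_gte(n_bh, sum(pv <= 0.05 / 30))
    expect_lte(n_bh, sum(pv <= 0.05))
  }
})

test_that("summary_anova equals raw-data ANOVA by construction", {
  # construct groups with exact means/sds
  mk <- function(n, mean, sd) {
    x <- scale(rnorm(n))[, 1]   # exact mean 0, sd 1
    mean + sd * x
  }
  set.seed(49)
  g1 <- mk(18, 50.1, 6.6); g2 <- mk(23, 50.8, 9.8); g3 <- mk(20, 49.5, 9.2)
  raw <- anova(lm(c(g1, g2, g3) ~ rep(c("a", "b", "c"), c(18, 23, 20))))
  res <- summary_anova(c(50.1, 50.8, 49.5), c(6.6, 9.8, 9.2), c(18, 23, 20))
  expect_lt(abs(res$F - raw[1, "F value"]), 1e-10)
  expect_equal(res$p, raw[1, "Pr(>F)"], tolerance = 1e-10)
  # identical groups -> F = 0, p = 1
  res0 <- summary_anova(c(1, 1, 1), c(2, 2, 2), c(5, 5, 5))
  expect_equal(res0$F, 0)
  expect_equal(res0$p, 1)
  expect_error(summary_anova(c(1, 2), c(1, 1), c(1, 5)), "n >= 2")
})

test_that("chisq_counts matches the hand-computed Pearson statistic", {
  tab <- matrix(c(10L, 5L, 8L, 7L), 2, 2)
  res <- chisq_counts(tab)
  # manual expected counts oracle
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_lt(abs(res$chi2 - sum((tab - E)^2 / E)), 1e-12)
  expect_equal(res$p, chisq.test(tab, correct = FALSE)$p.value,
               tolerance = 1e-12)
  # perfectly proportional table
  prop <- matrix(c(10L, 20L, 5L, 10L, 15L, 30L), 3, 2, byrow = TRUE)
  expect_equal(chisq_counts(prop)$chi2, 0)
  expect_equal(chisq_counts(prop)$p, 1)
  expect_error(chisq_counts(matrix(c(0L, 0L, 1L, 2L), 2)), "marginal")
  expect_error(chisq_counts(matrix(c(0.5, 1, 1, 2), 2)), "integers")
})

test_that("phes_correlation recovers exact and planted couplings", {
  phes <- c(-9, -7, -5, -8, -6)
  conn <- 0.1 * phes + 2
  res <- phes_correlation(conn, phes)
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_error(phes_correlation(rep(1, 5), phes), "zero variance")
  # null distribution at n = 20: |r| < 0.45 in ~95% of replicates
  set.seed(50)
  r_null <- replicate(400, phes_correlation(rnorm(20), rnorm(20))$r)
  expect_gt(mean(abs(r_null) < 0.45), 0.90)
})

test_that("cohort-level PHES coupling is recovered at the MHE sample size", {
  r_hat <- vapply(1:100, function(i) {
    truth <- default_ground_truth("null", phes_coupling = -0.6, seed = 500 + i)
    cohort <- generate_cohort(truth, volumes = FALSE, keep_tcs = FALSE)
    mhe <- cohort$subjects$group == "MHE"
    phes_correlation(cohort$truth$subject_z[mhe, "ipDMN", "SN"],
                     cohort$subjects$phes_composite[mhe])$r
  }, numeric(1))
  expect_lt(mean(r_hat), 0)
  expect_lt(abs(mean(r_hat) - (-0.6)), 0.25)
})

test_that("monte_carlo_extent agrees with an independent re-simulation oracle", {
  # oracle clustering: iterative min-label propagation over shifted arrays,
  # algorithmically unrelated to the package's flood fill
  prop_max_cluster <- function(supra) {
    dims <- dim(supra)
    lab <- array(0L, dims)
    lab[supra] <- seq_len(sum(supra))
    shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    shifts <- shifts[rowSums(abs(shifts)) > 0, ]
    repeat {
      nxt <- lab
      for (s in seq_len(nrow(shifts))) {
        sh <- shifts[s, ]
        src <- list(seq_len(dims[1]) - sh[1], seq_len(dims[2]) - sh[2],
                    seq_len(dims[3]) - sh[3])
        ok <- lapply(seq_len(3), function(d) src[[d]] >= 1 & src[[d]] <= dims[d])
        moved <- array(0L, dims)
        moved[ok[[1]], ok[[2]], ok[[3]]] <-
          lab[src[[1]][ok[[1]]], src[[2]][ok[[2]]], src[[3]][ok[[3]]]]
        upd <- supra & moved > 0 & (nxt == 0 | moved < nxt)
        nxt[upd] <- moved[upd]
      }
      if (identical(nxt, lab)) break
      lab <- nxt
    }
    if (sum(supra) == 0) 0L else max(table(lab[supra]))
  }
  dims <- c(14L, 14L, 14L)
  mask <- brain_mask(array(TRUE, dims))
  n_sim <- 300
  ext <- monte_carlo_extent(mask, smoothness_fwhm = 0, voxel_p = 0.05,
                            alpha = 0.05, n_simulations = n_sim, seed = 61)
  zthr <- qnorm(1 - 0.05 / 2)
  set.seed(61)  # same fields; independent clustering and quantile path
  max_ext <- vapply(seq_len(n_sim), function(s) {
    v <- rnorm(prod(dims))
    v <- (v - mean(v)) / sd(v)
    prop_max_cluster(array(abs(v) > zthr, dims))
  }, numeric(1))
  k <- 1L
  while (mean(max_ext >= k) > 0.05) k <- k + 1L
  expect_lte(abs(as.integer(ext) - k), 1L)
})

test_that("monte_carlo_extent edge behavior and monotonicity", {
  mask <- brain_mask(array(TRUE, c(12, 12, 12)))
  expect_identical(as.integer(monte_carlo_extent(mask, 0, alpha = 1.0,
                                                 n_simulations = 50,
                                                 seed = 3)), 1L)
  exts <- vapply(c(0, 1.5, 3), function(fw) {
    as.integer(monte_carlo_extent(mask, fw, voxel_p = 0.01, alpha = 0.05,
                                  n_simulations = 300, seed = 7))
  }, integer(1))
  expect_true(all(diff(exts) >= 0))
  expect_error(monte_carlo_extent(brain_mask(array(FALSE, c(4, 4, 4))), 0),
               "degenerate")
})

test_that("voxelwise_anova recovers a planted deficit and nulls cleanly", {
  mask <- brain_mask(array(TRUE, c(12, 12, 12)))
  subjects <- random_subjects(c(12, 12, 12), seed = 71)
  design <- covariate_design(subjects)
  nets <- make_network_maps(c(12, 12, 12), 7, seed = 5)
  blob <- as.vector(nets$maps$SN)[mask$data]
  sigma <- fwhm_to_sigma(2)
  set.seed(72)
  maps <- t(sapply(seq_len(36), function(i) {
    f <- gaussian_smooth_3d(array(rnorm(12^3), c(12, 12, 12)), sigma)
    v <- f[mask$data]
    v <- (v - mean(v)) / sd(v)
    if (subjects$group[i] == "MHE") v <- v - 1.2 * blob else v
  }))
  res <- voxelwise_anova(maps, design, mask, voxel_p = 0.01,
                         n_simulations = 500, seed = 73)
  expect_gt(nrow(res$clusters), 0)
  # surviving voxels overlap the planted blob (Dice > 0.5)
  vol <- array(FALSE, c(12, 12, 12))
  idx <- which(mask$data)
  sig_voxels <- !is.na(res$p_map) & res$p_map < 0.01
  lab <- label_clusters({ s <- array(FALSE, c(12, 12, 12)); s[idx] <- sig_voxels; s },
                        26L)
  surviving <- lab$labels > 0 &
    array(lab$labels %in% res$clusters$id, dim = c(12, 12, 12))
  planted <- nets$maps$SN > 0.5
  dice <- 2 * sum(surviving & planted) / (sum(surviving) + sum(planted))
  expect_gt(dice, 0.5)
  # constant maps: no clusters
  res0 <- voxelwise_anova(matrix(1, 36, sum(mask$data)) +
                            matrix(rnorm(36 * sum(mask$data), 0, 1e-8), 36),
                          design, mask, min_extent = 5L, seed = 74)
  expect_identical(nrow(res0$clusters), 0L)
  expect_error(voxelwise_anova(maps, design, mask,
                               analysis_mask = rep(FALSE, sum(mask$data))),
               "empty")
})

test_that("group power reaches 0.8 for a 1 SD Fisher-Z shift at published sizes", {
  subjects <- random_subjects(c(18, 23, 20), seed = 81)
  design <- covariate_design(subjects)
  mhe <- subjects$group == "MHE"
  set.seed(82)
  rejections <- replicate(200, {
    y <- rnorm(61, 0, 0.3)          # subject-level Z noise
    y[mhe] <- y[mhe] + 0.3          # 1 SD shift
    ancova_anova(y, design)$p < 0.05
  })
  expect_gte(mean(rejections), 0.8)
})

test_that("estimate_fwhm roughly recovers known smoothness", {
  mask <- brain_mask(array(TRUE, c(16, 16, 16)))
  set.seed(91)
  for (fw in c(2, 3)) {
    maps <- t(sapply(1:6, function(i) {
      f <- gaussian_smooth_3d(array(rnorm(16^3), c(16, 16, 16)),
                              fwhm_to_sigma(fw))
      v <- f[mask$data]
      (v - mean(v)) / sd(v)
    }))
    est <- estimate_fwhm(maps, mask)
    expect_lt(abs(est - fw) / fw, 0.25)
  }
})

test_that("trend contrast detects an ordered progression", {
  subjects <- random_subjects(c(12, 12, 12), seed = 95)
  g <- factor(subjects$group, levels = c("HC", "NHE", "MHE"))
  set.seed(96)
  y <- rnorm(36, 0, 0.2) + 0.4 * (as.integer(g) - 1)
  res <- trend_contrast(y, subjects)
  expect_lt(res$p, 0.01)
  expect_gt(res$estimate, 0)
})
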