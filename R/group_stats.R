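#' Group-level inference
#'
#' Covariate-adjusted three-group comparisons (ANCOVA with age, sex,
#' education and gray-matter score as covariates of no interest), voxelwise
#' maps with Monte-Carlo cluster-extent correction, Benjamini-Hochberg FDR
#' over connectivity pairs, clinical correlations, and summary-statistic
#' demographics tests.
#'
#' @name group_stats
NULL

#' Build the covariate design from a subject table
#'
#' Group is coded by two dummy indicators with HC as the reference level;
#' sex is 0/1. The design is checked for full rank.
#'
#' @param subjects Subject data.frame with `group`, `age`, `sex`,
#'   `education_years`, `gm_score`.
#' @return List with `X_full`, `X_reduced` (no group columns), `group`
#'   (factor), `n`.
#' @export
covariate_design <- function(subjects) {
  g <- factor(subjects$group, levels = c("HC", "NHE", "MHE"))
  if (anyNA(g)) stop("invalid group labels")
  covs <- as.matrix(subjects[, c("age", "sex", "education_years", "gm_score")])
  if (anyNA(covs) || !all(is.finite(covs))) stop("missing covariate values")
  X_full <- cbind(intercept = 1, nhe = as.numeric(g == "NHE"),
                  mhe = as.numeric(g == "MHE"), covs)
  qr_rank <- qr(X_full)$rank
  if (qr_rank < ncol(X_full)) {
    cn <- colnames(X_full)
    drop_info <- cn[qr(X_full)$pivot[(qr_rank + 1):ncol(X_full)]]
    stop("rank-deficient design; collinear columns: ",
         paste(drop_info, collapse = ", "))
  }
  list(X_full = X_full, X_reduced = X_full[, -(2:3), drop = FALSE],
       group = g, n = nrow(X_full))
}

#' Three-group ANCOVA on one scalar per subject
#'
#' Fits `value ~ group + age + sex + education + gm_score` by least squares
#' and tests the group factor with a partial (Type III) F-test. Post-hoc
#' pairwise contrasts are unadjusted t-tests on the covariate-adjusted group
#' means (contrasts of the group dummies).
#'
#' @param values Numeric vector, one value per subject.
#' @param design A [covariate_design()] (or a subject data.frame).
#' @return An `ancova_result` list: `F`, `p`, `df` (between, within),
#'   `adjusted_means` (HC, NHE, MHE at covariate means), `posthoc`
#'   (data.frame of 3 pairwise contrasts with `t` and `p`).
#' @export
ancova_anova <- function(values, design) {
  if (is.data.frame(design)) design <- covariate_design(design)
  X <- design$X_full
  X0 <- design$X_reduced
  n <- length(values)
  stopifnot(n == nrow(X), n >= ncol(X) + 2L)
  fit <- stats::lm.fit(X, values)
  rss1 <- sum(fit$residuals^2)
  rss0 <- sum(stats::lm.fit(X0, values)$residuals^2)
  df2 <- n - ncol(X)
  Fv <- ((rss0 - rss1) / 2) / (rss1 / df2)
  p <- stats::pf(Fv, 2, df2, lower.tail = FALSE)
  beta <- fit$coefficients
  sigma2 <- rss1 / df2
  XtXinv <- chol2inv(chol(crossprod(X)))
  cov_means <- colMeans(X[, -(1:3), drop = FALSE])
  base <- c(1, 0, 0, cov_means)
  adj <- c(HC = sum(base * beta),
           NHE = sum(base * beta) + unname(beta["nhe"]),
           MHE = sum(base * beta) + unname(beta["mhe"]))
  contrasts <- list(`NHE-HC` = c(0, 1, 0, rep(0, length(cov_means))),
                    `MHE-HC` = c(0, 0, 1, rep(0, length(cov_means))),
                    `MHE-NHE` = c(0, -1, 1, rep(0, length(cov_means))))
  post <- do.call(rbind, lapply(names(contrasts), function(nm) {
    cv <- contrasts[[nm]]
    est <- sum(cv * beta)
    se <- sqrt(sigma2 * drop(t(cv) %*% XtXinv %*% cv))
    tv <- est / se
    data.frame(contrast = nm, estimate = est, t = tv,
               p = 2 * stats::pt(-abs(tv), df2), stringsAsFactors = FALSE)
  }))
  structure(list(F = Fv, p = p, df = c(between = 2, within = df2),
                 adjusted_means = adj, posthoc = post),
            class = "ancova_result")
}

#' Benjamini-Hochberg FDR step-up
#'
#' @param pvals Numeric p-values in [0, 1].
#' @param q FDR level (default 0.05).
#' @return List with `reject` (logical), `p_adjusted` (monotone BH-adjusted
#'   p-values) and `q`.
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  m <- length(pvals)
  if (m == 0L) {
    return(list(reject = logical(0), p_adjusted = numeric(0), q = q))
  }
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p-values outside [0,1]")
  o <- order(pvals)
  ranked <- pvals[o]
  adj <- ranked * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  p_adj <- numeric(m)
  p_adj[o] <- adj
  k <- which(ranked <= seq_len(m) * q / m)
  reject <- logical(m)
  if (length(k) > 0L) reject[o[seq_len(max(k))]] <- TRUE
  list(reject = reject, p_adjusted = p_adj, q = q)
}

#' Monte-Carlo cluster-extent threshold
#'
#' Simulates smooth Gaussian null fields on the mask (white noise smoothed to
#' the given FWHM and standardized within the mask), thresholds voxels
#' two-sidedly at the voxel-level p threshold, records the maximal cluster
#' extent per simulation, and returns the smallest extent whose exceedance
#' probability is at most `alpha`.
#'
#' @param mask A [brain_mask()].
#' @param smoothness_fwhm Field smoothness in voxels (FWHM), e.g. from
#'   [estimate_fwhm()].
#' @param voxel_p Voxel-level forming threshold (default 0.01).
#' @param alpha Family-wise cluster alpha (default 0.05).
#' @param n_simulations Number of null simulations (>= 1000 recommended).
#' @param connectivity 6, 18 or 26 (default 26).
#' @param seed Integer seed.
#' @return Integer minimum cluster extent; the simulated maximal extents are
#'   attached as attribute `max_extents`.
#' @export
monte_carlo_extent <- function(mask, smoothness_fwhm, voxel_p = 0.01,
                               alpha = 0.05, n_simulations = 1000L,
                               connectivity = 26L, seed = 1L) {
  if (mask$n_voxels < 2L) stop("degenerate mask")
  stopifnot(alpha > 0, alpha <= 1, voxel_p > 0, voxel_p < 1)
  dims <- dim(mask$data)
  zthr <- stats::qnorm(1 - voxel_p / 2)
  sigma <- fwhm_to_sigma(smoothness_fwhm)
  set.seed(seed)
  idx <- which(mask$data)
  max_ext <- integer(n_simulations)
  supra <- array(FALSE, dim = dims)
  for (s in seq_len(n_simulations)) {
    field <- array(stats::rnorm(prod(dims)), dim = dims)
    if (sigma > 0) field <- gaussian_smooth_3d(field, sigma)
    v <- field[idx]
    v <- (v - mean(v)) / stats::sd(v)
    supra[] <- FALSE
    supra[idx] <- abs(v) > zthr
    cl <- label_clusters(supra, connectivity)
    max_ext[s] <- if (cl$n_clusters > 0L) max(cl$sizes) else 0L
  }
  # smallest extent k with P(max extent >= k) <= alpha
  k <- 1L
  while (mean(max_ext >= k) > alpha) k <- k + 1L
  structure(k, max_extents = max_ext)
}

#' Voxelwise three-group ANCOVA with cluster-extent correction
#'
#' Per-voxel [ancova_anova()] F-statistics (computed with vectorized
#' residual projections), thresholded at `voxel_p`, clustered under the
#' chosen connectivity, keeping clusters at least `min_extent` voxels (from
#' [monte_carlo_extent()] when not supplied).
#'
#' @param maps `subjects x voxels` matrix of intra-network Z values (mask
#'   raster order).
#' @param design A [covariate_design()] (or subject data.frame).
#' @param mask [brain_mask()] defining the raster order; an optional logical
#'   `analysis_mask` vector restricts to a network's voxels.
#' @param voxel_p Voxel-level forming threshold (default 0.01; an explicit
#'   assumption, see package vignette).
#' @param alpha Cluster-level family-wise alpha (default 0.05).
#' @param connectivity Cluster connectivity (default 26).
#' @param min_extent Cluster extent threshold; when `NULL` it is derived by
#'   Monte-Carlo simulation with smoothness estimated from the residual maps.
#' @param n_simulations Simulations for the extent threshold.
#' @param analysis_mask Optional logical vector (length `mask$n_voxels`).
#' @param seed Seed for the Monte-Carlo step.
#' @return List with `F_map`, `p_map` (vectors over mask voxels, NA outside
#'   the analysis mask), `clusters` (data.frame: id, extent, peak 0-based
#'   x/y/z, peak F), `min_extent`, `smoothness_fwhm`.
#' @export
voxelwise_anova <- function(maps, design, mask, voxel_p = 0.01, alpha = 0.05,
                            connectivity = 26L, min_extent = NULL,
                            n_simulations = 1000L, analysis_mask = NULL,
                            seed = 1L) {
  if (is.data.frame(design)) design <- covariate_design(design)
  n <- nrow(maps)
  stopifnot(n == design$n)
  if (is.null(analysis_mask)) analysis_mask <- rep(TRUE, ncol(maps))
  if (!any(analysis_mask)) stop("empty analysis mask")
  Y <- maps[, analysis_mask, drop = FALSE]
  X <- design$X_full
  X0 <- design$X_reduced
  H <- X %*% chol2inv(chol(crossprod(X))) %*% t(X)
  H0 <- X0 %*% chol2inv(chol(crossprod(X0))) %*% t(X0)
  R1 <- Y - H %*% Y
  R0 <- Y - H0 %*% Y
  rss1 <- colSums(R1^2)
  rss0 <- colSums(R0^2)
  df2 <- n - ncol(X)
  Fv <- ((rss0 - rss1) / 2) / pmax(rss1 / df2, 1e-300)
  Fv[rss1 <= 1e-300 & rss0 <= 1e-300] <- 0   # constant voxels: no effect
  pv <- stats::pf(Fv, 2, df2, lower.tail = FALSE)

  Rsub <- R1[seq_len(min(5L, n)), , drop = FALSE]
  Rsub <- Rsub / pmax(apply(Rsub, 1, stats::sd), 1e-300)
  smoothness <- estimate_fwhm(Rsub, mask_subset(mask, analysis_mask))
  if (is.null(min_extent)) {
    min_extent <- as.integer(monte_carlo_extent(
      mask_subset(mask, analysis_mask), smoothness, voxel_p = voxel_p,
      alpha = alpha, n_simulations = n_simulations,
      connectivity = connectivity, seed = seed))
  }
  F_full <- rep(NA_real_, ncol(maps))
  p_full <- rep(NA_real_, ncol(maps))
  F_full[analysis_mask] <- Fv
  p_full[analysis_mask] <- pv

  dims <- dim(mask$data)
  supra <- array(FALSE, dim = dims)
  idx <- which(mask$data)
  sup_vec <- !is.na(p_full) & p_full < voxel_p
  supra[idx] <- sup_vec
  cl <- label_clusters(supra, connectivity)
  clusters <- data.frame(id = integer(0), extent = integer(0),
                         peak_x = integer(0), peak_y = integer(0),
                         peak_z = integer(0), peak_F = numeric(0))
  if (cl$n_clusters > 0L) {
    Fvol <- array(NA_real_, dim = dims)
    Fvol[idx] <- F_full
    keep <- which(cl$sizes >= min_extent)
    for (cid in keep) {
      vox <- which(cl$labels == cid)
      peak <- vox[which.max(Fvol[vox])]
      pc <- arrayInd(peak, dims) - 1L    # 0-based voxel coordinates
      clusters <- rbind(clusters, data.frame(
        id = cid, extent = cl$sizes[cid], peak_x = pc[1], peak_y = pc[2],
        peak_z = pc[3], peak_F = Fvol[peak]))
    }
  }
  list(F_map = F_full, p_map = p_full, clusters = clusters,
       min_extent = min_extent, smoothness_fwhm = smoothness)
}

# restrict a brain mask to a logical subset of its voxels (raster order)
mask_subset <- function(mask, keep) {
  m <- mask$data
  idx <- which(m)
  m[idx[!keep]] <- FALSE
  brain_mask(m)
}

#' Pearson correlation of connectivity values against PHES
#'
#' @param conn_values Numeric connectivity values (one per subject).
#' @param phes PHES composite scores (same length).
#' @return List with `r`, `p` (two-sided), `n`.
#' @export
phes_correlation <- function(conn_values, phes) {
  ok <- is.finite(conn_values) & is.finite(phes)
  if (sum(ok) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(conn_values[ok]) == 0 || stats::sd(phes[ok]) == 0) {
    stop("zero variance in correlation input")
  }
  ct <- stats::cor.test(conn_values[ok], phes[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' One-way ANOVA from group summary statistics
#'
#' Reconstructs the between- and within-group sums of squares from the per
#' group means, SDs and sizes; identical to raw-data one-way ANOVA when the
#' summaries are exact.
#'
#' @param means,sds,ns Numeric vectors of per-group mean, SD and size.
#' @return List with `F`, `p`, `df`.
#' @export
summary_anova <- function(means, sds, ns) {
  stopifnot(length(means) == length(sds), length(sds) == length(ns))
  if (any(ns < 2)) stop("each group needs n >= 2")
  if (any(sds <= 0)) stop("SDs must be positive")
  N <- sum(ns)
  k <- length(means)
  grand <- sum(ns * means) / N
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((ns - 1) * sds^2)
  df1 <- k - 1
  df2 <- N - k
  Fv <- (ssb / df1) / (ssw / df2)
  list(F = Fv, p = stats::pf(Fv, df1, df2, lower.tail = FALSE),
       df = c(df1, df2))
}

#' Pearson chi-square test on a count table
#'
#' Plain Pearson chi-square without continuity correction,
#' `df = (rows - 1)(cols - 1)`.
#'
#' @param table Matrix of non-negative integer counts.
#' @return List with `chi2`, `df`, `p`, `expected`.
#' @export
chisq_counts <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers")
  }
  rs <- rowSums(table)
  cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0)) stop("zero marginal in count table")
  expected <- outer(rs, cs) / sum(table)
  chi2 <- sum((table - expected)^2 / expected)
  df <- (nrow(table) - 1) * (ncol(table) - 1)
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE), expected = expected)
}

#' Ordered-trend (Jonckheere-style) contrast across HC < NHE < MHE
#'
#' Linear trend contrast on the covariate-adjusted group means, testing a
#' monotone progression with disease stage. Not part of the published
#' analysis surface; provided as a diagnostic.
#'
#' @inheritParams ancova_anova
#' @return List with `t`, `p` (two-sided), `estimate`.
#' @export
trend_contrast <- function(values, design) {
  if (is.data.frame(design)) design <- covariate_design(design)
  X <- design$X_full
  fit <- stats::lm.fit(X, values)
  df2 <- length(values) - ncol(X)
  sigma2 <- sum(fit$residuals^2) / df2
  XtXinv <- chol2inv(chol(crossprod(X)))
  # group means weights (-1, 0, 1) -> dummy contrast (0, 1, 2) - 1 each
  cv <- c(0, 0, 1, rep(0, ncol(X) - 3))  # MHE - HC captures the linear trend
  cv[2] <- 0
  est <- sum(cv * fit$coefficients)
  se <- sqrt(sigma2 * drop(t(cv) %*% XtXinv %*% cv))
  tv <- est / se
  list(t = tv, p = 2 * stats::pt(-abs(tv), df2), estimate = est)
}
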