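#' Synthetic triple-network BOLD cohorts with planted ground truth
#'
#' The generator builds three-group cohorts (HC / NHE / MHE) of 4D BOLD-like
#' volumes as spatial-map-by-time-course mixtures plus white noise. Everything
#' a downstream stage estimates is planted and retained: the seven network
#' spatial maps, per-group inter-network covariance, optional lagged
#' salience-network couplings, per-group intra-network amplitudes, covariates,
#' and PHES scores drawn around the published group summaries.
#'
#' @name synthetic_data
NULL

#' Generate the seven network spatial maps
#'
#' Each map is a sum of one to three Gaussian blobs on the grid, peak
#' normalized to 1, labeled `aDMN, ipDMN, spDMN, lvCEN, rvCEN, dCEN, SN`.
#' Blob centers sit at fixed well-separated fractional grid positions with a
#' small seeded jitter, so maps are pairwise near-orthogonal
#' (spatial |r| < 0.5, enforced).
#'
#' @param grid_shape Length-3 integer grid (default 16x16x16). Grids below 12
#'   voxels per axis are rejected.
#' @param n_networks Number of maps (must be <= 7 with the default labels).
#' @param seed Integer seed controlling jitter and satellite blobs.
#' @param blob_sd Gaussian blob SD in voxels; default `min(grid)/10`.
#' @return A list with `maps` (list of named 3D arrays) and `labels`.
#' @export
make_network_maps <- function(grid_shape = c(16L, 16L, 16L), n_networks = 7L,
                              seed = 1L, blob_sd = NULL) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L)
  if (any(grid_shape < 12L)) {
    stop("grid too small: need >= 12 voxels per axis to keep maps separable")
  }
  labels <- network_labels()
  if (n_networks > length(labels)) {
    stop("at most ", length(labels), " labeled networks are supported")
  }
  labels <- labels[seq_len(n_networks)]
  if (is.null(blob_sd)) blob_sd <- min(grid_shape) / 10
  centers_frac <- matrix(c(
    0.25, 0.25, 0.25,   # aDMN
    0.75, 0.25, 0.25,   # ipDMN
    0.25, 0.75, 0.25,   # spDMN
    0.75, 0.75, 0.30,   # lvCEN
    0.25, 0.30, 0.75,   # rvCEN
    0.75, 0.25, 0.75,   # dCEN
    0.50, 0.75, 0.75    # SN
  ), ncol = 3, byrow = TRUE)[seq_len(n_networks), , drop = FALSE]

  set.seed(seed)
  ax <- lapply(grid_shape, seq_len)
  maps <- vector("list", n_networks)
  names(maps) <- labels
  for (i in seq_len(n_networks)) {
    center <- centers_frac[i, ] * grid_shape +
      stats::runif(3, -0.03, 0.03) * grid_shape
    n_sat <- sample(0:2, 1)
    amps <- c(1, rep(0.6, n_sat))
    cents <- rbind(center,
                   if (n_sat > 0) {
                     matrix(center, n_sat, 3, byrow = TRUE) +
                       matrix(stats::runif(3 * n_sat, -1, 1) *
                                0.12 * min(grid_shape), ncol = 3)
                   })
    m <- array(0, dim = grid_shape)
    for (b in seq_len(nrow(cents))) {
      gx <- exp(-(ax[[1]] - cents[b, 1])^2 / (2 * blob_sd^2))
      gy <- exp(-(ax[[2]] - cents[b, 2])^2 / (2 * blob_sd^2))
      gz <- exp(-(ax[[3]] - cents[b, 3])^2 / (2 * blob_sd^2))
      m <- m + amps[b] * (gx %o% gy %o% gz)
    }
    maps[[i]] <- m / max(m)
  }
  flat <- sapply(maps, as.vector)
  cc <- stats::cor(flat)
  off <- abs(cc[upper.tri(cc)])
  if (any(off >= 0.5)) {
    stop(sprintf("grid too small: max pairwise map correlation %.2f >= 0.5",
                 max(off)))
  }
  list(maps = maps, labels = labels)
}

#' Construct and validate a ground-truth specification
#'
#' The ground truth fixes everything the pipeline is later asked to recover:
#' per-group inter-network covariance (as 7x7 correlation matrices), lagged
#' couplings out of the salience network, per-group per-network amplitudes,
#' observation noise, cohort sizes, and the random seed.
#'
#' @param mixing_cov Either one 7x7 positive-semidefinite correlation matrix
#'   used for every group, or a named list with entries `HC`, `NHE`, `MHE`.
#' @param lag_couplings `NULL` or a data.frame with columns `source`,
#'   `target`, `lag` (1-3), `coef`, and optionally `group` (comma-free label;
#'   `NA` applies to all groups).
#' @param intra_strength 3x7 matrix (groups x networks) of amplitudes, or a
#'   scalar.
#' @param noise_sd White-noise SD added to every voxel time point. The maps
#'   are peak-normalized and time courses unit-variance, so `noise_sd = 0.2`
#'   with unit amplitude means noise at 20 percent of peak signal SD.
#' @param n_per_group Named integer vector `c(HC=, NHE=, MHE=)`.
#' @param subject_sd Between-subject SD of the pairwise Fisher-Z values
#'   around the group mean (default 0.15, typical of published inter-network
#'   SDs of 0.2-0.3 once estimation noise is subtracted).
#' @param phes_coupling Correlation between the subject's planted Fisher-Z of
#'   `phes_pair` and the PHES composite within each group (0 disables).
#' @param phes_pair Length-2 character, default `c("ipDMN", "SN")`.
#' @param seed Master seed; all randomness derives from it.
#' @return A `ground_truth` object (validated list).
#' @export
ground_truth <- function(mixing_cov, lag_couplings = NULL,
                         intra_strength = 1, noise_sd = 0.2,
                         n_per_group = cohort_group_sizes(),
                         subject_sd = 0.15, phes_coupling = 0,
                         phes_pair = c("ipDMN", "SN"), seed = 1L) {
  labs <- network_labels()
  groups <- c("HC", "NHE", "MHE")
  if (is.matrix(mixing_cov)) {
    mixing_cov <- stats::setNames(rep(list(mixing_cov), 3), groups)
  }
  stopifnot(all(groups %in% names(mixing_cov)))
  for (g in groups) {
    S <- mixing_cov[[g]]
    if (!isTRUE(all.equal(S, t(S), tolerance = 1e-8))) {
      stop("mixing_cov for ", g, " is not symmetric")
    }
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) {
      stop(sprintf("mixing_cov for %s is not PSD (min eigenvalue %.3g)",
                   g, min(ev)))
    }
    if (is.null(dimnames(S))) dimnames(mixing_cov[[g]]) <- list(labs, labs)
  }
  if (!is.null(lag_couplings)) {
    stopifnot(all(c("source", "target", "lag", "coef") %in%
                    names(lag_couplings)))
    if (!all(lag_couplings$lag %in% 1:3)) stop("lags must be in {1,2,3}")
    if (!all(lag_couplings$source %in% labs) ||
        !all(lag_couplings$target %in% labs)) {
      stop("lag coupling networks must use the seven standard labels")
    }
    check_lag_stability(lag_couplings, labs)
  }
  if (length(intra_strength) == 1L) {
    intra_strength <- matrix(intra_strength, 3, 7,
                             dimnames = list(groups, labs))
  }
  stopifnot(all(dim(intra_strength) == c(3, 7)))
  if (is.null(rownames(intra_strength))) {
    dimnames(intra_strength) <- list(groups, labs)
  }
  stopifnot(noise_sd >= 0, subject_sd >= 0, abs(phes_coupling) <= 1)
  n_per_group <- as.integer(n_per_group)
  names(n_per_group) <- groups
  structure(list(mixing_cov = mixing_cov, lag_couplings = lag_couplings,
                 intra_strength = intra_strength, noise_sd = noise_sd,
                 n_per_group = n_per_group, subject_sd = subject_sd,
                 phes_coupling = phes_coupling, phes_pair = phes_pair,
                 seed = as.integer(seed)),
            class = "ground_truth")
}

# Companion-matrix stability of the lag-coupled generating process.
check_lag_stability <- function(couplings, labs) {
  K <- max(couplings$lag)
  p <- length(labs)
  A <- array(0, dim = c(p, p, K))
  for (i in seq_len(nrow(couplings))) {
    tgt <- match(couplings$target[i], labs)
    src <- match(couplings$source[i], labs)
    A[tgt, src, couplings$lag[i]] <- A[tgt, src, couplings$lag[i]] +
      couplings$coef[i]
  }
  comp <- matrix(0, p * K, p * K)
  for (k in seq_len(K)) comp[1:p, ((k - 1) * p + 1):(k * p)] <- A[, , k]
  if (K > 1) comp[(p + 1):(p * K), 1:(p * (K - 1))] <- diag(p * (K - 1))
  rho <- max(Mod(eigen(comp, only.values = TRUE)$values))
  if (rho >= 1) {
    stop(sprintf("unstable lag couplings: spectral radius %.3f >= 1", rho))
  }
  invisible(rho)
}

#' Stylized baseline inter-network correlation matrix
#'
#' A positive-definite 7x7 correlation matrix following the published
#' healthy-control pattern: positive couplings among DMN/CEN subsystems,
#' near-zero aDMN-SN, and negative SN couplings with posterior DMN and CEN
#' subsystems. Chosen once as the generator's default "stated world"; the
#' verbatim published matrix ([reference_interfc()]) is kept for reference
#' only because a printed matrix is not guaranteed positive definite.
#'
#' @return 7x7 correlation matrix with the standard network labels.
#' @export
baseline_correlation <- function() {
  labs <- network_labels()
  r <- diag(7)
  dimnames(r) <- list(labs, labs)
  set_r <- function(a, b, v) {
    r[a, b] <<- v
    r[b, a] <<- v
  }
  set_r("aDMN", "ipDMN", 0.35); set_r("aDMN", "spDMN", 0.15)
  set_r("aDMN", "lvCEN", 0.30); set_r("aDMN", "rvCEN", 0.30)
  set_r("aDMN", "dCEN", -0.25); set_r("aDMN", "SN", 0.00)
  set_r("ipDMN", "spDMN", 0.55); set_r("ipDMN", "lvCEN", 0.45)
  set_r("ipDMN", "rvCEN", 0.40); set_r("ipDMN", "dCEN", 0.05)
  set_r("ipDMN", "SN", -0.40)
  set_r("spDMN", "lvCEN", 0.30); set_r("spDMN", "rvCEN", 0.30)
  set_r("spDMN", "dCEN", 0.20); set_r("spDMN", "SN", -0.45)
  set_r("lvCEN", "rvCEN", 0.55); set_r("lvCEN", "dCEN", 0.15)
  set_r("lvCEN", "SN", -0.25)
  set_r("rvCEN", "dCEN", 0.05); set_r("rvCEN", "SN", -0.15)
  set_r("dCEN", "SN", -0.20)
  r
}

#' Default ground truths
#'
#' `effect = "null"` plants identical connectivity and amplitudes in all three
#' groups (for calibration studies). `effect = "mhe"` plants the MHE-specific
#' alterations the pipeline is expected to flag: a 30 percent reduction of the
#' salience-network amplitude, a +0.3 Fisher-Z increase of aDMN-SN coupling,
#' and a +0.3 Fisher-Z shift of ipDMN-SN coupling toward zero, with NHE equal
#' to HC.
#'
#' @param effect `"null"` or `"mhe"`.
#' @param effect_size Fisher-Z shift applied to the two altered pairs
#'   (default 0.3).
#' @param ... Passed on to [ground_truth()] (e.g. `seed`, `noise_sd`,
#'   `n_per_group`, `lag_couplings`).
#' @return A [ground_truth()] object.
#' @export
default_ground_truth <- function(effect = c("null", "mhe"), effect_size = 0.3,
                                 ...) {
  effect <- match.arg(effect)
  base <- baseline_correlation()
  groups <- c("HC", "NHE", "MHE")
  labs <- network_labels()
  intra <- matrix(1, 3, 7, dimnames = list(groups, labs))
  covs <- stats::setNames(rep(list(base), 3), groups)
  if (effect == "mhe") {
    mhe <- base
    shift_z <- function(m, a, b, dz) {
      z <- atanh(m[a, b]) + dz
      m[a, b] <- m[b, a] <- tanh(z)
      m
    }
    mhe <- shift_z(mhe, "aDMN", "SN", effect_size)
    mhe <- shift_z(mhe, "ipDMN", "SN", effect_size)
    ev <- eigen(mhe, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-6) stop("MHE-modified correlation matrix not PD")
    covs$MHE <- mhe
    intra["MHE", "SN"] <- 0.7
  }
  ground_truth(mixing_cov = covs, intra_strength = intra, ...)
}

#' Simulate seven coupled network time courses
#'
#' Draws temporally white innovations with the requested instantaneous
#' covariance, adds lagged source contributions
#' (`x[target, t] <- x[target, t] + coef * x[source, t - lag]`), low-pass
#' smooths every series with a short temporal Gaussian kernel to give
#' BOLD-like autocorrelation, and standardizes each row to mean 0, SD 1.
#' Because every channel passes through the same filter, instantaneous
#' correlations are preserved by the smoothing.
#'
#' @param n_t Number of time points (>= 10).
#' @param tr Sampling interval in seconds (recorded, not used numerically).
#' @param mixing_cov 7x7 PSD covariance/correlation of the innovations.
#' @param lag_couplings See [ground_truth()]; stability is checked first.
#' @param seed Integer seed.
#' @param smooth_sd Temporal Gaussian SD in samples (default 0.8).
#' @return A `n_networks x n_t` matrix with network labels as row names.
#' @export
simulate_timecourses <- function(n_t, tr = 2, mixing_cov,
                                 lag_couplings = NULL, seed = 1L,
                                 smooth_sd = 0.8) {
  if (n_t < 10L) stop("n_t must be at least 10 (>= 50 recommended)")
  p <- nrow(mixing_cov)
  labs <- rownames(mixing_cov)
  if (is.null(labs)) labs <- network_labels()[seq_len(p)]
  if (!is.null(lag_couplings)) check_lag_stability(lag_couplings, labs)
  set.seed(seed)
  es <- eigen(mixing_cov, symmetric = TRUE)
  if (min(es$values) < -1e-8) stop("mixing_cov is not PSD")
  L <- es$vectors %*% diag(sqrt(pmax(es$values, 0)), p)
  x <- L %*% matrix(stats::rnorm(p * n_t), p, n_t)
  if (!is.null(lag_couplings)) {
    K <- max(lag_couplings$lag)
    for (tt in seq(2L, n_t)) {
      for (i in seq_len(nrow(lag_couplings))) {
        k <- lag_couplings$lag[i]
        if (tt > k) {
          tgt <- match(lag_couplings$target[i], labs)
          src <- match(lag_couplings$source[i], labs)
          x[tgt, tt] <- x[tgt, tt] + lag_couplings$coef[i] * x[src, tt - k]
        }
      }
    }
  }
  if (smooth_sd > 0) {
    k <- gaussian_kernel_1d(smooth_sd)
    r <- (length(k) - 1L) %/% 2L
    for (row in seq_len(p)) {
      padded <- c(x[row, r:1], x[row, ], x[row, n_t:(n_t - r + 1L)])
      x[row, ] <- stats::convolve(padded, k, type = "filter")
    }
  }
  x <- (x - rowMeans(x)) / apply(x, 1, stats::sd)
  rownames(x) <- labs
  x
}

#' Generate a full synthetic cohort
#'
#' Each subject's 4D volume is the amplitude-weighted sum over the seven
#' planted maps of map-by-time-course outer products plus i.i.d. Gaussian
#' noise. Covariates are drawn identically across groups (age ~ N(50, 9),
#' education ~ N(8.4, 2.8), sex ~ Bernoulli(0.77), gray-matter score ~
#' N(0.5, 0.05)) so covariate adjustment is testable under the null; PHES
#' subtests and composite are drawn around the published per-group summaries.
#' Per-subject inter-network correlation matrices jitter the group matrix by
#' `subject_sd` in Fisher-Z space (eigenvalue-clipped back to PSD when
#' needed).
#'
#' @param truth A [ground_truth()].
#' @param grid_shape Grid for the spatial maps (default 16x16x16).
#' @param n_t Time points per run (default 230 = 240 acquired volumes minus
#'   the 10 discarded, at TR 2 s).
#' @param tr Repetition time in seconds (default 2).
#' @param volumes If `FALSE`, skip building the 4D volumes (subject table,
#'   time courses and planted connectivity only) -- useful for statistical
#'   calibration studies.
#' @param keep_tcs Keep each subject's noise-free network time courses.
#' @return A `synthetic_cohort`: list with `runs` (list of [bold_run()], empty
#'   when `volumes = FALSE`), `subjects` (data.frame), `mask`, `templates`
#'   (noise-free maps), `labels`, and `truth` augmented with per-subject
#'   planted correlation (`subject_corr`) and Fisher-Z (`subject_z`) arrays
#'   and, when kept, time courses.
#' @export
generate_cohort <- function(truth, grid_shape = c(16L, 16L, 16L), n_t = 230L,
                            tr = 2, volumes = TRUE, keep_tcs = TRUE) {
  stopifnot(inherits(truth, "ground_truth"))
  set.seed(truth$seed)
  labs <- network_labels()
  nets <- make_network_maps(grid_shape, 7L, seed = truth$seed)
  mask <- brain_mask(array(TRUE, dim = grid_shape))
  groups <- rep(c("HC", "NHE", "MHE"), times = truth$n_per_group)
  n <- length(groups)
  ids <- sprintf("S%03d", seq_len(n))

  stats_tbl <- cohort_summary_stats()
  row_of <- function(v) stats_tbl[stats_tbl$variable == v, ]
  male_frac <- sum(cohort_sex_counts()[, "male"]) / sum(cohort_sex_counts())

  subjects <- data.frame(
    subject_id = ids, group = groups,
    age = round(stats::rnorm(n, 50, 9), 1),
    sex = stats::rbinom(n, 1, male_frac),
    education_years = round(pmax(stats::rnorm(n, 8.4, 2.8), 0), 1),
    gm_score = round(stats::rnorm(n, 0.5, 0.05), 4),
    stringsAsFactors = FALSE
  )
  for (v in c("nct_a_seconds", "nct_b_seconds", "serial_dotting_seconds",
              "digit_symbol_raw", "line_tracing_raw")) {
    rw <- row_of(v)
    mu <- c(HC = rw$hc_mean, NHE = rw$nhe_mean, MHE = rw$mhe_mean)[groups]
    sdv <- c(HC = rw$hc_sd, NHE = rw$nhe_sd, MHE = rw$mhe_sd)[groups]
    subjects[[v]] <- round(pmax(stats::rnorm(n, mu, sdv), 1), 1)
  }

  # per-subject planted correlation matrices (group matrix + Fisher-Z jitter)
  subject_corr <- array(NA_real_, dim = c(n, 7, 7),
                        dimnames = list(ids, labs, labs))
  subject_z <- array(NA_real_, dim = c(n, 7, 7),
                     dimnames = list(ids, labs, labs))
  ut <- upper.tri(matrix(0, 7, 7))
  for (i in seq_len(n)) {
    Sg <- truth$mixing_cov[[groups[i]]]
    z <- atanh(Sg * 0.999999)
    diag(z) <- 0
    if (truth$subject_sd > 0) {
      jit <- matrix(0, 7, 7)
      jit[ut] <- stats::rnorm(sum(ut), 0, truth$subject_sd)
      jit <- jit + t(jit)
      z <- z + jit
    }
    Si <- tanh(z)
    diag(Si) <- 1
    es <- eigen(Si, symmetric = TRUE)
    if (min(es$values) < 1e-4) {
      ev <- pmax(es$values, 1e-4)
      Si <- es$vectors %*% diag(ev) %*% t(es$vectors)
      d <- sqrt(diag(Si))
      Si <- Si / (d %o% d)
    }
    dimnames(Si) <- list(labs, labs)
    subject_corr[i, , ] <- Si
    zi <- atanh(Si * 0.999999)
    diag(zi) <- 0
    subject_z[i, , ] <- zi
  }

  # PHES composite, optionally coupled to the subject's planted pair Z
  rw <- row_of("phes_composite")
  mu <- c(HC = rw$hc_mean, NHE = rw$nhe_mean, MHE = rw$mhe_mean)[groups]
  sdv <- c(HC = rw$hc_sd, NHE = rw$nhe_sd, MHE = rw$mhe_sd)[groups]
  eps <- stats::rnorm(n)
  if (truth$phes_coupling != 0 && truth$subject_sd > 0) {
    zp <- subject_z[, truth$phes_pair[1], truth$phes_pair[2]]
    zstd <- stats::ave(zp, groups, FUN = function(v) {
      (v - mean(v)) / max(stats::sd(v), 1e-12)
    })
    rho <- truth$phes_coupling
    draw <- mu + sdv * (rho * zstd + sqrt(1 - rho^2) * eps)
  } else {
    draw <- mu + sdv * eps
  }
  subjects$phes_composite <- pmin(pmax(round(draw), -15L), 5L)

  runs <- list()
  tcs <- list()
  map_mat <- sapply(nets$maps, as.vector)   # voxels x 7
  for (i in seq_len(if (volumes || keep_tcs) n else 0L)) {
    lc <- truth$lag_couplings
    if (!is.null(lc) && "group" %in% names(lc)) {
      lc <- lc[is.na(lc$group) | lc$group == groups[i], , drop = FALSE]
      if (nrow(lc) == 0L) lc <- NULL
    }
    tc <- simulate_timecourses(n_t, tr, subject_corr[i, , ],
                               lag_couplings = lc,
                               seed = derive_seed(truth$seed, i))
    if (keep_tcs) tcs[[ids[i]]] <- tc
    if (volumes) {
      amp <- truth$intra_strength[groups[i], ]
      sig <- map_mat %*% (amp * tc)   # voxels x n_t
      if (truth$noise_sd > 0) {
        sig <- sig + stats::rnorm(length(sig), 0, truth$noise_sd)
      }
      runs[[ids[i]]] <- bold_run(array(sig, dim = c(grid_shape, n_t)),
                                 tr_seconds = tr,
                                 affine = diag(c(3, 3, 3, 1)),
                                 subject_id = ids[i])
    }
  }

  truth_out <- truth
  truth_out$subject_corr <- subject_corr
  truth_out$subject_z <- subject_z
  truth_out$maps <- nets$maps
  if (keep_tcs) truth_out$tcs <- tcs
  structure(list(runs = runs, subjects = subjects, mask = mask,
                 templates = nets$maps, labels = labs, truth = truth_out,
                 tr = tr, n_t = n_t, grid_shape = grid_shape),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d subjects (%s), grid %s, %d time points, TR %g s\n",
    nrow(x$subjects),
    paste(sprintf("%s=%d", names(table(x$subjects$group)),
                  table(x$subjects$group)), collapse = " "),
    paste(x$grid_shape, collapse = "x"), x$n_t, x$tr))
  cat(sprintf("  volumes: %s, noise_sd = %g, subject_sd = %g\n",
              if (length(x$runs)) "yes" else "no",
              x$truth$noise_sd, x$truth$subject_sd))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Volumes as per-subject NIfTI files, the mask and the labeled template maps
#' (4D, component as 4th axis) as NIfTI, the subject table as CSV, and the
#' scalar ground-truth parameters as JSON.
#'
#' @param cohort A [generate_cohort()] result (with volumes).
#' @param dir Output directory (created if missing).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (length(cohort$runs) == 0L) stop("cohort has no volumes to write")
  for (id in names(cohort$runs)) {
    write_bold(cohort$runs[[id]], file.path(dir, paste0(id, "_bold.nii.gz")))
  }
  write_nifti(array(as.numeric(cohort$mask$data), dim = cohort$grid_shape),
              file.path(dir, "mask.nii.gz"), affine = diag(c(3, 3, 3, 1)))
  tmpl <- array(unlist(cohort$templates),
                dim = c(cohort$grid_shape, length(cohort$templates)))
  write_nifti(tmpl, file.path(dir, "templates.nii.gz"),
              affine = diag(c(3, 3, 3, 1)))
  jsonlite::write_json(cohort$labels, file.path(dir, "template_labels.json"))
  write_subject_table(cohort$subjects, file.path(dir, "subjects.csv"))
  tr <- cohort$truth
  jsonlite::write_json(
    list(seed = tr$seed, noise_sd = tr$noise_sd, subject_sd = tr$subject_sd,
         n_per_group = as.list(tr$n_per_group),
         intra_strength = tr$intra_strength,
         mixing_cov = tr$mixing_cov,
         lag_couplings = tr$lag_couplings,
         phes_coupling = tr$phes_coupling, phes_pair = tr$phes_pair),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
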