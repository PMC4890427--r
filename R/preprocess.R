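#' Temporal and spatial preprocessing
#'
#' The preprocessing applied before decomposition and before inter-network
#' connectivity: discard of initial volumes (scanner equilibration), head
#' motion screening, spatial Gaussian smoothing, and per-row linear detrending
#' followed by a zero-phase frequency-domain band-pass.
#'
#' @name preprocess
NULL

#' Drop the first n volumes of a run
#'
#' @param run A [bold_run()].
#' @param n Number of initial volumes to discard (default 10, the usual
#'   scanner-calibration allowance).
#' @return A [bold_run()] with `t - n` volumes; remaining frames unchanged.
#' @export
discard_initial <- function(run, n = 10L) {
  stopifnot(inherits(run, "bold_run"))
  n <- as.integer(n)
  if (n < 0L) stop("n must be >= 0")
  t <- dim(run$data)[4]
  if (n >= t) stop("cannot discard ", n, " of ", t, " volumes")
  if (n == 0L) return(run)
  bold_run(run$data[, , , (n + 1L):t, drop = FALSE], run$tr_seconds,
           run$affine, run$subject_id)
}

#' Motion parameters and screening
#'
#' `motion_params()` holds per-volume rigid-body estimates;
#' `read_motion_params()` reads the conventional 6-column whitespace/tab
#' table (3 translations in mm, 3 rotations in degrees).
#' `motion_screen()` fails a subject whose maximum absolute translation
#' exceeds `trans_limit_mm` on any axis or whose maximum absolute rotation
#' exceeds `rot_limit_deg`. The bounds are exclusive: a maximum of exactly
#' 3.0 mm passes under the default limits ("more than" reading).
#'
#' @param translations t x 3 matrix of translations (mm).
#' @param rotations t x 3 matrix of rotations (degrees).
#' @return `motion_screen()` returns a list with `pass` (logical),
#'   `max_translation_mm` and `max_rotation_deg` (named per-axis maxima) and
#'   `failed_axes` (character).
#' @export
motion_params <- function(translations, rotations) {
  translations <- as.matrix(translations)
  rotations <- as.matrix(rotations)
  stopifnot(ncol(translations) == 3L, ncol(rotations) == 3L,
            nrow(translations) == nrow(rotations))
  if (!all(is.finite(translations)) || !all(is.finite(rotations))) {
    stop("motion parameters contain non-finite values")
  }
  colnames(translations) <- colnames(rotations) <- c("x", "y", "z")
  structure(list(translations = translations, rotations = rotations),
            class = "motion_params")
}

#' @rdname motion_params
#' @param path Path to a 6-column text file (tx ty tz rx ry rz).
#' @export
read_motion_params <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(m) != 6L) stop("expected 6 columns in motion file, got ", ncol(m))
  motion_params(m[, 1:3, drop = FALSE], m[, 4:6, drop = FALSE])
}

#' @rdname motion_params
#' @param params A `motion_params` object.
#' @param trans_limit_mm Exclusive translation limit (default 3 mm).
#' @param rot_limit_deg Exclusive rotation limit (default 3 degrees).
#' @export
motion_screen <- function(params, trans_limit_mm = 3, rot_limit_deg = 3) {
  stopifnot(inherits(params, "motion_params"))
  max_t <- apply(abs(params$translations), 2, max)
  max_r <- apply(abs(params$rotations), 2, max)
  bad_t <- max_t > trans_limit_mm
  bad_r <- max_r > rot_limit_deg
  failed <- unique(c(names(max_t)[bad_t], names(max_r)[bad_r]))
  list(pass = !any(bad_t) && !any(bad_r),
       max_translation_mm = max_t,
       max_rotation_deg = max_r,
       failed_axes = failed)
}

#' Spatial Gaussian smoothing of a run
#'
#' Per-volume separable 3D Gaussian convolution with
#' `sigma = fwhm / (2 sqrt(2 ln 2))` converted to voxel units using the voxel
#' spacing from the affine. Boundary handling is half-sample reflection, which
#' preserves each volume's mean exactly.
#'
#' @param run A [bold_run()] or a 3D array (then `voxel_mm` must be given).
#' @param fwhm_mm Full width at half maximum in millimetres; 0 is the identity.
#' @param voxel_mm Voxel spacing (scalar or length-3), required for plain
#'   arrays.
#' @return Same type as the input.
#' @export
smooth_gaussian <- function(run, fwhm_mm, voxel_mm = NULL) {
  if (fwhm_mm < 0) stop("fwhm_mm must be >= 0")
  if (inherits(run, "bold_run")) {
    voxel_mm <- sqrt(colSums(run$affine[1:3, 1:3]^2))
    if (fwhm_mm == 0) return(run)
    sigma_vox <- fwhm_to_sigma(fwhm_mm) / voxel_mm
    out <- run$data
    for (tt in seq_len(dim(out)[4])) {
      out[, , , tt] <- gaussian_smooth_3d(out[, , , tt], sigma_vox)
    }
    return(bold_run(out, run$tr_seconds, run$affine, run$subject_id))
  }
  stopifnot(length(dim(run)) == 3L)
  if (fwhm_mm == 0) return(run)
  if (is.null(voxel_mm)) stop("voxel_mm required when smoothing a plain array")
  if (length(voxel_mm) == 1L) voxel_mm <- rep(voxel_mm, 3L)
  gaussian_smooth_3d(run, fwhm_to_sigma(fwhm_mm) / voxel_mm)
}

#' Linear detrend and zero-phase band-pass filtering
#'
#' Removes each row's least-squares linear trend, then applies an ideal
#' frequency-domain band-pass that retains Fourier bins with frequency in
#' `[band_hz[1], band_hz[2]]` and zeroes all others (including DC, so output
#' rows have mean 0). Because the pass band is a binary mask in the frequency
#' domain the filter is zero-phase and idempotent.
#'
#' @param mat Rows-by-time numeric matrix (voxels or component time courses).
#' @param tr Sampling interval in seconds.
#' @param band_hz Length-2 pass band `(low, high)` in Hz, default
#'   `c(0.01, 0.08)`, the standard resting-state convention.
#' @param detrend Remove the linear trend first (default TRUE).
#' @return Matrix of the same shape with zero-mean rows.
#' @export
detrend_and_bandpass <- function(mat, tr, band_hz = c(0.01, 0.08),
                                 detrend = TRUE) {
  if (is.vector(mat)) mat <- matrix(mat, nrow = 1L)
  if (tr <= 0) stop("tr must be positive")
  nyquist <- 1 / (2 * tr)
  if (length(band_hz) != 2L || band_hz[1] < 0 || band_hz[2] <= band_hz[1] ||
      band_hz[2] >= nyquist) {
    stop(sprintf("band must satisfy 0 <= low < high < Nyquist (%.3f Hz)",
                 nyquist))
  }
  t_len <- ncol(mat)
  if (detrend) {
    x <- seq_len(t_len)
    X <- cbind(1, x - mean(x))
    beta <- solve(crossprod(X), crossprod(X, t(mat)))
    mat <- mat - t(X %*% beta)
  }
  freqs <- (seq_len(t_len) - 1L) / (t_len * tr)
  freqs <- pmin(freqs, 1 / tr - freqs)        # two-sided frequency axis
  keep <- freqs >= band_hz[1] & freqs <= band_hz[2]
  ft <- t(stats::mvfft(t(mat)))
  ft[, !keep] <- 0
  out <- Re(t(stats::mvfft(t(ft), inverse = TRUE))) / t_len
  out - rowMeans(out)
}
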