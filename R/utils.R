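#' @keywords internal
"_PACKAGE"

# FWHM of a Gaussian = 2*sqrt(2*ln 2) * sigma
FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))

#' Convert a Gaussian FWHM to its standard deviation
#' @param fwhm Full width at half maximum (any unit).
#' @return Standard deviation in the same unit.
#' @export
fwhm_to_sigma <- function(fwhm) fwhm * FWHM_TO_SIGMA

# Discrete normalized Gaussian kernel truncated at 4 sigma.
gaussian_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

# n x n convolution operator with half-sample symmetric (reflect) boundary:
# extension ... d c b a | a b c d ... ; rows and columns each sum to 1 for a
# normalized kernel, so convolution preserves per-volume means exactly.
conv_matrix_reflect <- function(n, sigma) {
  k <- gaussian_kernel_1d(sigma)
  r <- (length(k) - 1L) %/% 2L
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in (-r):r) {
      pos <- i + j
      # fold half-sample reflections back into [1, n]
      while (pos < 1L || pos > n) {
        if (pos < 1L) pos <- 1L - pos
        if (pos > n) pos <- 2L * n + 1L - pos
      }
      A[i, pos] <- A[i, pos] + k[j + r + 1L]
    }
  }
  A
}

#' Separable Gaussian smoothing of a 3D array
#'
#' Mode-k products with reflective-boundary convolution operators; preserves
#' the array mean exactly. Used by [smooth_gaussian()] and the Monte-Carlo
#' null-field simulator.
#'
#' @param arr 3D numeric array.
#' @param sigma_vox Gaussian SD in voxels (scalar or per-axis length 3).
#' @return Smoothed array of the same shape.
#' @export
gaussian_smooth_3d <- function(arr, sigma_vox) {
  dims <- dim(arr)
  stopifnot(length(dims) == 3L, length(sigma_vox) %in% c(1L, 3L))
  if (length(sigma_vox) == 1L) sigma_vox <- rep(sigma_vox, 3L)
  if (all(sigma_vox <= 0)) return(arr)
  x <- arr
  if (sigma_vox[1] > 0) {
    A <- conv_matrix_reflect(dims[1], sigma_vox[1])
    x <- array(A %*% matrix(x, nrow = dims[1]), dim = dims)
  }
  if (sigma_vox[2] > 0) {
    A <- conv_matrix_reflect(dims[2], sigma_vox[2])
    x <- aperm(array(A %*% matrix(aperm(x, c(2, 1, 3)), nrow = dims[2]),
                     dim = dims[c(2, 1, 3)]), c(2, 1, 3))
  }
  if (sigma_vox[3] > 0) {
    A <- conv_matrix_reflect(dims[3], sigma_vox[3])
    x <- aperm(array(A %*% matrix(aperm(x, c(3, 1, 2)), nrow = dims[3]),
                     dim = dims[c(3, 1, 2)]), c(2, 3, 1))
  }
  x
}

neighbor_offsets <- function(connectivity = 26L) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L)) {
    stop("connectivity must be 6, 18 or 26")
  }
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  ord <- abs(g$dx) + abs(g$dy) + abs(g$dz)
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1, "18" = ord <= 2, "26" = rep(TRUE, nrow(g)))
  as.matrix(g[keep, ])
}

#' Label connected clusters of supra-threshold voxels
#'
#' Flood-fill labelling of `TRUE` voxels in a 3D logical array under 6-, 18-
#' or 26-neighbour connectivity.
#'
#' @param supra 3D logical array.
#' @param connectivity One of 6, 18, 26.
#' @return List with `labels` (3D integer array, 0 = background), `sizes`
#'   (integer vector of cluster extents, cluster id order) and `n_clusters`.
#' @export
label_clusters <- function(supra, connectivity = 26L) {
  dims <- dim(supra)
  stopifnot(length(dims) == 3L)
  offs <- neighbor_offsets(connectivity)
  labels <- array(0L, dim = dims)
  idx_all <- which(supra)
  if (length(idx_all) == 0L) {
    return(list(labels = labels, sizes = integer(0), n_clusters = 0L))
  }
  coords <- arrayInd(idx_all, dims)
  coord_of <- matrix(0L, nrow = prod(dims), ncol = 3L)
  coord_of[idx_all, ] <- coords
  current <- 0L
  sizes <- integer(0)
  stack <- integer(length(idx_all))
  for (start in idx_all) {
    if (labels[start] != 0L) next
    current <- current + 1L
    size <- 0L
    top <- 1L
    stack[1L] <- start
    labels[start] <- current
    while (top > 0L) {
      v <- stack[top]; top <- top - 1L
      size <- size + 1L
      cx <- coord_of[v, 1L]; cy <- coord_of[v, 2L]; cz <- coord_of[v, 3L]
      for (o in seq_len(nrow(offs))) {
        nx <- cx + offs[o, 1L]; ny <- cy + offs[o, 2L]; nz <- cz + offs[o, 3L]
        if (nx < 1L || nx > dims[1] || ny < 1L || ny > dims[2] ||
            nz < 1L || nz > dims[3]) next
        ni <- nx + (ny - 1L) * dims[1] + (nz - 1L) * dims[1] * dims[2]
        if (supra[ni] && labels[ni] == 0L) {
          labels[ni] <- current
          top <- top + 1L
          if (top > length(stack)) stack <- c(stack, integer(length(stack)))
          stack[top] <- ni
        }
      }
    }
    sizes <- c(sizes, size)
  }
  list(labels = labels, sizes = sizes, n_clusters = current)
}

# Derive a stream of sub-seeds from one master seed (documented splitting
# scheme: seed_i = (master * 100003 + 7919 * i) mod (2^31 - 1)).
derive_seed <- function(master, i) {
  as.integer((as.numeric(master) * 100003 + 7919 * as.numeric(i)) %% 2147483647)
}

#' Estimate the smoothness (FWHM, in voxels) of residual maps
#'
#' Classic Gaussian-autocorrelation estimator: for a smooth Gaussian field the
#' lag-1 spatial autocorrelation along an axis satisfies
#' `rho = exp(-1 / (4 sigma^2))`, so `sigma = sqrt(-1 / (4 log rho))`. The
#' estimate is averaged over the three axes and over maps.
#'
#' @param maps Matrix (maps x voxels) of residual maps in mask raster order,
#'   or a single 3D array.
#' @param mask A [brain_mask()] giving the geometry of the raster order.
#' @return Estimated FWHM in voxel units (scalar).
#' @export
estimate_fwhm <- function(maps, mask) {
  if (is.array(maps) && length(dim(maps)) == 3L) {
    maps <- matrix(maps[mask$data], nrow = 1L)
  }
  dims <- dim(mask$data)
  idx <- which(mask$data)
  vol <- array(NA_real_, dim = dims)
  rhos <- c()
  for (m in seq_len(nrow(maps))) {
    vol[idx] <- maps[m, ]
    for (ax in 1:3) {
      shifted <- shift_array(vol, ax)
      ok <- is.finite(vol) & is.finite(shifted)
      if (sum(ok) > 10L) {
        r <- stats::cor(vol[ok], shifted[ok])
        if (is.finite(r)) rhos <- c(rhos, r)
      }
    }
  }
  rho <- mean(rhos)
  if (!is.finite(rho) || rho <= 0) return(0)
  rho <- min(rho, 0.99)
  sigma <- sqrt(-1 / (4 * log(rho)))
  sigma / FWHM_TO_SIGMA
}

shift_array <- function(vol, axis) {
  dims <- dim(vol)
  out <- array(NA_real_, dim = dims)
  if (axis == 1L) out[2:dims[1], , ] <- vol[1:(dims[1] - 1L), , ]
  if (axis == 2L) out[, 2:dims[2], ] <- vol[, 1:(dims[2] - 1L), ]
  if (axis == 3L) out[, , 2:dims[3]] <- vol[, , 1:(dims[3] - 1L)]
  out
}
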