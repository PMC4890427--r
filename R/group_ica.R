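#' Group spatial ICA: two-step PCA, Infomax, ICASSO, back-reconstruction
#'
#' Spatial group ICA in the GIFT tradition: each subject's voxels-by-time
#' matrix is reduced along time by PCA (step 1), the reduced data are
#' concatenated across subjects and reduced again (step 2), the group-level
#' whitened data are unmixed with natural-gradient Infomax (optionally
#' stabilised over repeated runs, ICASSO style), and subject-specific spatial
#' maps and time courses are recovered by GICA back-projection through the
#' stored reduction bases.
#'
#' @name group_ica
NULL

#' Two-step PCA reduction for group spatial ICA
#'
#' Step 1 reduces each subject's temporal dimension to `k_subject` principal
#' directions; step 2 concatenates the reduced data across subjects (stacking
#' reduced-time rows) and reduces to `k_group` components, which are then
#' symmetrically whitened. Both bases are stored for back-reconstruction.
#'
#' @param mats List of voxels-by-time matrices, one per subject, all with the
#'   same voxel count. Voxel time series are demeaned internally.
#' @param k_subject Step-1 retained order; default `round(1.5 * k_group)`.
#' @param k_group Step-2 (final) model order.
#' @return A `reduction_result` list: `whitened` (`k_group x voxels`, zero
#'   mean rows, identity covariance), `subject_bases` (list of `t x k_subject`
#'   orthonormal bases), `group_basis`, `whitener`, `reduced` (stacked step-1
#'   data), `variance_retained` (per step), `subject_ids`.
#' @export
two_step_pca <- function(mats, k_group, k_subject = NULL) {
  stopifnot(is.list(mats), length(mats) >= 1L)
  if (is.null(k_subject)) k_subject <- as.integer(round(1.5 * k_group))
  n_vox <- nrow(mats[[1]])
  ids <- names(mats)
  if (is.null(ids)) ids <- sprintf("subject%02d", seq_along(mats))
  subject_bases <- vector("list", length(mats))
  names(subject_bases) <- ids
  reduced <- matrix(0, nrow = k_subject * length(mats), ncol = n_vox)
  var1 <- numeric(length(mats))
  for (i in seq_along(mats)) {
    V <- mats[[i]]
    if (nrow(V) != n_vox) {
      stop("subject ", ids[i], " has ", nrow(V), " voxels, expected ", n_vox)
    }
    t_len <- ncol(V)
    if (k_subject > min(t_len, n_vox)) {
      stop("k_subject = ", k_subject, " exceeds data rank for subject ", ids[i])
    }
    V <- V - rowMeans(V)
    Ct <- crossprod(V) / n_vox            # t x t temporal covariance
    es <- eigen(Ct, symmetric = TRUE)
    ev <- pmax(es$values, 0)
    if (ev[k_subject] <= ev[1] * 1e-12 && ev[k_subject] <= 1e-12) {
      stop("k_subject = ", k_subject, " exceeds numerical rank for subject ",
           ids[i])
    }
    U <- es$vectors[, seq_len(k_subject), drop = FALSE]
    subject_bases[[i]] <- U
    reduced[((i - 1L) * k_subject + 1L):(i * k_subject), ] <- t(U) %*% t(V)
    var1[i] <- sum(ev[seq_len(k_subject)]) / max(sum(ev), 1e-300)
  }
  K <- nrow(reduced)
  if (k_group > K) stop("k_group = ", k_group, " exceeds stacked dimension ", K)
  reduced_c <- reduced - rowMeans(reduced)
  Cg <- tcrossprod(reduced_c) / n_vox
  es <- eigen(Cg, symmetric = TRUE)
  ev <- pmax(es$values, 0)
  if (ev[k_group] <= ev[1] * 1e-12 && ev[k_group] <= 1e-12) {
    stop("k_group = ", k_group, " exceeds numerical rank of stacked data")
  }
  G <- es$vectors[, seq_len(k_group), drop = FALSE]
  Z <- t(G) %*% reduced_c               # k_group x voxels, orthogonal rows
  Z <- Z - rowMeans(Z)
  Cz <- tcrossprod(Z) / ncol(Z)
  esz <- eigen(Cz, symmetric = TRUE)
  Q <- esz$vectors %*% diag(1 / sqrt(pmax(esz$values, 1e-300)), k_group) %*%
    t(esz$vectors)
  whitened <- Q %*% Z
  structure(list(
    whitened = whitened, subject_bases = subject_bases, group_basis = G,
    whitener = Q, reduced = reduced, k_subject = k_subject, k_group = k_group,
    variance_retained = c(step1 = mean(var1),
                          step2 = sum(ev[seq_len(k_group)]) /
                            max(sum(ev), 1e-300)),
    subject_ids = ids, n_vox = n_vox
  ), class = "reduction_result")
}

#' Natural-gradient Infomax ICA
#'
#' Bell-Sejnowski Infomax with the natural-gradient update
#' `W <- W + lrate * (I + (1 - 2 g(u)) u' / block) W`, logistic nonlinearity
#' `g(u) = 1 / (1 + exp(-u))`, block updates, and GIFT-style learning-rate
#' annealing (rate multiplied by `anneal` when the angle between successive
#' weight changes exceeds 60 degrees). Suited to super-Gaussian sources such
#' as sparse spatial network maps.
#'
#' @param X Whitened `k x n` matrix: rows zero mean, identity covariance
#'   (checked; tolerance 1e-4).
#' @param seed Seed for the random orthogonal initial unmixing matrix.
#' @param lrate Initial learning rate.
#' @param max_iter Maximum sweeps over the data.
#' @param tol Convergence threshold on the weight-change norm.
#' @param block Block size (default `ceiling(sqrt(n / 3))`, the GIFT default).
#' @param anneal Annealing factor applied on angle criterion.
#' @param extended Use the extended-Infomax update with per-component
#'   kurtosis-sign switching (`I - K tanh(u) u' / b - u u' / b`), which also
#'   separates sub-Gaussian sources. Default `FALSE`: the plain logistic
#'   update, the classic default for super-Gaussian spatial fMRI sources.
#' @return List with `W` (unmixing, `k x k`), `S` (sources, unit-variance
#'   rows), `A` (mixing, `solve(W)`), `iterations`, `converged`.
#' @export
infomax <- function(X, seed = 1L, lrate = 0.01, max_iter = 512L, tol = 1e-6,
                    block = NULL, anneal = 0.9, extended = FALSE) {
  k <- nrow(X)
  n <- ncol(X)
  rm_ <- rowMeans(X)
  if (max(abs(rm_)) > 1e-4) stop("infomax input rows are not zero-mean")
  Cx <- tcrossprod(X) / n
  if (max(abs(Cx - diag(k))) > 1e-4) {
    stop("infomax input is not whitened (covariance differs from identity)")
  }
  if (is.null(block)) block <- max(8L, as.integer(ceiling(sqrt(n / 3))))
  set.seed(seed)
  M <- matrix(stats::rnorm(k * k), k, k)
  W <- qr.Q(qr(M))
  I_k <- diag(k)
  old_dW <- NULL
  converged <- FALSE
  iter <- 0L
  restarts <- 0L
  perm_seed <- seed
  K <- rep(1, k)   # kurtosis signs for the extended update
  while (iter < max_iter) {
    iter <- iter + 1L
    perm_seed <- perm_seed + 1L
    set.seed(perm_seed)
    perm <- sample.int(n)
    W_prev <- W
    blow_up <- FALSE
    if (extended) {
      u_all <- W %*% X
      # Lee-Girolami-Sejnowski switching criterion
      K <- sign(colMeans(t(1 / cosh(u_all)^2)) * rowMeans(u_all^2) -
                  rowMeans(u_all * tanh(u_all)))
      K[K == 0] <- 1
    }
    for (start in seq(1L, n, by = block)) {
      idx <- perm[start:min(start + block - 1L, n)]
      u <- W %*% X[, idx, drop = FALSE]
      if (extended) {
        dW <- lrate * (I_k - (K * tanh(u)) %*% t(u) / length(idx) -
                         u %*% t(u) / length(idx)) %*% W
      } else {
        y <- 1 / (1 + exp(-u))
        dW <- lrate * (I_k + (1 - 2 * y) %*% t(u) / length(idx)) %*% W
      }
      W <- W + dW
      if (!all(is.finite(W)) || max(abs(W)) > 1e8) {
        blow_up <- TRUE
        break
      }
    }
    if (blow_up) {
      restarts <- restarts + 1L
      if (restarts > 5L) {
        stop("infomax diverged repeatedly despite learning-rate annealing")
      }
      lrate <- lrate / 2
      set.seed(seed + restarts)
      W <- qr.Q(qr(matrix(stats::rnorm(k * k), k, k)))
      old_dW <- NULL
      next
    }
    dW_full <- W - W_prev
    if (!is.null(old_dW)) {
      denom <- sqrt(sum(dW_full^2) * sum(old_dW^2))
      if (denom > 0) {
        cos_angle <- sum(dW_full * old_dW) / denom
        if (cos_angle < cos(60 * pi / 180)) lrate <- lrate * anneal
      }
    }
    old_dW <- dW_full
    if (sqrt(sum(dW_full^2)) < tol) {
      converged <- TRUE
      break
    }
  }
  S <- W %*% X
  sds <- apply(S, 1, stats::sd)
  S <- S / sds
  W <- W / sds
  list(W = W, S = S, A = solve(W), iterations = iter, converged = converged)
}

#' Amari index of a permutation matrix estimate
#'
#' Permutation- and scale-invariant distance between `P = W %*% A` and a
#' signed permutation; 0 means perfect source recovery.
#'
#' @param P Square matrix, typically estimated-unmixing times true-mixing.
#' @return Non-negative scalar.
#' @export
amari_index <- function(P) {
  P <- abs(P)
  k <- nrow(P)
  r <- sum(rowSums(P / apply(P, 1, max)) - 1)
  c_ <- sum(colSums(t(t(P) / apply(P, 2, max))) - 1)
  (r + c_) / (2 * k * (k - 1))
}

#' ICASSO-style stability analysis
#'
#' Runs Infomax `n_runs` times from different random initialisations, pools
#' all estimated components, clusters them by absolute spatial correlation
#' (agglomerative, average linkage) into `k` clusters, and returns per
#' cluster the centrotype (the member with maximal total within-cluster
#' similarity; ties broken by lowest run index) and the quality index
#' `iq = mean within-cluster similarity - mean between-cluster similarity`.
#'
#' @param X Whitened `k x n` matrix as for [infomax()].
#' @param n_runs Number of ICA repetitions (>= 2).
#' @param seed Master seed; run seeds derive from it.
#' @param seeds Optional explicit per-run seeds (length `n_runs`), e.g. to
#'   force duplicate runs.
#' @param ... Passed to [infomax()].
#' @return List with `S` (centrotype sources, `k x n`), `W` (unmixing
#'   assembled from the centrotypes), `iq` (per-cluster quality in [0, 1]),
#'   `cluster` (assignment of pooled components), `run_of`, `runs`.
#' @export
icasso <- function(X, n_runs = 20L, seed = 1L, seeds = NULL, ...) {
  if (n_runs < 2L) stop("icasso needs n_runs >= 2")
  if (is.null(seeds)) seeds <- vapply(seq_len(n_runs), derive_seed,
                                      integer(1), master = seed)
  stopifnot(length(seeds) == n_runs)
  k <- nrow(X)
  runs <- vector("list", n_runs)
  pool <- matrix(0, nrow = n_runs * k, ncol = ncol(X))
  for (r in seq_len(n_runs)) {
    fit <- infomax(X, seed = seeds[r], ...)
    runs[[r]] <- fit
    pool[((r - 1L) * k + 1L):(r * k), ] <- fit$S
  }
  sim <- abs(stats::cor(t(pool)))
  d <- stats::as.dist(1 - sim)
  cl <- stats::cutree(stats::hclust(d, method = "average"), k = k)
  run_of <- rep(seq_len(n_runs), each = k)
  centro_idx <- integer(k)
  iq <- numeric(k)
  for (cc in seq_len(k)) {
    members <- which(cl == cc)
    if (length(members) == 1L) {
      centro_idx[cc] <- members
      iq[cc] <- 1 - mean(sim[members, -members])
      next
    }
    within <- rowMeans(sim[members, members, drop = FALSE])
    best <- members[order(-within, run_of[members])][1]
    centro_idx[cc] <- best
    outside <- setdiff(seq_len(nrow(sim)), members)
    iq[cc] <- mean(sim[members, members][upper.tri(diag(length(members)))]) -
      if (length(outside)) mean(sim[members, outside]) else 0
  }
  S <- pool[centro_idx, , drop = FALSE]
  # project centrotypes back to an unmixing matrix for the whitened data
  W <- S %*% t(X) / ncol(X)
  S_hat <- W %*% X
  sds <- apply(S_hat, 1, stats::sd)
  W <- W / sds
  list(S = W %*% X, W = W, iq = pmin(pmax(iq, 0), 1), cluster = cl,
       run_of = run_of, runs = runs, centrotype_index = centro_idx)
}

#' GICA back-reconstruction of subject maps and time courses
#'
#' Given the group unmixing on the whitened data and the stored two-step PCA
#' bases, recovers for each subject a `k_group x voxels` spatial map matrix
#' (Z-scaled: spatial mean 0, SD 1 per component) and a `t x k_group` time
#' course matrix, by projecting the group mixing through the subject's
#' partition of the step-2 basis (GICA projection, the GIFT-era default).
#'
#' @param W Group unmixing matrix on the whitened data (`k_group x k_group`).
#' @param reduction A [two_step_pca()] result.
#' @return List with `subject_maps` (list of Z-scaled `k_group x voxels`
#'   matrices), `subject_tcs` (list of `t x k_group` matrices), `group_maps`
#'   (Z-scaled group sources).
#' @export
back_reconstruct <- function(W, reduction) {
  stopifnot(inherits(reduction, "reduction_result"))
  k1 <- reduction$k_subject
  G <- reduction$group_basis
  Q <- reduction$whitener
  n_sub <- length(reduction$subject_bases)
  # overall map from stacked reduced data Y to sources: S = H Y
  H <- W %*% Q %*% t(G)                 # k_group x (n_sub * k1)
  A_hat <- pracma_pinv(H)               # (n_sub * k1) x k_group
  subject_maps <- vector("list", n_sub)
  subject_tcs <- vector("list", n_sub)
  names(subject_maps) <- names(subject_tcs) <- reduction$subject_ids
  for (i in seq_len(n_sub)) {
    rows <- ((i - 1L) * k1 + 1L):(i * k1)
    Y_i <- reduction$reduced[rows, , drop = FALSE]
    A_i <- A_hat[rows, , drop = FALSE]  # k1 x k_group
    S_i <- pracma_pinv(A_i) %*% (Y_i - rowMeans(Y_i))
    subject_maps[[i]] <- zscale_rows(S_i)
    subject_tcs[[i]] <- reduction$subject_bases[[i]] %*% A_i
  }
  S_group <- W %*% reduction$whitened
  list(subject_maps = subject_maps, subject_tcs = subject_tcs,
       group_maps = zscale_rows(S_group))
}

zscale_rows <- function(M) {
  (M - rowMeans(M)) / apply(M, 1, stats::sd)
}

# Moore-Penrose pseudoinverse via SVD (tolerance-rank).
pracma_pinv <- function(M) {
  s <- svd(M)
  tol <- max(dim(M)) * max(s$d) * .Machine$double.eps
  pos <- s$d > tol
  if (!any(pos)) return(t(M) * 0)
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Run the full group spatial ICA
#'
#' Convenience wrapper: two-step PCA, Infomax (single run or ICASSO-stabilised
#' when `n_runs >= 2`), sign orientation (each component flipped so its peak
#' group-map value is positive), and GICA back-reconstruction.
#'
#' @param mats List of voxels-by-time matrices (see [two_step_pca()]).
#' @param n_components Model order (75 is the documented real-data default;
#'   use 7-20 for small synthetic grids).
#' @param n_runs ICASSO repetitions; 1 = single Infomax run.
#' @param seed Integer seed.
#' @param k_subject Step-1 order, default `round(1.5 * n_components)`.
#' @param ... Passed to [infomax()].
#' @return A `decomposition` object: `group_maps` (`k x voxels`, Z-scaled),
#'   `subject_maps`, `subject_tcs`, `n_components`, `stability_iq` (NULL for
#'   single runs), `reduction`, `W`.
#' @export
run_group_ica <- function(mats, n_components, n_runs = 1L, seed = 1L,
                          k_subject = NULL, ...) {
  red <- two_step_pca(mats, k_group = n_components, k_subject = k_subject)
  if (n_runs >= 2L) {
    fit <- icasso(red$whitened, n_runs = n_runs, seed = seed, ...)
    iq <- fit$iq
  } else {
    fit <- infomax(red$whitened, seed = seed, ...)
    iq <- NULL
  }
  W <- fit$W
  S <- W %*% red$whitened
  flip <- ifelse(apply(S, 1, max) >= abs(apply(S, 1, min)), 1, -1)
  W <- W * flip
  br <- back_reconstruct(W, red)
  structure(list(group_maps = br$group_maps, subject_maps = br$subject_maps,
                 subject_tcs = br$subject_tcs, n_components = n_components,
                 stability_iq = iq, reduction = red, W = W),
            class = "decomposition")
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf("<decomposition> %d components, %d subjects, %d voxels\n",
              x$n_components, length(x$subject_maps),
              ncol(x$group_maps)))
  if (!is.null(x$stability_iq)) {
    cat(sprintf("  ICASSO iq: min %.2f, median %.2f\n",
                min(x$stability_iq), stats::median(x$stability_iq)))
  }
  invisible(x)
}
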