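#' Intra-, inter- and time-lagged inter-network connectivity
#'
#' Three connectivity measures per subject: the intra-network voxelwise
#' Z-maps (the subject's back-reconstructed, Z-scaled component maps), the
#' 7x7 inter-network Fisher-Z matrix of pairwise time-course correlations,
#' and the salience-network-centered time-lagged Fisher-Z matrix at lags 1-3.
#'
#' @name connectivity
NULL

#' Fisher Z-transformation
#'
#' @param r Correlation value(s), `|r| < 1`.
#' @return `atanh(r)`.
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1)) {
    stop("fisher_z requires |r| < 1")
  }
  atanh(r)
}

#' Inter-network Fisher-Z connectivity matrix
#'
#' Pairwise Pearson correlations between the (detrended, band-passed) network
#' time courses, Fisher-Z transformed. The diagonal is stored as 0 and
#' flagged via the `diag_valid` attribute.
#'
#' @param tcs `n_networks x t` matrix with labeled rows.
#' @return Symmetric Fisher-Z matrix with 0 diagonal.
#' @export
inter_ifc <- function(tcs) {
  if (ncol(tcs) < 10L) stop("need at least 10 time points")
  sds <- apply(tcs, 1, stats::sd)
  if (any(sds == 0)) {
    stop("constant time course for network: ",
         paste(rownames(tcs)[sds == 0], collapse = ", "))
  }
  r <- stats::cor(t(tcs))
  off <- r[upper.tri(r)]
  if (any(abs(off) >= 1)) {
    stop("degenerate pair with |r| = 1 between networks")
  }
  z <- atanh(r)
  diag(z) <- 0
  attr(z, "diag_valid") <- FALSE
  z
}

#' Time-lagged inter-network connectivity centered on one source network
#'
#' For each target network X and lag k, correlates the source's earlier
#' samples with the target's later samples:
#' `r_k = cor(SN[1 .. t-k], X[(1+k) .. t])`, i.e. the source preceding the
#' target by k samples ("SN -> X"). Each overlapping window is standardized
#' by `cor()` itself; no padding is used. `direction = "target_leads"`
#' reverses the convention.
#'
#' @param tcs `n_networks x t` matrix with labeled rows.
#' @param lags Integer lags (default 1:3).
#' @param source Source network label (default `"SN"`).
#' @param direction `"source_leads"` (default) or `"target_leads"`.
#' @return `length(lags) x (n_networks - 1)` Fisher-Z matrix, rows named
#'   `lag1, ...`, columns the target networks.
#' @export
lagged_ifc <- function(tcs, lags = 1:3, source = "SN",
                       direction = c("source_leads", "target_leads")) {
  direction <- match.arg(direction)
  t_len <- ncol(tcs)
  if (any(lags >= t_len)) stop("lag must be smaller than the series length")
  if (t_len - max(lags) < 10L) stop("need t - max(lag) >= 10")
  if (!source %in% rownames(tcs)) stop("source network not found: ", source)
  targets <- setdiff(rownames(tcs), source)
  out <- matrix(NA_real_, length(lags), length(targets),
                dimnames = list(paste0("lag", lags), targets))
  s <- tcs[source, ]
  for (li in seq_along(lags)) {
    k <- lags[li]
    for (tg in targets) {
      x <- tcs[tg, ]
      r <- if (direction == "source_leads") {
        stats::cor(s[1:(t_len - k)], x[(1 + k):t_len])
      } else {
        stats::cor(x[1:(t_len - k)], s[(1 + k):t_len])
      }
      if (abs(r) >= 1) r <- sign(r) * (1 - 1e-12)
      out[li, tg] <- atanh(r)
    }
  }
  out
}

#' Per-subject intra-network Z-maps
#'
#' Extracts each subject's Z-scaled back-reconstructed map for each assigned
#' network component, and builds per-network group mean maps together with
#' per-network analysis masks: voxels whose one-sample t-test across subjects
#' survives Benjamini-Hochberg FDR at `q` (the conventional one-sample
#' definition of the network's spatial extent).
#'
#' @param decomp A [run_group_ica()] decomposition.
#' @param assignment A [assign_networks()] result.
#' @param mask [brain_mask()] in whose raster order the maps live.
#' @param q FDR level for the one-sample network masks (default 0.05).
#' @return List with `maps` (list per network label of `subjects x voxels`
#'   matrices), `group_mean` (list of mean map vectors), `network_mask`
#'   (list of logical vectors within the brain mask).
#' @export
intra_maps <- function(decomp, assignment, mask, q = 0.05) {
  stopifnot(inherits(decomp, "decomposition"))
  n_sub <- length(decomp$subject_maps)
  out_maps <- list()
  group_mean <- list()
  net_mask <- list()
  for (i in seq_len(nrow(assignment))) {
    lab <- assignment$label[i]
    comp <- assignment$component[i]
    M <- t(vapply(decomp$subject_maps,
                  function(sm) sm[comp, ], numeric(ncol(decomp$group_maps))))
    out_maps[[lab]] <- M
    group_mean[[lab]] <- colMeans(M)
    mu <- colMeans(M)
    se <- apply(M, 2, stats::sd) / sqrt(n_sub)
    tv <- mu / pmax(se, 1e-300)
    pv <- 2 * stats::pt(-abs(tv), df = n_sub - 1)
    rej <- fdr_bh(pv, q)$reject
    net_mask[[lab]] <- rej & (mu > 0)
  }
  list(maps = out_maps, group_mean = group_mean, network_mask = net_mask)
}
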