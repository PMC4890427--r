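#' Template-based identification of the seven triple-network components
#'
#' Among all estimated independent components, the seven subsystems of the
#' triple-network model (aDMN, ipDMN, spDMN, lvCEN, rvCEN, dCEN, SN) are
#' identified by multiple spatial regression of each labeled template map on
#' the component maps, followed by a greedy one-to-one assignment on the
#' standardized regression coefficients.
#'
#' @name network_select
NULL

#' Spatial fit of templates against component maps
#'
#' For each template, the template map is regressed jointly on all component
#' maps (multiple regression with intercept); the fit score of a
#' (template, component) pair is the standardized regression coefficient
#' `b * sd(component) / sd(template)`. Simple pairwise spatial correlations
#' are returned alongside as a diagnostic. Collinear component maps are
#' handled by a ridge term `eps` on the normal equations, with a warning when
#' the design is near-singular.
#'
#' @param ic_maps `n_components x voxels` matrix of component spatial maps.
#' @param templates Matrix `n_templates x voxels` with row names as labels,
#'   or a list of 3D arrays (optionally restricted by `mask`).
#' @param mask Optional [brain_mask()] used to vectorise template arrays.
#' @param eps Ridge added to the normal equations (default 1e-8).
#' @return List with `beta` (standardized coefficients,
#'   `n_templates x n_components`) and `correlation` (same shape).
#' @export
spatial_fit <- function(ic_maps, templates, mask = NULL, eps = 1e-8) {
  templates <- as_template_matrix(templates, mask)
  if (ncol(templates) != ncol(ic_maps)) {
    stop("templates have ", ncol(templates), " voxels but component maps have ",
         ncol(ic_maps))
  }
  if (any(apply(templates, 1, stats::sd) == 0)) {
    stop("constant template map")
  }
  X <- t(ic_maps)                       # voxels x k
  Xc <- sweep(X, 2, colMeans(X))
  sx <- apply(Xc, 2, stats::sd)
  XtX <- crossprod(Xc)
  cn <- kappa(XtX, exact = FALSE)
  if (!is.finite(cn) || cn > 1e10) {
    warning("near-collinear component maps; ridge-regularized fit")
  }
  XtX_r <- XtX + diag(eps * max(diag(XtX)), ncol(Xc))
  k <- nrow(ic_maps)
  n_t <- nrow(templates)
  beta <- matrix(0, n_t, k, dimnames = list(rownames(templates), NULL))
  for (j in seq_len(n_t)) {
    y <- templates[j, ] - mean(templates[j, ])
    b <- solve(XtX_r, crossprod(Xc, y))
    beta[j, ] <- b * sx / stats::sd(y)
  }
  corr <- stats::cor(t(templates), X)
  list(beta = beta, correlation = corr)
}

as_template_matrix <- function(templates, mask = NULL) {
  if (is.list(templates) && !is.matrix(templates)) {
    vecs <- lapply(templates, function(m) {
      if (!is.null(mask)) m[mask$data] else as.vector(m)
    })
    templates <- do.call(rbind, vecs)
  }
  if (is.null(rownames(templates))) {
    rownames(templates) <- network_labels()[seq_len(nrow(templates))]
  }
  templates
}

#' Greedy one-to-one assignment of labels to components
#'
#' Assigns labels to components in descending order of the best available
#' absolute fit score; every component is used at most once; ties are broken
#' by the lower component index. The full ranking is retained.
#'
#' @param fit A [spatial_fit()] result (or a plain score matrix with labeled
#'   rows).
#' @param labels Labels to assign; default the row names of the fit matrix.
#' @return A `network_assignment`: data.frame with columns `label`,
#'   `component`, `score`, `correlation`, plus the full `fit_matrix` as an
#'   attribute.
#' @export
assign_networks <- function(fit, labels = NULL) {
  score <- if (is.list(fit)) fit$beta else fit
  corr <- if (is.list(fit) && !is.null(fit$correlation)) fit$correlation else score
  if (!all(is.finite(score))) stop("non-finite fit scores")
  if (is.null(labels)) labels <- rownames(score)
  if (ncol(score) < length(labels)) {
    stop("fewer components (", ncol(score), ") than labels (",
         length(labels), ")")
  }
  remaining_labels <- labels
  remaining_comps <- seq_len(ncol(score))
  out <- data.frame(label = character(0), component = integer(0),
                    score = numeric(0), correlation = numeric(0),
                    stringsAsFactors = FALSE)
  while (length(remaining_labels) > 0L) {
    sub <- abs(score[remaining_labels, remaining_comps, drop = FALSE])
    best <- which(sub == max(sub), arr.ind = TRUE)
    # ties: lowest component index, then first label
    best <- best[order(remaining_comps[best[, 2]], best[, 1]), , drop = FALSE]
    lab <- remaining_labels[best[1, 1]]
    comp <- remaining_comps[best[1, 2]]
    out <- rbind(out, data.frame(
      label = lab, component = comp, score = score[lab, comp],
      correlation = corr[lab, comp], stringsAsFactors = FALSE))
    remaining_labels <- setdiff(remaining_labels, lab)
    remaining_comps <- setdiff(remaining_comps, comp)
  }
  out <- out[match(labels, out$label), ]
  rownames(out) <- NULL
  if (anyDuplicated(out$component)) stop("internal error: non-unique assignment")
  attr(out, "fit_matrix") <- score
  class(out) <- c("network_assignment", "data.frame")
  out
}
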