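#' End-to-end triple-network analysis pipeline
#'
#' Runs the full analysis on a cohort of runs: optional initial-volume
#' discard and spatial smoothing, masking, two-step PCA + Infomax (optionally
#' ICASSO-stabilised) group spatial ICA, template-based identification of the
#' seven networks, per-subject intra-network Z-maps, detrending/band-pass of
#' the assigned component time courses, and per-subject inter- and
#' time-lagged inter-network Fisher-Z matrices.
#'
#' @param runs List of [bold_run()] objects, or a `synthetic_cohort` (then
#'   `mask` and `templates` default to the cohort's).
#' @param mask A [brain_mask()].
#' @param templates Template maps (list of 3D arrays or labeled matrix).
#' @param n_components ICA model order (default 10 for synthetic grids; 75 is
#'   the documented real-data order).
#' @param n_runs ICASSO repetitions (1 = single Infomax run).
#' @param n_discard Initial volumes to drop (default 0: synthetic cohorts are
#'   generated post-discard).
#' @param fwhm_mm Spatial smoothing FWHM in mm (default 0).
#' @param band_hz Band-pass for the component time courses before
#'   connectivity (default 0.01-0.08 Hz). ICA itself runs on unfiltered
#'   (detrended-only) data; filtering applies to the extracted time courses,
#'   mirroring the conventional ordering.
#' @param lags Lags for the salience-centered lagged connectivity.
#' @param seed Integer seed for the ICA.
#' @param k_subject Step-1 PCA order override (see [two_step_pca()]).
#' @return A `triplenet_result` list: `decomposition`, `assignment`,
#'   `match_correlation` (spatial r of each assigned component to its
#'   template), `intra` ([intra_maps()] output), `inter` (list per subject of
#'   7x7 Fisher-Z matrices), `lagged` (list per subject of lag matrices),
#'   `network_tcs` (list per subject of filtered 7 x t matrices).
#' @export
run_pipeline <- function(runs, mask = NULL, templates = NULL,
                         n_components = 10L, n_runs = 1L, n_discard = 0L,
                         fwhm_mm = 0, band_hz = c(0.01, 0.08), lags = 1:3,
                         seed = 1L, k_subject = NULL) {
  if (inherits(runs, "synthetic_cohort")) {
    cohort <- runs
    runs <- cohort$runs
    if (is.null(mask)) mask <- cohort$mask
    if (is.null(templates)) templates <- cohort$templates
  }
  if (length(runs) == 0L) stop("no runs supplied")
  tr <- runs[[1]]$tr_seconds
  mats <- lapply(runs, function(r) {
    if (n_discard > 0L) r <- discard_initial(r, n_discard)
    if (fwhm_mm > 0) r <- smooth_gaussian(r, fwhm_mm)
    to_matrix(r, mask)
  })
  names(mats) <- vapply(runs, function(r) r$subject_id, character(1))

  decomp <- run_group_ica(mats, n_components = n_components,
                          n_runs = n_runs, seed = seed,
                          k_subject = k_subject)
  tmpl <- as_template_matrix(templates, mask)
  fit <- spatial_fit(decomp$group_maps, tmpl, mask = NULL)
  assignment <- assign_networks(fit)
  match_cor <- vapply(seq_len(nrow(assignment)), function(i) {
    stats::cor(decomp$group_maps[assignment$component[i], ],
               tmpl[assignment$label[i], ])
  }, numeric(1))
  names(match_cor) <- assignment$label

  intra <- intra_maps(decomp, assignment, mask)

  labs <- assignment$label
  inter <- list()
  lagged <- list()
  network_tcs <- list()
  for (id in names(decomp$subject_tcs)) {
    tc <- t(decomp$subject_tcs[[id]][, assignment$component, drop = FALSE])
    rownames(tc) <- labs
    tc_f <- detrend_and_bandpass(tc, tr = tr, band_hz = band_hz)
    rownames(tc_f) <- labs
    network_tcs[[id]] <- tc_f
    inter[[id]] <- inter_ifc(tc_f)
    lagged[[id]] <- lagged_ifc(tc_f, lags = lags)
  }
  structure(list(decomposition = decomp, assignment = assignment,
                 match_correlation = match_cor, intra = intra,
                 inter = inter, lagged = lagged, network_tcs = network_tcs,
                 mask = mask, tr = tr),
            class = "triplenet_result")
}

#' @export
print.triplenet_result <- function(x, ...) {
  cat(sprintf("<triplenet_result> %d subjects, %d components\n",
              length(x$inter), x$decomposition$n_components))
  cat("  template match |r|: ",
      paste(sprintf("%s=%.2f", names(x$match_correlation),
                    abs(x$match_correlation)), collapse = " "), "\n")
  invisible(x)
}

#' Group statistics over a pipeline result
#'
#' ANCOVA across the three groups for every unordered network pair (and
#' every lag-target cell of the lagged matrices) with BH-FDR over the 21
#' pairs, in the layout of the published connectivity tables.
#'
#' @param result A [run_pipeline()] result.
#' @param subjects Subject table aligned with the runs.
#' @param q FDR level.
#' @return List with `inter` (data.frame: pair, per-group mean and SD,
#'   F, p, p_fdr, significant) and `lagged` (same per lag).
#' @export
pipeline_group_stats <- function(result, subjects, q = 0.05) {
  design <- covariate_design(subjects)
  labs <- result$assignment$label
  ids <- subjects$subject_id
  pairs <- utils::combn(labs, 2)
  z_of <- function(id) result$inter[[id]]
  rows <- list()
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    vals <- vapply(ids, function(id) z_of(id)[a, b], numeric(1))
    an <- ancova_anova(vals, design)
    gm <- tapply(vals, subjects$group, mean)
    gs <- tapply(vals, subjects$group, stats::sd)
    rows[[j]] <- data.frame(
      pair = paste(a, b, sep = "-"), net_a = a, net_b = b,
      hc_mean = gm["HC"], hc_sd = gs["HC"], nhe_mean = gm["NHE"],
      nhe_sd = gs["NHE"], mhe_mean = gm["MHE"], mhe_sd = gs["MHE"],
      F = an$F, p = an$p, stringsAsFactors = FALSE)
  }
  inter <- do.call(rbind, rows)
  rownames(inter) <- NULL
  bh <- fdr_bh(inter$p, q)
  inter$p_fdr <- bh$p_adjusted
  inter$significant <- bh$reject

  lag_names <- rownames(result$lagged[[1]])
  targets <- colnames(result$lagged[[1]])
  lrows <- list()
  for (ln in lag_names) {
    for (tg in targets) {
      vals <- vapply(ids, function(id) result$lagged[[id]][ln, tg],
                     numeric(1))
      an <- ancova_anova(vals, design)
      lrows[[paste(ln, tg)]] <- data.frame(
        lag = ln, target = tg, F = an$F, p = an$p, stringsAsFactors = FALSE)
    }
  }
  lagged <- do.call(rbind, lrows)
  rownames(lagged) <- NULL
  # FDR within each lag over its 6 targets, as for the published lag tables
  lagged$p_fdr <- NA_real_
  lagged$significant <- NA
  for (ln in lag_names) {
    sel <- lagged$lag == ln
    bh <- fdr_bh(lagged$p[sel], q)
    lagged$p_fdr[sel] <- bh$p_adjusted
    lagged$significant[sel] <- bh$reject
  }
  list(inter = inter, lagged = lagged)
}
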