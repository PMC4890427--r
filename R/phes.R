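#' PHES composite scoring and MHE classification
#'
#' The psychometric hepatic encephalopathy score (PHES) sums banded deviation
#' scores of five paper-pencil subtests: number connection tests A and B,
#' serial dotting (all timed, slower = worse), digit symbol (raw score,
#' higher = better) and line tracing (raw score, higher = worse). Each
#' subtest contributes +1 (better than 1 SD above the norm) down to -3
#' (worse than 3 SD below), so the composite ranges over [-15, +5]. MHE is
#' diagnosed at a composite of -5 points or lower.
#'
#' @name phes_clinical
NULL

phes_subtests <- function() {
  data.frame(
    subtest = c("nct_a_seconds", "nct_b_seconds", "serial_dotting_seconds",
                "digit_symbol_raw", "line_tracing_raw"),
    higher_is_worse = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Load a PHES norm table
#'
#' CSV with columns `subtest`, `mean`, `sd` and optionally `higher_is_worse`.
#' The packaged default (`phes_norms_synthetic.csv`) is a synthetic stand-in
#' built from the healthy-control summaries of the emulated cohort; it is not
#' a published normative sample and should be replaced with population norms
#' for real use.
#'
#' @param path CSV path; default the packaged synthetic norms.
#' @return Data.frame with one row per subtest.
#' @export
load_phes_norms <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "phes_norms_synthetic.csv",
                        package = "triplenet")
  }
  norms <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subtest", "mean", "sd")
  missing <- setdiff(required, names(norms))
  if (length(missing)) stop("norm table missing columns: ",
                            paste(missing, collapse = ", "))
  if (any(norms$sd <= 0)) stop("norm SDs must be positive")
  if (!"higher_is_worse" %in% names(norms)) {
    norms <- merge(norms, phes_subtests(), by = "subtest")
  }
  norms
}

#' Compute the PHES composite for one subject record
#'
#' Each subtest value is converted to a deviation z relative to the norm
#' (sign-oriented so larger z = worse performance) and banded:
#' z < -1 gives +1 point, z in [-1, 1] gives 0, (1, 2] gives -1, (2, 3]
#' gives -2, and z > 3 gives -3. The summed composite is clamped to
#' [-15, +5].
#'
#' @param record A list/one-row data.frame with the five subtest columns
#'   (`nct_a_seconds`, `nct_b_seconds`, `serial_dotting_seconds`,
#'   `digit_symbol_raw`, `line_tracing_raw`).
#' @param norms A [load_phes_norms()] table.
#' @return Integer composite score.
#' @export
phes_score <- function(record, norms = load_phes_norms()) {
  total <- 0L
  for (i in seq_len(nrow(norms))) {
    st <- norms$subtest[i]
    val <- record[[st]]
    if (is.null(val) || length(val) != 1L || is.na(val)) {
      stop("missing subtest value: ", st)
    }
    z <- (val - norms$mean[i]) / norms$sd[i]
    if (!norms$higher_is_worse[i]) z <- -z
    pts <- if (z < -1) 1L else if (z <= 1) 0L else if (z <= 2) -1L else
      if (z <= 3) -2L else -3L
    total <- total + pts
  }
  max(min(total, 5L), -15L)
}

#' @rdname phes_score
#' @param subjects Subject data.frame; a `phes_composite` column is added or
#'   replaced.
#' @export
phes_score_table <- function(subjects, norms = load_phes_norms()) {
  subjects$phes_composite <- vapply(
    seq_len(nrow(subjects)),
    function(i) phes_score(subjects[i, ], norms), integer(1))
  subjects
}

#' Classify MHE from the PHES composite
#'
#' MHE is diagnosed when the composite is less than or equal to -5.0 points
#' (boundary inclusive).
#'
#' @param phes_composite Numeric composite score(s).
#' @return Character vector, `"MHE"` or `"not-MHE"`.
#' @export
classify_mhe <- function(phes_composite) {
  if (any(!is.finite(phes_composite))) stop("non-finite PHES composite")
  ifelse(phes_composite <= -5.0, "MHE", "not-MHE")
}
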