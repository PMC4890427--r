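#' Published cohort summary statistics
#'
#' Demographic and clinical summary statistics of the three-group cohort
#' (healthy controls HC, cirrhotic patients without minimal hepatic
#' encephalopathy NHE, and patients with MHE) that the synthetic generator
#' emulates and the demographic acceptance checks recompute. Group sizes are
#' 18 / 23 / 20.
#'
#' @return `cohort_summary_stats()`: a data.frame with one row per summary
#'   variable and per-group `mean`/`sd` columns plus `direction`
#'   (`"higher_worse"` for timed subtests). `cohort_sex_counts()`: a 3x2
#'   integer matrix of male/female counts. `reference_interfc()`: the
#'   published healthy-control mean inter-network Fisher-Z matrix (7x7,
#'   diagonal 0), useful as a reference connectivity pattern.
#' @export
cohort_summary_stats <- function() {
  df <- data.frame(
    variable = c("age", "education_years", "phes_composite",
                 "nct_a_seconds", "nct_b_seconds", "serial_dotting_seconds",
                 "digit_symbol_raw", "line_tracing_raw"),
    hc_mean  = c(50.1, 8.4, 0.44, 38.2, 63.2, 43.3, 44.9, 113.8),
    hc_sd    = c(6.6, 2.6, 2.12, 12.6, 31.2, 8.1, 9.3, 17.9),
    nhe_mean = c(50.8, 8.2, -0.87, 39.5, 73.3, 46.4, 41.6, 148.9),
    nhe_sd   = c(9.8, 2.9, 2.16, 11.7, 19.6, 9.1, 11.9, 37.0),
    mhe_mean = c(49.5, 8.6, -7.80, 57.1, 120.2, 59.1, 28.9, 183.7),
    mhe_sd   = c(9.2, 2.8, 2.28, 14.7, 47.8, 8.8, 8.4, 37.2),
    direction = c("none", "none", "higher_better", "higher_worse",
                  "higher_worse", "higher_worse", "higher_better",
                  "higher_worse"),
    stringsAsFactors = FALSE
  )
  df
}

#' @rdname cohort_summary_stats
#' @export
cohort_group_sizes <- function() c(HC = 18L, NHE = 23L, MHE = 20L)

#' @rdname cohort_summary_stats
#' @export
cohort_sex_counts <- function() {
  m <- matrix(c(13L, 5L, 19L, 4L, 15L, 5L), nrow = 3, byrow = TRUE,
              dimnames = list(c("HC", "NHE", "MHE"), c("male", "female")))
  m
}

#' @rdname cohort_summary_stats
#' @export
network_labels <- function() {
  c("aDMN", "ipDMN", "spDMN", "lvCEN", "rvCEN", "dCEN", "SN")
}

#' @rdname cohort_summary_stats
#' @export
reference_interfc <- function() {
  labs <- network_labels()
  z <- matrix(0, 7, 7, dimnames = list(labs, labs))
  set_z <- function(a, b, v) {
    z[a, b] <<- v
    z[b, a] <<- v
  }
  set_z("aDMN", "ipDMN", 0.466); set_z("aDMN", "spDMN", 0.154)
  set_z("aDMN", "SN", 0.013);    set_z("aDMN", "lvCEN", 0.435)
  set_z("aDMN", "rvCEN", 0.410); set_z("aDMN", "dCEN", -0.449)
  set_z("ipDMN", "spDMN", 1.131); set_z("ipDMN", "SN", -0.494)
  set_z("ipDMN", "lvCEN", 1.037); set_z("ipDMN", "rvCEN", 0.903)
  set_z("ipDMN", "dCEN", 0.084)
  set_z("spDMN", "SN", -0.545);  set_z("spDMN", "lvCEN", 0.539)
  set_z("spDMN", "rvCEN", 0.533); set_z("spDMN", "dCEN", 0.358)
  set_z("SN", "lvCEN", -0.320);  set_z("SN", "rvCEN", -0.226)
  set_z("SN", "dCEN", -0.256)
  set_z("lvCEN", "rvCEN", 0.984); set_z("lvCEN", "dCEN", 0.185)
  set_z("rvCEN", "dCEN", 0.001)
  z
}
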