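# Shared fixtures, built in code. Expensive objects are cached per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# a tiny 9-subject null cohort on a 12^3 grid, used by several suites
tiny_cohort <- function() {
  fixture("tiny_cohort", function() {
    truth <- default_ground_truth("null", n_per_group = c(3, 3, 3),
                                  noise_sd = 0.2, subject_sd = 0, seed = 7)
    generate_cohort(truth, grid_shape = c(12L, 12L, 12L), n_t = 120L)
  })
}

# whiten rows of a matrix (independent of the package's internal whitening)
whiten_rows <- function(X) {
  Xc <- X - rowMeans(X)
  es <- eigen(tcrossprod(Xc) / ncol(Xc), symmetric = TRUE)
  W0 <- es$vectors %*% diag(1 / sqrt(es$values), nrow(X)) %*% t(es$vectors)
  list(X = W0 %*% Xc, W0 = W0)
}

random_subjects <- function(n_per_group = c(6L, 6L, 6L), seed = 1L) {
  set.seed(seed)
  n <- sum(n_per_group)
  data.frame(
    subject_id = sprintf("T%03d", seq_len(n)),
    group = rep(c("HC", "NHE", "MHE"), times = n_per_group),
    age = rnorm(n, 50, 9), sex = rbinom(n, 1, 0.7),
    education_years = rnorm(n, 8.4, 2.8), gm_score = rnorm(n, 0.5, 0.05),
    nct_a_seconds = rnorm(n, 40, 10), nct_b_seconds = rnorm(n, 70, 20),
    serial_dotting_seconds = rnorm(n, 45, 8),
    digit_symbol_raw = rnorm(n, 44, 9), line_tracing_raw = rnorm(n, 120, 20),
    stringsAsFactors = FALSE
  )
}
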