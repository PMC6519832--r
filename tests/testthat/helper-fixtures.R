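# shared fixtures: everything is built in code at test time

ref_params <- function(...) pk_params(...)

# reference estimate with all variability switched off
zero_bsv_estimate <- function() {
  est <- reference_estimate()
  est$bsv <- 0
  est
}

# exact mono-exponential profile C(t) = c0 * exp(-k t)
monoexp_profile <- function(times, c0 = 10, k = 0.5) {
  tibble::tibble(TIME_H = times, CONC_UG_ML = c0 * exp(-k * times))
}

# study sampling schedule used throughout
study_times <- c(0, 0.25, 0.5, 0.75, 1, 1.5, 2, 2.5, 3, 4, 5, 6, 8, 12,
                 24, 36, 48)

# small canonical two-subject dataset (one IR, one GR), noise-free
canonical_dataset <- function() {
  coh <- generate_cohort(
    study_design(n_subjects = 1, arms = c("IR", "GR"), residual_cv = 0,
                 seed = 3),
    zero_bsv_estimate())
  coh$data
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_true(all(abs(actual / expected - 1) <= tol),
              label = sprintf("max rel err %.3g vs tol %.3g",
                              max(abs(actual / expected - 1)), tol))
}
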