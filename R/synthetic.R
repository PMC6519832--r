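#' Study design for a virtual dog study
#'
#' Describes a parallel-group single-dose study: arms, subjects per arm,
#' dose, sampling schedule, assay quantification limit and residual
#' error. Defaults reproduce the reference Beagle-dog design: 5 dogs per
#' arm, one 100 mg oral dose, sampling at 0, 0.25, 0.5, 0.75, 1, 1.5, 2,
#' 2.5, 3, 4, 5, 6, 8, 12, 24, 36 and 48 h, LLOQ 0.05 ug/mL, and a 10%
#' proportional residual CV (inside the assay's stated precision).
#'
#' @param n_subjects Subjects per arm (>= 1).
#' @param arms Character subset of `c("IR", "GR", "SR")`. SR arms have no
#'   mechanistic model of their own and require explicit parameters in
#'   [generate_cohort()].
#' @param dose Dose (mg).
#' @param times Sampling times (h), strictly increasing, first >= 0.
#' @param lloq Lower limit of quantification (ug/mL).
#' @param residual_cv Proportional residual error CV (fraction).
#' @param seed Master seed for cohort generation.
#' @return A list of class `pk_design`.
#' @export
study_design <- function(n_subjects = 5, arms = c("IR", "GR"), dose = 100,
                         times = .pk_default_times, lloq = 0.05,
                         residual_cv = 0.1, seed = 1) {
  stopifnot(n_subjects >= 1, all(arms %in% c("IR", "GR", "SR")),
            dose > 0, all(diff(times) > 0), times[1] >= 0, lloq >= 0,
            residual_cv >= 0)
  structure(list(n_subjects = as.integer(n_subjects), arms = arms,
                 dose = dose, times = times, lloq = lloq,
                 residual_cv = residual_cv, seed = as.integer(seed)),
            class = "pk_design")
}

#' @export
print.pk_design <- function(x, ...) {
  cat("<pk_design>", x$n_subjects, "subjects/arm;",
      paste(x$arms, collapse = "+"), "arms;", x$dose, "mg;",
      length(x$times), "samples to", max(x$times), "h; LLOQ", x$lloq,
      "ug/mL; residual CV", x$residual_cv, "; seed", x$seed, "\n")
  invisible(x)
}

#' Draw individual parameter sets from a population estimate
#'
#' Between-subject variability follows the exponential model
#' `theta_i = theta_pop * exp(eta_i)` with independent
#' `eta_i ~ N(0, omega^2)` per parameter; parameters flagged fixed are
#' identical across subjects. Reproducible given `seed`.
#'
#' @param estimate A `pk_estimate` table ([reference_estimate()],
#'   [population_estimate()] or a fit's `tidy()` output).
#' @param n Number of subjects.
#' @param seed Integer seed.
#' @param formulation `"IR"` or `"GR"`; selects which relative
#'   bioavailability (`Frel_IR`/`Frel_GR`) each subject carries.
#' @return A tibble with one row per subject: `ID`, `FORM` and the 12
#'   structural parameters.
#' @export
sample_individuals <- function(estimate, n, seed = 1, formulation = "GR") {
  estimate <- as_pk_estimate(estimate)
  stopifnot(n >= 1)
  set.seed(seed)
  draws <- purrr::map(seq_len(n), function(i) {
    eta <- draw_eta(estimate)
    p <- estimate_to_params(estimate, formulation = formulation, eta = eta)
    tibble::as_tibble(as.list(unclass(p)))
  })
  dplyr::bind_cols(
    tibble::tibble(ID = sprintf("S%03d", seq_len(n)), FORM = formulation),
    dplyr::bind_rows(draws))
}

# one eta vector (named, non-fixed parameters only) from the BSV variances
draw_eta <- function(estimate) {
  vary <- estimate[!estimate$fixed & estimate$bsv > 0, ]
  if (nrow(vary) == 0) return(NULL)
  setNames(rnorm(nrow(vary), 0, sqrt(vary$bsv)), vary$parameter)
}

#' Censor a profile at the quantification limit
#'
#' Flags concentrations below `lloq` as below-quantification (`BLQ = 1`)
#' and blanks the concentration value, the way a bioanalytical report
#' would deliver them.
#'
#' @param profile A data frame with a `CONC_UG_ML` column.
#' @param lloq Lower limit of quantification (ug/mL), >= 0.
#' @return The profile with a `BLQ` column; the number of censored
#'   records is in attribute `n_censored`.
#' @export
apply_lloq <- function(profile, lloq) {
  stopifnot(lloq >= 0, "CONC_UG_ML" %in% names(profile))
  blq <- !is.na(profile$CONC_UG_ML) & profile$CONC_UG_ML < lloq
  profile$BLQ <- as.integer(blq)
  profile$CONC_UG_ML[blq] <- NA_real_
  attr(profile, "n_censored") <- sum(blq)
  profile
}

#' Generate a virtual parallel-group study
#'
#' For each subject: draw individual parameters from the population
#' estimate (exponential BSV model), simulate the formulation's profile
#' at the design's sampling times, apply multiplicative residual noise
#' `C * (1 + eps)` with `eps ~ N(0, CV^2)` truncated at zero, and censor
#' below the LLOQ. One master seed drives per-subject substreams whose
#' seeds are recorded with the truth record, so regeneration is exact.
#'
#' @param design A [study_design()].
#' @param estimate A `pk_estimate` table used for IR and GR arms.
#' @param sr_estimate Optional `pk_estimate` for an SR arm (the package
#'   deliberately has no mechanistic SR model; an SR arm is generated
#'   descriptively from these user-supplied parameters with the same
#'   equations).
#' @param engine Integration engine, see [simulate_profile()].
#' @return A list of class `pk_cohort`: `data` (dataset tibble in the
#'   package's format), `truth` (per-subject true parameters and
#'   substream seed) and the echoed `design`.
#' @examples
#' coh <- generate_cohort(study_design(n_subjects = 2, seed = 7),
#'                        reference_estimate())
#' head(coh$data)
#' @export
generate_cohort <- function(design, estimate, sr_estimate = NULL,
                            engine = "rk45") {
  stopifnot(inherits(design, "pk_design"))
  estimate <- as_pk_estimate(estimate)
  if ("SR" %in% design$arms && is.null(sr_estimate))
    stop("an SR arm needs sr_estimate: the package has no mechanistic SR ",
         "model", call. = FALSE)
  rows <- list()
  truth <- list()
  idx <- 0L
  for (arm in design$arms) {
    est <- if (arm == "SR") as_pk_estimate(sr_estimate) else estimate
    for (i in seq_len(design$n_subjects)) {
      idx <- idx + 1L
      id <- sprintf("%s%03d", arm, i)
      sub_seed <- (design$seed * 10000L + idx * 7919L) %% .Machine$integer.max
      sim <- simulate_subject(est, arm, design, sub_seed, engine)
      rows[[idx]] <- sim$rows
      truth[[idx]] <- dplyr::bind_cols(
        tibble::tibble(ID = id, FORM = arm, seed = sub_seed), sim$params)
      rows[[idx]]$ID <- id
    }
  }
  out <- list(data = dplyr::bind_rows(rows), truth = dplyr::bind_rows(truth),
              design = design)
  class(out) <- "pk_cohort"
  out
}

simulate_subject <- function(est, arm, design, sub_seed, engine,
                             max_retries = 5) {
  form_sim <- if (arm == "IR") "IR" else "GR"
  set.seed(sub_seed)
  for (attempt in seq_len(max_retries)) {
    params_try <- try({
      eta <- draw_eta(est)
      p <- estimate_to_params(est, formulation = if (arm == "IR") "IR" else "GR",
                              eta = eta)
      tpos <- design$times[design$times > 0]
      sim <- simulate_profile(p, dose = design$dose, formulation = form_sim,
                              times = tpos, engine = engine)
      eps <- rnorm(length(tpos), 0, design$residual_cv)
      conc <- pmax(sim$CONC_UG_ML * (1 + eps), 0)
      list(p = p, conc = conc, tpos = tpos)
    }, silent = TRUE)
    if (!inherits(params_try, "try-error")) break
    message("regenerating subject after simulation failure (attempt ",
            attempt, ")")
  }
  if (inherits(params_try, "try-error"))
    stop("subject simulation failed after ", max_retries, " retries",
         call. = FALSE)
  x <- params_try
  obs_t <- design$times
  conc_full <- rep(NA_real_, length(obs_t))
  conc_full[obs_t > 0] <- x$conc
  conc_full[obs_t == 0] <- 0  # pre-dose sample
  obs <- tibble::tibble(ID = NA_character_, TIME_H = obs_t,
                        CONC_UG_ML = conc_full, BLQ = 0L,
                        DOSE_MG = NA_real_, FORM = arm, EVID = 0L)
  obs <- apply_lloq(obs, design$lloq)
  dose_row <- tibble::tibble(ID = NA_character_, TIME_H = 0,
                             CONC_UG_ML = NA_real_, BLQ = 0L,
                             DOSE_MG = design$dose, FORM = arm, EVID = 1L)
  list(rows = dplyr::bind_rows(dose_row, obs),
       params = tibble::as_tibble(as.list(unclass(x$p))))
}

#' @export
print.pk_cohort <- function(x, ...) {
  cat("<pk_cohort>", nrow(x$truth), "subjects (",
      paste(unique(x$truth$FORM), collapse = "+"), "),",
      sum(x$data$EVID == 0), "observations,",
      sum(x$data$BLQ == 1, na.rm = TRUE), "BLQ\n")
  invisible(x)
}
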