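#' Terminal slope (lambda-z) estimation
#'
#' Log-linear regression over the terminal phase of a concentration-time
#' profile. Candidate point sets are all contiguous terminal runs of at
#' least three quantifiable post-Cmax observations, excluding Cmax
#' itself; the set with the best adjusted r-squared wins, with ties
#' (within 1e-4) resolved in favour of more points — the "best fit"
#' convention of standard NCA software.
#'
#' @param profile A data frame with columns `TIME_H` and `CONC_UG_ML`
#'   (and optionally `BLQ`; flagged rows are ignored).
#' @param min_points Minimum number of terminal points (default 3).
#' @return A one-row tibble with `lambda_z` (1/h), `n_points`, `r2_adj`,
#'   `t_first`, `t_last`. All-`NA` values (with a warning) when no valid
#'   point set exists, e.g. a non-decaying tail.
#' @examples
#' prof <- tibble::tibble(TIME_H = c(4, 6, 8, 12, 24),
#'                        CONC_UG_ML = 10 * exp(-0.5 * c(4, 6, 8, 12, 24)))
#' lambda_z(prof)
#' @export
lambda_z <- function(profile, min_points = 3) {
  obs <- quantifiable_obs(profile)
  na_row <- tibble::tibble(lambda_z = NA_real_, n_points = NA_integer_,
                           r2_adj = NA_real_, t_first = NA_real_,
                           t_last = NA_real_)
  if (nrow(obs) == 0) {
    warning("lambda-z undetermined: no quantifiable observations")
    return(na_row)
  }
  imax <- which.max(obs$CONC_UG_ML)
  tail_obs <- obs[seq_len(nrow(obs)) > imax & obs$CONC_UG_ML > 0, ]
  n <- nrow(tail_obs)
  if (n < min_points) {
    warning("lambda-z undetermined: fewer than ", min_points,
            " quantifiable post-Cmax points")
    return(na_row)
  }
  best <- NULL
  for (k in seq(min_points, n)) {
    sub <- tail_obs[(n - k + 1):n, ]
    fit <- lm(log(CONC_UG_ML) ~ TIME_H, data = sub)
    slope <- coef(fit)[[2]]
    if (!is.finite(slope) || slope >= 0) next
    # summary.lm warns on machine-perfect fits; the r-squared is still 1
    r2 <- suppressWarnings(summary(fit)$r.squared)
    r2a <- 1 - (1 - r2) * (k - 1) / (k - 2)
    cand <- list(lambda = -slope, k = k, r2a = r2a,
                 t_first = sub$TIME_H[1], t_last = sub$TIME_H[k])
    if (is.null(best) || cand$r2a > best$r2a + 1e-4 ||
        (abs(cand$r2a - best$r2a) <= 1e-4 && cand$k > best$k)) {
      best <- cand
    }
  }
  if (is.null(best)) {
    warning("lambda-z undetermined: no decaying terminal point set")
    return(na_row)
  }
  tibble::tibble(lambda_z = best$lambda, n_points = as.integer(best$k),
                 r2_adj = best$r2a, t_first = best$t_first,
                 t_last = best$t_last)
}

# quantifiable observation rows, time-ordered; leading BLQ (and pre-dose
# zeros) are kept as zeros for AUC but dropped for regression
quantifiable_obs <- function(profile) {
  stopifnot(all(c("TIME_H", "CONC_UG_ML") %in% names(profile)))
  x <- profile
  if ("EVID" %in% names(x)) x <- x[x$EVID == 0, ]
  if ("BLQ" %in% names(x)) x <- x[!is.na(x$BLQ) & x$BLQ == 0, ]
  x <- x[!is.na(x$CONC_UG_ML), c("TIME_H", "CONC_UG_ML")]
  if (anyDuplicated(x$TIME_H)) stop("duplicate observation times", call. = FALSE)
  x[order(x$TIME_H), ]
}

# observation rows for AUC: leading BLQ as zero, trailing/embedded BLQ
# dropped (values beyond the last quantifiable point are not used)
auc_obs <- function(profile) {
  x <- profile
  if ("EVID" %in% names(x)) x <- x[x$EVID == 0, ]
  has_blq <- "BLQ" %in% names(x)
  if (!has_blq) return(quantifiable_obs(x))
  x <- x[order(x$TIME_H), ]
  q <- !is.na(x$BLQ) & x$BLQ == 0 & !is.na(x$CONC_UG_ML)
  if (!any(q)) return(x[0, c("TIME_H", "CONC_UG_ML")])
  first_q <- which(q)[1]
  last_q <- tail(which(q), 1)
  keep <- x[seq_len(last_q), ]
  keep$CONC_UG_ML[seq_len(nrow(keep)) < first_q] <- 0  # leading BLQ -> 0
  keep <- keep[seq_len(nrow(keep)) < first_q |
                 (!is.na(keep$BLQ) & keep$BLQ == 0), ]
  keep[, c("TIME_H", "CONC_UG_ML")]
}

#' Area under the concentration-time curve
#'
#' Trapezoidal AUC over the observed profile (`AUC_all`) with optional
#' extrapolation to infinity using the terminal slope:
#' `AUC_inf = AUC_all + C_last/lambda_z`, and the corresponding first
#' moment `AUMC_inf = AUMC_all + C_last*t_last/lambda_z +
#' C_last/lambda_z^2`. The default method is the linear trapezoid;
#' `"linuplogdown"` uses the logarithmic trapezoid on strictly
#' decreasing positive segments.
#'
#' @inheritParams lambda_z
#' @param method `"linear"` or `"linuplogdown"`.
#' @param extrapolate Extrapolate to infinity (requires a lambda-z).
#' @param lz Optional precomputed [lambda_z()] row.
#' @return A one-row tibble with `AUC_all`, `AUC_inf`, `AUMC_all`,
#'   `AUMC_inf` (ug.h/mL and ug.h^2/mL); infinity values are `NA` when
#'   lambda-z is undetermined.
#' @export
auc <- function(profile, method = c("linear", "linuplogdown"),
                extrapolate = TRUE, lz = NULL) {
  method <- match.arg(method)
  obs <- auc_obs(profile)
  stopifnot(nrow(obs) >= 2)
  tt <- obs$TIME_H
  cc <- obs$CONC_UG_ML
  n <- length(tt)
  dt <- diff(tt)
  c1 <- cc[-n]; c2 <- cc[-1]
  lin_a <- dt * (c1 + c2) / 2
  lin_m <- dt * (tt[-n] * c1 + tt[-1] * c2) / 2
  if (method == "linuplogdown") {
    logdown <- c2 < c1 & c2 > 0 & c1 > 0
    k <- log(c1[logdown] / c2[logdown]) / dt[logdown]
    lin_a[logdown] <- (c1[logdown] - c2[logdown]) / k
    # first moment of an exponential segment
    t1 <- tt[-n][logdown]; t2 <- tt[-1][logdown]
    lin_m[logdown] <- (t1 * c1[logdown] - t2 * c2[logdown]) / k +
      (c1[logdown] - c2[logdown]) / k^2
  }
  auc_all <- sum(lin_a)
  aumc_all <- sum(lin_m)
  auc_inf <- aumc_inf <- NA_real_
  if (extrapolate) {
    if (is.null(lz)) lz <- suppressWarnings(lambda_z(profile))
    if (is.finite(lz$lambda_z)) {
      clast <- cc[n]; tlast <- tt[n]
      auc_inf <- auc_all + clast / lz$lambda_z
      aumc_inf <- aumc_all + clast * tlast / lz$lambda_z +
        clast / lz$lambda_z^2
    }
  }
  tibble::tibble(AUC_all = auc_all, AUC_inf = auc_inf,
                 AUMC_all = aumc_all, AUMC_inf = aumc_inf)
}

#' Non-compartmental analysis
#'
#' Full NCA summary per subject: Cmax and Tmax read directly from the
#' observations, terminal slope and half-life from [lambda_z()],
#' trapezoidal AUC/AUMC with extrapolation, `MRT = AUMC_inf/AUC_inf`,
#' `CL/F = dose/AUC_inf` (reported in mL/min), and
#' `Vz/F = dose/(lambda_z * AUC_inf)` (L). Parameters that depend on an
#' undetermined lambda-z are reported as `NA`.
#'
#' @param data A dataset tibble in the package's format (observation rows
#'   with `ID`, `TIME_H`, `CONC_UG_ML`, `BLQ` and one `EVID = 1` dose row
#'   per subject carrying `DOSE_MG` and `FORM`), or a single-profile data
#'   frame with `TIME_H`/`CONC_UG_ML` if `dose` is given.
#' @param dose Dose (mg), only for the single-profile form.
#' @param formulation Formulation label for the single-profile form.
#' @param method AUC method, see [auc()].
#' @return A tibble with one row per subject: `ID`, `FORM`, `DOSE_MG`,
#'   `t_half`, `Tmax`, `Cmax`, `AUC_all`, `AUC_inf`, `Vz_F`, `MRT`,
#'   `CL_F`, `lambda_z`, `lambda_z_npoints`, `lambda_z_r2adj`.
#' @examples
#' sim <- simulate_profile(pk_params(Frel = 1), 100, "IR",
#'                         times = c(0.25, 0.5, 1, 2, 3, 4, 6, 8, 12, 24))
#' nca(sim, dose = 100, formulation = "IR")
#' @export
nca <- function(data, dose = NULL, formulation = NA_character_,
                method = c("linear", "linuplogdown")) {
  method <- match.arg(method)
  if (!"ID" %in% names(data)) {
    stopifnot(!is.null(dose))
    return(dplyr::bind_cols(
      tibble::tibble(ID = "1", FORM = formulation, DOSE_MG = dose),
      nca_profile(data, dose, method)))
  }
  dose_rows <- data[data$EVID == 1, , drop = FALSE]
  data |>
    dplyr::filter(.data$EVID == 0) |>
    dplyr::group_by(.data$ID) |>
    dplyr::group_modify(function(d, key) {
      dr <- dose_rows[dose_rows$ID == key$ID, ]
      if (nrow(dr) != 1)
        stop("subject ", key$ID, " must have exactly one dose row",
             call. = FALSE)
      dplyr::bind_cols(
        tibble::tibble(FORM = dr$FORM[1], DOSE_MG = dr$DOSE_MG[1]),
        nca_profile(d, dr$DOSE_MG[1], method))
    }) |>
    dplyr::ungroup()
}

nca_profile <- function(profile, dose, method = "linear") {
  obs <- quantifiable_obs(profile)
  if (nrow(obs) < 3)
    stop("NCA needs at least 3 quantifiable observations", call. = FALSE)
  imax <- which.max(obs$CONC_UG_ML)
  cmax <- obs$CONC_UG_ML[imax]
  tmax <- obs$TIME_H[imax]
  lz <- suppressWarnings(lambda_z(profile))
  a <- auc(profile, method = method, extrapolate = TRUE, lz = lz)
  t_half <- log(2) / lz$lambda_z
  mrt <- a$AUMC_inf / a$AUC_inf
  cl_f <- dose / a$AUC_inf * 1000 / 60  # L/h -> mL/min
  vz_f <- dose / (lz$lambda_z * a$AUC_inf)
  tibble::tibble(t_half = t_half, Tmax = tmax, Cmax = cmax,
                 AUC_all = a$AUC_all, AUC_inf = a$AUC_inf, Vz_F = vz_f,
                 MRT = mrt, CL_F = cl_f, lambda_z = lz$lambda_z,
                 lambda_z_npoints = lz$n_points,
                 lambda_z_r2adj = lz$r2_adj)
}

#' Group summary of NCA parameters
#'
#' Mean and standard deviation of each NCA parameter by formulation,
#' mirroring the usual per-group reporting of small crossover/parallel
#' studies.
#'
#' @param nca_table Output of [nca()].
#' @return A tibble with one row per formulation and parameter.
#' @export
nca_group_summary <- function(nca_table) {
  nca_table |>
    dplyr::select(-"ID") |>
    tidyr::pivot_longer(cols = -c("FORM", "DOSE_MG"),
                        names_to = "parameter", values_to = "value") |>
    dplyr::group_by(.data$FORM, .data$parameter) |>
    dplyr::summarise(
      n = sum(is.finite(.data$value)),
      mean = mean(.data$value, na.rm = TRUE),
      sd = sd(.data$value, na.rm = TRUE),
      .groups = "drop")
}

#' Relative bioavailability
#'
#' Dose-normalised `AUC_inf` ratio of a test formulation versus the
#' immediate-release reference, in percent:
#' `100 * (AUC_test/dose_test) / (AUC_ref/dose_ref)`.
#'
#' @param test,ref Either `AUC_inf` values (ug.h/mL) or one-row NCA
#'   tibbles carrying `AUC_inf` (and `DOSE_MG`, which then overrides the
#'   dose arguments).
#' @param dose_test,dose_ref Doses (mg).
#' @return Relative bioavailability in percent (`NA` if either AUC is
#'   missing).
#' @examples
#' frel(28.90, 23.56)  # 122.67 % for the GR system vs IR
#' @export
frel <- function(test, ref, dose_test = 100, dose_ref = 100) {
  pick <- function(x, dose) {
    if (is.data.frame(x)) {
      if ("DOSE_MG" %in% names(x)) dose <- x$DOSE_MG[1]
      x <- x$AUC_inf[1]
    }
    c(auc = x, dose = dose)
  }
  a <- pick(test, dose_test)
  b <- pick(ref, dose_ref)
  stopifnot(a[["dose"]] > 0, b[["dose"]] > 0)
  if (!is.finite(a[["auc"]]) || !is.finite(b[["auc"]])) return(NA_real_)
  100 * (a[["auc"]] / a[["dose"]]) / (b[["auc"]] / b[["dose"]])
}
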