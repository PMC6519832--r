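#' Structural model parameters
#'
#' Constructs and validates the parameter set of the gastroretentive (GR)
#' pharmacokinetic model: two-compartment disposition, transit + gut
#' absorption, and a time-varying first-order dissolution rate whose
#' activation follows a Hill-type function of time.
#'
#' Units: volumes in L, clearances in L/h, times in h, rate constants in
#' 1/h; amounts are in mg so concentrations come out in mg/L, numerically
#' identical to the reported ug/mL.
#'
#' @param V1,V2 Central and peripheral distribution volumes (L).
#' @param CL Systemic clearance (L/h).
#' @param CLD Distribution clearance between central and peripheral (L/h).
#' @param Tlag Lag time before dissolution from the GR system starts (h).
#' @param Kdiss0 Initial first-order dissolution rate constant (1/h).
#' @param Tchange50 Time after `Tlag` of half-maximal change in the
#'   dissolution rate (h).
#' @param Dissmax Maximal fractional change of the dissolution rate
#'   (dimensionless; negative values describe a slowing rate and require
#'   `1 + Dissmax >= 0`).
#' @param Hill Hill coefficient of the rate activation (dimensionless;
#'   conventionally fixed at 10, giving a near-switch-like transition).
#' @param Ka_trans Transit-to-gut rate constant (1/h).
#' @param Ka Gut-to-central absorption rate constant (1/h).
#' @param Frel Relative bioavailability versus the immediate-release
#'   reference (dimensionless; 1 for IR by definition).
#'
#' @return A named numeric vector of class `pk_params`.
#' @examples
#' p <- pk_params()           # reference GR estimates
#' kdiss_at(c(1, 6.2, 20), p)
#' @export
pk_params <- function(V1 = 8.83, V2 = 3.47, CL = 4.57, CLD = 1.75,
                      Tlag = 0.0189, Kdiss0 = 0.0683, Tchange50 = 6.15,
                      Dissmax = 7.86, Hill = 10, Ka_trans = 2.63,
                      Ka = 2.68, Frel = 1.19) {
  p <- c(V1 = V1, V2 = V2, CL = CL, CLD = CLD, Tlag = Tlag,
         Kdiss0 = Kdiss0, Tchange50 = Tchange50, Dissmax = Dissmax,
         Hill = Hill, Ka_trans = Ka_trans, Ka = Ka, Frel = Frel)
  validate_pk_params(p)
  structure(p, class = "pk_params")
}

#' Coerce to a `pk_params` vector
#'
#' Accepts a `pk_params` object, a named numeric vector or list, or a
#' one-row data frame with parameter columns; missing parameters take the
#' reference defaults.
#'
#' @param x Object to coerce.
#' @return A `pk_params` vector.
#' @export
as_pk_params <- function(x) {
  if (inherits(x, "pk_params")) return(x)
  if (is.data.frame(x)) {
    if (nrow(x) != 1L) stop("expected a one-row data frame", call. = FALSE)
    x <- unlist(x[intersect(names(x), .pk_param_names)])
  }
  x <- unlist(x)
  unknown <- setdiff(names(x), .pk_param_names)
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(pk_params, as.list(x))
}

validate_pk_params <- function(p) {
  p <- unclass(p)
  if (!all(.pk_param_names %in% names(p)))
    stop("missing parameter(s): ",
         paste(setdiff(.pk_param_names, names(p)), collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(p))) stop("parameters must be finite", call. = FALSE)
  pos <- c("V1", "V2", "CL", "CLD", "Kdiss0", "Tchange50", "Ka_trans",
           "Ka", "Frel", "Hill")
  bad <- pos[p[pos] <= 0]
  if (length(bad))
    stop("parameter(s) must be strictly positive: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (p[["Tlag"]] < 0) stop("Tlag must be >= 0", call. = FALSE)
  if (1 + p[["Dissmax"]] < 0)
    stop("1 + Dissmax must be >= 0 (asymptotic rate non-negative)",
         call. = FALSE)
  invisible(p)
}

#' @export
print.pk_params <- function(x, ...) {
  cat("<pk_params> (volumes L, clearances L/h, times h, rates 1/h)\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Reference population estimates for the acyclovir GR study
#'
#' Loads the package's canonical population-estimate table for the
#' acyclovir gastroretentive system in Beagle dogs (100 mg single oral
#' dose): population means, between-subject variability (BSV, interpreted
#' as the variance omega^2 of the log-scale random effect), relative
#' standard errors, and fixed flags. `Hill` and `Frel_IR` are fixed (10
#' and 1). Stored as a plain-text fixture under `inst/extdata`.
#'
#' @return A tibble of class `pk_estimate` with columns `parameter`,
#'   `mean`, `se_pct`, `bsv`, `bsv_se_pct`, `fixed`.
#' @examples
#' reference_estimate()
#' @export
reference_estimate <- function() {
  path <- system.file("extdata", "acyclovir_gr_poppk.csv",
                      package = "gastropk", mustWork = TRUE)
  read_estimate(path)
}

#' Read / write a population-estimate file
#'
#' The on-disk format is a comma-delimited table with header
#' `parameter,mean,se_pct,bsv,bsv_se_pct,fixed` and one row per parameter
#' using the keys `V1, V2, CL, CLD, Tlag, Kdiss0, Tchange50, Dissmax,
#' Hill, Ka_trans, Ka, Frel_IR, Frel_GR`. `bsv` holds the variance of the
#' log-scale between-subject random effect.
#'
#' @param path File path.
#' @param estimate A `pk_estimate` tibble.
#' @return `read_estimate()` returns a `pk_estimate` tibble;
#'   `write_estimate()` returns `path` invisibly.
#' @export
read_estimate <- function(path) {
  x <- tibble::as_tibble(utils::read.csv(
    path, colClasses = c(parameter = "character", mean = "numeric",
                         se_pct = "numeric", bsv = "numeric",
                         bsv_se_pct = "numeric", fixed = "logical")))
  as_pk_estimate(x)
}

#' @rdname read_estimate
#' @export
write_estimate <- function(estimate, path) {
  readr::write_csv(estimate, path)
  invisible(path)
}

.estimate_keys <- c("V1", "V2", "CL", "CLD", "Tlag", "Kdiss0", "Tchange50",
                    "Dissmax", "Hill", "Ka_trans", "Ka", "Frel_IR",
                    "Frel_GR")

#' Build a population-estimate table
#'
#' @param means Named numeric vector over the keys `V1 ... Frel_GR` (see
#'   [read_estimate()]).
#' @param bsv Named numeric vector of log-scale random-effect variances
#'   (omega^2); defaults to 0 for all parameters.
#' @param fixed Character vector of parameter names whose population mean
#'   (and BSV) must not be updated by estimation; always includes `Hill`
#'   and `Frel_IR`.
#' @return A `pk_estimate` tibble.
#' @export
population_estimate <- function(means, bsv = NULL, fixed = c("Hill", "Frel_IR")) {
  stopifnot(all(.estimate_keys %in% names(means)))
  if (is.null(bsv)) bsv <- setNames(numeric(length(.estimate_keys)), .estimate_keys)
  fixed <- union(fixed, c("Hill", "Frel_IR"))
  as_pk_estimate(tibble::tibble(
    parameter = .estimate_keys,
    mean = as.numeric(means[.estimate_keys]),
    se_pct = NA_real_,
    bsv = as.numeric(bsv[.estimate_keys] %|0|% 0),
    bsv_se_pct = NA_real_,
    fixed = .estimate_keys %in% fixed))
}

`%|0|%` <- function(x, default) {
  x[is.na(x)] <- default
  x
}

as_pk_estimate <- function(x) {
  need <- c("parameter", "mean", "bsv", "fixed")
  if (!all(need %in% names(x)))
    stop("estimate table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  missing_keys <- setdiff(.estimate_keys, x$parameter)
  if (length(missing_keys))
    stop("estimate table is missing parameter(s): ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  if (any(x$bsv < 0, na.rm = TRUE))
    stop("BSV variances must be >= 0", call. = FALSE)
  x <- x[match(.estimate_keys, x$parameter), , drop = FALSE]
  # fixed parameters are non-negotiable
  x$fixed[x$parameter %in% c("Hill", "Frel_IR")] <- TRUE
  class(x) <- c("pk_estimate", class(tibble::tibble()))
  x
}

# Resolve an estimate table to a pk_params vector for one formulation,
# applying multiplicative random effects exp(eta) where given.
estimate_to_params <- function(estimate, formulation = "GR", eta = NULL) {
  m <- setNames(estimate$mean, estimate$parameter)
  if (!is.null(eta)) {
    m[names(eta)] <- m[names(eta)] * exp(eta)
  }
  frel <- if (formulation == "IR") m[["Frel_IR"]] else m[["Frel_GR"]]
  pk_params(V1 = m[["V1"]], V2 = m[["V2"]], CL = m[["CL"]], CLD = m[["CLD"]],
            Tlag = m[["Tlag"]], Kdiss0 = m[["Kdiss0"]],
            Tchange50 = m[["Tchange50"]], Dissmax = m[["Dissmax"]],
            Hill = m[["Hill"]], Ka_trans = m[["Ka_trans"]], Ka = m[["Ka"]],
            Frel = frel)
}
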