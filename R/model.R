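#' Time-varying dissolution rate constant
#'
#' The first-order dissolution rate of the GR system is gated to zero up
#' to the lag time and then follows a Hill-type activation,
#' \deqn{K_{diss}(t) = K_{diss}(0)\,\Big[1 + Diss_{max}\,
#'   \frac{(t - T_{lag})^{H}}{T_{change50}^{H} + (t - T_{lag})^{H}}\Big],}
#' so the rate moves from `Kdiss0` towards `Kdiss0 * (1 + Dissmax)` with
#' half the change at `Tlag + Tchange50`. With the conventional Hill
#' coefficient of 10 the transition is near-switch-like, which produces
#' the biphasic in vivo release of floating tablet-in-device systems.
#'
#' @param t Time(s) since dose (h), vectorised.
#' @param params A [pk_params()] set (or anything [as_pk_params()] takes).
#' @return Dissolution rate constant(s) in 1/h (0 for `t <= Tlag`).
#' @examples
#' kdiss_at(0.0189 + 6.15, pk_params())  # half-maximal change: 0.3367
#' @export
kdiss_at <- function(t, params) {
  p <- as_pk_params(params)
  stopifnot(all(t >= 0))
  u <- t - p[["Tlag"]]
  out <- numeric(length(t))
  on <- u > 0
  if (any(on)) {
    # logistic form in log space: stable for Hill = 10 at extreme arguments
    lf <- p[["Hill"]] * (log(u[on]) - log(p[["Tchange50"]]))
    frac <- 1 / (1 + exp(-lf))
    out[on] <- pmax(p[["Kdiss0"]] * (1 + p[["Dissmax"]] * frac), 0)
  }
  out
}

#' Right-hand side of the structural model
#'
#' Amount balance for the five model compartments plus a cumulative
#' elimination bookkeeping term: GR system (undissolved drug), transit,
#' gut, central and peripheral. Dissolved drug enters the transit
#' compartment scaled by the relative bioavailability `Frel`; absorption
#' proceeds transit -> gut -> central; disposition is a standard
#' two-compartment model with clearances `CL` (elimination) and `CLD`
#' (distribution). For IR dosing the dose is placed directly in the
#' transit compartment and the GR terms vanish.
#'
#' Exposed mainly for inspection and for use with external ODE solvers;
#' the signature matches [deSolve::lsoda()].
#'
#' @param t Time (h).
#' @param state Named state vector `X_GRsystem, X_Gut_trans, X_Gut, X_c,
#'   X_p, X_elim` (mg).
#' @param params A [pk_params()] set.
#' @return A list holding the derivative vector (mg/h).
#' @export
pk_rhs <- function(t, state, params) {
  p <- as_pk_params(params)
  kd <- kdiss_at(t, p)
  C1 <- state[[4]] / p[["V1"]]
  C2 <- state[[5]] / p[["V2"]]
  list(c(
    -kd * state[[1]],
    kd * p[["Frel"]] * state[[1]] - p[["Ka_trans"]] * state[[2]],
    p[["Ka_trans"]] * state[[2]] - p[["Ka"]] * state[[3]],
    p[["Ka"]] * state[[3]] - (p[["CLD"]] + p[["CL"]]) * C1 + p[["CLD"]] * C2,
    p[["CLD"]] * (C1 - C2),
    p[["CL"]] * C1))
}

.state_names <- c("X_GRsystem", "X_Gut_trans", "X_Gut", "X_c", "X_p",
                  "X_elim")

#' Simulate a concentration-time and dissolution profile
#'
#' Solves the structural model for a single oral dose given at time 0 and
#' returns the plasma concentration (central amount / `V1`, ug/mL), the
#' fraction of dose dissolved, and the full state trajectory. The
#' fraction dissolved is taken from the state itself
#' (`1 - X_GRsystem/dose`) so simulation and dissolution outputs cannot
#' disagree; it is 1 at all times for IR dosing.
#'
#' Two integration engines are available: `"lsoda"` (default) uses the
#' stiff-capable [deSolve::lsoda()] with evaluation forced at the
#' dissolution lag and around the Hill activation midpoint, which the
#' adaptive solver could otherwise step over; `"rk45"` uses the package's
#' compiled Dormand-Prince 5(4) solver, the engine used inside population
#' estimation. Both honour the same tolerances and agree to within the
#' integration tolerance.
#'
#' @param params A [pk_params()] set.
#' @param dose Dose (mg), > 0.
#' @param formulation `"GR"` (dose enters the GR system), `"IR"` (dose
#'   enters the transit compartment) or `"bolus"` (dose enters the
#'   central compartment directly; validation route bypassing absorption).
#' @param times Strictly increasing output grid (h), first element >= 0.
#' @param engine `"lsoda"` or `"rk45"`.
#' @param rtol,atol Relative / absolute (mg) integration tolerances.
#' @return A tibble of class `pk_simulation` with columns `TIME_H`,
#'   `CONC_UG_ML`, `FRAC_DISSOLVED` and the six state columns; the dose,
#'   formulation, parameters and solver settings are carried in
#'   attributes.
#' @examples
#' sim <- simulate_profile(pk_params(), dose = 100, formulation = "GR")
#' t_percent_dissolved(sim, 80)
#' @export
simulate_profile <- function(params, dose = 100,
                             formulation = c("GR", "IR", "bolus"),
                             times = seq(0, 48, by = 0.1),
                             engine = c("lsoda", "rk45"),
                             rtol = 1e-8, atol = 1e-10) {
  p <- as_pk_params(params)
  formulation <- match.arg(formulation)
  engine <- match.arg(engine)
  stopifnot(dose > 0, length(times) >= 1, all(times >= 0),
            all(diff(times) > 0))

  states <- if (engine == "rk45") {
    pk_ode_cpp(unclass(p), .route_code(formulation), dose, times,
               rtol = rtol, atol = atol)
  } else {
    y0 <- setNames(numeric(6), .state_names)
    slot <- switch(formulation, GR = 1L, IR = 2L, bolus = 4L)
    y0[slot] <- dose
    # force evaluation at the rate switch and the activation midpoint,
    # which the adaptive solver could otherwise step over
    extra <- c(p[["Tlag"]], p[["Tlag"]] + 1e-6,
               p[["Tlag"]] + p[["Tchange50"]])
    tgrid <- sort(unique(c(0, times, extra[extra > 0 & extra < max(times)])))
    fn <- function(t, y, parms) pk_rhs(t, y, p)
    sol <- deSolve::lsoda(y0, tgrid, fn, parms = NULL,
                          rtol = rtol, atol = atol, maxsteps = 50000)
    if (attr(sol, "istate")[1] < 0)
      stop("integration failure: lsoda did not converge (istate = ",
           attr(sol, "istate")[1], ")", call. = FALSE)
    unname(sol[match(times, sol[, "time"]), -1, drop = FALSE])
  }
  states <- as.matrix(states)
  colnames(states) <- .state_names

  frac <- if (formulation == "GR") pmin(1, pmax(0, 1 - states[, 1] / dose))
          else rep(1, length(times))
  out <- tibble::tibble(
    TIME_H = times,
    CONC_UG_ML = pmax(states[, 4] / p[["V1"]], 0),
    FRAC_DISSOLVED = frac) |>
    dplyr::bind_cols(tibble::as_tibble(states))
  attr(out, "params") <- p
  attr(out, "dose") <- dose
  attr(out, "formulation") <- formulation
  attr(out, "solver") <- list(engine = engine, rtol = rtol, atol = atol)
  class(out) <- c("pk_simulation", class(out))
  out
}

# mass-balance residual of a simulated trajectory, relative to dose:
# Frel*X_GR + X_trans + X_Gut + X_c + X_p + X_elim must equal the
# bioavailable dose (Frel*dose for GR, dose otherwise) at all times
mass_balance_error <- function(sim) {
  p <- attr(sim, "params")
  dose <- attr(sim, "dose")
  gr <- attr(sim, "formulation") == "GR"
  frel <- if (gr) p[["Frel"]] else 1
  total <- frel * sim$X_GRsystem + sim$X_Gut_trans + sim$X_Gut + sim$X_c +
    sim$X_p + sim$X_elim
  max(abs(total - frel * dose)) / dose
}

#' Closed-form two-compartment bolus solution
#'
#' Biexponential concentration curve for an intravenous-type bolus into
#' the central compartment of the disposition sub-model, used as an
#' independent oracle for the numerical integrator. Macro-constants are
#' derived from `V1`, `V2`, `CL`, `CLD` in the usual way
#' (`k10 = CL/V1`, `k12 = CLD/V1`, `k21 = CLD/V2`).
#'
#' @param params A [pk_params()] set (absorption/dissolution entries are
#'   ignored).
#' @param dose Dose (mg).
#' @param times Output times (h).
#' @return A tibble with `TIME_H` and `CONC_UG_ML`.
#' @export
analytic_two_compartment <- function(params, dose = 100,
                                     times = seq(0, 48, by = 0.1)) {
  p <- as_pk_params(params)
  k10 <- p[["CL"]] / p[["V1"]]
  k12 <- p[["CLD"]] / p[["V1"]]
  k21 <- p[["CLD"]] / p[["V2"]]
  s <- k10 + k12 + k21
  disc <- sqrt(max(s^2 - 4 * k10 * k21, 0))
  alpha <- (s + disc) / 2
  beta <- (s - disc) / 2
  conc <- if (disc < 1e-12) {
    # repeated root: limit of the biexponential
    (dose / p[["V1"]]) * exp(-alpha * times) * (1 + (alpha - k21) * times)
  } else {
    (dose / p[["V1"]]) *
      ((alpha - k21) * exp(-alpha * times) -
         (beta - k21) * exp(-beta * times)) / (alpha - beta)
  }
  tibble::tibble(TIME_H = times, CONC_UG_ML = conc)
}

#' Model-predicted in vivo dissolution profile
#'
#' Fraction of the dose dissolved from the GR system over time, read
#' directly from the simulated state (`1 - X_GRsystem(t)/dose`). With a
#' positive `Dissmax` the curve is biphasic: slow constant-rate release
#' until the Hill activation raises the rate, then fast release.
#'
#' @inheritParams simulate_profile
#' @return A tibble with `TIME_H` and `FRAC_DISSOLVED` (non-decreasing,
#'   in \[0, 1\]).
#' @examples
#' diss <- dissolution_profile(pk_params())
#' t_percent_dissolved(diss, 80)  # in vivo T80, about 8.2 h
#' @export
dissolution_profile <- function(params, dose = 100,
                                times = seq(0, 48, by = 0.05),
                                engine = c("lsoda", "rk45"),
                                rtol = 1e-8, atol = 1e-10) {
  sim <- simulate_profile(params, dose = dose, formulation = "GR",
                          times = times, engine = match.arg(engine),
                          rtol = rtol, atol = atol)
  out <- sim[, c("TIME_H", "FRAC_DISSOLVED")]
  attr(out, "params") <- attr(sim, "params")
  attr(out, "dose") <- dose
  out
}

#' Time to a given percent dissolved
#'
#' Linearly interpolates the first crossing of `p` percent on a
#' non-decreasing dissolution curve, e.g. `p = 80` gives the T80. If the
#' curve never attains the target within the grid, `NA` is returned with
#' a warning rather than extrapolating.
#'
#' @param curve A data frame with columns `TIME_H` and either
#'   `FRAC_DISSOLVED` (0-1) or `PCT_DISSOLVED` (0-100), or a
#'   `pk_simulation`.
#' @param p Target percent dissolved, in (0, 100).
#' @return Interpolated time (h), or `NA_real_` if not attained.
#' @export
t_percent_dissolved <- function(curve, p = 80) {
  stopifnot(is.data.frame(curve), p > 0, p < 100)
  tt <- curve$TIME_H
  frac <- if ("FRAC_DISSOLVED" %in% names(curve)) curve$FRAC_DISSOLVED
          else if ("PCT_DISSOLVED" %in% names(curve)) curve$PCT_DISSOLVED / 100
          else stop("curve needs a FRAC_DISSOLVED or PCT_DISSOLVED column",
                    call. = FALSE)
  stopifnot(length(tt) >= 2, all(diff(tt) > 0))
  target <- p / 100
  idx <- which(frac >= target)
  if (!length(idx)) {
    warning(sprintf("curve does not attain %g%% dissolved within the grid", p))
    return(NA_real_)
  }
  i <- idx[1]
  if (frac[i] == target || i == 1) return(tt[i])
  # linear interpolation between the bracketing grid points
  tt[i - 1] + (target - frac[i - 1]) / (frac[i] - frac[i - 1]) *
    (tt[i] - tt[i - 1])
}
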