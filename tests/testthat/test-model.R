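# structural model: dissolution rate, right-hand side, simulation,
# closed-form oracle, dissolution extraction

test_that("time-varying dissolution rate follows the Hill activation", {
  p <- ref_params()
  tlag <- p[["Tlag"]]
  # gated to zero up to the lag, rate constant just after it
  expect_equal(kdiss_at(c(0, tlag / 2, tlag), p), c(0, 0, 0))
  expect_equal(kdiss_at(tlag + 1e-9, p), 0.0683, tolerance = 1e-6)
  # half-maximal change at Tlag + Tchange50
  expect_equal(kdiss_at(tlag + 6.15, p), 0.0683 * (1 + 7.86 / 2),
               tolerance = 1e-10)
  # large-argument plateau, hand-evaluated: 0.0683*(1 + 7.86e10/(1+1e10))
  expect_equal(kdiss_at(tlag + 61.5, p), 0.60513780, tolerance = 1e-6)
  # negative Dissmax decreases the rate but never below zero
  pneg <- pk_params(Dissmax = -1)
  expect_true(all(diff(kdiss_at(seq(0.1, 48, 0.5), pneg)) <= 0))
  expect_true(all(kdiss_at(seq(0.1, 48, 0.5), pneg) >= 0))
})

test_that("parameter validation rejects impossible values", {
  expect_error(pk_params(Kdiss0 = 0), "strictly positive")
  expect_error(pk_params(Tchange50 = -1), "strictly positive")
  expect_error(pk_params(Tlag = -0.1), "Tlag")
  expect_error(pk_params(Dissmax = -1.5), "Dissmax")
  expect_error(as_pk_params(c(V1 = 5, nope = 1)), "unknown parameter")
})

test_that("model right-hand side matches hand substitution and is linear", {
  p <- ref_params()
  zero <- setNames(numeric(6), c("X_GRsystem", "X_Gut_trans", "X_Gut",
                                 "X_c", "X_p", "X_elim"))
  expect_equal(unlist(pk_rhs(1, zero, p)), setNames(numeric(6), NULL))

  # C1 = 1 mg/L: dXc = -(CLD+CL), dXp = CLD, dXelim = CL
  st <- zero
  st["X_c"] <- p[["V1"]]
  d <- pk_rhs(3, st, p)[[1]]
  expect_equal(d[4], -(1.75 + 4.57), tolerance = 1e-12)
  expect_equal(d[5], 1.75, tolerance = 1e-12)
  expect_equal(d[6], 4.57, tolerance = 1e-12)

  # linearity in the state
  st2 <- setNames(c(50, 3, 2, 10, 4, 1), names(zero))
  d1 <- pk_rhs(5, st2, p)[[1]]
  d2 <- pk_rhs(5, 2 * st2, p)[[1]]
  expect_equal(d2, 2 * d1, tolerance = 1e-12)
})

test_that("GR dissolution is essentially complete by 48 h", {
  sim <- simulate_profile(ref_params(), 100, "GR",
                          times = seq(0, 48, by = 0.5))
  expect_gt(tail(sim$FRAC_DISSOLVED, 1), 0.999)
  expect_true(all(diff(sim$FRAC_DISSOLVED) >= -1e-12))
})

test_that("both integration engines agree with the closed-form bolus solution", {
  tg <- seq(0, 48, by = 0.5)
  p <- ref_params()
  a <- analytic_two_compartment(p, 100, tg)
  for (eng in c("lsoda", "rk45")) {
    s <- simulate_profile(p, 100, "bolus", times = tg, engine = eng)
    expect_lt(max(abs(s$CONC_UG_ML - a$CONC_UG_ML) /
                    pmax(a$CONC_UG_ML, 1e-300)), 1e-6)
  }
})

test_that("concentrations scale exactly with dose", {
  # the absolute tolerance is in mg, so the scale-invariant control
  # scales it with the dose; linearity is then exact on both engines
  tg <- seq(0, 48, by = 1)
  p <- ref_params()
  for (eng in c("rk45", "lsoda")) {
    s1 <- simulate_profile(p, 100, "GR", times = tg, engine = eng,
                           atol = 1e-10)
    s2 <- simulate_profile(p, 200, "GR", times = tg, engine = eng,
                           atol = 2e-10)
    nz <- s1$CONC_UG_ML > 0
    expect_lt(max(abs(s2$CONC_UG_ML[nz] / s1$CONC_UG_ML[nz] - 2)), 1e-9)
  }
})

test_that("closed-form two-compartment solution has the right limits", {
  p1 <- pk_params(CLD = 1e-12)  # effectively one-compartment
  tg <- seq(0, 24, by = 0.5)
  a <- analytic_two_compartment(p1, 100, tg)
  expect_equal(a$CONC_UG_ML, (100 / 8.83) * exp(-(4.57 / 8.83) * tg),
               tolerance = 1e-9)
  expect_equal(analytic_two_compartment(ref_params(), 100, 0)$CONC_UG_ML,
               100 / 8.83)
  # clearance identity: integral to infinity = dose / CL
  tg2 <- seq(0, 600, by = 0.01)
  a2 <- analytic_two_compartment(ref_params(), 100, tg2)
  auc_num <- sum(diff(tg2) * (head(a2$CONC_UG_ML, -1) + tail(a2$CONC_UG_ML, -1)) / 2)
  expect_equal(auc_num, 100 / 4.57, tolerance = 1e-4)
})

test_that("dissolution profile reduces to the constant-hazard closed form", {
  tg <- seq(0, 48, by = 0.1)
  p <- pk_params(Dissmax = 1e-12, Kdiss0 = 0.0683, Tlag = 0.0189)
  d <- dissolution_profile(p, 100, tg)
  closed <- 1 - exp(-0.0683 * pmax(tg - 0.0189, 0))
  expect_lt(max(abs(d$FRAC_DISSOLVED - closed)), 1e-6)
  expect_identical(d$FRAC_DISSOLVED[1], 0)
})

test_that("reference dissolution is biphasic: slow near Tchange50, above 80% by 10 h", {
  d <- dissolution_profile(ref_params(), 100, seq(0, 12, by = 0.05))
  at <- function(t) d$FRAC_DISSOLVED[which.min(abs(d$TIME_H - t))]
  expect_lt(at(6.15), 0.6)
  expect_gt(at(10), 0.8)
})

test_that("time to a percent dissolved interpolates and signals non-attainment", {
  # constant-hazard closed form inverts to Tlag + ln(5)/k for 80%
  tg <- seq(0, 60, by = 0.02)
  p <- pk_params(Dissmax = 1e-12, Kdiss0 = 0.0683, Tlag = 0.0189)
  t80 <- t_percent_dissolved(dissolution_profile(p, 100, tg), 80)
  expect_equal(t80, 0.0189 + log(5) / 0.0683, tolerance = 1e-4)

  # exact hit at a grid point returns that grid time
  step <- tibble::tibble(TIME_H = c(0, 1, 2), FRAC_DISSOLVED = c(0, 0.8, 1))
  expect_identical(t_percent_dissolved(step, 80), 1)

  # never attained: NA with a warning, no extrapolation
  flat <- tibble::tibble(TIME_H = c(0, 1, 2), FRAC_DISSOLVED = c(0, 0.1, 0.2))
  expect_warning(out <- t_percent_dissolved(flat, 80), "does not attain")
  expect_true(is.na(out))
})

test_that("mass balance holds and engines agree across random parameter draws", {
  est <- reference_estimate()
  tg <- c(0.25, 0.5, 1, 2, 4, 8, 12, 24, 48)
  set.seed(2024)
  for (i in 1:25) {
    eta <- gastropk:::draw_eta(est)
    p <- gastropk:::estimate_to_params(est, "GR", eta = eta)
    a <- simulate_profile(p, 100, "GR", times = tg, engine = "rk45")
    b <- simulate_profile(p, 100, "GR", times = tg, engine = "lsoda")
    expect_lt(gastropk:::mass_balance_error(a), 1e-6)
    expect_lt(gastropk:::mass_balance_error(b), 1e-6)
    expect_lt(max(abs(a$CONC_UG_ML - b$CONC_UG_ML)), 1e-6)
  }
})

test_that("simulation fails loudly instead of returning a wrong trajectory", {
  p <- ref_params()
  expect_error(
    gastropk:::pk_ode_cpp(unclass(p), 1L, 100, c(1, 24), max_steps = 10),
    "integration failure")
})
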