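# Population estimation: importance-sampling Monte Carlo EM (MC-PEM)
# with a per-subject two-stage estimator as initializer / cross-check.
#
# Random-effect model: theta_i = theta_pop * exp(eta_i),
# eta_i ~ N(0, Omega) with diagonal Omega (variances = the BSV column).
# Residual model: Gaussian on the concentration scale with
# sd = sqrt(sigma_add^2 + (sigma_prop * pred)^2); proportional by default.

# ---- dataset plumbing -------------------------------------------------

# split a dataset tibble into per-subject likelihood inputs; BLQ records
# are discarded from the likelihood (M1 method, LLOQ 0.05 ug/mL)
build_subjects <- function(data) {
  validate_dataset(data)
  ids <- unique(data$ID)
  purrr::map(ids, function(id) {
    d <- data[data$ID == id, ]
    dr <- d[d$EVID == 1, ]
    obs <- d[d$EVID == 0 & d$BLQ == 0 & !is.na(d$CONC_UG_ML) &
               d$TIME_H > 0 & d$CONC_UG_ML > 0, ]
    obs <- obs[order(obs$TIME_H), ]
    if (nrow(obs) < 1)
      stop("subject ", id, " has no quantifiable observations", call. = FALSE)
    list(id = id, form = dr$FORM[1], dose = dr$DOSE_MG[1],
         route = .route_code(if (dr$FORM[1] == "IR") "IR" else "GR"),
         times = obs$TIME_H, conc = obs$CONC_UG_ML)
  })
}

# expand a named eta matrix (draws x d, columns = estimate keys) into the
# 12-column theta matrix the compiled core expects, for one subject
theta_matrix <- function(means, eta, eta_names, form) {
  n <- if (is.null(eta)) 1L else nrow(eta)
  th <- matrix(rep(means[.pk_param_names2(form)], each = n), nrow = n)
  if (!is.null(eta)) {
    for (j in seq_along(eta_names)) {
      key <- eta_names[j]
      col <- .theta_col(key, form)
      if (!is.na(col)) th[, col] <- th[, col] * exp(eta[, j])
    }
  }
  th
}

# estimate keys in pk_params order, resolving Frel by formulation
.pk_param_names2 <- function(form) {
  c("V1", "V2", "CL", "CLD", "Tlag", "Kdiss0", "Tchange50", "Dissmax",
    "Hill", "Ka_trans", "Ka", if (form == "IR") "Frel_IR" else "Frel_GR")
}

# column of the 12-wide theta matrix that an estimate key maps to, or NA
# when the key does not enter this formulation (e.g. Frel_GR for IR)
.theta_col <- function(key, form) {
  if (key %in% c("Frel_IR", "Frel_GR")) {
    if ((form == "IR") == (key == "Frel_IR")) 12L else NA_integer_
  } else {
    match(key, .pk_param_names)
  }
}

# ---- likelihood -------------------------------------------------------

#' Individual likelihood contribution
#'
#' Negative Gaussian log-likelihood of one subject's quantifiable
#' observations around the model prediction, under a proportional,
#' additive or combined residual-error model
#' (`sd = sqrt(sigma_add^2 + (sigma_prop * pred)^2)`). BLQ records are
#' excluded (M1 method). Deterministic given its inputs.
#'
#' @param params A [pk_params()] set for this subject.
#' @param profile Data frame with `TIME_H`, `CONC_UG_ML` (and optional
#'   `BLQ`) observation rows.
#' @param dose Dose (mg).
#' @param formulation `"IR"` or `"GR"`.
#' @param sigma_prop Proportional error CV (fraction).
#' @param sigma_add Additive error SD (ug/mL).
#' @return Negative log-likelihood (scalar); `Inf` if the simulation
#'   fails.
#' @export
individual_objective <- function(params, profile, dose = 100,
                                 formulation = "GR", sigma_prop = 0.1,
                                 sigma_add = 0) {
  stopifnot(sigma_prop > 0 || sigma_add > 0)
  p <- as_pk_params(params)
  obs <- quantifiable_obs(profile)
  obs <- obs[obs$TIME_H > 0 & obs$CONC_UG_ML > 0, ]
  stopifnot(nrow(obs) >= 1)
  ll <- try(pk_loglik_cpp(matrix(unclass(p), nrow = 1),
                          .route_code(formulation), dose, obs$TIME_H,
                          obs$CONC_UG_ML, sigma_prop, sigma_add)$loglik,
            silent = TRUE)
  if (inherits(ll, "try-error") || !is.finite(ll)) return(Inf)
  -as.numeric(ll)
}

#' Percent prediction error
#'
#' `100 * |predicted - observed| / observed`, the absolute percent
#' prediction error used to judge model predictive performance.
#'
#' @param predicted,observed Numeric vectors (recycled).
#' @return Percent error(s); errors if any `observed` is zero.
#' @examples
#' pe_percent(11, 10)  # 10
#' @export
pe_percent <- function(predicted, observed) {
  if (any(observed == 0))
    stop("%PE is undefined for observed = 0", call. = FALSE)
  100 * abs(predicted - observed) / abs(observed)
}

# ---- two-stage estimator ----------------------------------------------

#' Two-stage population estimation
#'
#' Per-subject fits followed by log-scale pooling: population means are
#' the geometric means of the subject estimates and BSV variances the
#' sample variances of the log estimates. Each subject is fitted by
#' least squares on log concentrations (the maximum-likelihood estimate
#' under log-normally distributed residuals, which agrees with the
#' proportional-error model to first order in the CV), using repeated
#' Nelder-Mead/quasi-Newton rounds on log-transformed parameters until
#' the objective stalls; positivity holds by construction and the
#' log-scale objective avoids the spurious local minima of the
#' concentrated proportional likelihood. Deterministic; serves as
#' initializer and sanity cross-check for [fit_mcpem()].
#'
#' Within a single oral-dose profile the bioavailability is confounded
#' with the volume and clearance terms, so `Frel_GR` (and `Tlag`, which
#' lies below the first sampling time in the reference design) are held
#' at their initial values by default.
#'
#' @param data A dataset tibble (see [read_pk_dataset()] for the format).
#' @param init A `pk_estimate` table of starting values and fixed flags.
#' @param fix Extra parameters (beyond the always-fixed `Hill`,
#'   `Frel_IR`) to hold at their initial values; default
#'   `c("Tlag", "Frel_GR")`.
#' @param control Passed to [stats::optim()] for the Nelder-Mead stage.
#' @param max_rounds Maximum Nelder-Mead/BFGS restart rounds per subject
#'   (each round restarts from the best point so far; fewer rounds trade
#'   precision for speed in large simulation studies).
#' @return A `pk_fit` object; see [tidy.pk_fit()], [glance.pk_fit()],
#'   [gof_table()].
#' @export
fit_two_stage <- function(data, init, fix = c("Tlag", "Frel_GR"),
                          control = list(maxit = 3000, reltol = 1e-12),
                          max_rounds = 8) {
  init <- as_pk_estimate(init)
  subjects <- build_subjects(data)
  if (length(subjects) < 2) stop("need at least 2 subjects", call. = FALSE)
  fixed_keys <- union(init$parameter[init$fixed], fix)
  means0 <- setNames(init$mean, init$parameter)

  fits <- purrr::map(subjects, function(s) {
    free <- setdiff(.pk_param_names2(s$form), fixed_keys)
    # drop dissolution parameters for IR subjects: the GR system never
    # enters their equations
    if (s$form == "IR")
      free <- setdiff(free, c("Tlag", "Kdiss0", "Tchange50", "Dissmax"))
    lp0 <- log(means0[free])
    obj <- function(lp) {
      # keep the search inside a generous box around the start: beyond
      # ~e^4 the model is physiologically meaningless and the solver slow
      if (any(abs(lp - lp0) > 4)) return(1e10 + sum((lp - lp0)^2))
      m <- means0
      m[free] <- exp(lp)
      f <- try(conc_for(m, s), silent = TRUE)
      if (inherits(f, "try-error") || any(!is.finite(f)) || any(f <= 0))
        return(1e10)
      sum((log(s$conc) - log(f))^2)
    }
    res <- try({
      par <- lp0
      val <- Inf
      for (round in seq_len(max_rounds)) {
        nm <- optim(par, obj, method = "Nelder-Mead", control = control)
        bf <- try(optim(nm$par, obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14)),
                  silent = TRUE)
        cand <- if (!inherits(bf, "try-error") && bf$value <= nm$value)
          bf else nm
        stalled <- val - cand$value < 1e-10
        par <- cand$par
        val <- cand$value
        if (stalled) break
      }
      list(par = par, value = val)
    }, silent = TRUE)
    if (inherits(res, "try-error") || !all(is.finite(res$par))) return(NULL)
    est <- means0
    est[free] <- exp(res$par)
    f <- conc_for(est, s)
    list(id = s$id, form = s$form, free = free, est = est,
         cv2 = mean(((s$conc - f) / f)^2), n = length(s$times))
  })
  ok <- !purrr::map_lgl(fits, is.null)
  if (sum(ok) < length(fits))
    warning(sum(!ok), " subject(s) excluded for non-convergence")
  fits <- fits[ok]
  if (length(fits) < 2)
    stop("fewer than 2 subjects converged", call. = FALSE)

  est <- init
  est$se_pct <- NA_real_
  est$bsv_se_pct <- NA_real_
  for (key in setdiff(.estimate_keys, fixed_keys)) {
    vals <- purrr::map_dbl(fits, function(f)
      if (key %in% f$free) f$est[[key]] else NA_real_)
    vals <- vals[is.finite(vals)]
    if (length(vals) >= 1) {
      est$mean[est$parameter == key] <- exp(mean(log(vals)))
      est$bsv[est$parameter == key] <-
        if (length(vals) >= 2) var(log(vals)) else 0
    }
  }
  sigma <- sqrt(sum(purrr::map_dbl(fits, ~ .x$cv2 * .x$n)) /
                  sum(purrr::map_dbl(fits, "n")))
  individual <- purrr::map_dfr(fits, function(f)
    dplyr::bind_cols(tibble::tibble(ID = f$id, FORM = f$form),
                     tibble::as_tibble(as.list(f$est[.pk_param_names2(f$form)] |>
                                                 setNames(.pk_param_names)))))
  new_pk_fit(estimate = as_pk_estimate(est), sigma_prop = sigma,
             method = "two-stage", individual = individual,
             n_subjects = length(fits),
             n_obs = sum(purrr::map_dbl(fits, "n")), trace = NULL,
             logLik = NA_real_)
}

# typical concentration at a subject's sampling times for estimate means m
conc_for <- function(m, s) {
  th <- theta_matrix(m, NULL, NULL, s$form)
  st <- pk_ode_cpp(th[1, ], s$route, s$dose, s$times, max_steps = 2e5)
  st[, 4] / th[1, 1]
}

# ---- MC-PEM -----------------------------------------------------------

#' Population estimation by importance-sampling Monte Carlo EM
#'
#' Parametric EM for the nonlinear mixed-effects model with exponential
#' between-subject variability. E-step: for each subject, draw
#' random-effect samples from a full-covariance Gaussian importance
#' proposal and weight by `likelihood x prior / proposal`; the proposal
#' is centred on the subject's conditional mode (found by a
#' warm-started quasi-Newton search) with a Laplace covariance from a
#' batched finite-difference Hessian whenever the previous effective
#' sample size was poor, and refreshed from the weighted posterior
#' moments (mean and covariance, mildly inflated) otherwise.
#' Random-effect dimensions a formulation cannot inform (the
#' dissolution machinery of IR subjects) keep the prior as proposal and
#' contribute their exact prior moments. M-step: closed-form update of
#' the log-scale population means, the diagonal BSV variances and the
#' residual-error parameter from the weighted moments; parameters
#' flagged fixed are never updated.
#'
#' @param data Dataset tibble (IR and/or GR arms).
#' @param init `pk_estimate` starting values; BSV entries of zero freeze
#'   that random effect at zero (EM cannot leave an exact zero).
#' @param n_samples Importance samples per subject and iteration
#'   (>= 100).
#' @param n_iter EM iterations.
#' @param seed Integer seed; all Monte Carlo draws derive from it.
#' @param error_model `"proportional"` (default) or `"additive"`.
#' @param sigma_init Initial residual parameter (CV for proportional,
#'   ug/mL for additive).
#' @param verbose Print per-iteration progress (time, marginal
#'   likelihood, effective sample sizes).
#' @param common_rng Reuse one set of standard-normal draws across
#'   iterations (common random numbers; gives a monotone marginal
#'   likelihood up to Monte Carlo error).
#' @param ess_floor Fraction of `n_samples` below which the proposal is
#'   rebuilt at the conditional mode (and inflated, with a warning).
#' @param rtol,atol Integration tolerances of the likelihood engine
#'   (default 1e-5/1e-7: estimation needs far less than the reporting
#'   tolerance of [simulate_profile()], and the Monte Carlo error of the
#'   E-step dominates).
#' @return A `pk_fit` with the estimate table, residual estimate,
#'   per-iteration `trace`, and per-subject empirical-Bayes parameter
#'   sets (`individual`).
#' @export
fit_mcpem <- function(data, init, n_samples = 1000, n_iter = 100, seed = 1,
                      error_model = c("proportional", "additive"),
                      sigma_init = 0.15, common_rng = FALSE,
                      ess_floor = 0.02, rtol = 1e-5, atol = 1e-7,
                      verbose = FALSE) {
  error_model <- match.arg(error_model)
  init <- as_pk_estimate(init)
  stopifnot(n_samples >= 100, n_iter >= 1)
  subjects <- build_subjects(data)
  ns <- length(subjects)

  eta_keys <- init$parameter[!init$fixed & init$bsv > 1e-10]
  d <- length(eta_keys)
  if (d == 0) stop("no non-fixed parameters with positive BSV", call. = FALSE)
  mean_keys <- init$parameter[!init$fixed]

  mu <- log(setNames(init$mean, init$parameter))  # log-scale means (all keys)
  omega2 <- setNames(init$bsv[match(eta_keys, init$parameter)], eta_keys)
  sigma <- sigma_init

  act_list <- purrr::map(subjects, ~ active_dims(eta_keys, .x$form))
  # per-subject proposal over the active dimensions: mean and upper
  # Cholesky factor of the covariance (cov = t(R) %*% R)
  prop <- purrr::map(act_list, function(act)
    list(m = numeric(sum(act)), R = diag(sqrt(omega2[act]), sum(act))))
  need_hess <- rep(TRUE, ns)
  inflate <- rep(1, ns)

  set.seed(seed)
  z_common <- if (common_rng)
    purrr::map(seq_len(ns), ~ matrix(rnorm(n_samples * d), n_samples, d))
  else NULL

  trace <- vector("list", n_iter)
  eta_hat <- matrix(0, ns, d, dimnames = list(NULL, eta_keys))

  for (it in seq_len(n_iter)) {
    it_t0 <- Sys.time()
    sum_eta <- numeric(d)
    sum_eta2 <- numeric(d)
    sum_rss <- 0
    n_obs <- 0
    loglik <- 0
    low_ess <- 0L
    min_ess <- Inf

    means <- exp(mu)
    for (i in seq_len(ns)) {
      s <- subjects[[i]]
      act <- act_list[[i]]
      da <- sum(act)
      z <- if (common_rng) z_common[[i]] else
        matrix(rnorm(n_samples * d), n_samples, d)

      # re-centre the proposal on the conditional mode every iteration:
      # self-normalised importance weights are biased toward the
      # proposal centre at modest effective sample sizes, and a lagging
      # centre stalls the EM mean updates. The Laplace covariance is
      # refreshed periodically and whenever the weights degenerated.
      refresh_R <- need_hess[i] || it <= 2 || it %% 5 == 0
      lap <- conditional_laplace(prop[[i]]$m, act, means, eta_keys, s,
                                 sigma, error_model, omega2, rtol, atol,
                                 do_hessian = refresh_R)
      prop[[i]]$m <- lap$m
      if (!is.null(lap$R)) {
        prop[[i]]$R <- lap$R
        inflate[i] <- 1
      }
      m <- prop[[i]]$m
      R <- prop[[i]]$R * inflate[i]
      za <- z[, act, drop = FALSE]
      eta <- matrix(0, n_samples, d)
      eta[, act] <- sweep(za %*% R, 2, m, `+`)
      if (da < d)  # inert dimensions: proposal == prior, ratio == 1
        eta[, !act] <- sweep(z[, !act, drop = FALSE], 2,
                             sqrt(omega2[!act]), `*`)

      th <- theta_matrix(means, eta, eta_keys, s$form)
      lk <- pk_loglik_cpp(th, s$route, s$dose, s$times, s$conc,
                          if (error_model == "proportional") sigma else 0,
                          if (error_model == "additive") sigma else 0,
                          rtol = rtol, atol = atol)
      ea <- eta[, act, drop = FALSE]
      lp <- rowSums(sweep(-0.5 * sweep(ea, 2, sqrt(omega2[act]), `/`)^2,
                          2, 0.5 * log(2 * pi * omega2[act]), `-`))
      lq <- -0.5 * rowSums(za^2) - sum(log(diag(R))) -
        da / 2 * log(2 * pi)
      lw <- lk$loglik + lp - lq
      ok <- is.finite(lw)
      if (!any(ok)) {
        warning("subject ", s$id, ": all importance weights non-finite at ",
                "iteration ", it, "; subject skipped this iteration")
        inflate[i] <- min(inflate[i] * 1.5, 3)
        need_hess[i] <- TRUE
        next
      }
      mx <- max(lw[ok])
      w <- ifelse(ok, exp(lw - mx), 0)
      loglik <- loglik + mx + log(mean(w))
      w <- w / sum(w)
      ess <- 1 / sum(w^2)
      min_ess <- min(min_ess, ess)
      if (ess < ess_floor * n_samples) {
        low_ess <- low_ess + 1L
        inflate[i] <- min(inflate[i] * 1.2, 2)
        need_hess[i] <- TRUE
      } else {
        inflate[i] <- max(inflate[i] / 1.1, 1)
        need_hess[i] <- FALSE
      }

      em <- colSums(w * eta)
      ev <- colSums(w * eta^2)
      em[!act] <- 0                 # exact prior moments, no MC noise
      ev[!act] <- omega2[!act]
      sum_eta <- sum_eta + em
      sum_eta2 <- sum_eta2 + ev
      sum_rss <- sum_rss + sum(w * (if (error_model == "proportional")
        lk$rss_prop else lk$rss_add))
      n_obs <- n_obs + length(s$times)
      eta_hat[i, ] <- em

      # refresh the proposal covariance from the weighted posterior
      # moments when the sample supports it (the centre comes from the
      # conditional mode next iteration)
      prop[[i]]$m <- em[act]
      if (ess >= max(15, ess_floor * n_samples)) {
        C <- crossprod(sqrt(w) * sweep(ea, 2, em[act], `-`)) * 1.15^2 +
          diag(1e-6, da)
        Rn <- try(chol(C), silent = TRUE)
        if (!inherits(Rn, "try-error")) prop[[i]]$R <- Rn
      }
    }
    if (verbose)
      message(sprintf(
        "it %3d: %5.2fs  loglik %10.3f  sigma %.4f  minESS %5.1f  low-ESS %d",
        it, as.numeric(Sys.time() - it_t0, units = "secs"), loglik,
        sqrt(sum_rss / max(n_obs, 1)), min_ess, low_ess))
    if (low_ess > 0)
      warning(sprintf(
        "iteration %d: effective sample size below %.0f%% of n_samples for %d subject(s); proposal inflated",
        it, 100 * ess_floor, low_ess))

    # M-step: log-normal means and diagonal BSV, fixed flags respected
    delta <- sum_eta / ns
    mu[eta_keys] <- mu[eta_keys] + delta
    omega2 <- setNames(pmin(pmax(sum_eta2 / ns - 2 * delta *
                                   (sum_eta / ns) + delta^2, 1e-8), 4),
                       eta_keys)
    # floor and cap: a single degenerate subject (all draws predicting
    # near-zero where data are positive) can otherwise inflate the
    # residual update beyond recovery and flatten the likelihood
    sigma <- min(max(sqrt(sum_rss / n_obs), 1e-6), 2)
    # etas are deviations from the population mean: re-centre
    eta_hat <- sweep(eta_hat, 2, delta, `-`)
    for (i in seq_len(ns))
      prop[[i]]$m <- prop[[i]]$m - delta[act_list[[i]]]

    trace[[it]] <- tibble::tibble(
      iteration = it, loglik = loglik, sigma = sigma,
      !!!setNames(as.list(exp(mu[mean_keys])), mean_keys),
      !!!setNames(as.list(omega2), paste0("bsv_", eta_keys)))
  }

  est <- init
  est$mean <- unname(exp(mu[est$parameter]))
  est$mean[est$fixed] <- init$mean[est$fixed]
  est$bsv <- unname(ifelse(est$parameter %in% eta_keys,
                           omega2[est$parameter], init$bsv))
  est$bsv[est$fixed] <- init$bsv[est$fixed]
  est$se_pct <- NA_real_
  est$bsv_se_pct <- NA_real_
  est <- as_pk_estimate(est)

  individual <- purrr::map_dfr(seq_len(ns), function(i) {
    s <- subjects[[i]]
    p <- estimate_to_params(est, formulation = if (s$form == "IR") "IR" else "GR",
                            eta = setNames(eta_hat[i, ], eta_keys))
    dplyr::bind_cols(tibble::tibble(ID = s$id, FORM = s$form),
                     tibble::as_tibble(as.list(unclass(p))))
  })

  new_pk_fit(estimate = est, sigma_prop = sigma, method = "mcpem",
             individual = individual, n_subjects = ns,
             n_obs = sum(purrr::map_dbl(subjects, ~ length(.x$times))),
             trace = dplyr::bind_rows(trace),
             logLik = trace[[n_iter]]$loglik,
             error_model = error_model, eta = eta_hat,
             settings = list(n_samples = n_samples, n_iter = n_iter,
                             seed = seed))
}

# conditional mode of one subject's random-effect posterior (found by a
# warm-started quasi-Newton search) plus the upper Cholesky factor of a
# Laplace covariance from a batched central-difference Hessian, floored
# against the prior and mildly inflated
conditional_laplace <- function(start_m, act, means, eta_keys, s, sigma,
                                error_model, omega2, rtol, atol,
                                do_hessian = TRUE) {
  da <- sum(act)
  d <- length(act)
  sda <- sqrt(omega2[act])

  nlp_batch <- function(E) {
    eta <- matrix(0, nrow(E), d)
    eta[, act] <- E
    th <- theta_matrix(means, eta, eta_keys, s$form)
    lk <- pk_loglik_cpp(th, s$route, s$dose, s$times, s$conc,
                        if (error_model == "proportional") sigma else 0,
                        if (error_model == "additive") sigma else 0,
                        rtol = rtol, atol = atol)
    -(lk$loglik + rowSums(-0.5 * sweep(E, 2, sda, `/`)^2))
  }
  nlp1 <- function(ev) {
    # box at 4 prior sd: beyond it the posterior mass is negligible and
    # the solver slow; quadratic pull keeps the search pointed inward
    over <- abs(ev) - 4 * sda
    if (any(over > 0)) return(1e6 + sum(pmax(over, 0)^2))
    v <- nlp_batch(matrix(ev, 1))
    if (!is.finite(v)) 1e6 else v
  }
  opt <- try(optim(start_m, nlp1, method = "BFGS",
                   control = list(maxit = 25, reltol = 1e-6)),
             silent = TRUE)
  mode <- if (inherits(opt, "try-error")) start_m else opt$par
  if (!do_hessian) return(list(m = mode, R = NULL))

  # batched Hessian: diagonal and cross second differences
  h <- 0.08
  pts <- matrix(mode, 1, da)[rep(1, 1 + 2 * da + 2 * da * (da - 1)), ,
                             drop = FALSE]
  row <- 1
  diag_rows <- matrix(0L, da, 2)
  for (j in seq_len(da)) {
    pts[row + 1, j] <- mode[j] + h
    pts[row + 2, j] <- mode[j] - h
    diag_rows[j, ] <- c(row + 1L, row + 2L)
    row <- row + 2
  }
  cross <- which(upper.tri(diag(da)), arr.ind = TRUE)
  cross_rows <- matrix(0L, nrow(cross), 4)
  if (nrow(cross) > 0) for (q in seq_len(nrow(cross))) {
    j <- cross[q, 1]; k <- cross[q, 2]
    pts[row + 1, c(j, k)] <- mode[c(j, k)] + c(h, h)
    pts[row + 2, c(j, k)] <- mode[c(j, k)] + c(h, -h)
    pts[row + 3, c(j, k)] <- mode[c(j, k)] + c(-h, h)
    pts[row + 4, c(j, k)] <- mode[c(j, k)] + c(-h, -h)
    cross_rows[q, ] <- row + 1:4
    row <- row + 4
  }
  v <- nlp_batch(pts[seq_len(row), , drop = FALSE])
  vmax <- max(v[is.finite(v)])
  v[!is.finite(v)] <- vmax + 100
  f0 <- v[1]
  H <- matrix(0, da, da)
  for (j in seq_len(da))
    H[j, j] <- (v[diag_rows[j, 1]] + v[diag_rows[j, 2]] - 2 * f0) / h^2
  if (nrow(cross) > 0) for (q in seq_len(nrow(cross))) {
    j <- cross[q, 1]; k <- cross[q, 2]
    H[j, k] <- H[k, j] <-
      (v[cross_rows[q, 1]] - v[cross_rows[q, 2]] - v[cross_rows[q, 3]] +
         v[cross_rows[q, 4]]) / (4 * h^2)
  }
  eig <- eigen((H + t(H)) / 2, symmetric = TRUE)
  lam <- pmax(eig$values, 0.25 / max(omega2[act]))
  Sigma <- eig$vectors %*% (t(eig$vectors) / lam)
  # cap the marginal spreads at twice the prior sd, inflate mildly
  capf <- pmin(1, 2 * sda / sqrt(pmax(diag(Sigma), 1e-12)))
  Sigma <- Sigma * tcrossprod(capf) * 1.2^2 + diag(1e-8, da)
  R <- try(chol(Sigma), silent = TRUE)
  if (inherits(R, "try-error")) R <- diag(sqrt(omega2[act]), da)
  list(m = mode, R = R)
}

# which random-effect dimensions the likelihood of this formulation can
# see: for IR subjects the GR dissolution machinery never enters the
# equations, so those etas stay at their (exact) prior posterior
active_dims <- function(eta_keys, form) {
  if (form == "IR")
    eta_keys %in% c("V1", "V2", "CL", "CLD", "Ka_trans", "Ka", "Frel_IR")
  else eta_keys != "Frel_IR"
}

# ---- fit object -------------------------------------------------------

new_pk_fit <- function(estimate, sigma_prop, method, individual,
                       n_subjects, n_obs, trace, logLik,
                       error_model = "proportional", eta = NULL,
                       settings = list()) {
  structure(list(estimate = estimate, sigma_prop = sigma_prop,
                 method = method, individual = individual,
                 n_subjects = n_subjects, n_obs = n_obs, trace = trace,
                 logLik = logLik, error_model = error_model, eta = eta,
                 settings = settings),
            class = "pk_fit")
}

#' @export
print.pk_fit <- function(x, ...) {
  cat("<pk_fit>", x$method, "fit:", x$n_subjects, "subjects,", x$n_obs,
      "observations\n")
  cat("residual", x$error_model, "error:",
      signif(x$sigma_prop, 4), "\n")
  print(as.data.frame(x$estimate[, c("parameter", "mean", "bsv", "fixed")]),
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Tidy a population fit
#'
#' @param x A `pk_fit`.
#' @param ... Unused.
#' @return The estimate table (`parameter`, `mean`, `se_pct`, `bsv`,
#'   `bsv_se_pct`, `fixed`) as a tibble.
#' @export
tidy.pk_fit <- function(x, ...) {
  tibble::as_tibble(x$estimate)
}

#' One-row fit summary
#'
#' @param x A `pk_fit`.
#' @param ... Unused.
#' @return A one-row tibble with `method`, `n_subjects`, `n_obs`,
#'   `sigma`, `error_model`, `logLik`.
#' @export
glance.pk_fit <- function(x, ...) {
  tibble::tibble(method = x$method, n_subjects = x$n_subjects,
                 n_obs = x$n_obs, sigma = x$sigma_prop,
                 error_model = x$error_model, logLik = x$logLik)
}

# ---- diagnostics ------------------------------------------------------

#' Visual predictive check
#'
#' Simulates replicate virtual cohorts under the estimate (between-
#' subject variability plus residual error) and summarises the simulated
#' concentrations by percentile at each design sampling time, for
#' overlay with observed points. Deterministic given `seed`.
#'
#' @param object A `pk_estimate` table or `pk_fit`.
#' @param design A [study_design()]; its residual CV is overridden by
#'   `sigma_prop` when supplied or by the fit's residual estimate.
#' @param n_replicates Number of simulated cohorts (>= 1).
#' @param percentiles Percentiles (0-100) to report.
#' @param seed Integer seed.
#' @param observed Optional dataset tibble of observations to carry for
#'   overlay (stored in attribute `observed`, used by [autoplot()]).
#' @param sigma_prop Optional residual CV override.
#' @return A tibble of class `pk_vpc`: `FORM`, `TIME_H`, `percentile`,
#'   `CONC_UG_ML`.
#' @export
vpc <- function(object, design = study_design(), n_replicates = 500,
                percentiles = c(5, 50, 95), seed = 1, observed = NULL,
                sigma_prop = NULL) {
  estimate <- if (inherits(object, "pk_fit")) object$estimate
              else as_pk_estimate(object)
  if (is.null(sigma_prop))
    sigma_prop <- if (inherits(object, "pk_fit")) object$sigma_prop
                  else design$residual_cv
  stopifnot(n_replicates >= 1)
  sims <- purrr::map_dfr(seq_len(n_replicates), function(r) {
    des <- design
    des$seed <- (seed + 7717L * r) %% .Machine$integer.max
    des$lloq <- 0          # summarise uncensored simulated concentrations
    des$residual_cv <- sigma_prop
    coh <- generate_cohort(des, estimate)
    coh$data[coh$data$EVID == 0, c("FORM", "TIME_H", "CONC_UG_ML")]
  })
  out <- sims |>
    dplyr::group_by(.data$FORM, .data$TIME_H) |>
    dplyr::reframe(percentile = percentiles,
                   CONC_UG_ML = quantile(.data$CONC_UG_ML, percentiles / 100,
                                         names = FALSE, na.rm = TRUE))
  attr(out, "observed") <- observed
  attr(out, "percentiles") <- percentiles
  class(out) <- c("pk_vpc", class(out))
  out
}

#' Observed-versus-predicted table
#'
#' Pairs every quantifiable observation with its population prediction
#' (typical parameters for the subject's formulation) and its individual
#' prediction (the subject's empirical-Bayes / subject-level parameter
#' set stored in the fit), for identity-line goodness-of-fit plots.
#'
#' @param fit A `pk_fit`.
#' @param data The dataset the fit used.
#' @return A tibble of class `pk_gof`: `ID`, `FORM`, `TIME_H`,
#'   `observed`, `pred`, `ipred`.
#' @export
gof_table <- function(fit, data) {
  stopifnot(inherits(fit, "pk_fit"))
  subjects <- build_subjects(data)
  est <- fit$estimate
  out <- purrr::map_dfr(subjects, function(s) {
    typ <- estimate_to_params(est,
                              formulation = if (s$form == "IR") "IR" else "GR")
    pred <- conc_for(setNames(unclass(typ), .pk_param_names) |>
                       rename_to_keys(s$form), s)
    ind <- fit$individual[fit$individual$ID == s$id, ]
    ipred <- if (nrow(ind) == 1) {
      pi <- unlist(ind[, .pk_param_names])
      st <- pk_ode_cpp(pi, s$route, s$dose, s$times)
      st[, 4] / pi[["V1"]]
    } else rep(NA_real_, length(s$times))
    tibble::tibble(ID = s$id, FORM = s$form, TIME_H = s$times,
                   observed = s$conc, pred = pred, ipred = ipred)
  })
  class(out) <- c("pk_gof", class(out))
  out
}

# conc_for() expects estimate-keyed means; rebuild them from a pk_params
# vector for a given formulation
rename_to_keys <- function(p, form) {
  m <- p[setdiff(.pk_param_names, "Frel")]
  if (form == "IR") m[["Frel_IR"]] <- p[["Frel"]]
  else m[["Frel_GR"]] <- p[["Frel"]]
  m
}

#' Bootstrap standard errors for a population fit
#'
#' Nonparametric bootstrap over subjects: resamples subjects with
#' replacement, refits, and reports the relative standard error of each
#' population mean and BSV across resamples (in percent of the point
#' estimate), robust at small n and agnostic to the estimation
#' algorithm. Off by default in the fitters because it multiplies the
#' fitting cost by `n_boot`.
#'
#' @param data Dataset tibble.
#' @param init `pk_estimate` starting values.
#' @param fitter Fitting function (`fit_two_stage` or a wrapper around
#'   [fit_mcpem()]).
#' @param n_boot Number of resamples.
#' @param seed Integer seed.
#' @param ... Passed to `fitter`.
#' @return The point-estimate `pk_fit` with `se_pct`/`bsv_se_pct`
#'   columns filled in its estimate table.
#' @export
bootstrap_se <- function(data, init, fitter = fit_two_stage, n_boot = 100,
                         seed = 1, ...) {
  fit0 <- fitter(data, init, ...)
  ids <- unique(data$ID)
  set.seed(seed)
  boots <- purrr::map(seq_len(n_boot), function(b) {
    take <- sample(ids, length(ids), replace = TRUE)
    bd <- purrr::imap_dfr(take, function(id, k) {
      d <- data[data$ID == id, ]
      d$ID <- sprintf("B%03d", k)
      d
    })
    f <- try(suppressWarnings(fitter(bd, init, ...)), silent = TRUE)
    if (inherits(f, "try-error")) NULL else f$estimate
  })
  boots <- boots[!purrr::map_lgl(boots, is.null)]
  if (length(boots) < 2) {
    warning("too few successful bootstrap fits; SEs not computed")
    return(fit0)
  }
  mean_mat <- sapply(boots, function(e) e$mean)
  bsv_mat <- sapply(boots, function(e) e$bsv)
  est <- fit0$estimate
  est$se_pct <- 100 * apply(mean_mat, 1, sd) / est$mean
  est$bsv_se_pct <- ifelse(est$bsv > 0,
                           100 * apply(bsv_mat, 1, sd) / est$bsv, NA_real_)
  est$se_pct[est$fixed] <- NA_real_
  fit0$estimate <- as_pk_estimate(est)
  fit0$settings$n_boot <- length(boots)
  fit0
}
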