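# ggplot2 methods for the package's result types. Tables out, plots on
# request; nothing here is needed by the numerical pipeline.

#' Plot a simulated profile
#'
#' Concentration-time curve with the fraction-dissolved curve in a
#' second panel (GR dosing).
#'
#' @param object A `pk_simulation`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pk_simulation <- function(object, ...) {
  long <- object |>
    dplyr::select("TIME_H", "CONC_UG_ML", "FRAC_DISSOLVED") |>
    tidyr::pivot_longer(-"TIME_H", names_to = "panel") |>
    dplyr::mutate(panel = dplyr::recode(.data$panel,
                                        CONC_UG_ML = "plasma concentration (ug/mL)",
                                        FRAC_DISSOLVED = "fraction dissolved"))
  ggplot2::ggplot(long, ggplot2::aes(.data$TIME_H, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = NULL,
                  title = paste(attr(object, "formulation"),
                                attr(object, "dose"), "mg")) +
    ggplot2::theme_minimal()
}

#' Plot a visual predictive check
#'
#' Percentile ribbons of the simulated cohorts, with observed points
#' overlaid when the VPC carries them.
#'
#' @param object A `pk_vpc` from [vpc()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pk_vpc <- function(object, ...) {
  pct <- attr(object, "percentiles")
  wide <- tidyr::pivot_wider(object, names_from = "percentile",
                             values_from = "CONC_UG_ML",
                             names_prefix = "p")
  lo <- paste0("p", min(pct)); hi <- paste0("p", max(pct))
  mid <- paste0("p", pct[which.min(abs(pct - 50))])
  g <- ggplot2::ggplot(wide, ggplot2::aes(.data$TIME_H)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data[[lo]],
                                      ymax = .data[[hi]]),
                         alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data[[mid]])) +
    ggplot2::facet_wrap(~FORM, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "concentration (ug/mL)") +
    ggplot2::theme_minimal()
  obs <- attr(object, "observed")
  if (!is.null(obs)) {
    od <- obs[obs$EVID == 0 & !is.na(obs$CONC_UG_ML), ]
    g <- g + ggplot2::geom_point(
      data = od, ggplot2::aes(.data$TIME_H, .data$CONC_UG_ML),
      shape = 1, inherit.aes = FALSE)
  }
  g
}

#' Plot observed versus predicted
#'
#' Identity-line goodness-of-fit panels for population and individual
#' predictions.
#'
#' @param object A `pk_gof` from [gof_table()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pk_gof <- function(object, ...) {
  long <- object |>
    tidyr::pivot_longer(c("pred", "ipred"), names_to = "type",
                        values_to = "predicted") |>
    dplyr::mutate(type = dplyr::recode(.data$type,
                                       pred = "population prediction",
                                       ipred = "individual prediction"))
  ggplot2::ggplot(long, ggplot2::aes(.data$predicted, .data$observed)) +
    ggplot2::geom_abline(linetype = 2) +
    ggplot2::geom_point(shape = 1) +
    ggplot2::facet_wrap(~type) +
    ggplot2::labs(x = "predicted (ug/mL)", y = "observed (ug/mL)") +
    ggplot2::theme_minimal()
}

#' Plot an estimation trace
#'
#' Per-iteration population means and marginal-likelihood estimate of
#' an MC-PEM fit.
#'
#' @param object A `pk_fit` with a trace (from [fit_mcpem()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pk_fit <- function(object, ...) {
  if (is.null(object$trace)) stop("fit has no iteration trace", call. = FALSE)
  long <- object$trace |>
    tidyr::pivot_longer(-"iteration", names_to = "quantity")
  ggplot2::ggplot(long, ggplot2::aes(.data$iteration, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "EM iteration", y = NULL) +
    ggplot2::theme_minimal()
}
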