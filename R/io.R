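# File formats. All files are comma-delimited UTF-8 text with a
# mandatory header row, decimal points, times in hours and
# concentrations in ug/mL; the dose clock starts at 0 h for every
# subject (single-dose studies).

.dataset_cols <- c("ID", "TIME_H", "CONC_UG_ML", "BLQ", "DOSE_MG",
                   "FORM", "EVID")

#' Read / write a concentration-time dataset
#'
#' The dataset dialect has the columns `ID` (subject label), `TIME_H`
#' (h), `CONC_UG_ML` (empty for BLQ records), `BLQ` (0/1), `DOSE_MG`
#' (on dose rows), `FORM` (`IR`/`SR`/`GR`) and `EVID` (0 = observation,
#' 1 = dose). Each subject carries exactly one dose row; observation
#' rows must have a concentration or `BLQ = 1`; times must be unique
#' and non-negative per subject. Malformed files fail with an error
#' naming the offending row. `write_pk_dataset()` followed by
#' [read_pk_dataset()] is the identity on canonical tables.
#'
#' @param path File path.
#' @param data A dataset tibble.
#' @return `read_pk_dataset()` returns a validated tibble;
#'   `write_pk_dataset()` returns `path` invisibly.
#' @export
read_pk_dataset <- function(path) {
  # base parser: correctly-rounded doubles, so write -> read -> write is
  # byte-stable on canonical files
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE)
  missing_cols <- setdiff(.dataset_cols, names(raw))
  if (length(missing_cols))
    stop(path, ": missing column(s) ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  num <- function(col, what) {
    v <- raw[[col]]
    v[v == ""] <- NA
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(out))
    if (length(bad))
      stop(path, ": non-numeric ", what, " '", v[bad[1]], "' at line ",
           bad[1] + 1, call. = FALSE)
    out
  }
  x <- tibble::tibble(
    ID = raw$ID,
    TIME_H = num("TIME_H", "TIME_H"),
    CONC_UG_ML = num("CONC_UG_ML", "CONC_UG_ML"),
    BLQ = as.integer(num("BLQ", "BLQ")),
    DOSE_MG = num("DOSE_MG", "DOSE_MG"),
    FORM = raw$FORM,
    EVID = as.integer(num("EVID", "EVID")))
  validate_dataset(x, path = path)
  x
}

#' @rdname read_pk_dataset
#' @export
write_pk_dataset <- function(data, path) {
  validate_dataset(data)
  readr::write_csv(data[, .dataset_cols], path, na = "")
  invisible(path)
}

validate_dataset <- function(x, path = "dataset") {
  missing_cols <- setdiff(.dataset_cols, names(x))
  if (length(missing_cols))
    stop(path, ": missing column(s) ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  row_of <- function(i) i + 1L  # header line
  bad <- which(is.na(x$TIME_H) | x$TIME_H < 0)
  if (length(bad))
    stop(path, ": negative or missing TIME_H at line ", row_of(bad[1]),
         call. = FALSE)
  bad <- which(!x$EVID %in% c(0L, 1L))
  if (length(bad))
    stop(path, ": EVID must be 0 or 1 at line ", row_of(bad[1]),
         call. = FALSE)
  obs <- x$EVID == 0
  bad <- which(obs & is.na(x$CONC_UG_ML) & (is.na(x$BLQ) | x$BLQ != 1L))
  if (length(bad))
    stop(path, ": observation without concentration or BLQ flag at line ",
         row_of(bad[1]), call. = FALSE)
  for (id in unique(x$ID)) {
    rows <- which(x$ID == id)
    ndose <- sum(x$EVID[rows] == 1)
    if (ndose != 1)
      stop(path, ": subject ", id, " has ", ndose,
           " dose rows (expected 1)", call. = FALSE)
    drow <- rows[x$EVID[rows] == 1]
    if (is.na(x$DOSE_MG[drow]) || x$DOSE_MG[drow] <= 0)
      stop(path, ": invalid DOSE_MG for subject ", id, " at line ",
           row_of(drow), call. = FALSE)
    ot <- x$TIME_H[rows][x$EVID[rows] == 0]
    if (anyDuplicated(ot)) {
      dup <- ot[duplicated(ot)][1]
      line <- rows[x$EVID[rows] == 0][which(ot == dup)[2]]
      stop(path, ": duplicated time ", dup, " h for subject ", id,
           " at line ", row_of(line), call. = FALSE)
    }
  }
  invisible(x)
}

#' Read an in vitro dissolution file
#'
#' Delimited text with columns `TIME_H`, `PCT_DISSOLVED` (0-100) and an
#' optional `REPLICATE` column; times must be strictly increasing within
#' a replicate.
#'
#' @param path File path.
#' @return A tibble with `REPLICATE`, `TIME_H`, `PCT_DISSOLVED`.
#' @export
read_dissolution <- function(path) {
  x <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  if (!all(c("TIME_H", "PCT_DISSOLVED") %in% names(x)))
    stop(path, ": needs columns TIME_H, PCT_DISSOLVED", call. = FALSE)
  if (!"REPLICATE" %in% names(x)) x$REPLICATE <- 1
  if (any(x$PCT_DISSOLVED < 0 | x$PCT_DISSOLVED > 100))
    stop(path, ": PCT_DISSOLVED outside [0, 100]", call. = FALSE)
  bad <- x |>
    dplyr::group_by(.data$REPLICATE) |>
    dplyr::summarise(ok = all(diff(.data$TIME_H) > 0), .groups = "drop")
  if (any(!bad$ok))
    stop(path, ": TIME_H not strictly increasing within replicate ",
         bad$REPLICATE[!bad$ok][1], call. = FALSE)
  x[, c("REPLICATE", "TIME_H", "PCT_DISSOLVED")]
}

#' Summarise dissolution curves at a target percent
#'
#' Interpolated time to `p` percent dissolved per replicate (first
#' crossing, with a warning on non-monotone curves), and the mean and
#' standard deviation across the replicates that attain the target;
#' replicates that never reach `p` are excluded from the summary with a
#' warning.
#'
#' @param data A dissolution tibble ([read_dissolution()]) or a file
#'   path.
#' @param p Target percent, in (0, 100).
#' @return A list of class `pk_tp` with `$replicates` (tibble:
#'   `REPLICATE`, `T_p`, `attained`) and `$summary` (tibble: `p`,
#'   `mean`, `sd`, `n_attained`, `n_replicates`).
#' @examples
#' d <- tibble::tibble(TIME_H = c(0, 1, 2), PCT_DISSOLVED = c(0, 50, 100))
#' summarize_dissolution(d, 80)$replicates
#' @export
summarize_dissolution <- function(data, p = 80) {
  if (is.character(data)) data <- read_dissolution(data)
  if (!"REPLICATE" %in% names(data)) data$REPLICATE <- 1
  reps <- data |>
    dplyr::group_by(.data$REPLICATE) |>
    dplyr::group_modify(function(d, key) {
      if (any(diff(d$PCT_DISSOLVED) < 0))
        warning("non-monotone dissolution curve for replicate ",
                key$REPLICATE, "; using first crossing")
      tp <- suppressWarnings(
        t_percent_dissolved(
          tibble::tibble(TIME_H = d$TIME_H, PCT_DISSOLVED = d$PCT_DISSOLVED),
          p))
      tibble::tibble(T_p = tp, attained = is.finite(tp))
    }) |>
    dplyr::ungroup()
  if (any(!reps$attained))
    warning(sum(!reps$attained), " replicate(s) never reach ", p,
            "%; excluded from the summary")
  att <- reps$T_p[reps$attained]
  out <- list(replicates = reps,
              summary = tibble::tibble(
                p = p, mean = mean(att), sd = sd(att),
                n_attained = length(att), n_replicates = nrow(reps)))
  class(out) <- "pk_tp"
  out
}

#' @export
print.pk_tp <- function(x, ...) {
  s <- x$summary
  cat(sprintf("T%g = %.3f +/- %.3f h (%d/%d replicates attain the target)\n",
              s$p, s$mean, s$sd, s$n_attained, s$n_replicates))
  invisible(x)
}

#' Write a simulation result
#'
#' Delimited text with columns `TIME_H`, `CONC_UG_ML`, `FRAC_DISSOLVED`
#' preceded by a commented header block (`# key: value`) recording the
#' parameters, dose, formulation and solver settings.
#'
#' @param sim A `pk_simulation` from [simulate_profile()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_simulation <- function(sim, path) {
  stopifnot(inherits(sim, "pk_simulation"))
  p <- attr(sim, "params")
  solver <- attr(sim, "solver")
  hdr <- c(
    sprintf("# dose_mg: %g", attr(sim, "dose")),
    sprintf("# formulation: %s", attr(sim, "formulation")),
    sprintf("# engine: %s rtol=%g atol=%g", solver$engine, solver$rtol,
            solver$atol),
    sprintf("# param %s: %g", names(p), unclass(p)))
  writeLines(hdr, path)
  readr::write_csv(sim[, c("TIME_H", "CONC_UG_ML", "FRAC_DISSOLVED")],
                   path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a simulation file written by [write_simulation()]
#'
#' @param path File path.
#' @return A tibble with `TIME_H`, `CONC_UG_ML`, `FRAC_DISSOLVED`; the
#'   header block is returned in attribute `header`.
#' @export
read_simulation <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  x <- tibble::as_tibble(utils::read.csv(
    text = paste(lines[!startsWith(lines, "#")], collapse = "\n")))
  attr(x, "header") <- hdr
  x
}

#' Write / read a cohort truth record
#'
#' Subject-level true parameters (and per-subject substream seed) of a
#' generated cohort; round-trips unchanged through file I/O.
#'
#' @param truth The `truth` tibble of a [generate_cohort()] result.
#' @param path File path.
#' @return `read_truth()` returns the tibble; `write_truth()` the path,
#'   invisibly.
#' @export
write_truth <- function(truth, path) {
  readr::write_csv(truth, path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- utils::read.csv(path, check.names = FALSE,
                       colClasses = c(ID = "character",
                                      FORM = "character"))
  tibble::as_tibble(x)
}
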