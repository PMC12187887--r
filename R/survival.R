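#' Kaplan-Meier fit with Greenwood log-log confidence bands
#'
#' Product-limit estimate of the survivor function, with the Greenwood
#' variance and a log-log-transformed 95% band (the band is undefined, and
#' reported as `NA`, while the estimate is still 1).
#'
#' @param times Non-negative follow-up times.
#' @param events Logical (or 0/1) event indicators; `FALSE` = censored.
#' @param conf_type Transformation for the confidence band; `"log-log"`
#'   (default) or any type accepted by [survival::survfit()].
#' @return An object of class `km_curve`: a list with `table` (tibble of
#'   `time`, `n_risk`, `n_event`, `n_censor`, `estimate`, `std_err`,
#'   `conf_low`, `conf_high`), `n`, and the underlying `survfit` object.
#' @examples
#' km <- km_fit(c(1, 2, 3), c(TRUE, TRUE, TRUE))
#' km$table$estimate  # 2/3, 1/3, 0
#' @export
km_fit <- function(times, events, conf_type = "log-log") {
  stopifnot(length(times) > 0, length(times) == length(events))
  if (any(times < 0)) stop("negative follow-up times")
  events <- as.integer(as.logical(events))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = conf_type, conf.int = 0.95)
  structure(list(
    table = tibble::tibble(
      time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
      n_censor = fit$n.censor, estimate = fit$surv,
      std_err = fit$surv * fit$std.err,  # survfit reports se of log S
      conf_low = fit$lower, conf_high = fit$upper),
    n = length(times), fit = fit), class = "km_curve")
}

#' Aalen-Johansen cumulative incidence with a competing risk
#'
#' Nonparametric cumulative incidence of graft loss and of death treated as
#' mutually competing events, via the Aalen-Johansen (multi-state) estimator:
#' `F_k(t) = sum over event times <= t of S(t-) d_k(t)/n(t)`, where `S` is
#' the all-cause Kaplan-Meier survivor. Variances use the standard
#' counting-process estimator. At every time the identity
#' `F_graft + F_death + S = 1` holds exactly.
#'
#' @param times Non-negative follow-up times.
#' @param event_codes Integer codes: 0 censored, 1 graft loss, 2 death.
#' @return An object of class `aj_curve`: a list with `table` (tibble of
#'   `time`, `n_risk`, per-cause event counts, `surv`, and per-cause
#'   `cif_*`, `cif_*_low`, `cif_*_high`), `n`, and the `survfit` object.
#' @examples
#' aj <- aj_fit(c(1, 2), c(1L, 2L))
#' aj$table[, c("time", "cif_graft_loss", "cif_death")]
#' @export
aj_fit <- function(times, event_codes) {
  stopifnot(length(times) > 0, length(times) == length(event_codes))
  if (!all(event_codes %in% 0:2)) stop("event_codes must be 0, 1 or 2")
  status <- factor(event_codes, levels = 0:2,
                   labels = c("censored", "graft_loss", "death"))
  if (all(event_codes == 0)) {
    # degenerate all-censored sample: no transitions to estimate
    ts <- sort(unique(times))
    n_risk <- vapply(ts, function(t) sum(times >= t), 1)
    zero <- rep(0, length(ts))
    return(structure(list(
      table = tibble::tibble(
        time = ts, n_risk = n_risk,
        n_event_graft_loss = zero, n_event_death = zero,
        surv = rep(1, length(ts)),
        cif_graft_loss = zero, cif_graft_loss_low = zero,
        cif_graft_loss_high = zero,
        cif_death = zero, cif_death_low = zero, cif_death_high = zero),
      n = length(times), fit = NULL), class = "aj_curve"))
  }
  fit <- survival::survfit(survival::Surv(times, status) ~ 1, conf.int = 0.95)
  st <- fit$states
  s0 <- match("(s0)", st)
  zero <- rep(0, length(fit$time))
  col <- function(mat, state, default = zero) {
    k <- match(state, st)
    if (is.na(k)) default else mat[, k]
  }
  structure(list(
    table = tibble::tibble(
      time = fit$time, n_risk = fit$n.risk[, s0],
      n_event_graft_loss = col(fit$n.event, "graft_loss"),
      n_event_death = col(fit$n.event, "death"),
      surv = fit$pstate[, s0],
      cif_graft_loss = col(fit$pstate, "graft_loss"),
      cif_graft_loss_low = col(fit$lower, "graft_loss"),
      cif_graft_loss_high = col(fit$upper, "graft_loss"),
      cif_death = col(fit$pstate, "death"),
      cif_death_low = col(fit$lower, "death"),
      cif_death_high = col(fit$upper, "death")),
    n = length(times), fit = fit), class = "aj_curve")
}

step_lookup <- function(times, values, t, before = NA_real_) {
  idx <- findInterval(t, times)
  out <- ifelse(idx == 0, before, values[pmax(idx, 1)])
  out
}

#' Evaluate a fitted curve at given times
#'
#' Right-continuous step-function evaluation; values before the first
#' observed time are the null state (survival 1, incidence 0), and values
#' beyond the last time carry the last step forward.
#'
#' @param curve A `km_curve` or `aj_curve`.
#' @param t Non-negative evaluation times.
#' @param ... Passed to methods.
#' @return A tibble with `time`, `estimate`, `conf_low`, `conf_high` (for
#'   `aj_curve`, one row per requested cause and time).
#' @export
survival_at <- function(curve, t, ...) UseMethod("survival_at")

#' @export
survival_at.km_curve <- function(curve, t, ...) {
  if (any(t < 0)) stop("evaluation times must be non-negative")
  tb <- curve$table
  tibble::tibble(
    time = t,
    estimate = step_lookup(tb$time, tb$estimate, t, before = 1),
    conf_low = step_lookup(tb$time, tb$conf_low, t, before = 1),
    conf_high = step_lookup(tb$time, tb$conf_high, t, before = 1))
}

#' @rdname survival_at
#' @param cause `"graft_loss"` or `"death"`.
#' @export
cif_at <- function(curve, t, cause = "graft_loss") {
  stopifnot(inherits(curve, "aj_curve"), cause %in% c("graft_loss", "death"))
  if (any(t < 0)) stop("evaluation times must be non-negative")
  tb <- curve$table
  col <- paste0("cif_", cause)
  tibble::tibble(
    time = t, cause = cause,
    estimate = step_lookup(tb$time, tb[[col]], t, before = 0),
    conf_low = step_lookup(tb$time, tb[[paste0(col, "_low")]], t, before = 0),
    conf_high = step_lookup(tb$time, tb[[paste0(col, "_high")]], t, before = 0))
}

#' @rdname survival_at
#' @details `graft_survival_at()` is the death-censored graft-survival
#'   convenience `1 - F_graft(t)`, with the confidence band complemented and
#'   flipped accordingly.
#' @export
graft_survival_at <- function(curve, t) {
  ci <- cif_at(curve, t, "graft_loss")
  tibble::tibble(time = t, estimate = 1 - ci$estimate,
                 conf_low = 1 - ci$conf_high, conf_high = 1 - ci$conf_low)
}

#' @export
survival_at.aj_curve <- function(curve, t, cause = "graft_loss", ...) {
  cif_at(curve, t, cause)
}

#' Fit survival and cumulative-incidence curves by age class
#'
#' Applies the Kaplan-Meier estimator for overall survival (death as the
#' event; graft loss and study end censor) and the Aalen-Johansen estimator
#' for graft failure with death as the competing risk, within each stratum
#' and overall, and summarises both at a landmark time.
#'
#' @param outcomes Outcome tibble from [assemble_outcomes()] with an added
#'   `age_class` column (or the column named in `strata`).
#' @param strata Name of the stratification column; `NULL` for no strata.
#' @param at_years Landmark evaluation time in years.
#' @return A tibble with one row per stratum (plus `"all"`): `n`, event
#'   counts, overall survival at the landmark with its band, and graft
#'   survival (`1 - F_graft`) likewise. Empty strata are skipped with a
#'   warning. The fitted curves are attached as the `curves` attribute
#'   (a named list with `km` and `aj` per stratum).
#' @export
stratified_outcomes <- function(outcomes, strata = "age_class", at_years = 5) {
  groups <- if (is.null(strata)) list(all = outcomes) else
    c(list(all = outcomes),
      split(outcomes, outcomes[[strata]], drop = TRUE))
  curves <- list()
  rows <- purrr::imap(groups, function(d, label) {
    if (nrow(d) == 0) {
      warning("empty stratum skipped: ", label)
      return(NULL)
    }
    km <- km_fit(d$time_years, d$event_code == 2)
    aj <- aj_fit(d$time_years, d$event_code)
    curves[[label]] <<- list(km = km, aj = aj)
    s <- survival_at(km, at_years)
    g <- graft_survival_at(aj, at_years)
    tibble::tibble(
      stratum = label, n = nrow(d),
      n_graft_loss = sum(d$event_code == 1), n_death = sum(d$event_code == 2),
      surv = s$estimate, surv_low = s$conf_low, surv_high = s$conf_high,
      graft_surv = g$estimate, graft_surv_low = g$conf_low,
      graft_surv_high = g$conf_high)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "curves") <- curves
  attr(out, "at_years") <- at_years
  out
}

#' @export
print.km_curve <- function(x, ...) {
  cat("<km_curve> n =", x$n, "subjects,", sum(x$table$n_event), "events\n")
  print(utils::head(x$table, 10))
  invisible(x)
}

#' @export
print.aj_curve <- function(x, ...) {
  cat("<aj_curve> n =", x$n, "subjects,",
      sum(x$table$n_event_graft_loss), "graft losses,",
      sum(x$table$n_event_death), "deaths\n")
  print(utils::head(x$table[, c("time", "n_risk", "surv", "cif_graft_loss",
                                "cif_death")], 10))
  invisible(x)
}
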