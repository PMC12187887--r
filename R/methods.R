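#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted survival or cumulative-incidence curve
#'
#' @param x A `km_curve` or `aj_curve`.
#' @param ... Unused.
#' @return For `km_curve`, the step table (one row per distinct time). For
#'   `aj_curve`, a long tibble with one row per time and cause
#'   (`graft_loss`, `death`) plus the all-cause survivor as `surv`.
#' @export
tidy.km_curve <- function(x, ...) x$table

#' @rdname tidy.km_curve
#' @export
tidy.aj_curve <- function(x, ...) {
  tb <- x$table
  dplyr::bind_rows(
    tibble::tibble(time = tb$time, cause = "graft_loss", n_risk = tb$n_risk,
                   n_event = tb$n_event_graft_loss, surv = tb$surv,
                   estimate = tb$cif_graft_loss,
                   conf_low = tb$cif_graft_loss_low,
                   conf_high = tb$cif_graft_loss_high),
    tibble::tibble(time = tb$time, cause = "death", n_risk = tb$n_risk,
                   n_event = tb$n_event_death, surv = tb$surv,
                   estimate = tb$cif_death,
                   conf_low = tb$cif_death_low,
                   conf_high = tb$cif_death_high)) |>
    dplyr::arrange(.data$time, .data$cause)
}

#' Glance at a fitted curve
#'
#' @param x A `km_curve` or `aj_curve`.
#' @param ... Unused.
#' @return One-row tibble of sample size, event counts and the final-time
#'   estimates.
#' @export
glance.km_curve <- function(x, ...) {
  tb <- x$table
  tibble::tibble(n = x$n, n_event = sum(tb$n_event),
                 n_censor = sum(tb$n_censor),
                 time_max = max(tb$time),
                 estimate_final = tb$estimate[nrow(tb)])
}

#' @rdname glance.km_curve
#' @export
glance.aj_curve <- function(x, ...) {
  tb <- x$table
  tibble::tibble(n = x$n,
                 n_graft_loss = sum(tb$n_event_graft_loss),
                 n_death = sum(tb$n_event_death),
                 time_max = max(tb$time),
                 cif_graft_loss_final = tb$cif_graft_loss[nrow(tb)],
                 cif_death_final = tb$cif_death[nrow(tb)])
}

#' Plot fitted curves
#'
#' Step plots with 95% confidence ribbons: the survivor function for a
#' `km_curve`, and both cause-specific cumulative incidence functions for an
#' `aj_curve`.
#'
#' @param object A `km_curve` or `aj_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.km_curve <- function(object, ...) {
  tb <- dplyr::bind_rows(
    tibble::tibble(time = 0, estimate = 1, conf_low = 1, conf_high = 1),
    object$table)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$time, y = .data$estimate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf_low,
                                      ymax = .data$conf_high),
                         stat = StatStepribbon, alpha = 0.2, na.rm = TRUE) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Years since transplantation", y = "Survival probability") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.km_curve
#' @export
autoplot.aj_curve <- function(object, ...) {
  tb <- tidy.aj_curve(object)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$time, y = .data$estimate,
                                   colour = .data$cause, fill = .data$cause)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf_low,
                                      ymax = .data$conf_high),
                         stat = StatStepribbon, alpha = 0.15, colour = NA,
                         na.rm = TRUE) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Years since transplantation",
                  y = "Cumulative incidence", colour = "Cause", fill = "Cause") +
    ggplot2::theme_minimal()
}

# step-ribbon stat: ribbons drawn as right-continuous steps
StatStepribbon <- ggplot2::ggproto(
  "StatStepribbon", ggplot2::Stat,
  required_aes = c("x", "ymin", "ymax"),
  compute_group = function(data, scales, ...) {
    data <- data[order(data$x), , drop = FALSE]
    n <- nrow(data)
    if (n <= 1) return(data)
    idx <- rep(seq_len(n), each = 2)[-2 * n]
    out <- data[idx, , drop = FALSE]
    out$x <- c(data$x[1], rep(data$x[-1], each = 2))
    out
  })

#' Bar chart of treatment-class use
#'
#' @param treatment Output of [treatment_table()].
#' @param era Era label to display (default `"overall"`).
#' @return A ggplot object.
#' @export
plot_treatment_table <- function(treatment, era = "overall") {
  d <- dplyr::filter(treatment, .data$era == !!era, .data$level == "class")
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$treatment, .data$pct),
                                  y = .data$pct)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "% of transplanted patients") +
    ggplot2::theme_minimal()
}
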