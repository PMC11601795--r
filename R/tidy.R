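#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a network simulation
#'
#' Long-format probe records: one row per time sample, vessel and variable.
#'
#' @param x A `myoflow_sim`.
#' @param ... Unused.
#' @return A tibble with columns `t`, `vessel`, `generation`, `variable`,
#'   `value`.
#' @export
tidy.myoflow_sim <- function(x, ...) {
  tidyr::pivot_longer(x$probes, cols = -c("t", "vessel", "generation"),
                      names_to = "variable", values_to = "value")
}

#' One-row summary of a network simulation
#'
#' @param x A `myoflow_sim`.
#' @param ... Unused.
#' @return A one-row tibble: vessels, steps, time step, coupling mode,
#'   mean/max fixed-point iterations, worst final coupling RMSRE, worst
#'   relative junction mass-conservation residual, wall-clock seconds.
#' @export
glance.myoflow_sim <- function(x, ...) {
  d <- x$diagnostics
  tibble(n_vessels = nrow(x$topology), n_steps = d$n_steps, dt = d$dt,
         mode = x$config$mode,
         averaged = x$config$averaged_active_stress,
         mean_iterations = d$mean_iterations,
         max_iterations = d$max_iterations,
         max_coupling_rmsre = max(d$coupling_rmsre),
         max_junction_rel = d$max_junction_rel,
         wct_s = d$wct_s)
}

#' @rdname tidy.myoflow_sim
#' @export
tidy.myoflow_comparison <- function(x, ...) x$by_generation

#' @rdname glance.myoflow_sim
#' @export
glance.myoflow_comparison <- function(x, ...) x$summary

#' Plot probe traces of a network simulation
#'
#' Mid-vessel time series faceted by variable and coloured by vessel
#' generation (symmetric generations overlap).
#'
#' @param object A `myoflow_sim`.
#' @param vars Variables to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.myoflow_sim <- function(object,
                                 vars = c("P_mmHg", "Q_ml_s", "di_um", "u_fs"),
                                 ...) {
  dat <- tidy(object) |> dplyr::filter(.data$variable %in% vars)
  ggplot2::ggplot(dat, ggplot2::aes(.data$t, .data$value,
                                    colour = factor(.data$generation),
                                    group = .data$vessel)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "t (s)", y = NULL, colour = "generation") +
    ggplot2::theme_minimal()
}

#' Plot a single-vessel pressure-clamp run
#'
#' Outer diameter, Ca2+ concentration and the prescribed pressure over time.
#'
#' @param object A `myoflow_wall_sim`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.myoflow_wall_sim <- function(object, ...) {
  dat <- tidyr::pivot_longer(
    dplyr::select(object, "t", "P_mmHg", "Ca_nM", "do_um"),
    cols = -"t", names_to = "variable", values_to = "value")
  ggplot2::ggplot(dat, ggplot2::aes(.data$t, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "t (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a steady-state pressure-flow curve
#'
#' Root-vessel flow against final inlet pressure, one line per calcium mode.
#'
#' @param object A `myoflow_autoreg`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.myoflow_autoreg <- function(object, ...) {
  ggplot2::ggplot(object$flows,
                  ggplot2::aes(.data$P_final, .data$Q_G0_ml_s,
                               colour = .data$mode)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "final inlet pressure (mmHg)",
                  y = "G0 flow (ml/s)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
print.myoflow_sim <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf(
    "<myoflow_sim> %d vessels, %d steps of %g s (%s coupling%s)\n",
    nrow(x$topology), d$n_steps, d$dt, x$config$mode,
    if (x$config$averaged_active_stress) ", averaged active stress" else ""))
  cat(sprintf("  mean iterations %.2f | max coupling RMSRE %.2e | wct %.2f s\n",
              d$mean_iterations, max(d$coupling_rmsre), d$wct_s))
  print(x$probes, n = 5)
  invisible(x)
}

#' @export
print.myoflow_comparison <- function(x, ...) {
  cat("<myoflow_comparison>\n")
  print(x$summary)
  invisible(x)
}
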