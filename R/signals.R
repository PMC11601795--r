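#' Pressure signal specifications
#'
#' Constructors for the piecewise-defined inlet/luminal pressure signals used
#' throughout the package. All levels are in mmHg and times in seconds; every
#' signal is a deterministic, pure function of its specification (and seed,
#' where one applies), so generated driving data are reproducible fixtures.
#'
#' * `signal_constant()`: a flat level.
#' * `signal_step_train()`: piecewise-constant steps through `levels`, switching
#'   at `times` (e.g. the alternating 10/60 mmHg myography protocol).
#' * `signal_ramp()`: `from` until `t_start`, linear ramp to `to` over
#'   `[t_start, t_end]`, then held (e.g. the 50 to 120 mmHg surge).
#' * `signal_periodic()`: a sinusoid of given `amplitude` and `period`
#'   superposed on a piecewise-linear mean defined by `mean_t`/`mean_P`; the
#'   variable-mean periodic signal used for the numerical-settings studies.
#'
#' @param level,levels,from,to Pressure levels, mmHg.
#' @param times Switch times for `signal_step_train()`, strictly increasing;
#'   `length(times) == length(levels) - 1`.
#' @param t_start,t_end Ramp interval, s.
#' @param mean_t,mean_P Breakpoints of the piecewise-linear mean (mmHg); the
#'   mean is held constant outside `range(mean_t)`.
#' @param amplitude,period,phase Sinusoid parameters (mmHg, s, radians).
#' @param seed Integer retained in the spec for reproducibility metadata of
#'   randomized protocols; the bundled generators are fully deterministic.
#' @return An object of class `myoflow_signal`.
#' @seealso [make_signal()], [sample_signal()], [default_inlet_signal()]
#' @name signals
NULL

new_signal <- function(kind, pars) {
  structure(c(list(kind = kind), pars), class = "myoflow_signal")
}

#' @rdname signals
#' @export
signal_constant <- function(level) {
  stopifnot(is.numeric(level), length(level) == 1L, is.finite(level))
  new_signal("constant", list(level = level))
}

#' @rdname signals
#' @export
signal_step_train <- function(levels, times, seed = NULL) {
  stopifnot(is.numeric(levels), is.numeric(times),
            length(levels) == length(times) + 1L)
  if (is.unsorted(times, strictly = TRUE))
    abort("`times` must be strictly increasing.", class = "myoflow_spec_error")
  new_signal("step_train", list(levels = levels, times = times, seed = seed))
}

#' @rdname signals
#' @export
signal_ramp <- function(from = 50, to = 120, t_start = 120, t_end = 130) {
  if (!(t_end > t_start))
    abort("`t_end` must exceed `t_start`.", class = "myoflow_spec_error")
  new_signal("ramp", list(from = from, to = to, t_start = t_start, t_end = t_end))
}

#' @rdname signals
#' @export
signal_periodic <- function(mean_t, mean_P, amplitude = 8, period = 0.2,
                            phase = 0, seed = NULL) {
  stopifnot(length(mean_t) == length(mean_P), length(mean_t) >= 1L,
            period > 0, amplitude >= 0)
  if (is.unsorted(mean_t, strictly = TRUE))
    abort("`mean_t` must be strictly increasing.", class = "myoflow_spec_error")
  new_signal("periodic_variable_mean",
             list(mean_t = mean_t, mean_P = mean_P, amplitude = amplitude,
                  period = period, phase = phase, seed = seed))
}

#' Default variable-mean periodic inlet signal
#'
#' The documented inlet signal for the network numerical-settings experiments:
#' a heart-rate-like sinusoid (period 0.2 s, amplitude 8 mmHg) superposed on a
#' piecewise-linear mean that sweeps 60 to 90 to 70 to 85 mmHg over 10 s,
#' exercising the myogenic response over a wide pressure range.
#'
#' @return A `myoflow_signal`.
#' @export
default_inlet_signal <- function() {
  signal_periodic(mean_t = c(0, 3, 6, 10), mean_P = c(60, 90, 70, 85),
                  amplitude = 8, period = 0.2)
}

#' Realize a signal specification as a function of time
#'
#' @param spec A `myoflow_signal`.
#' @return A vectorized function `f(t)` returning pressure in mmHg for any
#'   `t >= 0` (signals extend by their first/last value outside their
#'   definition range).
#' @export
make_signal <- function(spec) {
  if (is.function(spec)) return(spec)
  stopifnot(inherits(spec, "myoflow_signal"))
  switch(spec$kind,
    constant = {
      level <- spec$level
      function(t) rep(level, length(t))
    },
    step_train = {
      levels <- spec$levels; times <- spec$times
      function(t) levels[findInterval(t, times) + 1L]
    },
    ramp = {
      from <- spec$from; to <- spec$to
      t0 <- spec$t_start; t1 <- spec$t_end
      function(t) {
        frac <- pmin(pmax((t - t0) / (t1 - t0), 0), 1)
        from + frac * (to - from)
      }
    },
    periodic_variable_mean = {
      mt <- spec$mean_t; mp <- spec$mean_P
      a <- spec$amplitude; Tp <- spec$period; ph <- spec$phase
      function(t) {
        m <- approx(mt, mp, xout = pmin(pmax(t, mt[1]), mt[length(mt)]),
                    rule = 2)$y
        m + a * sin(2 * pi * t / Tp + ph)
      }
    },
    abort("Unknown signal kind.", class = "myoflow_spec_error")
  )
}

#' Sample a signal on a time grid
#'
#' @param spec A `myoflow_signal` (or function of time).
#' @param times Numeric vector of times, s.
#' @return A tibble with columns `t` and `P_mmHg`.
#' @export
sample_signal <- function(spec, times) {
  f <- make_signal(spec)
  tibble(t = times, P_mmHg = f(times))
}
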