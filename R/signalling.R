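#' Signalling state constructor
#'
#' The seven normalized intracellular variables of one smooth muscle cell:
#' Ca2+ (xi0), ROCK (xi1), HSP27-P (xi2), MLCP-P (xi3), cofilin-P (xi4),
#' LC20-P (xi5) and G-actin content (xi6). All are dimensionless activity
#' levels in \[0, 1\]. The standard initial condition sets all seven to 0.
#'
#' @param xi Either a single value recycled to all seven variables or a
#'   length-7 numeric vector `(xi0, ..., xi6)`.
#' @return A named numeric vector of class `myoflow_signalling_state`.
#' @export
signalling_state <- function(xi = 0) {
  if (length(xi) == 1L) xi <- rep(xi, 7L)
  stopifnot(length(xi) == 7L, all(is.finite(xi)))
  structure(setNames(as.numeric(xi), paste0("xi", 0:6)),
            class = "myoflow_signalling_state")
}

#' Evaluate one logistic link
#'
#' Returns `1 / (1 + exp(-slope * (x - half_activation)))`, complemented when
#' the link is inverted. Strictly monotone in `x`, output in (0, 1).
#'
#' @param link A [logistic_link()] (or one row of a [link_table()] as a list).
#' @param x Driving value(s); must be finite.
#' @return Activation value(s) in (0, 1).
#' @export
evaluate_link <- function(link, x) {
  if (!all(is.finite(x)))
    abort("Link input must be finite.", class = "myoflow_state_error")
  y <- 1 / (1 + exp(-link$slope * (x - link$half_activation)))
  if (isTRUE(link$inverted)) 1 - y else y
}

# Evaluate link j (0-based, chi_j) of a link table against a driving value.
chi_eval <- function(links, j, x) {
  row <- links[links$name == paste0("chi", j), ]
  evaluate_link(list(slope = row$slope, half_activation = row$half_activation,
                     inverted = row$inverted), x)
}

# Resolve the driving value for a link from (P, state).
link_input_value <- function(input, P, state) {
  if (input == "P") P else unname(state[[paste0("xi", sub("xi", "", input))]])
}

#' Pressure to Ca2+ target
#'
#' The relaxation target of the Ca2+ variable xi0 under the three calcium
#' modes: `"control"` uses the chi0 pressure link; `"diltiazem"` (L-type
#' channel block) leaves only a small residual stretch-operated component;
#' `"zero_ca"` (no extracellular Ca2+) gives 0 at any pressure.
#'
#' @param P Luminal pressure, mmHg (non-negative).
#' @param params A [signalling_params()]; its `calcium_mode` selects the mode.
#' @return Target xi0 in \[0, 1\] (vectorized over `P`).
#' @export
pressure_to_calcium_target <- function(P, params) {
  stopifnot(inherits(params, "myoflow_signalling_params"))
  if (!all(is.finite(P)) || any(P < 0))
    abort("`P` must be finite and non-negative (mmHg).",
          class = "myoflow_state_error")
  switch(params$calcium_mode,
    control = chi_eval(params$links, 0, P),
    diltiazem = params$dilt_scale /
      (1 + exp(-params$dilt_slope * (P - params$dilt_half))),
    zero_ca = rep(0, length(P)),
    abort("Unknown calcium mode.", class = "myoflow_config_error")
  )
}

# All nine link outputs for a given (P, state); row 0 honours calcium_mode.
chi_all <- function(state, P, params) {
  lt <- params$links
  out <- numeric(9)
  for (j in 0:8) {
    row <- lt[j + 1L, ]
    out[j + 1L] <- if (j == 0L) {
      pressure_to_calcium_target(P, params)
    } else {
      evaluate_link(list(slope = row$slope, half_activation = row$half_activation,
                         inverted = row$inverted),
                    link_input_value(row$input, P, state))
    }
  }
  out
}

#' Right-hand side of the signalling ODE system
#'
#' Time derivatives of the seven signalling variables. Rows 0-2 and 4 are
#' plain relaxations `(chi - xi) / tau`; row 3 relaxes to the inverted MLCP
#' link target `(1 - chi3)`; row 5 balances production against
#' dephosphorylation, `chi5 (1 - xi5) - (1 - chi6) xi5`; row 6 relaxes to the
#' logical-OR target `(1 - chi7) + (1 - chi8) - (1 - chi7)(1 - chi8)`
#' (equivalently `1 - chi7 chi8`).
#'
#' Requires all seven time constants to be positive: pass finite `tau_fast`
#' in [signalling_params()] (the quasi-steady treatment used by
#' [step_signalling()] corresponds to the limit `tau_fast -> 0`).
#'
#' @param state A [signalling_state()].
#' @param P Luminal pressure, mmHg.
#' @param params A [signalling_params()] with all-positive time constants.
#' @return Named numeric vector of derivatives, 1/s.
#' @export
signalling_rhs <- function(state, P, params) {
  stopifnot(inherits(params, "myoflow_signalling_params"))
  if (!is.finite(P)) abort("`P` must be finite.", class = "myoflow_state_error")
  taus <- c(rep(params$tau_c, 3), params$tau_fast)
  if (any(taus <= 0))
    abort("All time constants must be > 0 to evaluate the ODE right-hand side.",
          class = "myoflow_config_error")
  ch <- chi_all(state, P, params)
  d <- numeric(7)
  d[1] <- (ch[1] - state[["xi0"]]) / taus[1]
  d[2] <- (ch[2] - state[["xi1"]]) / taus[2]
  d[3] <- (ch[3] - state[["xi2"]]) / taus[3]
  d[4] <- ((1 - ch[4]) - state[["xi3"]]) / taus[4]
  d[5] <- (ch[5] - state[["xi4"]]) / taus[5]
  d[6] <- (ch[6] * (1 - state[["xi5"]]) - (1 - ch[7]) * state[["xi5"]]) / taus[6]
  t6 <- (1 - ch[8]) + (1 - ch[9]) - (1 - ch[8]) * (1 - ch[9])
  d[7] <- (t6 - state[["xi6"]]) / taus[7]
  setNames(d, paste0("dxi", 0:6))
}

# Fill the quasi-steady variables xi3..xi6 from the slow variables xi0..xi2.
signalling_algebraic <- function(state, P, params) {
  lt <- params$links
  ev <- function(j, x) chi_eval(lt, j, x)
  xi3 <- 1 - ev(3, state[["xi1"]])
  xi4 <- ev(4, state[["xi1"]])
  chi5 <- ev(5, state[["xi0"]])
  chi6 <- ev(6, xi3)
  xi5 <- chi5 / (chi5 + 1 - chi6)
  xi6 <- 1 - ev(7, state[["xi2"]]) * ev(8, xi4)
  state[["xi3"]] <- xi3; state[["xi4"]] <- xi4
  state[["xi5"]] <- xi5; state[["xi6"]] <- xi6
  state
}

#' Steady state of the signalling system at constant pressure
#'
#' The fixed point of the signalling ODEs is unique and can be computed
#' sequentially: xi0, xi1 relax to their pressure targets, xi2 to chi2(xi1),
#' the quasi-steady variables follow algebraically (in particular
#' `xi5 = chi5 / (chi5 + 1 - chi6)` and `xi6 = 1 - chi7 chi8`).
#'
#' @inheritParams signalling_rhs
#' @return A [signalling_state()] at the fixed point.
#' @export
signalling_steady_state <- function(P, params) {
  st <- signalling_state(0)
  st[["xi0"]] <- pressure_to_calcium_target(P, params)
  st[["xi1"]] <- chi_eval(params$links, 1, P)
  st[["xi2"]] <- chi_eval(params$links, 2, st[["xi1"]])
  signalling_algebraic(st, P, params)
}

#' Advance the signalling state one time step
#'
#' The three slow variables (xi0, xi1, xi2) are advanced with the two-step
#' Adams-Bashforth scheme (forward Euler on the first step), with the new-step
#' derivative evaluated at the current pressure; the quasi-instantaneous
#' variables (xi3..xi6) are then set to their algebraic targets.
#'
#' @param state A [signalling_state()] at time t.
#' @param P_now Luminal pressure at the new time level, mmHg.
#' @param dt Time step, s (> 0).
#' @param params A [signalling_params()].
#' @param prev_deriv Length-3 vector of the previous step's slow-variable
#'   derivatives, or `NULL` at start-up (forward Euler is then used).
#' @return A list with elements `state` (the new [signalling_state()]) and
#'   `deriv` (the length-3 derivative vector to pass as `prev_deriv` next step).
#' @export
step_signalling <- function(state, P_now, dt, params, prev_deriv = NULL) {
  stopifnot(dt > 0)
  ch0 <- pressure_to_calcium_target(P_now, params)
  ch1 <- chi_eval(params$links, 1, P_now)
  ch2 <- chi_eval(params$links, 2, state[["xi1"]])
  f <- c(ch0 - state[["xi0"]], ch1 - state[["xi1"]],
         ch2 - state[["xi2"]]) / params$tau_c
  new <- state
  slow <- c("xi0", "xi1", "xi2")
  if (is.null(prev_deriv)) {
    new[slow] <- state[slow] + dt * f
  } else {
    new[slow] <- state[slow] + dt * (1.5 * f - 0.5 * prev_deriv)
  }
  new[slow] <- pmin(pmax(new[slow], 0), 1)
  new <- signalling_algebraic(new, P_now, params)
  list(state = new, deriv = f)
}

#' Simulate the signalling system under a prescribed pressure
#'
#' Reference R time-marching loop over [step_signalling()], mainly used for
#' single-cell studies and convergence checks. For coupled network runs the
#' same scheme runs inside the compiled solver.
#'
#' @param signal A pressure signal ([signal_constant()] and friends) or a
#'   function of time returning mmHg.
#' @param t_end Final time, s.
#' @param dt Time step, s.
#' @param params A [signalling_params()].
#' @param init Initial [signalling_state()]; default all-zero.
#' @return A tibble with columns `t`, `P_mmHg`, `xi0`..`xi6` and `Ca_nM`
#'   (`xi0 * ca_max_nM`).
#' @export
simulate_signalling <- function(signal, t_end, dt, params = signalling_params(),
                                init = signalling_state(0)) {
  Pfun <- if (is.function(signal)) signal else make_signal(signal)
  n <- ceiling(t_end / dt)
  times <- seq(0, by = dt, length.out = n + 1L)
  out <- matrix(NA_real_, n + 1L, 7L)
  st <- signalling_algebraic(init, Pfun(0), params)
  out[1L, ] <- st
  deriv <- NULL
  for (k in seq_len(n)) {
    stp <- step_signalling(st, Pfun(times[k + 1L]), dt, params, deriv)
    st <- stp$state
    deriv <- stp$deriv
    out[k + 1L, ] <- st
  }
  res <- as_tibble(setNames(as.data.frame(out), paste0("xi", 0:6)))
  dplyr::mutate(res, t = times, P_mmHg = Pfun(times),
                Ca_nM = .data$xi0 * params$ca_max_nM, .before = 1L)
}
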