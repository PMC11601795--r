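#' Single-vessel pressure-clamp protocol
#'
#' Simulates one cannulated vessel segment (no flow: the luminal pressure is
#' prescribed directly) under a pressure protocol, e.g. the alternating
#' 10/60 mmHg step train used in pressure myography, with the layer-resolved
#' wall model at a coarse time step. Supports the pharmacological calcium
#' modes: `"control"`, `"diltiazem"` (L-type block with residual
#' stretch-operated entry) and `"zero_ca"` (passive response).
#'
#' @param signal Luminal pressure signal (mmHg).
#' @param t_end Protocol duration, s.
#' @param dt Time step, s (default 0.5 s — adequate for the slow signalling
#'   dynamics that dominate this protocol).
#' @param mode Calcium mode; overrides the mode in `params`.
#' @param geometry A [wall_geometry()]; default the 135 um load-free control
#'   vessel.
#' @param params A [myoflow_params()].
#' @param averaged Use the averaged-active-stress variant? Default `FALSE`.
#' @return A `myoflow_wall_sim`: tibble with columns `t`, `P_mmHg`, `Ca_nM`,
#'   `di_um`, `do_um`, `A_cm2`, `C_A`, `u_fs` (thickness average) and
#'   `xi0`..`xi6`; attribute `"u_fs_layers"` carries the per-layer sliding
#'   matrix.
#' @export
single_vessel_protocol <- function(signal, t_end, dt = 0.5,
                                   mode = c("control", "diltiazem", "zero_ca"),
                                   geometry = load_free_geometry(135, 0.2),
                                   params = myoflow_params(),
                                   averaged = FALSE) {
  mode <- match.arg(mode)
  params$signalling$calcium_mode <- mode
  stopifnot(inherits(geometry, "myoflow_wall_geometry"), t_end > 0, dt > 0)
  Pfun <- make_signal(signal)
  n_steps <- as.integer(round(t_end / dt))
  times <- seq(0, by = dt, length.out = n_steps + 1L)
  res <- cpp_single_vessel(pars_for_cpp(params, geometry),
                           mmHg_to_cgs(Pfun(times)), dt, averaged)
  out <- tibble(
    t = times, P_mmHg = Pfun(times),
    Ca_nM = res$xi[, 1] * params$signalling$ca_max_nM,
    di_um = res$di / .UM, do_um = res$do / .UM,
    A_cm2 = res$A, C_A = res$C_A, u_fs = res$ufs)
  xi <- as_tibble(setNames(as.data.frame(res$xi), paste0("xi", 0:6)))
  out <- dplyr::bind_cols(out, xi)
  attr(out, "u_fs_layers") <- res$u
  attr(out, "params") <- params
  attr(out, "geometry") <- geometry
  class(out) <- c("myoflow_wall_sim", class(out))
  out
}

#' Score a simulated trace against a reference trace
#'
#' Interpolates a simulated variable onto the reference time base and returns
#' the root mean square relative error over a scoring window — the metric used
#' to rank time-constant combinations against experimental diameter
#' recordings (reference traces are user-supplied).
#'
#' @param sim A tibble with a time column `t` and the variable `var`.
#' @param reference A tibble with columns `t` and `value`.
#' @param var Name of the simulated variable (default `"do_um"`).
#' @param window Optional `c(t0, t1)` scoring window, s.
#' @return The RMSRE (dimensionless).
#' @export
rmsre_score <- function(sim, reference, var = "do_um", window = NULL) {
  stopifnot(all(c("t", "value") %in% names(reference)), var %in% names(sim))
  ref <- reference
  if (!is.null(window))
    ref <- dplyr::filter(ref, .data$t >= window[1], .data$t <= window[2])
  if (!nrow(ref)) abort("Empty scoring window.", class = "myoflow_spec_error")
  sim_vals <- approx(sim$t, sim[[var]], xout = ref$t, rule = 2)$y
  rmsre(sim_vals, ref$value)
}

#' Sweep the signalling and sliding time constants
#'
#' Runs the single-vessel protocol over a grid of the intracellular time
#' constant `tau_c` and the filament-sliding time constant `tau_m`,
#' optionally scoring each run against a user-supplied reference outer
#' diameter trace.
#'
#' @param tau_c Values of the shared signalling time constant, s.
#' @param tau_m Values of the sliding time constant, s.
#' @inheritParams single_vessel_protocol
#' @param reference Optional reference tibble (`t`, `value` in um) for scoring.
#' @param window Optional scoring window `c(t0, t1)`, s.
#' @return A tibble with columns `tau_c`, `tau_m`, `rmsre` (NA when no
#'   reference is supplied) and the list-column `sim`.
#' @export
tau_sweep <- function(tau_c = c(1, 5, 10, 30, 60),
                      tau_m = 6.188e-5 * c(1e3, 1e2, 1e1, 1, 1e-1),
                      signal, t_end, dt = 0.5,
                      mode = "control",
                      geometry = load_free_geometry(135, 0.2),
                      params = myoflow_params(),
                      reference = NULL, window = NULL) {
  grid <- tidyr::expand_grid(tau_c = tau_c, tau_m = tau_m)
  runs <- purrr::pmap(grid, function(tau_c, tau_m) {
    p <- params
    p$signalling$tau_c <- tau_c
    p$tau_m <- tau_m
    single_vessel_protocol(signal, t_end, dt, mode = mode,
                           geometry = geometry, params = p)
  })
  scores <- if (is.null(reference)) rep(NA_real_, nrow(grid)) else
    vapply(runs, rmsre_score, numeric(1), reference = reference,
           window = window)
  dplyr::mutate(grid, rmsre = scores, sim = runs)
}

#' Default numerical-settings case table
#'
#' The five solution procedures compared on the network benchmark: the
#' reference (case 1: strong coupling, layer-resolved active stress,
#' dt = 1e-4 s) and four cheaper alternatives varying the time step, the
#' coupling mode and active-stress averaging.
#'
#' @return A tibble with columns `case`, `dt`, `coupling`, `averaged`.
#' @export
default_cases <- function() {
  tibble(case = 1:5,
         dt = c(1e-4, 2e-4, 2.5e-4, 2.5e-4, 2.5e-4),
         coupling = c("strong", "strong", "strong", "weak", "weak"),
         averaged = c(FALSE, FALSE, FALSE, FALSE, TRUE))
}

#' Compare numerical solution procedures on a network
#'
#' Runs each requested case on the same topology and inlet signal, then
#' scores every non-reference case against the reference case by the RMSRE of
#' the mid-vessel flow and luminal area per vessel generation, on a shared
#' sampling grid (`record_dt`, default 1e-2 s; the t = 0 sample, where the
#' flow is identically zero, is excluded). Relative wall-clock times are
#' reported against the reference.
#'
#' @param topology A `myoflow_topology` with boundaries.
#' @param signal Inlet pressure signal.
#' @param t_end Horizon, s.
#' @param cases A case table as from [default_cases()]; the first row is the
#'   reference.
#' @param params A [myoflow_params()].
#' @param epsilon,max_iters Strong-coupling settings shared by all cases.
#' @param record_dt Shared sampling interval, s.
#' @return A `myoflow_comparison`: list with `by_generation` (tibble: `case`,
#'   `generation`, `Q_rmsre`, `A_rmsre`), `summary` (per case: mean/min/max
#'   over generations and relative wall-clock time `wct_rel`), `cases`, and
#'   the reference diagnostics.
#' @export
settings_comparison <- function(topology, signal, t_end = 10,
                                cases = default_cases(),
                                params = myoflow_params(),
                                epsilon = 1e-6, max_iters = 50L,
                                record_dt = 1e-2) {
  stopifnot(nrow(cases) >= 1L)
  run_case <- function(dt, coupling, averaged) {
    run_simulation(topology, signal, t_end,
                   config = coupling_config(mode = coupling, epsilon = epsilon,
                                            max_iters = max_iters, dt = dt,
                                            averaged_active_stress = averaged,
                                            record_dt = record_dt),
                   params = params)
  }
  sims <- purrr::pmap(cases[c("dt", "coupling", "averaged")], run_case)
  ref <- sims[[1]]
  gens <- sort(unique(topology$generation))
  # mid-vessel traces of the first vessel of each generation (identical across
  # a symmetric generation), t = 0 excluded
  gen_trace <- function(sim, g) {
    v <- topology$vessel[topology$generation == g][1]
    dplyr::filter(sim$probes, .data$vessel == v, .data$t > 0)
  }
  by_gen <- purrr::map_dfr(seq_along(sims)[-1], function(k) {
    purrr::map_dfr(gens, function(g) {
      a <- gen_trace(sims[[k]], g)
      b <- gen_trace(ref, g)
      stopifnot(isTRUE(all.equal(a$t, b$t)))
      tibble(case = cases$case[k], generation = g,
             Q_rmsre = rmsre(a$Q_ml_s, b$Q_ml_s),
             A_rmsre = rmsre(a$A_cm2, b$A_cm2))
    })
  })
  wct <- vapply(sims, function(s) s$diagnostics$wct_s, numeric(1))
  summary <- by_gen |>
    dplyr::group_by(.data$case) |>
    dplyr::summarise(
      mean_Q_rmsre = mean(.data$Q_rmsre), min_Q_rmsre = min(.data$Q_rmsre),
      max_Q_rmsre = max(.data$Q_rmsre),
      mean_A_rmsre = mean(.data$A_rmsre), min_A_rmsre = min(.data$A_rmsre),
      max_A_rmsre = max(.data$A_rmsre), .groups = "drop") |>
    dplyr::left_join(tibble(case = cases$case,
                            wct_rel = wct / wct[1]), by = "case")
  structure(list(by_generation = by_gen, summary = summary, cases = cases,
                 wct_s = wct, reference_diagnostics = ref$diagnostics),
            class = "myoflow_comparison")
}

#' Steady-state pressure-flow (autoregulation) curve
#'
#' For each final inlet pressure and calcium mode, ramps the inlet pressure
#' from a baseline to the final level and integrates until the nominal steady
#' time, then records the root-vessel flow and the per-generation luminal
#' diameters. A steadiness flag reports whether every probe variable drifted
#' by less than `drift_tol` (relative) over the trailing `steady_window`
#' seconds. The diameter ratio (control over zero-Ca) quantifies the level of
#' myogenic constriction across the network.
#'
#' @param topology A `myoflow_topology` with boundaries.
#' @param final_pressures Final inlet pressures, mmHg.
#' @param modes Calcium modes to compare (default control and zero-Ca).
#' @param baseline Baseline inlet pressure, mmHg (default 50).
#' @param ramp_start,ramp_end Ramp interval, s (defaults 120-130 s).
#' @param t_end Recording (nominal steady-state) time, s (default 360 s).
#' @param config A [coupling_config()]; the default uses the cheap
#'   weak-coupling averaged-active-stress settings.
#' @param params A [myoflow_params()].
#' @param steady_window,drift_tol Steadiness check parameters (s, relative).
#' @return A `myoflow_autoreg`: list with `flows` (tibble: `P_final`, `mode`,
#'   `Q_G0_ml_s`, `steady`), `diameters` (per generation) and
#'   `diameter_ratio` (control / zero_ca per generation, when both modes are
#'   present).
#' @export
autoregulation_curve <- function(topology, final_pressures,
                                 modes = c("control", "zero_ca"),
                                 baseline = 50, ramp_start = 120,
                                 ramp_end = 130, t_end = 360,
                                 config = coupling_config(
                                   mode = "weak", averaged_active_stress = TRUE),
                                 params = myoflow_params(),
                                 steady_window = 10, drift_tol = 1e-5) {
  stopifnot(t_end > ramp_end, ramp_end > ramp_start)
  grid <- tidyr::expand_grid(P_final = final_pressures, mode = modes)
  # All runs share the pre-ramp baseline trajectory, so equilibrate each mode
  # once at the baseline pressure and branch the ramps from the stored state
  # (deterministic continuation: identical to running each case end to end).
  base_states <- purrr::map(setNames(modes, modes), function(mode) {
    p <- params
    p$signalling$calcium_mode <- mode
    run_simulation(topology, signal_constant(baseline), ramp_start,
                   config = config, params = p)$final_state
  })
  runs <- purrr::pmap(grid, function(P_final, mode) {
    p <- params
    p$signalling$calcium_mode <- mode
    sig <- signal_ramp(from = baseline, to = P_final, t_start = 0,
                       t_end = ramp_end - ramp_start)
    sim <- run_simulation(topology, sig, t_end - ramp_start, config = config,
                          params = p, init_state = base_states[[mode]])
    sim$probes$t <- sim$probes$t + ramp_start
    sim
  })
  root <- topology$vessel[is.na(topology$parent)]
  check_steady <- function(sim) {
    tail_probe <- dplyr::filter(sim$probes, .data$t >= t_end - steady_window)
    drift <- tail_probe |>
      dplyr::group_by(.data$vessel) |>
      dplyr::summarise(dplyr::across(c("P_mmHg", "Q_ml_s", "A_cm2", "u_fs"),
                                     ~ {
                                       span <- max(.x) - min(.x)
                                       scale <- max(abs(.x), 1e-12)
                                       span / scale
                                     }), .groups = "drop")
    max(as.matrix(drift[-1])) < drift_tol
  }
  final_row <- function(sim) dplyr::filter(sim$probes, .data$t == max(.data$t))
  flows <- dplyr::mutate(grid,
    Q_G0_ml_s = vapply(runs, function(s)
      final_row(s)$Q_ml_s[final_row(s)$vessel == root], numeric(1)),
    steady = vapply(runs, check_steady, logical(1)))
  diameters <- purrr::map2_dfr(seq_len(nrow(grid)), runs, function(i, s) {
    fr <- final_row(s) |>
      dplyr::group_by(.data$generation) |>
      dplyr::summarise(di_um = mean(.data$di_um), .groups = "drop")
    dplyr::mutate(fr, P_final = grid$P_final[i], mode = grid$mode[i],
                  .before = 1L)
  })
  ratio <- NULL
  if (all(c("control", "zero_ca") %in% modes)) {
    ratio <- diameters |>
      tidyr::pivot_wider(names_from = "mode", values_from = "di_um") |>
      dplyr::mutate(ratio = .data$control / .data$zero_ca)
  }
  if (!all(flows$steady))
    warn("Some runs had not reached steady state at `t_end`.")
  structure(list(flows = flows, diameters = diameters,
                 diameter_ratio = ratio, t_end = t_end),
            class = "myoflow_autoreg")
}
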