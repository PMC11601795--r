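#' Root mean square relative error
#'
#' `sqrt(mean(((values - reference) / reference)^2))` — the accuracy and
#' coupling-convergence metric used throughout the package.
#'
#' @param values Numeric vector.
#' @param reference Numeric vector of the same length with no zero entries.
#' @return A non-negative scalar.
#' @export
rmsre <- function(values, reference) {
  if (length(values) != length(reference))
    abort("`values` and `reference` must have equal length.",
          class = "myoflow_state_error")
  if (any(reference == 0))
    abort("`reference` must have no zero entries.", class = "myoflow_state_error")
  sqrt(mean(((values - reference) / reference)^2))
}

#' Coupling and time-stepping configuration
#'
#' @param mode `"strong"` (fixed-point iteration of the fluid-wall exchange
#'   until the network-wide area RMSRE between successive iterates falls below
#'   `epsilon`) or `"weak"` (a single sequential fluid-then-wall pass per
#'   step).
#' @param epsilon Fixed-point tolerance on the area RMSRE (default 1e-6).
#' @param max_iters Iteration cap for strong coupling (default 50).
#' @param dt Time step, s (default 2.5e-4).
#' @param averaged_active_stress Use the thickness-averaged active-stress wall
#'   variant (two unknowns per node instead of `n_layers + 1`)?
#' @param record_dt Probe sampling interval, s (default 1e-2); rounded to a
#'   multiple of `dt`.
#' @return A list of class `myoflow_coupling_config`.
#' @export
coupling_config <- function(mode = c("strong", "weak"), epsilon = 1e-6,
                            max_iters = 50L, dt = 2.5e-4,
                            averaged_active_stress = FALSE,
                            record_dt = 1e-2) {
  mode <- match.arg(mode)
  if (!is.numeric(epsilon) || epsilon <= 0)
    abort("`epsilon` must be > 0.", class = "myoflow_config_error")
  if (max_iters < 1L)
    abort("`max_iters` must be >= 1.", class = "myoflow_config_error")
  stopifnot(dt > 0, record_dt >= dt)
  structure(list(mode = mode, epsilon = epsilon,
                 max_iters = as.integer(max_iters), dt = dt,
                 averaged_active_stress = isTRUE(averaged_active_stress),
                 record_dt = record_dt),
            class = "myoflow_coupling_config")
}

# Shared plumbing: flatten everything for the compiled solver.
simulate_cpp_call <- function(topology, signal, n_steps, config, params,
                              init_state = NULL, n_layers = 5,
                              k_omega = 1, lambda_z = 1) {
  b <- boundaries_of(topology)
  params$Pext_mmHg <- b$Pext_mmHg
  tp <- topology_for_cpp(topology)
  geoms <- vessel_geometries(topology, k_omega = k_omega, lambda_z = lambda_z,
                             n_layers = n_layers)
  tp$vessel_Ri <- vapply(geoms, `[[`, numeric(1), "Ri")
  tp$vessel_H <- vapply(geoms, `[[`, numeric(1), "H")
  Pfun <- make_signal(signal)
  times <- seq(0, by = config$dt, length.out = n_steps + 1L)
  inlet <- mmHg_to_cgs(Pfun(times))
  if (any(!is.finite(inlet)))
    abort("Inlet signal must be finite over the simulated interval.",
          class = "myoflow_spec_error")
  z_mode <- b$Z_mode
  conf <- list(
    dt = config$dt, n_steps = as.integer(n_steps),
    coupling = if (config$mode == "strong") 1L else 0L,
    eps = config$epsilon, max_iters = config$max_iters,
    averaged = config$averaged_active_stress,
    record_every = max(1L, as.integer(round(config$record_dt / config$dt))),
    Pout = mmHg_to_cgs(b$Pout_mmHg),
    z_mode = if (is.numeric(z_mode)) 2L else match(z_mode,
                                                   c("none", "characteristic")) - 1L,
    z_value = if (is.numeric(z_mode)) z_mode else 0,
    komega = k_omega, lamz = lambda_z, nCL = as.integer(n_layers))
  cpp_simulate(tp, pars_for_cpp(params), inlet, conf, init_state)
}

#' Run a coupled fluid-wall network simulation
#'
#' Time-marches the 1-D network haemodynamics coupled to the per-node
#' chemo-mechanical wall model from the standard initial conditions (pressure
#' set to the first inlet value everywhere, zero flow, all signalling
#' variables 0, filament sliding -2e-2, unit circumferential stretch) or from
#' a supplied state. Probes record pressure, flow, area, diameters and
#' sliding at the mid-axial node of every vessel.
#'
#' @param topology A `myoflow_topology` with boundaries attached.
#' @param signal Inlet pressure signal (a `myoflow_signal` or function of time
#'   returning mmHg).
#' @param t_end Simulated interval, s.
#' @param config A [coupling_config()].
#' @param params A [myoflow_params()]. The external pressure is taken from the
#'   topology's boundary attributes.
#' @param init_state Optional network state (as returned in `$final_state` of
#'   a previous run, or by [initial_network_state()]) to continue from.
#' @param n_layers,k_omega,lambda_z Wall discretization and kinematic
#'   parameters shared by all vessels.
#' @return A `myoflow_sim` object: list with `probes` (tibble: `t`, `vessel`,
#'   `generation`, `P_mmHg`, `Q_ml_s`, `A_cm2`, `di_um`, `do_um`, `u_fs`),
#'   `diagnostics` (iteration counts, final coupling RMSRE per step, junction
#'   mass-conservation residuals, wall-clock time), `final_state`, `Z`,
#'   `config`, `topology`.
#' @export
run_simulation <- function(topology, signal, t_end,
                           config = coupling_config(),
                           params = myoflow_params(),
                           init_state = NULL, n_layers = 5,
                           k_omega = 1, lambda_z = 1) {
  stopifnot(inherits(config, "myoflow_coupling_config"), t_end > 0)
  n_steps <- as.integer(round(t_end / config$dt))
  res <- simulate_cpp_call(topology, signal, n_steps, config, params,
                           init_state, n_layers, k_omega, lambda_z)
  nv <- nrow(topology)
  n_rec <- length(res$t_rec)
  probes <- tibble(
    t = rep(res$t_rec, nv),
    vessel = rep(seq_len(nv), each = n_rec),
    generation = rep(topology$generation, each = n_rec),
    P_mmHg = cgs_to_mmHg(as.vector(res$P)),
    Q_ml_s = as.vector(res$Q),
    A_cm2 = as.vector(res$A),
    di_um = as.vector(res$di) / .UM,
    do_um = as.vector(res$do) / .UM,
    u_fs = as.vector(res$ufs))
  diagnostics <- list(
    iterations = res$iters, coupling_rmsre = res$rmsre_final,
    mean_iterations = mean(res$iters), max_iterations = max(res$iters),
    max_junction_abs = res$max_jun_abs, max_junction_rel = res$max_jun_rel,
    wct_s = res$wct, n_steps = n_steps, dt = config$dt)
  structure(list(probes = probes, diagnostics = diagnostics,
                 final_state = res$final_state, Z = res$Z,
                 config = config, topology = topology, t_end = t_end),
            class = "myoflow_sim")
}

#' Standard initial network state
#'
#' Builds the t = 0 state used by [run_simulation()]: nodal pressure equal to
#' `P0_mmHg`, zero flow, all signalling variables 0, per-layer filament
#' sliding -2e-2, unit circumferential stretch (reference areas), and the
#' compliance of that configuration.
#'
#' @inheritParams run_simulation
#' @param P0_mmHg Initial nodal pressure, mmHg.
#' @return A network state list accepted by `init_state` arguments.
#' @export
initial_network_state <- function(topology, P0_mmHg,
                                  config = coupling_config(),
                                  params = myoflow_params(), n_layers = 5,
                                  k_omega = 1, lambda_z = 1) {
  res <- simulate_cpp_call(topology, signal_constant(P0_mmHg), 0L, config,
                           params, NULL, n_layers, k_omega, lambda_z)
  res$final_state
}

#' Advance a network state by one coupled time step
#'
#' One step of the fluid-structure interaction from a given state: in strong
#' mode the fluid solve, per-node signalling update, wall solve and compliance
#' update are fixed-point iterated until the network area RMSRE between
#' successive iterates falls below `config$epsilon`; in weak mode a single
#' sequential pass is taken.
#'
#' @inheritParams run_simulation
#' @param state A network state (see [initial_network_state()]).
#' @param Pin_next_mmHg Inlet pressure at the new time level, mmHg.
#' @return A list with `state` (the advanced state), `iterations` and
#'   `coupling_rmsre` (final iterate RMSRE; 0 in weak mode and for rigid
#'   walls).
#' @export
advance_step <- function(topology, state, Pin_next_mmHg,
                         config = coupling_config(),
                         params = myoflow_params(), n_layers = 5,
                         k_omega = 1, lambda_z = 1) {
  res <- simulate_cpp_call(topology, signal_constant(Pin_next_mmHg), 1L,
                           config, params, state, n_layers, k_omega, lambda_z)
  list(state = res$final_state, iterations = res$iters[1],
       coupling_rmsre = res$rmsre_final[1])
}
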