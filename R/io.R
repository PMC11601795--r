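#' Write probe time series to CSV
#'
#' @param sim A `myoflow_sim` or `myoflow_wall_sim`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_probes_csv <- function(sim, path) {
  dat <- if (inherits(sim, "myoflow_sim")) sim$probes else as_tibble(sim)
  utils::write.csv(dat, path, row.names = FALSE)
  invisible(path)
}

#' Write run metadata as JSON
#'
#' Records the numerical settings, boundary conditions, package version and
#' wall-clock time of a run alongside its outputs, for reproducibility.
#'
#' @param sim A `myoflow_sim`.
#' @param path Output file.
#' @param seed Optional integer seed used to generate the driving signal.
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(sim, path, seed = NULL) {
  b <- boundaries_of(sim$topology)
  meta <- list(
    package = "myoflow",
    version = as.character(utils::packageVersion("myoflow")),
    config = unclass(sim$config),
    boundaries = b,
    t_end = sim$t_end,
    n_vessels = nrow(sim$topology),
    seed = seed,
    wct_s = sim$diagnostics$wct_s,
    mean_iterations = sim$diagnostics$mean_iterations,
    max_junction_rel = sim$diagnostics$max_junction_rel)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a run configuration file
#'
#' Parses the structured YAML configuration used by the command-line driver:
#' a `network` block (either a path to a topology JSON or the symmetric-tree
#' fields `Do0_um`, `hw0`, `lengths`, `n_elements`), a `signal` block
#' (`kind` plus the fields of the matching signal constructor), an optional
#' `settings` block (fields of [coupling_config()] plus `t_end`) and an
#' optional `parameters` block (`tau_c`, `tau_m`, `calcium_mode`, `wall_mode`,
#' `Pout_mmHg`, `Pext_mmHg`, `Z_mode`).
#'
#' @param path YAML file path.
#' @return A list with `topology`, `signal`, `config`, `params`, `t_end`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  net <- y$network
  topo <- if (!is.null(net$file)) topology_from_json(net$file) else
    default_mca_tree(Do0_um = net$Do0_um %||% 135, hw0 = net$hw0 %||% 0.2,
                     lengths = unlist(net$lengths %||%
                                        c(0.40, 0.30, 0.20, 0.15)),
                     n_elements = as.integer(net$n_elements %||% 2L))
  pb <- y$parameters %||% list()
  topo <- attach_boundaries(topo,
                            Pout_mmHg = pb$Pout_mmHg %||% 50,
                            Pext_mmHg = pb$Pext_mmHg %||% 10,
                            Z_mode = pb$Z_mode %||% "characteristic")
  s <- y$signal %||% list(kind = "default")
  signal <- switch(s$kind %||% "default",
    default = default_inlet_signal(),
    constant = signal_constant(s$level),
    step_train = signal_step_train(unlist(s$levels), unlist(s$times)),
    ramp = signal_ramp(s$from %||% 50, s$to %||% 120, s$t_start %||% 120,
                       s$t_end %||% 130),
    periodic_variable_mean = signal_periodic(unlist(s$mean_t),
                                             unlist(s$mean_P),
                                             s$amplitude %||% 8,
                                             s$period %||% 0.2),
    abort("Unknown signal kind in config.", class = "myoflow_spec_error"))
  st <- y$settings %||% list()
  config <- coupling_config(mode = st$mode %||% "strong",
                            epsilon = st$epsilon %||% 1e-6,
                            max_iters = st$max_iters %||% 50L,
                            dt = st$dt %||% 2.5e-4,
                            averaged_active_stress =
                              isTRUE(st$averaged_active_stress),
                            record_dt = st$record_dt %||% 1e-2)
  params <- myoflow_params(
    signalling = signalling_params(tau_c = pb$tau_c %||% 10,
                                   calcium_mode = pb$calcium_mode %||% "control"),
    tau_m = pb$tau_m %||% 6.188e-2,
    Pext_mmHg = pb$Pext_mmHg %||% 10,
    wall_mode = pb$wall_mode %||% "active")
  list(topology = topo, signal = signal, config = config, params = params,
       t_end = st$t_end %||% 10)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
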