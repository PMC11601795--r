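#' Wall state constructor
#'
#' State of one wall cross-section (one fluid node): per-layer normalized
#' relative filament sliding `u_fs`, luminal area `A` (cm^2) and compliance
#' `C_A = dA/dP` (cm^2 per dyn/cm^2). The per-layer circumferential stretches
#' follow from `A` through the incompressible kinematics and are stored for
#' convenience.
#'
#' @param geometry A [wall_geometry()].
#' @param u_fs Per-layer sliding; a scalar is recycled. Default -2e-2, the
#'   standard initial value.
#' @param A Luminal area, cm^2; default the reference area `pi * Ri^2 /
#'   k_omega^2` (unit luminal stretch).
#' @param C_A Compliance; default `NA` (computed on the first step).
#' @return A list of class `myoflow_wall_state`.
#' @export
wall_state <- function(geometry, u_fs = -2e-2, A = NULL, C_A = NA_real_) {
  stopifnot(inherits(geometry, "myoflow_wall_geometry"))
  n <- geometry$n_layers
  if (length(u_fs) == 1L) u_fs <- rep(u_fs, n)
  stopifnot(length(u_fs) == n)
  if (is.null(A)) A <- pi * geometry$Ri^2 / geometry$k_omega^2
  stopifnot(A > 0)
  k <- kinematics(sqrt(A / pi), geometry$R_mid, geometry)
  structure(list(u_fs = u_fs, A = A, C_A = C_A,
                 lambda_theta = k$lambda_theta, geometry = geometry),
            class = "myoflow_wall_state")
}

#' Filament overlap factor
#'
#' Gaussian-shaped overlap between actin and myosin filaments as a function of
#' the relative sliding: `exp(-(u_fs - u_fs_opt)^2 / (2 (s_f0 / L_m)^2))`,
#' maximal (= 1) at the optimal sliding and symmetric about it.
#'
#' @param u_fs Normalized relative filament sliding (vectorized).
#' @param params A [contractile_params()].
#' @return Overlap factor(s) in (0, 1].
#' @export
filament_overlap <- function(u_fs, params = contractile_params()) {
  if (!all(is.finite(u_fs)))
    abort("`u_fs` must be finite.", class = "myoflow_state_error")
  s <- params$s_f0 / params$L_m
  exp(-(u_fs - params$u_fs_opt)^2 / (2 * s^2))
}

# Series stiffness of a chain of contractile units anchored by two actin
# cortex springs; both stiffnesses zero returns 0 (no engaged machinery).
series_stiffness <- function(ktCU, kAC) {
  den <- 2 * ktCU + kAC
  ifelse(den > 0, ktCU * kAC / den, 0)
}

#' Contractile system forces and stiffnesses
#'
#' Evaluates, for one or more layers, the cross-bridge driving force `Fc`, the
#' contractile-unit chain stiffness `ktCU`, the actin-cortex stiffness `kAC`
#' (Hill function of the F-actin content xi7 = 1 - xi6) and the reaction force
#' `Fa` of the fibre, the product of the total elongation
#' `lambda_theta - 1 - 2 N_CU u_fs` and the series stiffness
#' `ktCU kAC / (2 ktCU + kAC)`. Forces are in normalized units (multiply by
#' `N_CF` for stress).
#'
#' @param u_fs Normalized relative filament sliding (vectorized over layers).
#' @param xi5 LC20 phosphorylation level in \[0, 1\].
#' @param xi7 F-actin content in \[0, 1\] (`1 - xi6`).
#' @param lambda_theta Circumferential stretch (> 0), vectorized.
#' @param params A [contractile_params()].
#' @return A tibble with columns `Fc`, `ktCU`, `kAC`, `Fa`.
#' @export
contractile_system <- function(u_fs, xi5, xi7, lambda_theta,
                               params = contractile_params()) {
  stopifnot(xi5 >= 0, xi5 <= 1, xi7 >= 0, xi7 <= 1, all(lambda_theta > 0))
  p <- params
  Lfo <- filament_overlap(u_fs, p)
  Fc <- Lfo * (p$L_m / p$delta_m) * xi5 * p$n_XB_max * p$k_XB * p$u_PS
  ktCU <- Lfo * p$L_m * xi5 * p$n_XB_max * p$k_XB / (2 * p$delta_m * p$N_CU)
  kAC <- p$k_AC_max * xi7^p$n_AC / (xi7^p$n_AC + p$K_AC^p$n_AC)
  Fa <- (lambda_theta - 1 - 2 * p$N_CU * u_fs) * series_stiffness(ktCU, kAC)
  tibble(Fc = Fc, ktCU = ktCU, kAC = kAC, Fa = Fa)
}

#' Incompressible thick-walled tube kinematics
#'
#' Maps reference radii `R` to deformed radii
#' `r = sqrt((R^2 - Ri^2) / (k_omega lambda_z) + ri^2)` and returns the
#' circumferential and radial stretches `lambda_theta = k_omega r / R`,
#' `lambda_r = R / (r k_omega lambda_z)`; incompressibility
#' `lambda_r lambda_theta lambda_z = 1` holds by construction.
#'
#' @param ri Deformed luminal radius, cm (> 0).
#' @param R Reference radius or radii in `[Ri, Ri + H]`, cm.
#' @param geometry A [wall_geometry()].
#' @return A list with `r`, `lambda_r`, `lambda_theta`.
#' @export
kinematics <- function(ri, R, geometry) {
  stopifnot(ri > 0)
  if (any(R < geometry$Ri - 1e-12) || any(R > geometry$Ri + geometry$H + 1e-12))
    abort("`R` must lie within the reference wall.", class = "myoflow_geometry_error")
  arg <- (R^2 - geometry$Ri^2) / (geometry$k_omega * geometry$lambda_z) + ri^2
  if (any(arg <= 0))
    abort("Degenerate deformation: negative squared radius.",
          class = "myoflow_geometry_error")
  r <- sqrt(arg)
  list(r = r,
       lambda_r = R / (r * geometry$k_omega * geometry$lambda_z),
       lambda_theta = geometry$k_omega * r / R)
}

#' Strain-energy densities of the wall material
#'
#' Active part `Psi_a = N_CF/2 * k_series * (lambda_theta - 1 - 2 N_CU u_fs)^2`
#' (the potential of the fibre reaction force at frozen sliding and
#' stiffnesses) and passive part
#' `Psi_p = c0 (I1 - 3) + c1/(2 c2) (exp(c2 (I4 - 1)^2) - 1)`.
#'
#' @param lambda_r,lambda_theta,lambda_z Principal stretches (> 0); vectorized
#'   over layers.
#' @param u_fs Per-layer sliding.
#' @param xi5,xi7 Signalling inputs of the contractile system.
#' @param contractile A [contractile_params()].
#' @param passive A [passive_params()].
#' @return A tibble with columns `Psi_a`, `Psi_p` (dyn/cm^2).
#' @export
strain_energy <- function(lambda_r, lambda_theta, lambda_z, u_fs, xi5, xi7,
                          contractile = contractile_params(),
                          passive = passive_params()) {
  cs <- contractile_system(u_fs, xi5, xi7, lambda_theta, contractile)
  ks <- series_stiffness(cs$ktCU, cs$kAC)
  el <- lambda_theta - 1 - 2 * contractile$N_CU * u_fs
  Psi_a <- contractile$N_CF / 2 * ks * el^2
  I1 <- lambda_r^2 + lambda_theta^2 + lambda_z^2
  I4 <- lambda_theta^2 * cos(passive$phi)^2 + lambda_z^2 * sin(passive$phi)^2
  e <- exp(passive$c2 * (I4 - 1)^2)
  if (any(!is.finite(e)))
    abort("Overflow in the fibre exponential (material instability).",
          class = "myoflow_material_error")
  Psi_p <- passive$c0 * (I1 - 3) + passive$c1 / (2 * passive$c2) * (e - 1)
  tibble(Psi_a = Psi_a, Psi_p = Psi_p)
}

#' Strain-energy derivatives
#'
#' Partial derivatives used by the transmural momentum balance:
#' `dPsi_a/dlt = N_CF k_series (lambda_theta - 1 - 2 N_CU u_fs)` (at frozen
#' sliding), `dPsi_p/dlt = 2 c0 lt + 2 c1 (I4 - 1) exp(c2 (I4 - 1)^2) lt
#' cos(phi)^2` and `dPsi_p/dlr = 2 c0 lr`.
#'
#' @inheritParams strain_energy
#' @return A tibble with columns `dPsi_a_dlt`, `dPsi_p_dlt`, `dPsi_p_dlr`
#'   (dyn/cm^2 per unit stretch).
#' @export
strain_energy_derivatives <- function(lambda_r, lambda_theta, lambda_z, u_fs,
                                      xi5, xi7,
                                      contractile = contractile_params(),
                                      passive = passive_params()) {
  stopifnot(all(lambda_r > 0), all(lambda_theta > 0), all(lambda_z > 0))
  cs <- contractile_system(u_fs, xi5, xi7, lambda_theta, contractile)
  ks <- series_stiffness(cs$ktCU, cs$kAC)
  el <- lambda_theta - 1 - 2 * contractile$N_CU * u_fs
  dPsi_a_dlt <- contractile$N_CF * ks * el
  I4 <- lambda_theta^2 * cos(passive$phi)^2 + lambda_z^2 * sin(passive$phi)^2
  e <- exp(passive$c2 * (I4 - 1)^2)
  if (any(!is.finite(e)))
    abort("Overflow in the fibre exponential (material instability).",
          class = "myoflow_material_error")
  dPsi_p_dlt <- 2 * passive$c0 * lambda_theta +
    2 * passive$c1 * (I4 - 1) * e * lambda_theta * cos(passive$phi)^2
  dPsi_p_dlr <- 2 * passive$c0 * lambda_r
  tibble(dPsi_a_dlt = dPsi_a_dlt, dPsi_p_dlt = dPsi_p_dlt,
         dPsi_p_dlr = dPsi_p_dlr)
}

#' Transmural pressure from the radial momentum balance
#'
#' Luminal pressure sustained by the wall at luminal area `A`:
#' `P = Pext + integral over [Ri, Ri+H] of
#' (lt dPsi/dlt - lr dPsi/dlr) dR / (lt lz r)`, evaluated with the
#' interpolatory (Simpson-type) quadrature on the layer midpoints.
#'
#' @param A Luminal area, cm^2 (> 0).
#' @param u_fs Per-layer sliding (length `n_layers`).
#' @param xi5,xi7 Signalling inputs; set `active = FALSE` for a passive tube.
#' @param geometry A [wall_geometry()].
#' @param contractile,passive Parameter sets.
#' @param Pext External pressure, dyn/cm^2.
#' @param active Include the active stress? Default `TRUE`.
#' @param n_quad Optional number of fine quadrature points; `NULL` (default)
#'   uses the layer-midpoint rule. A large odd value gives a composite-Simpson
#'   reference evaluation (per-layer `u_fs` is then interpolated in `R`).
#' @return Luminal pressure, dyn/cm^2.
#' @export
transmural_pressure <- function(A, u_fs, xi5 = 0, xi7 = 0, geometry,
                                contractile = contractile_params(),
                                passive = passive_params(),
                                Pext = 0, active = TRUE, n_quad = NULL) {
  stopifnot(inherits(geometry, "myoflow_wall_geometry"), A > 0)
  if (length(u_fs) != geometry$n_layers)
    abort("`u_fs` must have one entry per layer.", class = "myoflow_config_error")
  if (is.null(n_quad)) {
    R <- geometry$R_mid
    w <- geometry$w
    u <- u_fs
  } else {
    n_quad <- as.integer(n_quad)
    if (n_quad < 3L || n_quad %% 2L == 0L)
      abort("`n_quad` must be odd and >= 3.", class = "myoflow_config_error")
    R <- seq(geometry$Ri, geometry$Ri + geometry$H, length.out = n_quad)
    h <- R[2] - R[1]
    # composite Simpson weights: 1,4,2,4,...,2,4,1 scaled by h/3
    w <- h / 3 * c(1, ifelse(seq_len(n_quad - 2L) %% 2L == 1L, 4, 2), 1)
    u <- approx(geometry$R_mid, u_fs, xout = R, rule = 2)$y
  }
  ri <- sqrt(A / pi)
  k <- kinematics(ri, R, geometry)
  d <- strain_energy_derivatives(k$lambda_r, k$lambda_theta, geometry$lambda_z,
                                 u, xi5, xi7, contractile, passive)
  dlt <- d$dPsi_p_dlt + if (active) d$dPsi_a_dlt else 0
  integrand <- (k$lambda_theta * dlt - k$lambda_r * d$dPsi_p_dlr) /
    (k$lambda_theta * geometry$lambda_z * k$r)
  Pext + sum(w * integrand)
}

#' Pressure-area sweep of the wall model
#'
#' Evaluates the transmural pressure over a range of luminal areas at frozen
#' sliding and signalling — the static constitutive curve of the cross-section.
#'
#' @param A Vector of luminal areas, cm^2.
#' @inheritParams transmural_pressure
#' @return A tibble with columns `A`, `P` (dyn/cm^2), `P_mmHg`, `di_um`.
#' @export
pressure_area_curve <- function(A, geometry, u_fs = rep(-2e-2, geometry$n_layers),
                                xi5 = 0, xi7 = 0,
                                contractile = contractile_params(),
                                passive = passive_params(),
                                Pext = 0, active = TRUE) {
  P <- vapply(A, transmural_pressure, numeric(1), u_fs = u_fs, xi5 = xi5,
              xi7 = xi7, geometry = geometry, contractile = contractile,
              passive = passive, Pext = Pext, active = active)
  tibble(A = A, P = P, P_mmHg = cgs_to_mmHg(P), di_um = 2 * sqrt(A / pi) / .UM)
}

# Two-step backward difference (BDF2) rate; backward Euler when x_prev2 is NULL.
bdf_rate <- function(x_new, x_prev, x_prev2, dt) {
  if (is.null(x_prev2)) (x_new - x_prev) / dt
  else (3 * x_new - 4 * x_prev + x_prev2) / (2 * dt)
}

#' Wall residual system
#'
#' Residuals of the time-discretized wall equations at a candidate new state:
#' the first `n_layers` entries are the filament-sliding relations
#' `F_k = D(u_k) - (Fa_k - Fc_k)/tau_m - D(lambda_theta_k)/(2 N_CU)` (with `D`
#' the two-step backward difference, backward Euler at start-up) and the last
#' entry is the pressure balance `J = P - Pext - I(A, u)` (reported in mmHg for
#' balanced scaling). With `averaged = TRUE` the system reduces to two
#' equations: one sliding relation driven by the thickness-averaged stretch and
#' the pressure balance with the shared sliding value.
#'
#' @param u_new Candidate sliding at the new time level (length `n_layers`, or
#'   length 1 when `averaged`).
#' @param A_new Candidate luminal area, cm^2.
#' @param P Luminal pressure at the new time level, dyn/cm^2.
#' @param dt Time step, s.
#' @param history List with `u_prev`, `A_prev` and (optionally) `u_prev2`,
#'   `A_prev2` for the two-step form.
#' @param xi5,xi7 Signalling inputs at the new time level.
#' @param geometry,params A [wall_geometry()] and [myoflow_params()].
#' @param averaged Use the averaged-active-stress two-equation variant?
#' @return Numeric residual vector (length `n_layers + 1`, or 2 when averaged).
#' @export
wall_residuals <- function(u_new, A_new, P, dt, history, xi5, xi7,
                           geometry, params, averaged = FALSE) {
  stopifnot(inherits(params, "myoflow_params"), A_new > 0)
  cp <- params$contractile
  lt_of <- function(A) kinematics(sqrt(A / pi), geometry$R_mid, geometry)$lambda_theta
  lt_new <- lt_of(A_new)
  lt_prev <- lt_of(history$A_prev)
  lt_prev2 <- if (is.null(history$A_prev2)) NULL else lt_of(history$A_prev2)
  wbar <- geometry$w / geometry$H
  if (averaged) {
    stopifnot(length(u_new) == 1L)
    ltb_new <- sum(wbar * lt_new)
    ltb_prev <- sum(wbar * lt_prev)
    ltb_prev2 <- if (is.null(lt_prev2)) NULL else sum(wbar * lt_prev2)
    cs <- contractile_system(u_new, xi5, xi7, ltb_new, cp)
    Fk <- bdf_rate(u_new, history$u_prev, history$u_prev2, dt) -
      (cs$Fa - cs$Fc) / params$tau_m -
      bdf_rate(ltb_new, ltb_prev, ltb_prev2, dt) / (2 * cp$N_CU)
    u_layers <- rep(u_new, geometry$n_layers)
  } else {
    stopifnot(length(u_new) == geometry$n_layers)
    cs <- contractile_system(u_new, xi5, xi7, lt_new, cp)
    Fk <- bdf_rate(u_new, history$u_prev, history$u_prev2, dt) -
      (cs$Fa - cs$Fc) / params$tau_m -
      bdf_rate(lt_new, lt_prev, lt_prev2, dt) / (2 * cp$N_CU)
    u_layers <- u_new
  }
  Pw <- transmural_pressure(A_new, u_layers, xi5, xi7, geometry,
                            cp, params$passive,
                            Pext = mmHg_to_cgs(params$Pext_mmHg),
                            active = params$wall_mode == "active")
  c(Fk, cgs_to_mmHg(P - Pw))
}

#' Advance one wall cross-section by one time step
#'
#' Solves the wall residual system for the new sliding and luminal area at a
#' prescribed luminal pressure (damped Newton with finite-difference Jacobian,
#' run in compiled code), then recovers the compliance `C_A = dA/dP` by a
#' centered finite difference of the frozen-intracellular-state pressure-area
#' relation (perturbation equivalent to 0.1 mmHg).
#'
#' @param P_new Luminal pressure at the new time level, mmHg.
#' @param state A [wall_state()] at time t.
#' @param signalling A [signalling_state()] at the new time level.
#' @param dt Time step, s.
#' @param params A [myoflow_params()].
#' @param history Optional list with `u_prev2`, `A_prev2` (states at t - dt)
#'   enabling the two-step backward form; `NULL` uses backward Euler.
#' @param averaged Use the averaged-active-stress variant?
#' @return The new [wall_state()]; attribute `"residual_norm"` carries the
#'   final Newton residual norm.
#' @export
step_wall <- function(P_new, state, signalling, dt, params = myoflow_params(),
                      history = NULL, averaged = FALSE) {
  stopifnot(inherits(state, "myoflow_wall_state"), dt > 0)
  geometry <- state$geometry
  xi5 <- unname(signalling[["xi5"]])
  xi7 <- 1 - unname(signalling[["xi6"]])
  res <- cpp_wall_step(
    pars_for_cpp(params, geometry),
    u_prev = state$u_fs, A_prev = state$A,
    u_prev2 = if (is.null(history)) numeric(0) else history$u_prev2,
    A_prev2 = if (is.null(history)) -1 else history$A_prev2,
    P_new = mmHg_to_cgs(P_new), xi5 = xi5, xi7 = xi7, dt = dt,
    C_prev = if (is.finite(state$C_A)) state$C_A else -1,
    averaged = averaged)
  if (!res$converged)
    abort(sprintf("Wall step failed to converge (residual %.3e).",
                  res$resid_norm), class = "myoflow_step_error")
  new <- wall_state(geometry, u_fs = res$u, A = res$A, C_A = res$C_A)
  attr(new, "residual_norm") <- res$resid_norm
  new
}
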