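#' Logistic signalling link
#'
#' One edge of the logic-based intracellular signalling graph: a logistic
#' function `1 / (1 + exp(-slope * (x - half_activation)))` connecting a
#' driving variable (luminal pressure, in mmHg, or one of the signalling
#' variables `xi0..xi6`) to the activation of a downstream process. An
#' `inverted` link returns the complement, `1 - logistic(x)`, and is used for
#' inhibitory edges.
#'
#' @param slope Dimensionless steepness; must be finite and non-zero.
#' @param half_activation Input value at which the (non-inverted) output is 0.5,
#'   in the units of the driving variable.
#' @param input Identifier of the driving variable: `"P"` (pressure, mmHg) or
#'   `"xi0"`..`"xi6"`.
#' @param inverted Logical; if `TRUE` the output is complemented.
#' @return A list of class `myoflow_link`.
#' @seealso [evaluate_link()], [link_table()]
#' @export
logistic_link <- function(slope, half_activation, input = "P", inverted = FALSE) {
  stopifnot(is.numeric(slope), length(slope) == 1L, is.finite(slope),
            is.numeric(half_activation), length(half_activation) == 1L,
            is.finite(half_activation), is.logical(inverted), length(inverted) == 1L)
  if (slope == 0) abort("`slope` must be non-zero.", class = "myoflow_config_error")
  input <- match.arg(input, c("P", paste0("xi", 0:6)))
  structure(list(slope = slope, half_activation = half_activation,
                 input = input, inverted = inverted),
            class = "myoflow_link")
}

#' Table of the nine signalling links
#'
#' Bundles the nine logistic links chi0..chi8 that wire the signalling graph.
#' The default wiring is: chi0 and chi1 map luminal pressure onto the Ca2+ and
#' ROCK targets; chi2, chi3 (inverted) and chi4 map ROCK activity onto HSP27,
#' MLCP and cofilin phosphorylation; chi5 maps Ca2+ onto LC20 phosphorylation
#' (cross-bridge recruitment); chi6 maps MLCP phosphorylation onto the arrest of
#' LC20 dephosphorylation; chi7 and chi8 map HSP27 and cofilin phosphorylation
#' onto actin polymerization (G-actin depletion). Parameter values are
#' package defaults chosen so that the pressure-driven pathways rise
#' sigmoidally over 10-120 mmHg with limited ROCK/MLCP engagement below
#' 60 mmHg; they are fully overridable.
#'
#' @param ... Named `myoflow_link` overrides, e.g. `chi0 = logistic_link(...)`.
#' @return A tibble with one row per link (class `myoflow_link_table`):
#'   columns `name`, `input`, `slope`, `half_activation`, `inverted`.
#' @export
link_table <- function(...) {
  defaults <- list(
    chi0 = logistic_link(0.06, 50,  "P"),
    chi1 = logistic_link(0.08, 85,  "P"),
    chi2 = logistic_link(5,    0.25, "xi1"),
    chi3 = logistic_link(6,    0.5, "xi1", inverted = TRUE),
    chi4 = logistic_link(5,    0.25, "xi1"),
    chi5 = logistic_link(8,    0.35, "xi0"),
    chi6 = logistic_link(6,    0.5, "xi3"),
    chi7 = logistic_link(4,    0.3, "xi2"),
    chi8 = logistic_link(4,    0.3, "xi4")
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(defaults))
    if (length(bad))
      abort(paste0("Unknown link name(s): ", paste(bad, collapse = ", ")),
            class = "myoflow_config_error")
    ok <- vapply(overrides, inherits, logical(1), "myoflow_link")
    if (!all(ok)) abort("Link overrides must be `logistic_link()` objects.",
                        class = "myoflow_config_error")
    defaults[names(overrides)] <- overrides
  }
  tbl <- purrr::imap_dfr(defaults, function(l, nm)
    tibble(name = nm, input = l$input, slope = l$slope,
           half_activation = l$half_activation, inverted = l$inverted))
  class(tbl) <- c("myoflow_link_table", class(tbl))
  tbl
}

#' Intracellular signalling parameters
#'
#' Time constants and link table for the seven normalized signalling variables:
#' Ca2+ concentration (xi0), ROCK activity (xi1), HSP27 phosphorylation (xi2),
#' MLCP phosphorylation (xi3), cofilin phosphorylation (xi4), LC20
#' phosphorylation (xi5) and G-actin content (xi6). The three upstream
#' pressure-induced pathways share a single time constant `tau_c`
#' (tau_c0 = tau_c1 = tau_c2); the downstream processes (tau_c3..tau_c6) are
#' treated as quasi-instantaneous by default (`tau_fast = 0`), i.e. those
#' variables are pinned to their algebraic targets at every step.
#'
#' @param tau_c Shared time constant of the Ca2+/ROCK/HSP27 relaxations, s.
#'   Default 10 s.
#' @param tau_fast Length-4 vector (tau_c3, tau_c4, tau_c5, tau_c6) in s; 0
#'   means quasi-instantaneous (the default). Finite positive values are only
#'   used by [signalling_rhs()] and fine-grained ODE integrations.
#' @param links A [link_table()].
#' @param calcium_mode `"control"` (full pressure-driven Ca2+ entry),
#'   `"diltiazem"` (L-type channels blocked: a small residual stretch-operated
#'   component remains) or `"zero_ca"` (no extracellular Ca2+: the Ca2+ target
#'   is identically 0).
#' @param ca_max_nM Concentration corresponding to xi0 = 1, used only for
#'   reporting Ca2+ traces in nM. Default 230 nM.
#' @param dilt_scale,dilt_slope,dilt_half Residual stretch-operated Ca2+ entry
#'   under diltiazem: target is `dilt_scale * logistic(dilt_slope, dilt_half)`.
#' @return A list of class `myoflow_signalling_params`.
#' @export
signalling_params <- function(tau_c = 10, tau_fast = c(0, 0, 0, 0),
                              links = link_table(),
                              calcium_mode = c("control", "diltiazem", "zero_ca"),
                              ca_max_nM = 230,
                              dilt_scale = 0.15, dilt_slope = 0.03, dilt_half = 60) {
  calcium_mode <- match.arg(calcium_mode)
  if (!is.numeric(tau_c) || length(tau_c) != 1L || !is.finite(tau_c) || tau_c <= 0)
    abort("`tau_c` must be a single positive number (seconds).",
          class = "myoflow_config_error")
  stopifnot(length(tau_fast) == 4L, all(is.finite(tau_fast)), all(tau_fast >= 0))
  if (!inherits(links, "myoflow_link_table"))
    abort("`links` must be a `link_table()`.", class = "myoflow_config_error")
  structure(list(tau_c = tau_c, tau_fast = as.numeric(tau_fast), links = links,
                 calcium_mode = calcium_mode, ca_max_nM = ca_max_nM,
                 dilt_scale = dilt_scale, dilt_slope = dilt_slope,
                 dilt_half = dilt_half),
            class = "myoflow_signalling_params")
}

#' Contractile machinery parameters
#'
#' Parameters of the cross-bridge / contractile-unit model of smooth muscle
#' force generation. Forces produced by the contractile system are expressed in
#' normalized (reference cross-bridge) units; the surface density of
#' contractile fibres `N_CF` (dyn/cm^2 per unit normalized force) carries the
#' conversion to wall stress, so that the active first Piola-Kirchhoff stress
#' is `N_CF * Fa`. Lengths entering only as ratios (`L_m`, `delta_m`, `s_f0`)
#' are in micrometres.
#'
#' @param L_m Average myosin filament length (um).
#' @param delta_m Average spacing between myosin monomer heads (um);
#'   `L_m / delta_m` is the number of heads per filament.
#' @param n_XB_max Maximum fraction of phosphorylated cross-bridges engaged
#'   (dimensionless).
#' @param k_XB Cross-bridge elastic stiffness (normalized units).
#' @param u_PS Average power-stroke displacement (normalized by `L_m`).
#' @param N_CU Number of contractile units in series per contractile fibre.
#' @param s_f0 Width parameter of the filament-overlap bell (um).
#' @param u_fs_opt Relative filament sliding at which overlap is maximal
#'   (dimensionless).
#' @param N_CF Surface density of contractile fibres, dyn/cm^2 per unit
#'   normalized force.
#' @param k_AC_max Maximum actin-cortex stiffness (normalized units).
#' @param n_AC,K_AC Hill coefficient and half-activation of the cortex
#'   stiffness dependence on F-actin content (xi7 = 1 - xi6).
#' @return A list of class `myoflow_contractile_params`.
#' @export
contractile_params <- function(L_m = 1.1, delta_m = 0.0143, n_XB_max = 0.8,
                               k_XB = 1, u_PS = 0.01, N_CU = 5,
                               s_f0 = 0.308, u_fs_opt = 0.01,
                               N_CF = 1.2e6, k_AC_max = 10, n_AC = 2,
                               K_AC = 0.3) {
  p <- list(L_m = L_m, delta_m = delta_m, n_XB_max = n_XB_max, k_XB = k_XB,
            u_PS = u_PS, N_CU = N_CU, s_f0 = s_f0, u_fs_opt = u_fs_opt,
            N_CF = N_CF, k_AC_max = k_AC_max, n_AC = n_AC, K_AC = K_AC)
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                logical(1))
  if (!all(num)) abort("All contractile parameters must be finite scalars.",
                       class = "myoflow_config_error")
  pos <- setdiff(names(p), "u_fs_opt")
  if (any(unlist(p[pos]) <= 0))
    abort("All contractile parameters (except `u_fs_opt`) must be positive.",
          class = "myoflow_config_error")
  structure(p, class = "myoflow_contractile_params")
}

#' Passive (hyperelastic) wall parameters
#'
#' Media constitutive parameters of the passive strain-energy density
#' `Psi_p = c0 (I1 - 3) + c1/(2 c2) * (exp(c2 (I4 - 1)^2) - 1)` with
#' `I1 = lr^2 + lt^2 + lz^2` and `I4 = lt^2 cos(phi)^2 + lz^2 sin(phi)^2`,
#' i.e. an isotropic ground matrix plus an exponentially stiffening collagen
#' fibre family at angle `phi` from the circumferential direction.
#'
#' @param c0 Ground-matrix modulus, dyn/cm^2.
#' @param c1 Fibre modulus, dyn/cm^2.
#' @param c2 Dimensionless fibre stiffening exponent.
#' @param phi Fibre-family angle from the circumferential direction, radians
#'   (default 0: circumferential fibres).
#' @return A list of class `myoflow_passive_params`.
#' @export
passive_params <- function(c0 = 4.0e4, c1 = 4.0e4, c2 = 8, phi = 0) {
  stopifnot(is.numeric(c0), is.numeric(c1), is.numeric(c2), is.numeric(phi))
  if (c0 < 0 || c1 < 0 || c2 < 0)
    abort("`c0`, `c1`, `c2` must be non-negative.", class = "myoflow_config_error")
  structure(list(c0 = c0, c1 = c1, c2 = c2, phi = phi),
            class = "myoflow_passive_params")
}

#' Blood properties
#'
#' @param rho Density, g/cm^3 (default 1.04).
#' @param mu Dynamic viscosity, poise (default 0.05).
#' @return A list of class `myoflow_fluid_params`.
#' @export
fluid_params <- function(rho = 1.04, mu = 0.05) {
  stopifnot(rho > 0, mu > 0)
  structure(list(rho = rho, mu = mu), class = "myoflow_fluid_params")
}

#' Wall cross-section reference geometry
#'
#' Reference (stress-free) geometry of one vessel wall cross-section: luminal
#' radius `Ri`, thickness `H`, residual-strain parameter `k_omega`, axial
#' stretch `lambda_z`, and the number of concentric smooth-muscle layers
#' `n_layers` (odd, so the layer midpoints support the transmural quadrature).
#'
#' @param Ri Reference luminal radius, cm.
#' @param H Reference wall thickness, cm.
#' @param k_omega Residual-strain (opening-angle) parameter; default 1.
#' @param lambda_z Axial stretch; default 1.
#' @param n_layers Number of SMC layers (odd, >= 1); default 5.
#' @return A list of class `myoflow_wall_geometry` with, in addition, the layer
#'   midpoint radii `R_mid` and transmural quadrature weights `w` (summing to
#'   `H`).
#' @seealso [load_free_geometry()] to derive `Ri`, `H` from a load-free outer
#'   diameter and thickness ratio.
#' @export
wall_geometry <- function(Ri, H, k_omega = 1, lambda_z = 1, n_layers = 5) {
  stopifnot(is.numeric(Ri), is.numeric(H), Ri > 0, H > 0,
            k_omega > 0, lambda_z > 0)
  n_layers <- as.integer(n_layers)
  if (n_layers < 1L || n_layers %% 2L == 0L)
    abort("`n_layers` must be odd and >= 1.", class = "myoflow_config_error")
  R_mid <- Ri + (seq_len(n_layers) - 0.5) * H / n_layers
  structure(list(Ri = Ri, H = H, k_omega = k_omega, lambda_z = lambda_z,
                 n_layers = n_layers, R_mid = R_mid,
                 w = midpoint_quadrature_weights(n_layers) * H),
            class = "myoflow_wall_geometry")
}

# Interpolatory quadrature weights for n equispaced midpoint abscissae
# x_k = (k - 1/2)/n on [0, 1]: exact for polynomials up to degree n - 1.
midpoint_quadrature_weights <- function(n) {
  x <- (seq_len(n) - 0.5) / n
  V <- t(vapply(seq_len(n) - 1L, function(p) x^p, numeric(n)))
  moments <- 1 / seq_len(n)
  solve(V, moments)
}

#' Reference geometry from load-free measurements
#'
#' Vessels are usually specified by their load-free outer diameter `Do` and the
#' thickness-to-mean-radius ratio `hw` measured under zero transmural load.
#' With no residual strain (`k_omega = 1`) and no axial pre-stretch the
#' load-free configuration is the stress-free reference, so
#' `Rm = Do / (2 + hw)`, `H = hw * Rm`, `Ri = Rm - H / 2`.
#'
#' @param Do_um Load-free outer diameter, micrometres.
#' @param hw Thickness-to-mean-radius ratio (0 < hw < 1).
#' @inheritParams wall_geometry
#' @return A `myoflow_wall_geometry`.
#' @export
load_free_geometry <- function(Do_um, hw, k_omega = 1, lambda_z = 1, n_layers = 5) {
  stopifnot(Do_um > 0, hw > 0, hw < 1)
  Rm <- Do_um * .UM / (2 + hw)
  H <- hw * Rm
  wall_geometry(Ri = Rm - H / 2, H = H, k_omega = k_omega,
                lambda_z = lambda_z, n_layers = n_layers)
}

#' Full model parameter set
#'
#' Bundles the signalling, contractile, passive and fluid parameter sets with
#' the remaining simulation-level physical constants.
#'
#' @param signalling A [signalling_params()].
#' @param contractile A [contractile_params()].
#' @param passive A [passive_params()].
#' @param fluid A [fluid_params()].
#' @param tau_m Filament-sliding time constant, s. Default 6.188e-2 s
#'   (1e3 times the mouse descending-aorta estimate 6.188e-5 s, the
#'   best-fitting value for cerebral arteries).
#' @param Pext_mmHg External (tissue) pressure on the outer wall surface, mmHg.
#' @param wall_mode `"active"` (full chemo-mechanics), `"passive"`
#'   (hyperelastic tube, contractility removed) or `"rigid"` (areas frozen at
#'   their initial values, zero compliance).
#' @return A list of class `myoflow_params`.
#' @export
myoflow_params <- function(signalling = signalling_params(),
                           contractile = contractile_params(),
                           passive = passive_params(),
                           fluid = fluid_params(),
                           tau_m = 6.188e-2,
                           Pext_mmHg = 10,
                           wall_mode = c("active", "passive", "rigid")) {
  wall_mode <- match.arg(wall_mode)
  stopifnot(inherits(signalling, "myoflow_signalling_params"),
            inherits(contractile, "myoflow_contractile_params"),
            inherits(passive, "myoflow_passive_params"),
            inherits(fluid, "myoflow_fluid_params"))
  if (!is.numeric(tau_m) || tau_m <= 0)
    abort("`tau_m` must be positive (seconds).", class = "myoflow_config_error")
  structure(list(signalling = signalling, contractile = contractile,
                 passive = passive, fluid = fluid, tau_m = tau_m,
                 Pext_mmHg = Pext_mmHg, wall_mode = wall_mode),
            class = "myoflow_params")
}

# Flatten parameter sets into the plain lists consumed by the C++ core.
pars_for_cpp <- function(params, geometry = NULL) {
  sg <- params$signalling
  lt <- sg$links
  input_code <- function(x) {
    out <- integer(length(x))
    isxi <- x != "P"
    out[isxi] <- as.integer(sub("xi", "", x[isxi])) + 1L
    out
  }
  cp <- params$contractile
  pp <- params$passive
  out <- list(
    link_slope = lt$slope, link_half = lt$half_activation,
    link_inv = as.integer(lt$inverted), link_input = input_code(lt$input),
    tau_c = sg$tau_c,
    calcium_mode = match(sg$calcium_mode, c("control", "diltiazem", "zero_ca")) - 1L,
    dilt_scale = sg$dilt_scale, dilt_slope = sg$dilt_slope, dilt_half = sg$dilt_half,
    Lm = cp$L_m, dm = cp$delta_m, nXB = cp$n_XB_max, kXB = cp$k_XB,
    uPS = cp$u_PS, NCU = cp$N_CU, sf0 = cp$s_f0, ufs_opt = cp$u_fs_opt,
    NCF = cp$N_CF, kACmax = cp$k_AC_max, nAC = cp$n_AC, KAC = cp$K_AC,
    c0 = pp$c0, c1 = pp$c1, c2 = pp$c2, phi = pp$phi,
    rho = params$fluid$rho, mu = params$fluid$mu,
    tau_m = params$tau_m, Pext = mmHg_to_cgs(params$Pext_mmHg),
    wall_mode = match(params$wall_mode, c("active", "passive", "rigid")) - 1L
  )
  if (!is.null(geometry))
    out <- c(out, list(Ri = geometry$Ri, H = geometry$H,
                       komega = geometry$k_omega, lamz = geometry$lambda_z,
                       nCL = geometry$n_layers))
  out
}
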