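cp <- contractile_params()
pp <- passive_params()

test_that("filament overlap is a unit-peak symmetric bell", {
  expect_equal(filament_overlap(cp$u_fs_opt, cp), 1)
  d <- 0.07
  expect_equal(filament_overlap(cp$u_fs_opt + d, cp),
               filament_overlap(cp$u_fs_opt - d, cp))
  u <- seq(-0.5, 0.5, by = 0.05)
  expect_true(all(filament_overlap(u, cp) <= 1))
})

test_that("contractile system limits behave physically", {
  # no phosphorylated cross-bridges: no driving force, no CU stiffness
  cs0 <- contractile_system(-0.02, xi5 = 0, xi7 = 0.5, lambda_theta = 1.2, cp)
  expect_equal(cs0$Fc, 0)
  expect_equal(cs0$ktCU, 0)
  expect_equal(cs0$Fa, 0)
  # Hill half-activation of the actin cortex
  cs1 <- contractile_system(0, 0.5, xi7 = cp$K_AC, 1.1, cp)
  expect_equal(cs1$kAC, cp$k_AC_max / 2)
  # zero total elongation cancels the fibre reaction force
  u <- 0.015
  cs2 <- contractile_system(u, 0.7, 0.6, 1 + 2 * cp$N_CU * u, cp)
  expect_equal(cs2$Fa, 0)
})

test_that("kinematics maps the wall incompressibly", {
  g <- wall_geometry(Ri = 50e-4, H = 12e-4, k_omega = 1.1, lambda_z = 1.2)
  expect_equal(kinematics(55e-4, g$Ri, g)$r, 55e-4)
  g1 <- wall_geometry(Ri = 50e-4, H = 12e-4)
  k1 <- kinematics(g1$Ri, g1$R_mid, g1)
  expect_equal(k1$lambda_theta[1], 1, tolerance = 1e-12)
  set.seed(4)
  for (i in 1:10) {
    ri <- runif(1, 30e-4, 90e-4)
    k <- kinematics(ri, g$R_mid, g)
    expect_equal(k$lambda_r * k$lambda_theta * g$lambda_z,
                 rep(1, g$n_layers), tolerance = 1e-13)
  }
  expect_error(kinematics(1e-4, 200e-4, g), class = "myoflow_geometry_error")
})

test_that("strain-energy derivatives match finite differences of the energy", {
  lz <- 1.1
  u <- c(-0.03, -0.01, 0.005, 0.02, 0.04)
  lt <- c(1.05, 1.1, 1.15, 1.2, 1.25)
  lr <- 1 / (lt * lz)
  d <- strain_energy_derivatives(lr, lt, lz, u, 0.6, 0.5, cp, pp)
  h <- 1e-6
  # active part: frozen sliding and stiffnesses
  Ea <- function(l) strain_energy(lr, l, lz, u, 0.6, 0.5, cp, pp)$Psi_a
  expect_equal(d$dPsi_a_dlt, (Ea(lt + h) - Ea(lt - h)) / (2 * h),
               tolerance = 1e-6)
  Ep_t <- function(l) strain_energy(lr, l, lz, u, 0.6, 0.5, cp, pp)$Psi_p
  expect_equal(d$dPsi_p_dlt, (Ep_t(lt + h) - Ep_t(lt - h)) / (2 * h),
               tolerance = 1e-6)
  Ep_r <- function(l) strain_energy(l, lt, lz, u, 0.6, 0.5, cp, pp)$Psi_p
  expect_equal(d$dPsi_p_dlr, (Ep_r(lr + h) - Ep_r(lr - h)) / (2 * h),
               tolerance = 1e-6)
})

test_that("the passive energy vanishes at the identity configuration", {
  e <- strain_energy(1, 1, 1, -0.02, 0, 0, cp, pp)
  expect_equal(e$Psi_p, 0)
  d <- strain_energy_derivatives(1, 1, 1, -0.02, 0, 0, cp, pp)
  expect_equal(d$dPsi_p_dlt, 2 * pp$c0) # I4 = 1: only the c0 term remains
  expect_equal(d$dPsi_p_dlr, 2 * pp$c0)
  # circumferential fibres at unit stretch: I4 = 1 exactly
  expect_equal(1^2 * cos(pp$phi)^2 + 1^2 * sin(pp$phi)^2, 1)
})

test_that("active stress derivative integrates back to the active energy", {
  u <- rep(-0.015, 5)
  lz <- 1
  lts <- seq(1, 1.3, length.out = 401)
  vals <- vapply(lts, function(l)
    strain_energy_derivatives(1 / l, l, lz, u[1], 0.7, 0.6, cp, pp)$dPsi_a_dlt,
    numeric(1))
  quad <- sum((vals[-1] + vals[-length(vals)]) / 2 * diff(lts))
  E <- function(l) strain_energy(1 / l, l, lz, u[1], 0.7, 0.6, cp, pp)$Psi_a
  expect_equal(quad, E(1.3) - E(1), tolerance = 1e-6)
})

test_that("transmural pressure reduces to Pext at the reference state and is monotone", {
  g <- default_geom()
  A0 <- pi * g$Ri^2
  Pext <- mmHg_to_cgs(10)
  expect_equal(transmural_pressure(A0, rep(-0.02, 5), 0, 0, g, cp, pp,
                                   Pext = Pext, active = FALSE), Pext)
  As <- seq(0.8, 1.4, by = 0.025) * A0
  Ps <- vapply(As, transmural_pressure, numeric(1), u_fs = rep(-0.02, 5),
               xi5 = 0, xi7 = 0, geometry = g, contractile = cp, passive = pp,
               Pext = Pext, active = FALSE)
  expect_true(all(diff(Ps) > 0))
})

test_that("layer-midpoint quadrature agrees with a 1001-point reference", {
  g <- default_geom()
  A0 <- pi * g$Ri^2
  for (A in c(0.8, 1.0, 1.2, 1.4) * A0) {
    coarse <- transmural_pressure(A, rep(-0.02, 5), 0.5, 0.4, g, cp, pp,
                                  Pext = 0, active = TRUE)
    fine <- transmural_pressure(A, rep(-0.02, 5), 0.5, 0.4, g, cp, pp,
                                Pext = 0, active = TRUE, n_quad = 1001)
    expect_lt(abs(coarse - fine) / abs(fine), 0.005)
  }
})

test_that("geometry constructor enforces the odd-layer quadrature requirement", {
  expect_error(wall_geometry(50e-4, 12e-4, n_layers = 4),
               class = "myoflow_config_error")
  g <- wall_geometry(50e-4, 12e-4, n_layers = 7)
  expect_equal(sum(g$w), g$H)
})

test_that("compiled transmural pressure matches the R reference", {
  g <- default_geom()
  prm <- myoflow_params()
  pars <- myoflow:::pars_for_cpp(prm, g)
  set.seed(7)
  for (i in 1:8) {
    A <- pi * g$Ri^2 * runif(1, 0.8, 1.5)
    u <- runif(5, -0.06, 0.03)
    xi5 <- runif(1); xi7 <- runif(1)
    expect_equal(
      myoflow:::cpp_transmural_pressure(pars, A, u, xi5, xi7, TRUE),
      transmural_pressure(A, u, xi5, xi7, g, prm$contractile, prm$passive,
                          Pext = mmHg_to_cgs(prm$Pext_mmHg), active = TRUE),
      tolerance = 1e-12)
  }
})

test_that("wall stepping preserves a passive equilibrium and reports dA/dP", {
  g <- default_geom()
  prm <- myoflow_params(wall_mode = "passive")
  st <- wall_state(g)
  # settle to the static area for 50 mmHg, then hold: area must stay put
  s1 <- step_wall(50, st, signalling_state(0), dt = 0.5, params = prm)
  s2 <- step_wall(50, s1, signalling_state(0), dt = 0.5, params = prm,
                  history = list(u_prev2 = st$u_fs, A_prev2 = st$A))
  expect_equal(s2$A, s1$A, tolerance = 1e-9)
  # compliance against the analytic slope of the passive P(A) curve
  dA <- 1e-4 * s2$A
  Pf <- function(A) transmural_pressure(A, st$u_fs, 0, 0, g, prm$contractile,
                                        prm$passive,
                                        Pext = mmHg_to_cgs(prm$Pext_mmHg),
                                        active = FALSE)
  slope <- 2 * dA / (Pf(s2$A + dA) - Pf(s2$A - dA))
  expect_equal(s2$C_A, slope, tolerance = 0.01)
})

test_that("the wall residuals vanish at a solver-produced solution", {
  g <- default_geom()
  prm <- myoflow_params()
  st <- wall_state(g)
  sig <- signalling_steady_state(60, prm$signalling)
  s1 <- step_wall(60, st, sig, dt = 0.5, params = prm)
  res <- wall_residuals(s1$u_fs, s1$A, mmHg_to_cgs(60), dt = 0.5,
                        history = list(u_prev = st$u_fs, A_prev = st$A),
                        xi5 = unname(sig[["xi5"]]), xi7 = 1 - unname(sig[["xi6"]]),
                        geometry = g, params = prm)
  # sliding rows are 1/s rates; compare on the same scale as the solver (x dt)
  expect_lt(max(abs(res[1:5] * 0.5)), 1e-8)
  expect_lt(abs(res[6]), 1e-8)
  # the pressure row is zero exactly when P equals the transmural pressure
  Pw <- transmural_pressure(s1$A, s1$u_fs, unname(sig[["xi5"]]),
                            1 - unname(sig[["xi6"]]), g, prm$contractile,
                            prm$passive, Pext = mmHg_to_cgs(prm$Pext_mmHg))
  res2 <- wall_residuals(s1$u_fs, s1$A, Pw, dt = 0.5,
                         history = list(u_prev = st$u_fs, A_prev = st$A),
                         xi5 = unname(sig[["xi5"]]), xi7 = 1 - unname(sig[["xi6"]]),
                         geometry = g, params = prm)
  expect_equal(res2[6], 0)
})

test_that("sustained pressure leaves a toned vessel narrower than a Ca-free one", {
  sig <- signal_step_train(c(20, 60), 10)
  ctl <- single_vessel_protocol(sig, 150, dt = 0.5, mode = "control")
  zca <- single_vessel_protocol(sig, 150, dt = 0.5, mode = "zero_ca")
  n <- nrow(ctl)
  expect_lt(ctl$A_cm2[n], zca$A_cm2[n])
  expect_lt(ctl$do_um[n], zca$do_um[n])
})

test_that("averaged and layer-resolved variants agree for thin walls", {
  # H/Ri <= 0.15 requires hw <= ~0.14 in load-free terms
  g <- load_free_geometry(135, 0.13)
  prm <- myoflow_params()
  for (P in c(10, 40, 80, 120)) {
    full <- single_vessel_protocol(signal_constant(P), 250, dt = 0.5,
                                   geometry = g, params = prm)
    avg <- single_vessel_protocol(signal_constant(P), 250, dt = 0.5,
                                  geometry = g, params = prm, averaged = TRUE)
    n <- nrow(full)
    expect_lt(abs(avg$di_um[n] - full$di_um[n]) / full$di_um[n], 0.02)
  }
})
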