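test_that("element matrices encode the friction and rest-state identities", {
  # hand-evaluated Poiseuille drag coefficient 8 pi mu / A^2
  A <- pi * 0.01^2
  mu <- 0.05
  fl <- fluid_params(rho = 1.04, mu = mu)
  elem <- list(len = 0.2, A = c(A, A), C_A = c(0, 0))
  prev <- list(P = c(0, 0), Q = c(0, 0))
  em <- element_matrices(elem, prev, dt = 1e-3, fluid = fl)
  drag <- em$Ge[2, 1] - (elem$len / 2) * (fl$rho / A) / 1e-3
  expect_equal(drag, (elem$len / 2) * 8 * pi * mu / A^2, tolerance = 1e-12)
  expect_equal(drag * 1e-6 / (elem$len / 2), 8 * pi * mu * 1e-6 / A^2)
  # rigid element at rest: mass row enforces dQ/dz = 0 and both rows balance
  expect_equal(em$Fe[1, ], c(0, 0))
  expect_equal(em$Ge[1, ], c(-1, 1))
  expect_equal(em$he, c(0, 0))
  expect_error(element_matrices(list(len = 0.2, A = c(0, A), C_A = c(0, 0)),
                                prev, 1e-3, fl),
               class = "myoflow_singular_error")
})

test_that("a rigid tube with no pressure difference carries no flow", {
  topo <- single_tube()
  tp <- list(P = rep(mmHg_to_cgs(50), 3), Q = rep(0, 3),
             A = rep(1e-4, 3), C_A = rep(0, 3))
  sol <- assemble_and_solve(topo, tp, dt = 1e-3, Pin = mmHg_to_cgs(50),
                            Pout = mmHg_to_cgs(50), Z = 0)
  expect_lt(max(abs(sol$Q)), 1e-12)
  expect_equal(sol$P, rep(mmHg_to_cgs(50), 3), tolerance = 1e-12)
})

test_that("a rigid tube reaches the Poiseuille steady state", {
  topo <- single_tube(n_elements = 4L)
  fl <- fluid_params()
  A <- 1.1e-4
  L <- 0.4
  Pin <- mmHg_to_cgs(51)
  Pout <- mmHg_to_cgs(50)
  st <- list(P = rep(Pout, 5), Q = rep(0, 5), A = rep(A, 5), C_A = rep(0, 5))
  # rigid + inertial transient decays in a few viscous times
  for (k in 1:400) {
    sol <- assemble_and_solve(topo, st, dt = 1e-5, Pin, Pout, Z = 0, fluid = fl)
    st$P2 <- st$P; st$Q2 <- st$Q
    st$P <- sol$P; st$Q <- sol$Q
  }
  Q_exact <- A^2 * (Pin - Pout) / (8 * pi * fl$mu * L)
  expect_equal(st$Q[3], Q_exact, tolerance = 1e-3)
})

test_that("compiled and reference flow assemblies give identical solutions", {
  topo <- tiny_tree()
  tpl <- myoflow:::topology_for_cpp(topo)
  set.seed(21)
  N <- tpl$n_nodes
  st <- list(P = mmHg_to_cgs(runif(N, 49, 61)), Q = runif(N, -1e-3, 1e-3),
             A = runif(N, 0.8e-4, 1.3e-4), C_A = runif(N, 1e-10, 5e-10))
  st$A_prev <- st$A
  prm <- myoflow_params()
  Z <- c(1e6, 2e6)
  r_ref <- assemble_and_solve(topo, st, dt = 2.5e-4, Pin = mmHg_to_cgs(62),
                              Pout = mmHg_to_cgs(50), Z = Z,
                              fluid = prm$fluid)
  r_cpp <- myoflow:::cpp_flow_step(tpl, myoflow:::pars_for_cpp(prm), st,
                                   2.5e-4, mmHg_to_cgs(62), mmHg_to_cgs(50),
                                   Z)
  expect_equal(as.numeric(r_cpp$P), r_ref$P, tolerance = 1e-10)
  expect_equal(as.numeric(r_cpp$Q), r_ref$Q, tolerance = 1e-10)
  # and with BDF2 histories
  st$P2 <- st$P * 0.99; st$Q2 <- st$Q * 0.98
  r_ref2 <- assemble_and_solve(topo, st, dt = 2.5e-4, Pin = mmHg_to_cgs(62),
                               Pout = mmHg_to_cgs(50), Z = Z,
                               fluid = prm$fluid)
  r_cpp2 <- myoflow:::cpp_flow_step(tpl, myoflow:::pars_for_cpp(prm), st,
                                    2.5e-4, mmHg_to_cgs(62), mmHg_to_cgs(50),
                                    Z)
  expect_equal(as.numeric(r_cpp2$Q), r_ref2$Q, tolerance = 1e-10)
})

test_that("a symmetric bifurcation splits flow equally and conserves mass", {
  topo <- attach_boundaries(tiny_tree(), Z_mode = "none")
  prm <- myoflow_params(wall_mode = "rigid")
  sim <- run_simulation(topo, signal_constant(60), t_end = 0.02,
                        config = coupling_config(mode = "weak", dt = 1e-4,
                                                 record_dt = 1e-2),
                        params = prm)
  last <- dplyr::filter(sim$probes, t == max(t))
  expect_equal(last$Q_ml_s[last$vessel == 2], last$Q_ml_s[last$vessel == 3],
               tolerance = 1e-10)
  expect_lt(sim$diagnostics$max_junction_rel, 1e-10)
})

test_that("characteristic impedance follows rho c / A", {
  A <- 1e-4; CA <- 1e-10; rho <- 1.04
  c_pw <- sqrt(A / (rho * CA))
  expect_equal(characteristic_impedance(A, CA, rho), rho * c_pw / A)
  # doubling the area at fixed wave speed halves Z
  CA2 <- 2 * CA # keeps c = sqrt(A/(rho CA)) fixed when A doubles
  expect_equal(characteristic_impedance(2 * A, CA2, rho),
               characteristic_impedance(A, CA, rho) / 2)
  expect_error(characteristic_impedance(A, -1e-10), class = "myoflow_state_error")
})

test_that("a matched terminal impedance absorbs an incident pulse", {
  # Wave transmission needs the viscous relaxation time rho A/(8 pi mu) to
  # exceed the transit time, so this synthetic fixture uses a larger vessel
  # than the cerebral defaults. A Gaussian pulse is launched from rest; after
  # it has passed the midpoint, a matched termination leaves only a small
  # residual whereas a closed end (huge Z) keeps ringing.
  mk <- function(Z) single_tube(n_elements = 40L, L_cm = 12, Do_um = 1350,
                                Z_mode = Z)
  prm <- myoflow_params(wall_mode = "passive")
  gauss <- function(t) 50 + 2 * exp(-(t - 0.008)^2 / (2 * 0.0015^2))
  cfg <- coupling_config(mode = "weak", dt = 1e-4, record_dt = 5e-4)
  run <- function(topo) run_simulation(topo, gauss, t_end = 0.1,
                                       config = cfg, params = prm)
  s_abs <- run(mk("characteristic"))
  s_cls <- run(mk(1e9))
  peak_incident <- max(s_abs$probes$P_mmHg[s_abs$probes$t < 0.03]) - 50
  late <- function(s) max(abs(dplyr::filter(s$probes, t > 0.05)$P_mmHg - 50))
  expect_gt(peak_incident, 0.2) # the pulse does reach the midpoint
  expect_lt(late(s_abs), 0.05 * peak_incident)
  expect_gt(late(s_cls), 5 * late(s_abs))
})

test_that("the coupled scheme is second order in time on a smooth problem", {
  topo <- single_tube(Z_mode = "characteristic")
  prm <- myoflow_params(wall_mode = "passive")
  # settle to a smooth state, then drive with a sinusoid and Richardson-
  # extrapolate the final flow over dt halvings
  settle <- run_simulation(topo, signal_constant(55), 0.5,
                           config = coupling_config(mode = "strong",
                                                    dt = 2e-4,
                                                    epsilon = 1e-10),
                           params = prm)
  sig <- function(t) 55 + 3 * sin(2 * pi * 5 * t)
  run_dt <- function(dt) {
    s <- run_simulation(topo, sig, 0.2,
                        config = coupling_config(mode = "strong", dt = dt,
                                                 epsilon = 1e-12,
                                                 record_dt = 0.2),
                        params = prm, init_state = settle$final_state)
    dplyr::filter(s$probes, t == max(t))$P_mmHg[1]
  }
  q1 <- run_dt(2e-4); q2 <- run_dt(1e-4); q3 <- run_dt(5e-5)
  order <- log2(abs(q1 - q2) / abs(q2 - q3))
  expect_gt(order, 1.8)
})
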