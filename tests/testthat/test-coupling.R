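test_that("rmsre matches a direct elementwise computation", {
  expect_equal(rmsre(c(1, 2, 3), c(1, 2, 3)), 0)
  r <- c(2, 4, 8)
  expect_equal(rmsre(1.01 * r, r), 0.01)
  set.seed(5)
  v <- runif(5, 1, 2); ref <- runif(5, 1, 2)
  expect_equal(rmsre(v, ref), sqrt(sum(((v - ref) / ref)^2) / 5))
  expect_error(rmsre(1:3, c(1, 0, 2)), class = "myoflow_state_error")
  expect_error(rmsre(1:3, 1:4), class = "myoflow_state_error")
})

test_that("rigid walls make the fixed point converge in one iteration", {
  topo <- attach_boundaries(tiny_tree(), Z_mode = "none")
  prm <- myoflow_params(wall_mode = "rigid")
  sim <- run_simulation(topo, signal_constant(60), t_end = 0.01,
                        config = coupling_config(mode = "strong", dt = 1e-3,
                                                 record_dt = 1e-2),
                        params = prm, n_layers = 5)
  expect_true(all(sim$diagnostics$iterations == 1L))
  expect_true(all(sim$diagnostics$coupling_rmsre == 0))
})

test_that("strong coupling accepts only iterates below the area tolerance", {
  topo <- tiny_tree()
  sim <- run_simulation(topo, default_inlet_signal(), t_end = 0.05,
                        config = coupling_config(mode = "strong", dt = 2.5e-4))
  expect_true(all(sim$diagnostics$iterations >= 1L))
  expect_true(all(sim$diagnostics$coupling_rmsre < 1e-6))
})

test_that("weak and strong single steps agree closely at the working time step", {
  topo <- default_mca_tree()
  # settle the wall at 60 mmHg first: the cold-start state is deliberately
  # out of equilibrium and its first step is a discontinuous snap
  st <- run_simulation(topo, signal_constant(60), 1,
                       config = coupling_config(mode = "strong",
                                                dt = 2.5e-4))$final_state
  stepped <- lapply(c("strong", "weak"), function(m)
    advance_step(topo, st, 60.5,
                 config = coupling_config(mode = m, dt = 2.5e-4)))
  A1 <- stepped[[1]]$state$A
  A2 <- stepped[[2]]$state$A
  expect_lt(max(abs(A1 - A2) / A1), 1e-3)
  expect_gte(stepped[[1]]$iterations, 1L)
})

test_that("a quiescent boundary keeps a passive network at rest", {
  topo <- attach_boundaries(tiny_tree(), Pout_mmHg = 50, Z_mode = "none")
  prm <- myoflow_params(wall_mode = "passive")
  sim <- run_simulation(topo, signal_constant(50), t_end = 0.2,
                        config = coupling_config(mode = "weak", dt = 2.5e-4,
                                                 record_dt = 0.05),
                        params = prm)
  last <- dplyr::filter(sim$probes, t == max(t))
  expect_lt(max(abs(last$Q_ml_s)), 1e-10)
  expect_equal(last$P_mmHg, rep(50, 3), tolerance = 1e-8)
})

test_that("halving the time step barely changes a short passive run", {
  topo <- tiny_tree()
  prm <- myoflow_params(wall_mode = "passive")
  run <- function(dt) run_simulation(topo, default_inlet_signal(),
                                     t_end = 0.5,
                                     config = coupling_config(mode = "strong",
                                                              dt = dt),
                                     params = prm)
  a <- dplyr::filter(run(2.5e-4)$probes, vessel == 1, t > 0)
  b <- dplyr::filter(run(1.25e-4)$probes, vessel == 1, t > 0)
  expect_lt(rmsre(a$Q_ml_s, b$Q_ml_s), 0.01)
})

test_that("runs start from the stated initial state and are deterministic", {
  topo <- tiny_tree()
  sim <- run_simulation(topo, default_inlet_signal(), t_end = 0.02,
                        config = coupling_config(mode = "weak", dt = 1e-3,
                                                 record_dt = 1e-2))
  first <- dplyr::filter(sim$probes, t == 0)
  expect_equal(first$u_fs, rep(-2e-2, 3)) # initial relative filament sliding
  expect_equal(first$Q_ml_s, rep(0, 3))
  expect_equal(first$P_mmHg,
               rep(make_signal(default_inlet_signal())(0), 3),
               tolerance = 1e-12)
  sim2 <- run_simulation(topo, default_inlet_signal(), t_end = 0.02,
                         config = coupling_config(mode = "weak", dt = 1e-3,
                                                  record_dt = 1e-2))
  expect_identical(sim$probes, sim2$probes)
})

test_that("continuation from a stored state reproduces the uninterrupted run", {
  topo <- tiny_tree()
  cfg <- coupling_config(mode = "strong", dt = 5e-4, record_dt = 5e-3)
  sig <- default_inlet_signal()
  whole <- run_simulation(topo, sig, t_end = 0.1, config = cfg)
  part1 <- run_simulation(topo, sig, t_end = 0.05, config = cfg)
  shifted <- function(t) make_signal(sig)(t + 0.05)
  part2 <- run_simulation(topo, shifted, t_end = 0.05, config = cfg,
                          init_state = part1$final_state)
  tail_whole <- dplyr::filter(whole$probes, t == 0.1)
  tail_part <- dplyr::filter(part2$probes, t == 0.05)
  expect_equal(tail_part$A_cm2, tail_whole$A_cm2, tolerance = 1e-10)
  expect_equal(tail_part$Q_ml_s, tail_whole$Q_ml_s, tolerance = 1e-8)
})
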