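test_that("a Ca-free vessel distends passively at every pressure up-step", {
  sig <- signal_step_train(c(10, 30, 60, 90), c(40, 80, 120))
  s <- single_vessel_protocol(sig, 160, dt = 0.5, mode = "zero_ca")
  at <- function(tt) s$do_um[match(tt, s$t)]
  expect_lt(at(39.5), at(79.5))
  expect_lt(at(79.5), at(119.5))
  expect_lt(at(119.5), at(159.5))
})

test_that("slower signalling time constants slow the Ca2+ response", {
  sig <- signal_step_train(c(10, 60), 5)
  run_tau <- function(tau) {
    prm <- myoflow_params(signalling = signalling_params(tau_c = tau))
    single_vessel_protocol(sig, 20, dt = 0.5, params = prm)
  }
  fast <- run_tau(5); slow <- run_tau(30)
  # shortly after the up-step the fast pathway has risen further
  i <- match(10, fast$t)
  expect_gt(fast$Ca_nM[i], slow$Ca_nM[i])
})

test_that("the trace scorer is exact on self-reference and windows correctly", {
  s <- single_vessel_protocol(signal_constant(40), 30, dt = 0.5)
  ref <- tibble::tibble(t = s$t, value = s$do_um)
  expect_equal(rmsre_score(s, ref), 0)
  expect_equal(rmsre_score(s, ref, window = c(10, 20)), 0)
  ref2 <- ref
  ref2$value <- ref2$value * 1.02
  expect_equal(rmsre_score(s, ref2), 0.02 / 1.02, tolerance = 1e-10)
  expect_error(rmsre_score(s, ref, window = c(100, 200)),
               class = "myoflow_spec_error")
})

test_that("the time-constant sweep covers the grid and scores when referenced", {
  sig <- signal_step_train(c(10, 60), 10)
  sw <- tau_sweep(tau_c = c(5, 10), tau_m = 6.188e-2 * c(1, 10), signal = sig,
                  t_end = 30, dt = 0.5)
  expect_equal(nrow(sw), 4L)
  expect_true(all(is.na(sw$rmsre)))
  ref <- tibble::tibble(t = sw$sim[[1]]$t, value = sw$sim[[1]]$do_um)
  sw2 <- tau_sweep(tau_c = c(5, 10), tau_m = 6.188e-2, signal = sig,
                   t_end = 30, dt = 0.5, reference = ref)
  expect_equal(sw2$rmsre[sw2$tau_c == 5], 0)
  expect_gt(sw2$rmsre[sw2$tau_c == 10], 0)
})

test_that("the default case table matches the benchmarked settings", {
  cs <- default_cases()
  expect_equal(cs$dt, c(1e-4, 2e-4, 2.5e-4, 2.5e-4, 2.5e-4))
  expect_equal(cs$coupling, c("strong", "strong", "strong", "weak", "weak"))
  expect_equal(cs$averaged, c(FALSE, FALSE, FALSE, FALSE, TRUE))
})

test_that("the settings harness scores a case against the reference consistently", {
  topo <- tiny_tree()
  cases <- tibble::tibble(case = c(1L, 2L),
                          dt = c(5e-4, 5e-4),
                          coupling = c("weak", "weak"),
                          averaged = c(FALSE, FALSE))
  cmp <- settings_comparison(topo, default_inlet_signal(), t_end = 0.3,
                             cases = cases, record_dt = 1e-2)
  # identical settings: all RMSRE exactly zero
  expect_true(all(cmp$by_generation$Q_rmsre == 0))
  expect_true(all(cmp$by_generation$A_rmsre == 0))
  # the mean across generations matches direct recomputation
  cases2 <- tibble::tibble(case = c(1L, 5L),
                           dt = c(2.5e-4, 5e-4),
                           coupling = c("strong", "weak"),
                           averaged = c(FALSE, TRUE))
  cmp2 <- settings_comparison(topo, default_inlet_signal(), t_end = 0.3,
                              cases = cases2, record_dt = 1e-2)
  bg <- cmp2$by_generation
  expect_equal(glance(cmp2)$mean_Q_rmsre,
               mean(bg$Q_rmsre[bg$case == 5]))
  expect_gt(glance(cmp2)$mean_Q_rmsre, 0)
})

test_that("the autoregulation harness produces finite ratios on a small network", {
  topo <- tiny_tree()
  suppressWarnings(
    ar <- autoregulation_curve(topo, final_pressures = 70,
                               ramp_start = 4, ramp_end = 6, t_end = 16,
                               config = coupling_config(
                                 mode = "weak", dt = 2.5e-4,
                                 averaged_active_stress = TRUE),
                               steady_window = 4, drift_tol = 1e-5))
  expect_equal(nrow(ar$flows), 2L)
  expect_true(all(is.finite(ar$flows$Q_G0_ml_s)))
  expect_true(all(is.finite(ar$diameter_ratio$ratio)))
  expect_true(all(ar$diameter_ratio$ratio <= 1 + 1e-9))
})
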