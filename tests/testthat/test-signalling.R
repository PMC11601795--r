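test_that("logistic links have the midpoint, saturation and monotonicity of a sigmoid", {
  l <- logistic_link(slope = 0.06, half_activation = 50)
  expect_equal(evaluate_link(l, 50), 0.5)
  expect_gt(evaluate_link(l, 1e4), 1 - 1e-10)
  x <- seq(0, 120, by = 5)
  expect_true(all(diff(evaluate_link(l, x)) > 0))
  inv <- logistic_link(6, 0.5, "xi1", inverted = TRUE)
  expect_equal(evaluate_link(inv, 0.3), 1 - evaluate_link(logistic_link(6, 0.5, "xi1"), 0.3))
  expect_error(evaluate_link(l, NaN), class = "myoflow_state_error")
  expect_error(logistic_link(0, 50), class = "myoflow_config_error")
})

test_that("calcium target honours the pharmacological mode", {
  ctl <- signalling_params(calcium_mode = "control")
  dil <- signalling_params(calcium_mode = "diltiazem")
  zca <- signalling_params(calcium_mode = "zero_ca")
  expect_equal(pressure_to_calcium_target(c(0, 30, 200), zca), c(0, 0, 0))
  half <- ctl$links$half_activation[ctl$links$name == "chi0"]
  expect_equal(pressure_to_calcium_target(half, ctl), 0.5)
  # L-type block leaves only a marginal stretch-operated component
  expect_lt(pressure_to_calcium_target(60, dil),
            pressure_to_calcium_target(60, ctl))
  expect_error(pressure_to_calcium_target(-5, ctl), class = "myoflow_state_error")
})

test_that("the ODE right-hand side vanishes at the analytic fixed point", {
  params <- signalling_params(tau_fast = rep(0.01, 4))
  for (P in c(15, 55, 95)) {
    st <- signalling_steady_state(P, params)
    d <- signalling_rhs(st, P, params)
    expect_lt(max(abs(d)), 1e-12)
  }
  bad <- signalling_params() # tau_fast = 0
  expect_error(signalling_rhs(signalling_state(0), 50, bad),
               class = "myoflow_config_error")
})

test_that("quasi-steady targets follow the stated algebra", {
  params <- signalling_params()
  st <- signalling_steady_state(70, params)
  lt <- params$links
  ev <- function(nm, x) {
    r <- lt[lt$name == nm, ]
    y <- 1 / (1 + exp(-r$slope * (x - r$half_activation)))
    if (r$inverted) 1 - y else y
  }
  chi5 <- ev("chi5", st[["xi0"]])
  chi6 <- ev("chi6", st[["xi3"]])
  expect_equal(unname(st[["xi5"]]), chi5 / (chi5 + 1 - chi6))
  # logical-OR target reduces to 1 - chi7 chi8
  expect_equal(unname(st[["xi6"]]),
               1 - ev("chi7", st[["xi2"]]) * ev("chi8", st[["xi4"]]))
})

test_that("quasi-steady variables equal their algebraic targets after every step", {
  params <- signalling_params()
  st <- signalling_state(0)
  deriv <- NULL
  set.seed(11)
  for (k in 1:25) {
    P <- runif(1, 10, 120)
    out <- step_signalling(st, P, 0.5, params, deriv)
    st <- out$state; deriv <- out$deriv
    ref <- st
    lt <- params$links
    chi3 <- evaluate_link(as.list(lt[4, -1]), st[["xi1"]])
    expect_equal(unname(st[["xi3"]]), 1 - chi3, tolerance = 1e-14)
    expect_true(all(st >= 0 & st <= 1))
  }
})

test_that("relaxation under constant drive matches the closed form at second order", {
  # oracle: xi0(t) = c (1 - exp(-t / tau_c)) for constant chi0 = c from xi0 = 0
  params <- signalling_params(tau_c = 10)
  P <- 60
  cc <- pressure_to_calcium_target(P, params)
  errs <- vapply(c(0.5, 0.25, 0.125, 0.0625), function(dt) {
    sim <- simulate_signalling(signal_constant(P), t_end = 10, dt = dt,
                               params = params)
    exact <- cc * (1 - exp(-sim$t / 10))
    max(abs(sim$xi0 - exact))
  }, numeric(1))
  fit <- stats::lm(log(errs) ~ log(c(0.5, 0.25, 0.125, 0.0625)))
  expect_gt(unname(coef(fit)[2]), 1.9)
  expect_lt(errs[1], 2e-3)
})

test_that("compiled and reference signalling paths agree", {
  # the same step scheme runs inside the compiled single-vessel loop
  geom <- default_geom()
  params <- myoflow_params()
  sig <- signal_step_train(c(10, 60, 10), c(30, 60))
  sv <- single_vessel_protocol(sig, 90, dt = 0.5, geometry = geom,
                               params = params)
  rr <- simulate_signalling(sig, 90, dt = 0.5, params = params$signalling)
  # pressure prescribed identically, so the xi trajectories must coincide
  for (v in paste0("xi", 0:2))
    expect_equal(sv[[v]], rr[[v]], tolerance = 1e-12)
})
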