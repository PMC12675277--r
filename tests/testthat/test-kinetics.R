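test_that("accumulation model reproduces its limiting cases", {
  p <- kinetic_params(I = 0.01, E = 0.005, K = 0.1)
  # at t = 0 only the adsorbed surface fraction is visible
  expect_equal(eval_accumulation(0, p, c0 = 2, f = 0.05), 0.1 * 2)
  # no influx, no adsorption: nothing accumulates
  p0 <- kinetic_params(I = 0, E = 0.005, K = 0)
  expect_equal(eval_accumulation(c(0, 100, 1e5), p0, c0 = 2, f = 0.05),
               c(0, 0, 0))
  # frozen reference value from RK4 integration (dt = 0.01 s)
  p1 <- kinetic_params(I = 0.01, E = 0.005, K = 0)
  expect_equal(eval_accumulation(300, p1, c0 = 2, f = 0.05),
               2.9380003323, tolerance = 1e-9)
  # degenerate f*I + E = 0: linear-growth limit, no division by zero
  pd <- kinetic_params(I = 0, E = 0, K = 0.05)
  expect_equal(eval_accumulation(c(0, 500), pd, c0 = 2, f = 0.05),
               rep(0.05 * 2, 2))
})

test_that("accumulation model rejects invalid inputs", {
  p <- kinetic_params(I = 0.01, E = 0.005)
  expect_error(eval_accumulation(-1, p, c0 = 2, f = 0.05),
               class = "ckflux_validation_error")
  expect_error(eval_accumulation(10, p, c0 = 0, f = 0.05),
               class = "ckflux_validation_error")
  expect_error(eval_accumulation(10, p, c0 = 2, f = -0.1),
               class = "ckflux_validation_error")
  expect_error(kinetic_params(I = -0.01, E = 0.005),
               class = "ckflux_validation_error")
  # f*K >= 1 makes the measured signal fraction non-positive
  expect_error(eval_accumulation(10, kinetic_params(0.01, 0.005, K = 30),
                                 c0 = 2, f = 0.05),
               class = "ckflux_validation_error")
})

test_that("closed form agrees with RK4 integration across random parameters", {
  draws <- draw_kinetics(20, seed = 101)
  times <- c(0, 60, 300, 900)
  for (i in seq_len(nrow(draws))) {
    d <- draws[i, ]
    p <- kinetic_params(d$I, d$E, d$K)
    closed <- eval_accumulation(times, p, c0 = 2, f = d$f)
    ode <- integrate_uptake_ode(times, I = d$I, E = d$E, K = d$K,
                                c0 = 2, f = d$f)[, 1]
    expect_lt(max(abs(closed - ode)), 1e-8 * 2)
  }
})

test_that("accumulation is monotone in time and linear in c0", {
  draws <- draw_kinetics(25, seed = 202)
  t_grid <- seq(0, 1800, length.out = 50)
  for (i in seq_len(nrow(draws))) {
    d <- draws[i, ]
    p <- kinetic_params(d$I, d$E, d$K)
    y <- eval_accumulation(t_grid, p, c0 = 2, f = d$f)
    expect_true(all(diff(y) >= -1e-12))
    # c_I(t; a*c0) = a * c_I(t; c0)
    y3 <- eval_accumulation(t_grid, p, c0 = 6, f = d$f)
    expect_equal(y3, 3 * y, tolerance = 1e-12)
  }
})

test_that("treatment model degenerates, is continuous, and reaches the new steady state", {
  p_eq <- kinetic_params(I = 0.02, E = 0.004, K = 0.02, I_prime = 0.02)
  t_grid <- seq(0, 900, length.out = 31)
  # I' = I collapses the piecewise form onto the plain model
  expect_equal(
    eval_accumulation_treatment(t_grid, p_eq, t_prime = 420, c0 = 2, f = 0.05),
    eval_accumulation(t_grid, p_eq, c0 = 2, f = 0.05), tolerance = 1e-12)

  p <- kinetic_params(I = 0.02, E = 0.004, K = 0.02, I_prime = 0.002)
  # continuity at the junction: both branches evaluated at t = t'
  at_tp <- eval_accumulation_treatment(420, p, t_prime = 420, c0 = 2, f = 0.05)
  expect_equal(at_tp, eval_accumulation(420, p, c0 = 2, f = 0.05),
               tolerance = 1e-12)
  just_after <- eval_accumulation_treatment(420 + 1e-6, p, t_prime = 420,
                                            c0 = 2, f = 0.05)
  expect_equal(just_after, at_tp, tolerance = 1e-6)
  # frozen reference value from piecewise RK4 (switch I -> I' at t')
  expect_equal(
    eval_accumulation_treatment(900, p, t_prime = 420, c0 = 2, f = 0.05),
    1.8584573982, tolerance = 1e-8)
  # long after the treatment the curve approaches the I' steady state
  p_prime <- kinetic_params(I = p$I_prime, E = p$E, K = p$K)
  expect_equal(
    eval_accumulation_treatment(1e6, p, t_prime = 420, c0 = 2, f = 0.05),
    steady_state(p_prime, c0 = 2, f = 0.05), tolerance = 1e-9)
  # missing configuration is a configuration error
  expect_error(
    eval_accumulation_treatment(100, kinetic_params(0.02, 0.004), 420, 2, 0.05),
    class = "ckflux_config_error")
})

test_that("piecewise closed form matches piecewise RK4 integration", {
  set.seed(303)
  times <- c(60, 420, 600, 900)
  for (i in 1:10) {
    I <- runif(1, 1e-3, 5e-2); Ip <- runif(1, 1e-4, 5e-2)
    E <- runif(1, 1e-4, 1e-2); K <- runif(1, 0, 0.2)
    p <- kinetic_params(I, E, K, I_prime = Ip)
    closed <- eval_accumulation_treatment(times, p, t_prime = 420,
                                          c0 = 2, f = 0.05)
    ode <- integrate_uptake_ode(times, I = I, E = E, K = K, c0 = 2, f = 0.05,
                                t_prime = 420, I_prime = Ip)[, 1]
    expect_lt(max(abs(closed - ode)), 1e-8 * 2)
  }
})

test_that("steady state matches the long-time limit and flags divergence", {
  # adsorption-only plateau
  expect_equal(steady_state(kinetic_params(0, 1e-3, K = 0.05), 2, 0.05), 0.1)
  p <- kinetic_params(I = 0.01, E = 0.005, K = 0)
  expect_equal(steady_state(p, 2, 0.05), 3.6363636364, tolerance = 1e-9)
  expect_equal(steady_state(p, 2, 0.05),
               eval_accumulation(1e6, p, 2, 0.05), tolerance = 1e-9)
  # equilibrative limit: I = E, f -> 0 gives c0
  expect_equal(steady_state(kinetic_params(0.01, 0.01, 0), 2, 1e-9), 2,
               tolerance = 1e-6)
  # with no efflux the plateau is set by extracellular depletion alone: c0/f
  expect_equal(steady_state(kinetic_params(0.01, 0, 0), 2, 0.05), 2 / 0.05)
})

test_that("visualization curves ignore the adsorption offset", {
  pK <- kinetic_params(I = 0.01, E = 0.005, K = 0.3)
  p0 <- kinetic_params(I = 0.01, E = 0.005, K = 0)
  grid <- seq(0, 900, by = 60)
  expect_equal(visualization_curve(pK, grid, f = 0.05),
               visualization_curve(p0, grid, f = 0.05))
  expect_equal(visualization_curve(pK, 0, f = 0.05)$conc_nM_model, 0)
  expect_equal(visualization_curve(pK, 300, f = 0.05)$conc_nM_model,
               2.9380003323, tolerance = 1e-9)
})
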