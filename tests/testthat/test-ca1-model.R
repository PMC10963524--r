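# Gating kinetics, right-hand side, bias solving and the simulator.

test_that("Boltzmann steady state matches its closed form and limits", {
  expect_equal(boltzmann(-50, -50, 6), 0.5)
  expect_equal(boltzmann(-50, -50, -3), 0.5)
  # one slope factor above half-activation
  expect_equal(boltzmann(-44, -50, 6), 1 / (1 + exp(-1)))
  expect_equal(boltzmann(1e4, -50, 6), 1)
  expect_equal(boltzmann(-1e4, -50, 6), 0, tolerance = 1e-12)
  # inactivation gate saturates the other way
  expect_lt(boltzmann(0, -50, -6), 1e-3)
  expect_error(boltzmann(Inf, -50, 6), class = "ganpop_bad_input")
  expect_error(boltzmann(-50, -50, 0), class = "ganpop_bad_input")
})

test_that("transient-sodium inactivation time constant follows the printed form", {
  expect_equal(tau_h_nat(40.6), 0.2 + 0.007 * exp(1))
  expect_equal(tau_h_nat(1e6), 0.207)
  # monotone decreasing on a voltage grid
  v <- seq(-120, 60, by = 0.5)
  expect_true(all(diff(tau_h_nat(v)) < 0))
  expect_true(all(tau_h_nat(v) > 0.2))
})

test_that("right-hand side matches an independently coded sum of currents", {
  proto <- protocol_depolarizing()
  proto$bias_current <- -1.2
  set.seed(11)
  for (i in 1:20) {
    params <- random_sweep_params()
    state <- c(runif(1, -100, 40), runif(10))
    t <- runif(1, 0, 700)
    expect_equal(ca1_rhs(state, t, params, proto),
                 setNames(oracle_rhs(state, t, params, proto),
                          names(ca1_rhs(state, t, params, proto))),
                 tolerance = 1e-12)
  }
})

test_that("right-hand side fixed points: leak-only rest and gate equilibria", {
  p <- leak_only_params()
  proto <- stim_protocol(0, bias_current = 0)
  gates_inf <- ganpop:::steady_gates(p, p$E[["E_L"]])
  d <- ca1_rhs(c(p$E[["E_L"]], unname(gates_inf)), 50, p, proto)
  expect_equal(unname(d), rep(0, 11), tolerance = 1e-12)

  # gates at steady state for an arbitrary voltage have zero gate derivative
  pr <- ca1_params()
  V <- -55
  d2 <- ca1_rhs(c(V, unname(ganpop:::steady_gates(pr, V))), 10, pr, proto)
  expect_equal(unname(d2[-1]), rep(0, 10), tolerance = 1e-12)

  expect_error(
    ca1_rhs(setNames(rep(0.5, 11), c("V", "bogus", names(d)[3:11])),
            0, pr, proto),
    class = "ganpop_unknown_gate")
})

test_that("leak-only simulation reproduces the closed-form RC decay", {
  p <- leak_only_params(g_L = 0.08, E_L = -70, C = 1.5)
  proto <- stim_protocol(0, pulse_onset = 0, pulse_duration = 0,
                         total_duration = 120, bias_current = 0,
                         dt_out = 0.1)
  V0 <- -40
  init <- c(V0, unname(ganpop:::steady_gates(p, V0)))
  tr <- simulate_ca1(p, proto, init = init)
  expected <- -70 + (V0 + 70) * exp(-0.08 * tr$t / 1.5)
  expect_equal(tr$V, expected, tolerance = 1e-6)
})

test_that("bias current solving holds the cell at the target", {
  # Ohmic algebra in the leak-only model
  p <- leak_only_params(g_L = 0.05, E_L = -70)
  expect_equal(find_bias_current(p, -70), 0, tolerance = 1e-10)
  expect_equal(find_bias_current(p, -60), 0.05 * 10, tolerance = 1e-10)
  expect_error(find_bias_current(p, -95), class = "ganpop_bad_input")

  # full model: settling simulation self-consistency
  pr <- ca1_params()
  b <- find_bias_current(pr, -80)
  proto <- protocol_depolarizing(dt_out = 0.1)
  proto$pulse_amplitude <- 0
  tr <- simulate_ca1(pr, proto)
  expect_lt(max(abs(tr$V - (-80))), 0.1)
})

test_that("with no pulse the post-settling trace is constant", {
  proto <- stim_protocol(0, pulse_onset = 100, pulse_duration = 500,
                         total_duration = 700, dt_out = 0.1)
  tr <- simulate_ca1(ca1_params(), proto)
  expect_lt(diff(range(tr$V)), 0.01)
})

test_that("default cell fires an action potential under the depolarizing pulse", {
  tr <- simulate_ca1(ca1_params(), protocol_depolarizing())
  t_peak <- detect_first_ap(tr)
  expect_gt(max(tr$V), 0)
  expect_gte(t_peak, 100)
  expect_lte(t_peak, 600)
})

test_that("adaptive solver agrees with the fixed-step RK4 oracle", {
  # 50 ms window around the pulse onset (the full 20-draw sweep of this
  # cross-check runs in the acceptance suite)
  proto <- stim_protocol(3, pulse_onset = 10, pulse_duration = 40,
                         total_duration = 50, dt_out = 0.1)
  set.seed(21)
  worst <- 0
  for (i in 1:8) {
    params <- random_sweep_params()
    a <- simulate_ca1(params, proto)
    b <- simulate_ca1(params, proto, method = "rk4", rk4_dt = 1e-3)
    worst <- max(worst, max(abs(a$V - b$V)))
  }
  expect_lt(worst, 0.1)
})

test_that("gates stay within [0,1] across sweep draws", {
  set.seed(31)
  proto <- protocol_depolarizing(dt_out = 0.05)
  for (i in 1:8) {
    tr <- simulate_ca1(random_sweep_params(), proto)
    gf <- attr(tr, "gating_final")
    expect_true(all(gf >= -1e-9 & gf <= 1 + 1e-9))
  }
})

test_that("jointly scaling capacitance, conductances and currents leaves V unchanged", {
  p1 <- ca1_params()
  g2 <- as.list(2 * p1$g)
  names(g2) <- names(p1$g)
  p2 <- do.call(ca1_params, c(list(C = 2 * p1$C), g2))
  proto1 <- protocol_depolarizing(dt_out = 0.1)
  proto2 <- proto1
  proto2$pulse_amplitude <- 2 * proto1$pulse_amplitude
  tr1 <- simulate_ca1(p1, proto1)
  tr2 <- simulate_ca1(p2, proto2)
  expect_equal(tr1$V, tr2$V, tolerance = 1e-4)
})

test_that("invalid inputs are rejected", {
  expect_error(ca1_params(g_KDR = -1), class = "ganpop_bad_input")
  expect_error(ca1_params(p = 1.5), class = "ganpop_bad_input")
  expect_error(stim_protocol(1, pulse_onset = -5), class = "ganpop_bad_input")
  expect_error(stim_protocol(1, pulse_onset = 100, pulse_duration = 500,
                             total_duration = 400),
               class = "ganpop_bad_input")
  expect_error(ca1_gating(nonsense = list(V_x = 0)),
               class = "ganpop_unknown_gate")
})
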