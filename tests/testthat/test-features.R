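# Feature extraction on constructed waveforms with known answers, plus
# invariance and grid-convergence properties.

make_linear_spike <- function(dt = 0.02, shift = 0) {
  # flat at -60, rise at +100 mV/ms for 1 ms to +40, fall at -50 mV/ms for
  # 2 ms back to -60, then flat
  t <- seq(0, 30, by = dt)
  V <- ramp_wave(t, shift + c(0, 5, 6, 8, 30),
                 c(-60, -60, 40, -60, -60))
  synthetic_trace(t, V, pulse_onset = 0, pulse_duration = 30)
}

test_that("first-AP detection finds the constructed peak and errors without one", {
  t <- seq(0, 50, by = 0.02)
  V <- -80 + 110 * exp(-(t - 12)^2 / (2 * 2^2))
  tr <- synthetic_trace(t, V, pulse_onset = 0, pulse_duration = 50)
  expect_equal(detect_first_ap(tr), 12, tolerance = 1e-8)

  flat <- synthetic_trace(t, rep(-80, length(t)), 0, 50)
  expect_error(detect_first_ap(flat), class = "ganpop_no_ap")

  # a subthreshold bump is not an AP
  low <- synthetic_trace(t, -80 + 30 * exp(-(t - 12)^2 / 8), 0, 50)
  expect_error(detect_first_ap(low), class = "ganpop_no_ap")
})

test_that("AP features of a piecewise-linear spike match the analytic values", {
  tr <- make_linear_spike()
  f <- extract_ap_features(tr)
  expect_equal(f$ap_peak, 40)
  expect_equal(f$ap_max_ror, 100, tolerance = 1e-9)
  expect_equal(f$ap_max_neg_ror, -50, tolerance = 1e-9)
  # threshold: first sample in the pre-peak window with dV/dt >= 10 mV/ms
  # is the foot of the ramp at -60 mV
  expect_equal(f$ap_threshold, -60)
  expect_equal(f$ap_trough, -60)
  expect_equal(f$ap_min_before, -60)
  # first sample attaining the max rate of rise sits one grid step up the
  # ramp; the level is -60 + dt * 100 and the width follows analytically
  lev <- -60 + 0.02 * 100
  t_up <- 5 + (lev + 60) / 100
  t_dn <- 6 + (40 - lev) / 50
  expect_equal(f$ap_v_at_max_ror, lev)
  expect_equal(f$ap_width, t_dn - t_up, tolerance = 1e-9)
  expect_equal(f$ap_v_at_max_neg_ror, 40 - 0.02 * 50)
})

test_that("AP features are invariant to time translation", {
  f0 <- extract_ap_features(make_linear_spike())
  f5 <- extract_ap_features(make_linear_spike(shift = 5))
  expect_equal(f0, f5, tolerance = 1e-9)
})

test_that("hyperpolarization features read off a constructed sag waveform", {
  dt <- 0.05
  on <- 100; off <- 600
  t <- seq(0, 800, by = dt)
  # exponential drop toward -110 over [on, on+25], linear sag recovery to
  # -100 by on+100, steady at -100, post-pulse rebound peaking at -78
  V <- numeric(length(t))
  V[t < on] <- -80
  seg1 <- t >= on & t <= on + 25
  V[seg1] <- -110 + 30 * exp(-(t[seg1] - on) / 5)
  v_neg <- -110 + 30 * exp(-5)
  seg2 <- t > on + 25 & t <= on + 100
  V[seg2] <- v_neg + (t[seg2] - (on + 25)) / 75 * (-100 - v_neg)
  V[t > on + 100 & t <= off] <- -100
  post1 <- t > off & t <= off + 100
  V[post1] <- -100 + (t[post1] - off) / 100 * 22
  V[t > off + 100] <- -78
  tr <- synthetic_trace(t, V, pulse_onset = on, pulse_duration = 500)

  f <- extract_hp_features(tr)
  expect_equal(f$hp_a, v_neg + 80, tolerance = 1e-6)
  expect_equal(f$hp_c, -20, tolerance = 1e-6)
  expect_equal(f$hp_d, 2, tolerance = 1e-6)
  # the fitted single-exponential asymptote recovers the -110 target
  expect_equal(f$hp_b, -30, tolerance = 1e-4)
})

test_that("a pure RC response has no sag and no rebound", {
  p <- leak_only_params(g_L = 0.1, E_L = -80)
  proto <- stim_protocol(-1, pulse_onset = 100, pulse_duration = 500,
                         total_duration = 800, bias_current = 0,
                         dt_out = 0.1, hold_target = -80)
  tr <- simulate_ca1(p, proto)
  f <- extract_hp_features(tr)
  dv <- -1 / 0.1
  expect_equal(f$hp_a, dv, tolerance = 1e-3)
  expect_equal(f$hp_b, dv, tolerance = 1e-3)
  expect_equal(f$hp_c, dv, tolerance = 1e-3)
  expect_equal(f$hp_d, 0, tolerance = 1e-6)
})

test_that("HP features are invariant to a constant voltage offset", {
  p <- ca1_params()
  tr <- simulate_ca1(p, protocol_hyperpolarizing(dt_out = 0.1))
  tr2 <- tr
  tr2$V <- tr$V + 7.5
  attr(tr2, "protocol") <- attr(tr, "protocol")
  expect_equal(extract_hp_features(tr), extract_hp_features(tr2),
               tolerance = 1e-6)
})

test_that("the full feature vector has exactly the 13 canonical entries", {
  p <- ca1_params()
  fv <- extract_features(simulate_ca1(p, protocol_depolarizing()),
                         simulate_ca1(p, protocol_hyperpolarizing()))
  expect_identical(names(fv), feature_names())
  expect_identical(ncol(fv), 13L)
  expect_true(all(is.finite(unlist(fv))))
  expect_gt(fv$ap_peak, fv$ap_threshold)
  expect_gte(fv$ap_peak, fv$ap_trough)
  expect_gt(fv$ap_width, 0)
  expect_gt(fv$ap_max_ror, 0)
  expect_lt(fv$ap_max_neg_ror, 0)
})

test_that("features are stable under output-grid refinement", {
  p <- ca1_params()
  f1 <- extract_features(simulate_ca1(p, protocol_depolarizing(dt_out = 0.01)),
                         simulate_ca1(p, protocol_hyperpolarizing(dt_out = 0.01)))
  f2 <- extract_features(simulate_ca1(p, protocol_depolarizing(dt_out = 0.005)),
                         simulate_ca1(p, protocol_hyperpolarizing(dt_out = 0.005)))
  rel <- abs(unlist(f2) - unlist(f1)) / pmax(abs(unlist(f1)), 1e-8)
  expect_true(all(rel < 0.01))
})

test_that("features are invariant to appending post-window padding", {
  tr <- make_linear_spike()
  t_extra <- seq(max(tr$t) + 0.02, max(tr$t) + 10, by = 0.02)
  tr2 <- synthetic_trace(c(tr$t, t_extra), c(tr$V, rep(-60, length(t_extra))),
                         pulse_onset = 0, pulse_duration = 30)
  expect_equal(extract_ap_features(tr), extract_ap_features(tr2),
               tolerance = 1e-9)
})

test_that("out-of-range features are replaced per strategy", {
  set.seed(5)
  train <- tibble::as_tibble(setNames(as.data.frame(matrix(rnorm(200 * 13),
                                                           200)),
                                      feature_names()))
  ranges <- feature_ranges(train)
  fv <- train[1, ]
  expect_equal(replace_out_of_range(fv, ranges), fv,
               ignore_attr = TRUE) # all in range: identity

  fv_hi <- fv
  fv_hi$ap_peak <- max(train$ap_peak) + 10
  r_med <- replace_out_of_range(fv_hi, ranges)
  expect_equal(r_med$ap_peak, median(train$ap_peak))
  expect_equal(r_med$ap_width, fv$ap_width)
  expect_true(attr(r_med, "replaced")[1, "ap_peak"])
  expect_equal(sum(attr(r_med, "replaced")), 1)

  fv_lo <- fv
  fv_lo$hp_a <- min(train$hp_a) - 1
  r_cl <- replace_out_of_range(fv_lo, ranges, strategy = "closest")
  expect_equal(r_cl$hp_a, min(train$hp_a))
  r_mean <- replace_out_of_range(fv_lo, ranges, strategy = "mean")
  expect_equal(r_mean$hp_a, mean(train$hp_a))
})
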