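# Independent oracles and waveform constructors used across the suite.

# Hand-written duplicate of the model right-hand side, written directly from
# the current table (independent of the compiled implementation).
oracle_rhs <- function(state, t, params, protocol) {
  V <- state[1]
  g <- params$g; E <- params$E; gt <- params$gating
  bz <- function(nm) {
    r <- gt[gt$name == nm, ]
    1 / (1 + exp(-(V - r$V_x) / r$k_x))
  }
  gate <- function(nm) state[match(nm, c("V", "h_NaT", "m_CaT", "h_CaT",
                                         "m_CaH", "h_CaH", "m_KDR", "h_KDR",
                                         "m_KM", "m_H", "n_H"))]
  I <- g[["g_NaT"]] * bz("m_NaT")^3 * gate("h_NaT") * (V - E[["E_Na"]]) +
    g[["g_NaP"]] * bz("m_NaP") * (V - E[["E_Na"]]) +
    g[["g_CaT"]] * gate("m_CaT")^2 * gate("h_CaT") * (V - E[["E_Ca"]]) +
    g[["g_CaH"]] * gate("m_CaH")^2 * gate("h_CaH") * (V - E[["E_Ca"]]) +
    g[["g_KDR"]] * gate("m_KDR") * gate("h_KDR") * (V - E[["E_K"]]) +
    g[["g_KM"]] * gate("m_KM") * (V - E[["E_K"]]) +
    g[["g_L"]] * (V - E[["E_L"]]) +
    g[["g_H"]] * (params$p * gate("m_H") + (1 - params$p) * gate("n_H")) *
      (V - E[["E_H"]])
  on <- protocol$pulse_onset
  Iapp <- protocol$bias_current +
    if (t >= on && t < on + protocol$pulse_duration) protocol$pulse_amplitude else 0
  dV <- (Iapp - I) / params$C
  tau <- c(h_NaT = 0.2 + 0.007 * exp(exp(-(V - 40.6) / 51.4)),
           setNames(gt$tau_x, gt$name)[c("m_CaT", "h_CaT", "m_CaH", "h_CaH",
                                         "m_KDR", "h_KDR", "m_KM", "m_H",
                                         "n_H")])
  dyn <- c("h_NaT", "m_CaT", "h_CaT", "m_CaH", "h_CaH", "m_KDR", "h_KDR",
           "m_KM", "m_H", "n_H")
  dx <- vapply(dyn, function(nm) {
    (bz(nm) - gate(nm)) / tau[[nm]]
  }, numeric(1))
  c(dV, dx)
}

# leak-only parameter set (all conductances but the leak set to zero)
leak_only_params <- function(g_L = 0.05, E_L = -70, C = 1) {
  ca1_params(g_NaT = 0, g_NaP = 0, g_CaT = 0, g_CaH = 0, g_KDR = 0,
             g_KM = 0, g_H = 0, g_L = g_L, E_L = E_L, C = C)
}

# wrap an arbitrary (t, V) waveform as a trace the extractors accept
synthetic_trace <- function(t, V, pulse_onset, pulse_duration,
                            total_duration = max(t), dt_out = t[2] - t[1]) {
  proto <- stim_protocol(pulse_amplitude = 1, pulse_onset = pulse_onset,
                         pulse_duration = pulse_duration,
                         total_duration = total_duration,
                         bias_current = 0, dt_out = dt_out)
  out <- tibble::tibble(t = t, V = V)
  structure(out, protocol = proto, class = c("ca1_trace", class(out)))
}

# piecewise-linear interpolator for constructed spikes
ramp_wave <- function(t, knots_t, knots_v) {
  stats::approx(knots_t, knots_v, xout = t, rule = 2)$y
}

# random valid parameter draw within the sweep bounds (helper for solver
# cross-checks; may or may not spike)
random_sweep_params <- function(bounds = ca1_bounds()) {
  vals <- stats::runif(nrow(bounds), bounds$low, bounds$high)
  ganpop:::set_conductances(ca1_params(), setNames(vals, bounds$parameter))
}
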