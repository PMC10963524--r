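# CA1 pyramidal-neuron conductance model: parameters, gating kinetics,
# stimulus protocols, right-hand side, bias-current solver and simulator.
# The numerical core (RHS + adaptive Dormand-Prince + fixed-step RK4) is
# compiled C; see src/ca1.c.

# canonical gate order used by the compiled core (instantaneous gates first
# where they appear in the current expressions; 10 dynamic gates form the
# ODE state together with V)
.gate_order <- c(
  "m_NaT", "h_NaT", "m_NaP", "m_CaT", "h_CaT", "m_CaH", "h_CaH",
  "m_KDR", "h_KDR", "m_KM", "m_H", "n_H"
)
.dynamic_gates <- setdiff(.gate_order, c("m_NaT", "m_NaP"))
.conductances <- c("g_NaT", "g_NaP", "g_CaT", "g_CaH", "g_KDR", "g_KM",
                   "g_L", "g_H")
.reversals <- c("E_Na", "E_Ca", "E_K", "E_L", "E_H")

#' Boltzmann steady-state activation
#'
#' Steady-state open fraction of a gating variable,
#' \eqn{x_\infty(V) = 1/(1 + \exp(-(V - V_x)/k_x))}. Activation gates have
#' \code{k_x > 0}, inactivation gates \code{k_x < 0}.
#'
#' @param V Membrane potential (mV). Must be finite.
#' @param V_x Half-(in)activation voltage (mV).
#' @param k_x Slope factor (mV); must be non-zero.
#' @return Activation fraction, strictly in (0, 1).
#' @examples
#' boltzmann(-50, -50, 6) # 0.5 at the half-activation voltage
#' @export
boltzmann <- function(V, V_x, k_x) {
  if (any(!is.finite(V))) abort("`V` must be finite.", class = "ganpop_bad_input")
  if (any(k_x == 0)) abort("`k_x` must be non-zero.", class = "ganpop_bad_input")
  1 / (1 + exp(-(V - V_x) / k_x))
}

#' Voltage-dependent time constant of transient-sodium inactivation
#'
#' The h-gate of the transient sodium current relaxes with a
#' double-exponential voltage dependence,
#' \eqn{\tau(V) = 0.2 + 0.007\,\exp(\exp(-(V - 40.6)/51.4))} ms; all other
#' gates use fixed time constants.
#'
#' @param V Membrane potential (mV).
#' @return Time constant in ms, always greater than 0.2.
#' @export
tau_h_nat <- function(V) {
  0.2 + 0.007 * exp(exp(-(V - 40.6) / 51.4))
}

#' Gating-kinetics table for the CA1 model
#'
#' One row per gating variable: half-(in)activation voltage \code{V_x},
#' slope \code{k_x}, fixed time constant \code{tau_x} (NA for the two
#' instantaneous activation gates and for \code{h_NaT}, whose time constant
#' is the voltage-dependent [tau_h_nat()]), the integer exponent with which
#' the gate enters its current, and an \code{instantaneous} flag.
#'
#' The numeric values are the package's own defaults, chosen once so that
#' the default model fires action potentials under the depolarizing
#' protocol and shows H-current sag and rebound under the hyperpolarizing
#' protocol; they are not a published parameter set.
#'
#' @param ... Named per-gate overrides, e.g.
#'   \code{m_NaT = list(V_x = -32)}.
#' @return A tibble with columns \code{name, V_x, k_x, tau_x, power,
#'   instantaneous}.
#' @export
ca1_gating <- function(...) {
  tbl <- tibble::tribble(
    ~name,    ~V_x, ~k_x, ~tau_x, ~power, ~instantaneous,
    "m_NaT",  -44,   10,   NA,      3L,   TRUE,
    "h_NaT",  -50,   -7,   NA,      1L,   FALSE, # tau = tau_h_nat(V)
    "m_NaP",  -50,    5,   NA,      1L,   TRUE,
    "m_CaT",  -50,    6,    5,      2L,   FALSE,
    "h_CaT",  -70,   -6,   30,      1L,   FALSE,
    "m_CaH",  -18,    6,    1,      2L,   FALSE,
    "h_CaH",  -45,   -6,   60,      1L,   FALSE,
    "m_KDR",  -25,   10,    2,      1L,   FALSE,
    "h_KDR",  -60,  -10, 1000,      1L,   FALSE,
    "m_KM",   -32,    8,   40,      1L,   FALSE,
    "m_H",    -82,   -8,   50,      1L,   FALSE,
    "n_H",    -82,   -8,  350,      1L,   FALSE
  )
  mods <- list(...)
  for (nm in names(mods)) {
    if (!nm %in% tbl$name) {
      abort(paste0("unknown gate `", nm, "`"), class = "ganpop_unknown_gate")
    }
    for (f in names(mods[[nm]])) {
      tbl[tbl$name == nm, f] <- mods[[nm]][[f]]
    }
  }
  stopifnot(all(tbl$k_x != 0), all(is.na(tbl$tau_x) | tbl$tau_x > 0))
  tbl
}

#' CA1 model parameters
#'
#' Membrane capacitance, the eight maximal conductances, reversal
#' potentials, the fast fraction \code{p} of the hyperpolarization-activated
#' (H) current, and the gating-kinetics table. Units: mV for voltages, ms
#' for time, and a consistent conductance/current/capacitance system
#' (nominally mS/cm^2, uA/cm^2 and uF/cm^2); only ratios of these enter the
#' voltage equation.
#'
#' The defaults are the package's synthetic reference cell (see
#' [ca1_gating()] for provenance); every value can be overridden.
#'
#' @param C Membrane capacitance.
#' @param g_NaT,g_NaP,g_CaT,g_CaH,g_KDR,g_KM,g_L,g_H Maximal conductances
#'   (non-negative): transient/persistent Na, T-type/high-voltage-activated
#'   Ca, delayed-rectifier/M-type K, leak, H-current.
#' @param E_Na,E_Ca,E_K,E_L,E_H Reversal potentials (mV).
#' @param p Fast fraction of the H-current, in \[0, 1\].
#' @param gating Gating table from [ca1_gating()].
#' @return An object of class \code{ca1_params} (a named list).
#' @examples
#' p <- ca1_params(g_KDR = 4)
#' @export
ca1_params <- function(C = 1,
                       g_NaT = 9, g_NaP = 0.15, g_CaT = 0.3, g_CaH = 1.5,
                       g_KDR = 3, g_KM = 0.5, g_L = 0.05, g_H = 0.04,
                       E_Na = 60, E_Ca = 120, E_K = -90, E_L = -70,
                       E_H = -30, p = 0.5,
                       gating = ca1_gating()) {
  g <- c(g_NaT = g_NaT, g_NaP = g_NaP, g_CaT = g_CaT, g_CaH = g_CaH,
         g_KDR = g_KDR, g_KM = g_KM, g_L = g_L, g_H = g_H)
  if (any(g < 0)) abort("conductances must be >= 0", class = "ganpop_bad_input")
  if (p < 0 || p > 1) abort("`p` must lie in [0, 1]", class = "ganpop_bad_input")
  missing_gates <- setdiff(.gate_order, gating$name)
  if (length(missing_gates)) {
    abort(paste("gating table is missing:", paste(missing_gates, collapse = ", ")),
          class = "ganpop_unknown_gate")
  }
  structure(
    list(C = C, g = g,
         E = c(E_Na = E_Na, E_Ca = E_Ca, E_K = E_K, E_L = E_L, E_H = E_H),
         p = p, gating = gating),
    class = "ca1_params"
  )
}

#' @export
print.ca1_params <- function(x, ...) {
  cat("<ca1_params>  C =", x$C, " p =", x$p, "\n")
  cat("  g:", paste(names(x$g), signif(x$g, 4), sep = "=", collapse = "  "), "\n")
  cat("  E:", paste(names(x$E), x$E, sep = "=", collapse = "  "), "\n")
  invisible(x)
}

# update conductances (and optionally gating half-activations) from a named
# vector; used by the sweep generators and DE
set_conductances <- function(params, values) {
  stopifnot(inherits(params, "ca1_params"))
  for (nm in names(values)) {
    if (nm %in% names(params$g)) {
      params$g[[nm]] <- values[[nm]]
    } else if (nm == "V_mNaT") {
      params$gating[params$gating$name == "m_NaT", "V_x"] <- values[[nm]]
    } else {
      abort(paste0("unknown parameter `", nm, "`"), class = "ganpop_bad_input")
    }
  }
  params
}

#' Current-clamp stimulus protocol
#'
#' A square current pulse on top of a holding (bias) current. The bias
#' current holds the cell near \code{hold_target} before the pulse; if
#' \code{bias_current} is NA it is solved by [find_bias_current()] at
#' simulation time.
#'
#' @param pulse_amplitude Step amplitude in model current units.
#' @param pulse_onset,pulse_duration,total_duration Times (ms).
#' @param hold_target Pre-pulse holding potential (mV).
#' @param bias_current Holding current (model units) or NA to solve.
#' @param dt_out Output sampling step (ms).
#' @return An object of class \code{stim_protocol}.
#' @export
stim_protocol <- function(pulse_amplitude,
                          pulse_onset = 100, pulse_duration = 500,
                          total_duration = pulse_onset + pulse_duration + 200,
                          hold_target = -80, bias_current = NA_real_,
                          dt_out = 0.01) {
  if (pulse_onset < 0 || pulse_onset + pulse_duration > total_duration ||
      dt_out <= 0) {
    abort("invalid protocol timing", class = "ganpop_bad_input")
  }
  structure(
    list(pulse_amplitude = pulse_amplitude, pulse_onset = pulse_onset,
         pulse_duration = pulse_duration, total_duration = total_duration,
         hold_target = hold_target, bias_current = bias_current,
         dt_out = dt_out),
    class = "stim_protocol"
  )
}

#' Default current-clamp protocols
#'
#' The two study protocols: a 500 ms depolarizing step (300 pA) and a 500 ms
#' hyperpolarizing step (-100 pA), both from a holding potential near
#' -80 mV. Experimental picoamperes are mapped to model current units by a
#' single scale constant (default 0.01 model units per pA, chosen once so
#' that the default cell fires at least one action potential under the
#' depolarizing step).
#'
#' @param current_scale Model current units per pA.
#' @param dt_out Output sampling step (ms).
#' @name protocols
#' @export
protocol_depolarizing <- function(current_scale = 0.01, dt_out = 0.01) {
  stim_protocol(pulse_amplitude = 300 * current_scale, dt_out = dt_out)
}

#' @rdname protocols
#' @export
protocol_hyperpolarizing <- function(current_scale = 0.01, dt_out = 0.01) {
  stim_protocol(pulse_amplitude = -100 * current_scale, dt_out = dt_out)
}

# ---- packing for the compiled core ----------------------------------------

pack_params <- function(params) {
  gt <- params$gating
  ord <- match(.gate_order, gt$name)
  gv <- as.matrix(gt[ord, c("V_x", "k_x", "tau_x")])
  gv[is.na(gv)] <- -1 # unused slots (instantaneous / voltage-dependent tau)
  c(params$C, unname(params$g), unname(params$E), params$p,
    as.vector(t(gv)))
}

pack_stim <- function(bias, amplitude, on, off) {
  c(bias, amplitude, on, off)
}

steady_gates <- function(params, V) {
  gt <- params$gating
  x <- boltzmann(V, gt$V_x, gt$k_x)
  setNames(x, gt$name)[.dynamic_gates]
}

# total ionic current at voltage V with every gate at steady state
ionic_current_ss <- function(params, V) {
  g <- params$g; E <- params$E
  xs <- boltzmann(V, params$gating$V_x, params$gating$k_x)
  names(xs) <- params$gating$name
  INaT <- g[["g_NaT"]] * xs[["m_NaT"]]^3 * xs[["h_NaT"]] * (V - E[["E_Na"]])
  INaP <- g[["g_NaP"]] * xs[["m_NaP"]] * (V - E[["E_Na"]])
  ICaT <- g[["g_CaT"]] * xs[["m_CaT"]]^2 * xs[["h_CaT"]] * (V - E[["E_Ca"]])
  ICaH <- g[["g_CaH"]] * xs[["m_CaH"]]^2 * xs[["h_CaH"]] * (V - E[["E_Ca"]])
  IKDR <- g[["g_KDR"]] * xs[["m_KDR"]] * xs[["h_KDR"]] * (V - E[["E_K"]])
  IKM <- g[["g_KM"]] * xs[["m_KM"]] * (V - E[["E_K"]])
  IL <- g[["g_L"]] * (V - E[["E_L"]])
  IH <- g[["g_H"]] * (params$p * xs[["m_H"]] + (1 - params$p) * xs[["n_H"]]) *
    (V - E[["E_H"]])
  INaT + INaP + ICaT + ICaH + IKDR + IKM + IL + IH
}

#' Model right-hand side
#'
#' Time derivative of the state (membrane potential plus the 10 dynamic
#' gating variables). The two fast sodium activation gates are evaluated at
#' their Boltzmann steady state. The applied current is the bias plus the
#' pulse amplitude inside the pulse window.
#'
#' @param state Named numeric vector \code{c(V, h_NaT, m_CaT, h_CaT, m_CaH,
#'   h_CaH, m_KDR, h_KDR, m_KM, m_H, n_H)} (names optional but, if present,
#'   checked).
#' @param t Time (ms).
#' @param params [ca1_params()].
#' @param protocol [stim_protocol()]; its \code{bias_current} must be set.
#' @return Named derivative vector of the same length.
#' @export
ca1_rhs <- function(state, t, params, protocol) {
  nms <- names(state)
  if (!is.null(nms)) {
    expected <- c("V", .dynamic_gates)
    if (!identical(nms, expected)) {
      unknown <- setdiff(nms, expected)
      abort(paste("unknown state entries:", paste(unknown, collapse = ", ")),
            class = "ganpop_unknown_gate")
    }
  }
  stopifnot(length(state) == 11L)
  bias <- protocol$bias_current
  if (is.na(bias)) abort("protocol bias_current is unset", class = "ganpop_bad_input")
  stim <- pack_stim(bias, protocol$pulse_amplitude, protocol$pulse_onset,
                    protocol$pulse_onset + protocol$pulse_duration)
  dy <- .Call(C_ca1_rhs, as.numeric(state), as.numeric(t),
              pack_params(params), stim)
  setNames(dy, c("V", .dynamic_gates))
}

#' Solve the holding (bias) current
#'
#' Finds the constant current that makes \code{hold_target} a settled
#' pre-pulse membrane potential: at a fixed point every gate sits at its
#' Boltzmann steady state, so the bias equals the total ionic current at
#' \code{hold_target}. The result is verified by a settling simulation; an
#' unstable fixed point (settled voltage off by more than \code{tol}) is an
#' error.
#'
#' @param params [ca1_params()].
#' @param hold_target Holding potential (mV); must lie between E_K and E_Na.
#' @param settle Settling-simulation length (ms).
#' @param tol Verification tolerance (mV).
#' @param verify Run the settling check (default TRUE).
#' @return Bias current in model units.
#' @export
find_bias_current <- function(params, hold_target = -80, settle = 1000,
                              tol = 0.1, verify = TRUE) {
  if (hold_target <= params$E[["E_K"]] || hold_target >= params$E[["E_Na"]]) {
    abort("hold_target must lie in (E_K, E_Na)", class = "ganpop_bad_input")
  }
  bias <- ionic_current_ss(params, hold_target)
  if (verify) {
    y0 <- c(hold_target, unname(steady_gates(params, hold_target)))
    stim <- pack_stim(bias, 0, 0, 0)
    out <- .Call(C_ca1_dopri, y0, c(0, settle / 2, settle),
                 pack_params(params), stim, 1e-8, 1e-10, 25, 5e6)
    v_end <- out$y[3, 1]
    if (abs(v_end - hold_target) > tol) {
      abort(sprintf(
        "holding state at %g mV is not stable (settles to %.3f mV)",
        hold_target, v_end), class = "ganpop_unstable_hold")
    }
  }
  unname(bias)
}

# low-level piecewise integration over [t0, t1] at output grid tout,
# splitting at the pulse edges so the solver never steps across the
# current discontinuity
integrate_piecewise <- function(y0, tout, pp, bias, amplitude, on, off,
                                rtol, atol, hmax = 25, max_steps = 5e6) {
  t0 <- tout[1]; t1 <- tout[length(tout)]
  edges <- sort(unique(c(t0, on, off, t1)))
  edges <- edges[edges >= t0 & edges <= t1]
  out <- matrix(NA_real_, nrow = length(tout), ncol = 11)
  y <- y0
  nstep <- 0
  for (i in seq_len(length(edges) - 1)) {
    a <- edges[i]; b <- edges[i + 1]
    if (b - a <= 0) next
    idx <- which(tout > a + 1e-12 & tout <= b + 1e-12)
    seg_t <- c(a, tout[idx])
    if (abs(seg_t[length(seg_t)] - b) > 1e-12) seg_t <- c(seg_t, b)
    stim <- pack_stim(bias, amplitude, on, off)
    res <- .Call(C_ca1_dopri, y, seg_t, pp, stim, rtol, atol, hmax, max_steps)
    nstep <- nstep + res$nstep
    y <- res$y[length(seg_t), ]
    if (length(idx)) out[idx, ] <- res$y[seq_along(idx) + 1, , drop = FALSE]
  }
  out[1, ] <- y0
  list(y = out, final = y, nstep = nstep)
}

#' Simulate the CA1 model under a current-clamp protocol
#'
#' Initializes the state at the holding potential (gates at steady state),
#' settles for \code{settle} ms under the bias current, then integrates over
#' \code{[0, total_duration]} and reports the membrane potential on the
#' uniform \code{dt_out} grid. Integration uses an adaptive Dormand-Prince
#' 5(4) method (\code{method = "dopri"}) or a fixed-step classical RK4
#' (\code{method = "rk4"}, step \code{rk4_dt}), the latter serving as a
#' numerical cross-check.
#'
#' @param params [ca1_params()].
#' @param protocol [stim_protocol()].
#' @param init Optional initial state (length 11) at t = 0; skips holding
#'   initialization and settling.
#' @param settle Settling time before the recorded window (ms).
#' @param rtol,atol Solver tolerances.
#' @param method \code{"dopri"} (default) or \code{"rk4"}.
#' @param rk4_dt Fixed step for \code{method = "rk4"} (ms).
#' @param gate_tol Gate-range overshoot tolerance; any excursion of a gating
#'   variable beyond \[0,1\] larger than this is an error, smaller ones are
#'   clipped.
#' @return A \code{ca1_trace}: a tibble with columns \code{t} (ms) and
#'   \code{V} (mV), carrying the protocol, the final full state and solver
#'   statistics as attributes.
#' @examples
#' \donttest{
#' tr <- simulate_ca1(ca1_params(), protocol_depolarizing(dt_out = 0.1))
#' max(tr$V) # spike overshoot
#' }
#' @export
simulate_ca1 <- function(params, protocol, init = NULL, settle = 1000,
                         rtol = 1e-8, atol = 1e-10,
                         method = c("dopri", "rk4"), rk4_dt = 1e-3,
                         gate_tol = 1e-9) {
  method <- match.arg(method)
  stopifnot(inherits(params, "ca1_params"), inherits(protocol, "stim_protocol"))
  pp <- pack_params(params)
  bias <- protocol$bias_current
  if (is.na(bias)) bias <- find_bias_current(params, protocol$hold_target,
                                             verify = FALSE)
  on <- protocol$pulse_onset
  off <- protocol$pulse_onset + protocol$pulse_duration

  err_with_params <- function(msg) {
    abort(message = msg, class = "ganpop_sim_failure",
          params = unclass(params)["g"])
  }

  if (is.null(init)) {
    y0 <- c(protocol$hold_target,
            unname(steady_gates(params, protocol$hold_target)))
    stim0 <- pack_stim(bias, 0, 0, 0)
    st <- tryCatch(
      .Call(C_ca1_dopri, y0, c(-settle, -settle / 2, 0), pp, stim0,
            rtol, atol, 25, 5e6),
      error = function(e) err_with_params(conditionMessage(e))
    )
    y0 <- st$y[3, ]
  } else {
    stopifnot(length(init) == 11L)
    y0 <- as.numeric(init)
  }

  tout <- seq(0, protocol$total_duration, by = protocol$dt_out)
  if (method == "dopri") {
    res <- tryCatch(
      integrate_piecewise(y0, tout, pp, bias, protocol$pulse_amplitude,
                          on, off, rtol, atol),
      error = function(e) err_with_params(conditionMessage(e))
    )
    Y <- res$y; final <- res$final; nstep <- res$nstep
  } else {
    stim <- pack_stim(bias, protocol$pulse_amplitude, on, off)
    # split at the pulse edges for the fixed-step method too
    Y <- matrix(NA_real_, length(tout), 11)
    y <- y0; Y[1, ] <- y0; nstep <- 0
    edges <- sort(unique(c(0, on, off, protocol$total_duration)))
    for (i in seq_len(length(edges) - 1)) {
      idx <- which(tout > edges[i] + 1e-12 & tout <= edges[i + 1] + 1e-12)
      seg_t <- unique(c(edges[i], tout[idx], edges[i + 1]))
      ym <- .Call(C_ca1_rk4, y, seg_t, rk4_dt, pp, stim)
      y <- ym[length(seg_t), ]
      if (length(idx)) Y[idx, ] <- ym[seq_along(idx) + 1, , drop = FALSE]
      nstep <- nstep + (edges[i + 1] - edges[i]) / rk4_dt
    }
    final <- y
  }

  if (any(!is.finite(Y))) err_with_params("non-finite state in solution")
  gates <- Y[, -1, drop = FALSE]
  over <- max(0, max(gates) - 1, -min(gates))
  if (over > gate_tol) {
    err_with_params(sprintf("gating variable left [0,1] by %.3g", over))
  }
  gates[gates < 0] <- 0
  gates[gates > 1] <- 1

  protocol$bias_current <- bias
  out <- tibble::tibble(t = tout, V = Y[, 1])
  structure(out,
            protocol = protocol,
            gating_final = setNames(final[-1], .dynamic_gates),
            final_state = final,
            nstep = nstep,
            class = c("ca1_trace", class(out)))
}

#' @export
print.ca1_trace <- function(x, ...) {
  p <- attr(x, "protocol")
  cat(sprintf("<ca1_trace> %d samples, dt = %g ms, pulse %g @ [%g, %g] ms\n",
              nrow(x), p$dt_out, p$pulse_amplitude, p$pulse_onset,
              p$pulse_onset + p$pulse_duration))
  NextMethod()
}
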