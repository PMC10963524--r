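# Extraction of the 13 electrophysiological features: 9 describing the
# first action potential of the depolarizing-pulse response and 4 describing
# the hyperpolarizing-pulse response (sag/steady-state/rebound).

#' Canonical feature names
#'
#' The 13 features in canonical order: 9 action-potential features from the
#' depolarizing protocol and 4 hyperpolarization features from the
#' hyperpolarizing protocol.
#' @return Character vector of length 13.
#' @export
feature_names <- function() {
  c("ap_threshold", "ap_peak", "ap_trough", "ap_width", "ap_min_before",
    "ap_max_ror", "ap_v_at_max_ror", "ap_max_neg_ror", "ap_v_at_max_neg_ror",
    "hp_a", "hp_b", "hp_c", "hp_d")
}

# dV/dt by central differences on the uniform grid (one-sided at the ends)
dvdt <- function(t, V) {
  n <- length(V)
  dt <- t[2] - t[1]
  d <- numeric(n)
  d[2:(n - 1)] <- (V[3:n] - V[1:(n - 2)]) / (2 * dt)
  d[1] <- (V[2] - V[1]) / dt
  d[n] <- (V[n] - V[n - 1]) / dt
  d
}

trace_protocol <- function(trace) {
  p <- attr(trace, "protocol")
  if (is.null(p)) abort("trace carries no protocol", class = "ganpop_bad_input")
  p
}

#' Detect the first action potential
#'
#' Returns the time of the first local maximum of the voltage inside the
#' pulse window that exceeds the spike-detection level.
#'
#' @param trace A voltage trace (tibble with \code{t}, \code{V} and a
#'   protocol attribute, as returned by [simulate_ca1()]).
#' @param detect_level Spike-detection level (mV).
#' @return Peak time in ms.
#' @export
detect_first_ap <- function(trace, detect_level = -20) {
  p <- trace_protocol(trace)
  on <- p$pulse_onset; off <- p$pulse_onset + p$pulse_duration
  idx <- which(trace$t >= on & trace$t <= off)
  V <- trace$V[idx]
  if (length(V) < 3) abort("pulse window too short", class = "ganpop_no_ap")
  im <- which(diff(sign(diff(V))) < 0) + 1L # interior local maxima
  im <- im[V[im] > detect_level]
  if (!length(im)) {
    abort("no action potential detected in the pulse window",
          class = "ganpop_no_ap")
  }
  trace$t[idx[im[1]]]
}

#' Extract the 9 action-potential features
#'
#' Works on the first action potential of a depolarizing-pulse trace.
#' Rates of rise are central-difference dV/dt; the max/min rate of rise are
#' taken in the 3 ms window from 1 ms before to 2 ms after the peak; the
#' trough is the minimum voltage in the 2 ms after the peak and the
#' "min before" the minimum in the 1 ms before it. The threshold is the
#' voltage at the first pre-peak sample (searched within 5 ms of the peak)
#' where dV/dt reaches 10 percent of the max rate of rise, and the width is
#' the time the voltage stays above the voltage at max rate of rise around
#' the peak (linear interpolation at the crossings).
#'
#' @inheritParams detect_first_ap
#' @param threshold_frac Fraction of the max rate of rise defining the
#'   threshold (default 0.1).
#' @param threshold_search Pre-peak search window for the threshold (ms).
#' @return A one-row tibble with the 9 AP features.
#' @export
extract_ap_features <- function(trace, detect_level = -20,
                                threshold_frac = 0.1, threshold_search = 5) {
  t <- trace$t; V <- trace$V
  dt <- t[2] - t[1]
  t_peak <- detect_first_ap(trace, detect_level)
  ip <- which.min(abs(t - t_peak))
  if (t_peak - 1 < t[1] || t_peak + 2 > t[length(t)]) {
    abort("AP window extends past the trace", class = "ganpop_window")
  }
  d <- dvdt(t, V)

  win <- which(t >= t_peak - 1 & t <= t_peak + 2)
  # first sample attaining the extremum wins; the comparison uses a tiny
  # relative slack so exact plateaus (ramps) are not broken by round-off
  first_at <- function(x, m) which(x >= m - 1e-9 * max(abs(m), 1))[1]
  mx <- max(d[win]); mn <- min(d[win])
  i_max <- win[first_at(d[win], mx)]
  i_min <- win[first_at(-d[win], -mn)]

  # parabolic sub-sample refinement of a strict interior extremum of the
  # sampled derivative (sign = +1 maximum, -1 minimum); plateaus (ramps)
  # keep the sample values so piecewise-linear waveforms stay exact
  refine <- function(i, sign) {
    out <- list(d = d[i], v = V[i])
    if (i <= 1 || i >= length(d)) return(out)
    dm <- sign * d[i - 1]; d0 <- sign * d[i]; dp <- sign * d[i + 1]
    tol <- 1e-9 * max(abs(d0), 1)
    if (dm >= d0 - tol || dp >= d0 - tol) return(out) # not strict
    # around a strict smooth extremum, re-estimate the derivative with a
    # fourth-order stencil (kills the O(dt^2) bias the plain central
    # difference leaves in a very fast upstroke) and take the parabola
    # vertex; plateaus returned above keep exact sample semantics
    n <- length(V)
    if (i < 7 || i > n - 6) { # too close to the trace edge: parabola on d
      denom <- dm - 2 * d0 + dp
      if (denom >= 0) return(out)
      s <- max(-0.5, min(0.5, 0.5 * (dm - dp) / denom))
      out$d <- sign * (d0 - 0.25 * (dm - dp) * s)
      out$v <- V[i] + 0.5 * s * (V[i + 1] - V[i - 1]) +
        0.5 * s^2 * (V[i + 1] - 2 * V[i] + V[i - 1])
      return(out)
    }
    # fourth-order derivative at offsets j (in grid units) around i
    d4 <- function(j) {
      k <- i + j
      sign * (V[k - 2] - 8 * V[k - 1] + 8 * V[k + 1] - V[k + 2]) / (12 * dt)
    }
    vertex <- function(h) { # parabola vertex from offsets -h, 0, +h
      a <- d4(-h); b0 <- d4(0); c <- d4(h)
      den <- a - 2 * b0 + c
      if (den >= 0) return(NULL)
      s <- max(-0.5, min(0.5, 0.5 * (a - c) / den)) * h
      list(s = s, d = b0 - 0.125 * (a - c)^2 / den)
    }
    v1 <- vertex(1); v2 <- vertex(2)
    if (is.null(v1) || is.null(v2)) {
      if (is.null(v1)) return(out)
      s <- v1$s; dval <- v1$d
    } else {
      # Richardson extrapolation of the O(dt^2) vertex-location error
      s <- (4 * v1$s - v2$s) / 3
      dval <- v1$d + (v1$d - v2$d) / 3
    }
    s <- max(-1, min(1, s))
    out$d <- sign * dval
    # cubic Lagrange interpolation of the voltage at the refined time
    js <- if (s >= 0) -1:2 else -2:1
    vv <- V[i + js]
    L <- vapply(seq_along(js), function(k) {
      oth <- js[-k]
      prod((s - oth) / (js[k] - oth))
    }, numeric(1))
    out$v <- sum(L * vv)
    out
  }
  rmax <- refine(i_max, 1)
  rmin <- refine(i_min, -1)
  ap_max_ror <- rmax$d
  ap_v_at_max_ror <- rmax$v
  ap_max_neg_ror <- rmin$d
  ap_v_at_max_neg_ror <- rmin$v

  post <- which(t > t_peak & t <= t_peak + 2)
  ap_trough <- min(V[post])
  pre <- which(t >= t_peak - 1 & t < t_peak)
  ap_min_before <- min(V[pre])

  # threshold: first pre-peak sample with dV/dt >= frac * max RoR
  th_win <- which(t >= t_peak - threshold_search & t <= t_peak)
  i_th <- th_win[which(d[th_win] >= threshold_frac * ap_max_ror)[1]]
  if (is.na(i_th)) abort("threshold not found", class = "ganpop_window")
  ap_threshold <- V[i_th]

  # width: time V stays above the voltage at max RoR around the peak,
  # with linear interpolation at the two crossings
  lev <- ap_v_at_max_ror
  iu <- ip
  while (iu > 1 && V[iu - 1] > lev) iu <- iu - 1
  idn <- ip
  n <- length(V)
  while (idn < n && V[idn + 1] > lev) idn <- idn + 1
  t_up <- if (iu == 1 || V[iu] <= lev) t[iu] else {
    t[iu - 1] + dt * (lev - V[iu - 1]) / (V[iu] - V[iu - 1])
  }
  t_dn <- if (idn == n || V[idn] <= lev) t[idn] else {
    t[idn] + dt * (lev - V[idn]) / (V[idn + 1] - V[idn])
  }
  ap_width <- t_dn - t_up

  tibble::tibble(
    ap_threshold = ap_threshold, ap_peak = V[ip], ap_trough = ap_trough,
    ap_width = ap_width, ap_min_before = ap_min_before,
    ap_max_ror = ap_max_ror, ap_v_at_max_ror = ap_v_at_max_ror,
    ap_max_neg_ror = ap_max_neg_ror,
    ap_v_at_max_neg_ror = ap_v_at_max_neg_ror
  )
}

#' Extract the 4 hyperpolarization features
#'
#' All four features are differences from the pre-pulse baseline (the mean
#' voltage over \code{baseline_window} ms before pulse onset):
#' \describe{
#'   \item{hp_a}{negative-peak voltage during the pulse minus baseline}
#'   \item{hp_b}{asymptote of a single-exponential fit
#'     \eqn{V(t) = a + b\,e^{-(t-t_0)/\tau}} over \[onset, negative-peak
#'     time\], minus baseline; captures where the passive decay was heading
#'     before the sag develops}
#'   \item{hp_c}{steady state: mean voltage over the last
#'     \code{steady_window} ms of the pulse, minus baseline}
#'   \item{hp_d}{rebound: maximum voltage in the \code{rebound_window} ms
#'     after pulse offset, minus baseline}
#' }
#'
#' @inheritParams detect_first_ap
#' @param baseline_window,steady_window,rebound_window Window lengths (ms).
#' @return A one-row tibble with the 4 HP features.
#' @export
extract_hp_features <- function(trace, baseline_window = 50,
                                steady_window = 50, rebound_window = 200) {
  p <- trace_protocol(trace)
  t <- trace$t; V <- trace$V
  on <- p$pulse_onset; off <- p$pulse_onset + p$pulse_duration

  baseline <- mean(V[t >= on - baseline_window & t < on])
  in_pulse <- which(t >= on & t <= off)
  i_neg <- in_pulse[which.min(V[in_pulse])]
  hp_a <- V[i_neg] - baseline

  steady <- V[t >= off - steady_window & t <= off]
  hp_c <- mean(steady) - baseline

  post <- V[t > off & t <= off + rebound_window]
  if (!length(post)) abort("no post-pulse window", class = "ganpop_window")
  hp_d <- max(post) - baseline

  # single-exponential fit from onset to negative-peak time
  fit_idx <- which(t >= on & t <= t[i_neg])
  tf <- t[fit_idx] - on; vf <- V[fit_idx]
  tau0 <- max((t[i_neg] - on) / 3, 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      vf ~ a + b * exp(-tf / tau),
      start = list(a = vf[length(vf)], b = vf[1] - vf[length(vf)],
                   tau = tau0),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) {
      abort(paste("exponential fit failed:", conditionMessage(e)),
            class = "ganpop_fit_failure",
            n_points = length(fit_idx), tau_start = tau0)
    }
  )
  hp_b <- unname(coef(fit)[["a"]]) - baseline

  tibble::tibble(hp_a = hp_a, hp_b = hp_b, hp_c = hp_c, hp_d = hp_d)
}

#' Extract the full 13-feature vector from a pair of traces
#'
#' @param ap_trace Depolarizing-pulse trace.
#' @param hp_trace Hyperpolarizing-pulse trace.
#' @param ... Passed to [extract_ap_features()] and [extract_hp_features()].
#' @return A one-row tibble with the 13 canonical features (see
#'   [feature_names()]).
#' @export
extract_features <- function(ap_trace, hp_trace, ...) {
  args <- list(...)
  ap_args <- args[names(args) %in% c("detect_level", "threshold_frac",
                                     "threshold_search")]
  hp_args <- args[names(args) %in% c("baseline_window", "steady_window",
                                     "rebound_window")]
  dplyr::bind_cols(
    do.call(extract_ap_features, c(list(ap_trace), ap_args)),
    do.call(extract_hp_features, c(list(hp_trace), hp_args))
  )
}

#' Per-feature ranges of a training dataset
#'
#' @param features A tibble of feature rows (e.g. the \code{features}
#'   element of a training dataset).
#' @return A tibble with columns \code{feature, min, median, max, mean}.
#' @export
feature_ranges <- function(features) {
  features |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "feature") |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(min = min(.data$value), median = median(.data$value),
                     max = max(.data$value), mean = mean(.data$value),
                     .groups = "drop") |>
    dplyr::arrange(match(.data$feature, feature_names()))
}

#' Replace out-of-range feature values
#'
#' Any feature value outside the \[min, max\] range observed in the training
#' dataset is replaced: by the training median (default), the training mean,
#' or the closest in-range value (the violated bound). Inference on such
#' values would ask the generator to extrapolate beyond its training
#' support.
#'
#' @param features Tibble of feature rows.
#' @param ranges Output of [feature_ranges()] on the training dataset.
#' @param strategy One of \code{"median"}, \code{"mean"}, \code{"closest"}.
#' @return The feature tibble with replacements applied; the logical
#'   replacement mask (same shape) is attached as attribute
#'   \code{"replaced"}.
#' @export
replace_out_of_range <- function(features, ranges,
                                 strategy = c("median", "mean", "closest")) {
  strategy <- match.arg(strategy)
  out <- features
  mask <- as.data.frame(features)
  mask[] <- FALSE
  for (f in intersect(names(features), ranges$feature)) {
    r <- ranges[ranges$feature == f, ]
    x <- features[[f]]
    low <- x < r$min; high <- x > r$max
    repl <- switch(strategy,
      median = list(low = r$median, high = r$median),
      mean = list(low = r$mean, high = r$mean),
      closest = list(low = r$min, high = r$max)
    )
    x[low] <- repl$low
    x[high] <- repl$high
    out[[f]] <- x
    mask[[f]] <- low | high
  }
  attr(out, "replaced") <- as.matrix(mask)
  out
}
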