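# Benchmark random-walk Metropolis-Hastings sampler: the baseline the
# amortized generator is compared against. Deliberately the simplest
# variant: isotropic Gaussian proposals, uniform box prior, Gaussian
# pseudo-likelihood on standardized feature discrepancy.

#' Metropolis-Hastings configuration
#'
#' @param bounds Tibble with columns \code{parameter, low, high} (the
#'   uniform prior box).
#' @param proposal_scale Per-parameter random-walk step SD; default 10
#'   percent of each prior width.
#' @param n_steps Chain length.
#' @param burn_in Discarded initial steps.
#' @param thin Keep every \code{thin}-th post-burn-in draw.
#' @param bandwidth Named per-feature pseudo-likelihood SD (typically the
#'   feature SDs of the training sweep). Ignored when an explicit log
#'   target is sampled.
#' @param seed Integer seed.
#' @return A list of class \code{mcmc_config}.
#' @export
mcmc_config <- function(bounds, proposal_scale = NULL, n_steps = 10000,
                        burn_in = 2000, thin = 1, bandwidth = NULL,
                        seed = 1L) {
  stopifnot(n_steps > burn_in, thin >= 1)
  if (is.null(proposal_scale)) {
    proposal_scale <- 0.1 * (bounds$high - bounds$low)
  }
  stopifnot(all(proposal_scale > 0),
            is.null(bandwidth) || all(bandwidth > 0))
  structure(list(bounds = bounds, proposal_scale = proposal_scale,
                 n_steps = as.integer(n_steps), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), bandwidth = bandwidth, seed = seed),
            class = "mcmc_config")
}

#' Random-walk Metropolis-Hastings sampling
#'
#' Samples parameter sets either from an explicit log target density
#' (\code{log_target}) or from the pseudo-posterior induced by a forward map
#' and target features: uniform prior on the bounds box and Gaussian
#' pseudo-likelihood \eqn{-\tfrac12 \sum_f ((F_f(\theta) - y_f)/h_f)^2}
#' summed over the supplied target feature vectors, with per-feature
#' bandwidths \eqn{h_f}. Proposals outside the prior box are rejected
#' outright.
#'
#' @param config [mcmc_config()].
#' @param log_target Optional function of the parameter vector returning the
#'   log target density (overrides \code{forward}/\code{target_features}).
#' @param forward Function mapping a named parameter vector to a named
#'   feature vector (or one-row data frame); e.g. simulate-and-extract.
#' @param target_features Data frame of target feature rows.
#' @param init Optional start point (defaults to the box centre).
#' @return A tibble of post-burn-in, thinned samples (one column per
#'   parameter), with the acceptance rate and the chain seed as attributes.
#'   A zero-acceptance window triggers a warning with the proposal scale.
#' @export
mh_sample <- function(config, log_target = NULL, forward = NULL,
                      target_features = NULL, init = NULL) {
  stopifnot(inherits(config, "mcmc_config"))
  b <- config$bounds
  d <- nrow(b)
  lo <- b$low; hi <- b$high
  nms <- b$parameter

  if (is.null(log_target)) {
    if (is.null(forward) || is.null(target_features)) {
      abort("supply either `log_target` or `forward` + `target_features`",
            class = "ganpop_bad_input")
    }
    bw <- config$bandwidth
    if (is.null(bw)) abort("`bandwidth` required for the feature pseudo-likelihood",
                           class = "ganpop_bad_input")
    tf <- as.matrix(target_features[, names(bw), drop = FALSE])
    log_target <- function(theta) {
      fv <- tryCatch(forward(setNames(theta, nms)), error = function(e) NULL)
      if (is.null(fv)) return(-Inf)
      fv <- unlist(fv)[names(bw)]
      -0.5 * sum(sweep(tf, 2, fv, "-")^2 %*% (1 / bw^2))
    }
  }

  with_seed(config$seed, {
    x <- if (is.null(init)) (lo + hi) / 2 else as.numeric(init)
    lt <- log_target(x)
    keep <- matrix(NA_real_, nrow = config$n_steps, ncol = d)
    acc <- 0L
    window_acc <- 0L
    for (s in seq_len(config$n_steps)) {
      prop <- x + rnorm(d, 0, config$proposal_scale)
      if (all(prop >= lo & prop <= hi)) {
        lt_prop <- log_target(prop)
        if (is.finite(lt_prop) && log(runif(1)) < lt_prop - lt) {
          x <- prop; lt <- lt_prop
          acc <- acc + 1L; window_acc <- window_acc + 1L
        }
      }
      keep[s, ] <- x
      if (s %% 1000 == 0) {
        if (window_acc == 0L) {
          warn(sprintf(
            "no acceptances in steps %d-%d; proposal scale (%s) may be too large",
            s - 999L, s, paste(signif(config$proposal_scale, 3),
                               collapse = ", ")),
            class = "ganpop_mh_stuck")
        }
        window_acc <- 0L
      }
    }
    idx <- seq(config$burn_in + 1L, config$n_steps, by = config$thin)
    out <- tibble::as_tibble(setNames(as.data.frame(keep[idx, , drop = FALSE]),
                                      nms))
    attr(out, "acceptance_rate") <- acc / config$n_steps
    attr(out, "seed") <- config$seed
    out
  })
}
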