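# Generators for every dataset the pipeline consumes: uniform training
# sweeps through the CA1 model, truncated-normal synthetic targets,
# enumerated two-group scenarios, the 4-category experimental mimic, and the
# Rosenbrock toy problem.

# run `code` under a temporary RNG state seeded with `seed` (NULL = use the
# current stream)
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' The varied conductances
#'
#' The five maximal conductances varied throughout the analysis (transient
#' Na, high-voltage-activated Ca, delayed-rectifier K, M-type K, H-current);
#' the remaining three have little influence on the features (see
#' [sobol_screen()]) and stay at their defaults.
#'
#' @return Character vector of length 5.
#' @export
varied_conductances <- function() c("g_NaT", "g_CaH", "g_KDR", "g_KM", "g_H")

#' Parameter bounds for the training sweep
#'
#' Per-parameter default value \eqn{\mu_p} and sweep bounds at plus/minus
#' 100 percent of the default, i.e. \eqn{[0, 2\mu_p]}.
#'
#' @param params Base [ca1_params()] supplying the defaults.
#' @param vary Names of the varied conductances.
#' @return A tibble with columns \code{parameter, mu, low, high}.
#' @export
ca1_bounds <- function(params = ca1_params(), vary = varied_conductances()) {
  mu <- params$g[vary]
  tibble::tibble(parameter = vary, mu = unname(mu), low = 0,
                 high = 2 * unname(mu))
}

#' Truncated-normal sampling by clamping
#'
#' Draws \eqn{N(\mu, \sigma^2)} and clamps values below \code{low} to
#' \code{low} and above \code{high} to \code{high} (truncation by clamping,
#' not rejection, so boundary atoms appear when \eqn{\mu} is near a bound).
#'
#' @param n Number of draws.
#' @param mu Mean.
#' @param sd Standard deviation (default \code{mu/8}).
#' @param low,high Clamping bounds.
#' @param seed Optional integer seed.
#' @return Numeric vector of length \code{n}.
#' @export
sample_truncated_normal <- function(n, mu, sd = mu / 8, low = 0,
                                    high = Inf, seed = NULL) {
  stopifnot(sd > 0)
  with_seed(seed, {
    x <- rnorm(n, mu, sd)
    pmin(pmax(x, low), high)
  })
}

# simulate a table of conductance values through both protocols and extract
# features; returns features with an `ok` flag and an error label
simulate_feature_rows <- function(par_tbl, base_params = ca1_params(),
                                  protocols = list(
                                    ap = protocol_depolarizing(),
                                    hp = protocol_hyperpolarizing()
                                  ),
                                  ...) {
  res <- purrr::map(seq_len(nrow(par_tbl)), function(i) {
    pr <- set_conductances(base_params, unlist(par_tbl[i, ]))
    tryCatch({
      ap <- simulate_ca1(pr, protocols$ap)
      ap_fv <- extract_ap_features(ap) # fails fast on no-AP draws
      hp <- simulate_ca1(pr, protocols$hp)
      fv <- dplyr::bind_cols(ap_fv, extract_hp_features(hp))
      fv$ok <- TRUE
      fv$error <- NA_character_
      fv
    }, error = function(e) {
      cls <- class(e)[1]
      tibble::as_tibble(setNames(as.list(rep(NA_real_, 13)),
                                 feature_names())) |>
        dplyr::mutate(ok = FALSE, error = cls)
    })
  })
  dplyr::bind_rows(res)
}

#' Build a uniform training sweep through the CA1 model
#'
#' Samples the varied conductances i.i.d. uniform on their \code{[low,
#' high]} bounds (the remaining conductances stay at the base defaults),
#' simulates both current-clamp protocols and extracts the 13 features.
#' Parameter draws whose simulation yields no action potential (or fails)
#' are discarded and redrawn until \code{n} valid rows exist; the discard
#' fraction is recorded. Normalization metadata (feature mean/sd, parameter
#' bounds) is computed on the accepted rows and stored with the dataset.
#'
#' The full-scale configuration of the study is 3,000,000 rows
#' (\code{scale_profile("full_scale")}); tests and examples use far smaller
#' sweeps.
#'
#' @param n Number of valid rows required.
#' @param bounds [ca1_bounds()].
#' @param base_params Base [ca1_params()].
#' @param protocols Named list with elements \code{ap} and \code{hp}.
#' @param seed Integer seed.
#' @param max_discard_frac Abort if the discard fraction exceeds this after
#'   at least one full batch.
#' @param batch Draw size per attempt round.
#' @return An object of class \code{ganpop_training}: a list with tibbles
#'   \code{params} (n x k) and \code{features} (n x 13), the discard count,
#'   normalization metadata, bounds and seed.
#' @export
make_training_dataset <- function(n, bounds = ca1_bounds(),
                                  base_params = ca1_params(),
                                  protocols = list(
                                    ap = protocol_depolarizing(),
                                    hp = protocol_hyperpolarizing()
                                  ),
                                  seed = 1L, max_discard_frac = 0.9,
                                  batch = max(64L, ceiling(n / 4))) {
  stopifnot(n >= 1)
  with_seed(seed, {
    kept_p <- list(); kept_f <- list()
    n_ok <- 0L; n_try <- 0L
    while (n_ok < n) {
      m <- min(batch, max(16L, n - n_ok))
      draw <- purrr::map(seq_len(nrow(bounds)), function(j) {
        runif(m, bounds$low[j], bounds$high[j])
      })
      draw <- tibble::as_tibble(setNames(draw, bounds$parameter))
      fv <- simulate_feature_rows(draw, base_params, protocols)
      ok <- fv$ok
      n_try <- n_try + m
      if (any(ok)) {
        kept_p[[length(kept_p) + 1]] <- draw[ok, ]
        kept_f[[length(kept_f) + 1]] <-
          fv[ok, feature_names()]
        n_ok <- n_ok + sum(ok)
      }
      if (n_try >= max(n, batch) && (1 - n_ok / n_try) > max_discard_frac) {
        abort(sprintf(
          "discard fraction %.2f exceeds %.2f after %d draws",
          1 - n_ok / n_try, max_discard_frac, n_try),
          class = "ganpop_sweep_failure")
      }
    }
    params <- dplyr::bind_rows(kept_p)[seq_len(n), ]
    features <- dplyr::bind_rows(kept_f)[seq_len(n), ]
    structure(
      list(params = params, features = features,
           discarded = n_try - n_ok, n_attempted = n_try,
           normalization = list(
             feature_mean = vapply(features, mean, numeric(1)),
             feature_sd = vapply(features, sd, numeric(1)),
             param_low = setNames(bounds$low, bounds$parameter),
             param_high = setNames(bounds$high, bounds$parameter)
           ),
           bounds = bounds, seed = seed),
      class = "ganpop_training")
  })
}

#' @export
print.ganpop_training <- function(x, ...) {
  cat(sprintf(
    "<ganpop_training> %d rows (%d discarded of %d attempted), %d parameters, %d features\n",
    nrow(x$params), x$discarded, x$n_attempted, ncol(x$params),
    ncol(x$features)))
  invisible(x)
}

#' Enumerate two-group parameter-structure scenarios
#'
#' All ways exactly \code{k} of the varied conductances can differ between
#' two groups: every size-\code{k} subset crossed with every low/high
#' assignment pattern, counted modulo swapping the group labels. The
#' canonical form fixes the first altered parameter to "low in Group 1", so
#' the number of cases is \eqn{\binom{5}{k} 2^{k-1}}. Ordering is
#' deterministic: lexicographic subsets, then the binary high/low code of
#' the remaining altered parameters.
#'
#' @param k Number of altered parameters (1..5).
#' @param parameters The varied parameter names.
#' @return A tibble with one row per scenario: \code{scenario} (id),
#'   \code{k}, \code{altered} (list of names), \code{low_in_g1} (list of
#'   logicals aligned with \code{altered}).
#' @export
enumerate_scenarios <- function(k, parameters = varied_conductances()) {
  d <- length(parameters)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > d) {
    abort(sprintf("`k` must be an integer in 1..%d", d),
          class = "ganpop_bad_input")
  }
  k <- as.integer(k)
  subsets <- utils::combn(parameters, k, simplify = FALSE)
  rows <- purrr::map(subsets, function(sub) {
    n_free <- k - 1L
    codes <- if (n_free == 0) list(logical(0)) else {
      purrr::map(seq_len(2^n_free) - 1L, function(b) {
        as.logical(bitwAnd(bitwShiftR(b, seq_len(n_free) - 1L), 1L))
      })
    }
    purrr::map(codes, function(hi) {
      tibble::tibble(
        k = k,
        altered = list(sub),
        low_in_g1 = list(c(TRUE, !hi)) # first altered param low in G1
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  rows$scenario <- purrr::map2_chr(rows$altered, rows$low_in_g1, function(a, l) {
    paste0("k", k, ":", paste0(ifelse(l, "-", "+"), a, collapse = ","))
  })
  rows[, c("scenario", "k", "altered", "low_in_g1")]
}

#' Synthetic two-group target data for a scenario
#'
#' Draws \code{n_per_group} parameter sets per group. Unaltered parameters
#' follow \eqn{N(\mu_p, (\mu_p/8)^2)} identically in both groups; altered
#' parameters follow \eqn{N(0.5\mu_p, (\mu_p/8)^2)} in the low group and
#' \eqn{N(1.5\mu_p, (\mu_p/8)^2)} in the high group, per the scenario's sign
#' pattern. All draws are clamped to the sweep bounds. If
#' \code{simulate = TRUE}, each draw is pushed through the model and the 13
#' features extracted; rows whose simulation fails are dropped and counted.
#'
#' @param scenario One row of [enumerate_scenarios()] (or a list with
#'   elements \code{altered} and \code{low_in_g1}).
#' @param bounds [ca1_bounds()].
#' @param n_per_group Draws per group.
#' @param seed Integer seed.
#' @param base_params,protocols Forwarded to the simulator.
#' @param simulate Simulate features (default TRUE).
#' @return A list with elements \code{g1} and \code{g2}, each containing
#'   \code{params} (tibble) and, if simulated, \code{features} plus a
#'   \code{dropped} count; and the scenario row itself.
#' @export
make_two_group_targets <- function(scenario, bounds = ca1_bounds(),
                                   n_per_group = 100, seed = 1L,
                                   base_params = ca1_params(),
                                   protocols = list(
                                     ap = protocol_depolarizing(),
                                     hp = protocol_hyperpolarizing()
                                   ),
                                   simulate = TRUE) {
  altered <- scenario$altered[[1]]
  low_in_g1 <- scenario$low_in_g1[[1]]
  stopifnot(length(altered) == length(low_in_g1))
  with_seed(seed, {
    draw_group <- function(is_g1) {
      cols <- purrr::map(seq_len(nrow(bounds)), function(j) {
        pnm <- bounds$parameter[j]
        mu <- bounds$mu[j]
        shift <- 1
        if (pnm %in% altered) {
          lo <- low_in_g1[match(pnm, altered)]
          shift <- if (lo == is_g1) 0.5 else 1.5
        }
        sample_truncated_normal(n_per_group, shift * mu, mu / 8,
                                low = bounds$low[j], high = bounds$high[j])
      })
      tibble::as_tibble(setNames(cols, bounds$parameter))
    }
    g1p <- draw_group(TRUE)
    g2p <- draw_group(FALSE)
    out <- list(scenario = scenario,
                g1 = list(params = g1p), g2 = list(params = g2p))
    if (simulate) {
      for (g in c("g1", "g2")) {
        fv <- simulate_feature_rows(out[[g]]$params, base_params, protocols)
        keep <- fv$ok
        out[[g]]$features <- fv[keep, feature_names()]
        out[[g]]$params <- out[[g]]$params[keep, ]
        out[[g]]$dropped <- sum(!keep)
      }
    }
    out
  })
}

#' Default conductance shifts for the 4-category experimental mimic
#'
#' Multipliers on the default conductances for the four cell categories
#' (12-month wildtype, 12-month tau-mutant rTg4510, 24-month wildtype,
#' 24-month amyloid-mutant PDAPP). Directions emulate the reported
#' phenotypes: delayed-rectifier K up and M-type K down in the tau mutant;
#' H-current and M-type K up and delayed rectifier down with age; transient
#' Na down (on top of the age effect) in the amyloid mutant. The magnitudes
#' are package choices for a synthetic stand-in, not measured values.
#'
#' @return Named list (one element per category) of named multiplier
#'   vectors.
#' @export
mimic_default_shifts <- function() {
  list(
    WT12 = c(g_NaT = 1, g_CaH = 1, g_KDR = 1, g_KM = 1, g_H = 1),
    rTg4510 = c(g_NaT = 1, g_CaH = 1, g_KDR = 1.3, g_KM = 0.7, g_H = 1),
    WT24 = c(g_NaT = 1, g_CaH = 1, g_KDR = 0.8, g_KM = 1.2, g_H = 1.4),
    PDAPP = c(g_NaT = 0.8, g_CaH = 1, g_KDR = 1.0, g_KM = 0.9, g_H = 1.4)
  )
}

#' Synthetic 4-category experimental mimic
#'
#' Stands in for the (unavailable) patch-clamp recordings: per category,
#' parameter sets are drawn from truncated normals centred at shifted
#' defaults (\code{shifts} times \eqn{\mu_p}, sd \eqn{\mu_p/8}), simulated,
#' and the 13 features extracted. Default cell counts are 19, 26, 26 and 30
#' for WT12, rTg4510, WT24 and PDAPP.
#'
#' @param shifts Named list of per-category multiplier vectors
#'   ([mimic_default_shifts()]).
#' @param n_cells Named integer vector of cells per category.
#' @param bounds,base_params,protocols,seed As in
#'   [make_two_group_targets()].
#' @return A tibble with columns \code{category}, \code{cell}, the 13
#'   features; the underlying parameter draws are attached as attribute
#'   \code{"params"}.
#' @export
make_category_mimic <- function(shifts = mimic_default_shifts(),
                                n_cells = c(WT12 = 19, rTg4510 = 26,
                                            WT24 = 26, PDAPP = 30),
                                bounds = ca1_bounds(),
                                base_params = ca1_params(),
                                protocols = list(
                                  ap = protocol_depolarizing(),
                                  hp = protocol_hyperpolarizing()
                                ),
                                seed = 1L) {
  stopifnot(all(names(n_cells) %in% names(shifts)))
  with_seed(seed, {
    out <- purrr::map(names(n_cells), function(cat) {
      mult <- shifts[[cat]]
      n <- n_cells[[cat]]
      cols <- purrr::map(seq_len(nrow(bounds)), function(j) {
        pnm <- bounds$parameter[j]
        mu <- bounds$mu[j] * (if (pnm %in% names(mult)) mult[[pnm]] else 1)
        sample_truncated_normal(n, mu, bounds$mu[j] / 8,
                                low = bounds$low[j], high = bounds$high[j])
      })
      par_tbl <- tibble::as_tibble(setNames(cols, bounds$parameter))
      fv <- simulate_feature_rows(par_tbl, base_params, protocols)
      keep <- fv$ok
      dplyr::bind_cols(
        tibble::tibble(category = cat, cell = which(keep)),
        fv[keep, feature_names()]
      ) |>
        structure(params = par_tbl[keep, ])
    })
    params <- dplyr::bind_rows(purrr::map(out, attr, "params"))
    res <- dplyr::bind_rows(out)
    attr(res, "params") <- params
    res
  })
}

#' Rosenbrock toy problem
#'
#' \eqn{Y = (1 - X_1)^2 + 100 (X_2 - X_1^2)^2}: a two-parameter, one-feature
#' toy mechanistic model used to illustrate and smoke-test conditional-GAN
#' training (its global minimum is at (1, 1)).
#'
#' @param x1,x2 Coordinates.
#' @return Function value.
#' @export
rosenbrock <- function(x1, x2) {
  (1 - x1)^2 + 100 * (x2 - x1^2)^2
}

#' @rdname rosenbrock
#' @param n Number of rows.
#' @param range Uniform sampling range for both inputs.
#' @param seed Integer seed.
#' @return For [rosenbrock_dataset()], a \code{ganpop_training}-classed
#'   dataset with params \code{(x1, x2)} and the single feature \code{y}.
#' @export
rosenbrock_dataset <- function(n, range = c(-5, 5), seed = 1L) {
  stopifnot(n >= 1)
  with_seed(seed, {
    x1 <- runif(n, range[1], range[2])
    x2 <- runif(n, range[1], range[2])
    params <- tibble::tibble(x1 = x1, x2 = x2)
    features <- tibble::tibble(y = rosenbrock(x1, x2))
    structure(
      list(params = params, features = features, discarded = 0L,
           n_attempted = n,
           normalization = list(
             feature_mean = c(y = mean(features$y)),
             feature_sd = c(y = sd(features$y)),
             param_low = c(x1 = range[1], x2 = range[1]),
             param_high = c(x1 = range[2], x2 = range[2])
           ),
           bounds = tibble::tibble(parameter = c("x1", "x2"),
                                   mu = mean(range), low = range[1],
                                   high = range[2]),
           seed = seed),
      class = "ganpop_training")
  })
}
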