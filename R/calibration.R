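# Model calibration: differential-evolution fitting of parameters to
# average voltage traces, and Sobol variance-based screening of which
# parameters drive the features.

#' Differential-evolution configuration
#'
#' Standard DE/rand/1/bin settings: population size (default 15 per
#' dimension), mutation factor F, crossover rate CR, generation budget.
#'
#' @param bounds Two-column matrix or data frame (\code{low}, \code{high})
#'   with one row per free parameter; row names or a \code{parameter}
#'   column name the parameters.
#' @param pop_size Population size (default \code{15 * d}).
#' @param F Mutation factor (> 0).
#' @param CR Crossover rate in (0, 1].
#' @param max_gen Number of generations.
#' @param seed Integer seed.
#' @return A list of class \code{de_config}.
#' @export
de_config <- function(bounds, pop_size = NULL, F = 0.8, CR = 0.9,
                      max_gen = 100, seed = 1L) {
  if (is.data.frame(bounds)) {
    nm <- if ("parameter" %in% names(bounds)) bounds$parameter else
      rownames(bounds)
    bounds <- cbind(low = bounds$low, high = bounds$high)
    rownames(bounds) <- nm
  }
  stopifnot(is.matrix(bounds), ncol(bounds) == 2,
            all(is.finite(bounds)), all(bounds[, 1] < bounds[, 2]),
            F > 0, CR > 0, CR <= 1)
  d <- nrow(bounds)
  if (is.null(pop_size)) pop_size <- 15L * d
  structure(list(bounds = bounds, pop_size = as.integer(pop_size), F = F,
                 CR = CR, max_gen = as.integer(max_gen), seed = seed),
            class = "de_config")
}

#' Differential-evolution global optimization (DE/rand/1/bin)
#'
#' Minimizes \code{objective} over the box in \code{config$bounds} with the
#' classic Storn-Price scheme: for each population member, a mutant
#' \code{a + F (b - c)} from three distinct random members, binomial
#' crossover at rate CR (one coordinate always inherited from the mutant),
#' reflection at the bounds, greedy selection. Used to fit the model's
#' maximal conductances (optionally plus the transient-sodium
#' half-activation voltage \code{V_mNaT}) to average voltage traces.
#'
#' @param objective Function of a named numeric vector returning a scalar.
#' @param config [de_config()].
#' @return A list of class \code{ganpop_de}: \code{par} (best member),
#'   \code{value}, and \code{trace}, a tibble of the per-generation best
#'   objective.
#' @examples
#' cfg <- de_config(cbind(low = c(-5, -5), high = c(5, 5)),
#'                  pop_size = 30, max_gen = 60, seed = 2)
#' fit <- de_fit(function(x) sum((x - 1)^2), cfg)
#' @export
de_fit <- function(objective, config) {
  stopifnot(inherits(config, "de_config"))
  b <- config$bounds
  d <- nrow(b); np <- config$pop_size
  lo <- b[, 1]; hi <- b[, 2]
  nms <- rownames(b)
  reflect <- function(x) {
    # reflect out-of-bounds coordinates back into the box
    for (r in 1:2) {
      over <- x > hi; x[over] <- 2 * hi[over] - x[over]
      under <- x < lo; x[under] <- 2 * lo[under] - x[under]
    }
    pmin(pmax(x, lo), hi)
  }
  eval_obj <- function(x) objective(setNames(x, nms))
  with_seed(config$seed, {
    pop <- matrix(runif(np * d, rep(lo, each = np), rep(hi, each = np)),
                  nrow = np)
    fit <- apply(pop, 1, eval_obj)
    best_log <- numeric(config$max_gen)
    for (gen in seq_len(config$max_gen)) {
      for (i in seq_len(np)) {
        idx <- sample(setdiff(seq_len(np), i), 3)
        mutant <- pop[idx[1], ] + config$F * (pop[idx[2], ] - pop[idx[3], ])
        mutant <- reflect(mutant)
        cross <- runif(d) < config$CR
        cross[sample.int(d, 1)] <- TRUE
        trial <- ifelse(cross, mutant, pop[i, ])
        f_trial <- eval_obj(trial)
        if (f_trial <= fit[i]) {
          pop[i, ] <- trial
          fit[i] <- f_trial
        }
      }
      best_log[gen] <- min(fit)
    }
    ibest <- which.min(fit)
    structure(
      list(par = setNames(pop[ibest, ], nms), value = fit[ibest],
           trace = tibble::tibble(generation = seq_len(config$max_gen),
                                  best = best_log),
           config = config),
      class = "ganpop_de")
  })
}

#' @export
print.ganpop_de <- function(x, ...) {
  cat(sprintf("<ganpop_de> best objective %.6g after %d generations\n",
              x$value, nrow(x$trace)))
  cat("  par:", paste(names(x$par), signif(x$par, 5), sep = "=",
                      collapse = "  "), "\n")
  invisible(x)
}

#' @export
tidy.ganpop_de <- function(x, ...) x$trace

#' @export
glance.ganpop_de <- function(x, ...) {
  tibble::tibble(best = x$value, generations = nrow(x$trace),
                 pop_size = x$config$pop_size)
}

#' Sum-of-squares trace objective
#'
#' For a candidate parameter vector, simulates both protocols and sums the
#' squared voltage differences to every target trace (one AP and one
#' hyperpolarization average trace per category), all on the targets' time
#' grids. Simulations that fail or produce no action potential return a
#' large penalty so DE moves away from them.
#'
#' @param targets A list of categories; each element is a list with numeric
#'   vectors \code{ap} and \code{hp} giving the average voltage traces on
#'   the protocols' \code{dt_out} grids.
#' @param base_params Base [ca1_params()]; the candidate overrides its
#'   conductances (names \code{g_*}) and optionally \code{V_mNaT}.
#' @param protocols Named list with protocols \code{ap} and \code{hp} used
#'   to generate the targets.
#' @param penalty Objective value for failed simulations.
#' @return A function of a named candidate vector, suitable for [de_fit()].
#' @export
objective_trace_sse <- function(targets, base_params = ca1_params(),
                                protocols = list(
                                  ap = protocol_depolarizing(),
                                  hp = protocol_hyperpolarizing()
                                ),
                                penalty = 1e9) {
  force(targets); force(base_params); force(protocols); force(penalty)
  function(candidate) {
    pr <- tryCatch(set_conductances(base_params, candidate),
                   error = function(e) NULL)
    if (is.null(pr)) return(penalty)
    tryCatch({
      ap <- simulate_ca1(pr, protocols$ap)
      detect_first_ap(ap) # no-AP candidates are penalized
      hp <- simulate_ca1(pr, protocols$hp)
      sse <- 0
      for (tg in targets) {
        sse <- sse + sum((ap$V - tg$ap)^2) + sum((hp$V - tg$hp)^2)
      }
      sse
    }, error = function(e) penalty)
  }
}

#' Sobol variance-based sensitivity screening
#'
#' Saltelli-sampled first-order (S1) and total-effect (ST) indices for a
#' vectorized multi-output function: two independent \code{n_base x d}
#' uniform matrices A and B plus the d cross matrices AB_i give the
#' classic estimators (Sobol/Janon for S1, Jansen for ST) at a cost of
#' \code{n_base * (d + 2)} evaluations. Outputs with zero variance are
#' excluded from the across-output averages. Parameters whose mean ST
#' exceeds \code{st_cutoff} are flagged highly influential.
#'
#' @param fn Function taking an \code{n x d} parameter matrix (columns named
#'   by \code{bounds$parameter}) and returning an \code{n x m} matrix or
#'   data frame of outputs (NA rows allowed; they are dropped pairwise).
#' @param bounds Tibble with columns \code{parameter, low, high}.
#' @param n_base Base sample size (a power of 2).
#' @param seed Integer seed.
#' @param st_cutoff Mean-ST threshold for the influential flag.
#' @return An object of class \code{ganpop_sobol}: tibble \code{indices}
#'   (parameter, output, S1, ST), tibble \code{summary} (parameter, mean_S1,
#'   mean_ST, influential), and the retained parameter names.
#' @export
sobol_screen <- function(fn, bounds, n_base = 1024, seed = 1L,
                         st_cutoff = 0.1) {
  if (abs(log2(n_base) - round(log2(n_base))) > 1e-9) {
    abort("`n_base` must be a power of 2", class = "ganpop_bad_input")
  }
  d <- nrow(bounds)
  with_seed(seed, {
    U <- matrix(runif(2 * n_base * d), ncol = 2 * d)
    scale_cols <- function(M) {
      sweep(sweep(M, 2, bounds$high - bounds$low, "*"), 2, bounds$low, "+")
    }
    A <- scale_cols(U[, 1:d, drop = FALSE])
    B <- scale_cols(U[, (d + 1):(2 * d), drop = FALSE])
    colnames(A) <- colnames(B) <- bounds$parameter
    fa <- as.matrix(fn(A)); fb <- as.matrix(fn(B))
    m <- ncol(fa)
    outs <- colnames(fa)
    if (is.null(outs)) outs <- paste0("y", seq_len(m))
    idx <- purrr::map(seq_len(d), function(i) {
      ABi <- A; ABi[, i] <- B[, i]
      fab <- as.matrix(fn(ABi))
      purrr::map(seq_len(m), function(j) {
        ok <- is.finite(fa[, j]) & is.finite(fb[, j]) & is.finite(fab[, j])
        ya <- fa[ok, j]; yb <- fb[ok, j]; yab <- fab[ok, j]
        vy <- var(c(ya, yb))
        if (!is.finite(vy) || vy == 0) {
          return(tibble::tibble(parameter = bounds$parameter[i],
                                output = outs[j], S1 = NA_real_,
                                ST = NA_real_))
        }
        # centering the B outputs leaves the S1 expectation unchanged
        # (E[f(AB_i) - f(A)] = 0) but removes the dominant variance term
        ybc <- yb - mean(c(ya, yb))
        s1 <- mean(ybc * (yab - ya)) / vy
        st <- 0.5 * mean((ya - yab)^2) / vy
        tibble::tibble(parameter = bounds$parameter[i], output = outs[j],
                       S1 = s1, ST = st)
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
    summary <- idx |>
      dplyr::group_by(.data$parameter) |>
      dplyr::summarise(mean_S1 = mean(.data$S1, na.rm = TRUE),
                       mean_ST = mean(.data$ST, na.rm = TRUE),
                       n_outputs = sum(is.finite(.data$ST)),
                       .groups = "drop") |>
      dplyr::mutate(influential = .data$mean_ST > st_cutoff) |>
      dplyr::arrange(match(.data$parameter, bounds$parameter))
    structure(
      list(indices = idx, summary = summary,
           retained = summary$parameter[summary$influential],
           n_base = n_base, st_cutoff = st_cutoff),
      class = "ganpop_sobol")
  })
}

#' @export
print.ganpop_sobol <- function(x, ...) {
  cat(sprintf("<ganpop_sobol> n_base = %d, cutoff mean ST > %g\n",
              x$n_base, x$st_cutoff))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.ganpop_sobol <- function(x, ...) x$indices

#' @export
glance.ganpop_sobol <- function(x, ...) {
  tibble::tibble(n_base = x$n_base, n_retained = length(x$retained))
}

#' Feature pushforward of the CA1 model for sensitivity analysis
#'
#' Wraps simulate-and-extract as a matrix-in, matrix-out function usable by
#' [sobol_screen()]: rows whose simulation fails (e.g. no action potential)
#' become NA and are excluded pairwise by the estimators.
#'
#' @param base_params,protocols As in [make_training_dataset()].
#' @return A function mapping an \code{n x d} conductance matrix to an
#'   \code{n x 13} feature matrix.
#' @export
ca1_feature_fn <- function(base_params = ca1_params(),
                           protocols = list(
                             ap = protocol_depolarizing(),
                             hp = protocol_hyperpolarizing()
                           )) {
  function(M) {
    fv <- simulate_feature_rows(tibble::as_tibble(M), base_params, protocols)
    as.matrix(fv[, feature_names()])
  }
}
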