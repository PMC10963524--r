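# End-to-end orchestration: scenario validation suites and the 4-category
# analysis, both driven by any object implementing sample_parameters().

#' @rdname sample_parameters
#' @export
sample_parameters.function <- function(object, features, n = 100,
                                       seed = NULL, ...) {
  object(features, n = n, seed = seed, ...)
}

#' Scale profiles
#'
#' Named problem-size bundles gating every stochastic stage: \code{smoke}
#' (plumbing checks), \code{desk} (single-workstation runs) and
#' \code{full_scale} (the full-scale study constants: a 3,000,000-row
#' sweep, minibatches of 10,000, 400 epochs, 100 generator samples per
#' cell). \code{full_scale} is provided for completeness and is not
#' exercised by the test suite.
#'
#' @param profile One of \code{"smoke"}, \code{"desk"},
#'   \code{"full_scale"}.
#' @return Named list: \code{n_train, minibatch, epochs, n_per_group,
#'   n_samples_per_cell, n_scenarios} (NA = all).
#' @export
scale_profile <- function(profile = c("desk", "smoke", "full_scale")) {
  profile <- match.arg(profile)
  switch(profile,
    smoke = list(n_train = 200, minibatch = 64, epochs = 3,
                 n_per_group = 20, n_samples_per_cell = 10, n_scenarios = 2),
    desk = list(n_train = 1500, minibatch = 128, epochs = 300,
                lr_g = 1e-3, lr_d = 2e-4,
                n_per_group = 100, n_samples_per_cell = 100,
                n_scenarios = NA),
    full_scale = list(n_train = 3e6, minibatch = 10000, epochs = 400,
                       lr_g = 1e-4, lr_d = 2e-5,
                       n_per_group = 100, n_samples_per_cell = 100,
                       n_scenarios = NA)
  )
}

# features for a parameter table via the forward model, dropping failed rows
pushforward_features <- function(params, base_params, protocols) {
  fv <- simulate_feature_rows(params, base_params, protocols)
  keep <- fv$ok
  list(params = params[keep, , drop = FALSE],
       features = fv[keep, feature_names()],
       dropped = sum(!keep))
}

#' Run a two-group scenario validation suite
#'
#' For each enumerated scenario with \code{k} altered parameters: generate
#' two-group target data, present each group's target features to the
#' trained generator, push the sampled parameter sets back through the
#' forward model, and score the agreement between target-based and
#' generator-based KS decisions ([scenario_agreement()]).
#'
#' @param model Trained generator ([train_cgan()] result) or any object with
#'   a [sample_parameters()] method.
#' @param k Number of altered parameters (1..5), or a vector of k values.
#' @param scenarios Optional subset: integer indices into the enumeration
#'   for each k (e.g. \code{1:2} for smoke runs).
#' @param bounds,base_params,protocols Forwarded to the data generators.
#' @param n_per_group Target draws per group.
#' @param n_samples_per_target Generator samples per target feature row
#'   (default 1, so generator groups match target group sizes).
#' @param alpha KS significance level.
#' @param seed Integer seed; each scenario derives its own sub-seed.
#' @return An object of class \code{ganpop_suite}: per-scenario agreement
#'   reports, a summary tibble, and a run manifest (seeds, sizes, timing).
#' @export
run_scenario_suite <- function(model, k, scenarios = NULL,
                               bounds = ca1_bounds(),
                               base_params = ca1_params(),
                               protocols = list(
                                 ap = protocol_depolarizing(),
                                 hp = protocol_hyperpolarizing()
                               ),
                               n_per_group = 100, n_samples_per_target = 1,
                               alpha = 0.01, seed = 1L) {
  t_start <- Sys.time()
  scn <- dplyr::bind_rows(purrr::map(k, enumerate_scenarios,
                                     parameters = bounds$parameter))
  if (!is.null(scenarios)) scn <- scn[scenarios, ]
  reports <- purrr::map(seq_len(nrow(scn)), function(i) {
    srow <- scn[i, ]
    sub_seed <- (seed * 1000L + i) %% .Machine$integer.max
    tgt <- make_two_group_targets(srow, bounds = bounds,
                                  n_per_group = n_per_group,
                                  seed = sub_seed,
                                  base_params = base_params,
                                  protocols = protocols)
    gen <- list()
    for (g in c("g1", "g2")) {
      smp <- sample_parameters(model, tgt[[g]]$features,
                               n = n_samples_per_target,
                               seed = sub_seed + 1L)
      smp <- smp[, bounds$parameter, drop = FALSE]
      gen[[g]] <- pushforward_features(smp, base_params, protocols)
    }
    scenario_agreement(srow, tgt, gen, alpha = alpha)
  })
  summary <- purrr::map2(reports, scn$scenario, function(r, id) {
    dplyr::mutate(glance(r), scenario = id, .before = 1)
  }) |> dplyr::bind_rows()
  structure(
    list(reports = reports, summary = summary, scenarios = scn,
         manifest = list(
           seed = seed, k = k, n_per_group = n_per_group,
           n_samples_per_target = n_samples_per_target, alpha = alpha,
           n_scenarios = nrow(scn),
           started = t_start, elapsed_s = as.numeric(
             difftime(Sys.time(), t_start, units = "secs"))
         )),
    class = "ganpop_suite")
}

#' @export
print.ganpop_suite <- function(x, ...) {
  tot <- sum(x$summary$n_tests)
  agr <- sum(x$summary$n_agree)
  cat(sprintf(
    "<ganpop_suite> %d scenarios, %d/%d G1-vs-G2 decisions agree\n",
    nrow(x$summary), agr, tot))
  invisible(x)
}

#' @export
tidy.ganpop_suite <- function(x, ...) x$summary

#' @export
glance.ganpop_suite <- function(x, ...) {
  tibble::tibble(n_scenarios = nrow(x$summary),
                 n_tests = sum(x$summary$n_tests),
                 n_agree = sum(x$summary$n_agree),
                 reject_vs_target_g1 = sum(x$summary$reject_vs_target_g1),
                 reject_vs_target_g2 = sum(x$summary$reject_vs_target_g2))
}

#' Four-category conductance analysis
#'
#' Per-cell amortized inference followed by the disease/age-effect
#' comparisons: each cell's features are range-checked against the training
#' support ([replace_out_of_range()]), the generator produces
#' \code{n_samples} parameter sets per cell, samples are pooled per
#' category, and the four pairwise comparisons (mutant vs age-matched
#' wildtype at both ages; older vs younger wildtype and mutant) are scored
#' by Cohen's d with categorical labels.
#'
#' @param model Trained generator (or any [sample_parameters()] object).
#' @param cells Feature table with a \code{category} column and the 13
#'   feature columns ([make_category_mimic()] or measured data).
#' @param ranges Training feature ranges ([feature_ranges()]).
#' @param comparisons Two-column matrix/list of category pairs; defaults to
#'   rTg4510-WT12, PDAPP-WT24, WT24-WT12, PDAPP-rTg4510.
#' @param n_samples Generator samples per cell (default 100).
#' @param thresholds Effect-size thresholds ([effect_size_thresholds()]).
#' @param seed Integer seed.
#' @return An object of class \code{ganpop_category_report}: tibble
#'   \code{effects} (comparison x parameter Cohen's d with labels and sign),
#'   pooled per-category samples, replacement counts and a manifest.
#' @export
run_category_analysis <- function(model, cells, ranges,
                                  comparisons = list(
                                    c("rTg4510", "WT12"),
                                    c("PDAPP", "WT24"),
                                    c("WT24", "WT12"),
                                    c("PDAPP", "rTg4510")
                                  ),
                                  n_samples = 100,
                                  thresholds = effect_size_thresholds(),
                                  seed = 1L) {
  stopifnot("category" %in% names(cells))
  cats <- unique(cells$category)
  for (cmp in comparisons) {
    missing <- setdiff(cmp, cats)
    if (length(missing)) {
      abort(paste("category missing from `cells`:",
                  paste(missing, collapse = ", ")),
            class = "ganpop_bad_input")
    }
  }
  feats <- cells[, intersect(feature_names(), names(cells)), drop = FALSE]
  repl <- replace_out_of_range(feats, ranges)
  n_replaced <- sum(attr(repl, "replaced"))

  samples <- sample_parameters(model, repl, n = n_samples, seed = seed)
  samples$category <- cells$category[samples$.condition]

  effects <- purrr::map(comparisons, function(cmp) {
    a <- samples[samples$category == cmp[1], , drop = FALSE]
    b <- samples[samples$category == cmp[2], , drop = FALSE]
    p_cols <- setdiff(names(samples), c(".condition", "category"))
    purrr::map(p_cols, function(pc) {
      d <- cohens_d(a[[pc]], b[[pc]])
      tibble::tibble(comparison = paste(cmp[1], "vs", cmp[2]),
                     parameter = pc, cohens_d = d,
                     label = classify_effect_size(d, thresholds),
                     direction = sign(mean(a[[pc]]) - mean(b[[pc]])))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  structure(
    list(effects = effects, samples = samples,
         n_replaced = n_replaced,
         manifest = list(seed = seed, n_samples = n_samples,
                         n_cells = nrow(cells),
                         comparisons = comparisons)),
    class = "ganpop_category_report")
}

#' @export
print.ganpop_category_report <- function(x, ...) {
  cat(sprintf(
    "<ganpop_category_report> %d cells, %d samples/cell, %d feature values replaced\n",
    x$manifest$n_cells, x$manifest$n_samples, x$n_replaced))
  print(x$effects)
  invisible(x)
}

#' @export
tidy.ganpop_category_report <- function(x, ...) x$effects

#' @export
glance.ganpop_category_report <- function(x, ...) {
  tibble::tibble(n_cells = x$manifest$n_cells,
                 n_comparisons = length(x$manifest$comparisons),
                 n_replaced = x$n_replaced,
                 max_d = max(x$effects$cohens_d))
}
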