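# Statistical comparison machinery: two-sample KS testing, Cohen's d with
# categorical classification, and two-group scenario agreement scoring.

#' Two-sample Kolmogorov-Smirnov test
#'
#' Thin wrapper around [stats::ks.test()] returning a tidy row with the
#' rejection decision at level \code{alpha} (reject iff p < alpha).
#'
#' @param a,b Numeric samples.
#' @param alpha Significance level (default 0.01).
#' @return One-row tibble: \code{statistic, p_value, reject}.
#' @export
ks_two_sample <- function(a, b, alpha = 0.01) {
  if (!length(a) || !length(b)) {
    abort("empty sample", class = "ganpop_bad_input")
  }
  if (length(a) < 5 || length(b) < 5) {
    warn("fewer than 5 observations in a sample; the KS p-value is unreliable",
         class = "ganpop_small_sample")
  }
  kt <- suppressWarnings(ks.test(a, b))
  tibble::tibble(statistic = unname(kt$statistic),
                 p_value = kt$p.value,
                 reject = kt$p.value < alpha)
}

#' Cohen's d effect size
#'
#' Absolute difference of means divided by the pooled standard deviation
#' \eqn{s_p = \sqrt{((n_a-1)s_a^2 + (n_b-1)s_b^2)/(n_a+n_b-2)}}.
#'
#' @param a,b Numeric samples (each of length at least 2).
#' @return Non-negative scalar.
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  stopifnot(na >= 2, nb >= 2)
  sp <- sqrt(((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2))
  if (sp == 0) abort("zero pooled standard deviation", class = "ganpop_bad_input")
  abs(mean(a) - mean(b)) / sp
}

#' Effect-size classification thresholds
#'
#' Ascending lower bounds for the categories small, medium, large, very
#' large and huge; everything below the first bound is "very small".
#' \code{"sawilowsky"} is the conventional scale (0.2, 0.5, 0.8, 1.2, 2.0);
#' \code{"study_compat"} shifts the medium/large/very-large bounds to 0.42,
#' 0.75 and 0.97 (huge at 2.0).
#'
#' @param profile \code{"sawilowsky"} (default) or \code{"study_compat"}.
#' @return Named numeric vector of ascending thresholds.
#' @export
effect_size_thresholds <- function(profile = c("sawilowsky", "study_compat")) {
  profile <- match.arg(profile)
  switch(profile,
    sawilowsky = c(small = 0.2, medium = 0.5, large = 0.8,
                   `very large` = 1.2, huge = 2.0),
    study_compat = c(small = 0.2, medium = 0.42, large = 0.75,
                     `very large` = 0.97, huge = 2.0)
  )
}

#' Classify an effect size
#'
#' Maps a non-negative Cohen's d to a label; a value exactly on a boundary
#' takes the higher category.
#'
#' @param d Effect size(s), non-negative.
#' @param thresholds Ascending named thresholds
#'   ([effect_size_thresholds()]).
#' @return Character label(s) in \{very small, small, medium, large, very
#'   large, huge\}.
#' @export
classify_effect_size <- function(d, thresholds = effect_size_thresholds()) {
  if (is.unsorted(thresholds, strictly = TRUE)) {
    abort("thresholds must be strictly ascending", class = "ganpop_bad_input")
  }
  stopifnot(all(d >= 0))
  labels <- c("very small", names(thresholds))
  labels[findInterval(d, thresholds) + 1L]
}

# run per-column KS tests between two sample tables over shared columns
ks_by_column <- function(a, b, cols, alpha = 0.01) {
  purrr::map(cols, function(cn) {
    dplyr::mutate(ks_two_sample(a[[cn]], b[[cn]], alpha), quantity = cn,
                  .before = 1)
  }) |> dplyr::bind_rows()
}

#' Scenario agreement between target data and generator samples
#'
#' For one two-group scenario, runs the 18 group-1-versus-group-2 KS tests
#' (5 parameters + 13 features) on the target data and on the generator
#' samples and counts how often the reject/fail decisions agree; it also
#' runs generator-versus-target KS tests per group and quantity and counts
#' the rejections (a calibrated generator should rarely reject).
#'
#' @param scenario Scenario row (from [enumerate_scenarios()]); carried into
#'   the report.
#' @param target List with \code{g1}/\code{g2}, each containing tibbles
#'   \code{params} and \code{features} (as from [make_two_group_targets()]).
#' @param cgan Same structure holding the generator-derived samples.
#' @param alpha Significance level.
#' @return An object of class \code{ganpop_agreement}: tibbles \code{g1_g2}
#'   (per-quantity target/generator decisions and agreement) and
#'   \code{vs_target} (per group and quantity), plus count summaries.
#' @export
scenario_agreement <- function(scenario, target, cgan, alpha = 0.01) {
  p_cols <- intersect(names(target$g1$params), names(cgan$g1$params))
  f_cols <- intersect(names(target$g1$features), names(cgan$g1$features))
  cols <- list(parameter = p_cols, feature = f_cols)
  for (side in c("g1", "g2")) {
    for (what in c("params", "features")) {
      if (is.null(target[[side]][[what]]) || is.null(cgan[[side]][[what]])) {
        abort(sprintf("missing %s for %s", what, side),
              class = "ganpop_bad_input")
      }
    }
  }

  one_block <- function(a1, a2, kind) {
    ks_by_column(a1, a2, cols[[kind]], alpha) |>
      dplyr::mutate(kind = kind, .before = 1)
  }
  tgt <- dplyr::bind_rows(
    one_block(target$g1$params, target$g2$params, "parameter"),
    one_block(target$g1$features, target$g2$features, "feature")
  )
  gen <- dplyr::bind_rows(
    one_block(cgan$g1$params, cgan$g2$params, "parameter"),
    one_block(cgan$g1$features, cgan$g2$features, "feature")
  )
  g1_g2 <- dplyr::bind_cols(
    tgt[, c("kind", "quantity")],
    tibble::tibble(target_reject = tgt$reject, cgan_reject = gen$reject,
                   agree = tgt$reject == gen$reject)
  )

  vs_target <- purrr::map(c("g1", "g2"), function(side) {
    dplyr::bind_rows(
      ks_by_column(cgan[[side]]$params, target[[side]]$params,
                   cols$parameter, alpha) |>
        dplyr::mutate(kind = "parameter", .before = 1),
      ks_by_column(cgan[[side]]$features, target[[side]]$features,
                   cols$feature, alpha) |>
        dplyr::mutate(kind = "feature", .before = 1)
    ) |> dplyr::mutate(group = side, .before = 1)
  }) |> dplyr::bind_rows()

  structure(
    list(scenario = scenario, g1_g2 = g1_g2, vs_target = vs_target,
         n_tests = nrow(g1_g2), n_agree = sum(g1_g2$agree),
         n_reject_vs_target = c(
           g1 = sum(vs_target$reject[vs_target$group == "g1"]),
           g2 = sum(vs_target$reject[vs_target$group == "g2"])
         ),
         alpha = alpha),
    class = "ganpop_agreement")
}

#' @export
print.ganpop_agreement <- function(x, ...) {
  cat(sprintf(
    "<ganpop_agreement> %d/%d G1-vs-G2 decisions agree; generator-vs-target rejections: g1 %d, g2 %d (alpha = %g)\n",
    x$n_agree, x$n_tests, x$n_reject_vs_target[["g1"]],
    x$n_reject_vs_target[["g2"]], x$alpha))
  invisible(x)
}

#' @export
tidy.ganpop_agreement <- function(x, ...) x$g1_g2

#' @export
glance.ganpop_agreement <- function(x, ...) {
  tibble::tibble(n_tests = x$n_tests, n_agree = x$n_agree,
                 reject_vs_target_g1 = x$n_reject_vs_target[["g1"]],
                 reject_vs_target_g2 = x$n_reject_vs_target[["g2"]])
}
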