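# Dataset generators: bounds, truncated normals, scenario enumeration,
# two-group targets, the category mimic and the Rosenbrock toy.

test_that("sweep bounds are zero to twice the default", {
  b <- ca1_bounds()
  expect_identical(b$parameter, varied_conductances())
  expect_true(all(b$low == 0))
  expect_equal(b$high, 2 * b$mu)
  expect_equal(b$mu, unname(ca1_params()$g[b$parameter]))
})

test_that("truncated-normal sampling clamps and keeps stated moments", {
  # mean at the lower bound: about half the draws clamp to it exactly
  x0 <- sample_truncated_normal(4000, mu = 0, sd = 1, low = 0, seed = 1)
  expect_gt(mean(x0 == 0), 0.45)
  expect_lt(mean(x0 == 0), 0.55)

  # far from the bounds clamping is essentially never active
  xin <- sample_truncated_normal(1e5, mu = 10, sd = 1.25, low = 0,
                                 high = 20, seed = 2)
  expect_lt(mean(xin %in% c(0, 20)), 1e-3)
  expect_equal(mean(xin), 10, tolerance = 0.02 / 10)
  expect_equal(sd(xin), 1.25, tolerance = 0.02 / 1.25)

  expect_error(sample_truncated_normal(10, 1, sd = 0))
})

test_that("scenario enumeration matches the combinatorial counts and a brute force", {
  counts <- vapply(1:5, function(k) nrow(enumerate_scenarios(k)), integer(1))
  expect_identical(counts, as.integer(choose(5, 1:5) * 2^(0:4)))
  expect_identical(counts, c(5L, 20L, 40L, 40L, 16L))

  # brute force: all (subset, sign) pairs deduplicated under group swap
  pars <- varied_conductances()
  for (k in 1:5) {
    keys <- character(0)
    for (sub in utils::combn(pars, k, simplify = FALSE)) {
      for (code in 0:(2^k - 1)) {
        lo <- as.logical(bitwAnd(bitwShiftR(code, seq_len(k) - 1L), 1L))
        canon <- min(paste(ifelse(lo, "-", "+"), sub, collapse = ","),
                     paste(ifelse(!lo, "-", "+"), sub, collapse = ","))
        keys <- c(keys, canon)
      }
    }
    expect_identical(nrow(enumerate_scenarios(k)),
                     length(unique(keys)))
  }

  # canonical form: first altered parameter is always low in group 1
  scn <- enumerate_scenarios(3)
  expect_true(all(vapply(scn$low_in_g1, function(l) l[1], logical(1))))
  expect_identical(anyDuplicated(scn$scenario), 0L)
  expect_error(enumerate_scenarios(0), class = "ganpop_bad_input")
  expect_error(enumerate_scenarios(6), class = "ganpop_bad_input")
})

test_that("the k=4 enumeration contains 5 all-same-direction cases", {
  scn <- enumerate_scenarios(4)
  all_same <- vapply(scn$low_in_g1, function(l) all(l) || all(!l), logical(1))
  expect_identical(sum(all_same), 5L)
  expect_identical(sum(!all_same), 35L)
})

test_that("two-group target draws follow the scenario structure", {
  scn <- enumerate_scenarios(1)
  s_nat <- scn[vapply(scn$altered, identical, logical(1), "g_NaT"), ]
  tg <- make_two_group_targets(s_nat, n_per_group = 100, seed = 8,
                               simulate = FALSE)
  b <- ca1_bounds()
  mu <- setNames(b$mu, b$parameter)
  # altered parameter separates the groups ...
  expect_true(ks_two_sample(tg$g1$params$g_NaT, tg$g2$params$g_NaT)$reject)
  expect_equal(mean(tg$g1$params$g_NaT), 0.5 * mu[["g_NaT"]],
               tolerance = 3 * (mu[["g_NaT"]] / 8) / 10 / (0.5 * mu[["g_NaT"]]))
  expect_equal(mean(tg$g2$params$g_NaT), 1.5 * mu[["g_NaT"]],
               tolerance = 3 * (mu[["g_NaT"]] / 8) / 10 / (1.5 * mu[["g_NaT"]]))
  # ... the others do not
  for (pn in setdiff(b$parameter, "g_NaT")) {
    expect_false(ks_two_sample(tg$g1$params[[pn]], tg$g2$params[[pn]])$reject)
  }
  # draws stay inside the sweep box
  all_draws <- dplyr::bind_rows(tg$g1$params, tg$g2$params)
  for (j in seq_len(nrow(b))) {
    expect_true(all(all_draws[[b$parameter[j]]] >= b$low[j] &
                      all_draws[[b$parameter[j]]] <= b$high[j]))
  }
})

test_that("identical group distributions rarely reject (type-I control)", {
  null_scn <- tibble::tibble(scenario = "null", k = 0L,
                             altered = list(character(0)),
                             low_in_g1 = list(logical(0)))
  rejections <- 0L; total <- 0L
  for (seed in 1:20) {
    tg <- make_two_group_targets(null_scn, n_per_group = 100, seed = seed,
                                 simulate = FALSE)
    for (pn in varied_conductances()) {
      rejections <- rejections +
        ks_two_sample(tg$g1$params[[pn]], tg$g2$params[[pn]])$reject
      total <- total + 1L
    }
  }
  expect_lte(rejections / total, 0.05) # alpha = 0.01 nominal
})

test_that("uniform sweep marginals pass a KS check against their target", {
  ds <- rosenbrock_dataset(10000, seed = 31)
  expect_gt(ks.test(ds$params$x1, "punif", -5, 5)$p.value, 0.01)
  expect_gt(ks.test(ds$params$x2, "punif", -5, 5)$p.value, 0.01)
})

test_that("the training sweep returns exactly n in-bounds rows with metadata", {
  ds <- make_training_dataset(40, seed = 12, batch = 20)
  expect_identical(nrow(ds$params), 40L)
  expect_identical(nrow(ds$features), 40L)
  expect_identical(names(ds$features), feature_names())
  b <- ds$bounds
  for (j in seq_len(nrow(b))) {
    expect_true(all(ds$params[[b$parameter[j]]] >= b$low[j] &
                      ds$params[[b$parameter[j]]] <= b$high[j]))
  }
  expect_true(all(is.finite(as.matrix(ds$features))))
  expect_gte(ds$discarded, 0L)
  # the last batch may overshoot n; accepted draws cover the requested rows
  expect_gte(ds$n_attempted - ds$discarded, 40)
  expect_named(ds$normalization,
               c("feature_mean", "feature_sd", "param_low", "param_high"))
  # bit-reproducible from (config, seed)
  ds2 <- make_training_dataset(40, seed = 12, batch = 20)
  expect_identical(ds$params, ds2$params)
  expect_identical(ds$features, ds2$features)
})

test_that("an unproductive sweep aborts with diagnostics", {
  # a pulse too weak to ever elicit a spike: every draw is discarded
  protos <- list(ap = stim_protocol(0.01, pulse_duration = 50,
                                    total_duration = 200, dt_out = 0.1),
                 hp = protocol_hyperpolarizing(dt_out = 0.1))
  expect_error(
    make_training_dataset(20, protocols = protos, seed = 5, batch = 20),
    class = "ganpop_sweep_failure")
})

test_that("the category mimic produces the configured cell counts", {
  mim <- make_category_mimic(n_cells = c(WT12 = 6, rTg4510 = 6, WT24 = 6,
                                         PDAPP = 6),
                             seed = 2)
  expect_identical(nrow(mim), 24L)
  expect_setequal(unique(mim$category), c("WT12", "rTg4510", "WT24", "PDAPP"))
  expect_true(all(feature_names() %in% names(mim)))
  expect_identical(nrow(attr(mim, "params")), 24L)
  # default counts mirror the study populations
  expect_identical(unname(eval(formals(make_category_mimic)$n_cells)),
                   c(19, 26, 26, 30))
})

test_that("a delayed-rectifier shift narrows the simulated action potential", {
  shifts <- list(base = c(g_KDR = 1), shifted = c(g_KDR = 1.3))
  mim <- make_category_mimic(shifts, n_cells = c(base = 15, shifted = 15),
                             seed = 4)
  w <- tapply(mim$ap_width, mim$category, mean)
  expect_lt(w[["shifted"]], w[["base"]])
})

test_that("the Rosenbrock toy evaluates and scales as configured", {
  expect_identical(rosenbrock(1, 1), 0)
  expect_identical(rosenbrock(0, 0), 1)
  ds <- rosenbrock_dataset(500, seed = 3)
  expect_equal(ds$features$y, rosenbrock(ds$params$x1, ds$params$x2))
  expect_identical(scale_profile("full_scale")$n_train, 3e6)
})
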