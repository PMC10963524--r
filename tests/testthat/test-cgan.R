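# Adversarial losses, the JSD estimator, training mechanics and sampling.

test_that("losses match the implemented forms at reference points", {
  # an indifferent discriminator
  l <- gan_losses(rep(0.5, 10), rep(0.5, 10))
  expect_equal(l$d_loss, 2 * log(2))
  expect_equal(l$g_loss, 0)
  # a perfect discriminator drives its loss toward zero
  l2 <- gan_losses(rep(1, 10), rep(0, 10))
  expect_lt(l2$d_loss, 1e-6)
  # random batches versus a hand-coded scalar loop (with clipping)
  set.seed(13)
  pr <- runif(50); pf <- runif(50)
  clip <- function(p) pmin(pmax(p, 1e-7), 1 - 1e-7)
  d_hand <- 0; g_hand <- 0
  for (i in 1:50) {
    d_hand <- d_hand - log(clip(pr[i])) / 50 - log(1 - clip(pf[i])) / 50
    g_hand <- g_hand + log(1 - clip(pf[i])) / 50 - log(clip(pf[i])) / 50
  }
  l3 <- gan_losses(pr, pf)
  expect_equal(l3$d_loss, d_hand, tolerance = 1e-6)
  expect_equal(l3$g_loss, g_hand, tolerance = 1e-6)
})

test_that("JSD estimator: identity, disjoint support, and a hand calculation", {
  set.seed(3)
  x <- rnorm(400)
  expect_equal(jsd(x, x), 0, tolerance = 1e-9)
  expect_equal(jsd(x, x + 100), 1, tolerance = 1e-6)
  # matrices: disjoint in every dimension
  A <- matrix(rnorm(600), ncol = 3)
  expect_equal(jsd(A, A + 50), 1, tolerance = 1e-6)
  expect_equal(jsd(A, A), 0, tolerance = 1e-9)

  # explicit 3-bin distributions (0.5, 0.3, 0.2) vs (0.2, 0.3, 0.5):
  # samples placed at bin centers so the histogram is exact
  a <- rep(c(0.5, 1.5, 2.5), times = c(50, 30, 20))
  b <- rep(c(0.5, 1.5, 2.5), times = c(20, 30, 50))
  p <- c(0.5, 0.3, 0.2); q <- c(0.2, 0.3, 0.5); m <- (p + q) / 2
  hand <- 0.5 * sum(p * log2(p / m)) + 0.5 * sum(q * log2(q / m))
  expect_equal(jsd(a, b, bins = 3), hand, tolerance = 1e-6)

  expect_error(jsd(numeric(0), x), class = "ganpop_bad_input")
  expect_error(jsd(A, matrix(0, 2, 2)), class = "ganpop_bad_input")
})

small_cfg <- function(...) {
  gan_config(latent_dim = 2, g_width = 32, d_width = 24, depth = 3,
             epochs = 4, minibatch = 64, holdout = 100,
             checkpoint_every = 5, seed = 7, ...)
}

test_that("training is deterministic under a fixed seed", {
  ds <- rosenbrock_dataset(600, seed = 2)
  m1 <- train_cgan(ds, small_cfg())
  m2 <- train_cgan(ds, small_cfg())
  expect_identical(m1$log, m2$log)
  expect_identical(m1$jsd_log, m2$jsd_log)
  expect_identical(m1$generator, m2$generator)
})

test_that("the selected checkpoint minimizes the recorded JSD", {
  ds <- rosenbrock_dataset(600, seed = 2)
  m <- train_cgan(ds, small_cfg())
  expect_equal(m$selected_jsd, min(m$jsd_log$jsd))
  expect_identical(m$selected_iteration,
                   m$jsd_log$iteration[which.min(m$jsd_log$jsd)])
  expect_lte(m$selected_jsd, m$jsd_log$jsd[nrow(m$jsd_log)])
  # log bookkeeping: an iteration-0 (untrained) reference checkpoint, then
  # one every checkpoint_every iterations plus the final one
  expect_identical(nrow(m$log), 4L * (600L - 100L) %/% 64L)
  expect_identical(m$jsd_log$iteration[1], 0L)
  expect_true(all(diff(m$jsd_log$iteration) > 0))
  expect_true(all(diff(m$jsd_log$iteration) <= 5))
  expect_identical(m$jsd_log$iteration[nrow(m$jsd_log)], nrow(m$log))
  expect_s3_class(tidy(m), "tbl_df")
  expect_identical(nrow(glance(m)), 1L)
})

test_that("sampling is amortized, reproducible, bounded and sized", {
  ds <- rosenbrock_dataset(600, seed = 2)
  m <- train_cgan(ds, small_cfg())
  cond <- ds$features[1:3, , drop = FALSE]
  s1 <- sample_parameters(m, cond, n = 100, seed = 11)
  s2 <- sample_parameters(m, cond, n = 100, seed = 11)
  expect_identical(s1, s2)
  expect_identical(nrow(s1), 300L)
  expect_identical(unique(s1$.condition), 1:3)
  expect_true(all(s1$x1 >= -5 & s1$x1 <= 5))
  expect_true(all(s1$x2 >= -5 & s1$x2 <= 5))
  expect_error(sample_parameters(m, tibble::tibble(bogus = 1)),
               class = "ganpop_bad_input")
})

test_that("a conditional generator concentrates on an identifiable problem", {
  # parameters are a deterministic, invertible function of the feature:
  # the conditional distribution is (nearly) a point mass
  set.seed(9)
  x <- runif(3000)
  ds <- structure(
    list(params = tibble::tibble(theta = x),
         features = tibble::tibble(y = x),
         discarded = 0L, n_attempted = 3000L,
         normalization = list(feature_mean = c(y = mean(x)),
                              feature_sd = c(y = sd(x)),
                              param_low = c(theta = 0),
                              param_high = c(theta = 1)),
         bounds = tibble::tibble(parameter = "theta", mu = 0.5, low = 0,
                                 high = 1),
         seed = 9L),
    class = "ganpop_training")
  # small net, scaled-up Adam step sizes for the tiny iteration budget
  cfg <- gan_config(latent_dim = 2, g_width = 48, d_width = 32, depth = 3,
                    epochs = 60, minibatch = 128, holdout = 300,
                    checkpoint_every = 20, seed = 15,
                    lr_g = 2.5e-3, lr_d = 5e-4)
  m <- train_cgan(ds, cfg)
  conds <- tibble::tibble(y = c(0.2, 0.5, 0.8))
  smp <- sample_parameters(m, conds, n = 200, seed = 3)
  sds <- tapply(smp$theta, smp$.condition, sd)
  prior_sd <- 1 / sqrt(12) # uniform prior on [0, 1]
  expect_true(all(sds < 0.1 * prior_sd)) # strong concentration
  # and the conditional means track the inverse map
  mns <- tapply(smp$theta, smp$.condition, mean)
  expect_lt(max(abs(mns - c(0.2, 0.5, 0.8))), 0.05)
})

test_that("training on the Rosenbrock toy improves and selects by JSD", {
  ds <- rosenbrock_dataset(8000, seed = 21)
  cfg <- gan_config(latent_dim = 2, epochs = 30, minibatch = 128,
                    holdout = 1000, checkpoint_every = 10, seed = 22,
                    lr_g = 1e-3, lr_d = 2e-4)
  m <- train_cgan(ds, cfg)
  # the JSD drops from its initial value to the selected minimum
  expect_lt(m$selected_jsd, m$jsd_log$jsd[1])
  expect_lt(m$selected_jsd, 0.5 * m$jsd_log$jsd[1])
  # pushing selected-generator samples through the forward map reproduces
  # the conditioned output distribution at the study's group size (n = 100)
  idx <- 2000:2099
  smp <- sample_parameters(m, ds$features[idx, , drop = FALSE], n = 1,
                           seed = 23)
  yhat <- rosenbrock(smp$x1, smp$x2)
  expect_false(ks_two_sample(yhat, ds$features$y[idx])$reject)
})
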