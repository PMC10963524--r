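# Conditional GAN for the stochastic inverse problem: the generator learns
# to sample parameter sets conditioned on feature vectors; training uses the
# non-saturating minimax losses with discriminator unrolling, and the
# Jensen-Shannon divergence between generator pushforward and held-out
# training data selects the checkpoint.

#' Conditional-GAN configuration
#'
#' Architecture and optimizer constants. Defaults: generator and
#' discriminator are ReLU MLPs with 8 hidden layers of 180 and 130 nodes;
#' Adam step sizes 1e-4 (generator) and 2e-5 (discriminator) with momentum
#' coefficients 0.9/0.999; discriminator unrolling with 5 inner steps at
#' step size 5e-4; weights checkpointed (for JSD scoring) every 10
#' iterations. The full-scale study configuration uses 400 epochs and
#' minibatches of 10,000 on a 3,000,000-row sweep; desk-scale runs shrink
#' epochs/minibatch, not the architecture.
#'
#' @param latent_dim Dimension of the standard-normal latent input.
#' @param g_width,d_width Hidden-layer widths.
#' @param depth Number of hidden layers.
#' @param epochs Training epochs.
#' @param minibatch Minibatch size.
#' @param lr_g,lr_d Adam step sizes for generator/discriminator.
#' @param beta1,beta2 Adam momentum coefficients.
#' @param unroll Number of unrolled discriminator steps (0 disables).
#' @param lr_unroll Step size of the unrolled inner updates.
#' @param checkpoint_every JSD-scoring interval (iterations).
#' @param holdout Number of training rows reserved for JSD scoring.
#' @param jsd_bins Histogram bins per dimension for the JSD estimate.
#' @param jsd_latent_reps Latent draws per held-out row when scoring a
#'   checkpoint (averaging down the histogram noise of the selection).
#' @param feature_transform Conditioning-feature normalization:
#'   \code{"rank"} (default; rank-Gaussian scores through the stored
#'   empirical CDF, robust to heavy-tailed features) or \code{"zscore"}.
#' @param seed Integer seed.
#' @return A list of class \code{gan_config}.
#' @export
gan_config <- function(latent_dim = 5, g_width = 180, d_width = 130,
                       depth = 8, epochs = 400, minibatch = 10000,
                       lr_g = 1e-4, lr_d = 2e-5, beta1 = 0.9, beta2 = 0.999,
                       unroll = 5, lr_unroll = 5e-4, checkpoint_every = 10,
                       holdout = NULL, jsd_bins = 20, jsd_latent_reps = 4,
                       feature_transform = c("rank", "zscore"), seed = 1L) {
  feature_transform <- match.arg(feature_transform)
  stopifnot(lr_g > 0, lr_d > 0, lr_unroll > 0, unroll >= 0,
            latent_dim >= 1, depth >= 1, epochs >= 1)
  structure(as.list(environment()), class = "gan_config")
}

#' Implemented GAN losses
#'
#' Given the discriminator's probabilities on a real batch and on a fake
#' batch, returns the minimized forms of the adversarial losses: the
#' discriminator loss \eqn{-E[\log D(x\|y)] - E[\log(1 - D(G(z\|y)))]} and
#' the non-saturating generator loss
#' \eqn{E[\log(1 - D(G(z\|y)))] - E[\log D(G(z\|y))]}. Probabilities are
#' clipped to \code{[clip, 1 - clip]} before the logarithms.
#'
#' @param d_real Discriminator outputs on real samples (probabilities).
#' @param d_fake Discriminator outputs on generated samples.
#' @param clip Clipping bound (default 1e-7).
#' @return A list with elements \code{d_loss} and \code{g_loss}.
#' @export
gan_losses <- function(d_real, d_fake, clip = 1e-7) {
  pr <- pmin(pmax(d_real, clip), 1 - clip)
  pf <- pmin(pmax(d_fake, clip), 1 - clip)
  out <- list(d_loss = -mean(log(pr)) - mean(log(1 - pf)),
              g_loss = mean(log(1 - pf)) - mean(log(pf)))
  if (!all(is.finite(unlist(out)))) {
    abort("non-finite GAN loss",
          class = "ganpop_gan_divergence",
          d_real_range = range(d_real), d_fake_range = range(d_fake))
  }
  out
}

#' Jensen-Shannon divergence between two sample sets
#'
#' Histogram estimator: each dimension is binned on a shared grid spanning
#' the pooled range of both sample sets, smoothed additively by \code{eps},
#' and the base-2 JSD \eqn{\tfrac12 KL(P\|M) + \tfrac12 KL(Q\|M)} with
#' \eqn{M = (P+Q)/2} is computed per dimension; the result is the mean
#' across dimensions (so it stays in \[0, 1\], with 0 for identical samples
#' and 1 for samples with disjoint support in every dimension).
#'
#' @param a,b Numeric vectors or matrices/data frames with matching columns.
#' @param bins Bins per dimension.
#' @param eps Additive smoothing.
#' @return Divergence in \[0, 1\] (bits).
#' @examples
#' jsd(rnorm(500), rnorm(500))
#' @export
jsd <- function(a, b, bins = 20, eps = 1e-10) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!nrow(a) || !nrow(b)) abort("empty input", class = "ganpop_bad_input")
  if (ncol(a) != ncol(b)) abort("dimension mismatch", class = "ganpop_bad_input")
  per_dim <- vapply(seq_len(ncol(a)), function(j) {
    x <- a[, j]; y <- b[, j]
    lo <- min(x, y); hi <- max(x, y)
    if (hi <= lo) return(0) # constant in both sets: identical distributions
    breaks <- seq(lo, hi, length.out = bins + 1)
    cx <- tabulate(pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE),
                             1L), bins), bins)
    cy <- tabulate(pmin(pmax(findInterval(y, breaks, rightmost.closed = TRUE),
                             1L), bins), bins)
    p <- (cx + eps) / sum(cx + eps)
    q <- (cy + eps) / sum(cy + eps)
    m <- (p + q) / 2
    kl <- function(u, v) sum(ifelse(u > 0, u * log2(u / v), 0))
    0.5 * kl(p, m) + 0.5 * kl(q, m)
  }, numeric(1))
  mean(per_dim)
}

# ---- normalization helpers --------------------------------------------------

# empirical-CDF support of each feature on a fixed probability grid (strictly
# increasing knots, so interpolation of new values is well defined)
feature_quantile_map <- function(features, n_knots = 257) {
  probs <- seq(0, 1, length.out = n_knots)
  lapply(as.data.frame(features), function(x) {
    q <- quantile(x, probs, names = FALSE, type = 7)
    keep <- c(TRUE, diff(q) > 0)
    list(q = q[keep], p = probs[keep])
  })
}

normalize_params <- function(X, norm) {
  sweep(sweep(as.matrix(X), 2, norm$param_low, "-"), 2,
        norm$param_high - norm$param_low, "/")
}

denormalize_params <- function(Xn, norm) {
  sweep(sweep(as.matrix(Xn), 2, norm$param_high - norm$param_low, "*"), 2,
        norm$param_low, "+")
}

normalize_features <- function(Y, norm) {
  Y <- as.matrix(Y)
  if (!is.null(norm$feature_quantiles)) {
    # rank-Gaussian scores: map through the stored empirical CDF, then the
    # normal quantile function; robust to the heavy tails of several
    # features (rate of rise, width) that plain z-scores handle poorly
    out <- Y
    for (j in seq_len(ncol(Y))) {
      qp <- norm$feature_quantiles[[colnames(Y)[j]]]
      u <- approx(qp$q, qp$p, xout = Y[, j], rule = 2)$y
      out[, j] <- qnorm(pmin(pmax(u, 1e-4), 1 - 1e-4))
    }
    return(out)
  }
  sweep(sweep(Y, 2, norm$feature_mean, "-"), 2, norm$feature_sd, "/")
}

# one discriminator update (real vs fake batch), returning the new net/opt
# and the batch losses
d_update <- function(D, optD, Xreal, Xfake, lr, beta1, beta2) {
  n <- nrow(Xreal)
  XB <- rbind(Xreal, Xfake)
  fw <- nn_forward(D, XB, cache = TRUE)
  p <- as.numeric(fw$out)
  pr <- p[seq_len(n)]; pf <- p[n + seq_len(n)]
  # BCE gradients w.r.t. the output pre-activation (logit)
  dZ <- matrix(c(pr - 1, pf) / n, ncol = 1)
  g <- nn_backward(D, fw, dZ)
  st <- adam_step(D, optD, g, lr, beta1, beta2)
  list(D = st$net, opt = st$opt, d_real = pr, d_fake = pf)
}

#' Train the conditional GAN
#'
#' Alternating adversarial training on a (parameters, features) dataset.
#' Parameters are min-max scaled to \[0, 1\] by the sweep bounds and
#' features standardized; this normalization metadata is stored with the
#' model and reused at inference. Each iteration performs one discriminator
#' update, then an unrolled generator update: the discriminator is copied,
#' advanced \code{unroll} inner Adam steps at \code{lr_unroll}, the
#' generator gradient is taken through the unrolled copy (first-order
#' approximation: the inner updates are not differentiated through), and the
#' copy is discarded. Losses are logged every iteration; every
#' \code{checkpoint_every} iterations the generator pushforward on a
#' held-out slice is scored by the joint parameter+feature [jsd()] against
#' the held-out rows, and the minimum-JSD weights are retained as the
#' selected generator.
#'
#' @param dataset A \code{ganpop_training} dataset
#'   ([make_training_dataset()], [rosenbrock_dataset()]).
#' @param config [gan_config()].
#' @return An object of class \code{ganpop_cgan} with the selected and final
#'   generator weights, per-iteration loss log, per-checkpoint JSD log,
#'   selected iteration, and normalization metadata.
#' @export
train_cgan <- function(dataset, config = gan_config()) {
  stopifnot(inherits(dataset, "ganpop_training"),
            inherits(config, "gan_config"))
  norm <- dataset$normalization
  if (config$feature_transform == "rank") {
    norm$feature_quantiles <- feature_quantile_map(dataset$features)
  }
  X <- normalize_params(dataset$params, norm)
  Y <- normalize_features(dataset$features, norm)
  n <- nrow(X); px <- ncol(X); py <- ncol(Y)
  n_hold <- config$holdout
  if (is.null(n_hold)) n_hold <- min(2000L, max(64L, floor(n / 5)))
  if (n_hold >= n) abort("holdout larger than dataset", class = "ganpop_bad_input")

  with_seed(config$seed, {
    hold_idx <- sample.int(n, n_hold)
    Xh <- X[hold_idx, , drop = FALSE]
    Yh <- Y[hold_idx, , drop = FALSE]
    Xt <- X[-hold_idx, , drop = FALSE]
    Yt <- Y[-hold_idx, , drop = FALSE]
    ntr <- nrow(Xt)
    mb <- min(config$minibatch, ntr)

    G <- nn_new(c(config$latent_dim + py, rep(config$g_width, config$depth),
                  px), "linear")
    D <- nn_new(c(px + py, rep(config$d_width, config$depth), 1), "sigmoid")
    optG <- adam_new(G); optD <- adam_new(D)

    iters_per_epoch <- max(1L, floor(ntr / mb))
    total_iters <- config$epochs * iters_per_epoch
    log_iter <- integer(total_iters)
    log_epoch <- integer(total_iters)
    log_d <- numeric(total_iters)
    log_g <- numeric(total_iters)
    it <- 0L

    gen_fake <- function(Gnet, Yb) {
      Z <- matrix(rnorm(nrow(Yb) * config$latent_dim), ncol = config$latent_dim)
      list(Z = Z, X = nn_forward(Gnet, cbind(Z, Yb)))
    }

    score_checkpoint <- function(Gnet) {
      # several latent draws per held-out row tame the histogram noise of
      # the checkpoint score (the selection is a minimum over many
      # checkpoints, so single-draw noise would dominate it)
      reps <- config$jsd_latent_reps
      Yr <- Yh[rep(seq_len(n_hold), reps), , drop = FALSE]
      Zh <- matrix(rnorm(n_hold * reps * config$latent_dim),
                   ncol = config$latent_dim)
      Xg <- nn_forward(Gnet, cbind(Zh, Yr))
      Xg <- pmin(pmax(Xg, 0), 1)
      jsd(cbind(Xg, Yr), cbind(Xh, Yh), bins = config$jsd_bins)
    }

    # iteration-0 reference: the untrained generator's pushforward
    j0 <- score_checkpoint(G)
    jsd_iter <- 0L; jsd_val <- j0
    best <- list(jsd = j0, G = nn_snapshot(G), iter = 0L)

    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(ntr)
      for (bi in seq_len(iters_per_epoch)) {
        it <- it + 1L
        rows <- ord[((bi - 1) * mb + 1):(bi * mb)]
        Xb <- Xt[rows, , drop = FALSE]
        Yb <- Yt[rows, , drop = FALSE]

        # discriminator step on the true D
        fake <- gen_fake(G, Yb)$X
        upd <- d_update(D, optD, cbind(Xb, Yb), cbind(fake, Yb),
                        config$lr_d, config$beta1, config$beta2)
        D <- upd$D; optD <- upd$opt
        d_loss <- gan_losses(upd$d_real, upd$d_fake)$d_loss

        # unrolled copy for the generator update (fixed real/fake batches;
        # only the discriminator weights evolve over the inner steps)
        Du <- nn_snapshot(D); optu <- adam_snapshot(optD)
        if (config$unroll > 0) {
          XYreal <- cbind(Xb, Yb)
          XYfake <- cbind(gen_fake(G, Yb)$X, Yb)
          for (u in seq_len(config$unroll)) {
            st <- d_update(Du, optu, XYreal, XYfake,
                           config$lr_unroll, config$beta1, config$beta2)
            Du <- st$D; optu <- st$opt
          }
        }

        # generator step through the (unrolled) discriminator
        fk <- gen_fake(G, Yb)
        fwG <- nn_forward(G, cbind(fk$Z, Yb), cache = TRUE)
        fwD <- nn_forward(Du, cbind(fwG$out, Yb), cache = TRUE)
        pf <- as.numeric(fwD$out)
        # d/dz [log(1-s) - log(s)] = -1
        dZd <- matrix(-1 / mb, nrow = mb, ncol = 1)
        gD <- nn_backward(Du, fwD, dZd)
        dFake <- gD$dX[, seq_len(px), drop = FALSE]
        gG <- nn_backward(G, fwG, dFake)
        st <- adam_step(G, optG, gG, config$lr_g, config$beta1, config$beta2)
        G <- st$net; optG <- st$opt
        g_loss <- gan_losses(upd$d_real, pf)$g_loss

        log_iter[it] <- it; log_epoch[it] <- ep
        log_d[it] <- d_loss; log_g[it] <- g_loss

        if (it %% config$checkpoint_every == 0 || it == total_iters) {
          j <- score_checkpoint(G)
          jsd_iter <- c(jsd_iter, it)
          jsd_val <- c(jsd_val, j)
          if (j < best$jsd) best <- list(jsd = j, G = nn_snapshot(G), iter = it)
        }
      }
    }

    structure(
      list(generator = best$G, final_generator = G,
           selected_iteration = best$iter, selected_jsd = best$jsd,
           log = tibble::tibble(iteration = log_iter, epoch = log_epoch,
                                d_loss = log_d, g_loss = log_g),
           jsd_log = tibble::tibble(iteration = jsd_iter, jsd = jsd_val),
           normalization = norm,
           param_names = colnames(dataset$params),
           feature_names = colnames(dataset$features),
           config = config),
      class = "ganpop_cgan")
  })
}

#' @export
print.ganpop_cgan <- function(x, ...) {
  cat(sprintf(
    "<ganpop_cgan> %d iterations; selected iteration %d (JSD %.4g)\n",
    nrow(x$log), x$selected_iteration, x$selected_jsd))
  invisible(x)
}

#' @export
tidy.ganpop_cgan <- function(x, ...) {
  dplyr::left_join(x$log, x$jsd_log, by = "iteration")
}

#' @export
glance.ganpop_cgan <- function(x, ...) {
  tibble::tibble(iterations = nrow(x$log),
                 selected_iteration = x$selected_iteration,
                 selected_jsd = x$selected_jsd,
                 final_d_loss = x$log$d_loss[nrow(x$log)],
                 final_g_loss = x$log$g_loss[nrow(x$log)])
}

#' Sample parameter sets conditioned on features
#'
#' Amortized inference: draws standard-normal latents, pushes them through
#' the selected generator together with the (normalized) conditioning
#' features, and returns de-normalized parameter sets clipped to the sweep
#' bounds. No retraining is needed for new targets.
#'
#' @param object A trained model ([train_cgan()]).
#' @param features A tibble/data frame of conditioning feature rows with the
#'   model's feature columns (apply [replace_out_of_range()] first for
#'   out-of-support targets).
#' @param n Samples per conditioning row (default 100).
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A tibble with \code{.condition} (input row index) and one column
#'   per parameter; \code{n} rows per condition.
#' @export
sample_parameters <- function(object, features, n = 100, seed = NULL, ...) {
  UseMethod("sample_parameters")
}

#' @rdname sample_parameters
#' @export
sample_parameters.ganpop_cgan <- function(object, features, n = 100,
                                          seed = NULL, ...) {
  miss <- setdiff(object$feature_names, names(features))
  if (length(miss)) {
    abort(paste("missing feature columns:", paste(miss, collapse = ", ")),
          class = "ganpop_bad_input")
  }
  Y <- normalize_features(features[, object$feature_names, drop = FALSE],
                          object$normalization)
  nc <- nrow(Y)
  with_seed(seed, {
    Yrep <- Y[rep(seq_len(nc), each = n), , drop = FALSE]
    Z <- matrix(rnorm(nc * n * object$config$latent_dim),
                ncol = object$config$latent_dim)
    Xn <- nn_forward(object$generator, cbind(Z, Yrep))
    Xn <- pmin(pmax(Xn, 0), 1)
    X <- denormalize_params(Xn, object$normalization)
    colnames(X) <- object$param_names
    dplyr::bind_cols(
      tibble::tibble(.condition = rep(seq_len(nc), each = n)),
      tibble::as_tibble(X)
    )
  })
}
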