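# Minimal dense neural-network machinery (ReLU MLP, manual backprop, Adam)
# used by the conditional GAN. Weights are (fan_in x fan_out) matrices; data
# matrices are row-per-sample. The numerical kernels live in src/nn.cpp.
#
# cpp_adam_step updates the weight/moment containers IN PLACE for speed;
# any net or optimizer state that must survive later updates (checkpoints,
# the pre-unroll discriminator) is protected with nn_snapshot()/adam_snapshot(),
# which create fresh list containers.

nn_new <- function(sizes, out_activation = c("linear", "sigmoid")) {
  out_activation <- match.arg(out_activation)
  L <- length(sizes) - 1L
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    # He initialization for ReLU hidden layers
    W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1]) * sqrt(2 / sizes[l]),
                     sizes[l], sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
  }
  list(W = W, b = b, out = out_activation)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# deep copies: cpp_adam_step mutates matrix memory in place, so snapshots
# must not share storage with the live nets
deep_copy <- function(xs) lapply(xs, function(m) m + 0)

nn_snapshot <- function(net) {
  list(W = deep_copy(net$W), b = deep_copy(net$b), out = net$out)
}

adam_snapshot <- function(opt) {
  list(mW = deep_copy(opt$mW), vW = deep_copy(opt$vW),
       mb = deep_copy(opt$mb), vb = deep_copy(opt$vb), t = opt$t)
}

# forward pass; keeps layer inputs for backprop when cache = TRUE
nn_forward <- function(net, X, cache = FALSE) {
  out_type <- if (net$out == "sigmoid") 1L else 0L
  res <- cpp_nn_forward(net$W, net$b, as.matrix(X), out_type, cache)
  if (cache) res else res$out
}

# backprop given dL/d(pre-activation of the output layer), shape n x out;
# returns weight/bias gradients and dL/dX
nn_backward <- function(net, fw, dZ) {
  cpp_nn_backward(net$W, fw$acts, dZ)
}

adam_new <- function(net) {
  zero_like <- function(p) {
    if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else numeric(length(p))
  }
  list(mW = lapply(net$W, zero_like), vW = lapply(net$W, zero_like),
       mb = lapply(net$b, zero_like), vb = lapply(net$b, zero_like),
       t = 0L)
}

# one Adam update; mutates net/opt containers in place and returns them
adam_step <- function(net, opt, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  cpp_adam_step(net$W, net$b, opt$mW, opt$vW, opt$mb, opt$vb,
                grads$W, grads$b, lr, beta1, beta2, opt$t, eps)
  list(net = net, opt = opt)
}
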