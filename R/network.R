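# Reference (pure R) forward implementations of every network stage.
# These are the executable definitions of the model: model_forward()
# composes them, and the test suite checks the compiled training engine
# against them. Activations are 3-d arrays (channels, length, batch).

as_batch <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  stopifnot(length(dim(x)) == 3L)
  x
}

bn_eps <- 1e-5

r_bn <- function(x, gamma, beta, mean, var) {
  xc <- sweep(x, 1L, mean, "-")
  xc <- sweep(xc, 1L, sqrt(var + bn_eps), "/")
  sweep(sweep(xc, 1L, gamma, "*"), 1L, beta, "+")
}

r_relu <- function(x) pmax(x, 0)

# same-padded 1-D convolution; W is (C_out x C_in * k) with columns ordered
# tap-major: column (t-1)*C_in + c holds input channel c at kernel tap t
r_conv <- function(x, W, b, k) {
  d <- dim(x)
  C <- d[1L]; L <- d[2L]; N <- d[3L]
  Cout <- nrow(W)
  pad <- (k - 1L) %/% 2L
  out <- array(0, dim = c(Cout, L, N))
  for (n in seq_len(N)) {
    xp <- cbind(matrix(0, C, pad), matrix(x[, , n], C, L), matrix(0, C, pad))
    acc <- matrix(rep(b, L), Cout, L)
    for (t in seq_len(k)) {
      acc <- acc + W[, (t - 1L) * C + seq_len(C), drop = FALSE] %*%
        xp[, t:(t + L - 1L), drop = FALSE]
    }
    out[, , n] <- acc
  }
  out
}

r_avgpool2 <- function(x) {
  d <- dim(x)
  L <- d[2L]; Lo <- L %/% 2L
  if (Lo < 1L) stop("average pooling needs length >= 2, got ", L)
  out <- array(0, dim = c(d[1L], Lo, d[3L]))
  for (p in seq_len(Lo)) {
    out[, p, ] <- (x[, 2L * p - 1L, , drop = FALSE] +
                     x[, 2L * p, , drop = FALSE]) / 2
  }
  out
}

#' Dense block forward pass
#'
#' Each layer computes `Conv(ReLU(BN(.)))` on the channel-concatenation of
#' the block input and all previous layer outputs, appending `growth_rate`
#' channels; the block output is the full concatenation, so a block entered
#' with `C` channels exits with `C + n_layers * growth_rate` channels at
#' unchanged length. An empty layer list is the identity.
#'
#' @param x Batch array (channels, length, batch) or a single
#'   (channels, length) matrix.
#' @param layers List of layer weights, each a list with `gamma`, `beta`,
#'   `mean`, `var` (batch-norm parameters and running statistics), `W`
#'   (`growth_rate x C_in * k` convolution weights) and `b`.
#' @param kernel_size Odd convolution kernel width.
#' @return Array (C + n_layers * growth, length, batch).
#' @export
dense_block_forward <- function(x, layers, kernel_size = 3L) {
  x <- as_batch(x)
  for (ly in layers) {
    a <- r_relu(r_bn(x, ly$gamma, ly$beta, ly$mean, ly$var))
    out <- r_conv(a, ly$W, ly$b, kernel_size)
    d <- dim(x)
    joined <- array(0, dim = c(d[1L] + dim(out)[1L], d[2L], d[3L]))
    joined[seq_len(d[1L]), , ] <- x
    joined[d[1L] + seq_len(dim(out)[1L]), , ] <- out
    x <- joined
  }
  x
}

#' Transition layer forward pass
#'
#' Batch normalization, then a 1x1 convolution compressing channels to
#' `ceiling(compression * C)`, then average pooling with window 2 and
#' stride 2, halving the length (`floor(L / 2)`).
#'
#' @param x Batch array (channels, length, batch).
#' @param weights List with `gamma`, `beta`, `mean`, `var`, `W`
#'   (`C_out x C_in`) and `b`.
#' @return Array (`nrow(weights$W)`, `floor(L / 2)`, batch).
#' @export
transition_forward <- function(x, weights) {
  x <- as_batch(x)
  if (dim(x)[2L] < 2L) stop("transition layer needs length >= 2, got ", dim(x)[2L])
  a <- r_bn(x, weights$gamma, weights$beta, weights$mean, weights$var)
  a <- r_conv(a, weights$W, weights$b, 1L)
  r_avgpool2(a)
}

pool_stats <- function(f) {
  f <- as_batch(f)
  list(avg = apply(f, c(1L, 3L), mean), max = apply(f, c(1L, 3L), max))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

attention_fnn <- function(v, fnn) {
  # shared two-layer bottleneck C -> C/r -> C
  u <- r_relu(fnn$W1 %*% v + fnn$b1)
  fnn$W2 %*% u + fnn$b2
}

#' Residual channel attention weights
#'
#' Global average and max pooling over the length axis give two per-channel
#' vectors. `mc` is the sigmoid of the summed outputs of a shared two-layer
#' bottleneck network applied to each pooled vector; `mr` (the short-circuit
#' term) is the sigmoid of the raw elementwise sum of the pooled vectors;
#' the residual weights are `mrc = mc + mr`, elementwise in (0, 2).
#'
#' @param f Feature batch (channels, length, batch) or (channels, length)
#'   matrix.
#' @param fnn List with `W1` (`h x C`), `b1`, `W2` (`C x h`), `b2`; the
#'   bottleneck width `h = floor(C / reduction_ratio)` must be >= 1.
#' @return List with `mc`, `mr`, `mrc`, each a `C x batch` matrix.
#' @export
rcam_weights <- function(f, fnn) {
  f <- as_batch(f)
  C <- dim(f)[1L]
  if (nrow(fnn$W1) < 1L) stop("attention bottleneck must have width >= 1")
  ps <- pool_stats(f)
  mc <- sigmoid(attention_fnn(ps$avg, fnn) + attention_fnn(ps$max, fnn))
  mr <- sigmoid(ps$avg + ps$max)
  list(mc = mc, mr = mr, mrc = mc + mr)
}

#' Plain channel attention weights (non-residual ablation)
#'
#' As [rcam_weights()] but without the short-circuit term: `mr` is zero and
#' the applied weights are `mrc = mc`, elementwise in (0, 1).
#'
#' @inheritParams rcam_weights
#' @return List with `mc`, `mr` (zero), `mrc = mc`.
#' @export
cam_weights <- function(f, fnn) {
  w <- rcam_weights(f, fnn)
  list(mc = w$mc, mr = 0 * w$mr, mrc = w$mc)
}

apply_channel_weights <- function(f, w) {
  f <- as_batch(f)
  out <- f
  for (n in seq_len(dim(f)[3L])) out[, , n] <- f[, , n] * w[, n]
  out
}

#' Apply residual channel attention to a feature batch
#'
#' Multiplies each channel of each sample by its residual attention weight:
#' `out[c, l, n] = mrc[c, n] * f[c, l, n]`. Shape is unchanged.
#'
#' @inheritParams rcam_weights
#' @return Array with the same shape as `f`.
#' @export
rcam_forward <- function(f, fnn) {
  apply_channel_weights(f, rcam_weights(f, fnn)$mrc)
}

#' Full model forward pass (reference implementation)
#'
#' Composes the pipeline: dense block and transition pairs, a final dense
#' block, the configured channel attention, flatten, the fully connected
#' head with ReLU, and a 2-class softmax. Runs in evaluation mode (batch
#' normalization uses the supplied running statistics; dropout disabled),
#' so the output is deterministic given the weights.
#'
#' @param x Batch array (`input_channels`, `input_length`, batch).
#' @param config A [model_config()].
#' @param weights Nested weight list (internally produced from the flat
#'   parameter vector of a fitted model).
#' @param return_stages Also return per-stage output shapes?
#' @return An `n x 2` matrix of class probabilities (rows sum to 1);
#'   with `return_stages = TRUE`, a list with `probs` and `stages`.
#' @export
model_forward <- function(x, config, weights, return_stages = FALSE) {
  x <- as_batch(x)
  stopifnot(dim(x)[1L] == config$input_channels,
            dim(x)[2L] == config$input_length)
  stages <- data.frame(stage = "input", channels = dim(x)[1L],
                       length = dim(x)[2L], stringsAsFactors = FALSE)
  rec <- function(name, x) {
    stages <<- rbind(stages, data.frame(stage = name, channels = dim(x)[1L],
                                        length = dim(x)[2L]))
  }
  for (b in seq_len(config$n_blocks)) {
    x <- dense_block_forward(x, weights$blocks[[b]], config$kernel_size)
    rec(sprintf("block%d", b), x)
    if (b < config$n_blocks) {
      x <- transition_forward(x, weights$transitions[[b]])
      rec(sprintf("transition%d", b), x)
    }
  }
  if (config$attention == "rcam") {
    x <- apply_channel_weights(x, rcam_weights(x, weights$attention)$mrc)
    rec("attention", x)
  } else if (config$attention == "cam") {
    x <- apply_channel_weights(x, cam_weights(x, weights$attention)$mrc)
    rec("attention", x)
  }
  d <- dim(x)
  h <- matrix(x, d[1L] * d[2L], d[3L])
  for (ly in weights$head) {
    h <- ly$W %*% h + ly$b
    if (ly$relu) h <- r_relu(h)
  }
  mx <- apply(h, 2L, max)
  e <- exp(sweep(h, 2L, mx, "-"))
  probs <- t(sweep(e, 2L, colSums(e), "/"))
  colnames(probs) <- c("negative", "positive")
  if (return_stages) list(probs = probs, stages = stages) else probs
}

# evaluation-mode forward through the compiled engine
net_eval <- function(params, state, x, config) {
  x <- as_batch(x)
  d <- dim(x)
  xm <- x
  dim(xm) <- c(d[1L], d[2L] * d[3L])
  res <- net_run_cpp(params, state, xm, d[3L], integer(0), config,
                     FALSE, FALSE, list(), 0.1)
  colnames(res$probs) <- c("negative", "positive")
  res
}
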