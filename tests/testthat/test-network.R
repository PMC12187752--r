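# random weights for the standalone stage functions
rand_dense_layers <- function(C_in, n_layers, growth, k, seed = 1) {
  set.seed(seed)
  layers <- list()
  C <- C_in
  for (l in seq_len(n_layers)) {
    layers[[l]] <- list(gamma = runif(C, 0.5, 1.5), beta = rnorm(C),
                        mean = rnorm(C, 0, 0.1), var = runif(C, 0.5, 2),
                        W = matrix(rnorm(growth * C * k, sd = 0.3), growth, C * k),
                        b = rnorm(growth))
    C <- C + growth
  }
  layers
}

rand_fnn <- function(C, r, seed = 1, zero = FALSE) {
  set.seed(seed)
  h <- max(1L, C %/% r)
  if (zero) {
    list(W1 = matrix(0, h, C), b1 = rep(0, h),
         W2 = matrix(0, C, h), b2 = rep(0, C))
  } else {
    list(W1 = matrix(rnorm(h * C), h, C), b1 = rnorm(h),
         W2 = matrix(rnorm(C * h), C, h), b2 = rnorm(C))
  }
}

test_that("dense block channel arithmetic and degenerate cases", {
  set.seed(4)
  x <- array(rnorm(80 * 29 * 2), dim = c(80, 29, 2))
  layers <- rand_dense_layers(80, 2, 32, 3)
  out <- dense_block_forward(x, layers, kernel_size = 3)
  expect_equal(dim(out), c(144L, 29L, 2L))        # 80 + 2 * 32
  expect_identical(out[1:80, , ], x)              # input rides along unchanged
  expect_identical(dense_block_forward(x, list()), x)  # zero layers = identity
})

test_that("dense block equals a hand-composed BN/ReLU/Conv chain", {
  set.seed(11)
  x <- array(rnorm(8 * 10 * 2), dim = c(8, 10, 2))
  layers <- rand_dense_layers(8, 2, 4, 3, seed = 12)
  got <- dense_block_forward(x, layers, kernel_size = 3)
  # scalar reimplementation with explicit loops
  cur <- x
  for (ly in layers) {
    C <- dim(cur)[1]; L <- dim(cur)[2]; N <- dim(cur)[3]
    conv <- array(0, dim = c(nrow(ly$W), L, N))
    for (n in seq_len(N)) {
      a <- matrix(0, C, L)
      for (c in seq_len(C)) for (p in seq_len(L)) {
        xh <- (cur[c, p, n] - ly$mean[c]) / sqrt(ly$var[c] + 1e-5)
        a[c, p] <- max(ly$gamma[c] * xh + ly$beta[c], 0)
      }
      for (o in seq_len(nrow(ly$W))) for (p in seq_len(L)) {
        acc <- ly$b[o]
        for (t in 1:3) {
          q <- p + t - 2
          if (q >= 1 && q <= L) {
            for (c in seq_len(C)) acc <- acc + ly$W[o, (t - 1) * C + c] * a[c, q]
          }
        }
        conv[o, p, n] <- acc
      }
    }
    nxt <- array(0, dim = c(C + nrow(ly$W), L, N))
    nxt[seq_len(C), , ] <- cur
    nxt[C + seq_len(nrow(ly$W)), , ] <- conv
    cur <- nxt
  }
  expect_equal(got, cur, tolerance = 1e-12)
})

test_that("transition layer compresses channels and halves length", {
  set.seed(5)
  x <- array(rnorm(144 * 29 * 2), dim = c(144, 29, 2))
  w <- list(gamma = rep(1, 144), beta = rep(0, 144),
            mean = rep(0, 144), var = rep(1 - 1e-5, 144),
            W = matrix(rnorm(72 * 144, sd = 0.1), 72, 144), b = rnorm(72))
  out <- transition_forward(x, w)
  expect_equal(dim(out), c(72L, 14L, 2L))
  # identity weights propagate a constant input to a constant output
  wid <- list(gamma = rep(1, 4), beta = rep(0, 4), mean = rep(0, 4),
              var = rep(1 - 1e-5, 4), W = diag(4), b = rep(0, 4))
  const <- array(3, dim = c(4, 6, 1))
  expect_equal(as.numeric(transition_forward(const, wid)), rep(3, 4 * 3))
  expect_error(transition_forward(array(1, c(4, 1, 1)), wid), "length >= 2")
})

test_that("rcam weights match a scalar loop oracle and stay in range", {
  for (case in 1:5) {
    set.seed(100 + case)
    C <- sample(3:10, 1); L <- sample(2:12, 1); N <- sample(1:4, 1)
    f <- array(rnorm(C * L * N), dim = c(C, L, N))
    fnn <- rand_fnn(C, 2, seed = case)
    got <- rcam_weights(f, fnn)
    h <- nrow(fnn$W1)
    sig <- function(z) 1 / (1 + exp(-z))
    for (n in seq_len(N)) {
      for (c in seq_len(C)) {
        avg <- mean(f[c, , n]); mx <- max(f[c, , n])
      }
      avgv <- sapply(seq_len(C), function(c) mean(f[c, , n]))
      maxv <- sapply(seq_len(C), function(c) max(f[c, , n]))
      fnn_out <- function(v) {
        u <- numeric(h)
        for (i in seq_len(h)) u[i] <- max(sum(fnn$W1[i, ] * v) + fnn$b1[i], 0)
        z <- numeric(C)
        for (c in seq_len(C)) z[c] <- sum(fnn$W2[c, ] * u) + fnn$b2[c]
        z
      }
      mc <- sig(fnn_out(avgv) + fnn_out(maxv))
      mr <- sig(avgv + maxv)
      expect_equal(got$mc[, n], mc, tolerance = 1e-12)
      expect_equal(got$mr[, n], mr, tolerance = 1e-12)
      expect_equal(got$mrc[, n], mc + mr, tolerance = 1e-12)
    }
    expect_true(all(got$mrc > 0 & got$mrc < 2))
    expect_true(all(got$mc > 0 & got$mc < 1))
  }
})

test_that("zeroed attention network gives the sigmoid(0) fixed point", {
  f <- array(0, dim = c(6, 8, 2))
  fnn <- rand_fnn(6, 2, zero = TRUE)
  w <- rcam_weights(f, fnn)
  expect_equal(as.numeric(w$mc), rep(0.5, 12))
  expect_equal(as.numeric(w$mr), rep(0.5, 12))
  expect_equal(as.numeric(w$mrc), rep(1.0, 12))
  # cam drops the short-circuit term
  wc <- cam_weights(f, fnn)
  expect_equal(as.numeric(wc$mrc), rep(0.5, 12))
  expect_equal(as.numeric(wc$mr), rep(0, 12))
})

test_that("cam equals rcam minus the short-circuit term", {
  set.seed(21)
  f <- array(rnorm(5 * 7 * 3), dim = c(5, 7, 3))
  fnn <- rand_fnn(5, 2, seed = 8)
  wr <- rcam_weights(f, fnn)
  wc <- cam_weights(f, fnn)
  expect_equal(wc$mrc, wr$mrc - wr$mr)
  expect_true(all(wc$mrc > 0 & wc$mrc < 1))
})

test_that("rcam_forward scales channels and preserves shape", {
  fnn <- rand_fnn(6, 2, zero = TRUE)
  z <- array(0, dim = c(6, 8, 2))
  expect_equal(rcam_forward(z, fnn), z)  # weight 1.0 on a zero input
  for (case in 1:3) {
    set.seed(case)
    C <- sample(2:8, 1); L <- sample(2:10, 1); N <- sample(1:3, 1)
    f <- array(rnorm(C * L * N), dim = c(C, L, N))
    fnn <- rand_fnn(C, 2, seed = case)
    out <- rcam_forward(f, fnn)
    expect_equal(dim(out), dim(f))
    w <- rcam_weights(f, fnn)$mrc
    for (n in seq_len(N)) {
      expect_equal(out[, , n], f[, , n] * w[, n], tolerance = 1e-12)
    }
  }
})

test_that("model_forward yields softmax rows and the documented length trace", {
  cfg <- model_config()  # default architecture
  set.seed(3)
  ini <- kcrnet:::init_params(cfg)
  w <- kcrnet:::unpack_params(cfg, ini$params, ini$state)
  x <- array(rnorm(80 * 29 * 2), dim = c(80, 29, 2))
  out <- model_forward(x, cfg, w, return_stages = TRUE)
  expect_equal(dim(out$probs), c(2L, 2L))
  expect_equal(rowSums(out$probs), c(1, 1), tolerance = 1e-6)
  expect_true(all(out$probs > 0 & out$probs < 1))
  tr <- out$stages
  expect_equal(tr$length[tr$stage %in% paste0("transition", 1:3)], c(14L, 7L, 3L))
  expect_equal(tr$channels[tr$stage == "block1"], 144L)
})

test_that("compiled forward equals the R reference for every attention variant", {
  for (att in c("rcam", "cam", "none")) {
    cfg <- tiny_model_config(attention = att, dropout = 0)
    set.seed(17)
    ini <- kcrnet:::init_params(cfg)
    x <- array(rnorm(12 * 29 * 4), dim = c(12, 29, 4))
    w <- kcrnet:::unpack_params(cfg, ini$params, ini$state)
    pr_r <- model_forward(x, cfg, w)
    res_c <- kcrnet:::net_eval(ini$params, ini$state, x, cfg)
    expect_equal(unname(res_c$probs), unname(pr_r), tolerance = 1e-10)
  }
})

test_that("attention variants share everything up to the attention stage", {
  cfg_r <- tiny_model_config(attention = "rcam", dropout = 0)
  cfg_n <- tiny_model_config(attention = "none", dropout = 0)
  set.seed(23)
  ini_r <- kcrnet:::init_params(cfg_r)
  lay_r <- kcrnet:::param_layout(cfg_r)$params
  lay_n <- kcrnet:::param_layout(cfg_n)$params
  # identical backbone parameter layout; extra attention tensors only
  shared <- setdiff(lay_r$name, lay_n$name)
  expect_true(all(grepl("^attention\\.", shared)))
  expect_equal(lay_n$name, lay_r$name[!grepl("^attention\\.", lay_r$name)])
  # stage traces agree before the attention row
  s_r <- summarize(cfg_r)$stages
  s_n <- summarize(cfg_n)$stages
  expect_equal(s_n, s_r[s_r$stage != "attention", ], ignore_attr = TRUE)
  # and the outputs genuinely differ at/after attention
  set.seed(23)
  ini_n <- kcrnet:::init_params(cfg_n)
  x <- array(rnorm(12 * 29 * 3), dim = c(12, 29, 3))
  pr_r <- model_forward(x, cfg_r, kcrnet:::unpack_params(cfg_r, ini_r$params, ini_r$state))
  pr_n <- model_forward(x, cfg_n, kcrnet:::unpack_params(cfg_n, ini_n$params, ini_n$state))
  expect_false(isTRUE(all.equal(pr_r, pr_n)))
})

test_that("summarize reports closed-form shapes and exact parameter counts", {
  s <- summarize(model_config())
  expect_equal(s$stages$channels[s$stages$stage == "block1"], 144L)
  expect_equal(s$stages$length[s$stages$stage == "attention"], 3L)
  s1 <- summarize(model_config(n_blocks = 1))
  expect_false(any(grepl("transition", s1$stages$stage)))
  for (cfg in list(model_config(), tiny_model_config(),
                   model_config(n_blocks = 2, attention = "none"))) {
    ini <- kcrnet:::init_params(cfg)
    expect_identical(summarize(cfg)$n_params, length(ini$params))
    expect_identical(summarize(cfg)$n_state, length(ini$state))
  }
})

test_that("infeasible depth and empty attention bottleneck are rejected", {
  expect_error(model_config(n_blocks = 6), "infeasible|length")
  expect_error(tiny_model_config(reduction_ratio = 1000), "bottleneck")
  expect_error(model_config(kernel_size = 2), "odd")
  expect_error(model_config(compression = 0), "compression")
})
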