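test_that("make_folds produces balanced stratified partitions", {
  f <- make_folds(10, rep(c(1, 0), each = 5), k = 5, seed = 1)
  sizes <- tabulate(f$assignments, 5)
  expect_equal(sizes, rep(2L, 5))
  for (i in 1:5) {
    expect_equal(sum(f$assignments == i & rep(c(1, 0), each = 5) == 1), 1L)
  }
  # union is everything, folds are disjoint by construction of a vector
  expect_setequal(seq_len(10), unlist(lapply(1:5, function(i) which(f$assignments == i))))

  # benchmark-sized split: 2 x 6,975 over 5 folds -> 2,790 per fold
  y <- rep(c(1, 0), each = 6975)
  f <- make_folds(length(y), y, k = 5, seed = 2)
  expect_equal(tabulate(f$assignments, 5), rep(2790L, 5))
  for (i in 1:5) expect_equal(sum(y[f$assignments == i]), 1395L)

  expect_error(make_folds(4, rep(0, 4), k = 5), "exceeds")
  expect_error(make_folds(10, rep(0:1, 5), k = 1), "k must be >= 2")
  # deterministic per seed
  expect_identical(make_folds(100, rep(0:1, 50), 5, seed = 3),
                   make_folds(100, rep(0:1, 50), 5, seed = 3))
})

test_that("fit is reproducible and respects epoch accounting", {
  ds <- tiny_dataset(n = 120)
  emb <- train_embedding(ds$windows$residues, d = 12, epochs = 2, seed = 2)
  enc <- encode_dataset(ds, emb)
  tc <- tiny_train_config(max_epochs = 3, patience = 3)
  m1 <- fit(enc, tiny_model_config(), tc)
  m2 <- fit(enc, tiny_model_config(), tc)
  expect_identical(m1$history, m2$history)   # same seed -> same history
  expect_identical(m1$params, m2$params)
  expect_equal(nrow(m1$history), 3L)

  tc1 <- tiny_train_config(max_epochs = 1, patience = 1)
  expect_equal(nrow(fit(enc, tiny_model_config(), tc1)$history), 1L)

  # different seed changes the trajectory
  m3 <- fit(enc, tiny_model_config(), tiny_train_config(max_epochs = 3, seed = 8))
  expect_false(identical(m1$history, m3$history))
})

test_that("fit rejects degenerate inputs", {
  ds <- tiny_dataset(n = 60)
  emb <- train_embedding(ds$windows$residues, d = 12, epochs = 1, seed = 1)
  enc <- encode_dataset(ds, emb)
  single <- list(x = enc$x[, , enc$y == 1, drop = FALSE], y = enc$y[enc$y == 1])
  expect_error(fit(single, tiny_model_config(), tiny_train_config()),
               "single class")
  expect_error(train_config(batch_size = 1), "batch_size")
  expect_error(train_config(validation_fraction = 1), "validation_fraction")
  expect_error(train_config(patience = 20, max_epochs = 10), "patience")
})

test_that("training loss falls quickly on separable motif data", {
  ds <- tiny_dataset(n = 300, strength = 1.0, seed = 13)
  # separability cross-check: a plain logistic model on one-hot features
  # classifies this data almost perfectly, so the network should learn it
  vocab <- build_vocabulary(ds$windows$residues)
  oh <- encode_dataset(ds, vocab)
  xf <- t(apply(oh$x, 3, as.numeric))
  glm_fit <- suppressWarnings(
    stats::glm.fit(cbind(1, xf), oh$y, family = stats::binomial()))
  glm_acc <- mean((glm_fit$fitted.values >= 0.5) == (oh$y == 1))
  expect_gte(glm_acc, 0.95)

  emb <- train_embedding(ds$windows$residues, d = 12, epochs = 3, seed = 5)
  enc <- encode_dataset(ds, emb)
  model <- fit(enc, tiny_model_config(), tiny_train_config(max_epochs = 5))
  expect_lt(model$history$train_loss[5], model$history$train_loss[1])
  scores <- predict_scores(model, enc$x)
  expect_gte(mean((scores >= 0.5) == (enc$y == 1)), 0.9)
})

test_that("cross_validate trains per-fold pipelines on disjoint folds", {
  ds <- tiny_dataset(n = 120, strength = 1.0, seed = 21)
  cv <- cross_validate(ds, tiny_model_config(),
                       tiny_train_config(max_epochs = 4),
                       k = 2, embedding_config = list(epochs = 2))
  expect_equal(nrow(cv$folds), 2L)
  expect_setequal(cv$assignments, 1:2)
  expect_equal(sum(cv$folds$n_test), 120L)
  expect_true(all(cv$folds$acc >= 0 & cv$folds$acc <= 1))
  # summary mean equals the mean over fold rows
  expect_equal(cv$summary$mean[cv$summary$metric == "acc"], mean(cv$folds$acc))
  expect_equal(cv$summary$mean[cv$summary$metric == "auc"], mean(cv$folds$auc))
})

test_that("grid_search covers the grid, flags infeasible cells and the winner", {
  ds <- tiny_dataset(n = 100, strength = 1.0, seed = 31)
  tbl <- grid_search(ds, blocks_grid = c(1L, 2L, 6L), layers_grid = 1L,
                     train_config = tiny_train_config(max_epochs = 2),
                     base_config = tiny_model_config(),
                     embedding_config = list(epochs = 1))
  expect_equal(nrow(tbl), 3L)
  expect_false(tbl$feasible[tbl$n_blocks == 6])  # 29 halves to zero length
  expect_true(all(tbl$feasible[tbl$n_blocks != 6]))
  expect_equal(sum(tbl$best), 1L)
  # winner matches an independent re-sort by Acc, then MCC, then size
  feas <- tbl[tbl$feasible, ]
  want <- feas[order(-feas$acc, -feas$mcc, feas$n_params), ][1, c("n_blocks", "layers_per_block")]
  expect_equal(tbl[tbl$best, c("n_blocks", "layers_per_block")], want,
               ignore_attr = TRUE)
})
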