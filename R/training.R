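#' Training configuration
#'
#' @param optimizer `"adam"` (default) or `"sgd"`.
#' @param learning_rate Step size, default 1e-3.
#' @param batch_size Minibatch size, default 64 (minimum 2: batch
#'   normalization needs at least two samples).
#' @param max_epochs Maximum training epochs, default 100.
#' @param patience Early-stopping patience in epochs on validation loss,
#'   default 10.
#' @param validation_fraction Fraction of the training data held out for
#'   early stopping, default 0.1.
#' @param seed Integer seed; fixes initialization, shuffling and dropout,
#'   making a fit bit-reproducible on a fixed machine.
#' @param class_threshold Positive-call threshold on the positive-class
#'   probability, default 0.5.
#' @param bn_momentum Running-statistics momentum of batch normalization,
#'   default 0.1.
#' @return A `kcr_train_config` list.
#' @export
train_config <- function(optimizer = c("adam", "sgd"), learning_rate = 1e-3,
                         batch_size = 64L, max_epochs = 100L, patience = 10L,
                         validation_fraction = 0.1, seed = 1L,
                         class_threshold = 0.5, bn_momentum = 0.1) {
  optimizer <- match.arg(optimizer)
  cfg <- list(optimizer = optimizer, learning_rate = learning_rate,
              batch_size = as.integer(batch_size),
              max_epochs = as.integer(max_epochs),
              patience = as.integer(patience),
              validation_fraction = validation_fraction,
              seed = as.integer(seed), class_threshold = class_threshold,
              bn_momentum = bn_momentum)
  if (cfg$batch_size < 2L) stop("batch_size must be >= 2")
  if (cfg$validation_fraction <= 0 || cfg$validation_fraction >= 1) {
    stop("validation_fraction must be in (0, 1)")
  }
  if (cfg$patience > cfg$max_epochs) stop("patience must be <= max_epochs")
  if (cfg$max_epochs < 1L) stop("max_epochs must be >= 1")
  structure(cfg, class = "kcr_train_config")
}

# stratified index split: returns indices of the validation part
stratified_holdout <- function(y, fraction) {
  val <- integer(0)
  for (cls in unique(y)) {
    idx <- which(y == cls)
    n_val <- max(1L, round(length(idx) * fraction))
    val <- c(val, sample(idx, n_val))
  }
  sort(val)
}

#' Fit the network on an encoded dataset
#'
#' Minimizes the 2-class cross-entropy with minibatch gradient descent
#' (Adam by default), early-stopping on the loss of a stratified validation
#' split and restoring the best-epoch weights. All randomness
#' (initialization, shuffling, dropout, the validation split) is driven by
#' `train_config$seed`, so two runs with the same seed produce identical
#' histories.
#'
#' @param data List with `x` (array channels x length x n) and `y`
#'   (integer 0/1), as returned by [encode_dataset()].
#' @param model_config A [model_config()].
#' @param train_config A [train_config()].
#' @param verbose Print per-epoch progress? Default `FALSE`.
#' @return A `kcr_model`: list with flat `params` and `state` vectors, the
#'   configurations, the per-epoch `history` data frame (train/validation
#'   loss, validation accuracy) and `best_epoch`.
#' @export
fit <- function(data, model_config, train_config = train_config(),
                verbose = FALSE) {
  x <- as_batch(data$x)
  y <- as.integer(data$y)
  n <- dim(x)[3L]
  stopifnot(length(y) == n, n > 0L)
  if (anyNA(y)) stop("fit() needs labeled data; found NA labels")
  if (length(unique(y)) < 2L) {
    stop("training data contains a single class; need both positives and negatives")
  }
  stopifnot(dim(x)[1L] == model_config$input_channels,
            dim(x)[2L] == model_config$input_length)

  set.seed(train_config$seed)
  val_idx <- stratified_holdout(y, train_config$validation_fraction)
  tr_idx <- setdiff(seq_len(n), val_idx)
  xv <- x[, , val_idx, drop = FALSE]
  yv <- y[val_idx]
  init <- init_params(model_config)
  params <- init$params
  state <- init$state

  n_fc <- length(model_config$fc_sizes)
  keep <- 1 - model_config$dropout
  adam_m <- numeric(length(params))
  adam_v <- numeric(length(params))
  step <- 0L
  lr <- train_config$learning_rate

  best_loss <- Inf
  best_params <- params
  best_state <- state
  best_epoch <- 0L
  bad_epochs <- 0L
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric(), val_acc = numeric())

  flat <- function(xa) { d <- dim(xa); dim(xa) <- c(d[1L], d[2L] * d[3L]); xa }

  for (epoch in seq_len(train_config$max_epochs)) {
    ord <- sample(tr_idx)
    starts <- seq.int(1L, length(ord), by = train_config$batch_size)
    batch_losses <- numeric(0)
    for (s in starts) {
      idx <- ord[s:min(s + train_config$batch_size - 1L, length(ord))]
      if (length(idx) < 2L) next  # batch normalization needs >= 2 samples
      xb <- x[, , idx, drop = FALSE]
      masks <- list()
      if (model_config$dropout > 0 && n_fc > 0L) {
        masks <- lapply(model_config$fc_sizes, function(h) {
          matrix((runif(h * length(idx)) < keep) / keep, h, length(idx))
        })
      }
      res <- net_run_cpp(params, state, flat(xb), length(idx), y[idx],
                         model_config, TRUE, TRUE, masks,
                         train_config$bn_momentum)
      if (!is.finite(res$loss)) {
        stop(sprintf("non-finite training loss at epoch %d (step %d); try a lower learning rate",
                     epoch, step + 1L))
      }
      batch_losses <- c(batch_losses, res$loss)
      state <- res$state
      g <- res$grad
      if (train_config$optimizer == "adam") {
        step <- step + 1L
        adam_m <- 0.9 * adam_m + 0.1 * g
        adam_v <- 0.999 * adam_v + 0.001 * g * g
        mhat <- adam_m / (1 - 0.9^step)
        vhat <- adam_v / (1 - 0.999^step)
        params <- params - lr * mhat / (sqrt(vhat) + 1e-8)
      } else {
        params <- params - lr * g
      }
    }
    vres <- net_run_cpp(params, state, flat(xv), length(yv), yv,
                        model_config, FALSE, FALSE, list(),
                        train_config$bn_momentum)
    if (!is.finite(vres$loss)) {
      stop(sprintf("non-finite validation loss at epoch %d; try a lower learning rate",
                   epoch))
    }
    val_acc <- mean((vres$probs[, 2L] >= train_config$class_threshold) == (yv == 1L))
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = mean(batch_losses),
      val_loss = vres$loss, val_acc = val_acc))
    if (verbose) {
      log_msg("fit", "epoch %d train_loss %.4f val_loss %.4f val_acc %.4f",
              epoch, mean(batch_losses), vres$loss, val_acc)
    }
    if (vres$loss < best_loss - 1e-8) {
      best_loss <- vres$loss
      best_params <- params
      best_state <- state
      best_epoch <- epoch
      bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      if (bad_epochs >= train_config$patience) break
    }
  }
  structure(
    list(params = best_params, state = best_state, config = model_config,
         train_config = train_config, history = history,
         best_epoch = best_epoch),
    class = "kcr_model"
  )
}

#' @export
print.kcr_model <- function(x, ...) {
  cat(sprintf("<kcr_model> %d parameters, trained %d epoch(s), best epoch %d (val loss %.4f)\n",
              length(x$params), nrow(x$history), x$best_epoch,
              x$history$val_loss[x$best_epoch]))
  invisible(x)
}

#' Positive-class scores of a fitted network
#'
#' Evaluation-mode forward pass (running batch-norm statistics, no
#' dropout); deterministic given the model.
#'
#' @param model A fitted `kcr_model`.
#' @param x Encoded batch (array channels x length x n).
#' @return Numeric vector of positive-class probabilities.
#' @export
predict_scores <- function(model, x) {
  net_eval(model$params, model$state, x, model$config)$probs[, 2L]
}

#' Stratified k-fold assignments
#'
#' Folds partition the indices, sizes differ by at most one, and each fold's
#' class balance matches the global one as closely as the counts allow.
#' Deterministic for a fixed seed.
#'
#' @param n Number of samples.
#' @param labels Binary (or categorical) label vector of length `n`.
#' @param k Number of folds, default 5.
#' @param seed Integer seed.
#' @return A `kcr_folds`: list with `k` and `assignments` (integer fold id
#'   per index).
#' @export
make_folds <- function(n, labels, k = 5L, seed = 1L) {
  n <- as.integer(n)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  if (k > n) stop("k (", k, ") exceeds the number of samples (", n, ")")
  stopifnot(length(labels) == n)
  set.seed(seed)
  assignments <- integer(n)
  offset <- 0L
  for (cls in sort(unique(as.character(labels)))) {
    idx <- which(as.character(labels) == cls)
    idx <- sample(idx)
    folds <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    assignments[idx] <- folds
    offset <- (offset + length(idx)) %% k
  }
  structure(list(k = k, assignments = assignments), class = "kcr_folds")
}

#' k-fold cross-validation of the full pipeline
#'
#' For each fold, the word embedding is retrained on that fold's training
#' windows only (no information from the held-out fold reaches the
#' encoder), the network is fitted, and the held-out fold is scored.
#'
#' @param dataset A labeled [kcr_dataset].
#' @param model_config A [model_config()].
#' @param train_config A [train_config()]; fold `i` uses `seed + i`.
#' @param k Number of folds, default 5.
#' @param embedding_config Named list of [train_embedding()] arguments
#'   (`d` defaults to `model_config$input_channels`).
#' @param verbose Log per-fold progress?
#' @return A `kcr_cv`: list with `folds` (per-fold metric data frame),
#'   `summary` (mean and sd per metric) and the fold `assignments`.
#' @export
cross_validate <- function(dataset, model_config, train_config = train_config(),
                           k = 5L, embedding_config = list(), verbose = FALSE) {
  windows <- dataset$windows
  n <- nrow(windows)
  folds <- make_folds(n, windows$label, k = k, seed = train_config$seed)
  rows <- vector("list", k)
  for (i in seq_len(k)) {
    if (verbose) log_msg("cv", "fold %d/%d (seed %d)", i, k, train_config$seed + i)
    test_idx <- which(folds$assignments == i)
    train_idx <- setdiff(seq_len(n), test_idx)
    emb_args <- utils::modifyList(
      list(corpus = windows$residues[train_idx],
           d = model_config$input_channels,
           seed = train_config$seed + i),
      embedding_config)
    emb <- do.call(train_embedding, emb_args)
    enc_tr <- encode_dataset(windows[train_idx, ], emb)
    enc_te <- encode_dataset(windows[test_idx, ], emb)
    tc <- train_config
    tc$seed <- train_config$seed + i
    model <- fit(enc_tr, model_config, tc)
    scores <- predict_scores(model, enc_te$x)
    rep <- evaluate(scores, enc_te$y, threshold = train_config$class_threshold)
    rows[[i]] <- cbind(data.frame(fold = i, n_test = length(test_idx)),
                       as.data.frame(rep))
  }
  per_fold <- do.call(rbind, rows)
  metric_cols <- c("sn", "sp", "acc", "mcc", "auc")
  summary <- data.frame(
    metric = metric_cols,
    mean = vapply(metric_cols, function(m) mean(per_fold[[m]]), numeric(1)),
    sd = vapply(metric_cols, function(m) stats::sd(per_fold[[m]]), numeric(1)),
    row.names = NULL
  )
  structure(list(folds = per_fold, summary = summary,
                 assignments = folds$assignments, k = k),
            class = "kcr_cv")
}

#' @export
print.kcr_cv <- function(x, ...) {
  cat(sprintf("<kcr_cv> %d folds\n", x$k))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Grid search over dense-block depth and width
#'
#' Trains one model per (n_blocks, layers_per_block) combination on a
#' stratified training split and evaluates each on the held-out remainder.
#' Combinations whose repeated length-halving underflows the input length
#' are marked infeasible instead of failing. The best feasible row
#' maximizes accuracy, breaking ties by MCC and then by fewer parameters.
#'
#' @param dataset A labeled [kcr_dataset].
#' @param blocks_grid,layers_grid Integer vectors of candidate values.
#' @param train_config A [train_config()].
#' @param base_config [model_config()] whose other fields are reused.
#' @param embedding_config Named list of [train_embedding()] arguments.
#' @param holdout_fraction Evaluation split fraction, default 0.2.
#' @param verbose Log per-cell progress?
#' @return Data frame with one row per combination: the grid coordinates,
#'   `feasible`, `n_params`, the held-out metrics and a logical `best`
#'   column flagging the winner.
#' @export
grid_search <- function(dataset, blocks_grid, layers_grid,
                        train_config = train_config(),
                        base_config = model_config(),
                        embedding_config = list(),
                        holdout_fraction = 0.2, verbose = FALSE) {
  stopifnot(length(blocks_grid) > 0L, length(layers_grid) > 0L)
  windows <- dataset$windows
  n <- nrow(windows)
  set.seed(train_config$seed)
  test_idx <- stratified_holdout(ifelse(windows$label == "positive", 1L, 0L),
                                 holdout_fraction)
  train_idx <- setdiff(seq_len(n), test_idx)
  emb_args <- utils::modifyList(
    list(corpus = windows$residues[train_idx],
         d = base_config$input_channels, seed = train_config$seed),
    embedding_config)
  emb <- do.call(train_embedding, emb_args)
  enc_tr <- encode_dataset(windows[train_idx, ], emb)
  enc_te <- encode_dataset(windows[test_idx, ], emb)

  grid <- expand.grid(n_blocks = as.integer(blocks_grid),
                      layers_per_block = as.integer(layers_grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg_args <- unclass(base_config)
    cfg_args$n_blocks <- grid$n_blocks[i]
    cfg_args$layers_per_block <- grid$layers_per_block[i]
    cfg <- tryCatch(do.call(model_config, cfg_args), error = function(e) NULL)
    if (is.null(cfg)) {
      rows[[i]] <- data.frame(n_blocks = grid$n_blocks[i],
                              layers_per_block = grid$layers_per_block[i],
                              feasible = FALSE, n_params = NA_integer_,
                              sn = NA_real_, sp = NA_real_, acc = NA_real_,
                              mcc = NA_real_, auc = NA_real_)
      next
    }
    if (verbose) {
      log_msg("grid", "n_blocks %d layers %d", cfg$n_blocks, cfg$layers_per_block)
    }
    model <- fit(enc_tr, cfg, train_config)
    scores <- predict_scores(model, enc_te$x)
    rep <- evaluate(scores, enc_te$y, threshold = train_config$class_threshold)
    rows[[i]] <- cbind(
      data.frame(n_blocks = cfg$n_blocks,
                 layers_per_block = cfg$layers_per_block,
                 feasible = TRUE, n_params = summarize(cfg)$n_params),
      as.data.frame(rep)[c("sn", "sp", "acc", "mcc", "auc")])
  }
  out <- do.call(rbind, rows)
  out$best <- FALSE
  feas <- which(out$feasible)
  if (length(feas) > 0L) {
    ord <- feas[order(-out$acc[feas], -out$mcc[feas], out$n_params[feas])]
    out$best[ord[1L]] <- TRUE
  }
  rownames(out) <- NULL
  out
}
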