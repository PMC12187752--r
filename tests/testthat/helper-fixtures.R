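# shared fixtures: a deliberately small architecture and dataset so unit
# tests of the training loop stay fast; the full-size default configuration
# is exercised in test-acceptance.R

tiny_model_config <- function(...) {
  args <- utils::modifyList(
    list(n_blocks = 2L, layers_per_block = 1L, growth_rate = 8L,
         kernel_size = 3L, compression = 0.5, attention = "rcam",
         reduction_ratio = 4L, fc_sizes = 16L, dropout = 0.2,
         input_channels = 12L, input_length = 29L),
    list(...))
  do.call(model_config, args)
}

tiny_train_config <- function(...) {
  args <- utils::modifyList(
    list(batch_size = 32L, max_epochs = 8L, patience = 8L,
         validation_fraction = 0.15, seed = 7L),
    list(...))
  args$patience <- min(args$patience, args$max_epochs)
  do.call(train_config, args)
}

tiny_dataset <- function(n = 200L, strength = 1.0, seed = 5L) {
  generate(synthetic_config(n_pos = n %/% 2L, n_neg = n %/% 2L,
                            motif_strength = strength, seed = seed))
}

random_window <- function(len = 29L) {
  res <- sample(c("A", "C", "D", "E", "K", "L", "S"), len, replace = TRUE)
  res[(len + 1L) %/% 2L] <- "K"
  paste(res, collapse = "")
}
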