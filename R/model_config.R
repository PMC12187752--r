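#' Network architecture configuration
#'
#' Hyperparameters of the dense convolutional classifier. The backbone has
#' no initial convolution: the encoded `input_channels x input_length`
#' feature matrix enters the first dense block directly. Dense blocks are
#' separated by transition layers (batch normalization, 1x1 convolution
#' compressing channels, average pooling halving the length); the final
#' block's output is re-weighted by the configured channel attention before
#' the fully connected head.
#'
#' @param n_blocks Number of dense blocks, default 4.
#' @param layers_per_block Convolutional layers per dense block, default 2.
#' @param growth_rate Channels added by each dense-block convolution,
#'   default 32.
#' @param kernel_size Odd 1-D convolution kernel width, default 3.
#' @param compression Transition-layer channel compression in (0, 1],
#'   default 0.5.
#' @param attention `"rcam"` (residual channel attention, default), `"cam"`
#'   (plain channel attention) or `"none"`.
#' @param reduction_ratio Bottleneck reduction of the attention network,
#'   default 8; the bottleneck width `floor(C / reduction_ratio)` must be
#'   at least 1.
#' @param fc_sizes Hidden widths of the fully connected head, default 64.
#' @param dropout Dropout rate after each hidden head layer, default 0.5.
#' @param input_channels Encoding dimension (embedding `d` or one-hot
#'   `|V|`), default 80.
#' @param input_length Window length, default 29.
#' @return A `kcr_model_config` list.
#' @export
model_config <- function(n_blocks = 4L, layers_per_block = 2L, growth_rate = 32L,
                         kernel_size = 3L, compression = 0.5,
                         attention = c("rcam", "cam", "none"),
                         reduction_ratio = 8L, fc_sizes = 64L, dropout = 0.5,
                         input_channels = 80L, input_length = 29L) {
  attention <- match.arg(attention)
  cfg <- list(
    n_blocks = as.integer(n_blocks),
    layers_per_block = as.integer(layers_per_block),
    growth_rate = as.integer(growth_rate),
    kernel_size = as.integer(kernel_size),
    compression = as.numeric(compression),
    attention = attention,
    reduction_ratio = as.integer(reduction_ratio),
    fc_sizes = as.integer(fc_sizes),
    dropout = as.numeric(dropout),
    input_channels = as.integer(input_channels),
    input_length = as.integer(input_length)
  )
  if (cfg$n_blocks < 1L) stop("n_blocks must be >= 1")
  if (cfg$layers_per_block < 1L) stop("layers_per_block must be >= 1")
  if (cfg$growth_rate < 1L) stop("growth_rate must be >= 1")
  if (cfg$kernel_size < 1L || cfg$kernel_size %% 2L == 0L) {
    stop("kernel_size must be an odd integer >= 1")
  }
  if (cfg$compression <= 0 || cfg$compression > 1) {
    stop("compression must be in (0, 1]")
  }
  if (cfg$dropout < 0 || cfg$dropout >= 1) stop("dropout must be in [0, 1)")
  if (cfg$input_channels < 1L || cfg$input_length < 1L) {
    stop("input_channels and input_length must be >= 1")
  }
  feas <- config_feasible(cfg)
  if (!feas$feasible) {
    stop("infeasible architecture: ", feas$reason)
  }
  if (attention != "none") {
    C_att <- feas$attention_channels
    if (C_att %/% cfg$reduction_ratio < 1L) {
      stop(sprintf(
        "reduction_ratio %d leaves an empty attention bottleneck (%d channels at attention)",
        cfg$reduction_ratio, C_att))
    }
  }
  structure(cfg, class = "kcr_model_config")
}

# channel/length arithmetic shared by summarize(), param_layout() and the
# feasibility guard: block b adds layers_per_block * growth_rate channels;
# each transition maps C -> ceiling(compression * C) and L -> floor(L / 2)
stage_trace <- function(config) {
  C <- config$input_channels
  L <- config$input_length
  stage <- "input"; channels <- C; lengths <- L
  feasible <- TRUE; reason <- ""
  for (b in seq_len(config$n_blocks)) {
    C <- C + config$layers_per_block * config$growth_rate
    stage <- c(stage, sprintf("block%d", b))
    channels <- c(channels, C); lengths <- c(lengths, L)
    if (b < config$n_blocks) {
      if (L < 2L) {
        feasible <- FALSE
        reason <- sprintf("transition %d needs length >= 2, has %d", b, L)
        break
      }
      C <- as.integer(ceiling(config$compression * C - 1e-9))
      L <- L %/% 2L
      stage <- c(stage, sprintf("transition%d", b))
      channels <- c(channels, C); lengths <- c(lengths, L)
    }
  }
  if (feasible && config$attention != "none") {
    stage <- c(stage, "attention")
    channels <- c(channels, C); lengths <- c(lengths, L)
  }
  list(stages = data.frame(stage = stage, channels = channels,
                           length = lengths, stringsAsFactors = FALSE),
       feasible = feasible, reason = reason,
       attention_channels = C, final_channels = C, final_length = L)
}

config_feasible <- function(config) {
  stage_trace(config)
}

#' Per-stage shapes and parameter count of a configuration
#'
#' Computes the channel/length trace and the trainable parameter count by
#' closed-form arithmetic, without instantiating the network.
#'
#' @param config A [model_config()].
#' @return A `kcr_model_summary`: list with `stages` (data frame of stage,
#'   channels, length), `head_sizes` and `n_params`.
#' @export
summarize <- function(config) {
  tr <- stage_trace(config)
  if (!tr$feasible) stop("infeasible architecture: ", tr$reason)
  lay <- param_layout(config)
  head_sizes <- c(tr$final_channels * tr$final_length, config$fc_sizes, 2L)
  structure(
    list(stages = tr$stages, head_sizes = head_sizes,
         n_params = sum(lay$params$size), n_state = sum(lay$state$size)),
    class = "kcr_model_summary"
  )
}

#' @export
print.kcr_model_summary <- function(x, ...) {
  print(x$stages, row.names = FALSE)
  cat(sprintf("head: %s\ntrainable parameters: %d\n",
              paste(x$head_sizes, collapse = " -> "), x$n_params))
  invisible(x)
}

# flat parameter-vector layout; order must match the C++ walker in
# src/network.cpp exactly
param_layout <- function(config) {
  pn <- character(); pr <- integer(); pc <- integer()
  sn <- character(); ssz <- integer()
  add <- function(name, r, c) {
    pn <<- c(pn, name); pr <<- c(pr, as.integer(r)); pc <<- c(pc, as.integer(c))
  }
  add_bn <- function(prefix, C) {
    add(paste0(prefix, ".gamma"), C, 1L)
    add(paste0(prefix, ".beta"), C, 1L)
    sn <<- c(sn, paste0(prefix, ".running")); ssz <<- c(ssz, 2L * C)
  }
  C <- config$input_channels
  L <- config$input_length
  for (b in seq_len(config$n_blocks)) {
    for (l in seq_len(config$layers_per_block)) {
      pre <- sprintf("block%d.layer%d", b, l)
      add_bn(paste0(pre, ".bn"), C)
      add(paste0(pre, ".conv.W"), config$growth_rate, C * config$kernel_size)
      add(paste0(pre, ".conv.b"), config$growth_rate, 1L)
      C <- C + config$growth_rate
    }
    if (b < config$n_blocks) {
      pre <- sprintf("transition%d", b)
      add_bn(paste0(pre, ".bn"), C)
      Cout <- as.integer(ceiling(config$compression * C - 1e-9))
      add(paste0(pre, ".conv.W"), Cout, C)
      add(paste0(pre, ".conv.b"), Cout, 1L)
      C <- Cout
      L <- L %/% 2L
    }
  }
  if (config$attention != "none") {
    h <- max(1L, C %/% config$reduction_ratio)
    add("attention.W1", h, C)
    add("attention.b1", h, 1L)
    add("attention.W2", C, h)
    add("attention.b2", C, 1L)
  }
  D <- C * L
  for (i in seq_along(config$fc_sizes)) {
    add(sprintf("head.fc%d.W", i), config$fc_sizes[i], D)
    add(sprintf("head.fc%d.b", i), config$fc_sizes[i], 1L)
    D <- config$fc_sizes[i]
  }
  add("head.out.W", 2L, D)
  add("head.out.b", 2L, 1L)
  size <- pr * pc
  offset <- cumsum(c(0L, size))[seq_along(size)]
  soff <- cumsum(c(0L, ssz))[seq_along(ssz)]
  list(params = data.frame(name = pn, nrow = pr, ncol = pc, size = size,
                           offset = offset, stringsAsFactors = FALSE),
       state = data.frame(name = sn, size = ssz, offset = soff,
                          stringsAsFactors = FALSE))
}

# He-style initialization using the current R RNG stream; BN running
# statistics start at mean 0, variance 1
init_params <- function(config) {
  lay <- param_layout(config)
  p <- lay$params
  params <- numeric(sum(p$size))
  for (i in seq_len(nrow(p))) {
    idx <- p$offset[i] + seq_len(p$size[i])
    nm <- p$name[i]
    if (grepl("\\.gamma$", nm)) {
      params[idx] <- 1
    } else if (grepl("\\.(beta|b)$", nm) || grepl("\\.b[12]$", nm)) {
      params[idx] <- 0
    } else {
      fan_in <- p$ncol[i]
      params[idx] <- rnorm(p$size[i], sd = sqrt(2 / fan_in))
    }
  }
  state <- numeric(sum(lay$state$size))
  for (i in seq_len(nrow(lay$state))) {
    C <- lay$state$size[i] %/% 2L
    state[lay$state$offset[i] + C + seq_len(C)] <- 1  # running variances
  }
  list(params = params, state = state)
}

# flat vectors -> nested weight list consumed by the R reference forward
unpack_params <- function(config, params, state) {
  lay <- param_layout(config)
  p <- lay$params
  get <- function(name) {
    i <- match(name, p$name)
    m <- matrix(params[p$offset[i] + seq_len(p$size[i])], p$nrow[i], p$ncol[i])
    if (p$ncol[i] == 1L) as.numeric(m) else m
  }
  get_state <- function(name) {
    i <- match(name, lay$state$name)
    C <- lay$state$size[i] %/% 2L
    v <- state[lay$state$offset[i] + seq_len(2L * C)]
    list(mean = v[seq_len(C)], var = v[C + seq_len(C)])
  }
  blocks <- vector("list", config$n_blocks)
  transitions <- vector("list", max(config$n_blocks - 1L, 0L))
  for (b in seq_len(config$n_blocks)) {
    layers <- vector("list", config$layers_per_block)
    for (l in seq_len(config$layers_per_block)) {
      pre <- sprintf("block%d.layer%d", b, l)
      st <- get_state(paste0(pre, ".bn.running"))
      layers[[l]] <- list(gamma = get(paste0(pre, ".bn.gamma")),
                          beta = get(paste0(pre, ".bn.beta")),
                          mean = st$mean, var = st$var,
                          W = get(paste0(pre, ".conv.W")),
                          b = get(paste0(pre, ".conv.b")))
    }
    blocks[[b]] <- layers
    if (b < config$n_blocks) {
      pre <- sprintf("transition%d", b)
      st <- get_state(paste0(pre, ".bn.running"))
      transitions[[b]] <- list(gamma = get(paste0(pre, ".bn.gamma")),
                               beta = get(paste0(pre, ".bn.beta")),
                               mean = st$mean, var = st$var,
                               W = get(paste0(pre, ".conv.W")),
                               b = get(paste0(pre, ".conv.b")))
    }
  }
  attention <- NULL
  if (config$attention != "none") {
    attention <- list(W1 = get("attention.W1"), b1 = get("attention.b1"),
                      W2 = get("attention.W2"), b2 = get("attention.b2"))
  }
  head <- list()
  for (i in seq_along(config$fc_sizes)) {
    head[[i]] <- list(W = get(sprintf("head.fc%d.W", i)),
                      b = get(sprintf("head.fc%d.b", i)), relu = TRUE)
  }
  head[[length(head) + 1L]] <- list(W = get("head.out.W"),
                                    b = get("head.out.b"), relu = FALSE)
  list(blocks = blocks, transitions = transitions, attention = attention,
       head = head)
}
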