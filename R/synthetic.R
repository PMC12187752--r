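#' Background amino-acid frequencies
#'
#' `"uniform"` gives equal mass to the 20 canonical residues; `"natural"`
#' gives average composition frequencies of curated protein sequences.
#'
#' @param preset `"uniform"` (default) or `"natural"`.
#' @return Named numeric 20-vector summing to 1, in [AA20] order.
#' @export
aa_frequencies <- function(preset = c("uniform", "natural")) {
  preset <- match.arg(preset)
  if (preset == "uniform") {
    f <- rep(1 / 20, 20)
  } else {
    # average composition of curated proteins (percent, rounded)
    f <- c(A = 8.25, C = 1.38, D = 5.46, E = 6.72, F = 3.86, G = 7.07,
           H = 2.27, I = 5.91, K = 5.80, L = 9.65, M = 2.41, N = 4.06,
           P = 4.74, Q = 3.93, R = 5.53, S = 6.65, T = 5.36, V = 6.85,
           W = 1.10, Y = 2.92)
    f <- f / sum(f)
  }
  names(f) <- AA20
  f
}

#' Synthetic benchmark configuration
#'
#' Describes a generator of fixed-length lysine-centered peptide windows:
#' negatives are drawn from the background composition at every non-center
#' position; positives additionally carry a position-specific motif around
#' the central K, where each motif position takes its consensus residue
#' with probability `motif_strength` and a background draw otherwise.
#'
#' @param n_pos,n_neg Class sizes, default 1000 each.
#' @param window_length Odd window length, default 29.
#' @param motif_positions Offsets of the motif relative to the central K
#'   (0 excluded), default `c(-2, -1, 1, 2)`.
#' @param motif_residues Consensus residue per motif position, default
#'   `c("E", "D", "A", "L")`.
#' @param motif_strength Probability of the consensus residue at each motif
#'   position in positives, in [0, 1]; default 0.9.
#' @param background_freqs Background distribution over [AA20], default
#'   uniform.
#' @param seed Integer seed, default 1.
#' @return A `kcr_synth_config` list.
#' @export
synthetic_config <- function(n_pos = 1000L, n_neg = 1000L, window_length = 29L,
                             motif_positions = c(-2L, -1L, 1L, 2L),
                             motif_residues = c("E", "D", "A", "L"),
                             motif_strength = 0.9,
                             background_freqs = aa_frequencies("uniform"),
                             seed = 1L) {
  window_length <- as.integer(window_length)
  if (window_length < 3L || window_length %% 2L == 0L) {
    stop("window_length must be an odd integer >= 3")
  }
  flank <- (window_length - 1L) %/% 2L
  motif_positions <- as.integer(motif_positions)
  if (any(motif_positions == 0L) || any(abs(motif_positions) > flank)) {
    stop("motif_positions must be non-zero offsets within the window flanks")
  }
  if (length(motif_residues) != length(motif_positions)) {
    stop("motif_residues must match motif_positions in length")
  }
  if (!all(motif_residues %in% AA20)) stop("motif_residues must be canonical residues")
  if (motif_strength < 0 || motif_strength > 1) {
    stop("motif_strength must be in [0, 1]")
  }
  if (length(background_freqs) != 20L || any(background_freqs < 0) ||
      abs(sum(background_freqs) - 1) > 1e-8) {
    stop("background_freqs must be a 20-vector of probabilities summing to 1")
  }
  names(background_freqs) <- AA20
  structure(
    list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
         window_length = window_length, motif_positions = motif_positions,
         motif_residues = motif_residues, motif_strength = motif_strength,
         background_freqs = background_freqs, seed = as.integer(seed)),
    class = "kcr_synth_config"
  )
}

#' Generate a labeled synthetic window dataset
#'
#' Deterministic for a fixed `config$seed`. Both classes have `K` at the
#' center position.
#'
#' @param config A [synthetic_config()].
#' @return A labeled [kcr_dataset].
#' @export
generate <- function(config) {
  stopifnot(inherits(config, "kcr_synth_config"))
  set.seed(config$seed)
  L <- config$window_length
  center <- (L - 1L) %/% 2L + 1L  # 1-based
  draw_class <- function(n, positive) {
    m <- matrix(sample(AA20, n * L, replace = TRUE,
                       prob = config$background_freqs), nrow = n, ncol = L)
    m[, center] <- "K"
    if (positive && config$motif_strength > 0) {
      for (j in seq_along(config$motif_positions)) {
        col <- center + config$motif_positions[j]
        hit <- runif(n) < config$motif_strength
        m[hit, col] <- config$motif_residues[j]
      }
    }
    apply(m, 1L, paste, collapse = "")
  }
  pos <- draw_class(config$n_pos, TRUE)
  neg <- draw_class(config$n_neg, FALSE)
  windows <- data.frame(
    id = c(sprintf("pos_%05d", seq_len(config$n_pos)),
           sprintf("neg_%05d", seq_len(config$n_neg))),
    residues = c(pos, neg),
    center_index = (L - 1L) %/% 2L,
    label = c(rep("positive", config$n_pos), rep("negative", config$n_neg)),
    source_id = NA_character_,
    source_position = NA_integer_,
    stringsAsFactors = FALSE
  )
  kcr_dataset(windows)
}

#' Bayes-optimal accuracy of the planted synthetic model
#'
#' Computed exactly from the two known generative distributions. Only the
#' motif positions differ between the classes, and conditional on whether a
#' position carries its consensus residue the classes agree, so the vector
#' of per-position consensus matches is a sufficient statistic. The
#' likelihood ratio is enumerated over all 2^m match patterns and the
#' balanced-prior Bayes accuracy `1/2 + TV/2` is returned, where TV is the
#' total-variation distance between the two pattern distributions.
#'
#' @param config A [synthetic_config()].
#' @return Bayes accuracy in [0.5, 1]; 0.5 when `motif_strength = 0`.
#' @export
expected_separability <- function(config) {
  stopifnot(inherits(config, "kcr_synth_config"))
  s <- config$motif_strength
  q <- config$background_freqs[config$motif_residues]
  p1 <- s + (1 - s) * q  # consensus-match probability in positives
  p0 <- q                # ... and in negatives
  m <- length(q)
  tv <- 0
  for (bits in 0:(2^m - 1)) {
    match <- as.logical(bitwAnd(bits, 2^(seq_len(m) - 1L)))
    pr1 <- prod(ifelse(match, p1, 1 - p1))
    pr0 <- prod(ifelse(match, p0, 1 - p0))
    tv <- tv + abs(pr1 - pr0)
  }
  0.5 + tv / 4  # tv accumulated unhalved: TV = tv/2, acc = 1/2 + TV/2
}
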