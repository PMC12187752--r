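#' Tokenize a peptide window into overlapping k-mers
#'
#' Tokens are the substrings of length `k` starting at positions
#' 1, 1 + stride, 1 + 2 * stride, ... that fit inside the window. With the
#' default 1-mers at stride 1 the token count equals the window length.
#'
#' @param residues A single residue string.
#' @param k k-mer length, default 1.
#' @param stride Step between token start positions, default 1.
#' @return Character vector of tokens.
#' @export
#' @examples
#' tokenize("KAKA", k = 2)
tokenize <- function(residues, k = 1L, stride = 1L) {
  stopifnot(length(residues) == 1L, is.character(residues))
  n <- nchar(residues)
  if (k < 1L || k > n) stop("k must be in [1, ", n, "], got ", k)
  if (stride < 1L) stop("stride must be >= 1")
  starts <- seq.int(1L, n - k + 1L, by = stride)
  substring(residues, starts, starts + k - 1L)
}

tokenize_corpus <- function(residues, k = 1L, stride = 1L) {
  lapply(residues, tokenize, k = k, stride = stride)
}

#' Build a token vocabulary from a corpus
#'
#' Tokens are ordered lexicographically; the pad and unknown tokens are
#' appended at the end (and are always present, whether or not they occur in
#' the corpus). The same corpus always yields the same vocabulary.
#'
#' @param corpus A list of token vectors (see [tokenize()]), or a character
#'   vector of window strings which is tokenized with `k = 1`.
#' @param pad_token,unk_token Pad and unknown symbols, defaults `"-"`, `"X"`.
#' @return A `kcr_vocab`: list with `tokens`, `pad_token`, `unk_token`.
#' @export
build_vocabulary <- function(corpus, pad_token = PAD_TOKEN, unk_token = UNK_TOKEN) {
  if (is.character(corpus)) corpus <- tokenize_corpus(corpus)
  if (length(corpus) == 0L) stop("empty corpus")
  toks <- sort(unique(unlist(corpus, use.names = FALSE)))
  toks <- setdiff(toks, c(pad_token, unk_token))
  structure(
    list(tokens = c(toks, pad_token, unk_token),
         pad_token = pad_token, unk_token = unk_token),
    class = "kcr_vocab"
  )
}

#' @export
print.kcr_vocab <- function(x, ...) {
  cat(sprintf("<kcr_vocab> %d tokens (pad '%s', unknown '%s')\n",
              length(x$tokens), x$pad_token, x$unk_token))
  invisible(x)
}

# token -> 1-based index, unknown tokens fall back to the unk token
vocab_index <- function(vocab, tokens) {
  i <- match(tokens, vocab$tokens)
  unk <- match(vocab$unk_token, vocab$tokens)
  i[is.na(i)] <- unk
  i
}

#' One-hot encode a peptide window
#'
#' @param residues A single window string.
#' @param vocab A [build_vocabulary()] vocabulary.
#' @param k,stride Tokenization parameters, defaults 1/1.
#' @return A `|V| x L` binary matrix; each column has exactly one 1.
#' @export
one_hot_encode <- function(residues, vocab, k = 1L, stride = 1L) {
  toks <- tokenize(residues, k = k, stride = stride)
  idx <- vocab_index(vocab, toks)
  m <- matrix(0, nrow = length(vocab$tokens), ncol = length(toks),
              dimnames = list(vocab$tokens, NULL))
  m[cbind(idx, seq_along(idx))] <- 1
  m
}

#' Train a k-mer word embedding on a window corpus
#'
#' Trains a two-layer skip-gram model with negative sampling over the token
#' sequences of the corpus and returns the input-side weight matrix: one
#' `d`-dimensional dense vector per vocabulary token (pad and unknown tokens
#' receive trained rows like any other token). Training is single-threaded
#' and bit-reproducible for a fixed seed.
#'
#' @param corpus Character vector of window strings, or a list of token
#'   vectors.
#' @param d Embedding dimension, default 80.
#' @param context_window Skip-gram context half-width, default 5.
#' @param epochs Passes over the corpus, default 25.
#' @param seed Integer RNG seed for the embedding trainer.
#' @param k,stride Tokenization parameters, defaults 1/1.
#' @param negative Negative samples per context pair, default 5.
#' @param learning_rate Initial learning rate (linearly decayed), default 0.025.
#' @param vocab Optional pre-built vocabulary; built from the corpus if `NULL`.
#' @return A `kcr_embedding`: list with `weights` (`|V| x d`, row names are
#'   tokens), `vocab`, `k`, `stride`, `d`.
#' @export
train_embedding <- function(corpus, d = 80L, context_window = 5L, epochs = 25L,
                            seed = 1L, k = 1L, stride = 1L, negative = 5L,
                            learning_rate = 0.025, vocab = NULL) {
  if (d < 1L) stop("embedding dimension d must be >= 1")
  if (is.character(corpus)) corpus <- tokenize_corpus(corpus, k = k, stride = stride)
  if (length(corpus) == 0L) stop("empty corpus")
  if (is.null(vocab)) vocab <- build_vocabulary(corpus)
  docs <- lapply(corpus, function(toks) as.integer(vocab_index(vocab, toks) - 1L))
  w <- sgns_train_cpp(docs, length(vocab$tokens), as.integer(d),
                      as.integer(context_window), as.integer(negative),
                      as.integer(epochs), learning_rate, as.integer(seed))
  rownames(w) <- vocab$tokens
  structure(
    list(weights = w, vocab = vocab, k = as.integer(k),
         stride = as.integer(stride), d = as.integer(d),
         context_window = as.integer(context_window),
         epochs = as.integer(epochs), seed = as.integer(seed)),
    class = "kcr_embedding"
  )
}

#' @export
print.kcr_embedding <- function(x, ...) {
  cat(sprintf("<kcr_embedding> %d tokens x %d dimensions (%d-mers, stride %d)\n",
              nrow(x$weights), x$d, x$k, x$stride))
  invisible(x)
}

#' Encode a peptide window with a trained embedding
#'
#' Column `j` of the result is the embedding row of token `j`; the result
#' equals the embedding weight matrix (transposed) multiplied by the one-hot
#' encoding of the window.
#'
#' @param residues A single window string.
#' @param embedding A [train_embedding()] result.
#' @return A `d x L` feature matrix.
#' @export
embed_encode <- function(residues, embedding) {
  toks <- tokenize(residues, k = embedding$k, stride = embedding$stride)
  idx <- vocab_index(embedding$vocab, toks)
  m <- t(embedding$weights[idx, , drop = FALSE])
  dimnames(m) <- NULL
  m
}

#' Encode a dataset into a feature array
#'
#' @param dataset A [kcr_dataset] or a window `data.frame`.
#' @param encoder A `kcr_embedding` (dense encoding) or a `kcr_vocab`
#'   (one-hot baseline encoding).
#' @return List with `x` (array `channels x length x n`), `y` (integer 0/1,
#'   `NA` for unlabeled windows) and `ids`.
#' @export
encode_dataset <- function(dataset, encoder) {
  windows <- if (inherits(dataset, "kcr_dataset")) dataset$windows else dataset
  n <- nrow(windows)
  if (n == 0L) stop("no windows to encode")
  enc1 <- if (inherits(encoder, "kcr_embedding")) {
    function(res) embed_encode(res, encoder)
  } else if (inherits(encoder, "kcr_vocab")) {
    function(res) one_hot_encode(res, encoder)
  } else {
    stop("encoder must be a kcr_embedding or a kcr_vocab")
  }
  first <- enc1(windows$residues[1L])
  x <- array(0, dim = c(nrow(first), ncol(first), n))
  x[, , 1L] <- first
  if (n > 1L) for (i in 2:n) x[, , i] <- enc1(windows$residues[i])
  y <- ifelse(windows$label == "positive", 1L,
              ifelse(windows$label == "negative", 0L, NA_integer_))
  list(x = x, y = as.integer(y), ids = windows$id)
}

#' Export an embedding as a TSV table
#'
#' One line per token: the token followed by its `d` weights, tab-separated.
#'
#' @param embedding A `kcr_embedding`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embedding_tsv <- function(embedding, path) {
  df <- data.frame(token = rownames(embedding$weights),
                   embedding$weights, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an embedding TSV written by [write_embedding_tsv()]
#'
#' @param path TSV path.
#' @param k,stride Tokenization parameters the embedding was trained with.
#' @return A `kcr_embedding` (vocabulary reconstructed from the token column).
#' @export
read_embedding_tsv <- function(path, k = 1L, stride = 1L) {
  df <- utils::read.table(path, sep = "\t", quote = "", comment.char = "",
                          stringsAsFactors = FALSE)
  w <- as.matrix(df[, -1L, drop = FALSE])
  rownames(w) <- df[[1L]]
  colnames(w) <- NULL
  vocab <- structure(
    list(tokens = df[[1L]], pad_token = PAD_TOKEN, unk_token = UNK_TOKEN),
    class = "kcr_vocab"
  )
  structure(
    list(weights = w, vocab = vocab, k = as.integer(k),
         stride = as.integer(stride), d = ncol(w),
         context_window = NA_integer_, epochs = NA_integer_,
         seed = NA_integer_),
    class = "kcr_embedding"
  )
}
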