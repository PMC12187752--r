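#' Read protein sequences from a FASTA file
#'
#' Parses a (possibly multi-line) FASTA file into one record per header.
#' Sequence lines are concatenated, whitespace is stripped and residues are
#' upper-cased. Non-canonical residue codes (B, J, O, U, Z and anything else
#' outside the 20 standard letters) are mapped to the unknown symbol `"X"`;
#' the gap/pad symbol `"-"` is kept as is.
#'
#' @param path Path to a FASTA file.
#' @param normalize Map non-canonical residues to `"X"`? Default `TRUE`.
#' @return A `data.frame` with columns `id` (header text without the
#'   leading `>`) and `residues`, in file order.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "MKV"), f)
#' read_fasta(f)
read_fasta <- function(path, normalize = TRUE) {
  if (!file.exists(path)) stop_data("FASTA file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop_data("empty FASTA file: %s", path)
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop_data("parse error in %s at line %d: sequence data before any header",
              path, first)
  }
  seqs <- Biostrings::readBStringSet(path)
  ids <- names(seqs)
  residues <- toupper(gsub("[[:space:]]", "", as.character(seqs)))
  empty <- !nzchar(residues)
  if (any(empty)) {
    stop_data("record '%s' in %s has an empty sequence", ids[which(empty)[1L]], path)
  }
  if (normalize) residues <- normalize_residues(residues)
  data.frame(id = unname(ids), residues = unname(residues),
             stringsAsFactors = FALSE)
}

#' Normalize residue strings
#'
#' Upper-cases and maps every character outside the 20 canonical amino-acid
#' letters (keeping the pad symbol `"-"`) to the unknown symbol `"X"`.
#'
#' @param residues Character vector of residue strings.
#' @return Normalized character vector.
#' @export
normalize_residues <- function(residues) {
  residues <- toupper(residues)
  gsub(sprintf("[^%s-]", paste(AA20, collapse = "")), UNK_TOKEN, residues)
}

#' Write peptide windows or sequence records to FASTA
#'
#' Writes one single-line record per row; `read_fasta()` on the output
#' reproduces `id` and `residues` exactly.
#'
#' @param x A `data.frame` with columns `id` and `residues` (as returned by
#'   [read_fasta()] or [extract_windows()]), or a `kcr_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, "kcr_dataset")) x <- x$windows
  stopifnot(is.data.frame(x), all(c("id", "residues") %in% names(x)))
  set <- Biostrings::BStringSet(x$residues)
  names(set) <- x$id
  Biostrings::writeXStringSet(set, filepath = path, width = 100000L)
  invisible(path)
}

#' Extract lysine-centered peptide windows from protein sequences
#'
#' Produces one fixed-length window per `K` residue, centered on that lysine.
#' Windows running off either end of the sequence are filled with the pad
#' symbol, so every K site yields a window of exactly `window_length`
#' residues.
#'
#' @param records A `data.frame` with columns `id` and `residues`, or a list
#'   with elements `id` and `residues` for a single sequence.
#' @param window_length Odd window length, default 29.
#' @param pad_symbol Single pad character for overhanging positions,
#'   default `"-"`.
#' @return A `data.frame` of unlabeled windows with columns `id`,
#'   `residues`, `center_index` (0-based position of the central K),
#'   `label`, `source_id` and `source_position` (1-based K index in the
#'   parent sequence).
#' @export
extract_windows <- function(records, window_length = 29L, pad_symbol = PAD_TOKEN) {
  if (!is.data.frame(records)) {
    records <- data.frame(id = records$id, residues = records$residues,
                          stringsAsFactors = FALSE)
  }
  window_length <- as.integer(window_length)
  if (window_length < 3L || window_length %% 2L == 0L) {
    stop("window_length must be an odd integer >= 3, got ", window_length)
  }
  stopifnot(nchar(pad_symbol) == 1L)
  flank <- (window_length - 1L) %/% 2L
  out <- lapply(seq_len(nrow(records)), function(i) {
    res <- records$residues[i]
    kpos <- which(strsplit(res, "")[[1]] == "K")
    if (length(kpos) == 0L) return(NULL)
    padded <- paste0(strrep(pad_symbol, flank), res, strrep(pad_symbol, flank))
    windows <- substring(padded, kpos, kpos + window_length - 1L)
    data.frame(
      id = sprintf("%s_K%d", records$id[i], kpos),
      residues = windows,
      center_index = flank,
      label = "unlabeled",
      source_id = records$id[i],
      source_position = kpos,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(id = character(), residues = character(),
                      center_index = integer(), label = character(),
                      source_id = character(), source_position = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Assemble a labeled dataset from window data frames
#'
#' @param windows A window `data.frame` with at least `id`, `residues`
#'   and `label` columns; `label` must be `"positive"`, `"negative"` or
#'   `"unlabeled"`.
#' @return A `kcr_dataset`: a list with elements `windows` and `counts`
#'   (named vector `n_positive`, `n_negative`).
#' @export
kcr_dataset <- function(windows) {
  stopifnot(is.data.frame(windows),
            all(c("id", "residues", "label") %in% names(windows)))
  stopifnot(all(windows$label %in% c("positive", "negative", "unlabeled")))
  structure(
    list(windows = windows,
         counts = c(n_positive = sum(windows$label == "positive"),
                    n_negative = sum(windows$label == "negative"))),
    class = "kcr_dataset"
  )
}

#' @export
print.kcr_dataset <- function(x, ...) {
  cat(sprintf("<kcr_dataset> %d windows (%d positive, %d negative), length %s\n",
              nrow(x$windows), x$counts[["n_positive"]], x$counts[["n_negative"]],
              paste(unique(nchar(x$windows$residues)), collapse = "/")))
  invisible(x)
}

#' Load a labeled positive/negative FASTA window pair
#'
#' Reads two FASTA files of fixed-length peptide windows; records in the
#' first are labeled positive, in the second negative. Every record is
#' length-checked, and windows whose central residue is not `K` are rejected
#' (or kept with a warning).
#'
#' @param pos_path,neg_path FASTA files of positive / negative windows.
#' @param window_length Expected window length, default 29.
#' @param on_noncenter `"reject"` (default) to error on a non-K center,
#'   `"warn"` to keep the window with a warning.
#' @return A [kcr_dataset].
#' @export
load_labeled_pair <- function(pos_path, neg_path, window_length = 29L,
                              on_noncenter = c("reject", "warn")) {
  on_noncenter <- match.arg(on_noncenter)
  window_length <- as.integer(window_length)
  flank <- (window_length - 1L) %/% 2L
  load_one <- function(path, label) {
    recs <- read_fasta(path)
    bad <- which(nchar(recs$residues) != window_length)
    if (length(bad) > 0L) {
      stop_data("record '%s' in %s has length %d, expected %d",
                recs$id[bad[1L]], path, nchar(recs$residues[bad[1L]]),
                window_length)
    }
    center <- substr(recs$residues, flank + 1L, flank + 1L)
    nonk <- which(center != "K")
    if (length(nonk) > 0L) {
      msg <- sprintf("%d window(s) in %s (e.g. '%s') do not have K at the center",
                     length(nonk), path, recs$id[nonk[1L]])
      if (on_noncenter == "reject") stop_data("%s", msg) else warning(msg)
    }
    dup <- duplicated(recs$id)
    if (any(dup)) {
      warning(sprintf("duplicate record id(s) in %s, e.g. '%s'",
                      path, recs$id[which(dup)[1L]]))
    }
    data.frame(id = recs$id, residues = recs$residues,
               center_index = flank, label = label,
               source_id = recs$id, source_position = NA_integer_,
               stringsAsFactors = FALSE)
  }
  windows <- rbind(load_one(pos_path, "positive"),
                   load_one(neg_path, "negative"))
  kcr_dataset(windows)
}
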