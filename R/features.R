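#' Vectorizer configuration
#'
#' Settings for turning normalized certificate text into binary n-gram
#' features. Defaults follow the surveillance method: words, bigrams and
#' trigrams (`ngram_min = 1`, `ngram_max = 3`), stop words excluded before
#' n-gram formation (so previously non-adjacent words may join), tokens
#' shorter than two characters dropped, and any n-gram appearing in fewer
#' than five documents discarded.
#'
#' @param ngram_min,ngram_max Inclusive n-gram length range, `1 <= ngram_min
#'   <= ngram_max`.
#' @param min_count Minimum frequency for an n-gram to enter the vocabulary
#'   (default 5).
#' @param stop_words Character vector of lowercase stop words.
#' @param count Frequency basis for `min_count`: `"document"` (number of
#'   documents containing the n-gram, the default) or `"total"` (total
#'   occurrences across the corpus).
#' @param token_min_chars Minimum token length; shorter alphanumeric runs
#'   are dropped (default 2).
#' @return A list of class `vectorizer_config`.
#' @export
vectorizer_config <- function(ngram_min = 1L, ngram_max = 3L, min_count = 5L,
                              stop_words = od_stop_words(),
                              count = c("document", "total"),
                              token_min_chars = 2L) {
  count <- match.arg(count)
  ngram_min <- as.integer(ngram_min)
  ngram_max <- as.integer(ngram_max)
  min_count <- as.integer(min_count)
  stopifnot(ngram_min >= 1L, ngram_min <= ngram_max, min_count >= 1L,
            token_min_chars >= 1L)
  structure(list(ngram_min = ngram_min, ngram_max = ngram_max,
                 min_count = min_count,
                 stop_words = sort(unique(tolower(stop_words))),
                 count = count,
                 token_min_chars = as.integer(token_min_chars)),
            class = "vectorizer_config")
}

#' Tokenize normalized text
#'
#' Extracts maximal alphanumeric runs, in order, of at least `min_chars`
#' characters (single characters are dropped by default). Capitalization is
#' preserved: certificate text arrives fully capitalized and is used
#' unaltered.
#'
#' @param text A single normalized string (see [normalize_text()]).
#' @param min_chars Minimum token length (default 2).
#' @return Character vector of tokens (possibly empty).
#' @examples
#' tokenize("ACUTE COCAINE TOXICITY")
#' @export
tokenize <- function(text, min_chars = 2L) {
  if (is.na(text) || !nzchar(text)) return(character(0))
  pattern <- sprintf("[A-Za-z0-9]{%d,}", as.integer(min_chars))
  regmatches(text, gregexpr(pattern, text))[[1]]
}

#' Remove stop words from a token sequence
#'
#' Tokens whose lowercase form is in `stop_words` are deleted; the remaining
#' tokens close ranks and become adjacent, so n-grams formed afterwards may
#' join words that were separated by a stop word in the original text.
#'
#' @param tokens Character vector of tokens.
#' @param stop_words Character vector of lowercase stop words.
#' @return Filtered token vector.
#' @export
remove_stop_words <- function(tokens, stop_words = od_stop_words()) {
  tokens[!(tolower(tokens) %in% stop_words)]
}

#' Enumerate contiguous n-grams of a token sequence
#'
#' All contiguous runs of `ngram_min` to `ngram_max` tokens, joined by a
#' single space, shorter n first, left to right within each length.
#'
#' @param tokens Character vector of tokens (stop words already removed).
#' @param ngram_min,ngram_max Inclusive n-gram length range.
#' @return Character vector of n-gram strings.
#' @examples
#' extract_ngrams(c("ACUTE", "COCAINE", "TOXICITY"), 1, 2)
#' @export
extract_ngrams <- function(tokens, ngram_min = 1L, ngram_max = 3L) {
  n <- length(tokens)
  out <- vector("list", ngram_max - ngram_min + 1L)
  k <- 0L
  for (len in seq.int(ngram_min, ngram_max)) {
    k <- k + 1L
    if (n < len) next
    if (len == 1L) {
      out[[k]] <- tokens
    } else {
      starts <- seq_len(n - len + 1L)
      mat <- vapply(seq_len(len) - 1L, function(off) tokens[starts + off],
                    character(length(starts)))
      if (length(starts) == 1L) mat <- matrix(mat, nrow = 1L)
      out[[k]] <- apply(mat, 1L, paste, collapse = " ")
    }
  }
  unlist(out, use.names = FALSE) %||% character(0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# tokenize -> stop-word removal -> n-grams, for one document
doc_ngrams <- function(text, cfg) {
  tok <- remove_stop_words(tokenize(text, cfg$token_min_chars),
                           cfg$stop_words)
  extract_ngrams(tok, cfg$ngram_min, cfg$ngram_max)
}

#' Build an n-gram vocabulary from a corpus
#'
#' Runs the tokenize / stop-word / n-gram pipeline over every document,
#' counts each n-gram (document frequency by default), discards n-grams
#' below `min_count`, and assigns column indices in lexicographic (C-locale)
#' order so the vocabulary is deterministic.
#'
#' @param corpus Character vector of normalized texts (see
#'   [combine_fields()]); must be non-empty.
#' @param config A [vectorizer_config()].
#' @return An object of class `od_vocabulary`: list with `ngrams` (ordered
#'   character vector), `index` (1-based column indices), `count` (the
#'   frequency basis actually counted), and `config`.
#' @export
fit_vocabulary <- function(corpus, config = vectorizer_config()) {
  if (!length(corpus)) {
    stop("corpus is empty: cannot fit a vocabulary", call. = FALSE)
  }
  stopifnot(inherits(config, "vectorizer_config"))
  per_doc <- lapply(corpus, doc_ngrams, cfg = config)
  pooled <- if (config$count == "document") {
    unlist(lapply(per_doc, unique), use.names = FALSE)
  } else {
    unlist(per_doc, use.names = FALSE)
  }
  counts <- table(pooled)
  keep <- names(counts)[counts >= config$min_count]
  keep <- sort(keep, method = "radix")
  structure(list(ngrams = keep,
                 index = seq_along(keep),
                 count = as.integer(counts[keep]),
                 config = config),
            class = "od_vocabulary")
}

#' @export
length.od_vocabulary <- function(x) length(x$ngrams)

#' @export
print.od_vocabulary <- function(x, ...) {
  n_tok <- lengths(strsplit(x$ngrams, " ", fixed = TRUE))
  cat(sprintf("n-gram vocabulary: %d features (%s)\n", length(x$ngrams),
              paste(sprintf("%d %d-grams", tabulate(n_tok), seq_along(tabulate(n_tok)))[tabulate(n_tok) > 0],
                    collapse = ", ")))
  cat(sprintf("  n-gram range %d-%d, min %s count %d\n",
              x$config$ngram_min, x$config$ngram_max,
              x$config$count, x$config$min_count))
  invisible(x)
}

#' Transform texts into a binary document-by-feature matrix
#'
#' Entry (i, j) is 1 iff vocabulary n-gram j occurs at least once in text i
#' (binary presence, not a count). N-grams of a text that are absent from
#' the vocabulary are ignored, so unseen tokens in later (test-year) data
#' contribute nothing.
#'
#' @param texts Character vector of normalized texts.
#' @param vocab An `od_vocabulary` from [fit_vocabulary()].
#' @return A sparse `dgCMatrix` (`Matrix` package) with `length(texts)` rows
#'   and `length(vocab)` columns, column names the vocabulary n-grams.
#' @export
transform_texts <- function(texts, vocab) {
  stopifnot(inherits(vocab, "od_vocabulary"))
  hits <- lapply(texts, function(txt) {
    grams <- unique(doc_ngrams(txt, vocab$config))
    idx <- match(grams, vocab$ngrams)
    idx[!is.na(idx)]
  })
  j <- unlist(hits, use.names = FALSE)
  i <- rep.int(seq_along(texts), lengths(hits))
  Matrix::sparseMatrix(i = i, j = j, x = 1,
                       dims = c(length(texts), length(vocab$ngrams)),
                       dimnames = list(NULL, vocab$ngrams))
}

#' Persist a vocabulary to a JSON sidecar
#'
#' Writes the n-grams, indices, counts and the full vectorizer
#' configuration (including the stop-word list, which is needed to
#' reproduce the transform) as plain-text JSON. [read_vocabulary()] restores
#' an identical object.
#'
#' @param vocab An `od_vocabulary`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vocabulary <- function(vocab, path) {
  stopifnot(inherits(vocab, "od_vocabulary"))
  payload <- list(
    config = list(ngram_min = vocab$config$ngram_min,
                  ngram_max = vocab$config$ngram_max,
                  min_count = vocab$config$min_count,
                  count = vocab$config$count,
                  token_min_chars = vocab$config$token_min_chars,
                  stop_words = vocab$config$stop_words),
    entries = data.frame(ngram = vocab$ngrams, index = vocab$index,
                         count = vocab$count, stringsAsFactors = FALSE)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Restore a vocabulary written by [write_vocabulary()]
#'
#' @param path Path to the JSON sidecar.
#' @return An `od_vocabulary` identical to the one written.
#' @export
read_vocabulary <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- vectorizer_config(ngram_min = payload$config$ngram_min,
                           ngram_max = payload$config$ngram_max,
                           min_count = payload$config$min_count,
                           stop_words = payload$config$stop_words,
                           count = payload$config$count,
                           token_min_chars = payload$config$token_min_chars)
  entries <- payload$entries
  if (!length(entries) || !nrow(entries)) {
    entries <- data.frame(ngram = character(0), index = integer(0),
                          count = integer(0))
  }
  ord <- order(entries$index)
  structure(list(ngrams = as.character(entries$ngram)[ord],
                 index = as.integer(entries$index)[ord],
                 count = as.integer(entries$count)[ord],
                 config = cfg),
            class = "od_vocabulary")
}
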