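#' Construct a rule-based phrase list
#'
#' The rule-based baseline classifies a certificate as an overdose death iff
#' its combined free text contains any phrase from a curated list of
#' overdose-indicative words and bigrams. Phrases are normalized with the
#' same pipeline as certificate text (uppercase, punctuation to space) and
#' deduplicated; each must be one or two tokens unless `allow_long = TRUE`.
#'
#' @param phrases Character vector of words/bigrams.
#' @param source Free-text provenance note stored with the list.
#' @param allow_long Permit phrases longer than two tokens (off by default;
#'   the method is defined over words and bigrams).
#' @return An object of class `od_phrases`.
#' @export
phrase_list <- function(phrases, source = "user", allow_long = FALSE) {
  norm <- normalize_text(phrases)
  norm <- norm[nzchar(norm)]
  toks <- lapply(norm, tokenize, min_chars = 1L)
  empty <- lengths(toks) == 0L
  norm <- norm[!empty]; toks <- toks[!empty]
  n_tok <- lengths(toks)
  if (any(n_tok > 2L) && !allow_long) {
    stop("phrase(s) longer than 2 tokens: ",
         paste(norm[n_tok > 2L], collapse = "; "),
         " (set allow_long = TRUE to keep them)", call. = FALSE)
  }
  canon <- vapply(toks, paste, "", collapse = " ")
  dup <- duplicated(canon)
  structure(list(phrases = canon[!dup], tokens = toks[!dup],
                 source = source),
            class = "od_phrases")
}

#' @export
length.od_phrases <- function(x) length(x$phrases)

#' @export
print.od_phrases <- function(x, ...) {
  cat(sprintf("rule-based phrase list: %d phrases (%s)\n",
              length(x$phrases), x$source))
  cat(strwrap(paste(x$phrases, collapse = ", "), width = 76,
              prefix = "  "), sep = "\n")
  invisible(x)
}

#' Read a phrase list from a plain-text file
#'
#' One phrase per line, UTF-8; `#` starts a comment; blank lines skipped.
#'
#' @param path Path to the file.
#' @inheritParams phrase_list
#' @return An `od_phrases` object.
#' @export
read_phrase_list <- function(path, source = path, allow_long = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  phrase_list(lines[nzchar(lines)], source = source, allow_long = allow_long)
}

#' The default overdose phrase list shipped with the package
#'
#' A constructed stand-in for the kind of 37-term word/bigram list an
#' overdose-surveillance epidemiologist would curate from a review of coded
#' certificates: generic overdose terms plus common substance names. It is
#' synthetic (not any jurisdiction's operational list) and fully
#' replaceable via [read_phrase_list()].
#'
#' @return An `od_phrases` object.
#' @export
default_phrase_list <- function() {
  read_phrase_list(system.file("extdata", "synthetic_phrase_list.txt",
                               package = "odcert", mustWork = TRUE),
                   source = "odcert synthetic default")
}

#' Rule-based overdose classification
#'
#' A text is classified positive iff any phrase occurs as a contiguous
#' token subsequence of the text. Matching is on token boundaries, never
#' raw substrings: the phrase "OD" does not fire on "METHOD".
#'
#' @param texts Character vector of normalized texts (see
#'   [combine_fields()]).
#' @param phrases An `od_phrases` list.
#' @return Logical vector, one per text.
#' @export
rule_classify <- function(texts, phrases) {
  stopifnot(inherits(phrases, "od_phrases"))
  n_tok <- lengths(phrases$tokens)
  uni <- phrases$phrases[n_tok == 1L]
  multi <- phrases$phrases[n_tok > 1L]
  max_len <- if (length(multi)) max(n_tok) else 1L
  vapply(texts, function(txt) {
    toks <- tokenize(txt, min_chars = 1L)
    if (!length(toks)) return(FALSE)
    if (length(uni) && any(toks %in% uni)) return(TRUE)
    for (len in 2:max_len) {
      if (length(toks) < len || !length(multi)) break
      starts <- seq_len(length(toks) - len + 1L)
      windows <- vapply(starts, function(s) {
        paste(toks[s:(s + len - 1L)], collapse = " ")
      }, "")
      if (any(windows %in% multi)) return(TRUE)
    }
    FALSE
  }, logical(1), USE.NAMES = FALSE)
}
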