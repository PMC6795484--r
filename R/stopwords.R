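#' Default English stop-word list
#'
#' A fixed, versioned list of high-frequency English function words excluded
#' from featureization (compared lowercase against lowercased tokens). The
#' list is deliberately frozen inside the package so that vocabularies are
#' reproducible across installations; supply your own vector (or a file via
#' [read_stop_words()]) to override.
#'
#' @return Character vector of lowercase stop words.
#' @export
od_stop_words <- function() {
  c("a", "about", "above", "after", "again", "against", "all", "am", "an",
    "and", "any", "are", "as", "at", "be", "because", "been", "before",
    "being", "below", "between", "both", "but", "by", "could", "did", "do",
    "does", "doing", "down", "during", "each", "few", "for", "from",
    "further", "had", "has", "have", "having", "he", "her", "here", "hers",
    "herself", "him", "himself", "his", "how", "i", "if", "in", "into",
    "is", "it", "its", "itself", "just", "me", "more", "most", "my",
    "myself", "no", "nor", "not", "now", "of", "off", "on", "once", "only",
    "or", "other", "our", "ours", "ourselves", "out", "over", "own", "s",
    "same", "she", "should", "so", "some", "such", "t", "than", "that",
    "the", "their", "theirs", "them", "themselves", "then", "there",
    "these", "they", "this", "those", "through", "to", "too", "under",
    "until", "up", "very", "was", "we", "were", "what", "when", "where",
    "which", "while", "who", "whom", "why", "will", "with", "you", "your",
    "yours", "yourself", "yourselves")
}

#' Read a stop-word list from a plain-text file
#'
#' One word per line; `#` starts a comment; blank lines are skipped. Words
#' are lowercased.
#'
#' @param path Path to a UTF-8 text file.
#' @return Character vector of lowercase stop words.
#' @export
read_stop_words <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  tolower(lines[nzchar(lines)])
}
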