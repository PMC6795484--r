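# Brute-force oracles, implemented independently of the package internals
# (different string mechanics), used to validate the vectorizer, the rule
# matcher and the UCOD labeler.

# split on non-alphanumeric runs, keep pieces of >= min_chars characters
oracle_tokens <- function(text, min_chars = 2) {
  pieces <- strsplit(text, "[^A-Za-z0-9]+")[[1]]
  pieces[nchar(pieces) >= min_chars]
}

# every n-gram window of every document, by explicit loops
oracle_doc_ngrams <- function(text, nmin, nmax, stop_words,
                              min_chars = 2) {
  toks <- oracle_tokens(text, min_chars)
  toks <- toks[!(tolower(toks) %in% stop_words)]
  grams <- character(0)
  for (n in nmin:nmax) {
    if (length(toks) < n) next
    for (s in 1:(length(toks) - n + 1)) {
      grams <- c(grams, paste(toks[s:(s + n - 1)], collapse = " "))
    }
  }
  grams
}

# vocabulary by counting every window in every document
oracle_vocabulary <- function(corpus, nmin, nmax, min_count, stop_words,
                              count = "document") {
  per_doc <- lapply(corpus, oracle_doc_ngrams, nmin = nmin, nmax = nmax,
                    stop_words = stop_words)
  pool <- if (count == "document") {
    unlist(lapply(per_doc, unique))
  } else {
    unlist(per_doc)
  }
  tab <- table(pool)
  sort(names(tab)[tab >= min_count], method = "radix")
}

# binary membership matrix against a fixed vocabulary
oracle_membership <- function(corpus, vocab_ngrams, nmin, nmax,
                              stop_words) {
  m <- matrix(0, length(corpus), length(vocab_ngrams))
  for (i in seq_along(corpus)) {
    grams <- oracle_doc_ngrams(corpus[[i]], nmin, nmax, stop_words)
    m[i, ] <- as.numeric(vocab_ngrams %in% grams)
  }
  m
}

# token-window scan for the rule matcher
oracle_rule_match <- function(text, phrases) {
  toks <- oracle_tokens(text, min_chars = 1)
  for (ph in phrases) {
    ptoks <- oracle_tokens(ph, min_chars = 1)
    np <- length(ptoks)
    if (np == 0 || length(toks) < np) next
    for (s in 1:(length(toks) - np + 1)) {
      if (all(toks[s:(s + np - 1)] == ptoks)) return(TRUE)
    }
  }
  FALSE
}

# enumerate every 3-character code A00..Z99 and test range membership
# directly against the stated overdose UCOD ranges
oracle_ucod_table <- function() {
  codes <- as.vector(outer(LETTERS, sprintf("%02d", 0:99), paste0))
  letter <- substr(codes, 1, 1)
  num <- as.integer(substr(codes, 2, 3))
  expected <- (letter == "X" & (num %in% 40:44 | num %in% 60:64 |
                                  num == 85)) |
    (letter == "Y" & num %in% 10:14)
  data.frame(code = codes, overdose = expected, stringsAsFactors = FALSE)
}

# a small random corpus over a fixed word pool (includes stop words and
# punctuation) for property-style checks
random_toy_corpus <- function(n_docs, seed, words = NULL) {
  if (is.null(words)) {
    words <- c("ACUTE", "COCAINE", "TOXICITY", "OVERDOSE", "THE", "AND",
               "OF", "HEART", "FAILURE", "DRUG", "ABUSE", "X42", "A")
  }
  set.seed(seed)
  vapply(seq_len(n_docs), function(i) {
    paste(sample(words, sample(2:8, 1), replace = TRUE), collapse = " ")
  }, "")
}

# the worked example certificate from the method description: immediate
# cause, blank due-to lines, significant conditions, injury description
example_certificate <- function() {
  data.frame(id = "T1",
             cause_a = "ACUTE COCAINE TOXICITY",
             cause_b = "", cause_c = "", cause_d = "",
             scc = "HYPERTENSIVE CARDIOVASCULAR DISEASE, OBESITY",
             injury_desc = "ACCIDENTAL OVERDOSE",
             ucod = "X42", label = TRUE,
             stringsAsFactors = FALSE)
}
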