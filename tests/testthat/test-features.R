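test_that("tokenize extracts alphanumeric runs of length >= 2 in order", {
  expect_equal(tokenize("ACUTE COCAINE TOXICITY"),
               c("ACUTE", "COCAINE", "TOXICITY"))
  expect_equal(tokenize(""), character(0))
  expect_equal(tokenize("A OD X42"), c("OD", "X42"))
  expect_equal(tokenize("X42", min_chars = 1), "X42")
  expect_equal(tokenize("A B C", min_chars = 1), c("A", "B", "C"))
})

test_that("stop-word removal deletes by lowercase match and closes ranks", {
  expect_equal(remove_stop_words(c("DUE", "TO", "COCAINE"),
                                 c("due", "to")), "COCAINE")
  expect_equal(remove_stop_words(c("ACUTE", "COCAINE", "TOXICITY"),
                                 od_stop_words()),
               c("ACUTE", "COCAINE", "TOXICITY"))
  expect_equal(remove_stop_words(c("THE", "AND"), od_stop_words()),
               character(0))
})

test_that("extract_ngrams enumerates contiguous windows", {
  expect_equal(extract_ngrams(c("ACUTE", "COCAINE", "TOXICITY"), 1, 2),
               c("ACUTE", "COCAINE", "TOXICITY",
                 "ACUTE COCAINE", "COCAINE TOXICITY"))
  expect_equal(extract_ngrams("ONLY", 2, 3), character(0))
  expect_equal(extract_ngrams(c("A1", "A2", "A3", "A4"), 3, 3),
               c("A1 A2 A3", "A2 A3 A4"))
  expect_equal(extract_ngrams(character(0), 1, 3), character(0))
})

test_that("fit_vocabulary applies the minimum-count threshold exactly", {
  cfg <- vectorizer_config(ngram_min = 1, ngram_max = 2, min_count = 5)
  at_threshold <- fit_vocabulary(rep("COCAINE OVERDOSE", 5), cfg)
  expect_setequal(at_threshold$ngrams,
                  c("COCAINE", "OVERDOSE", "COCAINE OVERDOSE"))
  expect_equal(at_threshold$count, rep(5L, 3))
  below <- fit_vocabulary(rep("COCAINE OVERDOSE", 4), cfg)
  expect_length(below$ngrams, 0)
  expect_error(fit_vocabulary(character(0), cfg), "empty")
})

test_that("document vs total frequency counting is a documented switch", {
  corpus <- c(rep("COCAINE COCAINE COCAINE", 2), "HEART FAILURE")
  doc_cfg <- vectorizer_config(1, 1, min_count = 5, count = "document")
  tot_cfg <- vectorizer_config(1, 1, min_count = 5, count = "total")
  expect_length(fit_vocabulary(corpus, doc_cfg)$ngrams, 0) # df(COCAINE)=2
  expect_equal(fit_vocabulary(corpus, tot_cfg)$ngrams, "COCAINE") # 6 occurrences
})

test_that("vocabulary and transform agree with the brute-force oracle", {
  stops <- c("the", "and", "of")
  for (seed in c(7, 19)) {
    corpus <- random_toy_corpus(30, seed)
    cfg <- vectorizer_config(1, 3, min_count = 3, stop_words = stops)
    vocab <- fit_vocabulary(corpus, cfg)
    expect_equal(vocab$ngrams,
                 oracle_vocabulary(corpus, 1, 3, 3, stops))
    x <- transform_texts(corpus, vocab)
    expect_equal(unname(as.matrix(x)),
                 oracle_membership(corpus, vocab$ngrams, 1, 3, stops))
  }
})

test_that("vocabulary ordering is lexicographic and indices are dense", {
  corpus <- random_toy_corpus(40, 3)
  vocab <- fit_vocabulary(corpus, vectorizer_config(1, 2, min_count = 2))
  expect_equal(vocab$ngrams, sort(vocab$ngrams, method = "radix"))
  expect_equal(vocab$index, seq_along(vocab$ngrams))
  expect_true(all(vocab$count >= 2))
})

test_that("transform is binary, ignores unseen n-grams, zeroes unrelated text", {
  # a corpus where the worked-example bigram clears the threshold and
  # POISONING appears only outside the example certificate
  example_txt <- combine_fields(example_certificate(), "no_scc")
  corpus <- c(rep(example_txt, 5), rep("DRUG POISONING", 5))
  vocab <- fit_vocabulary(corpus, vectorizer_config(1, 2, min_count = 5))
  x <- transform_texts(example_txt, vocab)
  expect_equal(unname(x[1, "ACUTE COCAINE"]), 1)
  expect_equal(unname(x[1, "POISONING"]), 0)
  # repetition stays binary
  x2 <- transform_texts("COCAINE COCAINE COCAINE", vocab)
  expect_equal(unname(x2[1, "COCAINE"]), 1)
  # no shared n-gram -> all-zero row; unseen tokens contribute nothing
  x3 <- transform_texts("CONGESTIVE HEART FAILURE", vocab)
  expect_equal(sum(x3), 0)
  expect_equal(dim(x3), c(1L, length(vocab)))
})

test_that("all_sections vocabulary nests no_scc for unigrams and is larger", {
  dc <- simulate_certificates(600, seed = 9)
  cfg <- vectorizer_config()
  v_all <- fit_vocabulary(combine_fields(dc, "all_sections"), cfg)
  v_no <- fit_vocabulary(combine_fields(dc, "no_scc"), cfg)
  expect_gt(length(v_all), length(v_no))
  uni <- function(v) v$ngrams[!grepl(" ", v$ngrams)]
  expect_true(all(uni(v_no) %in% uni(v_all)))
})

test_that("vocabulary persists to JSON and round-trips exactly", {
  corpus <- random_toy_corpus(25, 11)
  vocab <- fit_vocabulary(corpus, vectorizer_config(1, 3, min_count = 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_vocabulary(vocab, path)
  back <- read_vocabulary(path)
  expect_identical(back$ngrams, vocab$ngrams)
  expect_identical(back$index, vocab$index)
  expect_identical(back$count, vocab$count)
  expect_identical(unclass(back$config), unclass(vocab$config))
  # the restored vocabulary transforms identically
  expect_identical(as.matrix(transform_texts(corpus, back)),
                   as.matrix(transform_texts(corpus, vocab)))
})
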