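# a linearly separable toy problem: positives carry the OVERDOSE token
separable_toy <- function(n = 120, n_pos = 30, seed = 2) {
  set.seed(seed)
  neg <- sample(c("CONGESTIVE HEART FAILURE", "ACUTE MYOCARDIAL INFARCTION",
                  "METASTATIC LUNG CANCER", "SEPSIS PNEUMONIA"),
                n - n_pos, replace = TRUE)
  pos <- sample(c("HEROIN OVERDOSE", "ACUTE FENTANYL OVERDOSE",
                  "COCAINE OVERDOSE TOXICITY"), n_pos, replace = TRUE)
  texts <- c(neg, pos)[sample(n)]
  y <- grepl("OVERDOSE", texts)
  vocab <- fit_vocabulary(texts, vectorizer_config(1, 2, min_count = 2))
  list(x = transform_texts(texts, vocab), y = y, vocab = vocab,
       texts = texts)
}

test_that("stratified folds keep positives within 1 of n_pos/k, all repeats", {
  y <- rep(c(TRUE, FALSE), c(33, 467))
  folds <- stratified_folds(y, k = 10, repeats = 3, seed = 4)
  expect_length(folds, 3L)
  for (r in folds) {
    expect_length(r, 10L)
    # each repeat partitions all rows exactly once
    expect_equal(sort(unlist(r)), seq_along(y))
    pos_counts <- vapply(r, function(idx) sum(y[idx]), 0L)
    expect_true(all(abs(pos_counts - 3.3) < 1))
    sizes <- lengths(r)
    expect_true(max(sizes) - min(sizes) <= 2)
  }
})

test_that("too few positives for k folds is a configuration error", {
  y <- rep(c(TRUE, FALSE), c(4, 96))
  expect_error(stratified_folds(y, k = 10), "smaller k")
  expect_error(cross_validate(matrix(0, 100, 2), y,
                              od_model_spec("linear_svm"),
                              cv_config(k = 10)),
               "smaller k")
})

test_that("cross_validate scores a separable problem perfectly and is deterministic", {
  toy <- separable_toy()
  cv <- cv_config(k = 5, repeats = 2, seed = 9)
  spec <- od_model_spec("linear_svm", list(cost = c(0.1, 1)))
  res1 <- cross_validate(toy$x, toy$y, spec, cv)
  expect_equal(res1$mean_f, c(1, 1))
  res2 <- cross_validate(toy$x, toy$y, spec, cv)
  expect_identical(res1, res2)
  expect_error(cross_validate(toy$x, rep(FALSE, nrow(toy$x)), spec, cv),
               "both classes")
})

test_that("grid refinement brackets an edge winner and stops at a fixed point", {
  spec <- od_model_spec("linear_svm", list(cost = c(0.01, 0.1, 1)))
  res <- data.frame(cost = c(0.01, 0.1, 1), mean_f = c(0.2, 0.5, 0.9))
  attr(res, "family") <- "linear_svm"
  class(res) <- c("od_cv_results", "data.frame")
  refined <- refine_grid(res, spec)
  g <- refined$grid$cost
  expect_false(isTRUE(attr(refined, "converged")))
  expect_gt(max(g), 1)               # widened beyond the old edge
  expect_lt(min(g), 1)               # brackets the winner from below
  expect_gte(min(g), 0.1)            # but stays near the winner
  expect_true(min(g) > 1e-12 && max(g) <= 10 + 1e-9)
  # winner interior in the new grid
  expect_true(1 > min(g) && 1 < max(g))

  # interior winner with negligible improvement: unchanged, converged
  res2 <- data.frame(cost = c(0.1, 1, 10), mean_f = c(0.5, 0.9, 0.7))
  attr(res2, "family") <- "linear_svm"
  class(res2) <- c("od_cv_results", "data.frame")
  fixed <- refine_grid(res2, spec2 <- od_model_spec("linear_svm",
                                                    list(cost = c(0.1, 1, 10))),
                       prev_best = 0.8995, tol = 1e-3)
  expect_true(isTRUE(attr(fixed, "converged")))
  expect_identical(fixed$grid, spec2$grid)

  # single-point grid widens around the point
  res3 <- data.frame(cost = 1, mean_f = 0.9)
  attr(res3, "family") <- "linear_svm"
  class(res3) <- c("od_cv_results", "data.frame")
  widened <- refine_grid(res3, od_model_spec("linear_svm", list(cost = 1)))
  expect_gt(max(widened$grid$cost), 1)
  expect_lt(min(widened$grid$cost), 1)
})

test_that("ties go to the least complex model", {
  res <- data.frame(cost = c(10, 0.1, 1), mean_f = c(0.9, 0.9, 0.9))
  attr(res, "family") <- "linear_svm"
  class(res) <- c("od_cv_results", "data.frame")
  expect_equal(best_grid_point(res)$cost, 0.1)
})

test_that("od_train fits a separable problem and round-trips through disk", {
  toy <- separable_toy()
  model <- od_train(toy$x, toy$y, "linear_svm",
                    grid = list(cost = c(0.1, 1)),
                    cv = cv_config(k = 5, repeats = 1, seed = 3),
                    vocabulary = toy$vocab, max_rounds = 2)
  expect_s3_class(model, "od_model")
  expect_equal(predict(model, toy$x), toy$y)   # training-set F = 1

  # the OVERDOSE token must carry the largest positive weight
  w <- coef(model)
  expect_equal(names(which.max(w)), "OVERDOSE")

  dc <- simulate_certificates(1000, seed = 77)
  xnew <- transform_texts(combine_fields(dc, "no_scc"), toy$vocab)
  path <- withr::local_tempfile(fileext = ".rds")
  save_od_model(model, path)
  reloaded <- read_od_model(path)
  expect_identical(predict(reloaded, xnew), predict(model, xnew))
  expect_identical(predict(reloaded, xnew, type = "score"),
                   predict(model, xnew, type = "score"))
})

test_that("predict validates feature dimensions and handles empty input", {
  toy <- separable_toy()
  model <- od_train(toy$x, toy$y, "linear_svm", grid = list(cost = 1),
                    tune = FALSE)
  bad <- toy$x[, 1:3]
  err <- tryCatch(predict(model, bad), error = identity)
  expect_match(conditionMessage(err), as.character(ncol(toy$x)))
  expect_match(conditionMessage(err), "3")
  expect_equal(predict(model, toy$x[0, , drop = FALSE]), logical(0))
  # an all-zero row gets the majority-class (negative) prediction
  zero_row <- toy$x[1, , drop = FALSE] * 0
  expect_false(predict(model, zero_row))
})

test_that("all three families learn a planted keyword signal (F >= 0.9)", {
  dc <- simulate_certificates(900, od_prevalence = 0.08, seed = 301)
  holdout <- simulate_certificates(500, od_prevalence = 0.08, seed = 302)
  txt <- combine_fields(dc, "no_scc")
  vocab <- fit_vocabulary(txt, vectorizer_config())
  x <- transform_texts(txt, vocab)
  xh <- transform_texts(combine_fields(holdout, "no_scc"), vocab)
  grids <- list(linear_svm = list(cost = c(0.1, 1)),
                random_forest = list(n_trees = 100, max_depth = c(8, 0)),
                mlp = list(hidden = 8, alpha = 1e-3))
  for (fam in c("linear_svm", "random_forest", "mlp")) {
    model <- od_train(x, dc$label, fam, grid = grids[[fam]],
                      cv = cv_config(k = 5, repeats = 1, seed = 11),
                      max_rounds = 1)
    f <- evaluation_report(holdout$label, predict(model, xh))$f_score
    expect_gte(f, 0.9)
  }
})

test_that("tuning is seed-deterministic and cost selection is stable across seeds", {
  dc <- simulate_certificates(700, od_prevalence = 0.08, seed = 55)
  txt <- combine_fields(dc, "no_scc")
  vocab <- fit_vocabulary(txt, vectorizer_config())
  x <- transform_texts(txt, vocab)
  run <- function(seed) {
    od_train(x, dc$label, "linear_svm", grid = list(cost = c(0.01, 0.1, 1)),
             cv = cv_config(k = 5, repeats = 2, seed = seed),
             max_rounds = 2)
  }
  m1a <- run(1); m1b <- run(1)
  expect_identical(m1a$params, m1b$params)
  expect_identical(m1a$cv_history, m1b$cv_history)
  costs <- vapply(list(m1a, run(2), run(3)), function(m) m$params$cost, 0)
  # selection is stable: chosen costs stay within one decade across seeds
  expect_lte(max(costs) / min(costs), 10)
})

test_that("MLP refits are reproducible given the cv seed", {
  toy <- separable_toy(n = 150, n_pos = 40, seed = 6)
  fit2 <- lapply(1:2, function(i) {
    od_train(toy$x, toy$y, "mlp", grid = list(hidden = 4, alpha = 1e-3),
             tune = FALSE, cv = cv_config(k = 5, repeats = 1, seed = 21))
  })
  expect_identical(predict(fit2[[1]], toy$x, type = "score"),
                   predict(fit2[[2]], toy$x, type = "score"))
})
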