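#' Train-on-year-1 / test-on-year-2 comparison experiment
#'
#' The full surveillance experiment: for each requested field combination,
#' fit the n-gram vocabulary on the training year only, featureize both
#' years with it (test-year n-grams unseen in training contribute
#' nothing), tune and refit each requested classifier family on the
#' training year, deploy everything — including the rule-based keyword
#' baseline — on the test year, and compare. No information from the test
#' source reaches the vocabulary, the grids or the tuning.
#'
#' The report carries, per field set and method, PPV / sensitivity /
#' F-score and the confusion matrix, plus one-tailed two-proportion
#' z-tests of the best (highest F) learned model against the rule-based
#' baseline for sensitivity and PPV.
#'
#' @param train,test Labeled certificate data frames
#'   ([read_certificates()] or [simulate_certificates()]); every row needs
#'   a non-missing label.
#' @param families Classifier families to train (see [od_model_spec()]).
#' @param field_sets Field combinations to compare.
#' @param vectorizer A [vectorizer_config()].
#' @param cv An [cv_config()]; its seed drives all randomness.
#' @param phrases An `od_phrases` list for the rule baseline.
#' @param grids Optional named list (by family) of hyperparameter grids.
#' @param seed Optional convenience override of `cv$seed`.
#' @return An object of class `od_experiment`.
#' @export
run_experiment <- function(train, test,
                           families = c("linear_svm", "random_forest",
                                        "mlp"),
                           field_sets = c("all_sections", "no_scc"),
                           vectorizer = vectorizer_config(),
                           cv = cv_config(),
                           phrases = default_phrase_list(),
                           grids = NULL, seed = NULL) {
  families <- match.arg(families, several.ok = TRUE)
  field_sets <- match.arg(field_sets,
                          c("all_sections", "no_scc"), several.ok = TRUE)
  if (!is.null(seed)) cv$seed <- as.integer(seed)
  for (nm in c("train", "test")) {
    dc <- get(nm)
    if (!"label" %in% names(dc) || anyNA(dc$label)) {
      stop(nm, " data is not fully labeled; derive labels from a ucod ",
           "column, or use predict_unlabeled() for unlabeled deployment",
           call. = FALSE)
    }
  }
  y_train <- as.logical(train$label)
  y_test <- as.logical(test$label)

  sections <- lapply(field_sets, function(fs) {
    train_text <- combine_fields(train, fs)
    test_text <- combine_fields(test, fs)
    vocab <- fit_vocabulary(train_text, vectorizer)
    x_train <- transform_texts(train_text, vocab)
    x_test <- transform_texts(test_text, vocab)

    models <- lapply(families, function(fam) {
      model <- od_train(x_train, y_train, family = fam,
                        grid = grids[[fam]], cv = cv,
                        vocabulary = vocab, field_set = fs)
      pred <- predict(model, x_test)
      list(model = model, pred = pred,
           metrics = evaluation_report(y_test, pred))
    })
    names(models) <- families

    rule_pred <- rule_classify(test_text, phrases)
    rule_metrics <- evaluation_report(y_test, rule_pred)

    f_scores <- vapply(models, function(m) m$metrics$f_score, 0)
    best <- names(models)[which.max(f_scores)]
    bm <- models[[best]]$metrics$cm
    rm_ <- rule_metrics$cm
    list(vocab = vocab, models = models, best_family = best,
         rule = list(pred = rule_pred, metrics = rule_metrics),
         z_sensitivity = two_proportion_z_test(
           bm$tp, bm$tp + bm$fn, rm_$tp, rm_$tp + rm_$fn),
         z_ppv = two_proportion_z_test(
           bm$tp, bm$tp + bm$fp, rm_$tp, rm_$tp + rm_$fp))
  })
  names(sections) <- field_sets
  structure(list(sections = sections, families = families,
                 field_sets = field_sets,
                 n_train = nrow(train), n_test = nrow(test),
                 n_pos_test = sum(y_test), cv = cv,
                 phrase_source = phrases$source),
            class = "od_experiment")
}

method_label <- c(linear_svm = "SVM", random_forest = "RF", mlp = "MLP")

#' @export
print.od_experiment <- function(x, ...) {
  cat(sprintf("overdose classification experiment: %d train / %d test certificates (%d test OD)\n",
              x$n_train, x$n_test, x$n_pos_test))
  for (fs in x$field_sets) {
    sec <- x$sections[[fs]]
    cat(sprintf("\n== field set: %s (%d features) ==\n", fs,
                length(sec$vocab)))
    cat(sprintf("%-12s %8s %12s %9s\n", "Method", "PPV", "Sensitivity",
                "F-score"))
    for (fam in names(sec$models)) {
      m <- sec$models[[fam]]$metrics
      cat(sprintf("%-12s %8.4f %12.4f %9.4f\n",
                  method_label[[fam]], m$ppv, m$sensitivity, m$f_score))
    }
    rm_ <- sec$rule$metrics
    cat(sprintf("%-12s %8.4f %12.4f %9.4f\n", "Rule-based",
                rm_$ppv, rm_$sensitivity, rm_$f_score))
    cat(sprintf("best model (%s) vs rule-based, one-tailed z-tests:\n",
                method_label[[sec$best_family]]))
    cat(sprintf("  sensitivity: z = %.3f, p = %.4g\n",
                sec$z_sensitivity$z, sec$z_sensitivity$p))
    cat(sprintf("  PPV:         z = %.3f, p = %.4g\n",
                sec$z_ppv$z, sec$z_ppv$p))
  }
  invisible(x)
}

#' Serialize an experiment report to JSON
#'
#' @param x An `od_experiment`.
#' @param path Output path; `NULL` returns the JSON string.
#' @return `path` (invisibly) or a JSON string.
#' @export
experiment_report_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "od_experiment"))
  payload <- list(
    n_train = x$n_train, n_test = x$n_test, n_pos_test = x$n_pos_test,
    seed = x$cv$seed,
    field_sets = lapply(x$sections, function(sec) {
      methods <- lapply(sec$models, function(m) {
        with(m$metrics, list(ppv = ppv, sensitivity = sensitivity,
                             specificity = specificity, f_score = f_score,
                             confusion = unclass(cm)))
      })
      methods$rule_based <- with(sec$rule$metrics, list(
        ppv = ppv, sensitivity = sensitivity, specificity = specificity,
        f_score = f_score, confusion = unclass(cm)))
      list(n_features = length(sec$vocab), methods = methods,
           best_family = sec$best_family,
           z_sensitivity = list(z = sec$z_sensitivity$z,
                                p = sec$z_sensitivity$p),
           z_ppv = list(z = sec$z_ppv$z, p = sec$z_ppv$p))
    }))
  if (is.null(path)) {
    jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
  }
}

#' Deploy a trained model on unlabeled certificates
#'
#' @param newdata Certificate data frame or path to a CSV/TSV file.
#' @param model An `od_model` carrying its vocabulary and field set.
#' @param output Optional path; when given, the input rows plus prediction
#'   columns are written there as CSV/TSV.
#' @param column_map Passed to [read_certificates()] when `newdata` is a
#'   path.
#' @return The certificate data frame with appended columns
#'   `pred_overdose` (logical), `pred_score` (decision score) and
#'   `no_features` (TRUE when the record's text shares no n-gram with the
#'   training vocabulary, so the prediction is the model's empty-text
#'   default). Warns when any record has no features.
#' @export
predict_unlabeled <- function(newdata, model, output = NULL,
                              column_map = NULL) {
  stopifnot(inherits(model, "od_model"))
  if (is.character(newdata) && length(newdata) == 1L) {
    newdata <- read_certificates(newdata, column_map = column_map)
  }
  if (is.null(model$vocabulary) || is.null(model$field_set)) {
    stop("model must carry a vocabulary and field_set for deployment",
         call. = FALSE)
  }
  text <- combine_fields(newdata, model$field_set)
  x <- transform_texts(text, model$vocabulary)
  out <- newdata
  out$pred_overdose <- predict(model, x)
  out$pred_score <- predict(model, x, type = "score")
  out$no_features <- Matrix::rowSums(x) == 0
  if (any(out$no_features)) {
    warning(sum(out$no_features), " record(s) share no feature with the ",
            "training vocabulary; their predictions fall back to the ",
            "model's empty-text default", call. = FALSE)
  }
  if (!is.null(output)) write_certificates(out, output)
  out
}
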