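#' Classifier specification
#'
#' A model family plus its hyperparameter grid. Supported families and
#' tunable hyperparameters:
#' \describe{
#'   \item{`linear_svm`}{`cost` — the SVM regularization (C) parameter.}
#'   \item{`random_forest`}{`n_trees`, `max_depth` (0 = unbounded),
#'     `max_features` (`"sqrt"` or a fraction of features, as a string).}
#'   \item{`mlp`}{`hidden` — single hidden-layer size; `alpha` — L2
#'     weight-decay regularization.}
#' }
#' Default grids are deliberately coarse starting points; tuning proceeds by
#' iterative refinement around the best value (see [refine_grid()]).
#'
#' @param family One of `"linear_svm"`, `"random_forest"`, `"mlp"`.
#' @param grid Named list of candidate value vectors; `NULL` for the
#'   documented defaults.
#' @return An object of class `od_model_spec`.
#' @export
od_model_spec <- function(family = c("linear_svm", "random_forest", "mlp"),
                          grid = NULL) {
  family <- match.arg(family)
  allowed <- switch(family,
    linear_svm    = "cost",
    random_forest = c("n_trees", "max_depth", "max_features"),
    mlp           = c("hidden", "alpha"))
  if (is.null(grid)) {
    grid <- switch(family,
      linear_svm    = list(cost = c(0.01, 0.1, 1, 10)),
      random_forest = list(n_trees = c(100, 300),
                           max_depth = c(8, 16, 0),
                           max_features = c("sqrt", "0.1")),
      mlp           = list(hidden = c(32, 64), alpha = c(1e-4, 1e-2)))
  }
  bad <- setdiff(names(grid), allowed)
  if (length(bad)) {
    stop(family, " does not tune hyperparameter(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!length(grid) || any(!lengths(grid))) {
    stop("grid must provide at least one candidate per hyperparameter",
         call. = FALSE)
  }
  structure(list(family = family, grid = grid), class = "od_model_spec")
}

#' Cross-validation configuration
#'
#' The tuning protocol: `repeats` times repeated, stratified `k`-fold
#' cross-validation scored by F-score (the harmonic mean of PPV and
#' sensitivity). Stratification keeps each fold's class makeup equal to the
#' full data's (about 97% non-overdose / 3% overdose), which matters because
#' F-score, not accuracy, drives tuning under this imbalance.
#'
#' @param k Number of folds (default 10).
#' @param repeats Number of repetitions (default 3).
#' @param seed Integer seed controlling fold assignment and stochastic
#'   learners.
#' @return An object of class `od_cv_config`.
#' @export
cv_config <- function(k = 10L, repeats = 3L, seed = 1L) {
  k <- as.integer(k); repeats <- as.integer(repeats); seed <- as.integer(seed)
  stopifnot(k >= 2L, repeats >= 1L)
  structure(list(k = k, repeats = repeats, stratified = TRUE,
                 scoring = "f_score", seed = seed),
            class = "od_cv_config")
}

#' Stratified repeated k-fold assignment
#'
#' Assigns each observation to one test fold per repeat, independently
#' within each class, so every fold's positive count differs from `n_pos/k`
#' by less than 1. Deterministic given `seed`.
#'
#' @param y Logical label vector.
#' @param k Number of folds.
#' @param repeats Number of repetitions.
#' @param seed Integer seed.
#' @return List of `repeats` lists, each holding `k` integer vectors of
#'   test-row indices.
#' @export
stratified_folds <- function(y, k, repeats = 1L, seed = 1L) {
  y <- as.logical(y)
  n_pos <- sum(y)
  if (n_pos < k || sum(!y) < k) {
    stop("stratified ", k, "-fold CV needs at least ", k,
         " cases of each class (have ", n_pos, " positive, ", sum(!y),
         " negative); use a smaller k", call. = FALSE)
  }
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  lapply(seq_len(repeats), function(r) {
    assign_fold <- integer(length(y))
    for (cls in c(TRUE, FALSE)) {
      idx <- which(y == cls)
      assign_fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    lapply(seq_len(k), function(f) which(assign_fold == f))
  })
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# F-score from raw counts; 0 when there are no true positives but some
# predicted or actual positives exist (harmonic-mean limit)
fold_f_score <- function(tp, fp, fn) {
  denom <- 2 * tp + fp + fn
  if (denom == 0) return(NA_real_)
  2 * tp / denom
}

grid_frame <- function(spec) {
  expand.grid(spec$grid, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
}

# --- backend dispatch --------------------------------------------------

param_or <- function(params, name, default) {
  v <- params[[name]]
  if (is.null(v) || is.na(v)) default else v
}

resolve_mtry <- function(max_features, p) {
  if (identical(max_features, "sqrt")) return(max(1L, floor(sqrt(p))))
  frac <- suppressWarnings(as.numeric(max_features))
  if (is.na(frac) || frac <= 0 || frac > 1) {
    stop("max_features must be \"sqrt\" or a fraction in (0, 1], got: ",
         max_features, call. = FALSE)
  }
  max(1L, ceiling(frac * p))
}

as_dense <- function(x) {
  xm <- if (inherits(x, "Matrix")) as.matrix(x) else x
  storage.mode(xm) <- "double"
  xm
}

fit_one <- function(family, x, y, params, seed) {
  yf <- factor(y, levels = c(FALSE, TRUE))
  if (family == "linear_svm") {
    return(e1071::svm(x = as_dense(x), y = yf, kernel = "linear",
                      cost = param_or(params, "cost", 1), scale = FALSE))
  }
  xm <- as_dense(x)
  colnames(xm) <- paste0("f", seq_len(ncol(xm)))
  if (family == "random_forest") {
    ranger::ranger(x = xm, y = yf,
                   num.trees = param_or(params, "n_trees", 300),
                   max.depth = param_or(params, "max_depth", 0),
                   mtry = resolve_mtry(param_or(params, "max_features", "sqrt"),
                                       ncol(xm)),
                   probability = TRUE, seed = seed, num.threads = 1L)
  } else if (family == "mlp") {
    old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
    nnet::nnet(x = xm, y = as.numeric(y),
               size = param_or(params, "hidden", 32),
               decay = param_or(params, "alpha", 1e-4),
               entropy = TRUE, maxit = 150L, MaxNWts = 1e6,
               trace = FALSE)
  } else {
    stop("unknown model family: ", family, call. = FALSE)
  }
}

predict_one <- function(family, fit, x) {
  if (nrow(x) == 0L) {
    return(list(class = logical(0), score = numeric(0)))
  }
  if (family == "linear_svm") {
    pr <- stats::predict(fit, as_dense(x), decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    score <- dv[, 1]
    # orient the margin so that positive means overdose
    if (identical(colnames(dv)[1], "FALSE/TRUE")) score <- -score
    return(list(class = unname(pr == "TRUE"), score = unname(score)))
  }
  xm <- as_dense(x)
  colnames(xm) <- paste0("f", seq_len(ncol(xm)))
  if (family == "random_forest") {
    p <- stats::predict(fit, xm, num.threads = 1L)$predictions[, "TRUE"]
  } else {
    p <- stats::predict(fit, xm)[, 1]
  }
  list(class = unname(p > 0.5), score = unname(p))
}

# --- cross-validation and grid refinement ------------------------------

#' Cross-validate a hyperparameter grid
#'
#' Scores every grid point of `spec` by mean F-score over `cv$repeats` times
#' repeated stratified `cv$k`-fold cross-validation. Each fold's F-score is
#' computed from that fold's held-out confusion counts. Deterministic given
#' `cv$seed` (the seed controls fold assignment and, for the stochastic
#' learners, fitting).
#'
#' @param x Feature matrix (rows = certificates), dense or sparse.
#' @param y Logical label vector (TRUE = overdose).
#' @param spec An [od_model_spec()].
#' @param cv An [cv_config()].
#' @return Data frame of class `od_cv_results`: one row per grid point with
#'   the hyperparameter values and `mean_f`.
#' @export
cross_validate <- function(x, y, spec, cv = cv_config()) {
  stopifnot(inherits(spec, "od_model_spec"), inherits(cv, "od_cv_config"))
  y <- as.logical(y)
  if (nrow(x) != length(y)) {
    stop("x has ", nrow(x), " rows but y has ", length(y), " labels",
         call. = FALSE)
  }
  if (!any(y) || all(y)) {
    stop("training data must contain both classes (", sum(y),
         " positive of ", length(y), ")", call. = FALSE)
  }
  folds <- stratified_folds(y, cv$k, cv$repeats, cv$seed)
  grid <- grid_frame(spec)
  xw <- as_dense(x)
  mean_f <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    params <- as.list(grid[g, , drop = FALSE])
    fs <- numeric(0)
    for (r in seq_along(folds)) {
      for (f in seq_along(folds[[r]])) {
        test_idx <- folds[[r]][[f]]
        if (!any(y[test_idx])) {
          stop("fold without positive cases encountered; use a smaller k",
               call. = FALSE)
        }
        fit_seed <- cv$seed + 1009L * r + 101L * f + g
        fit <- fit_one(spec$family, xw[-test_idx, , drop = FALSE],
                       y[-test_idx], params, fit_seed)
        pred <- predict_one(spec$family, fit,
                            xw[test_idx, , drop = FALSE])$class
        truth <- y[test_idx]
        fs <- c(fs, fold_f_score(sum(pred & truth), sum(pred & !truth),
                                 sum(!pred & truth)))
      }
    }
    mean_f[g] <- mean(fs, na.rm = TRUE)
  }
  out <- cbind(grid, mean_f = mean_f)
  attr(out, "family") <- spec$family
  class(out) <- c("od_cv_results", "data.frame")
  out
}

# complexity ordering used to break F-score ties: the least complex (most
# regularized / smallest) model wins
complexity_order <- function(results, family) {
  switch(family,
    linear_svm = order(results$cost),
    random_forest = {
      depth <- results[["max_depth"]] %||% rep(0, nrow(results))
      depth <- ifelse(depth == 0, Inf, depth)
      trees <- results[["n_trees"]] %||% rep(300, nrow(results))
      mf <- results[["max_features"]] %||% rep("sqrt", nrow(results))
      mf_num <- ifelse(mf == "sqrt", NA_real_,
                       suppressWarnings(as.numeric(mf)))
      mf_num[is.na(mf_num)] <- 0  # sqrt shrinks with p; treat as simplest
      order(depth, trees, mf_num)
    },
    mlp = {
      hidden <- results[["hidden"]] %||% rep(32, nrow(results))
      alpha <- results[["alpha"]] %||% rep(1e-4, nrow(results))
      order(hidden, -alpha)
    })
}

#' Best grid point of a cross-validation run
#'
#' Highest mean F-score; exact ties go to the least complex model (lowest
#' cost, shallowest forest, smallest hidden layer / largest alpha).
#'
#' @param results An `od_cv_results` data frame.
#' @return One-row data frame with the winning hyperparameters and `mean_f`.
#' @export
best_grid_point <- function(results) {
  family <- attr(results, "family")
  ord <- complexity_order(results, family)
  ordered <- results[ord, , drop = FALSE]
  top <- which(ordered$mean_f >= max(ordered$mean_f) - 1e-12)[1]
  ordered[top, , drop = FALSE]
}

refine_numeric_log <- function(values, best) {
  g <- sort(unique(values))
  i <- which.min(abs(g - best))
  if (length(g) == 1L) {
    lo <- best / 3; hi <- best * 3
  } else {
    lo <- if (i > 1L) sqrt(g[i - 1L] * g[i]) else g[i] / (g[i + 1L] / g[i])
    hi <- if (i < length(g)) sqrt(g[i] * g[i + 1L]) else g[i] * (g[i] / g[i - 1L])
  }
  signif(exp(seq(log(lo), log(hi), length.out = 5L)), 3)
}

refine_integer <- function(values, best, minval = 1L) {
  g <- sort(unique(values))
  i <- which.min(abs(g - best))
  if (length(g) == 1L) {
    lo <- best - 1L; hi <- best + 1L
  } else {
    lo <- if (i > 1L) ceiling((g[i - 1L] + g[i]) / 2) else g[i] - (g[i + 1L] - g[i])
    hi <- if (i < length(g)) floor((g[i] + g[i + 1L]) / 2) else g[i] + (g[i] - g[i - 1L])
  }
  sort(unique(pmax(minval, unique(round(seq(lo, hi, length.out = 5L))))))
}

#' Refine a hyperparameter grid around its best point
#'
#' Builds the next search grid bracketing the winning value of each
#' hyperparameter: geometric neighbours for continuous hyperparameters
#' (`cost`, `alpha`), arithmetic steps for integer ones (`n_trees`,
#' `hidden`, finite `max_depth`); categorical-like values (`max_features`,
#' unbounded depth) are fixed at the winner. A winner at a grid edge widens
#' the grid outward so it becomes interior. When the winner is already
#' interior and the improvement over `prev_best` is below `tol`, the spec
#' is returned unchanged with attribute `converged = TRUE`.
#'
#' @param results An `od_cv_results` data frame from [cross_validate()].
#' @param spec The [od_model_spec()] that produced `results`.
#' @param prev_best Best mean F-score of the previous refinement round, or
#'   `NULL` on the first round.
#' @param tol Minimum F-score improvement that justifies another round.
#' @return A new `od_model_spec` (attribute `converged` signals a fixed
#'   point).
#' @export
refine_grid <- function(results, spec, prev_best = NULL, tol = 1e-3) {
  stopifnot(inherits(spec, "od_model_spec"))
  best <- best_grid_point(results)
  interior <- all(vapply(names(spec$grid), function(p) {
    vals <- spec$grid[[p]]
    if (!is.numeric(vals) || length(unique(vals)) == 1L) return(TRUE)
    b <- best[[p]]
    if (p == "max_depth" && b == 0) return(TRUE)
    g <- sort(unique(vals[!(p == "max_depth" & vals == 0)]))
    b > min(g) && b < max(g)
  }, logical(1)))
  if (interior && !is.null(prev_best) &&
      (best$mean_f - prev_best) < tol) {
    out <- spec
    attr(out, "converged") <- TRUE
    return(out)
  }
  new_grid <- lapply(stats::setNames(names(spec$grid), names(spec$grid)),
                     function(p) {
    vals <- spec$grid[[p]]
    b <- best[[p]]
    if (!is.numeric(vals)) return(b)              # categorical: fix winner
    if (p == "max_depth" && b == 0) return(0)     # unbounded: fix winner
    if (p %in% c("cost", "alpha")) {
      refine_numeric_log(vals, b)
    } else {
      minval <- if (p == "n_trees") 50L else 1L
      refine_integer(vals[!(p == "max_depth" & vals == 0)], b, minval)
    }
  })
  out <- od_model_spec(spec$family, new_grid)
  attr(out, "converged") <- FALSE
  out
}

# --- the fitted-model class --------------------------------------------

#' Train an overdose text classifier
#'
#' The main fitting function. With `tune = TRUE` (default) it runs the full
#' tuning protocol: repeated stratified k-fold cross-validation over the
#' spec's grid, scored by F-score, followed by iterative grid refinement
#' around the best value until the winner is interior and improves by less
#' than `tol` (or `max_rounds` is reached), then a final refit of the
#' chosen hyperparameters on all training rows.
#'
#' @param x Binary feature matrix from [transform_texts()] (or any numeric
#'   matrix), rows = certificates.
#' @param y Logical labels (TRUE = overdose), one per row.
#' @param family Classifier family, see [od_model_spec()].
#' @param grid Hyperparameter grid; `NULL` for defaults.
#' @param cv An [cv_config()].
#' @param tune If `FALSE`, `grid` must hold exactly one value per
#'   hyperparameter and is used directly without cross-validation.
#' @param vocabulary Optional [fit_vocabulary()] result stored with the
#'   model, enabling prediction directly from text or certificate data
#'   frames.
#' @param field_set Optional field combination (`"all_sections"` /
#'   `"no_scc"`) stored with the model.
#' @param max_rounds Cap on refinement rounds (default 5).
#' @param tol Refinement stopping tolerance on mean F-score (default 1e-3).
#' @return An object of class `od_model`.
#' @seealso [predict.od_model()], [save_od_model()]
#' @export
od_train <- function(x, y, family = c("linear_svm", "random_forest", "mlp"),
                     grid = NULL, cv = cv_config(), tune = TRUE,
                     vocabulary = NULL, field_set = NULL,
                     max_rounds = 5L, tol = 1e-3) {
  family <- match.arg(family)
  y <- as.logical(y)
  if (nrow(x) != length(y)) {
    stop("x has ", nrow(x), " rows but y has ", length(y), " labels",
         call. = FALSE)
  }
  if (!any(y) || all(y)) {
    stop("training data must contain both classes (", sum(y),
         " positive of ", length(y), ")", call. = FALSE)
  }
  if (!is.null(vocabulary) && ncol(x) != length(vocabulary)) {
    stop("x has ", ncol(x), " columns but the vocabulary has ",
         length(vocabulary), " entries", call. = FALSE)
  }
  spec <- od_model_spec(family, grid)
  history <- list()
  if (tune) {
    prev_best <- NULL
    for (round in seq_len(max_rounds)) {
      res <- cross_validate(x, y, spec, cv)
      history[[round]] <- res
      nxt <- refine_grid(res, spec, prev_best = prev_best, tol = tol)
      prev_best <- best_grid_point(res)$mean_f
      if (isTRUE(attr(nxt, "converged"))) break
      spec <- nxt
    }
    best <- best_grid_point(history[[length(history)]])
    params <- as.list(best[setdiff(names(best), "mean_f")])
    cv_f <- best$mean_f
  } else {
    if (any(lengths(spec$grid) != 1L)) {
      stop("tune = FALSE requires exactly one value per hyperparameter",
           call. = FALSE)
    }
    params <- lapply(spec$grid, `[[`, 1L)
    cv_f <- NA_real_
  }
  fit <- fit_one(family, x, y, params, seed = cv$seed)
  model <- structure(list(family = family, params = params, fit = fit,
                          n_features = ncol(x),
                          vocabulary = vocabulary, field_set = field_set,
                          cv = cv, cv_f = cv_f, cv_history = history,
                          n_train = nrow(x), n_pos = sum(y)),
                     class = "od_model")
  model$config_hash <- model_config_hash(model)
  model
}

#' Predict overdose status with a trained model
#'
#' @param object An `od_model`.
#' @param newdata A feature matrix with `object$n_features` columns; or a
#'   character vector of normalized texts, or a certificate data frame
#'   (both require the model to carry a vocabulary — and, for data frames,
#'   a field set — so the training featureization can be replayed).
#' @param type `"class"` for logical labels, `"score"` for the decision
#'   score (SVM margin or positive-class probability).
#' @param ... Unused.
#' @return Logical or numeric vector, one element per row/text.
#' @export
predict.od_model <- function(object, newdata, type = c("class", "score"),
                             ...) {
  type <- match.arg(type)
  newdata <- resolve_features(object, newdata)
  if (ncol(newdata) != object$n_features) {
    stop("feature-dimension mismatch: model expects ", object$n_features,
         " features but newdata has ", ncol(newdata), call. = FALSE)
  }
  pred <- predict_one(object$family, object$fit, newdata)
  if (type == "class") pred$class else pred$score
}

resolve_features <- function(model, newdata) {
  if (is.character(newdata)) {
    if (is.null(model$vocabulary)) {
      stop("model carries no vocabulary; supply a feature matrix",
           call. = FALSE)
    }
    return(transform_texts(newdata, model$vocabulary))
  }
  if (is.data.frame(newdata)) {
    if (is.null(model$vocabulary) || is.null(model$field_set)) {
      stop("model carries no vocabulary/field_set; supply a feature matrix",
           call. = FALSE)
    }
    return(transform_texts(combine_fields(newdata, model$field_set),
                           model$vocabulary))
  }
  newdata
}

#' @export
print.od_model <- function(x, ...) {
  cat(sprintf("overdose text classifier (%s)\n", x$family))
  cat("  hyperparameters:",
      paste(names(x$params), unlist(x$params), sep = " = ",
            collapse = ", "), "\n")
  cat(sprintf("  trained on %d certificates (%d overdose), %d features\n",
              x$n_train, x$n_pos, x$n_features))
  if (!is.na(x$cv_f)) {
    cat(sprintf("  tuning: %dx repeated stratified %d-fold CV, mean F = %.4f (%d round%s)\n",
                x$cv$repeats, x$cv$k, x$cv_f, length(x$cv_history),
                if (length(x$cv_history) == 1) "" else "s"))
  }
  if (!is.null(x$field_set)) cat("  field set:", x$field_set, "\n")
  invisible(x)
}

#' @export
summary.od_model <- function(object, ...) {
  print(object)
  if (length(object$cv_history)) {
    cat("\ntuning trajectory (best mean F per round):\n")
    for (i in seq_along(object$cv_history)) {
      b <- best_grid_point(object$cv_history[[i]])
      cat(sprintf("  round %d: %d grid points, best F = %.4f (%s)\n", i,
                  nrow(object$cv_history[[i]]), b$mean_f,
                  paste(names(b)[names(b) != "mean_f"],
                        unlist(b[names(b) != "mean_f"]),
                        sep = " = ", collapse = ", ")))
    }
  }
  invisible(object)
}

#' Feature weights of a linear SVM model
#'
#' Recovers the primal weight vector `w = t(coefs) %*% SV` of the linear
#' SVM, oriented so positive weights push toward the overdose class, named
#' by vocabulary n-gram where the model carries one. Only defined for
#' `family = "linear_svm"`.
#'
#' @param object An `od_model` with `family = "linear_svm"`.
#' @param ... Unused.
#' @return Named numeric vector of feature weights.
#' @export
coef.od_model <- function(object, ...) {
  if (object$family != "linear_svm") {
    stop("coefficients are only defined for the linear SVM family",
         call. = FALSE)
  }
  fit <- object$fit
  w <- as.numeric(crossprod(as_dense(fit$SV), fit$coefs))
  # e1071 orients the margin with the first factor level (FALSE) positive;
  # flip to make overdose-positive
  if (identical(levels(fit$fitted)[1], "FALSE")) w <- -w
  if (!is.null(object$vocabulary)) names(w) <- object$vocabulary$ngrams
  w
}

model_config_hash <- function(model) {
  desc <- paste(model$family,
                paste(names(model$params), unlist(model$params),
                      sep = "=", collapse = ";"),
                model$n_features,
                paste(model$vocabulary$ngrams, collapse = "|"),
                model$field_set %||% "", sep = "\n")
  poly_hash(desc)
}

poly_hash <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h1 <- 0; h2 <- 0
  for (b in bytes) {
    h1 <- (h1 * 131 + b) %% 1000000007
    h2 <- (h2 * 137 + b) %% 998244353
  }
  sprintf("%09d%09d", h1, h2)
}

#' Persist / restore a trained model
#'
#' Saves the fitted model, its vocabulary, field set and a configuration
#' hash as a single artifact. Reloading yields bit-identical predictions.
#'
#' @param model An `od_model`.
#' @param path Artifact path.
#' @return `path` invisibly ([save_od_model()]); the model
#'   ([read_od_model()]).
#' @export
save_od_model <- function(model, path) {
  stopifnot(inherits(model, "od_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_od_model
#' @export
read_od_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "od_model")) {
    stop(path, " does not contain an od_model artifact", call. = FALSE)
  }
  if (!identical(model$config_hash, model_config_hash(model))) {
    stop("model artifact configuration hash mismatch: ", path, call. = FALSE)
  }
  model
}
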