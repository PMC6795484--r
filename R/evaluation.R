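#' Confusion matrix for overdose classification
#'
#' Counts with overdose as the positive class: `tp` (both true and
#' predicted overdose), `fp` (predicted overdose only), `fn` (true overdose
#' only), `tn` (neither).
#'
#' @param y_true,y_pred Logical vectors of equal, non-zero length.
#' @return An object of class `od_confusion` with fields `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true has ", length(y_true), " labels but y_pred has ",
         length(y_pred), call. = FALSE)
  }
  if (!length(y_true)) stop("cannot tabulate zero predictions", call. = FALSE)
  y_true <- as.logical(y_true); y_pred <- as.logical(y_pred)
  confusion_from_counts(tp = sum(y_pred & y_true),
                        fp = sum(y_pred & !y_true),
                        fn = sum(!y_pred & y_true),
                        tn = sum(!y_pred & !y_true))
}

#' @rdname confusion
#' @param tp,fp,fn,tn Non-negative counts (e.g. transcribed from a
#'   published confusion matrix).
#' @export
confusion_from_counts <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn)),
            class = "od_confusion")
}

#' @export
print.od_confusion <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$tp + x$fn,
                x$fp, x$tn, x$fp + x$tn,
                x$tp + x$fp, x$fn + x$tn, x$tp + x$fp + x$fn + x$tn),
              nrow = 3,
              dimnames = list(c("predicted OD", "predicted not OD", "total"),
                              c("true OD", "true not OD", "total")))
  print(m[c(1, 2, 3), ])
  invisible(x)
}

#' Evaluation metrics from a confusion matrix
#'
#' Positive predictive value `tp/(tp+fp)`, sensitivity `tp/(tp+fn)`,
#' specificity `tn/(tn+fp)`, and the F-score — the harmonic mean
#' `2*ppv*sens/(ppv+sens)`. A metric with a zero denominator is undefined
#' and reported as `NA` with a warning, never as 0.
#'
#' @param cm An `od_confusion`.
#' @return An object of class `od_metrics` with fields `ppv`,
#'   `sensitivity`, `specificity`, `f_score` and the confusion matrix `cm`.
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "od_confusion"))
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " is undefined (zero denominator)", call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  ppv  <- ratio(cm$tp, cm$tp + cm$fp, "PPV")
  sens <- ratio(cm$tp, cm$tp + cm$fn, "sensitivity")
  spec <- ratio(cm$tn, cm$tn + cm$fp, "specificity")
  f <- if (is.na(ppv) || is.na(sens)) {
    NA_real_
  } else if (ppv + sens == 0) {
    0
  } else {
    2 * ppv * sens / (ppv + sens)
  }
  structure(list(ppv = ppv, sensitivity = sens, specificity = spec,
                 f_score = f, cm = cm),
            class = "od_metrics")
}

#' @rdname classification_metrics
#' @param y_true,y_pred Logical vectors; convenience wrapper computing the
#'   confusion matrix first.
#' @export
evaluation_report <- function(y_true, y_pred) {
  classification_metrics(confusion(y_true, y_pred))
}

#' @export
print.od_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "   NA " else sprintf("%.4f", v)
  cat(sprintf("PPV %s  Sensitivity %s  F-score %s  (Specificity %s)\n",
              fmt(x$ppv), fmt(x$sensitivity), fmt(x$f_score),
              fmt(x$specificity)))
  invisible(x)
}

#' One-tailed two-proportion z-test
#'
#' Pooled-variance two-proportion z-test without continuity correction:
#' `z = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2))` with pooled
#' `p = (x1 + x2)/(n1 + n2)`. Used to compare the sensitivity (or PPV) of
#' two classifiers; the default alternative is "greater", i.e. group 1
#' exceeds group 2, with `p = 1 - pnorm(z)`. When the pooled proportion is
#' 0 or 1 both sample proportions are necessarily equal and the statistic
#' is degenerate; the test returns `z = 0, p = 0.5` with a warning.
#'
#' @param x1,n1 Successes and trials in group 1.
#' @param x2,n2 Successes and trials in group 2.
#' @param alternative `"greater"` (default), `"less"` or `"two.sided"`.
#' @return An object of class `od_proportion_test` with fields `z`, `p`,
#'   `estimate` (the two proportions), and the inputs.
#' @export
two_proportion_z_test <- function(x1, n1, x2, n2,
                                  alternative = c("greater", "less",
                                                  "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(n1 >= 1, n2 >= 1, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  p1 <- x1 / n1; p2 <- x2 / n2
  pooled <- (x1 + x2) / (n1 + n2)
  if (pooled == 0 || pooled == 1) {
    warning("degenerate two-proportion test: pooled proportion is ",
            pooled, "; proportions are equal by construction", call. = FALSE)
    z <- 0
  } else {
    z <- (p1 - p2) / sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  }
  p <- switch(alternative,
              greater = 1 - stats::pnorm(z),
              less = stats::pnorm(z),
              two.sided = 2 * (1 - stats::pnorm(abs(z))))
  structure(list(z = z, p = p, estimate = c(p1 = p1, p2 = p2),
                 x = c(x1, x2), n = c(n1, n2), alternative = alternative),
            class = "od_proportion_test")
}

#' @export
print.od_proportion_test <- function(x, ...) {
  cat(sprintf("two-proportion z-test (%s): p1 = %.4f (%d/%d), p2 = %.4f (%d/%d)\n",
              x$alternative, x$estimate[1], x$x[1], x$n[1],
              x$estimate[2], x$x[2], x$n[2]))
  cat(sprintf("  z = %.4f, p = %s\n", x$z,
              if (x$p < 1e-4) format(x$p, digits = 3) else sprintf("%.4f", x$p)))
  invisible(x)
}

#' Reconstruct a count from a published proportion
#'
#' Published reports often print a proportion (e.g. a sensitivity of 0.9243
#' on 912 true positives) without the underlying count. `round(p * n)`
#' recovers the most plausible integer count; this is approximate whenever
#' the printed proportion was itself rounded, and is intended only for
#' re-deriving comparison inputs from published tables.
#'
#' @param p Proportion as printed.
#' @param n Denominator.
#' @return Integer count.
#' @export
count_from_proportion <- function(p, n) {
  stopifnot(p >= 0, p <= 1, n >= 0)
  as.integer(round(p * n))
}
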