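# Classification metrics: per-class one-vs-rest sensitivity,
# specificity and accuracy as percentages, with macro averages.

#' Metrics from a single confusion table
#'
#' `sensitivity = TP/(TP+FN)`, `specificity = TN/(TN+FP)`,
#' `accuracy = (TP+TN)/(TP+TN+FP+FN)`, each as a percentage. Undefined
#' ratios (zero denominator) are returned as `NA`.
#'
#' @param TP,TN,FP,FN Confusion counts.
#' @return Named numeric vector (percent).
#' @export
confusion_metrics <- function(TP, TN, FP, FN) {
  ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  c(sensitivity = ratio(TP, TP + FN),
    specificity = ratio(TN, TN + FP),
    accuracy = ratio(TP + TN, TP + TN + FP + FN))
}

#' Per-class and macro classification metrics
#'
#' Builds one-vs-rest confusion counts for every class of the scheme and
#' reports sensitivity, specificity and accuracy (percent) per class,
#' their macro averages, and the plain overall accuracy
#' (`100 * mean(y_true == y_pred)`).
#'
#' @param y_true,y_pred Equal-length label vectors; every label must be
#'   a class of `scheme`.
#' @param scheme A [label_scheme()] or a character vector of classes.
#' @return A `metrics_report`: `per_class` (data frame), `macro`
#'   (named vector), `overall_accuracy`, `n`.
#' @export
compute_metrics <- function(y_true, y_pred, scheme) {
  classes <- if (inherits(scheme, "label_scheme")) scheme$classes else as.character(scheme)
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) == 0L) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("y_true and y_pred lengths differ")
  bad <- setdiff(unique(c(y_true, y_pred)), classes)
  if (length(bad)) stop("labels outside the scheme: ", paste(bad, collapse = ", "))
  n <- length(y_true)
  rows <- lapply(classes, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    fp <- sum(y_true != cl & y_pred == cl)
    tn <- n - tp - fn - fp
    m <- confusion_metrics(tp, tn, fp, fn)
    data.frame(class = cl, TP = tp, TN = tn, FP = fp, FN = fn,
               sensitivity = m["sensitivity"], specificity = m["specificity"],
               accuracy = m["accuracy"], row.names = NULL)
  })
  per_class <- do.call(rbind, rows)
  macro <- c(sensitivity = mean(per_class$sensitivity, na.rm = TRUE),
             specificity = mean(per_class$specificity, na.rm = TRUE),
             accuracy = mean(per_class$accuracy, na.rm = TRUE))
  structure(list(per_class = per_class, macro = macro,
                 overall_accuracy = 100 * mean(y_true == y_pred), n = n),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n=%d, overall accuracy %.2f%%\n", x$n,
              x$overall_accuracy))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}
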