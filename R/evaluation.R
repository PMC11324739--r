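#' Confusion matrix
#'
#' Counts with capsulitis as the positive class.
#'
#' @param tp,fp,fn,tn Nonnegative integer counts.
#' @return An object of class `acdx_confusion`.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("confusion counts must be nonnegative integers", call. = FALSE)
  counts <- as.integer(counts)
  structure(list(tp = counts[1], fp = counts[2], fn = counts[3],
                 tn = counts[4]), class = "acdx_confusion")
}

#' @export
print.acdx_confusion <- function(x, ...) {
  cat(sprintf("<acdx_confusion> TP %d  FP %d  FN %d  TN %d\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' @export
format.acdx_confusion <- function(x, ...) {
  sprintf("(tp=%d, fp=%d, fn=%d, tn=%d)", x$tp, x$fp, x$fn, x$tn)
}

#' Round half up to 4 decimals
#'
#' Reported metrics are rendered at four decimals with halves rounded up
#' (unlike [round()]'s round-half-to-even).
#'
#' @param x Numeric vector.
#' @return `x` rounded half-up at the 4th decimal.
#' @export
round4 <- function(x) floor(x * 1e4 + 0.5) / 1e4

#' Performance metrics from confusion counts
#'
#' Exact ratios: accuracy `(tp+tn)/total`, precision `tp/(tp+fp)`, recall
#' (sensitivity) `tp/(tp+fn)`, specificity `tn/(tn+fp)`. A metric with a
#' zero denominator is `NA` (undefined); an all-zero matrix is an error.
#'
#' @param cm An `acdx_confusion`, or `tp` as a count with `fp`, `fn`, `tn`.
#' @param fp,fn,tn Counts when `cm` is given as `tp`.
#' @return A one-row tibble with columns `accuracy`, `precision`, `recall`,
#'   `specificity` (exact, unrounded; see [round4()] for reporting).
#' @examples
#' metrics_from_counts(confusion_matrix(23, 5, 9, 18))
#' @export
metrics_from_counts <- function(cm, fp = NULL, fn = NULL, tn = NULL) {
  if (!inherits(cm, "acdx_confusion")) cm <- confusion_matrix(cm, fp, fn, tn)
  tot <- cm$tp + cm$fp + cm$fn + cm$tn
  if (tot == 0) stop("all-zero confusion matrix: metrics undefined",
                     call. = FALSE)
  rat <- function(num, den) if (den == 0) NA_real_ else num / den
  tibble::tibble(
    accuracy = (cm$tp + cm$tn) / tot,
    precision = rat(cm$tp, cm$tp + cm$fp),
    recall = rat(cm$tp, cm$tp + cm$fn),
    specificity = rat(cm$tn, cm$tn + cm$fp)
  )
}

#' Recover integer confusion counts from printed metrics
#'
#' Exhaustively searches `tp` in `0..n_pos` and `fp` in `0..n_neg` for the
#' confusion matrix whose exact precision, recall and specificity each lie
#' within `tol` of the printed values. The default `tol = 1e-4` accommodates
#' both truncation and rounding of values printed at four decimals. Exactly
#' one matrix must qualify: no match raises an inconsistency error, several
#' raise an ambiguity error listing all of them.
#'
#' @param n_pos,n_neg Cohort sizes of the positive and negative class.
#' @param precision,recall,specificity Printed metric values in `[0, 1]`.
#' @param tol Absolute tolerance (default 1e-4).
#' @return An `acdx_confusion`.
#' @examples
#' counts_from_metrics(32, 23, precision = 0.9000, recall = 0.2812,
#'                     specificity = 0.9565)
#' @export
counts_from_metrics <- function(n_pos, n_neg, precision, recall, specificity,
                                tol = 1e-4) {
  stopifnot(n_pos > 0, n_neg > 0)
  for (m in c(precision, recall, specificity))
    if (m < 0 || m > 1) stop("metrics must be in [0, 1]", call. = FALSE)
  hits <- list()
  for (tp in 0:n_pos) {
    if (abs(tp / n_pos - recall) >= tol) next
    for (fp in 0:n_neg) {
      tn <- n_neg - fp
      if (abs(tn / n_neg - specificity) >= tol) next
      prec <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
      if (is.na(prec) || abs(prec - precision) >= tol) next
      hits[[length(hits) + 1]] <- confusion_matrix(tp, fp, n_pos - tp, tn)
    }
  }
  if (length(hits) == 0)
    stop("no integer confusion matrix is consistent with the printed metrics",
         call. = FALSE)
  if (length(hits) > 1)
    stop("printed metrics are ambiguous; consistent matrices: ",
         paste(vapply(hits, format, ""), collapse = ", "), call. = FALSE)
  hits[[1]]
}

#' Evaluate diagnoses against cohort labels
#'
#' @param predictions A tibble with columns `patient_id`, `diagnosis`
#'   (logical, `TRUE` = capsulitis), e.g. from [classify_cohort()].
#' @param labels A tibble with columns `patient_id`, `label`
#'   (`"capsulitis"` / `"non_capsulitis"`).
#' @return An object of class `acdx_eval` with elements `confusion`
#'   (`acdx_confusion`) and `metrics` (one-row tibble); see [tidy.acdx_eval()]
#'   and [glance.acdx_eval()].
#' @export
evaluate_cohort <- function(predictions, labels) {
  miss <- setdiff(predictions$patient_id, labels$patient_id)
  if (length(miss) > 0)
    stop("no label for patient(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  j <- dplyr::inner_join(predictions, labels, by = "patient_id")
  pos <- j$label == "capsulitis"
  cm <- confusion_matrix(
    tp = sum(j$diagnosis & pos), fp = sum(j$diagnosis & !pos),
    fn = sum(!j$diagnosis & pos), tn = sum(!j$diagnosis & !pos)
  )
  structure(list(confusion = cm, metrics = metrics_from_counts(cm)),
            class = "acdx_eval")
}

#' @export
print.acdx_eval <- function(x, ...) {
  cat("<acdx_eval>\n ")
  print(x$confusion)
  m <- x$metrics
  cat(sprintf("  accuracy %.4f  precision %.4f  recall %.4f  specificity %.4f\n",
              round4(m$accuracy), round4(m$precision), round4(m$recall),
              round4(m$specificity)))
  invisible(x)
}

#' Tidy an evaluation
#'
#' @param x An `acdx_eval`.
#' @param ... Unused.
#' @return `tidy()`: a long tibble with one row per metric; `glance()`: a
#'   one-row tibble with the counts and the four metrics.
#' @method tidy acdx_eval
#' @export
tidy.acdx_eval <- function(x, ...) {
  tidyr::pivot_longer(x$metrics, dplyr::everything(),
                      names_to = "metric", values_to = "value")
}

#' @rdname tidy.acdx_eval
#' @method glance acdx_eval
#' @export
glance.acdx_eval <- function(x, ...) {
  dplyr::bind_cols(tibble::as_tibble(unclass(x$confusion)), x$metrics)
}

#' Plot an evaluation
#'
#' A two-panel display: the confusion matrix as a tile plot and the four
#' metrics as a bar chart.
#'
#' @param object An `acdx_eval`.
#' @param ... Unused.
#' @return A ggplot object (metrics bar chart annotated with counts).
#' @method autoplot acdx_eval
#' @export
autoplot.acdx_eval <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.4f", round4(.data$value))),
                       vjust = -0.4, size = 3) +
    ggplot2::ylim(0, 1.05) +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = "Cohort diagnostic performance",
      subtitle = format(object$confusion)
    ) +
    ggplot2::theme_minimal()
}
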