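# Evaluation: binary confusion counts, precision / recall / F1, Matthews
# correlation, and inter-annotator agreement measured as F1. Zero
# denominators yield 0.0 throughout, so an all-positive classifier scores
# recall 1 and MCC 0 (no true or false negatives).

#' Confusion counts for predicted vs gold instances
#'
#' Instances are aligned on (document, sentence, relation type, source span,
#' target span); both tables must cover exactly the same candidate keys.
#'
#' @param pred Instance tibble with predicted 0/1 labels.
#' @param gold Instance tibble with gold 0/1 labels.
#' @return A `relex_confusion` object with fields `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(pred, gold) {
  stopifnot(all(pred$label %in% c(0L, 1L)), all(gold$label %in% c(0L, 1L)))
  kp <- instance_key(pred); kg <- instance_key(gold)
  if (anyDuplicated(kp) || anyDuplicated(kg)) {
    abort("Duplicate instance keys in pred or gold",
          class = "biodivrelex_alignment_error")
  }
  only_p <- setdiff(kp, kg); only_g <- setdiff(kg, kp)
  if (length(only_p) || length(only_g)) {
    abort(sprintf(
      "Prediction and gold instance keys differ (%d only in pred, %d only in gold); first offenders: %s",
      length(only_p), length(only_g),
      paste(gsub("\r", "/", head(c(only_p, only_g), 3)), collapse = "; ")
    ), class = "biodivrelex_alignment_error")
  }
  p <- pred$label[order(kp)]
  g <- gold$label[order(kg)]
  structure(list(
    tp = sum(p == 1 & g == 1), fp = sum(p == 1 & g == 0),
    fn = sum(p == 0 & g == 1), tn = sum(p == 0 & g == 0)
  ), class = "relex_confusion")
}

#' @export
print.relex_confusion <- function(x, ...) {
  cat(sprintf("<confusion> tp=%d fp=%d fn=%d tn=%d\n", x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Precision, recall and F1 from confusion counts
#'
#' @param cc A `relex_confusion` object (or list with tp/fp/fn/tn).
#' @return Named numeric vector `precision`, `recall`, `f1` in `[0, 1]`.
#' @export
prf1 <- function(cc) {
  precision <- safe_div(cc$tp, cc$tp + cc$fp)
  recall <- safe_div(cc$tp, cc$tp + cc$fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

safe_div <- function(num, den) if (den == 0) 0 else num / den

#' Matthews correlation coefficient
#'
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`, with the
#' convention that any zero factor in the denominator gives 0.0 — so the
#' all-positive co-occurrence baseline scores exactly 0.
#'
#' @inheritParams prf1
#' @return A number in `[-1, 1]`.
#' @export
mcc <- function(cc) {
  tp <- as.numeric(cc$tp); fp <- as.numeric(cc$fp)
  fn <- as.numeric(cc$fn); tn <- as.numeric(cc$tn)
  den2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den2 == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den2)
}

#' Inter-annotator agreement as F1
#'
#' Binary F1 treating one annotator's labels as reference and the other's as
#' prediction; exchanging the annotators swaps precision and recall and
#' leaves F1 unchanged, so the measure is symmetric. When full instance
#' tables are given, they are aligned on instance keys (micro-averaged over
#' whatever relation types they contain).
#'
#' @param a,b 0/1 label vectors of equal length, or two instance tibbles
#'   over the same candidate keys.
#' @return Agreement in `[0, 1]`.
#' @export
#' @examples
#' agreement_f1(c(1, 1, 0, 1), c(1, 0, 0, 1))
agreement_f1 <- function(a, b) {
  if (is.data.frame(a)) {
    cc <- confusion_counts(b, a)
  } else {
    stopifnot(length(a) == length(b), all(a %in% 0:1), all(b %in% 0:1))
    cc <- list(tp = sum(b == 1 & a == 1), fp = sum(b == 1 & a == 0),
               fn = sum(b == 0 & a == 1), tn = sum(b == 0 & a == 0))
  }
  unname(prf1(cc)[["f1"]])
}

#' Evaluate predicted relations against gold
#'
#' @param pred Instance tibble with predicted 0/1 labels.
#' @param gold Instance tibble with gold 0/1 labels over the same keys.
#' @param method Optional label recorded in the result (e.g. `"regex"`).
#' @return A `relex_eval` object; use [tidy()] for a long metric table,
#'   [glance()] for a one-row summary, [autoplot()] for a bar chart.
#' @export
evaluate_relations <- function(pred, gold, method = NULL) {
  cc <- confusion_counts(pred, gold)
  p <- prf1(cc)
  if (is.null(method)) {
    tags <- unique(stats::na.omit(pred$predicted_by))
    method <- if (length(tags)) paste(tags, collapse = "+") else "unknown"
  }
  structure(list(
    method = method,
    confusion = cc,
    precision = p[["precision"]], recall = p[["recall"]], f1 = p[["f1"]],
    mcc = mcc(cc),
    n_instances = cc$tp + cc$fp + cc$fn + cc$tn
  ), class = "relex_eval")
}

#' @export
print.relex_eval <- function(x, ...) {
  cat(sprintf("<relex_eval> method=%s n=%d\n", x$method, x$n_instances))
  cat(sprintf("  P=%.2f%%  R=%.2f%%  F1=%.2f%%  MCC=%.2f\n",
              100 * x$precision, 100 * x$recall, 100 * x$f1, x$mcc))
  invisible(x)
}

#' @export
tidy.relex_eval <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    metric = c("precision", "recall", "f1", "mcc"),
    value = c(x$precision, x$recall, x$f1, x$mcc)
  )
}

#' @export
glance.relex_eval <- function(x, ...) {
  tibble::tibble(
    method = x$method, precision = x$precision, recall = x$recall,
    f1 = x$f1, mcc = x$mcc,
    tp = x$confusion$tp, fp = x$confusion$fp,
    fn = x$confusion$fn, tn = x$confusion$tn,
    n_instances = x$n_instances
  )
}

#' @export
autoplot.relex_eval <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_cartesian(ylim = c(min(0, min(d$value)), 1)) +
    ggplot2::labs(title = sprintf("Relation extraction metrics (%s)", object$method),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Per-method metrics report
#'
#' Formats one or more evaluations the way relation-extraction results are
#' conventionally tabulated: percentages with two decimals for P/R/F1 and a
#' raw two-decimal MCC.
#'
#' @param evals A `relex_eval`, or a list of them.
#' @param format `"markdown"` or `"tsv"`.
#' @return A single string (also suitable for `cat()`).
#' @export
metrics_report <- function(evals, format = c("markdown", "tsv")) {
  format <- match.arg(format)
  if (inherits(evals, "relex_eval")) evals <- list(evals)
  d <- bind_rows(purrr::map(evals, glance))
  cells <- cbind(
    d$method,
    sprintf("%.2f", 100 * d$precision), sprintf("%.2f", 100 * d$recall),
    sprintf("%.2f", 100 * d$f1), sprintf("%.2f", d$mcc)
  )
  header <- c("Method", "P(%)", "R(%)", "F(%)", "MCC")
  if (format == "tsv") {
    paste(c(paste(header, collapse = "\t"),
            apply(cells, 1, paste, collapse = "\t")), collapse = "\n")
  } else {
    paste(c(paste0("| ", paste(header, collapse = " | "), " |"),
            paste0("|", paste(rep("---", 5), collapse = "|"), "|"),
            apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))),
          collapse = "\n")
  }
}
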