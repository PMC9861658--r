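# Evaluation: confusion counts at the strict >0.5 threshold, AUROC with
# tie handling equal to the pairwise-comparison probability, AUPRC as the
# area under the precision-recall step curve, earliness in hours, and the
# percentage-point comparison arithmetic used when contrasting runs.

#' Confusion counts at a probability threshold
#'
#' A positive call requires a score strictly above the threshold.
#'
#' @param scores Episode scores.
#' @param labels Logical (or 0/1) episode labels.
#' @param threshold Decision threshold (default 0.5, strict).
#' @return Tibble: `tp`, `fp`, `tn`, `fn`, `precision`, `recall`.
#' @export
confusion_counts <- function(scores, labels, threshold = 0.5) {
  if (length(scores) != length(labels)) abort("scores/labels length mismatch.")
  labels <- as.logical(labels)
  call_pos <- scores > threshold
  tp <- sum(call_pos & labels); fp <- sum(call_pos & !labels)
  tn <- sum(!call_pos & !labels); fn <- sum(!call_pos & labels)
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_
  )
}

#' Area under the receiver operating characteristic curve
#'
#' Computed from ranks so that the result equals the pairwise-comparison
#' probability `P(score_pos > score_neg) + 0.5 P(tie)`.
#'
#' @param scores Episode scores.
#' @param labels Logical labels; both classes must be present.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    abort("AUROC is undefined with a single class.")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall step curve
#'
#' Descending-score sweep with tied scores grouped; the area is
#' `sum(delta recall * precision)` over threshold groups, which equals the
#' average-precision form of the step-curve integral.
#'
#' @param scores Episode scores.
#' @param labels Logical labels; at least one positive required.
#' @return AUPRC in `[0, 1]`.
#' @export
auprc <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  if (n_pos == 0L) abort("AUPRC requires at least one positive.")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp_end <- which(s != c(s[-1], NA) | seq_along(s) == length(s))
  tp_cum <- cumsum(y)[grp_end]
  n_cum <- grp_end
  prec <- tp_cum / n_cum
  rec <- tp_cum / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' Median prediction earliness over true-positive episodes
#'
#' For episodes that are truly septic and locked (first window with
#' probability strictly above 0.5), the lead is
#' `onset_window - lock_window` hours; the earliness is the median lead.
#' Larger is better. With zero true positives the value is absent, with a
#' warning.
#'
#' @param traces Prediction tibble from [predict_cohort()] (`label`,
#'   `onset_window`, `lock_window`).
#' @return Median lead in hours, or `NA` with a warning.
#' @export
earliness <- function(traces) {
  tp <- traces$label & !is.na(traces$lock_window)
  if (!any(tp)) {
    warn("no true-positive episodes; earliness is undefined.")
    return(NA_real_)
  }
  stats::median(traces$onset_window[tp] - traces$lock_window[tp])
}

#' Full metrics report for a set of prediction traces
#'
#' @param traces Prediction tibble from [predict_cohort()].
#' @param threshold Decision threshold for the confusion counts.
#' @return One-row `metrics_report` tibble: `auprc`, `auroc`,
#'   `earliness_h`, the confusion counts, and `n_episodes`.
#' @export
evaluate_predictions <- function(traces, threshold = 0.5) {
  cc <- confusion_counts(traces$episode_score, traces$label, threshold)
  out <- tibble::tibble(
    auprc = auprc(traces$episode_score, traces$label),
    auroc = auroc(traces$episode_score, traces$label),
    earliness_h = if (cc$tp >= 1)
      earliness(traces) else suppressWarnings(earliness(traces)),
    tp = cc$tp, fp = cc$fp, tn = cc$tn, fn = cc$fn,
    n_episodes = nrow(traces)
  )
  class(out) <- c("metrics_report", class(out))
  out
}

#' Percentage-point deltas between two metric reports
#'
#' `(a - b) * 100` for AUPRC and AUROC, rounded half-up to two decimals --
#' the arithmetic used when comparing input-feature regimes or aggregation
#' rules across runs.
#'
#' @param a,b One-row metric reports (or any lists with `auprc`/`auroc`
#'   fractions).
#' @return Tibble with `auprc_delta_pp` and `auroc_delta_pp`.
#' @export
#' @examples
#' compare_reports(list(auprc = 0.9655, auroc = 0.9935),
#'                 list(auprc = 0.8730, auroc = 0.9831))
compare_reports <- function(a, b) {
  tibble::tibble(
    auprc_delta_pp = round_half_up((a$auprc - b$auprc) * 100, 2),
    auroc_delta_pp = round_half_up((a$auroc - b$auroc) * 100, 2)
  )
}
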