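#' Confusion summary of a model screen
#'
#' Cross-tabulates model truth (optimal / true) against screen predictions
#' (feasible / positive) and derives prestudy odds R (true : false models in
#' the tested set), FPR, FNR, FDR, PPV and the false omission rate.
#'
#' @param truth Logical vector: is the model true (optimal)?
#' @param predicted Logical vector: did the screen call the model positive
#'   (feasible)?
#' @return One-row tibble with `tp`, `fp`, `tn`, `fn`, `odds`, `fpr`,
#'   `fnr`, `fdr`, `ppv`, `fomr`.
#' @export
confusion_summary <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  ok <- !is.na(truth) & !is.na(predicted)
  truth <- truth[ok]; predicted <- predicted[ok]
  tp <- sum(truth & predicted); fp <- sum(!truth & predicted)
  tn <- sum(!truth & !predicted); fn <- sum(truth & !predicted)
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    odds = (tp + fn) / (fp + tn),
    fpr = fp / (fp + tn),
    fnr = fn / (tp + fn),
    fdr = if (tp + fp > 0) fp / (tp + fp) else NA_real_,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    fomr = if (tn + fn > 0) fn / (tn + fn) else NA_real_
  )
}

#' False discovery rate from prestudy odds and error rates
#'
#' FDR = FPR / (R - FNR * R + FPR), where R is the prestudy odds (true :
#' false models in the tested set), FPR the false-positive rate and FNR the
#' false-negative rate. Identical to the count-based FDR of
#' [confusion_summary()].
#'
#' @param odds Prestudy odds R (> 0).
#' @param fpr,fnr Error rates in \[0, 1\].
#' @return FDR in \[0, 1\].
#' @export
fdr_from_rates <- function(odds, fpr, fnr) {
  stopifnot(odds > 0, fpr >= 0, fpr <= 1, fnr >= 0, fnr <= 1)
  den <- odds - fnr * odds + fpr
  if (den == 0) stop("FDR undefined: no predicted positives (denominator 0)")
  fpr / den
}
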