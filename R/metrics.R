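#' ROC curve and area under the curve
#'
#' Sweeps every decision threshold (scores `>=` threshold predict positive),
#' building ROC vertices from the sorted unique scores plus `+/-Inf`
#' sentinels; the AUC is the trapezoidal area, which equals the tie-corrected
#' Mann-Whitney statistic (probability that a random positive outscores a
#' random negative, ties counted half).
#'
#' @param scores numeric decision values.
#' @param labels `{+1, -1}` with both classes present.
#' @return list with `roc` (data.frame of `threshold`, `specificity`,
#'   `sensitivity`) and `auc`.
#' @export
roc_and_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(scores) != length(labels)) pm_stop("scores/labels length mismatch", "dim_mismatch")
  if (!all(labels %in% c(-1, 1))) pm_stop("labels must be +1/-1", "bad_labels")
  if (length(unique(labels)) < 2L) pm_stop("both classes required for a ROC", "single_class")
  npos <- sum(labels > 0); nneg <- sum(labels < 0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tp <- vapply(thr, function(t) sum(scores >= t & labels > 0), numeric(1))
  fp <- vapply(thr, function(t) sum(scores >= t & labels < 0), numeric(1))
  sens <- tp / npos
  spec <- 1 - fp / nneg
  auc <- sum(diff(1 - spec) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
  list(roc = data.frame(threshold = thr, specificity = spec, sensitivity = sens),
       auc = auc)
}

#' Sensitivity at a fixed specificity setpoint
#'
#' Linearly interpolates the ROC between the two vertices bracketing the
#' requested specificity (the screening convention used for reporting a
#' sensitivity at specificity 0.85); if the setpoint is attained exactly at a
#' vertex, that vertex's sensitivity is returned (taking the best such vertex
#' when ties occur).
#'
#' @param roc data.frame from [roc_and_auc()] (`specificity`, `sensitivity`).
#' @param setpoint target specificity in \[0, 1\] (default 0.85).
#' @return interpolated sensitivity.
#' @export
sensitivity_at_specificity <- function(roc, setpoint = 0.85) {
  # reduce to the attainable ROC staircase: best sensitivity per specificity
  sp_u <- sort(unique(roc$specificity))
  se_u <- vapply(sp_u, function(s) max(roc$sensitivity[roc$specificity == s]),
                 numeric(1))
  exact <- sp_u == setpoint
  if (any(exact)) return(se_u[exact])
  lo <- max(which(sp_u < setpoint))
  hi <- min(which(sp_u > setpoint))
  se_u[lo] + (se_u[hi] - se_u[lo]) * (setpoint - sp_u[lo]) / (sp_u[hi] - sp_u[lo])
}

#' Sensitivity, specificity and balanced accuracy from confusion counts
#'
#' Balanced accuracy is the mean of sensitivity `tp/(tp+fn)` and specificity
#' `tn/(tn+fp)` -- the appropriate summary for a 2.6%-prevalence screening
#' cohort, where raw accuracy is dominated by the negatives.
#'
#' @param tp,fp,tn,fn confusion counts; each class must be represented
#'   (`tp+fn >= 1`, `tn+fp >= 1`).
#' @return named numeric vector `(sensitivity, specificity, balanced_accuracy)`.
#' @export
balanced_accuracy <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) pm_stop("confusion counts must be non-negative", "bad_counts")
  if (tp + fn < 1 || tn + fp < 1) pm_stop("each class needs at least one subject", "single_class")
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  c(sensitivity = sens, specificity = spec, balanced_accuracy = (sens + spec) / 2)
}
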