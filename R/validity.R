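## Content validity of the scoring instrument and cut-off validation of the
## score against independent clinical rater labels.

#' Item-level content validity index (I-CVI)
#'
#' Proportion of experts rating the item 3 or 4 on the 4-point Likert scale
#' (the standard Lynn dichotomization of "relevant").
#'
#' @param ratings Integer Likert ratings in 1..4, one per rater.
#' @return Proportion in `[0, 1]`.
#' @export
item_cvi <- function(ratings) {
  if (length(ratings) == 0) stop("item_cvi: empty ratings")
  if (any(!ratings %in% 1:4)) stop("item_cvi: ratings must be integers 1..4")
  mean(ratings >= 3)
}

#' Scale-level content validity index, averaging method (S-CVI/Ave)
#'
#' @param i_cvis Per-item I-CVI proportions.
#' @return Their arithmetic mean.
#' @export
scale_cvi_ave <- function(i_cvis) {
  if (length(i_cvis) == 0) stop("scale_cvi_ave: empty input")
  if (any(i_cvis < 0 | i_cvis > 1)) stop("scale_cvi_ave: I-CVIs must be in [0, 1]")
  mean(i_cvis)
}

#' Content validity report for an expert panel
#'
#' Computes, per item, the I-CVI and mean Likert score for relevance and
#' clarity, and the S-CVI/Ave per scale plus overall (mean over all item
#' I-CVIs of both scales).
#'
#' @param panel A validated panel data.frame (see [read_panel()]).
#' @return A list of class `pp_cvi`: `items` (per-item data.frame),
#'   `s_cvi_ave_relevance`, `s_cvi_ave_clarity`, `s_cvi_ave_overall`,
#'   `n_raters`.
#' @export
cvi_report <- function(panel) {
  panel <- validate_panel(panel)
  items <- intersect(.pp_items, unique(panel$item_id))
  per <- do.call(rbind, lapply(items, function(it) {
    sub <- panel[panel$item_id == it, ]
    data.frame(item_id = it,
               n_raters = nrow(sub),
               i_cvi_relevance = item_cvi(sub$relevance),
               i_cvi_clarity = item_cvi(sub$clarity),
               mean_relevance = mean(sub$relevance),
               mean_clarity = mean(sub$clarity),
               stringsAsFactors = FALSE)
  }))
  structure(list(
    items = per,
    s_cvi_ave_relevance = scale_cvi_ave(per$i_cvi_relevance),
    s_cvi_ave_clarity = scale_cvi_ave(per$i_cvi_clarity),
    s_cvi_ave_overall = scale_cvi_ave(c(per$i_cvi_relevance,
                                        per$i_cvi_clarity)),
    n_raters = length(unique(panel$rater_id))), class = "pp_cvi")
}

#' @export
print.pp_cvi <- function(x, ...) {
  cat("Content validity (", x$n_raters, " raters, ", nrow(x$items),
      " items)\n", sep = "")
  print(x$items, row.names = FALSE, digits = 3)
  cat(sprintf("S-CVI/Ave: relevance %.3f, clarity %.3f, overall %.3f\n",
              x$s_cvi_ave_relevance, x$s_cvi_ave_clarity, x$s_cvi_ave_overall))
  invisible(x)
}

## Cut-off validation ---------------------------------------------------------

## Score-based prediction at a cut-off: the headache-naive pathway is
## diagnostic on its own (with A and D), the pre-existing pathway needs
## total >= cutoff (ties predict positive, matching the ">= 9" threshold).
predict_at_cutoff <- function(scores, cutoff) {
  AD <- scores$criterion_A & scores$criterion_D
  (scores$pathway == "new_onset_B" & AD) |
    (scores$pathway == "preexisting_C" & AD & scores$total >= cutoff)
}

#' Validate a score cut-off against one rater's labels
#'
#' Builds the confusion matrix of the score-based prediction against the
#' rater's binary classification (the rater is the reference standard) and
#' reports sensitivity, specificity, and the single-threshold AUC
#' `(sensitivity + specificity) / 2` -- the trapezoidal area under the
#' three-point ROC `(0,0), (1 - spec, sens), (1,1)` of an
#' already-thresholded classifier.
#'
#' @param scores A [score_cohort()] result.
#' @param labels Rater labels for a single rater (`rater_id`, `patient_id`,
#'   `label`).
#' @param cutoff Integer cut-off applied to the pre-existing-pathway total.
#' @return A list of class `pp_cutoff_validation`: `rater_id`, `cutoff`,
#'   `tp`, `fp`, `tn`, `fn`, `sensitivity`, `specificity`, `auc`.
#' @export
confusion_at_cutoff <- function(scores, labels, cutoff) {
  labels <- validate_raters(labels)
  if (length(unique(labels$rater_id)) != 1)
    stop("confusion_at_cutoff validates one rater at a time; got ",
         length(unique(labels$rater_id)))
  unknown <- setdiff(labels$patient_id, scores$patient_id)
  if (length(unknown) > 0)
    stop("rater labels reference unknown patient(s): ",
         paste(unknown, collapse = ", "))
  idx <- match(labels$patient_id, scores$patient_id)
  pred <- predict_at_cutoff(scores[idx, ], cutoff)
  truth <- labels$label
  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  tn <- sum(!pred & !truth); fn <- sum(!pred & truth)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  structure(list(rater_id = labels$rater_id[1], cutoff = cutoff,
                 tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = sens, specificity = spec,
                 auc = (sens + spec) / 2),
            class = "pp_cutoff_validation")
}

#' Sweep cut-offs across raters
#'
#' @param scores A [score_cohort()] result.
#' @param labels Rater labels, possibly several raters.
#' @param cutoffs Integer cut-offs to test (default the three candidate
#'   values 8, 9, 10).
#' @return A data.frame with one row per (rater, cutoff).
#' @export
validate_cutoffs <- function(scores, labels, cutoffs = c(8, 9, 10)) {
  labels <- validate_raters(labels)
  grid <- expand.grid(rater_id = unique(labels$rater_id), cutoff = cutoffs,
                      stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    cv <- confusion_at_cutoff(scores,
                              labels[labels$rater_id == grid$rater_id[i], ],
                              grid$cutoff[i])
    as.data.frame(unclass(cv), stringsAsFactors = FALSE)
  }))
}

#' Rater agreement with a reference classification
#'
#' Operating characteristics of a rater's labels against a known reference
#' (e.g. simulation ground truth): the probability of labelling a true
#' positive as positive and a true negative as negative. This is the
#' direction the rater-simulation flip model controls.
#'
#' @param labels One rater's labels.
#' @param reference A data.frame with `patient_id` and logical `truth`.
#' @return A list with `sensitivity`, `specificity`, and counts.
#' @export
rater_agreement <- function(labels, reference) {
  labels <- validate_raters(labels)
  idx <- match(labels$patient_id, reference$patient_id)
  if (anyNA(idx)) stop("labels reference unknown patient(s)")
  truth <- reference$truth[idx]
  lab <- labels$label
  list(sensitivity = sum(lab & truth) / sum(truth),
       specificity = sum(!lab & !truth) / sum(!truth),
       n_positive = sum(truth), n_negative = sum(!truth))
}

## Binormal ROC ---------------------------------------------------------------

#' Fit a binormal ROC model
#'
#' Assumes the score is normally distributed within each label class. With
#' the label-positive group as reference: `a = (mean_pos - mean_neg)/sd_pos`,
#' `b = sd_neg/sd_pos`; the smooth ROC is `TPR(t) = Phi(a + b * Phi^-1(t))`
#' and its area `Phi(a / sqrt(1 + b^2))`.
#'
#' @param pos_scores Score totals of label-positive patients.
#' @param neg_scores Score totals of label-negative patients.
#' @return A list of class `pp_binormal`: `a`, `b`, `auc_smooth`.
#' @export
fit_binormal <- function(pos_scores, neg_scores) {
  if (length(unique(pos_scores)) < 2 || length(unique(neg_scores)) < 2)
    stop("binormal fit requires >= 2 distinct values in each group")
  sd_pos <- stats::sd(pos_scores)
  if (sd_pos == 0) stop("degenerate binormal fit: zero variance in positives")
  a <- (mean(pos_scores) - mean(neg_scores)) / sd_pos
  b <- stats::sd(neg_scores) / sd_pos
  structure(list(a = a, b = b,
                 auc_smooth = stats::pnorm(a / sqrt(1 + b^2))),
            class = "pp_binormal")
}

#' Smooth ROC curve coordinates of a binormal fit
#'
#' @param fit A [fit_binormal()] result.
#' @param fpr Grid of false-positive rates.
#' @return A data.frame with `fpr`, `tpr`.
#' @export
binormal_curve <- function(fit, fpr = seq(0, 1, by = 0.01)) {
  stopifnot(inherits(fit, "pp_binormal"))
  data.frame(fpr = fpr, tpr = stats::pnorm(fit$a + fit$b * stats::qnorm(fpr)))
}

#' Trapezoidal area under an ROC polyline
#'
#' @param fpr,tpr Curve coordinates; `(0,0)` and `(1,1)` are appended if
#'   absent.
#' @return Area in `[0, 1]`.
#' @export
auc_trapezoid <- function(fpr, tpr) {
  stopifnot(length(fpr) == length(tpr))
  ord <- order(fpr, tpr)
  x <- c(0, fpr[ord], 1)
  y <- c(0, tpr[ord], 1)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}
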