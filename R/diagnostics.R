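# Cohort tables are plain data.frames with columns subject_id,
# reference_pmol_L, predicted_pmol_L and (optionally) flag. Rows whose
# flag is not "ok" carry a clamped/extrapolated prediction whose
# magnitude is not usable: they take part in classification via the
# flag, but are excluded from bias and correlation.

usable_rows <- function(cohort, need_positive_ref = TRUE) {
  flag <- if (is.null(cohort$flag)) rep("ok", nrow(cohort)) else cohort$flag
  ok <- flag == "ok" & is.finite(cohort$predicted_pmol_L)
  if (need_positive_ref) ok <- ok & cohort$reference_pmol_L > 0
  ok
}

#' Median relative bias of predicted vs reference concentrations
#'
#' The median over subjects of `100 * (predicted - reference) /
#' reference`. Range-flagged rows and rows with a non-positive
#' reference are excluded (with a message giving the count): a clamped
#' "greater-than" prediction has no usable magnitude.
#'
#' @param cohort cohort table (see [predict_cohort()]).
#' @return Median bias in percent.
#' @export
median_bias <- function(cohort) {
  ok <- usable_rows(cohort)
  if (sum(!ok) > 0)
    message(sprintf("median_bias: excluded %d range-flagged/unusable row(s)",
                    sum(!ok)))
  if (!any(ok)) abort_input("no usable rows for bias computation")
  with(cohort[ok, ], median(100 * (predicted_pmol_L - reference_pmol_L) /
                              reference_pmol_L))
}

#' Correlation of predicted vs reference concentrations
#'
#' Pearson correlation (the conventional signed method-comparison
#' report) with the two-sided p-value from the t transform; Spearman is
#' available as an option. Range-flagged rows are excluded.
#'
#' For a small worked check, the 4-subject table with reference
#' (100, 200, 300, 400) and predicted (110, 190, 310, 390) has
#' r = 48000 / sqrt(50000 * 46400) = 0.99655 by the product-moment
#' formula.
#'
#' @param cohort cohort table.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List with `estimate`, `p_value`, `n`, `method`.
#' @export
cohort_correlation <- function(cohort, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- usable_rows(cohort)
  if (sum(ok) < 3L) abort_input("correlation needs at least 3 usable pairs")
  x <- cohort$reference_pmol_L[ok]
  y <- cohort$predicted_pmol_L[ok]
  if (sd(x) == 0 || sd(y) == 0)
    abort_input("correlation undefined: zero variance")
  ct <- cor.test(x, y, method = method, exact = FALSE)
  list(estimate = unname(ct$estimate), p_value = ct$p.value,
       n = sum(ok), method = method)
}

#' Classify a concentration against a deficiency cut-off
#'
#' Deficient iff concentration is strictly below the cut-off. Range
#' flags override the magnitude: `below_range` classifies as deficient,
#' `above_range` as not deficient, whatever the cut-off.
#'
#' @param conc concentration(s), pmol/L.
#' @param cutoff clinical cut-off, pmol/L (e.g. 150, 221, 258 or 332
#'   for vitamin-B12 deficiency).
#' @param flag optional range flag(s) (`"ok"`, `"below_range"`,
#'   `"above_range"`), recycled.
#' @return Character vector, `"deficient"` or `"not_deficient"`.
#' @export
classify_deficiency <- function(conc, cutoff, flag = "ok") {
  flag <- rep_len(flag, length(conc))
  out <- ifelse(conc < cutoff, "deficient", "not_deficient")
  out[flag == "below_range"] <- "deficient"
  out[flag == "above_range"] <- "not_deficient"
  out
}

#' Sensitivity and specificity at a clinical cut-off
#'
#' The reference classification (deficient = reference concentration
#' strictly below `cutoff`) defines the positive class; the prediction
#' is classified with the same cut-off (flags respected). An undefined
#' metric (no positives, or no negatives) is returned as `NA` with the
#' reason in attribute `"reason"`.
#'
#' @param cohort cohort table.
#' @param cutoff cut-off, pmol/L.
#' @return List: `cutoff`, `sensitivity`, `specificity`, `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
sens_spec <- function(cohort, cutoff) {
  flag <- if (is.null(cohort$flag)) rep("ok", nrow(cohort)) else cohort$flag
  truth <- cohort$reference_pmol_L < cutoff
  call <- classify_deficiency(cohort$predicted_pmol_L, cutoff, flag) ==
    "deficient"
  tp <- sum(truth & call); fn <- sum(truth & !call)
  tn <- sum(!truth & !call); fp <- sum(!truth & call)
  sens <- if (tp + fn == 0)
    structure(NA_real_, reason = "no reference-positive subjects")
  else tp / (tp + fn)
  spec <- if (tn + fp == 0)
    structure(NA_real_, reason = "no reference-negative subjects")
  else tn / (tn + fp)
  list(cutoff = cutoff, sensitivity = sens, specificity = spec,
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' ROC curve for deficiency detection
#'
#' Deficiency (reference concentration strictly below
#' `reference_cutoff`) is the positive class; predictions enter as
#' concentrations with the "predicted < threshold means positive"
#' decision rule. Thresholds sweep every distinct predicted value plus
#' the two infinities, yielding the full (FPR, TPR) staircase; the AUC
#' is the trapezoidal integral, which for a staircase equals the
#' Mann-Whitney concordance probability.
#'
#' @param cohort cohort table.
#' @param reference_cutoff deficiency cut-off applied to the reference
#'   values, pmol/L.
#' @return List with `points` (data.frame `fpr`, `tpr`, `cutoff`,
#'   nondecreasing in `fpr`) and `auc`.
#' @export
roc_curve <- function(cohort, reference_cutoff) {
  truth <- cohort$reference_pmol_L < reference_cutoff
  if (!any(truth) || all(truth))
    abort_input("ROC needs at least one positive and one negative subject")
  pred <- cohort$predicted_pmol_L
  thresholds <- c(sort(unique(pred[is.finite(pred)])), Inf)
  pts <- t(vapply(thresholds, function(t) {
    call <- pred < t
    c(fpr = sum(call & !truth) / sum(!truth),
      tpr = sum(call & truth) / sum(truth))
  }, c(fpr = 0, tpr = 0)))
  pts <- data.frame(fpr = c(0, pts[, "fpr"], 1),
                    tpr = c(0, pts[, "tpr"], 1),
                    cutoff = c(-Inf, thresholds, Inf))
  pts <- pts[order(pts$fpr, pts$tpr), , drop = FALSE]
  pts <- pts[!duplicated(pts[, c("fpr", "tpr")]), , drop = FALSE]
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + diff(pts$tpr) / 2))
  list(points = pts, auc = auc)
}

#' Summarise diagnostic performance of a cohort
#'
#' Bundles the method-comparison and classification statistics for a
#' cohort table: median relative bias, Pearson correlation,
#' sensitivity/specificity at each requested clinical cut-off, and the
#' ROC curve with AUC at the reference cut-off.
#'
#' @param cohort cohort table with `reference_pmol_L`,
#'   `predicted_pmol_L` and optionally `flag`.
#' @param cutoffs cut-offs at which to report sensitivity/specificity;
#'   defaults to the vitamin-B12 deficiency cut-offs in clinical use
#'   (150, 221, 258, 332 pmol/L).
#' @param reference_cutoff cut-off defining the positive class for the
#'   ROC (default 332 pmol/L).
#' @return A `diagnostic_summary` list: `median_bias_pct`, `pearson`
#'   (list), `per_cutoff` (data.frame), `roc`, `auc`, `n`,
#'   `n_excluded`.
#' @export
diagnostic_summary <- function(cohort, cutoffs = c(150, 221, 258, 332),
                               reference_cutoff = 332) {
  if (any(diff(cutoffs) <= 0) || any(cutoffs <= 0))
    abort_config("`cutoffs` must be positive and strictly increasing")
  ok <- usable_rows(cohort)
  ss <- lapply(cutoffs, function(k) sens_spec(cohort, k))
  per_cutoff <- data.frame(
    cutoff = cutoffs,
    sensitivity = vapply(ss, function(s) as.numeric(s$sensitivity), 0),
    specificity = vapply(ss, function(s) as.numeric(s$specificity), 0),
    tp = vapply(ss, `[[`, 0, "tp"), fp = vapply(ss, `[[`, 0, "fp"),
    tn = vapply(ss, `[[`, 0, "tn"), fn = vapply(ss, `[[`, 0, "fn")
  )
  roc <- roc_curve(cohort, reference_cutoff)
  structure(
    list(
      median_bias_pct = suppressMessages(median_bias(cohort)),
      pearson = cohort_correlation(cohort),
      per_cutoff = per_cutoff,
      roc = roc$points, auc = roc$auc,
      reference_cutoff = reference_cutoff,
      n = nrow(cohort), n_excluded = sum(!ok)
    ),
    class = "diagnostic_summary"
  )
}

#' @export
print.diagnostic_summary <- function(x, ...) {
  cat(sprintf("<diagnostic_summary> n = %d (%d range-flagged excluded from bias/correlation)\n",
              x$n, x$n_excluded))
  cat(sprintf("  median bias: %+.2f%%   Pearson r: %.3f (p = %.2g)\n",
              x$median_bias_pct, x$pearson$estimate, x$pearson$p_value))
  cat(sprintf("  ROC AUC at %g pmol/L: %.3f\n", x$reference_cutoff, x$auc))
  print(x$per_cutoff, row.names = FALSE, digits = 3)
  invisible(x)
}
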