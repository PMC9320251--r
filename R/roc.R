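#' ROC curve of a candidate biomarker
#'
#' Builds the full ROC path over all observed score values plus infinite
#' sentinels, so (0,0) and (1,1) are always on the curve. The orientation
#' (whether large or small values indicate frailty) is chosen automatically
#' as the direction giving AUC >= 0.5, and is part of the returned object
#' (print it to see the implied inequality, e.g. "positive if value <=
#' cutoff"). Classification is non-strict on the positive side. Missing
#' scores are dropped with a message.
#'
#' @param values numeric index values, one per subject.
#' @param labels group labels (character/factor/logical).
#' @param positive label of the positive (frail) class; default `"F"`.
#' @param orientation `"auto"` (default), `"positive_if_greater"` or
#'   `"positive_if_less"`.
#' @param indexName name used in printing and result tables.
#' @return a [ROCCurve-class] object.
#' @export
rocCurve <- function(values, labels, positive = "F",
                     orientation = c("auto", "positive_if_greater",
                                     "positive_if_less"),
                     indexName = "index") {
  orientation <- match.arg(orientation)
  .stopIfNot(length(values) == length(labels),
             "values and labels must have equal length")
  pos <- if (is.logical(labels)) labels else labels == positive
  keep <- is.finite(values) & !is.na(pos)
  if (any(!keep))
    message(sprintf("dropping %d subject(s) with missing values",
                    sum(!keep)))
  values <- values[keep]
  pos <- pos[keep]
  .stopIfNot(any(pos) && any(!pos),
             "both classes must be present for a ROC curve")
  build <- function(orient) {
    if (orient == "positive_if_greater") {
      thr <- c(Inf, sort(unique(values), decreasing = TRUE), -Inf)
      pred <- outer(values, thr, ">=")
    } else {
      thr <- c(-Inf, sort(unique(values)), Inf)
      pred <- outer(values, thr, "<=")
    }
    tpr <- colSums(pred & pos) / sum(pos)
    fpr <- colSums(pred & !pos) / sum(!pos)
    list(thr = thr, tpr = tpr, fpr = fpr)
  }
  if (orientation == "auto") {
    g <- build("positive_if_greater")
    aucG <- pracma::trapz(g$fpr, g$tpr)
    orientation <- if (aucG >= 0.5) "positive_if_greater" else
      "positive_if_less"
  }
  b <- build(orientation)
  new("ROCCurve", thresholds = b$thr, tpr = b$tpr, fpr = b$fpr,
      orientation = orientation, scores = values, labels = pos,
      indexName = indexName, positiveLabel = as.character(positive))
}

#' AUC with Hanley-McNeil confidence interval
#'
#' Trapezoidal AUC along the ROC path (identical to the midrank
#' Mann-Whitney estimator `U / (n1 * n2)`), standard error by the
#' Hanley-McNeil formula, 95% CI `AUC +/- 1.96 * SE`, and a two-sided
#' normal-approximation p-value for the null AUC = 0.5.
#'
#' @param curve a [ROCCurve-class].
#' @param conf confidence level, default 0.95.
#' @return one-row data.frame with `auc`, `ci_lo`, `ci_hi`, `se`,
#'   `p_value`, `n_pos`, `n_neg`, `unreliable` (TRUE when either class has
#'   fewer than 2 subjects).
#' @export
aucWithCi <- function(curve, conf = 0.95) {
  .stopIfNot(is(curve, "ROCCurve"), "curve must be a ROCCurve")
  ord <- order(curve@fpr, curve@tpr)
  auc <- pracma::trapz(curve@fpr[ord], curve@tpr[ord])
  n1 <- sum(curve@labels)
  n2 <- sum(!curve@labels)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  rad <- (auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
            (n2 - 1) * (q2 - auc^2)) / (n1 * n2)
  se <- sqrt(max(rad, 0))   # guards rounding at auc = 1 exactly
  z <- qnorm(1 - (1 - conf) / 2)
  p <- if (se > 0) 2 * pnorm(-abs(auc - 0.5) / se) else
    as.numeric(auc == 0.5)
  data.frame(auc = auc, ci_lo = auc - z * se, ci_hi = auc + z * se,
             se = se, p_value = p, n_pos = n1, n_neg = n2,
             unreliable = n1 < 2 || n2 < 2)
}

#' Optimal cut-off by shortest orthogonal distance
#'
#' Selects the ROC point minimizing the Euclidean distance
#' `sqrt(fpr^2 + (1 - tpr)^2)` to the optimal corner (0, 1), i.e. maximum
#' simultaneous sensitivity and specificity. Ties are broken toward higher
#' sensitivity, then toward the less extreme threshold (closest to the
#' score median; infinite sentinels lose).
#'
#' @param curve a [ROCCurve-class].
#' @return one-row data.frame with `cutoff`, `distance`, `sens_at_cut`,
#'   `spec_at_cut`, `inequality` (the emitted decision rule as text).
#' @export
bestCutoffOrthogonal <- function(curve) {
  .stopIfNot(is(curve, "ROCCurve"), "curve must be a ROCCurve")
  d <- sqrt(curve@fpr^2 + (1 - curve@tpr)^2)
  tol <- 1e-12
  best <- which(d <= min(d) + tol)
  if (length(best) > 1) {
    best <- best[curve@tpr[best] >= max(curve@tpr[best]) - tol]
    if (length(best) > 1) {
      med <- median(curve@scores)
      ext <- abs(curve@thresholds[best] - med)
      best <- best[which.min(ext)]
    }
  }
  best <- best[1]
  ineq <- if (curve@orientation == "positive_if_greater") ">=" else "<="
  data.frame(
    cutoff = curve@thresholds[best], distance = d[best],
    sens_at_cut = curve@tpr[best], spec_at_cut = 1 - curve@fpr[best],
    inequality = sprintf("%s %s %.4g predicts %s", curve@indexName, ineq,
                         curve@thresholds[best], curve@positiveLabel),
    stringsAsFactors = FALSE)
}

#' Confusion counts at a cut-off
#'
#' Applies the emitted decision rule (non-strict on the positive side) and
#' tallies the 2x2 confusion matrix.
#'
#' @param values numeric scores.
#' @param labels group labels.
#' @param cutoff decision threshold (finite).
#' @param orientation `"positive_if_greater"` or `"positive_if_less"`.
#' @param positive label of the positive class.
#' @return list with `tp`, `fn`, `fp`, `tn`.
#' @export
confusionAtCutoff <- function(values, labels, cutoff,
                              orientation = c("positive_if_greater",
                                              "positive_if_less"),
                              positive = "F") {
  orientation <- match.arg(orientation)
  .stopIfNot(.isScalar(cutoff), "cutoff must be a finite number")
  pos <- if (is.logical(labels)) labels else labels == positive
  keep <- is.finite(values) & !is.na(pos)
  values <- values[keep]
  pos <- pos[keep]
  pred <- if (orientation == "positive_if_greater") values >= cutoff else
    values <= cutoff
  list(tp = sum(pred & pos), fn = sum(!pred & pos),
       fp = sum(pred & !pos), tn = sum(!pred & !pos))
}

#' Diagnostic performance with Wald confidence intervals
#'
#' Sensitivity, specificity, PPV and NPV as percentages, each with the 95%
#' Wald interval `100 * (p +/- z * sqrt(p(1-p)/n))` on its own denominator.
#' Bounds are deliberately not clipped to `[0, 100]`, matching how such
#' intervals are conventionally printed (an upper bound above 100% is
#' possible). A metric with a zero denominator is returned as `NA`.
#'
#' @param tp,fn,fp,tn confusion counts (non-negative, not all zero).
#' @param conf confidence level, default 0.95.
#' @return data.frame with one row per metric: `metric`, `estimate`, `lo`,
#'   `hi` (all %), `n` (denominator).
#' @examples
#' diagnosticPerformanceWald(tp = 23, fn = 5, fp = 4, tn = 10)
#' @export
diagnosticPerformanceWald <- function(tp, fn, fp, tn, conf = 0.95) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  .stopIfNot(all(vapply(counts, .isScalar, logical(1))) &&
               all(counts >= 0) && all(counts == round(counts)),
             "confusion counts must be non-negative integers")
  .stopIfNot(sum(counts) > 0, "all-zero confusion matrix")
  z <- qnorm(1 - (1 - conf) / 2)
  wald <- function(num, den) {
    if (den == 0) return(c(NA_real_, NA_real_, NA_real_, 0))
    p <- num / den
    half <- z * sqrt(p * (1 - p) / den)
    100 * c(p, p - half, p + half, den / 100)
  }
  m <- rbind(sensitivity = wald(tp, tp + fn),
             specificity = wald(tn, tn + fp),
             ppv = wald(tp, tp + fp),
             npv = wald(tn, tn + fn))
  data.frame(metric = rownames(m), estimate = m[, 1], lo = m[, 2],
             hi = m[, 3], n = m[, 4], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Evaluate a set of candidate biomarkers
#'
#' For each index column: ROC curve with automatic orientation, AUC with
#' Hanley-McNeil CI and p-value, orthogonal-distance optimal cut-off, and
#' the diagnostic performance at that cut-off with Wald CIs. The per-index
#' sample sizes are always reported alongside the estimates.
#'
#' @param data data.frame of subjects (one row each).
#' @param indexCols character vector of index column names to evaluate.
#' @param labelCol name of the group label column.
#' @param positive,negative labels of the positive (frail) and negative
#'   (non-frail) classes; other rows are ignored.
#' @return list with `roc` (index, auc, ci, p, cutoff, inequality, n) and
#'   `performance` (index, metric, estimate, lo, hi, n) data.frames.
#' @export
evaluateBiomarkers <- function(data, indexCols, labelCol = "group",
                               positive = "F", negative = "nF") {
  .stopIfNot(is.data.frame(data), "data must be a data.frame")
  .stopIfNot(all(c(indexCols, labelCol) %in% names(data)),
             "missing columns in data")
  sub <- data[data[[labelCol]] %in% c(positive, negative), , drop = FALSE]
  rocRows <- list()
  perfRows <- list()
  for (idx in indexCols) {
    v <- sub[[idx]]
    keep <- is.finite(v)
    if (sum(keep & sub[[labelCol]] == positive) < 1 ||
        sum(keep & sub[[labelCol]] == negative) < 1) next
    curve <- rocCurve(v[keep], sub[[labelCol]][keep], positive = positive,
                      indexName = idx)
    a <- aucWithCi(curve)
    cut <- bestCutoffOrthogonal(curve)
    cm <- confusionAtCutoff(v[keep], sub[[labelCol]][keep], cut$cutoff,
                            orientation = curve@orientation,
                            positive = positive)
    perf <- diagnosticPerformanceWald(cm$tp, cm$fn, cm$fp, cm$tn)
    perf <- cbind(index = idx, perf, stringsAsFactors = FALSE)
    rocRows[[idx]] <- data.frame(
      index = idx, auc = a$auc, ci_lo = a$ci_lo, ci_hi = a$ci_hi,
      p_value = a$p_value, cutoff = cut$cutoff,
      inequality = cut$inequality, n_pos = a$n_pos, n_neg = a$n_neg,
      stringsAsFactors = FALSE)
    perfRows[[idx]] <- perf
  }
  list(roc = do.call(rbind, c(rocRows, list(make.row.names = FALSE))),
       performance = do.call(rbind, c(perfRows,
                                      list(make.row.names = FALSE))))
}
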