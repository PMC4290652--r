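# Single-feature threshold learning (top-decile MCC split averaging),
# quantile thresholds for positives-only data, and evaluation metrics.

.asBiological <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    bad <- setdiff(unique(labels), c("biological", "packing"))
    if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
    return(labels == "biological")
  }
  stop("labels must be logical or biological/packing")
}

.confusion <- function(predicted, truth) {
  c(tp = sum(predicted & truth), fp = sum(predicted & !truth),
    tn = sum(!predicted & !truth), fn = sum(!predicted & truth))
}

.mcc <- function(tp, fp, tn, fn) {
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)  # zero-denominator convention
  (tp * tn - fp * fn) / den
}

#' Binary classification metrics
#'
#' Biological interfaces are the positive class.  Precision, recall,
#' specificity, accuracy and the Matthews correlation coefficient are
#' computed from the confusion counts; any metric with a zero denominator
#' (including MCC) is reported as 0.
#'
#' @param predicted predicted labels: logical (`TRUE` = biological) or
#'   `"biological"`/`"packing"`.
#' @param labels true labels, same encodings.
#' @return one-row data.frame: `tp`, `fp`, `tn`, `fn`, `precision`,
#'   `recall`, `specificity`, `accuracy`, `mcc`.
#' @export
interfaceMetrics <- function(predicted, labels) {
  p <- .asBiological(predicted)
  y <- .asBiological(labels)
  if (length(p) != length(y))
    stop("predictions and labels differ in length")
  cf <- .confusion(p, y)
  rate <- function(num, den) if (den == 0) 0 else num / den
  data.frame(tp = cf["tp"], fp = cf["fp"], tn = cf["tn"], fn = cf["fn"],
             precision = rate(cf["tp"], cf["tp"] + cf["fp"]),
             recall = rate(cf["tp"], cf["tp"] + cf["fn"]),
             specificity = rate(cf["tn"], cf["tn"] + cf["fp"]),
             accuracy = rate(cf["tp"] + cf["tn"], sum(cf)),
             mcc = .mcc(cf["tp"], cf["fp"], cf["tn"], cf["fn"]),
             row.names = NULL)
}

.splitMCC <- function(scores, pos, split, positiveIsBiological) {
  pred <- if (positiveIsBiological) scores > split else scores < split
  cf <- .confusion(pred, pos)
  .mcc(cf["tp"], cf["fp"], cf["tn"], cf["fn"])
}

#' Learn a single-feature threshold by top-decile MCC split averaging
#'
#' Candidate splits are the midpoints between consecutive distinct sorted
#' scores.  Each split is scored by the better of its two decision
#' directions' MCC; the splits ranked in the top `topFraction` (at least
#' one, ties at the cut included) are averaged into the threshold.
#' Averaging the best splits rather than taking the single best one
#' stabilizes the learned rule across datasets.
#'
#' @param scores numeric feature scores.
#' @param labels class labels (logical or biological/packing); both
#'   classes must be present and at least 10 items supplied.
#' @param topFraction fraction of best-ranked splits to average.
#' @param featureName stored in the model.
#' @return a [ThresholdModel].
#' @export
optimalThreshold <- function(scores, labels, topFraction = 0.10,
                             featureName = "feature") {
  stopifnot(is.numeric(scores), all(is.finite(scores)),
            topFraction > 0, topFraction <= 1)
  pos <- .asBiological(labels)
  if (length(scores) != length(pos))
    stop("scores and labels differ in length")
  if (length(scores) < 10L) stop("need at least 10 scored interfaces")
  if (!any(pos) || all(pos)) stop("both classes must be present")
  u <- sort(unique(scores))
  if (length(u) < 2L) stop("all scores identical: no candidate splits")
  splits <- (u[-1] + u[-length(u)]) / 2
  mccPos <- vapply(splits, function(s) .splitMCC(scores, pos, s, TRUE), 1)
  mccNeg <- vapply(splits, function(s) .splitMCC(scores, pos, s, FALSE), 1)
  best <- pmax(mccPos, mccNeg)
  kTop <- ceiling(topFraction * length(splits))
  cut <- sort(best, decreasing = TRUE)[kTop]
  keep <- which(best >= cut)  # ties at the decile boundary all included
  dirPos <- mccPos[keep] >= mccNeg[keep]
  direction <- if (mean(dirPos) >= 0.5) "positive-is-biological"
               else "negative-is-biological"
  new("ThresholdModel", featureName = featureName,
      threshold = mean(splits[keep]), direction = direction,
      topFraction = topFraction, candidateSplits = splits[keep],
      meta = list(n = length(scores), nCandidates = length(splits),
                  keptMCC = best[keep], method = "top-fraction-split-mean"))
}

#' Quantile threshold for positives-only training data
#'
#' When only true binding complexes are available (no packing negatives),
#' the threshold is placed at an empirical quantile of the positive scores
#' (linear-interpolation, type 7); the decision direction must be supplied
#' from the feature's known polarity.
#'
#' @param scores numeric scores of positive (biological) interfaces.
#' @param q quantile in (0, 1); 0.25 by default.
#' @param direction `"positive-is-biological"` or
#'   `"negative-is-biological"`.
#' @param featureName stored in the model.
#' @return a [ThresholdModel].
#' @export
quantileThreshold <- function(scores, q = 0.25,
                              direction = "positive-is-biological",
                              featureName = "feature") {
  if (length(scores) == 0L) stop("no scores supplied")
  stopifnot(is.numeric(scores), all(is.finite(scores)), q > 0, q < 1)
  th <- unname(quantile(scores, q, type = 7))
  new("ThresholdModel", featureName = featureName, threshold = th,
      direction = direction, topFraction = q, candidateSplits = th,
      meta = list(n = length(scores), method = "quantile", quantileType = 7L))
}

#' Apply a learned threshold
#'
#' @param model a [ThresholdModel].
#' @param scores numeric scores.
#' @return logical vector, `TRUE` = predicted biological.  Scores exactly
#'   at the threshold fall on the packing side.
#' @export
predictInterface <- function(model, scores) {
  if (model@direction == "positive-is-biological") scores > model@threshold
  else scores < model@threshold
}

#' Cross-dataset evaluation of one feature
#'
#' Fits the threshold on each training dataset ([optimalThreshold()], or
#' [quantileThreshold()] when the training data contain positives only)
#' and applies it unchanged to every test dataset.
#'
#' @param datasets named list of data.frames with columns `score` and
#'   `label`.
#' @param topFraction passed to [optimalThreshold()].
#' @param q,positiveDirection settings for positives-only training sets:
#'   the threshold is placed so that a fraction `q` of the training
#'   positives falls on the packing side (for a negative-is-biological
#'   feature this is the upper `1 - q` quantile).
#' @param featureName label carried through.
#' @return data.frame with one row per (train, test) combination:
#'   threshold, direction and all [interfaceMetrics()] columns.
#' @export
crossDatasetEval <- function(datasets, topFraction = 0.10, q = 0.25,
                             positiveDirection = "positive-is-biological",
                             featureName = "feature") {
  stopifnot(is.list(datasets), !is.null(names(datasets)))
  out <- list()
  for (tr in names(datasets)) {
    d <- datasets[[tr]]
    pos <- .asBiological(d$label)
    effQ <- if (positiveDirection == "negative-is-biological") 1 - q else q
    model <- if (all(pos))
      quantileThreshold(d$score, effQ, positiveDirection, featureName)
    else optimalThreshold(d$score, d$label, topFraction, featureName)
    for (te in names(datasets)) {
      t <- datasets[[te]]
      if (all(.asBiological(t$label)) && te != tr) next  # nothing to test
      m <- interfaceMetrics(predictInterface(model, t$score), t$label)
      out[[length(out) + 1L]] <-
        cbind(data.frame(train = tr, test = te, feature = featureName,
                         threshold = model@threshold,
                         direction = model@direction), m)
    }
  }
  do.call(rbind, out)
}
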