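# Evaluation statistics: one-vs-rest confusion counts, accuracy, macro
# precision/recall/F1, adjusted Rand index, ROC/AUC and PR curves.

#' One-vs-rest confusion counts per class
#'
#' For each class, cells of that class are the positives and every other
#' cell the negatives. \code{"unknown"} predictions are negative for every
#' real class, so a rejected cell can contribute FN but never FP or TP.
#'
#' @param yTrue,yPred equal-length label vectors; predictions may contain
#'   \code{"unknown"}.
#' @param classes class set to score (default: classes present in
#'   \code{yTrue}).
#' @return data.frame with one row per class and columns \code{class},
#'   \code{TP}, \code{FP}, \code{FN}, \code{TN}.
#' @export
confusionCounts <- function(yTrue, yPred, classes = NULL) {
  yTrue <- as.character(yTrue); yPred <- as.character(yPred)
  if (length(yTrue) != length(yPred))
    stop("label vectors differ in length: ", length(yTrue), " vs ",
         length(yPred))
  if (is.null(classes)) classes <- sort(unique(yTrue))
  n <- length(yTrue)
  rows <- lapply(classes, function(cl) {
    tp <- sum(yTrue == cl & yPred == cl)
    fp <- sum(yTrue != cl & yPred == cl)
    fn <- sum(yTrue == cl & yPred != cl)
    data.frame(class = cl, TP = tp, FP = fp, FN = fn, TN = n - tp - fp - fn,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Overall classification accuracy
#'
#' Fraction of cells whose predicted label equals the true label; in the
#' binary one-vs-rest case this equals \code{(TP + TN) / n}.
#'
#' @param yTrue,yPred equal-length label vectors.
#' @return accuracy in \[0, 1\].
#' @export
accuracyScore <- function(yTrue, yPred) {
  if (length(yTrue) == 0L) stop("empty label vectors")
  if (length(yTrue) != length(yPred)) stop("label vectors differ in length")
  mean(as.character(yTrue) == as.character(yPred))
}

#' Precision, recall and F1 per class and macro-averaged
#'
#' \code{precision = TP/(TP+FP)}, \code{recall = TP/(TP+FN)},
#' \code{F1 = 2PR/(P+R)}. A zero denominator yields 0 with a warning. Macro
#' values are unweighted means over classes, which keeps rare cell types on
#' an equal footing with abundant ones.
#'
#' @param yTrue,yPred label vectors, or a data.frame of counts from
#'   [confusionCounts()] passed as \code{yTrue}.
#' @param classes optional class set.
#' @return list with \code{perClass} (data.frame) and \code{macro} (named
#'   vector precision/recall/f1).
#' @export
precisionRecallF1 <- function(yTrue, yPred = NULL, classes = NULL) {
  counts <- if (is.data.frame(yTrue)) yTrue
            else confusionCounts(yTrue, yPred, classes)
  safeDiv <- function(num, den, what) {
    out <- ifelse(den == 0, 0, num / den)
    if (any(den == 0))
      warning("zero denominator in ", what, " for class(es) ",
              paste(counts$class[den == 0], collapse = ", "),
              "; reporting 0", call. = FALSE)
    out
  }
  prec <- safeDiv(counts$TP, counts$TP + counts$FP, "precision")
  rec <- safeDiv(counts$TP, counts$TP + counts$FN, "recall")
  f1 <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
  list(perClass = data.frame(class = counts$class, precision = prec,
                             recall = rec, f1 = f1,
                             stringsAsFactors = FALSE),
       macro = c(precision = mean(prec), recall = mean(rec),
                 f1 = mean(f1)))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same cells,
#' computed from the contingency table of pair counts:
#' \deqn{ARI = \frac{\sum_{jj'} \binom{n_{jj'}}{2} - [\sum_j \binom{a_j}{2}
#'   \sum_{j'} \binom{b_{j'}}{2}] / \binom{n}{2}}
#'   {\frac12 [\sum_j \binom{a_j}{2} + \sum_{j'} \binom{b_{j'}}{2}] -
#'   [\sum_j \binom{a_j}{2} \sum_{j'} \binom{b_{j'}}{2}] / \binom{n}{2}}}
#' with \eqn{n_{jj'}} the number of cells in cluster j of the first
#' partition and j' of the second, and \eqn{a_j}, \eqn{b_{j'}} the marginal
#' cluster sizes. Symmetric in its arguments and invariant to relabeling;
#' 1 for identical partitions, about 0 for independent ones.
#'
#' @param labelsA,labelsB equal-length label vectors (n >= 2).
#' @return ARI value in \[-1, 1\].
#' @export
adjustedRandIndex <- function(labelsA, labelsB) {
  if (length(labelsA) != length(labelsB))
    stop("label vectors differ in length")
  n <- length(labelsA)
  if (n < 2L) stop("ARI needs at least two cells")
  tab <- table(labelsA, labelsB)
  choose2 <- function(x) x * (x - 1) / 2
  sumNij <- sum(choose2(tab))
  sumA <- sum(choose2(rowSums(tab)))
  sumB <- sum(choose2(colSums(tab)))
  expected <- sumA * sumB / choose2(n)
  maxIndex <- (sumA + sumB) / 2
  if (maxIndex == expected) return(1)  # both partitions degenerate
  (sumNij - expected) / (maxIndex - expected)
}

#' ROC curve and trapezoid AUC for one class
#'
#' Sweeps the decision threshold over the unique scores and reports false
#' positive rate (x) and true positive rate (y) at each, plus the
#' trapezoid-rule area \eqn{AUC = \frac12 \sum_i (x_{i+1} - x_i)(y_i +
#' y_{i+1})}.
#'
#' @param scores per-cell scores for the positive class (e.g. its softmax
#'   probability).
#' @param truth binary truth (logical, or 0/1).
#' @return list with \code{fpr}, \code{tpr}, \code{thresholds}, \code{auc}.
#' @export
rocCurveAuc <- function(scores, truth) {
  truth <- as.logical(truth)
  if (length(scores) != length(truth)) stop("scores/truth length mismatch")
  nPos <- sum(truth); nNeg <- sum(!truth)
  if (nPos == 0L || nNeg == 0L)
    stop("ROC needs at least one positive and one negative cell")
  ths <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(ths, function(t) sum(scores >= t & truth) / nPos, numeric(1))
  fpr <- vapply(ths, function(t) sum(scores >= t & !truth) / nNeg, numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1))) / 2
  list(fpr = fpr, tpr = tpr, thresholds = ths, auc = auc)
}

#' One-vs-rest ROC/AUC for all classes with macro average
#'
#' @param probabilities cells x classes probability matrix with class
#'   column names.
#' @param labels true labels.
#' @return list with per-class curves (\code{perClass}) and \code{macroAuc}.
#' @export
multiclassRocAuc <- function(probabilities, labels) {
  labels <- as.character(labels)
  classes <- colnames(probabilities)
  curves <- lapply(classes, function(cl)
    rocCurveAuc(probabilities[, cl], labels == cl))
  names(curves) <- classes
  list(perClass = curves,
       macroAuc = mean(vapply(curves, `[[`, numeric(1), "auc")))
}

#' Precision-recall curve for one class
#'
#' Precision and recall at each unique score threshold, in order of
#' decreasing score.
#'
#' @param scores per-cell scores for the positive class.
#' @param truth binary truth.
#' @return data.frame with \code{threshold}, \code{precision},
#'   \code{recall}.
#' @export
precisionRecallCurve <- function(scores, truth) {
  truth <- as.logical(truth)
  if (length(scores) != length(truth)) stop("scores/truth length mismatch")
  nPos <- sum(truth)
  if (nPos == 0L) stop("precision-recall curve needs at least one positive")
  ths <- sort(unique(scores), decreasing = TRUE)
  rows <- lapply(ths, function(t) {
    sel <- scores >= t
    data.frame(threshold = t,
               precision = if (any(sel)) sum(truth & sel) / sum(sel) else 1,
               recall = sum(truth & sel) / nPos)
  })
  do.call(rbind, rows)
}

#' All evaluation metrics in one call
#'
#' Convenience wrapper returning accuracy, macro precision/recall/F1,
#' per-class metrics, ARI, and (when probabilities are supplied) macro AUC.
#'
#' @param yTrue true labels.
#' @param yPred predicted labels (may contain \code{"unknown"}).
#' @param probabilities optional cells x classes probability matrix.
#' @return named list of metrics.
#' @export
evaluatePredictions <- function(yTrue, yPred, probabilities = NULL) {
  prf <- precisionRecallF1(yTrue, yPred)
  out <- list(accuracy = accuracyScore(yTrue, yPred),
              macro_precision = unname(prf$macro["precision"]),
              macro_recall = unname(prf$macro["recall"]),
              macro_f1 = unname(prf$macro["f1"]),
              per_class = prf$perClass,
              ari = adjustedRandIndex(yTrue, yPred))
  if (!is.null(probabilities))
    out$macro_auc <- multiclassRocAuc(probabilities, yTrue)$macroAuc
  out
}
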