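# Multiclass evaluation: confusion matrix, macro precision/recall/F1,
# accuracy, and macro one-vs-rest ROC AUC (MAUC) from per-class softmax
# scores.

.classAUC <- function(truthPos, scores) {
  r <- pROC::roc(response = factor(as.integer(truthPos), levels = c(0L, 1L)),
                 predictor = scores, direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}

#' Metrics from predicted classes and scores
#'
#' Builds the confusion matrix (rows = truth) and the macro-averaged
#' metrics. Per-class precision or recall whose denominator is zero (a class
#' never predicted, or absent from the truth) counts as 0. MAUC is the
#' macro-averaged one-vs-rest ROC AUC over the classes present in the truth;
#' it requires `scores` and at least two distinct truth classes.
#'
#' @param truth,pred integer class vectors (1-based).
#' @param scores optional B x K matrix of class scores (e.g. softmax
#'   probabilities) for the AUC.
#' @param numClasses K (default: largest label seen).
#' @param classNames optional class names for the report.
#' @return a [MetricsReport-class].
#' @examples
#' m <- metricsFromPredictions(c(1, 1, 2, 2, 3), c(1, 1, 1, 2, 3))
#' accuracy(m) # 0.8
#' @export
metricsFromPredictions <- function(truth, pred, scores = NULL,
                                   numClasses = max(truth, pred),
                                   classNames = NULL) {
  K <- numClasses
  if (is.null(classNames)) classNames <- paste0("C", seq_len(K))
  cm <- matrix(0L, K, K, dimnames = list(truth = classNames,
                                         predicted = classNames))
  for (i in seq_along(truth)) cm[truth[i], pred[i]] <- cm[truth[i], pred[i]] + 1L
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  present <- which(rowSums(cm) > 0)
  aucs <- rep(NA_real_, K)
  maucVal <- NA_real_
  if (!is.null(scores)) {
    if (length(unique(truth)) < 2L)
      stop("MAUC undefined for a single-class dataset")
    for (cl in present)
      aucs[cl] <- .classAUC(truth == cl, scores[, cl])
    maucVal <- mean(aucs[present])
  }
  new("MetricsReport", confusion = cm,
      accuracy = sum(tp) / sum(cm),
      macroPrecision = mean(prec), macroRecall = mean(rec),
      macroF1 = mean(f1), mauc = maucVal,
      perClass = data.frame(class = classNames, precision = prec,
                            recall = rec, f1 = f1,
                            support = rowSums(cm), auc = aucs))
}

.predictProbs <- function(model, images, batchSize = 32L,
                          mean = .IMNET_MEAN, std = .IMNET_STD) {
  n <- length(images)
  out <- matrix(0, n, model@config@numClasses)
  for (start in seq(1L, n, by = batchSize)) {
    idx <- start:min(start + batchSize - 1L, n)
    X <- .imagesToBatch(images[idx], TRUE, mean, std)
    out[idx, ] <- .softmaxRows(modelForward(model, X))
  }
  out
}

#' Evaluate a model on a labeled dataset
#'
#' Runs the model in eval mode over the (optionally index-subset) dataset
#' and computes the full metric report, with MAUC from the per-class
#' softmax scores.
#'
#' @param model a [DermViTModel-class].
#' @param data a [SyntheticDermData-class] or list with `images`, `labels`.
#' @param indices optional subset of image indices (e.g. a test split).
#' @param batchSize forward-pass batch size.
#' @return a [MetricsReport-class].
#' @export
evaluateModel <- function(model, data, indices = NULL, batchSize = 32L) {
  parts <- .datasetParts(data)
  if (!is.null(indices)) {
    parts$images <- parts$images[indices]
    parts$labels <- parts$labels[indices]
  }
  cn <- if (is(data, "SyntheticDermData")) data@classNames
  probs <- .predictProbs(model, parts$images, batchSize)
  metricsFromPredictions(parts$labels,
                         max.col(probs, ties.method = "first"),
                         scores = probs,
                         numClasses = model@config@numClasses,
                         classNames = cn)
}

#' Write a metrics report to disk
#'
#' `writeMetricsJSON` stores the scalar metrics and per-class table as JSON;
#' `writeConfusionCSV` stores the confusion matrix as CSV.
#'
#' @param report a [MetricsReport-class].
#' @param path output file path.
#' @export
writeMetricsJSON <- function(report, path) {
  jsonlite::write_json(list(
    accuracy = report@accuracy, macro_precision = report@macroPrecision,
    macro_recall = report@macroRecall, macro_f1 = report@macroF1,
    mauc = report@mauc, per_class = report@perClass), path,
    auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname writeMetricsJSON
#' @export
writeConfusionCSV <- function(report, path) {
  utils::write.csv(report@confusion, path)
  invisible(path)
}
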