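#' Confusion counts for binary predictions
#'
#' Coding (label 1) is the positive class.
#'
#' @param predicted 0/1 predicted labels (1 = coding).
#' @param truth 0/1 true labels.
#' @return Named integer vector \code{(TP, FP, TN, FN)}.
#' @export
confusion_counts <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  c(TP = sum(predicted == 1L & truth == 1L),
    FP = sum(predicted == 1L & truth == 0L),
    TN = sum(predicted == 0L & truth == 0L),
    FN = sum(predicted == 0L & truth == 1L))
}

#' Confusion-matrix performance metrics
#'
#' Sensitivity \eqn{TP/(TP+FN)}, specificity \eqn{TN/(TN+FP)}, F1
#' \eqn{2TP/(2TP+FP+FN)}, accuracy \eqn{(TP+TN)/total}, and the Matthews
#' correlation coefficient
#' \eqn{(TP\,TN - FP\,FN)/\sqrt{(TP+FN)(TP+FP)(TN+FP)(TN+FN)}}. A metric
#' whose denominator is zero is reported as 0 and flagged in the
#' \code{degenerate} attribute so batch reports stay numeric.
#'
#' @param counts Counts from [confusion_counts()].
#' @return Named vector \code{(sensitivity, specificity, f1, accuracy, mcc)}
#'   with attribute \code{degenerate} naming any zero-denominator metrics.
#' @export
metrics <- function(counts) {
  # double precision: the MCC denominator overflows integer arithmetic
  TP <- as.numeric(counts[["TP"]]); FP <- as.numeric(counts[["FP"]])
  TN <- as.numeric(counts[["TN"]]); FN <- as.numeric(counts[["FN"]])
  if (TP + FP + TN + FN == 0) stop("no evaluated records")
  degenerate <- character(0)
  safe <- function(num, den, nm) {
    if (den == 0) {
      degenerate <<- c(degenerate, nm)
      0
    } else num / den
  }
  out <- c(
    sensitivity = safe(TP, TP + FN, "sensitivity"),
    specificity = safe(TN, TN + FP, "specificity"),
    f1 = safe(2 * TP, 2 * TP + FP + FN, "f1"),
    accuracy = (TP + TN) / (TP + FP + TN + FN),
    mcc = safe(TP * TN - FP * FN,
               sqrt((TP + FN) * (TP + FP) * (TN + FP) * (TN + FN)), "mcc"))
  attr(out, "degenerate") <- degenerate
  out
}

#' ROC curve and AUC
#'
#' The AUC is computed from the midrank statistic (the probability that a
#' random positive scores above a random negative, ties counting one half),
#' which equals the trapezoidal area under the ROC curve.
#'
#' @param scores Numeric scores, larger = more likely positive.
#' @param labels 0/1 true labels (1 = positive).
#' @return List with \code{auc} and \code{roc}, a data frame of
#'   (fpr, tpr) points at every distinct threshold, descending.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC undefined: labels contain a single class")
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(labels[ord] == 1L)
  fp <- cumsum(labels[ord] == 0L)
  keep <- c(diff(scores[ord]) != 0, TRUE)   # last point of each tie group
  roc <- data.frame(fpr = c(0, fp[keep] / n0), tpr = c(0, tp[keep] / n1))
  list(auc = auc, roc = roc)
}

#' Stratify transcripts by longest-ORF length
#'
#' A transcript is "long-ORF" when its longest ORF exceeds 303 nt (100 codons
#' plus the stop codon); transcripts with a 303-nt or shorter ORF, or with no
#' ORF at all, are "short-ORF".
#'
#' @param records Data frame with columns \code{id} and \code{sequence}.
#' @return Logical vector, \code{TRUE} for long-ORF records.
#' @export
is_long_orf <- function(records) {
  vapply(records$sequence, function(s) {
    orf <- find_longest_orf(s)
    !is.null(orf) && orf$nt_length > 303L
  }, logical(1), USE.NAMES = FALSE)
}

#' @rdname is_long_orf
#' @return \code{split_by_orf_length}: list with elements \code{long_orf} and
#'   \code{short_orf}, each a subset of \code{records}.
#' @export
split_by_orf_length <- function(records) {
  long <- is_long_orf(records)
  list(long_orf = records[long, , drop = FALSE],
       short_orf = records[!long, , drop = FALSE])
}

#' Evaluate a fitted model on labelled transcripts
#'
#' @param model A fitted \code{corenet} object.
#' @param records Data frame with \code{id} and \code{sequence}.
#' @param labels 0/1 labels (1 = coding), aligned or named by id.
#' @param stratify_orf Also report the long-ORF/short-ORF strata (303-nt
#'   rule).
#' @return A list of evaluation reports. Each report holds \code{counts},
#'   the five confusion metrics, \code{auc}, \code{n} and \code{stratum}.
#' @export
evaluate_model <- function(model, records, labels, stratify_orf = FALSE) {
  records <- as_records(records)
  labels <- align_labels(labels, records)
  p_nc <- predict(model, records, type = "prob")
  reports <- list(all = score_report(p_nc, labels, "all"))
  if (stratify_orf) {
    long <- is_long_orf(records)
    if (any(long)) {
      reports$long_orf <- score_report(p_nc[long], labels[long], "long_orf")
    }
    if (any(!long)) {
      reports$short_orf <- score_report(p_nc[!long], labels[!long],
                                        "short_orf")
    }
  }
  reports
}

score_report <- function(p_noncoding, labels, stratum) {
  pred <- as.integer(p_noncoding < 0.5)   # predicted coding
  counts <- confusion_counts(pred, labels)
  m <- metrics(counts)
  auc <- if (length(unique(labels)) == 2L) {
    roc_auc(1 - p_noncoding, labels)$auc
  } else NA_real_
  list(stratum = stratum, n = length(labels), counts = counts,
       metrics = m, auc = auc)
}

#' Stratified k-fold cross-validation of the full pipeline
#'
#' Folds are assigned by stratified sampling within each class under the
#' configured seed. Inside every fold the reference tables, the feature
#' scaler and the network are all re-trained on the training split only, so
#' no information leaks from the held-out fold.
#'
#' @param records Data frame with \code{id} and \code{sequence}.
#' @param labels 0/1 labels (1 = coding).
#' @param k Number of folds.
#' @param config Hyperparameters from [corenet_config()].
#' @param pseudocount Hexamer-table smoothing constant.
#' @return List with \code{folds} (one evaluation report per fold) and
#'   \code{mean} (arithmetic mean of the five metrics and AUC across folds).
#' @export
cross_validate <- function(records, labels, k = 10L,
                           config = corenet_config(), pseudocount = 1) {
  records <- as_records(records)
  labels <- align_labels(labels, records)
  if (k < 2L) stop("k must be at least 2")
  if (k > min(table(labels))) {
    stop("k exceeds the size of the smaller class")
  }
  set.seed(config$seed)
  fold <- integer(length(labels))
  for (cls in c(0L, 1L)) {
    ic <- sample(which(labels == cls))
    fold[ic] <- rep_len(seq_len(k), length(ic))
  }
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    test <- fold == f
    fit <- corenet(records[!test, , drop = FALSE], labels[!test],
                   config = config, pseudocount = pseudocount)
    p_nc <- predict(fit, records[test, , drop = FALSE], type = "prob")
    reports[[f]] <- score_report(p_nc, labels[test], sprintf("fold%d", f))
  }
  tab <- t(vapply(reports, function(r) c(r$metrics, auc = r$auc),
                  numeric(6)))
  list(folds = reports, mean = colMeans(tab))
}

#' Write an evaluation report as TSV
#' @param reports Output of [evaluate_model()].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_report <- function(reports, path) {
  rows <- lapply(reports, function(r) {
    data.frame(stratum = r$stratum, n = r$n, t(r$counts), t(r$metrics),
               auc = r$auc)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
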