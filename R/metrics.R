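#' Area under the ROC curve
#'
#' Rank-statistic formulation: the probability that a randomly chosen
#' positive outranks a randomly chosen negative, with ties counting 1/2
#' (equivalently the normalised Mann-Whitney U). Invariant under strictly
#' monotone transforms of the scores. A single-class input is an error,
#' never a silent default.
#'
#' @param scores numeric vector of prediction scores.
#' @param labels 0/1 vector of the same length.
#' @return auROC in \[0, 1\].
#' @examples
#' auROC(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
#' @export
auROC <- function(scores, labels) {
  .checkScored(scores, labels)
  nPos <- sum(labels == 1); nNeg <- sum(labels == 0)
  if (nPos == 0L || nNeg == 0L)
    stop("auROC needs at least one positive and one negative label")
  r <- rank(scores)  # midranks handle ties as 1/2
  (sum(r[labels == 1]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision: the sum over score-descending distinct
#' thresholds of (recall increment x precision at that threshold), with no
#' trapezoidal interpolation — the conservative standard.
#'
#' @inheritParams auROC
#' @return auPRC in \[0, 1\].
#' @examples
#' auPRC(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.8333...
#' @export
auPRC <- function(scores, labels) {
  .checkScored(scores, labels)
  nPos <- sum(labels == 1)
  if (nPos == 0L) stop("auPRC needs at least one positive label")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y == 1); fp <- cumsum(y == 0)
  # evaluate only at the last index of each distinct score (tie groups)
  last <- which(c(s[-1] != s[-length(s)], TRUE))
  prec <- tp[last] / (tp[last] + fp[last])
  rec <- tp[last] / nPos
  sum(diff(c(0, rec)) * prec)
}

.checkScored <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length")
  if (!length(scores)) stop("empty input")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1")
  invisible(TRUE)
}

#' Per-target evaluation report
#'
#' Computes auROC and auPRC for every target column and macro averages.
#' Targets with a single observed class cannot be scored; they are flagged
#' (`degenerate`), reported as NA, excluded from the macro averages, and a
#' warning is raised.
#'
#' @param scoreMatrix numeric `n x nTargets` score matrix.
#' @param labelMatrix 0/1 matrix of the same shape.
#' @return list with `perTarget` (data.frame: target, auROC, auPRC,
#'   degenerate) and `macro` (named vector of macro-averaged auROC/auPRC).
#' @export
perTargetReport <- function(scoreMatrix, labelMatrix) {
  scoreMatrix <- as.matrix(scoreMatrix)
  labelMatrix <- as.matrix(labelMatrix)
  if (!identical(dim(scoreMatrix), dim(labelMatrix)))
    stop("score and label matrices must have identical shape")
  nt <- ncol(scoreMatrix)
  res <- data.frame(target = if (is.null(colnames(labelMatrix)))
                      paste0("target", seq_len(nt)) else colnames(labelMatrix),
                    auROC = NA_real_, auPRC = NA_real_,
                    degenerate = FALSE, stringsAsFactors = FALSE)
  for (j in seq_len(nt)) {
    y <- labelMatrix[, j]
    if (length(unique(y)) < 2L) {
      res$degenerate[j] <- TRUE
    } else {
      res$auROC[j] <- auROC(scoreMatrix[, j], y)
      res$auPRC[j] <- auPRC(scoreMatrix[, j], y)
    }
  }
  if (any(res$degenerate))
    warning(sprintf("%d target(s) with a single observed class excluded from macro averages",
                    sum(res$degenerate)))
  ok <- !res$degenerate
  list(perTarget = res,
       macro = c(auROC = mean(res$auROC[ok]), auPRC = mean(res$auPRC[ok])))
}
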