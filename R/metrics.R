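#' @include utils.R
NULL

#' One-vs-rest confusion counts per class
#'
#' For each class k, counts pixels where prediction and reference agree on
#' k (TP), where only the prediction says k (FP), where only the reference
#' says k (FN), and where both say not-k (TN). Rows always sum to the
#' number of pixels.
#'
#' @param pred,ref Integer label matrices of identical shape.
#' @param numClasses Number of classes K (labels 0..K-1).
#' @return Integer matrix with one row per class and columns
#'   \code{tp}, \code{fp}, \code{tn}, \code{fn}.
#' @export
#' @examples
#' confusionCounts(matrix(0:3, 2), matrix(c(0L, 1L, 3L, 3L), 2))
confusionCounts <- function(pred, ref, numClasses = 4L) {
  if (!identical(dim(pred), dim(ref)))
    stop("prediction (", paste(dim(pred), collapse = "x"),
         ") and reference (", paste(dim(ref), collapse = "x"),
         ") differ in shape")
  n <- length(ref)
  out <- matrix(0L, numClasses, 4L,
                dimnames = list(paste0("class", seq_len(numClasses) - 1L),
                                c("tp", "fp", "tn", "fn")))
  for (k in seq_len(numClasses) - 1L) {
    p <- pred == k
    r <- ref == k
    tp <- sum(p & r)
    fp <- sum(p & !r)
    fn <- sum(!p & r)
    out[k + 1L, ] <- c(tp, fp, n - tp - fp - fn, fn)
  }
  out
}

# ratio with the empty-set convention: 1 when both sets are empty
# (num = den = 0), else ordinary division with 0/positive = 0.
.safeRatio <- function(num, den) ifelse(den == 0, 1, num / den)

#' The six segmentation metrics from confusion counts
#'
#' Accuracy (TP+TN)/N, precision TP/(TP+FP), recall TP/(TP+FN), their
#' harmonic mean F1, intersection-over-union TP/(TP+FP+FN) and Dice
#' 2TP/(2TP+FP+FN) -- the set forms |I1 n I2|/|I1 u I2| and
#' 2|I1 n I2|/(|I1|+|I2|) expressed in counts. Zero-denominator cases
#' (a class absent from both maps) score 1 by convention, otherwise 0.
#'
#' @param counts Confusion matrix from \code{\link{confusionCounts}}.
#' @param macro Which classes enter the macro average:
#'   \code{"foreground"} (default; background row excluded, the
#'   segmentation-community convention) or \code{"all"}.
#' @return A data.frame with one row per class plus a final \code{macro}
#'   row and columns \code{acc}, \code{pre}, \code{re}, \code{f1},
#'   \code{iou}, \code{dsc}, all in [0, 1].
#' @export
#' @examples
#' cm <- matrix(c(8L, 2L, 88L, 2L), 1, dimnames = list("class1",
#'   c("tp", "fp", "tn", "fn")))
#' computeMetrics(cm, macro = "all")
computeMetrics <- function(counts, macro = c("foreground", "all")) {
  macro <- match.arg(macro)
  tp <- counts[, "tp"]; fp <- counts[, "fp"]
  tn <- counts[, "tn"]; fn <- counts[, "fn"]
  n <- tp + fp + tn + fn
  acc <- (tp + tn) / n
  pre <- .safeRatio(tp, tp + fp)
  re <- .safeRatio(tp, tp + fn)
  f1 <- ifelse(pre + re == 0, 0, 2 * pre * re / (pre + re))
  both_empty <- (tp + fp + fn) == 0
  f1[both_empty] <- 1
  iou <- .safeRatio(tp, tp + fp + fn)
  dsc <- .safeRatio(2 * tp, 2 * tp + fp + fn)
  df <- data.frame(class = rownames(counts), acc = acc, pre = pre,
                   re = re, f1 = f1, iou = iou, dsc = dsc,
                   row.names = NULL)
  keep <- if (macro == "foreground" && nrow(df) > 1L)
    seq_len(nrow(df))[-1L] else seq_len(nrow(df))
  macroRow <- data.frame(class = "macro",
                         t(colMeans(df[keep, -1L, drop = FALSE])))
  rbind(df, macroRow)
}

#' Evaluate a dataset of predicted masks against references
#'
#' Computes the six metrics per case and macro-averages across cases.
#'
#' @param preds,refs Equal-length lists of integer label matrices.
#' @param numClasses Number of classes K.
#' @param macro Macro-averaging mode, see \code{\link{computeMetrics}}.
#' @param csvPath If non-NULL, the per-case table is written there as CSV
#'   (columns case, class, acc, pre, re, f1, iou, dsc).
#' @return List with \code{perCase} (data.frame of per-case, per-class and
#'   per-case macro rows) and \code{macro} (named numeric: the mean of the
#'   per-case macro rows).
#' @export
evaluateDataset <- function(preds, refs, numClasses = 4L,
                            macro = "foreground", csvPath = NULL) {
  if (length(preds) != length(refs))
    stop("preds (", length(preds), ") and refs (", length(refs),
         ") differ in length")
  if (!length(preds)) stop("empty evaluation set")
  tabs <- lapply(seq_along(preds), function(i) {
    m <- computeMetrics(confusionCounts(preds[[i]], refs[[i]], numClasses),
                        macro = macro)
    cbind(case = i, m)
  })
  perCase <- do.call(rbind, tabs)
  macroRows <- perCase[perCase$class == "macro", ]
  macroMeans <- colMeans(macroRows[, c("acc", "pre", "re", "f1",
                                       "iou", "dsc")])
  if (!is.null(csvPath))
    utils::write.csv(perCase, csvPath, row.names = FALSE)
  list(perCase = perCase, macro = macroMeans)
}
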