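# Comparison of machine annotations against human selection tables:
# xi-merging of ground truth, lambda-extended duration-weighted
# precision/recall, frame-wise ROC/AUC, confusion matrices and UAR.

# interval helpers: intervals are data.frames/lists with start < end
.mergeIntervals <- function(start, end, gap = 0) {
  if (length(start) == 0L)
    return(data.frame(start = numeric(), end = numeric()))
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  outS <- start[1]; outE <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] - outE[length(outE)] <= gap + 1e-12) {
      outE[length(outE)] <- max(outE[length(outE)], end[i])
    } else {
      outS <- c(outS, start[i]); outE <- c(outE, end[i])
    }
  }
  data.frame(start = outS, end = outE)
}

.totalLength <- function(iv) sum(iv$end - iv$start)

# total length of the intersection of two interval unions
.intersectLength <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(0)
  tot <- 0
  for (i in seq_len(nrow(a)))
    tot <- tot + sum(pmax(0, pmin(a$end[i], b$end) -
                            pmax(a$start[i], b$start)))
  tot
}

#' Merge nearby ground-truth annotations
#'
#' Ground-truth annotations separated by gaps of at most `mergeXi` seconds
#' are combined (transitively) into one annotation, reflecting that a
#' sliding window spanning such a gap still mostly contains vocalization.
#'
#' @param gt annotation data.frame (`start`, `end`, `label`).
#' @param cfg a [TimewiseEvalConfig-class].
#' @return merged annotation data.frame.
#' @examples
#' gt <- data.frame(start = c(0, 1.2), end = c(1, 2), label = "t")
#' mergeGroundTruth(gt, timewiseEvalConfig(epsilon = 1))
#' @export
mergeGroundTruth <- function(gt, cfg) {
  m <- .mergeIntervals(gt$start, gt$end, gap = cfg@mergeXi)
  if (nrow(m)) m$label <- if (nrow(gt)) gt$label[1] else character()
  m
}

#' Time-wise precision and recall of machine annotations
#'
#' The ground truth is first xi-merged. Precision is the fraction of
#' predicted time that falls inside the lambda-extended merged ground truth
#' (start - lambda, end + lambda, clipped to the recording bounds); recall
#' (TPR) is the fraction of merged (unextended) ground-truth time covered
#' by predictions. Both are duration-weighted.
#'
#' @param pred predicted annotation data.frame (`start`, `end`).
#' @param gt ground-truth annotation data.frame (`start`, `end`).
#' @param cfg a [TimewiseEvalConfig-class].
#' @param recordingDuration optional recording length for clipping the
#'   lambda extension (extensions are always clipped at 0).
#' @return list with elements `PREC` and `TPR`; an empty prediction yields
#'   PREC = NA and TPR = 0, an empty ground truth yields TPR = NA and
#'   PREC = 0.
#' @export
timewisePrecisionRecall <- function(pred, gt, cfg,
                                    recordingDuration = NULL) {
  predIv <- .mergeIntervals(pred$start, pred$end)
  gtM <- .mergeIntervals(gt$start, gt$end, gap = cfg@mergeXi)
  if (nrow(predIv) == 0L && nrow(gtM) == 0L)
    return(list(PREC = NA_real_, TPR = NA_real_))
  if (nrow(predIv) == 0L) return(list(PREC = NA_real_, TPR = 0))
  if (nrow(gtM) == 0L) return(list(PREC = 0, TPR = NA_real_))
  ext <- data.frame(start = pmax(0, gtM$start - cfg@extendLambda),
                    end = gtM$end + cfg@extendLambda)
  if (!is.null(recordingDuration))
    ext$end <- pmin(recordingDuration, ext$end)
  ext <- .mergeIntervals(ext$start, ext$end)
  list(PREC = .intersectLength(predIv, ext) / .totalLength(predIv),
       TPR = .intersectLength(gtM, predIv) / .totalLength(gtM))
}

# binary ground-truth label per frame: positive iff at least half of the
# frame overlaps the merged ground truth
.frameTruth <- function(frames, gtMerged) {
  vapply(seq_len(nrow(frames)), function(i) {
    iv <- data.frame(start = frames$start[i], end = frames$end[i])
    ov <- .intersectLength(iv, gtMerged)
    ov >= 0.5 * (frames$end[i] - frames$start[i])
  }, TRUE)
}

#' Frame-wise ROC curve and AUC against ground truth
#'
#' Each frame receives a binary ground-truth label (positive when at least
#' 50\% of the frame overlaps the xi-merged ground truth). The ROC curve is
#' swept over the confidence threshold delta; the AUC is computed by
#' trapezoidal integration and equals the Mann-Whitney rank statistic with
#' midrank tie handling.
#'
#' @param frames frame-score data.frame from [scoreFrames()].
#' @param gt ground-truth annotation data.frame.
#' @param targetClass class whose probability column is used.
#' @param cfg a [TimewiseEvalConfig-class] (for xi-merging).
#' @return list with `roc` (data.frame fpr, tpr, threshold) and `auc`
#'   (NA when the frame ground truth is single-class).
#' @export
frameRocAuc <- function(frames, gt, targetClass,
                        cfg = timewiseEvalConfig(mergeXi = 0,
                                                 extendLambda = 0)) {
  scores <- frames[[paste0("prob.", targetClass)]]
  truth <- .frameTruth(frames, .mergeIntervals(gt$start, gt$end,
                                               gap = cfg@mergeXi))
  if (all(truth) || !any(truth))
    return(list(roc = NULL, auc = NA_real_))
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  roc <- t(vapply(thr, function(d) {
    pos <- scores >= d
    c(fpr = sum(pos & !truth) / sum(!truth),
      tpr = sum(pos & truth) / sum(truth))
  }, c(fpr = 0, tpr = 0)))
  roc <- data.frame(roc, threshold = thr)
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                utils::tail(roc$tpr, -1)) / 2)
  list(roc = roc, auc = auc)
}

#' Confusion matrix and unweighted average recall
#'
#' Builds the confusion matrix (rows = true classes, columns = predicted)
#' and the unweighted average recall, i.e. the mean of per-class recalls.
#' Classes without any true sample are excluded from the mean with a
#' warning.
#'
#' @param truth character vector of true labels.
#' @param pred character vector of predicted labels (same length).
#' @param classes class universe; defaults to the union of labels, sorted.
#' @return list with `confusion` (matrix) and `UAR`.
#' @examples
#' confusionAndUar(rep(c("a", "b"), c(10, 10)),
#'                 rep(c("a", "b", "a", "b"), c(8, 2, 5, 5)))$UAR  # 0.65
#' @export
confusionAndUar <- function(truth, pred,
                            classes = sort(unique(c(truth, pred)))) {
  if (length(truth) == 0L) stop("empty evaluation input")
  stopifnot(length(truth) == length(pred))
  cm <- table(factor(truth, levels = classes),
              factor(pred, levels = classes))
  cm <- unclass(cm)
  names(dimnames(cm)) <- c("truth", "predicted")
  support <- rowSums(cm)
  if (any(support == 0))
    warning("classes without true samples excluded from UAR: ",
            paste(classes[support == 0], collapse = ", "))
  recalls <- diag(cm)[support > 0] / support[support > 0]
  list(confusion = cm, UAR = mean(recalls))
}
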