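# Sliding-window detection over long recordings: window layout, frame
# scoring, neighbor smoothing, and run-merging into start/end annotations.

#' Sliding-window layout over a recording
#'
#' Windows of length epsilon start at 0, kappa, 2*kappa, ... while they fit
#' the recording. If uncovered audio remains after the last full window, one
#' final shorter window ending exactly at the recording end is appended (its
#' content is zero-padded for scoring). A recording shorter than epsilon
#' yields a single window covering the whole file.
#'
#' @param duration recording duration, seconds.
#' @param cfg a [SlidingWindowConfig-class].
#' @return data.frame with columns `start`, `end` (seconds).
#' @examples
#' nrow(makeWindows(10, slidingWindowConfig(1, 0.5)))  # 19 full windows
#' @export
makeWindows <- function(duration, cfg) {
  stopifnot(duration > 0)
  eps <- cfg@windowLength; kap <- cfg@step
  if (duration < eps)
    return(data.frame(start = 0, end = duration))
  n <- floor((duration - eps) / kap + 1e-9) + 1
  starts <- (seq_len(n) - 1) * kap
  ends <- starts + eps
  if (max(ends) < duration - 1e-9) {
    starts <- c(starts, n * kap)
    ends <- c(ends, duration)
  }
  data.frame(start = starts, end = ends)
}

#' Score sliding windows of a recording with a trained network
#'
#' Each window is cut from the waveform, preprocessed without augmentation
#' (centered fit, zero padding for a final partial window) and scored in
#' batch. The predicted label of a frame is its maximum-probability class.
#'
#' @param net a trained [AnimalNet-class].
#' @param recording a [Waveform-class].
#' @param pcfg a [PreprocessingConfig-class] (augmentation forced off).
#' @param swcfg a [SlidingWindowConfig-class].
#' @return data.frame of frame scores: `start`, `end`, one `prob.<class>`
#'   column per class, and `predicted_label`.
#' @export
scoreFrames <- function(net, recording, pcfg, swcfg) {
  mono <- toMonoResample(recording, pcfg@targetSampleRate)
  sr <- pcfg@targetSampleRate
  win <- makeWindows(duration(mono), swcfg)
  evalCfg <- pcfg
  evalCfg@augment <- FALSE
  nPad <- as.integer(round(swcfg@windowLength * sr))
  clips <- lapply(seq_len(nrow(win)), function(i) {
    i0 <- as.integer(round(win$start[i] * sr)) + 1L
    i1 <- min(length(mono@samples), as.integer(round(win$end[i] * sr)))
    s <- mono@samples[i0:i1]
    if (length(s) < nPad) s <- c(s, numeric(nPad - length(s)))
    preprocessClip(waveform(s, sr), evalCfg, mode = "center")
  })
  probs <- predictProba(net, clips)
  cls <- net@spec@classNames
  if (is.null(colnames(probs)))
    colnames(probs) <- paste0("class", seq_len(ncol(probs)))
  out <- data.frame(start = win$start, end = win$end)
  for (j in seq_len(ncol(probs)))
    out[[paste0("prob.", colnames(probs)[j])]] <- probs[, j]
  out$predicted_label <- colnames(probs)[apply(probs, 1, which.max)]
  out
}

# frames overlap when their open intervals intersect with positive measure
.overlapNeighbors <- function(frames, i, tol = 1e-9) {
  which(frames$start < frames$end[i] - tol &
          frames$end > frames$start[i] + tol &
          seq_len(nrow(frames)) != i)
}

# single pass of the neighbor rule over an arbitrary logical "is target"
# vector, always judged on the original labels so the pass is
# order-independent
.smoothPositive <- function(frames, positive) {
  out <- positive
  for (i in which(!positive)) {
    nb <- .overlapNeighbors(frames, i)
    if (length(nb) && all(positive[nb])) out[i] <- TRUE
  }
  out
}

#' Neighbor smoothing of frame labels
#'
#' A noise-labeled frame is relabeled as target when every temporally
#' overlapping frame is target-labeled (frames that share signal content
#' because of the window overlap). The pass judges neighbors on the original
#' labels, so smoothing is one-directional (never target to noise) and
#' order-independent. With non-overlapping windows (kappa = epsilon) the
#' neighbor set is empty and nothing changes.
#'
#' @param frames frame-score data.frame from [scoreFrames()], time-ordered.
#' @param noiseClass name of the noise class.
#' @return the data.frame with `predicted_label` smoothed; probabilities
#'   are unchanged.
#' @export
smoothFrames <- function(frames, noiseClass = "noise") {
  if (nrow(frames) == 0L) return(frames)
  positive <- frames$predicted_label != noiseClass
  targetLabs <- unique(frames$predicted_label[positive])
  if (length(targetLabs) != 1L) return(frames)  # only binary smoothing
  sm <- .smoothPositive(frames, positive)
  frames$predicted_label[sm] <- targetLabs
  frames
}

#' Extract annotations from thresholded frame scores
#'
#' A frame is positive when its target-class probability exceeds the
#' confidence threshold delta. With `smooth = TRUE` the neighbor rule of
#' [smoothFrames()] is first applied to the thresholded positives (a
#' sub-threshold frame becomes positive when all its overlapping neighbors
#' are positive). Maximal runs of successive positive frames are then
#' concatenated into one annotation spanning the first start to the last
#' end; the annotation confidence is the maximum frame probability in the
#' run.
#'
#' @param frames frame-score data.frame, time-ordered.
#' @param cfg a [SlidingWindowConfig-class] (supplies delta).
#' @param targetClass class to extract.
#' @param smooth apply neighbor smoothing before run-merging.
#' @return annotation data.frame: `start`, `end`, `label`, `confidence`.
#' @export
extractAnnotations <- function(frames, cfg, targetClass,
                               smooth = FALSE) {
  empty <- data.frame(start = numeric(), end = numeric(),
                      label = character(), confidence = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(frames) == 0L) return(empty)
  p <- frames[[paste0("prob.", targetClass)]]
  if (is.null(p)) stop("no probability column for class ", targetClass)
  positive <- p > cfg@threshold
  if (smooth) positive <- .smoothPositive(frames, positive)
  if (!any(positive)) return(empty)
  runs <- rle(positive)
  stops <- cumsum(runs$lengths)
  starts <- stops - runs$lengths + 1L
  keep <- which(runs$values)
  data.frame(start = frames$start[starts[keep]],
             end = frames$end[stops[keep]], label = targetClass,
             confidence = vapply(keep, function(k)
               max(p[starts[k]:stops[k]]), 1),
             stringsAsFactors = FALSE)
}

#' Write / read annotation selection tables
#'
#' `dialect = "simple"` writes a tab-separated table with header
#' `start_s end_s label confidence`; `dialect = "raven"` writes a
#' Raven-compatible selection table (Selection, View, Channel,
#' Begin Time (s), End Time (s), Label). [readSelectionTable()] detects the
#' dialect from the header.
#'
#' @param ann annotation data.frame (`start`, `end`, `label`, optional
#'   `confidence`).
#' @param path output file.
#' @param dialect "simple" or "raven".
#' @return `path` invisibly (write); an annotation data.frame (read).
#' @export
writeSelectionTable <- function(ann, path, dialect = c("simple", "raven")) {
  dialect <- match.arg(dialect)
  if (dialect == "simple") {
    out <- data.frame(start_s = ann$start, end_s = ann$end,
                      label = ann$label,
                      confidence = if (is.null(ann$confidence)) NA else
                        ann$confidence)
  } else {
    out <- data.frame(Selection = seq_len(nrow(ann)), View = "Spectrogram 1",
                      Channel = 1L, `Begin Time (s)` = ann$start,
                      `End Time (s)` = ann$end, Label = ann$label,
                      check.names = FALSE)
  }
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSelectionTable
#' @export
readSelectionTable <- function(path) {
  hdr <- strsplit(readLines(path, n = 1L), "\t")[[1]]
  tab <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if ("Begin Time (s)" %in% hdr) {
    data.frame(start = tab[["Begin Time (s)"]],
               end = tab[["End Time (s)"]],
               label = as.character(tab[["Label"]]),
               confidence = NA_real_, stringsAsFactors = FALSE)
  } else if ("start_s" %in% hdr) {
    data.frame(start = tab$start_s, end = tab$end_s,
               label = as.character(tab$label),
               confidence = suppressWarnings(as.numeric(tab$confidence)),
               stringsAsFactors = FALSE)
  } else stop("unrecognized selection-table header in ", path)
}
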