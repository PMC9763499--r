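# Second-stage multi-class classification of pre-segmented clips: the noise
# override rule, full-window-only sliding classification with cumulative
# probability-mass voting, and the combined detect-then-classify pipeline.

#' Vote of a single frame with the noise override
#'
#' If the most probable class is not noise it wins with its probability. A
#' noise argmax only stands when its confidence exceeds the threshold
#' (default 0.85); otherwise the runner-up class wins with the runner-up
#' probability.
#'
#' @param probs named probability vector over classes (must include the
#'   noise class).
#' @param ocfg a [NoiseOverrideConfig-class].
#' @return list with `class` and `probability`.
#' @examples
#' frameVote(c(noise = 0.6, A = 0.3, B = 0.1), noiseOverrideConfig())
#' @export
frameVote <- function(probs, ocfg) {
  if (!ocfg@noiseClassName %in% names(probs))
    stop("noise class '", ocfg@noiseClassName, "' absent from probabilities")
  ord <- order(-probs, names(probs))  # ties: lexicographic class name
  top <- ord[1]
  if (names(probs)[top] != ocfg@noiseClassName ||
      probs[top] > ocfg@noiseThreshold)
    return(list(class = names(probs)[top],
                probability = unname(probs[top])))
  runner <- ord[2]
  list(class = names(probs)[runner], probability = unname(probs[runner]))
}

#' Classify a pre-segmented clip by cumulative probability-mass voting
#'
#' A clip shorter than the window length epsilon is scored as a single
#' window equal to the clip (zero-padded or cropped to the network input).
#' Longer clips are scanned at 0, kappa, 2*kappa, ... using full windows
#' only (a trailing partial window is dropped to avoid misclassification).
#' Each frame's vote — after the noise override — adds its probability to
#' the voted class's mass; the decision is the class with maximal
#' accumulated mass, ties broken by class-name order.
#'
#' @param net a trained multi-class [AnimalNet-class].
#' @param clip a [Waveform-class].
#' @param pcfg a [PreprocessingConfig-class].
#' @param swcfg a [SlidingWindowConfig-class].
#' @param ocfg a [NoiseOverrideConfig-class].
#' @return list with `class`, `mass` (named vector over classes),
#'   `nFrames`, and `votes` (per-frame voted class and probability).
#' @export
classifyClip <- function(net, clip, pcfg, swcfg,
                         ocfg = noiseOverrideConfig()) {
  mono <- toMonoResample(clip, pcfg@targetSampleRate)
  if (length(mono@samples) == 0L) stop("empty clip")
  sr <- pcfg@targetSampleRate
  dur <- duration(mono)
  eps <- swcfg@windowLength; kap <- swcfg@step
  if (dur < eps) {
    starts <- 0
    ends <- dur
  } else {
    n <- floor((dur - eps) / kap + 1e-9) + 1
    starts <- (seq_len(n) - 1) * kap
    ends <- starts + eps  # full windows only: no trailing partial window
  }
  evalCfg <- pcfg
  evalCfg@augment <- FALSE
  clips <- lapply(seq_along(starts), function(i) {
    i0 <- as.integer(round(starts[i] * sr)) + 1L
    i1 <- min(length(mono@samples), as.integer(round(ends[i] * sr)))
    preprocessClip(waveform(mono@samples[i0:i1], sr), evalCfg,
                   mode = "center")
  })
  probs <- predictProba(net, clips)
  cls <- colnames(probs)
  mass <- setNames(numeric(length(cls)), cls)
  votes <- data.frame(start = starts, end = ends,
                      class = character(length(starts)),
                      probability = numeric(length(starts)),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(probs))) {
    v <- frameVote(setNames(probs[i, ], cls), ocfg)
    mass[[v$class]] <- mass[[v$class]] + v$probability
    votes$class[i] <- v$class
    votes$probability[i] <- v$probability
  }
  winner <- names(mass)[order(-mass, names(mass))[1]]
  list(class = winner, mass = mass, nFrames = nrow(probs), votes = votes)
}

#' Two-stage detection and classification of a recording
#'
#' Stage 1 runs sliding-window detection with the binary detector, smooths
#' the thresholded frames, and extracts annotations at confidence `delta`.
#' Stage 2 cuts each detected excerpt from the audio and classifies it with
#' the multi-class network under the noise-override voting rule.
#'
#' @param detNet binary detector [AnimalNet-class].
#' @param clsNet multi-class classifier [AnimalNet-class].
#' @param recording a [Waveform-class].
#' @param pcfgDet,pcfgCls preprocessing configurations of the two stages.
#' @param swcfg a [SlidingWindowConfig-class] (shared window layout).
#' @param delta detection confidence threshold; defaults to
#'   `swcfg@threshold`.
#' @param ocfg a [NoiseOverrideConfig-class].
#' @param targetClass detector class to extract; defaults to the detector's
#'   first non-noise class.
#' @param smooth apply neighbor smoothing before extraction.
#' @return annotation data.frame with added columns `class` (stage-2
#'   decision), `mass` and `n_frames`; zero rows when nothing is detected.
#' @export
detectThenClassify <- function(detNet, clsNet, recording, pcfgDet, pcfgCls,
                               swcfg, delta = swcfg@threshold,
                               ocfg = noiseOverrideConfig(),
                               targetClass = NULL, smooth = TRUE) {
  if (is.null(targetClass)) {
    targetClass <- setdiff(detNet@spec@classNames, ocfg@noiseClassName)[1]
    if (is.na(targetClass))
      stop("cannot infer the detector's target class")
  }
  swDelta <- new("SlidingWindowConfig", windowLength = swcfg@windowLength,
                 step = swcfg@step, threshold = delta)
  frames <- scoreFrames(detNet, recording, pcfgDet, swcfg)
  ann <- extractAnnotations(frames, swDelta, targetClass, smooth = smooth)
  if (nrow(ann) == 0L) {
    ann$class <- character()
    ann$mass <- numeric()
    ann$n_frames <- integer()
    return(ann)
  }
  mono <- toMonoResample(recording, pcfgDet@targetSampleRate)
  sr <- pcfgDet@targetSampleRate
  dec <- lapply(seq_len(nrow(ann)), function(i) {
    i0 <- as.integer(round(ann$start[i] * sr)) + 1L
    i1 <- min(length(mono@samples), as.integer(round(ann$end[i] * sr)))
    classifyClip(clsNet, waveform(mono@samples[i0:i1], sr), pcfgCls, swcfg,
                 ocfg)
  })
  ann$class <- vapply(dec, function(d) d$class, "")
  ann$mass <- vapply(dec, function(d) max(d$mass), 1)
  ann$n_frames <- vapply(dec, function(d) d$nFrames, 1L)
  ann
}
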