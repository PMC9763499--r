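# Seeded synthetic bioacoustic corpora: labeled clips on a filename grammar,
# long tapes with planted events, and matching ground-truth selection
# tables, so detection, training and the two-stage pipeline are all
# testable without field recordings.

#' Create a synthetic corpus specification
#'
#' The defaults describe a small tone-versus-noise study: 4 kHz audio, one
#' 1 kHz tonal target class plus a white-noise class, 100 clips per class
#' spread over 20 recordings, clip SNRs uniform on 0-10 dB, and 60 s tapes
#' carrying 10 planted calls per minute.
#'
#' @param sampleRate Hz.
#' @param classes list of class descriptors (name, kind, f0, bandwidth,
#'   durationRange); exactly one class must have kind "noise".
#' @param snrRange uniform clip SNR interval, dB.
#' @param nClipsPerClass clips per class.
#' @param nRecordings distinct recording ids.
#' @param tapeDuration tape length, seconds.
#' @param callDensity planted events per minute.
#' @param seed base RNG seed.
#' @return a [SynthSpec-class].
#' @export
synthSpec <- function(sampleRate = 4000,
                      classes = list(
                        list(name = "target", kind = "tone", f0 = 1000,
                             bandwidth = 0, durationRange = c(0.3, 0.5)),
                        list(name = "noise", kind = "noise", f0 = 0,
                             bandwidth = 0, durationRange = c(0.3, 0.5))),
                      snrRange = c(0, 10), nClipsPerClass = 100L,
                      nRecordings = 20L, tapeDuration = 60,
                      callDensity = 10, seed = 1L) {
  new("SynthSpec", sampleRate = sampleRate, classes = classes,
      snrRange = as.numeric(snrRange),
      nClipsPerClass = as.integer(nClipsPerClass),
      nRecordings = as.integer(nRecordings), tapeDuration = tapeDuration,
      callDensity = callDensity, seed = as.integer(seed))
}

# clean (noise-free) signal for one class descriptor
.cleanSignal <- function(classSpec, duration, sampleRate) {
  n <- max(1L, as.integer(round(duration * sampleRate)))
  t <- (seq_len(n) - 1L) / sampleRate
  switch(classSpec$kind,
    tone = sin(2 * pi * classSpec$f0 * t + runif(1, 0, 2 * pi)),
    chirp = {
      f0 <- classSpec$f0 - classSpec$bandwidth / 2
      rate <- classSpec$bandwidth / duration
      sin(2 * pi * (f0 * t + rate * t^2 / 2) + runif(1, 0, 2 * pi))
    },
    pulse_train = {
      gate <- as.numeric((t * 10) %% 1 < 0.5)  # 10 Hz, 50% duty cycle
      gate * sin(2 * pi * classSpec$f0 * t + runif(1, 0, 2 * pi))
    },
    noise = numeric(n),
    stop("unknown class kind: ", classSpec$kind))
}

#' Generate one synthetic labeled clip
#'
#' Tones are fixed-frequency sinusoids, chirps sweep linearly across the
#' class bandwidth, pulse trains are amplitude-gated tones; every signal is
#' mixed with white noise so that the mean-power ratio matches the requested
#' SNR exactly (`snrDb = Inf` gives the pure signal). The noise class is
#' white noise alone. The result is peak-normalized to \eqn{[-1, 1]}.
#'
#' @param classSpec one class descriptor from a [SynthSpec-class].
#' @param duration seconds.
#' @param snrDb requested signal-to-noise ratio, dB (may be `Inf`).
#' @param sampleRate Hz.
#' @return a [Waveform-class] with attribute `"snr_db"` carrying the
#'   realized component mean-power ratio.
#' @export
generateClip <- function(classSpec, duration, snrDb, sampleRate) {
  stopifnot(duration > 0)
  sig <- .cleanSignal(classSpec, duration, sampleRate)
  n <- length(sig)
  noise <- rnorm(n, sd = 0.1)
  if (classSpec$kind == "noise") {
    out <- noise
    realized <- -Inf
  } else if (is.infinite(snrDb)) {
    out <- sig
    realized <- Inf
  } else {
    pSig <- mean(sig^2)
    pNoise <- mean(noise^2)
    alpha <- sqrt(pNoise * 10^(snrDb / 10) / pSig)
    out <- alpha * sig + noise
    realized <- 10 * log10(mean((alpha * sig)^2) / pNoise)
  }
  peak <- max(abs(out))
  if (peak > 0) out <- out / peak * 0.95
  w <- waveform(out, sampleRate)
  attr(w, "snr_db") <- realized
  w
}

#' Generate a labeled clip corpus on disk
#'
#' Writes `nClipsPerClass` WAV clips per class, named by the
#' `LABEL_ID_RECORDING_STARTms_ENDms.wav` grammar and distributed
#' round-robin over `nRecordings` recording ids, so the corpus is directly
#' consumable by [scanCorpus()] and [splitByRecording()]. Deterministic
#' given `spec@seed`.
#'
#' @param spec a [SynthSpec-class].
#' @param dir output directory (created if missing).
#' @return data.frame of the generated clip records, invisibly.
#' @export
generateCorpus <- function(spec, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(spec@seed)
  recIds <- sprintf("rec%02d", seq_len(spec@nRecordings))
  rows <- list()
  for (cl in spec@classes) {
    for (k in seq_len(spec@nClipsPerClass)) {
      rid <- recIds[((k - 1L) %% spec@nRecordings) + 1L]
      dur <- runif(1, cl$durationRange[1], cl$durationRange[2])
      snr <- runif(1, spec@snrRange[1], spec@snrRange[2])
      w <- generateClip(cl, dur, snr, spec@sampleRate)
      startMs <- (k - 1L) * 2000L
      endMs <- startMs + as.integer(round(dur * 1000))
      name <- sprintf("%s_%04d_%s_%d_%d.wav", cl$name, k, rid, startMs,
                      endMs)
      path <- file.path(dir, name)
      writeWav(w, path)
      rows[[length(rows) + 1L]] <-
        data.frame(path = path, label = cl$name, recording_id = rid,
                   start_ms = startMs, end_ms = endMs,
                   stringsAsFactors = FALSE)
    }
  }
  invisible(do.call(rbind, rows))
}

#' Generate a long synthetic tape with ground truth
#'
#' Plants `round(callDensity * tapeDuration / 60)` events of the non-noise
#' classes (cycled) at uniformly random, non-overlapping positions in
#' continuous white background noise; event amplitudes follow the spec's
#' SNR range relative to the background. Ground truth lists the exact
#' start/end/label of every planted event.
#'
#' @param spec a [SynthSpec-class].
#' @param nEvents override for the number of planted events.
#' @return list with `wave` (a [Waveform-class]) and `annotations`
#'   (data.frame start, end, label).
#' @export
generateTape <- function(spec, nEvents = NULL) {
  sr <- spec@sampleRate
  dur <- spec@tapeDuration
  sigClasses <- Filter(function(cl) cl$kind != "noise", spec@classes)
  if (is.null(nEvents))
    nEvents <- as.integer(round(spec@callDensity * dur / 60))
  bg <- rnorm(as.integer(round(dur * sr)), sd = 0.1)
  pBg <- mean(bg^2)
  ann <- data.frame(start = numeric(), end = numeric(),
                    label = character(), stringsAsFactors = FALSE)
  if (nEvents > 0L) {
    maxDur <- max(vapply(sigClasses, function(cl) cl$durationRange[2], 1))
    if (dur <= maxDur) stop("tape shorter than the longest event")
    if (nEvents * maxDur > 0.8 * dur)
      stop("infeasible call density: events would cover >80% of the tape")
    placed <- data.frame(start = numeric(), end = numeric())
    tries <- 0L
    while (nrow(placed) < nEvents) {
      if ((tries <- tries + 1L) > 1000L * nEvents)
        stop("could not place events without overlap")
      cl <- sigClasses[[((nrow(placed)) %% length(sigClasses)) + 1L]]
      evDur <- runif(1, cl$durationRange[1], cl$durationRange[2])
      start <- runif(1, 0, dur - evDur)
      if (any(start < placed$end + 0.05 & start + evDur > placed$start -
                0.05)) next
      snr <- runif(1, spec@snrRange[1], spec@snrRange[2])
      sig <- .cleanSignal(cl, evDur, sr)
      alpha <- sqrt(pBg * 10^(snr / 10) / mean(sig^2))
      i0 <- as.integer(round(start * sr)) + 1L
      i1 <- min(length(bg), i0 + length(sig) - 1L)
      bg[i0:i1] <- bg[i0:i1] + alpha * sig[seq_len(i1 - i0 + 1L)]
      placed <- rbind(placed,
                      data.frame(start = start, end = start + evDur))
      ann <- rbind(ann, data.frame(start = start, end = start + evDur,
                                   label = cl$name,
                                   stringsAsFactors = FALSE))
    }
  }
  peak <- max(abs(bg))
  if (peak > 1) bg <- bg / peak * 0.95
  ann <- ann[order(ann$start), , drop = FALSE]
  rownames(ann) <- NULL
  list(wave = waveform(bg, sr), annotations = ann)
}

#' Preprocessing configuration matched to a synthetic study
#'
#' Derives the preprocessing settings used for the synthetic end-to-end
#' experiments from a corpus specification: FFT window 64 / hop 64 at the
#' spec's sampling rate, a 200-1800 Hz analysis band compressed to 32 bins,
#' a 0.5 s sequence, and dB normalization. The FFT window is chosen so the
#' analysis band holds fewer STFT bins than the 32 output rows: linear
#' nearest-neighbor compression then only upsamples and narrowband
#' synthetic signals can never fall between retained rows, while the small
#' input keeps CPU training of the residual classifier fast.
#'
#' @param spec a [SynthSpec-class].
#' @param augment enable augmentation (training-time configuration).
#' @return a [PreprocessingConfig-class].
#' @export
studyPreprocessingConfig <- function(spec = synthSpec(), augment = FALSE) {
  preprocessingConfig(
    targetSampleRate = spec@sampleRate, fftWindowLength = 64L,
    fftHop = 64L, fMin = 200, fMax = min(1800, spec@sampleRate / 2 - 100),
    nFreqBins = 32L, sequenceLength = 0.5, normalizationMode = "db",
    minDB = -100, refDB = 20, intensityInterval = c(-3, 3),
    pitchInterval = c(0.95, 1.05), timeInterval = c(0.95, 1.05),
    snrInterval = c(0, 10), augment = augment)
}
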