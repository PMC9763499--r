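#' Create a waveform
#'
#' @param samples numeric vector (mono) or samples-by-channels matrix with
#'   amplitudes nominally in \eqn{[-1, 1]}.
#' @param sampleRate sampling rate in Hz.
#' @return a [Waveform-class].
#' @examples
#' w <- waveform(sin(2 * pi * 440 * seq(0, 1, length.out = 8000)), 8000)
#' duration(w)
#' @export
waveform <- function(samples, sampleRate) {
  new("Waveform", samples = samples, sampleRate = sampleRate)
}

#' Create a power spectrogram
#'
#' @param values nonnegative F x T matrix of spectral power.
#' @param freq frequency of each row, Hz (strictly increasing).
#' @param time start time of each column, seconds.
#' @return a [PowerSpectrogram-class].
#' @export
powerSpectrogram <- function(values, freq, time) {
  new("PowerSpectrogram", values = values, freq = as.numeric(freq),
      time = as.numeric(time))
}

#' Create a preprocessing configuration
#'
#' @param targetSampleRate target sampling rate, Hz.
#' @param fftWindowLength STFT window length, samples.
#' @param fftHop STFT hop, samples.
#' @param fMin,fMax retained frequency band, Hz.
#' @param nFreqBins compressed frequency bin count.
#' @param sequenceLength network input duration, seconds.
#' @param normalizationMode "minmax" or "db".
#' @param minDB,refDB decibel anchors used by the "db" mode.
#' @param intensityInterval uniform gain augmentation interval, dB.
#' @param pitchInterval uniform pitch-scale augmentation interval.
#' @param timeInterval uniform time-scale augmentation interval.
#' @param snrInterval uniform SNR interval for noise mixing, dB.
#' @param augment logical, enable augmentation draws.
#' @return a [PreprocessingConfig-class].
#' @examples
#' cfg <- preprocessingConfig(targetSampleRate = 44100, fMin = 500,
#'                            fMax = 10000, sequenceLength = 1.28)
#' networkFrames(cfg)
#' @export
preprocessingConfig <- function(targetSampleRate, fftWindowLength = 1024L,
                                fftHop = 512L, fMin, fMax,
                                nFreqBins = 256L, sequenceLength,
                                normalizationMode = c("db", "minmax"),
                                minDB = -100, refDB = 20,
                                intensityInterval = c(-6, 6),
                                pitchInterval = c(0.9, 1.1),
                                timeInterval = c(0.9, 1.1),
                                snrInterval = c(-2, 10),
                                augment = FALSE) {
  normalizationMode <- match.arg(normalizationMode)
  new("PreprocessingConfig",
      targetSampleRate = as.numeric(targetSampleRate),
      fftWindowLength = as.integer(fftWindowLength),
      fftHop = as.integer(fftHop), fMin = as.numeric(fMin),
      fMax = as.numeric(fMax), nFreqBins = as.integer(nFreqBins),
      sequenceLength = as.numeric(sequenceLength),
      normalizationMode = normalizationMode, minDB = minDB, refDB = refDB,
      intensityInterval = as.numeric(intensityInterval),
      pitchInterval = as.numeric(pitchInterval),
      timeInterval = as.numeric(timeInterval),
      snrInterval = as.numeric(snrInterval), augment = augment)
}

#' Create a network architecture specification
#'
#' @param nClasses number of output classes (>= 2).
#' @param inputShape c(frequency bins, time frames).
#' @param channels stage channel widths.
#' @param blocksPerStage basic blocks per stage.
#' @param classNames optional class labels in output order.
#' @return a [NetworkSpec-class].
#' @export
networkSpec <- function(nClasses, inputShape = c(256L, 128L),
                        channels = c(64L, 128L, 256L, 512L),
                        blocksPerStage = c(2L, 2L, 2L, 2L),
                        classNames = character()) {
  new("NetworkSpec", nClasses = as.integer(nClasses),
      inputShape = as.integer(inputShape), channels = as.integer(channels),
      blocksPerStage = as.integer(blocksPerStage),
      classNames = as.character(classNames))
}

#' Create a training configuration
#'
#' @param batchSize clips per optimizer step.
#' @param learningRate initial Adam step size.
#' @param beta1,beta2 Adam moment decays.
#' @param lrDecayFactor learning-rate multiplier applied on plateau.
#' @param lrPatience epochs without validation improvement before a decay.
#' @param earlyStopPatience stale epochs before stopping.
#' @param maxEpochs hard epoch cap.
#' @param seed RNG seed.
#' @return a [TrainingConfig-class].
#' @export
trainingConfig <- function(batchSize = 8L, learningRate = 1e-5,
                           beta1 = 0.5, beta2 = 0.999,
                           lrDecayFactor = 0.5, lrPatience = 4L,
                           earlyStopPatience = 10L, maxEpochs = 50L,
                           seed = 1L) {
  new("TrainingConfig", batchSize = as.integer(batchSize),
      learningRate = learningRate, beta1 = beta1, beta2 = beta2,
      lrDecayFactor = lrDecayFactor, lrPatience = as.integer(lrPatience),
      earlyStopPatience = as.integer(earlyStopPatience),
      maxEpochs = as.integer(maxEpochs), seed = as.integer(seed))
}

#' Create a sliding-window configuration
#'
#' @param windowLength window length epsilon, seconds.
#' @param step step size kappa, seconds.
#' @param threshold decision threshold delta in \eqn{[0, 1]}.
#' @return a [SlidingWindowConfig-class].
#' @export
slidingWindowConfig <- function(windowLength, step = windowLength / 2,
                                threshold = 0.5) {
  new("SlidingWindowConfig", windowLength = windowLength, step = step,
      threshold = threshold)
}

#' Create a time-wise evaluation configuration
#'
#' Defaults follow the epsilon/2 convention for both the merging gap xi and
#' the border extension lambda.
#'
#' @param epsilon sliding-window length, seconds; used for the defaults.
#' @param mergeXi merging gap, seconds.
#' @param extendLambda border extension, seconds.
#' @return a [TimewiseEvalConfig-class].
#' @export
timewiseEvalConfig <- function(epsilon = 1, mergeXi = epsilon / 2,
                               extendLambda = epsilon / 2) {
  new("TimewiseEvalConfig", mergeXi = mergeXi, extendLambda = extendLambda)
}

#' Create a noise-override configuration
#'
#' @param noiseThreshold confidence a noise prediction must exceed to stand.
#' @param noiseClassName name of the noise class.
#' @return a [NoiseOverrideConfig-class].
#' @export
noiseOverrideConfig <- function(noiseThreshold = 0.85,
                                noiseClassName = "noise") {
  new("NoiseOverrideConfig", noiseThreshold = noiseThreshold,
      noiseClassName = noiseClassName)
}

#' Duration of a waveform in seconds
#' @param w a [Waveform-class].
#' @return duration in seconds.
#' @export
duration <- function(w) {
  n <- if (is.matrix(w@samples)) nrow(w@samples) else length(w@samples)
  n / w@sampleRate
}

#' Number of time frames of a network input clip
#'
#' T_net is derived from the configured sequence length as the nearest
#' integer number of STFT hops.
#'
#' @param cfg a [PreprocessingConfig-class].
#' @return integer frame count.
#' @export
networkFrames <- function(cfg) {
  max(1L, as.integer(round(cfg@sequenceLength * cfg@targetSampleRate /
                             cfg@fftHop)))
}

setMethod("show", "Waveform", function(object) {
  s <- object@samples
  ch <- if (is.matrix(s)) ncol(s) else 1L
  cat(sprintf("Waveform: %.3f s, %d channel(s) @ %g Hz\n",
              duration(object), ch, object@sampleRate))
})

setMethod("show", "PowerSpectrogram", function(object) {
  cat(sprintf(
    "PowerSpectrogram: %d bins x %d frames, %.1f-%.1f Hz, %.3f s\n",
    nrow(object@values), ncol(object@values), min(object@freq),
    max(object@freq),
    if (length(object@time) > 1) diff(range(object@time)) else 0))
})

setMethod("show", "PreprocessingConfig", function(object) {
  cat(sprintf(paste0(
    "PreprocessingConfig: %g Hz, FFT %d/%d, band %g-%g Hz -> %d bins,\n",
    "  sequence %.3g s (T_net = %d), normalization '%s', augment = %s\n"),
    object@targetSampleRate, object@fftWindowLength, object@fftHop,
    object@fMin, object@fMax, object@nFreqBins, object@sequenceLength,
    networkFrames(object), object@normalizationMode, object@augment))
})

setMethod("show", "DatasetSplit", function(object) {
  n <- c(nrow(object@train), nrow(object@validation), nrow(object@test))
  cat(sprintf(
    "DatasetSplit: %d/%d/%d clips (%.1f%%/%.1f%%/%.1f%%), %d recordings\n",
    n[1], n[2], n[3], 100 * n[1] / sum(n), 100 * n[2] / sum(n),
    100 * n[3] / sum(n),
    length(unique(c(object@train$recording_id,
                    object@validation$recording_id,
                    object@test$recording_id)))))
})

setMethod("show", "AnimalNet", function(object) {
  sp <- object@spec
  cat(sprintf(
    "AnimalNet: %d-class residual classifier, input %d x %d, stages [%s]\n",
    sp@nClasses, sp@inputShape[1], sp@inputShape[2],
    paste(sp@channels, collapse = ", ")))
  if (length(sp@classNames))
    cat("  classes:", paste(sp@classNames, collapse = ", "), "\n")
})

#' Partition accessors for a dataset split
#' @param x a [DatasetSplit-class].
#' @return a data.frame of clip records.
#' @export
trainSet <- function(x) x@train

#' @rdname trainSet
#' @export
validationSet <- function(x) x@validation

#' @rdname trainSet
#' @export
testSet <- function(x) x@test

#' Class names of a network
#' @param net an [AnimalNet-class].
#' @return character vector of class labels in output order.
#' @export
classNames <- function(net) net@spec@classNames
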