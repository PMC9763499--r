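#' @import methods
#' @importFrom stats rnorm runif setNames
#' @importFrom utils read.table write.table head tail
#' @useDynLib spotcall, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Mono or multi-channel audio waveform
#'
#' Holds PCM samples in \eqn{[-1, 1]} together with their sampling rate.
#' Multi-channel audio is stored as a samples-by-channels matrix; mono audio
#' as a plain numeric vector (a one-column matrix is accepted too).
#'
#' @slot samples numeric vector (mono) or samples-by-channels matrix.
#' @slot sampleRate sampling rate in Hz.
#' @export
setClass("Waveform",
  representation(samples = "ANY", sampleRate = "numeric"),
  validity = function(object) {
    s <- object@samples
    if (!(is.numeric(s) && (is.vector(s) || is.matrix(s))))
      return("samples must be a numeric vector or matrix")
    if (length(s) == 0L) return("samples must be non-empty")
    if (!all(is.finite(s))) return("samples must be finite")
    if (length(object@sampleRate) != 1L || object@sampleRate <= 0)
      return("sampleRate must be a single positive number")
    TRUE
  })

#' Power spectrogram
#'
#' A nonnegative F-by-T matrix of magnitude-squared STFT values with
#' frequency (Hz, per row) and time (seconds, frame start, per column) axes.
#'
#' @slot values F x T nonnegative matrix of spectral power.
#' @slot freq frequency per row, Hz, strictly increasing.
#' @slot time frame start time per column, seconds.
#' @export
setClass("PowerSpectrogram",
  representation(values = "matrix", freq = "numeric", time = "numeric"),
  validity = function(object) {
    if (nrow(object@values) != length(object@freq))
      return("length(freq) must equal nrow(values)")
    if (ncol(object@values) != length(object@time))
      return("length(time) must equal ncol(values)")
    if (any(object@values < 0)) return("power values must be nonnegative")
    if (length(object@freq) > 1L && any(diff(object@freq) <= 0))
      return("freq must be strictly increasing")
    TRUE
  })

#' Species-specific preprocessing configuration
#'
#' All tunable parameters of the eight-step preprocessing pipeline turning a
#' raw waveform into a normalized spectrogram clip: target sampling rate, FFT
#' framing, the retained frequency band \code{[fMin, fMax]} compressed to
#' \code{nFreqBins} rows, the network sequence length in seconds,
#' normalization mode and decibel anchors, and the uniform augmentation
#' intervals (intensity in dB, pitch/time as unitless scale factors, SNR of
#' mixed-in noise in dB).
#'
#' @slot targetSampleRate Hz.
#' @slot fftWindowLength STFT window length, samples.
#' @slot fftHop STFT hop, samples.
#' @slot fMin,fMax retained frequency band, Hz.
#' @slot nFreqBins number of compressed frequency bins (256 by default).
#' @slot sequenceLength network input length, seconds.
#' @slot normalizationMode \code{"minmax"} or \code{"db"}.
#' @slot minDB,refDB decibel anchors for \code{"db"} normalization.
#' @slot intensityInterval uniform gain interval, dB.
#' @slot pitchInterval uniform pitch-scale interval.
#' @slot timeInterval uniform time-scale interval.
#' @slot snrInterval uniform signal-to-noise interval for noise mixing, dB.
#' @slot augment logical; draw augmentations when preprocessing.
#' @export
setClass("PreprocessingConfig",
  representation(
    targetSampleRate = "numeric", fftWindowLength = "integer",
    fftHop = "integer", fMin = "numeric", fMax = "numeric",
    nFreqBins = "integer", sequenceLength = "numeric",
    normalizationMode = "character", minDB = "numeric", refDB = "numeric",
    intensityInterval = "numeric", pitchInterval = "numeric",
    timeInterval = "numeric", snrInterval = "numeric", augment = "logical"),
  validity = function(object) {
    if (object@fMin >= object@fMax)
      return("fMin must be < fMax")
    if (object@fMax > object@targetSampleRate / 2)
      return("fMax must not exceed the Nyquist frequency")
    if (object@nFreqBins < 1L) return("nFreqBins must be >= 1")
    if (object@sequenceLength <= 0) return("sequenceLength must be > 0")
    if (!object@normalizationMode %in% c("minmax", "db"))
      return("normalizationMode must be 'minmax' or 'db'")
    for (nm in c("intensityInterval", "pitchInterval", "timeInterval",
                 "snrInterval")) {
      iv <- slot(object, nm)
      if (length(iv) != 2L || iv[1] > iv[2])
        return(sprintf("%s must be a (lo <= hi) pair", nm))
    }
    if (any(c(object@pitchInterval, object@timeInterval) <= 0))
      return("pitch and time scale factors must be positive")
    if (object@fftHop < 1L || object@fftWindowLength < 2L)
      return("fftWindowLength/fftHop out of range")
    TRUE
  })

#' Normalized spectrogram clip (network input)
#'
#' The final nFreqBins x T_net matrix in \eqn{[0, 1]} produced by the
#' preprocessing pipeline, with a provenance record of the augmentation
#' parameters that were applied.
#'
#' @slot values matrix in \eqn{[0, 1]}; rows = frequency bins.
#' @slot provenance named list (source id, drawn augmentation factors).
#' @export
setClass("NormalizedClip",
  representation(values = "matrix", provenance = "list"),
  validity = function(object) {
    v <- object@values
    if (any(v < 0 | v > 1)) return("values must lie in [0, 1]")
    TRUE
  })

#' Network architecture specification
#'
#' Describes the modified 18-layer residual classifier: a 7x7 stride-2 stem
#' without the usual max-pooling stage, four stages of two basic blocks with
#' the given channel widths (stages 2-4 opening with stride 2), adaptive
#' global average pooling to a feature vector, and an n-class linear head.
#'
#' @slot nClasses number of output classes (>= 2).
#' @slot inputShape (frequency bins, time frames) of network inputs.
#' @slot channels channel width per stage, default c(64, 128, 256, 512).
#' @slot blocksPerStage basic blocks per stage, default c(2, 2, 2, 2).
#' @slot classNames class labels in output order.
#' @export
setClass("NetworkSpec",
  representation(nClasses = "integer", inputShape = "integer",
                 channels = "integer", blocksPerStage = "integer",
                 classNames = "character"),
  validity = function(object) {
    if (object@nClasses < 2L) return("nClasses must be >= 2")
    if (length(object@inputShape) != 2L || any(object@inputShape < 16L))
      return("inputShape must be two dimensions, each >= 16")
    if (length(object@channels) != length(object@blocksPerStage))
      return("channels and blocksPerStage must have equal length")
    if (length(object@classNames) &&
        length(object@classNames) != object@nClasses)
      return("classNames must have nClasses entries")
    TRUE
  })

#' Trained or untrained residual network classifier
#'
#' Bundles the architecture specification, all learnable parameters, the
#' batch-normalization running statistics, and the class-name ordering. The
#' preprocessing configuration used at training time is carried along so a
#' saved checkpoint is self-describing at prediction time.
#'
#' @slot spec a [NetworkSpec-class].
#' @slot params nested list of weight tensors.
#' @slot state nested list of batch-norm running means/variances.
#' @slot preprocessing the [PreprocessingConfig-class] used for training
#'   (may be absent in a freshly built network).
#' @export
setClass("AnimalNet",
  representation(spec = "NetworkSpec", params = "list", state = "list",
                 preprocessing = "ANY"))

#' Recording-exclusive dataset split
#'
#' Train/validation/test partition of labeled clips in which every recording
#' contributes to exactly one partition.
#'
#' @slot train,validation,test data.frames of clip records
#'   (path, label, recording_id, start_ms, end_ms).
#' @slot fractions target proportions, e.g. c(0.70, 0.15, 0.15).
#' @export
setClass("DatasetSplit",
  representation(train = "data.frame", validation = "data.frame",
                 test = "data.frame", fractions = "numeric"),
  validity = function(object) {
    ids <- list(object@train$recording_id, object@validation$recording_id,
                object@test$recording_id)
    ids <- lapply(ids, unique)
    if (length(intersect(ids[[1]], ids[[2]])) ||
        length(intersect(ids[[1]], ids[[3]])) ||
        length(intersect(ids[[2]], ids[[3]])))
      return("recording ids must be exclusive to one partition")
    if (length(object@fractions) != 3L ||
        abs(sum(object@fractions) - 1) > 1e-8)
      return("fractions must be three proportions summing to 1")
    TRUE
  })

#' Optimizer and schedule configuration
#'
#' Cross-entropy training with the Adam optimizer, plateau learning-rate
#' decay, and early stopping on validation accuracy. Defaults follow the
#' framework-wide settings: batch size 8, initial learning rate 1e-5 with
#' beta1 = 0.5 and beta2 = 0.999, halving the rate after 4 epochs without a
#' validation improvement.
#'
#' @slot batchSize clips per optimizer step.
#' @slot learningRate initial Adam step size.
#' @slot beta1,beta2 Adam moment decays.
#' @slot lrDecayFactor multiplicative decay on plateau.
#' @slot lrPatience epochs without improvement before a decay.
#' @slot earlyStopPatience stale epochs before training stops.
#' @slot maxEpochs hard epoch cap.
#' @slot seed RNG seed for shuffling, augmentation and initialization.
#' @export
setClass("TrainingConfig",
  representation(batchSize = "integer", learningRate = "numeric",
                 beta1 = "numeric", beta2 = "numeric",
                 lrDecayFactor = "numeric", lrPatience = "integer",
                 earlyStopPatience = "integer", maxEpochs = "integer",
                 seed = "integer"),
  validity = function(object) {
    if (object@batchSize < 1L || object@maxEpochs < 1L)
      return("batchSize and maxEpochs must be >= 1")
    if (object@learningRate <= 0) return("learningRate must be positive")
    if (any(c(object@beta1, object@beta2) <= 0) ||
        any(c(object@beta1, object@beta2) >= 1))
      return("beta1 and beta2 must lie in (0, 1)")
    if (object@lrDecayFactor <= 0 || object@lrDecayFactor > 1)
      return("lrDecayFactor must lie in (0, 1]")
    TRUE
  })

#' Sliding-window detection configuration
#'
#' Window length epsilon, step kappa and decision threshold delta used to
#' scan long recordings frame by frame.
#'
#' @slot windowLength window length epsilon, seconds.
#' @slot step step size kappa, seconds.
#' @slot threshold model-confidence threshold delta in \eqn{[0, 1]}.
#' @export
setClass("SlidingWindowConfig",
  representation(windowLength = "numeric", step = "numeric",
                 threshold = "numeric"),
  validity = function(object) {
    if (object@step <= 0 || object@step > object@windowLength)
      return("need 0 < step <= windowLength")
    if (object@threshold < 0 || object@threshold > 1)
      return("threshold must lie in [0, 1]")
    TRUE
  })

#' Time-wise evaluation configuration
#'
#' Ground-truth merging gap xi and border-extension lambda (both seconds,
#' both conventionally epsilon / 2) used when comparing machine annotations
#' against human selection tables.
#'
#' @slot mergeXi maximal gap merged between ground-truth annotations.
#' @slot extendLambda extension applied to ground-truth borders for the
#'   precision computation.
#' @export
setClass("TimewiseEvalConfig",
  representation(mergeXi = "numeric", extendLambda = "numeric"),
  validity = function(object) {
    if (object@mergeXi < 0 || object@extendLambda < 0)
      return("mergeXi and extendLambda must be >= 0")
    TRUE
  })

#' Noise-override configuration for multi-class voting
#'
#' A noise prediction is only accepted when its confidence exceeds the
#' threshold (default 0.85); otherwise the runner-up class wins the frame.
#'
#' @slot noiseThreshold probability bound in \eqn{[0, 1]}.
#' @slot noiseClassName name of the noise class.
#' @export
setClass("NoiseOverrideConfig",
  representation(noiseThreshold = "numeric", noiseClassName = "character"),
  validity = function(object) {
    if (object@noiseThreshold < 0 || object@noiseThreshold > 1)
      return("noiseThreshold must lie in [0, 1]")
    if (!nzchar(object@noiseClassName))
      return("noiseClassName must be non-empty")
    TRUE
  })

#' Synthetic corpus specification
#'
#' Controls the seeded generator of synthetic bioacoustic data: per-class
#' signal kinds (tone, chirp, pulse train, noise), clip SNR range, corpus
#' size and recording structure, and the long-tape event density.
#'
#' @slot sampleRate Hz.
#' @slot classes list of class descriptors, each a list with elements
#'   \code{name}, \code{kind} (one of tone/chirp/pulse_train/noise),
#'   \code{f0} (Hz), \code{bandwidth} (Hz) and \code{durationRange}
#'   (seconds, lo/hi). Exactly one class must have kind "noise".
#' @slot snrRange uniform clip SNR interval, dB.
#' @slot nClipsPerClass clips generated per class.
#' @slot nRecordings number of distinct recording ids.
#' @slot tapeDuration long-tape duration, seconds.
#' @slot callDensity planted events per minute of tape.
#' @slot seed base RNG seed.
#' @export
setClass("SynthSpec",
  representation(sampleRate = "numeric", classes = "list",
                 snrRange = "numeric", nClipsPerClass = "integer",
                 nRecordings = "integer", tapeDuration = "numeric",
                 callDensity = "numeric", seed = "integer"),
  validity = function(object) {
    nms <- vapply(object@classes, function(cl) cl$name, "")
    if (anyDuplicated(nms)) return("class names must be distinct")
    kinds <- vapply(object@classes, function(cl) cl$kind, "")
    if (sum(kinds == "noise") != 1L)
      return("exactly one class must have kind 'noise'")
    if (!all(kinds %in% c("tone", "chirp", "pulse_train", "noise")))
      return("unknown class kind")
    if (object@nClipsPerClass < 1L || object@nRecordings < 1L)
      return("counts must be positive")
    if (object@callDensity < 0) return("callDensity must be >= 0")
    TRUE
  })
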