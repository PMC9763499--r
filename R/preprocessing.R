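# Eight-step preprocessing pipeline: (1) mono + resample, (2) power STFT,
# (3) spectrogram-domain augmentation, (4) linear frequency compression,
# (5) SNR-controlled noise mixing, (6) dB conversion, (7) normalization,
# (8) fit to the network sequence length.

DB_POWER_FLOOR <- 1e-10  # power floor before log10; far below signal range

#' Convert to mono and resample
#'
#' Multi-channel audio is averaged across channels; sample-rate conversion
#' uses polyphase band-limited interpolation.
#'
#' @param w a [Waveform-class].
#' @param targetSampleRate target rate, Hz.
#' @return a mono [Waveform-class] at `targetSampleRate`.
#' @export
toMonoResample <- function(w, targetSampleRate) {
  stopifnot(targetSampleRate > 0)
  s <- w@samples
  if (is.matrix(s)) s <- rowMeans(s)
  if (length(s) == 0L) stop("empty waveform")
  if (w@sampleRate != targetSampleRate) {
    frac <- .ratApprox(targetSampleRate / w@sampleRate)
    s <- signal::resample(s, frac[1], frac[2])
    s <- as.numeric(s)
  }
  waveform(s, targetSampleRate)
}

# small continued-fraction rational approximation p/q of a positive ratio
.ratApprox <- function(x, maxDen = 1000L) {
  best <- c(round(x), 1)
  bestErr <- abs(x - best[1])
  for (q in seq_len(maxDen)) {
    p <- round(x * q)
    if (p < 1) next
    err <- abs(x - p / q)
    if (err < bestErr - 1e-15) {
      best <- c(p, q)
      bestErr <- err
    }
    if (bestErr < 1e-12) break
  }
  as.integer(best)
}

#' Power spectrogram via the short-time Fourier transform
#'
#' Hann-windowed magnitude-squared STFT. The output has
#' `fftWindowLength / 2 + 1` rows and one column per full hop fitting the
#' signal.
#'
#' @param w a mono [Waveform-class].
#' @param cfg a [PreprocessingConfig-class] (uses the FFT fields only).
#' @return a [PowerSpectrogram-class].
#' @export
stftPower <- function(w, cfg) {
  s <- w@samples
  if (is.matrix(s)) stop("stftPower expects mono audio; see toMonoResample")
  N <- cfg@fftWindowLength
  hop <- cfg@fftHop
  if (N > length(s)) stop("FFT window longer than the signal")
  win <- 0.5 * (1 - cos(2 * pi * (0:(N - 1)) / N))  # periodic Hann
  starts <- seq(1L, length(s) - N + 1L, by = hop)
  frames <- vapply(starts, function(i) s[i:(i + N - 1L)] * win,
                   numeric(N))
  spec <- stats::mvfft(frames)
  nf <- N %/% 2L + 1L
  pow <- Mod(spec[seq_len(nf), , drop = FALSE])^2
  sr <- w@sampleRate
  powerSpectrogram(pow, freq = (seq_len(nf) - 1L) * sr / N,
                   time = (starts - 1L) / sr)
}

# nearest-neighbor axis remap shared by pitch and time augmentation:
# output index i sources input index floor((i-1)/factor)+1 (clamped)
.remapIndex <- function(nOut, factor, nIn) {
  pmin(nIn, pmax(1L, floor((seq_len(nOut) - 1L) / factor) + 1L))
}

#' Random intensity, pitch and time augmentation of a spectrogram
#'
#' Draws one uniform scalar per augmentation from the configured intervals:
#' a gain g (dB) multiplying power by \eqn{10^{g/10}}, a pitch factor
#' rescaling the frequency axis (row count becomes round(F * p)), and a time
#' factor rescaling the time axis (column count becomes round(T * t)); both
#' axis remaps are nearest neighbor. Draws come from R's global RNG, so
#' results are reproducible under [set.seed()].
#'
#' @param s a [PowerSpectrogram-class].
#' @param cfg a [PreprocessingConfig-class].
#' @return augmented [PowerSpectrogram-class] with attribute
#'   `"augmentation"` recording the drawn factors.
#' @export
randomAugment <- function(s, cfg) {
  g <- runif(1, cfg@intensityInterval[1], cfg@intensityInterval[2])
  p <- runif(1, cfg@pitchInterval[1], cfg@pitchInterval[2])
  tf <- runif(1, cfg@timeInterval[1], cfg@timeInterval[2])
  v <- s@values * 10^(g / 10)
  Fin <- nrow(v); Tin <- ncol(v)
  Fout <- max(1L, as.integer(round(Fin * p)))
  Tout <- max(1L, as.integer(round(Tin * tf)))
  v <- v[.remapIndex(Fout, p, Fin), .remapIndex(Tout, tf, Tin),
         drop = FALSE]
  df <- if (Fin > 1L) s@freq[2] - s@freq[1] else 1
  dt <- if (Tin > 1L) s@time[2] - s@time[1] else 1
  out <- powerSpectrogram(v, freq = s@freq[1] + (seq_len(Fout) - 1L) * df,
                          time = s@time[1] + (seq_len(Tout) - 1L) * dt)
  attr(out, "augmentation") <- c(intensity_db = g, pitch = p, time = tf)
  out
}

#' Linear frequency compression
#'
#' Maps the spectrogram onto exactly `nFreqBins` rows whose target
#' frequencies are linearly spaced on \code{[fMin, fMax]}; each output row
#' copies the in-band input row with the nearest frequency. Rows outside the
#' band never contribute.
#'
#' @param s a [PowerSpectrogram-class].
#' @param cfg a [PreprocessingConfig-class].
#' @return compressed [PowerSpectrogram-class] with `nFreqBins` rows.
#' @export
compressFrequency <- function(s, cfg) {
  inBand <- which(s@freq >= cfg@fMin & s@freq <= cfg@fMax)
  if (length(inBand) == 0L)
    stop("no spectrogram rows inside [fMin, fMax]")
  targets <- if (cfg@nFreqBins == 1L) (cfg@fMin + cfg@fMax) / 2 else
    seq(cfg@fMin, cfg@fMax, length.out = cfg@nFreqBins)
  bandFreq <- s@freq[inBand]
  pick <- inBand[vapply(targets,
                        function(f) which.min(abs(bandFreq - f)), 1L)]
  powerSpectrogram(s@values[pick, , drop = FALSE], freq = targets,
                   time = s@time)
}

#' Mix a noise spectrogram into a signal spectrogram at a drawn SNR
#'
#' The noise spectrogram (already frequency-compressed to the same number of
#' rows) is pitch-/time-augmented, tiled or cropped to the signal's frame
#' count, scaled so that \eqn{10 \log_{10}(\bar{P}_s / (\alpha
#' \bar{P}_n)) = SNR} for an SNR drawn uniformly from `snrInterval`, and
#' added cell-wise.
#'
#' @param s signal [PowerSpectrogram-class].
#' @param noise noise [PowerSpectrogram-class] with the same row count.
#' @param cfg a [PreprocessingConfig-class].
#' @return mixed [PowerSpectrogram-class] with attribute `"snr_db"`.
#' @export
addNoise <- function(s, noise, cfg) {
  if (nrow(noise@values) != nrow(s@values))
    stop("noise spectrogram must have the same row count as the signal")
  snr <- runif(1, cfg@snrInterval[1], cfg@snrInterval[2])
  p <- runif(1, cfg@pitchInterval[1], cfg@pitchInterval[2])
  tf <- runif(1, cfg@timeInterval[1], cfg@timeInterval[2])
  nv <- noise@values
  # pitch/time remap with the row count held fixed so addition stays defined
  nv <- nv[.remapIndex(nrow(nv), p, nrow(nv)),
           .remapIndex(max(1L, as.integer(round(ncol(nv) * tf))), tf,
                       ncol(nv)), drop = FALSE]
  Tn <- ncol(s@values)
  if (ncol(nv) < Tn) {
    reps <- ceiling(Tn / ncol(nv))
    nv <- nv[, rep(seq_len(ncol(nv)), reps), drop = FALSE]
  }
  if (ncol(nv) > Tn) {
    off <- sample.int(ncol(nv) - Tn + 1L, 1L) - 1L
    nv <- nv[, (off + 1L):(off + Tn), drop = FALSE]
  }
  mn <- mean(nv)
  if (mn <= 0) stop("all-zero noise spectrogram: SNR scaling undefined")
  alpha <- mean(s@values) / (mn * 10^(snr / 10))
  out <- powerSpectrogram(s@values + alpha * nv, freq = s@freq,
                          time = s@time)
  attr(out, "snr_db") <- snr
  attr(out, "noise_scale") <- alpha
  out
}

#' Convert a power spectrogram to decibels
#'
#' Cell-wise \eqn{10 \log_{10}(\max(P, 10^{-10}))}; the floor keeps silent
#' cells finite.
#'
#' @param s a [PowerSpectrogram-class] or nonnegative matrix.
#' @return matrix of dB values (same shape).
#' @export
toDecibel <- function(s) {
  v <- if (is(s, "PowerSpectrogram")) s@values else s
  10 * log10(pmax(v, DB_POWER_FLOOR))
}

#' Normalize a dB spectrogram to \eqn{[0, 1]}
#'
#' `"minmax"` maps the spectral minimum/maximum to 0/1 (a constant matrix
#' maps to all zeros); `"db"` maps `minDB` to 0 and `refDB` to 1, clipping
#' outside values.
#'
#' @param sdb matrix of dB values.
#' @param cfg a [PreprocessingConfig-class].
#' @return matrix in \eqn{[0, 1]}.
#' @export
normalizeSpectrogram <- function(sdb, cfg) {
  if (cfg@normalizationMode == "minmax") {
    lo <- min(sdb); hi <- max(sdb)
    if (hi - lo <= 0) return(array(0, dim(sdb)))
    (sdb - lo) / (hi - lo)
  } else {
    pmin(pmax((sdb - cfg@minDB) / (cfg@refDB - cfg@minDB), 0), 1)
  }
}

#' Fit a spectrogram to the network sequence length
#'
#' Zero-pads short clips and crops long ones to exactly `networkFrames(cfg)`
#' columns. Training uses `mode = "random"` (uniform random placement);
#' validation and test use `mode = "center"`.
#'
#' @param m matrix (rows = frequency bins).
#' @param cfg a [PreprocessingConfig-class].
#' @param mode "random" or "center".
#' @return a [NormalizedClip-class].
#' @export
fitToLength <- function(m, cfg, mode = c("center", "random")) {
  mode <- match.arg(mode)
  Tnet <- networkFrames(cfg)
  Tin <- ncol(m)
  if (Tin < Tnet) {
    left <- if (mode == "center") (Tnet - Tin) %/% 2L else
      sample.int(Tnet - Tin + 1L, 1L) - 1L
    out <- matrix(0, nrow(m), Tnet)
    out[, (left + 1L):(left + Tin)] <- m
  } else if (Tin > Tnet) {
    off <- if (mode == "center") (Tin - Tnet) %/% 2L else
      sample.int(Tin - Tnet + 1L, 1L) - 1L
    out <- m[, (off + 1L):(off + Tnet), drop = FALSE]
  } else out <- m
  new("NormalizedClip", values = out, provenance = list(fit_mode = mode))
}

#' Run the full preprocessing pipeline on one clip
#'
#' Composes mono conversion/resampling, STFT, optional augmentation,
#' frequency compression, optional SNR-controlled noise mixing, dB
#' conversion, normalization, and length fitting. Augmentation and noise
#' mixing run only when `cfg@augment` is TRUE; evaluation-style calls
#' (augment = FALSE) are deterministic and centered.
#'
#' @param w a [Waveform-class].
#' @param cfg a [PreprocessingConfig-class].
#' @param noisePool optional list of frequency-compressed
#'   [PowerSpectrogram-class] noise templates (see [makeNoisePool()]).
#' @param mode length-fit mode; defaults to "random" when augmenting and
#'   "center" otherwise.
#' @return a [NormalizedClip-class] of shape `nFreqBins` x
#'   `networkFrames(cfg)`.
#' @export
preprocessClip <- function(w, cfg, noisePool = NULL,
                           mode = if (cfg@augment) "random" else "center") {
  prov <- list()
  x <- toMonoResample(w, cfg@targetSampleRate)
  if (length(x@samples) < cfg@fftWindowLength)  # pad very short clips
    x@samples <- c(x@samples,
                   numeric(cfg@fftWindowLength - length(x@samples)))
  s <- stftPower(x, cfg)
  if (cfg@augment) {
    s <- randomAugment(s, cfg)
    prov$augmentation <- attr(s, "augmentation")
  }
  s <- compressFrequency(s, cfg)
  if (cfg@augment && !is.null(noisePool) && length(noisePool)) {
    tmpl <- noisePool[[sample.int(length(noisePool), 1L)]]
    s <- addNoise(s, tmpl, cfg)
    prov$snr_db <- attr(s, "snr_db")
  }
  v <- normalizeSpectrogram(toDecibel(s), cfg)
  clip <- fitToLength(v, cfg, mode = mode)
  clip@provenance <- c(clip@provenance, prov)
  clip
}

#' Build a noise-template pool for augmentation
#'
#' Preprocesses noise waveforms up to the frequency-compression step so they
#' can be mixed into signal spectrograms by [addNoise()].
#'
#' @param waves list of [Waveform-class] noise clips.
#' @param cfg a [PreprocessingConfig-class].
#' @return list of compressed [PowerSpectrogram-class] templates.
#' @export
makeNoisePool <- function(waves, cfg) {
  lapply(waves, function(w) {
    x <- toMonoResample(w, cfg@targetSampleRate)
    if (length(x@samples) < cfg@fftWindowLength)
      x@samples <- c(x@samples,
                     numeric(cfg@fftWindowLength - length(x@samples)))
    compressFrequency(stftPower(x, cfg), cfg)
  })
}
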