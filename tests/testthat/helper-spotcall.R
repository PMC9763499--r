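# Shared fixtures: tiny configurations and in-code corpora so no binary
# files ship with the package.

# 32 x 16 network inputs; the 64-sample FFT keeps fewer in-band bins than
# output rows, so narrowband test tones survive the frequency compression
tinyPcfg <- function(augment = FALSE, sequenceLength = 0.256, ...) {
  preprocessingConfig(targetSampleRate = 4000, fftWindowLength = 64L,
                      fftHop = 64L, fMin = 200, fMax = 1800,
                      nFreqBins = 32L, sequenceLength = sequenceLength,
                      normalizationMode = "db", augment = augment, ...)
}

sineWave <- function(freq, dur = 1, sr = 4000, amp = 0.8) {
  waveform(amp * sin(2 * pi * freq * (seq_len(dur * sr) - 1) / sr), sr)
}

# spectrogram with prescribed row frequencies, random nonnegative values
randomSpec <- function(freqs, nT = 5L) {
  powerSpectrogram(matrix(runif(length(freqs) * nT), length(freqs)),
                   freq = freqs, time = (seq_len(nT) - 1) * 0.032)
}

# frame-score table with a single target class
frameTable <- function(starts, eps, probTarget) {
  data.frame(start = starts, end = starts + eps,
             prob.target = probTarget, prob.noise = 1 - probTarget,
             predicted_label = ifelse(probTarget > 0.5, "target", "noise"),
             stringsAsFactors = FALSE)
}

# synthetic clip corpus written to a temp dir, returned as records
makeTinyCorpus <- function(nClips = 6L, nRec = 3L, seed = 1L) {
  spec <- synthSpec(nClipsPerClass = nClips, nRecordings = nRec,
                    seed = seed)
  dir <- file.path(tempdir(), paste0("corpus-", seed, "-", nClips))
  if (!dir.exists(dir)) generateCorpus(spec, dir)
  scanCorpus(dir)
}

tinyNetSpec <- function(nClasses = 2L, classes = c("noise", "target")) {
  networkSpec(nClasses, inputShape = c(32L, 16L), classNames = classes)
}
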