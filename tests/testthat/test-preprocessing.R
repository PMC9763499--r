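test_that("mono conversion averages channels and preserves identity", {
  sr <- 44100
  x <- sin(2 * pi * 440 * (0:(sr - 1)) / sr)
  w <- waveform(x, sr)
  expect_equal(toMonoResample(w, sr)@samples, x)
  # antiphase stereo cancels exactly
  st <- waveform(cbind(x, -x), sr)
  expect_equal(toMonoResample(st, sr)@samples, numeric(sr))
  expect_error(toMonoResample(waveform(1, 10), 0))
})

test_that("resampling preserves the dominant tone frequency", {
  sr <- 44100
  w <- sineWave(1000, dur = 1, sr = sr)
  down <- toMonoResample(w, 22050)
  expect_equal(down@sampleRate, 22050)
  cfg <- preprocessingConfig(targetSampleRate = 22050,
                             fftWindowLength = 1024L, fftHop = 512L,
                             fMin = 10, fMax = 11000, sequenceLength = 1)
  s <- stftPower(down, cfg)
  peak <- s@freq[which.max(rowSums(s@values))]
  expect_lt(abs(peak - 1000), 22050 / 1024 + 1e-9)  # within one bin
})

test_that("STFT has analytic shape, peak bin and Parseval energy", {
  sr <- 16000
  w <- sineWave(1000, dur = 0.5, sr = sr)
  cfg <- preprocessingConfig(targetSampleRate = sr, fftWindowLength = 1024L,
                             fftHop = 256L, fMin = 10, fMax = 8000,
                             sequenceLength = 0.5)
  s <- stftPower(w, cfg)
  expect_equal(nrow(s@values), 1024L / 2L + 1L)
  expect_equal(ncol(s@values),
               floor((0.5 * sr - 1024) / 256) + 1)
  # peak at the bin nearest 1 kHz: bin index f*N/sr = 64 (0-based)
  expect_equal(which.max(rowSums(s@values)) - 1L, 64L)
  # Parseval: full two-sided power sum / N equals windowed frame energy
  win <- 0.5 * (1 - cos(2 * pi * (0:1023) / 1024))
  frame1 <- w@samples[1:1024] * win
  full <- Mod(stats::fft(frame1))^2
  expect_equal(sum(full) / 1024, sum(frame1^2))
  # one-sided power spectrum contains the same information at the peak
  expect_equal(s@values[, 1], full[1:513])
  # zero signal maps to zero spectrogram
  z <- stftPower(waveform(numeric(2048), sr), cfg)
  expect_true(all(z@values == 0))
  expect_error(stftPower(waveform(numeric(512), sr), cfg),
               "window longer")
})

test_that("augmentation identity, forced gain and time remap", {
  set.seed(42)
  s <- randomSpec(freqs = seq(0, 1900, length.out = 20), nT = 100L)
  idCfg <- tinyPcfg(intensityInterval = c(0, 0), pitchInterval = c(1, 1),
                    timeInterval = c(1, 1))
  expect_equal(randomAugment(s, idCfg)@values, s@values)
  g6 <- tinyPcfg(intensityInterval = c(6, 6), pitchInterval = c(1, 1),
                 timeInterval = c(1, 1))
  expect_equal(randomAugment(s, g6)@values, s@values * 10^0.6)
  # time factor 2: T doubles, output column j sources floor((j-1)/2)+1
  t2 <- tinyPcfg(intensityInterval = c(0, 0), pitchInterval = c(1, 1),
                 timeInterval = c(2, 2))
  a <- randomAugment(s, t2)
  expect_equal(ncol(a@values), 200L)
  srcCols <- floor((seq_len(200L) - 1L) / 2) + 1L
  expect_equal(a@values, s@values[, srcCols])
})

test_that("augmentation is deterministic under a fixed seed", {
  s <- randomSpec(freqs = seq(0, 1900, length.out = 30), nT = 40L)
  cfg <- tinyPcfg(augment = TRUE)
  set.seed(7)
  a1 <- randomAugment(s, cfg)
  set.seed(7)
  a2 <- randomAugment(s, cfg)
  expect_identical(a1@values, a2@values)
})

test_that("frequency compression matches a brute-force oracle", {
  # worked example: rows {0,100,200,300} Hz, 2 bins on [0,300] -> rows 1, 4
  s <- randomSpec(freqs = c(0, 100, 200, 300), nT = 3L)
  cfg <- preprocessingConfig(targetSampleRate = 4000, fMin = 0.001,
                             fMax = 300, nFreqBins = 2L,
                             sequenceLength = 0.5)
  cfg@fMin <- 0  # exercise a band starting at DC
  out <- compressFrequency(s, cfg)
  expect_equal(out@values, s@values[c(1, 4), ],
               ignore_attr = TRUE)
  # identity when rows already sit on the target grid
  grid <- seq(200, 1800, length.out = 32)
  s2 <- randomSpec(freqs = grid, nT = 4L)
  expect_equal(compressFrequency(s2, tinyPcfg())@values, s2@values)
  # out-of-band rows never contribute
  s3 <- randomSpec(freqs = c(500, 1000, 10000), nT = 2L)
  cfg3 <- preprocessingConfig(targetSampleRate = 40000, fMin = 400,
                              fMax = 2000, nFreqBins = 4L,
                              sequenceLength = 0.5)
  out3 <- compressFrequency(s3, cfg3)
  expect_false(any(out3@values %in% s3@values[3, ]))
  expect_error(compressFrequency(
    randomSpec(freqs = c(3000, 4000)), cfg3), "no spectrogram rows")

  # randomized oracle: nearest in-band row for every target
  set.seed(11)
  for (i in 1:100) {
    nf <- sample(5:30, 1)
    freqs <- sort(runif(nf, 0, 2000))
    freqs <- freqs[c(TRUE, diff(freqs) > 1e-6)]
    s <- randomSpec(freqs, nT = 2L)
    lo <- runif(1, 0, 900); hi <- runif(1, lo + 100, 2000)
    if (!any(freqs >= lo & freqs <= hi)) next
    nb <- sample(2:8, 1)
    cfg <- preprocessingConfig(targetSampleRate = 4000, fMin = lo,
                               fMax = hi, nFreqBins = nb,
                               sequenceLength = 0.5)
    out <- compressFrequency(s, cfg)
    targets <- seq(lo, hi, length.out = nb)
    inBand <- which(freqs >= lo & freqs <= hi)
    oracle <- vapply(targets, function(f)
      inBand[which.min(abs(freqs[inBand] - f))], 1L)
    expect_equal(out@values, s@values[oracle, , drop = FALSE],
                 ignore_attr = TRUE)
  }
})

test_that("noise mixing realizes the drawn SNR exactly", {
  set.seed(5)
  s <- randomSpec(seq(200, 1800, length.out = 32), nT = 20L)
  noise <- randomSpec(seq(200, 1800, length.out = 32), nT = 8L)
  # forced SNR 0 with equal mean powers: alpha = 1
  eq <- powerSpectrogram(matrix(mean(s@values), 32, 8),
                         freq = noise@freq, time = noise@time)
  cfg0 <- tinyPcfg(snrInterval = c(0, 0), pitchInterval = c(1, 1),
                   timeInterval = c(1, 1))
  out0 <- addNoise(s, eq, cfg0)
  expect_equal(attr(out0, "noise_scale"), 1)
  cfg10 <- tinyPcfg(snrInterval = c(10, 10), pitchInterval = c(1, 1),
                    timeInterval = c(1, 1))
  expect_equal(attr(addNoise(s, eq, cfg10), "noise_scale"), 0.1)
  # realized mean-power ratio reproduces the drawn SNR within 1e-9 dB
  cfg <- tinyPcfg(snrInterval = c(-5, 15))
  for (i in 1:20) {
    out <- addNoise(s, noise, cfg)
    added <- out@values - s@values
    realized <- 10 * log10(mean(s@values) / mean(added))
    expect_equal(realized, attr(out, "snr_db"), tolerance = 1e-9)
  }
  zero <- powerSpectrogram(matrix(0, 32, 4),
                           freq = noise@freq, time = noise@time[1:4])
  expect_error(addNoise(s, zero, cfg), "all-zero")
})

test_that("decibel conversion applies the log rule and floor", {
  expect_equal(toDecibel(matrix(1)), matrix(0))
  expect_equal(toDecibel(matrix(100)), matrix(20))
  expect_equal(toDecibel(matrix(0)), matrix(10 * log10(1e-10)))
})

test_that("normalization maps endpoints and clips", {
  cfg <- tinyPcfg()  # db mode, minDB -100, refDB 20
  m <- matrix(c(-10, 0, 10), 1)
  mm <- tinyPcfg(); mm@normalizationMode <- "minmax"
  expect_equal(normalizeSpectrogram(m, mm), matrix(c(0, 0.5, 1), 1))
  expect_equal(normalizeSpectrogram(matrix(c(-100, 20, -160), 1), cfg),
               matrix(c(0, 1, 0), 1))
  # constant matrix under minmax maps to zeros
  expect_equal(normalizeSpectrogram(matrix(5, 2, 2), mm),
               matrix(0, 2, 2))
})

test_that("length fitting pads and crops per the centering rules", {
  cfg <- tinyPcfg(sequenceLength = 128 * 64 / 4000)  # T_net = 128
  expect_equal(networkFrames(cfg), 128L)
  m <- matrix(runif(32 * 128), 32)
  expect_equal(fitToLength(m, cfg, "center")@values, m)
  short <- m[, 1:100]
  padded <- fitToLength(short, cfg, "center")@values
  expect_equal(dim(padded), c(32L, 128L))
  expect_true(all(padded[, 1:14] == 0) && all(padded[, 115:128] == 0))
  expect_equal(padded[, 15:114], short)
  long <- cbind(m, m[, 1:22])  # T = 150
  cropped <- fitToLength(long, cfg, "center")@values
  expect_equal(cropped, long[, 12:139])  # offset floor((150-128)/2) = 11
})

test_that("full pipeline yields the contracted shape, range, determinism", {
  set.seed(21)
  cfg <- tinyPcfg(augment = TRUE)
  w <- sineWave(1000, dur = 0.7)
  noisePool <- makeNoisePool(list(waveform(rnorm(4000) * 0.1, 4000)), cfg)
  for (i in 1:3) {
    clip <- preprocessClip(w, cfg, noisePool = noisePool)
    expect_equal(dim(clip@values), c(32L, 16L))
    expect_true(all(clip@values >= 0 & clip@values <= 1))
  }
  plain <- tinyPcfg()
  c1 <- preprocessClip(w, plain)
  c2 <- preprocessClip(w, plain)
  expect_identical(c1@values, c2@values)
  set.seed(9); a1 <- preprocessClip(w, cfg, noisePool = noisePool)
  set.seed(9); a2 <- preprocessClip(w, cfg, noisePool = noisePool)
  expect_identical(a1@values, a2@values)
})

test_that("a centered tone concentrates energy near the center row", {
  set.seed(3)
  cfg <- tinyPcfg()
  tone <- preprocessClip(sineWave(1000, 0.5), cfg)  # (200+1800)/2 = 1000 Hz
  noise <- preprocessClip(waveform(rnorm(2000) * 0.3, 4000), cfg)
  rowEnergy <- function(v) rowSums(v) / sum(v)
  centerBand <- 15:18
  expect_gt(sum(rowEnergy(tone@values)[centerBand]),
            2 * sum(rowEnergy(noise@values)[centerBand]))
})

test_that("config files round-trip", {
  cfg <- tinyPcfg(augment = TRUE, snrInterval = c(-2, 10))
  f <- tempfile(fileext = ".cfg")
  writeConfigFile(cfg, f)
  back <- readConfigFile(f)
  for (sl in slotNames(cfg)) expect_equal(slot(back, sl), slot(cfg, sl))
  writeLines("bogus_key=1", f)
  expect_error(readConfigFile(f), "unknown config key")
})
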