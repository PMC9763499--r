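# Flat key=value configuration files for the preprocessing parameters.
# Keys use the documented snake_case names; interval pairs are written as
# comma-separated "lo,hi".

.PCFG_KEYS <- c(
  target_sample_rate = "targetSampleRate",
  fft_window_length = "fftWindowLength", fft_hop = "fftHop",
  f_min = "fMin", f_max = "fMax", n_freq_bins = "nFreqBins",
  sequence_length = "sequenceLength",
  normalization_mode = "normalizationMode", min_db = "minDB",
  ref_db = "refDB", intensity_interval = "intensityInterval",
  pitch_interval = "pitchInterval", time_interval = "timeInterval",
  snr_interval = "snrInterval", augment = "augment")

#' Read / write a preprocessing configuration file
#'
#' Plain-text `key=value` files; keys are the snake_case parameter names
#' (`target_sample_rate`, `fft_window_length`, `fft_hop`, `f_min`, `f_max`,
#' `n_freq_bins`, `sequence_length`, `normalization_mode`, `min_db`,
#' `ref_db`, `intensity_interval`, `pitch_interval`, `time_interval`,
#' `snr_interval`, `augment`), intervals as `lo,hi` pairs. Lines starting
#' with `#` are comments.
#'
#' @param path configuration file path.
#' @param cfg a [PreprocessingConfig-class].
#' @return a [PreprocessingConfig-class] (read); `path` invisibly (write).
#' @export
readConfigFile <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) < 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  unknown <- setdiff(keys, names(.PCFG_KEYS))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  args <- list()
  for (i in seq_along(keys)) {
    slot <- .PCFG_KEYS[[keys[i]]]
    v <- vals[i]
    args[[slot]] <- switch(slot,
      normalizationMode = v,
      augment = as.logical(v),
      fftWindowLength = , fftHop = , nFreqBins = as.integer(v),
      intensityInterval = , pitchInterval = , timeInterval = ,
      snrInterval = as.numeric(strsplit(v, ",")[[1]]),
      as.numeric(v))
  }
  do.call(preprocessingConfig, args)
}

#' @rdname readConfigFile
#' @export
writeConfigFile <- function(cfg, path) {
  fmt <- function(slotName) {
    v <- slot(cfg, slotName)
    if (is.logical(v)) as.character(v)
    else paste(format(v, scientific = FALSE, trim = TRUE), collapse = ",")
  }
  lines <- vapply(names(.PCFG_KEYS), function(k)
    paste0(k, "=", fmt(.PCFG_KEYS[[k]])), "")
  writeLines(lines, path)
  invisible(path)
}
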