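# Corpus parsing and recording-exclusive splitting. A corpus is a directory
# of WAV clips named LABEL_ID_RECORDING_STARTms_ENDms.wav (the label may not
# contain underscores); an optional class subdirectory overrides the label.

CLIP_NAME_RE <- "^([^_]+)_([^_]+)_([^_]+)_([0-9]+)_([0-9]+)\\.(wav|WAV)$"

#' Parse a clip filename into a clip record
#'
#' Filenames follow `LABEL_ID_RECORDING_STARTms_ENDms.wav`, underscore
#' separated, with the label free of underscores and times in integer
#' milliseconds.
#'
#' @param name filename (a path is allowed; only the basename is parsed).
#' @return one-row data.frame with columns `path`, `label`, `recording_id`,
#'   `start_ms`, `end_ms`.
#' @examples
#' parseClipFilename("alarm_0001_tapeA_5000_6500.wav")
#' @export
parseClipFilename <- function(name) {
  base <- basename(name)
  m <- regmatches(base, regexec(CLIP_NAME_RE, base))[[1]]
  if (length(m) == 0L)
    stop("filename does not match LABEL_ID_RECORDING_STARTms_ENDms.wav: ",
         base)
  start <- as.integer(m[5]); end <- as.integer(m[6])
  if (start >= end)
    stop("start_ms must be < end_ms in filename: ", base)
  data.frame(path = name, label = m[2], recording_id = m[4],
             start_ms = start, end_ms = end, stringsAsFactors = FALSE)
}

#' Scan a corpus directory into a clip table
#'
#' Walks `dir` (recursively) for WAV files named per the clip grammar. When
#' a clip sits in a class subdirectory, the subdirectory name overrides the
#' filename label.
#'
#' @param dir corpus directory.
#' @return data.frame of clip records.
#' @export
scanCorpus <- function(dir) {
  files <- list.files(dir, pattern = "\\.(wav|WAV)$", recursive = TRUE,
                      full.names = TRUE)
  if (length(files) == 0L) stop("no WAV files under ", dir)
  recs <- do.call(rbind, lapply(files, parseClipFilename))
  sub <- dirname(substring(files, nchar(dir) + 2L))
  override <- sub != "."
  recs$label[override] <- basename(sub[override])
  recs
}

#' Recording-exclusive train/validation/test split
#'
#' Splits labeled clips so that all clips of one recording land in the same
#' partition. Per class, recordings are shuffled (seeded) and assigned
#' greedily to the partition whose clip deficit relative to its target
#' fraction is largest (ties resolved train > validation > test); a
#' recording already assigned while processing an earlier class keeps its
#' partition.
#'
#' @param records data.frame of clip records (needs `label` and
#'   `recording_id`; see [scanCorpus()]).
#' @param fractions target proportions for train/validation/test.
#' @param seed RNG seed for the per-class shuffles.
#' @return a [DatasetSplit-class].
#' @export
splitByRecording <- function(records, fractions = c(0.70, 0.15, 0.15),
                             seed = 1L) {
  if (is.null(records) || nrow(records) == 0L) stop("empty clip table")
  stopifnot(length(fractions) == 3L, all(fractions >= 0),
            abs(sum(fractions) - 1) < 1e-8)
  recIds <- unique(records$recording_id)
  if (length(recIds) < 3L)
    stop("recording-exclusive splitting needs at least 3 recordings, got ",
         length(recIds))
  set.seed(seed)
  assignment <- setNames(rep(NA_character_, length(recIds)), recIds)
  parts <- c("train", "validation", "test")
  for (cls in sort(unique(records$label))) {
    clsRecs <- records[records$label == cls, , drop = FALSE]
    perRec <- table(clsRecs$recording_id)
    total <- nrow(clsRecs)
    assigned <- setNames(numeric(3L), parts)
    order <- sample(names(perRec))
    for (rid in order) {
      cur <- assignment[[rid]]
      if (is.na(cur)) {
        # deficit relative to the target fraction; ties resolve
        # train > validation > test
        deficit <- ifelse(fractions > 0,
                          (fractions * total - assigned) / fractions, -Inf)
        cur <- parts[which.max(deficit)]
        assignment[[rid]] <- cur
      }
      assigned[[cur]] <- assigned[[cur]] + perRec[[rid]]
    }
  }
  pick <- function(p) {
    out <- records[assignment[records$recording_id] == p, , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  new("DatasetSplit", train = pick("train"), validation = pick("validation"),
      test = pick("test"), fractions = fractions)
}

#' Write split manifests
#'
#' Writes `train.csv`, `val.csv` and `test.csv` (columns path, label,
#' recording_id) into `dir`.
#'
#' @param split a [DatasetSplit-class].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeSplitManifests <- function(split, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sets <- list(train = split@train, val = split@validation,
               test = split@test)
  for (nm in names(sets)) {
    write.table(sets[[nm]][, c("path", "label", "recording_id")],
                file.path(dir, paste0(nm, ".csv")), sep = ",",
                row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}
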