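#' @include AllClasses.R
NULL

channelFileName <- function(channel) paste0(tolower(channel), ".txt")

#' Write a recording to a directory of delimited channel files
#'
#' One single-column text file per channel with a header line of the form
#' `# channel=ECG fs=1000 units=mV`, plus a `recording.json` metadata sidecar
#' holding subject id, condition and the channel file names.
#'
#' @param recording named list of [SignalRecord-class] objects (as returned
#'   by [simulateRecording()]; an `rr` element, if present, is ignored).
#' @param dir output directory (created if missing).
#' @return Invisibly, the directory path.
#' @seealso [readRecording()]
#' @export
writeRecording <- function(recording, dir) {
  recs <- Filter(function(x) methods::is(x, "SignalRecord"), recording)
  if (length(recs) == 0L) stop("no SignalRecord elements to write")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  channels <- list()
  for (rec in recs) {
    f <- channelFileName(rec@channel)
    con <- file(file.path(dir, f), "w")
    writeLines(sprintf("# channel=%s fs=%g units=%s", rec@channel, rec@fs,
                       rec@units), con)
    writeLines(sprintf("%.10g", rec@samples), con)
    close(con)
    channels[[rec@channel]] <- f
  }
  meta <- list(subject_id = recs[[1]]@subjectId,
               condition = recs[[1]]@condition,
               channels = channels)
  jsonlite::write_json(meta, file.path(dir, "recording.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

parseChannelHeader <- function(line) {
  if (!startsWith(line, "#")) stop("channel file must start with a '# channel=... fs=... units=...' header")
  kv <- regmatches(line, gregexpr("[A-Za-z]+=[^ ]+", line))[[1]]
  out <- list()
  for (pair in kv) {
    p <- strsplit(pair, "=", fixed = TRUE)[[1]]
    out[[p[1]]] <- p[2]
  }
  if (is.null(out$channel) || is.null(out$fs))
    stop("channel header must define channel= and fs=")
  out
}

#' Read a recording written by [writeRecording()]
#'
#' @param dir directory containing `recording.json` and the channel files.
#' @return Named list of [SignalRecord-class] objects (lower-case channel
#'   names, e.g. `ecg`, `skt`, `eda`).
#' @export
readRecording <- function(dir) {
  metaPath <- file.path(dir, "recording.json")
  if (!file.exists(metaPath)) stop("no recording.json in ", dir)
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  out <- list()
  for (ch in names(meta$channels)) {
    path <- file.path(dir, meta$channels[[ch]])
    hdr <- parseChannelHeader(readLines(path, n = 1L))
    x <- scan(path, skip = 1L, quiet = TRUE)
    out[[tolower(ch)]] <- new("SignalRecord",
      channel = hdr$channel, fs = as.numeric(hdr$fs), samples = x,
      units = if (is.null(hdr$units)) "" else hdr$units,
      subjectId = meta$subject_id, condition = meta$condition)
  }
  out
}

#' Write / read a feature matrix as CSV
#'
#' The CSV has the 16 feature columns plus `subject_id`, `condition` and
#' `window_index`; normalization bounds, when present, travel in a sibling
#' `<file>.bounds.csv` so a normalized matrix round-trips losslessly.
#'
#' @param fm a [FeatureMatrix-class].
#' @param file path of the CSV to write or read.
#' @return `writeFeatureCSV` returns the path invisibly; `readFeatureCSV`
#'   returns a [FeatureMatrix-class].
#' @export
writeFeatureCSV <- function(fm, file) {
  stopifnot(methods::is(fm, "FeatureMatrix"))
  df <- cbind(as.data.frame(fm@values), fm@windowInfo)
  utils::write.csv(df, file, row.names = FALSE)
  if (nrow(fm@normBounds) == 2L) {
    bdf <- as.data.frame(fm@normBounds)
    bdf <- cbind(bound = rownames(fm@normBounds), bdf)
    utils::write.csv(bdf, paste0(file, ".bounds.csv"), row.names = FALSE)
  }
  invisible(file)
}

#' @rdname writeFeatureCSV
#' @export
readFeatureCSV <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE)
  metaCols <- c("subject_id", "condition", "window_index")
  if (!all(metaCols %in% names(df)))
    stop("feature CSV must have subject_id, condition, window_index columns")
  vals <- as.matrix(df[, setdiff(names(df), metaCols), drop = FALSE])
  bounds <- matrix(numeric(0), 0, 0)
  bfile <- paste0(file, ".bounds.csv")
  if (file.exists(bfile)) {
    bdf <- utils::read.csv(bfile, check.names = FALSE)
    bounds <- as.matrix(bdf[, setdiff(names(bdf), "bound"), drop = FALSE])
    rownames(bounds) <- bdf$bound
  }
  new("FeatureMatrix", values = vals,
      windowInfo = df[, metaCols],
      normBounds = bounds)
}
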