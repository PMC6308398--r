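#' @include utils.R wavelet.R preprocess.R
NULL

#' The 16 feature names, grouped by source signal
#'
#' Nine heart-rate-variability features from the ECG, two skin-temperature
#' features and five electrodermal features.
#' @return Character vector of length 16.
#' @export
featureNames <- function() {
  c("MeanHRV", "SDNN", "RMSSD", "NN50", "pNN50",  # HRV time domain
    "LF_HF", "TP", "nHF", "nLF",                   # HRV frequency domain
    "MeanSKT", "SDSKT",                            # skin temperature
    "ZC_EDAP", "SD_EDAP", "Mean_EDAT", "SD_EDAT", "Amp_EDAT")  # EDA
}

#' Sliding-window specification
#'
#' Five-minute windows slid by 30 s; the final `selectionCount` windows of a
#' recording are retained as representative of the induced emotion (the
#' assumption being that the emotion is not yet induced at the start of the
#' stimulus).
#'
#' @param lengthS window length in seconds (default 300).
#' @param stepS slide step in seconds (default 30).
#' @param selectionCount number of windows kept, taken from the end of the
#'   recording (default 100).
#' @return A validated list.
#' @export
windowSpec <- function(lengthS = 300, stepS = 30, selectionCount = 100) {
  assertScalar(lengthS, "lengthS"); assertScalar(stepS, "stepS")
  assertScalar(selectionCount, "selectionCount")
  if (stepS > lengthS) stop("stepS must not exceed lengthS")
  list(lengthS = lengthS, stepS = stepS,
       selectionCount = as.integer(selectionCount))
}

#' Generate window time ranges over a recording
#'
#' Windows start at 0, stepS, 2 stepS, ...; the last window ends at or
#' before the recording duration. The final `selectionCount` windows are
#' then retained.
#'
#' @param durationS recording duration in seconds.
#' @param spec a [windowSpec()].
#' @param select if `TRUE` (default) keep only the last `selectionCount`
#'   windows; `FALSE` returns all windows.
#' @return data.frame with columns `start`, `end` (seconds) and
#'   `window_index` (index within the full, unselected sequence).
#' @export
slideWindows <- function(durationS, spec = windowSpec(), select = TRUE) {
  if (durationS < spec$lengthS)
    stop("recording shorter than one window")
  starts <- seq(0, durationS - spec$lengthS, by = spec$stepS)
  out <- data.frame(start = starts, end = starts + spec$lengthS,
                    window_index = seq_along(starts))
  if (select) {
    if (spec$selectionCount > nrow(out))
      stop(sprintf("selectionCount (%d) exceeds available windows (%d)",
                   spec$selectionCount, nrow(out)))
    out <- utils::tail(out, spec$selectionCount)
    rownames(out) <- NULL
  }
  out
}

#' Time-domain HRV features
#'
#' Over the usable RR intervals of a window: mean interval (MeanHRV),
#' sample standard deviation (SDNN), root-mean-square of successive
#' differences (RMSSD, N-1 successive differences), the number of successive
#' differences exceeding 50 ms in magnitude (NN50), and pNN50 = NN50 / N x
#' 100 (N = number of intervals).
#'
#' @param rr an [RRSeries-class] or a numeric vector of RR intervals in ms.
#' @return Named numeric vector: MeanHRV, SDNN, RMSSD, NN50, pNN50.
#' @examples
#' hrvTimeFeatures(c(800, 810, 790, 805, 795))
#' @export
hrvTimeFeatures <- function(rr) {
  v <- if (methods::is(rr, "RRSeries")) rrIntervals(rr) else as.numeric(rr)
  n <- length(v)
  if (n < 2L) stop("need at least 2 usable RR intervals")
  meanHRV <- mean(v)
  sdnn <- sqrt(sum((v - meanHRV)^2) / (n - 1))
  dv <- diff(v)
  rmssd <- sqrt(sum(dv^2) / (n - 1))
  nn50 <- sum(abs(dv) > 50)
  c(MeanHRV = meanHRV, SDNN = sdnn, RMSSD = rmssd, NN50 = nn50,
    pNN50 = nn50 / n * 100)
}

#' Frequency-domain HRV features
#'
#' The RR tachogram (interval vs. midpoint time) is cubic-spline resampled
#' at 4 Hz, its power spectral density estimated by Welch averaging
#' (256-sample Hann segments, 50% overlap), and band powers integrated
#' trapezoidally: total power TP over 0.003-0.4 Hz, LF over 0.04-0.15 Hz, HF
#' over 0.15-0.4 Hz. Normalized powers are nLF = LF / (LF + HF) and
#' nHF = HF / (LF + HF), so nLF + nHF = 1 identically.
#'
#' @param rr an [RRSeries-class] whose `times` cover the analysis window.
#' @param resampleFs tachogram resampling rate (Hz).
#' @return Named numeric vector: LF_HF, TP (ms^2), nHF, nLF.
#' @export
hrvFreqFeatures <- function(rr, resampleFs = 4) {
  stopifnot(methods::is(rr, "RRSeries"))
  ok <- rr@usable
  if (sum(ok) < 2L) stop("need at least 2 usable RR intervals")
  tach <- resampleUniform(rr@times[ok], rr@intervals[ok], resampleFs)
  w <- welchPsd(tach$v, resampleFs)
  tp <- bandPower(w$freq, w$psd, 0.003, 0.4)
  lf <- bandPower(w$freq, w$psd, 0.04, 0.15)
  hf <- bandPower(w$freq, w$psd, 0.15, 0.4)
  if (hf <= 0) stop("zero HF power: LF/HF undefined for this window")
  c(LF_HF = lf / hf, TP = tp, nHF = hf / (lf + hf), nLF = lf / (lf + hf))
}

#' Skin-temperature features
#'
#' @param x numeric vector of SKT samples within a window.
#' @return Named numeric vector: MeanSKT, SDSKT (sample SD).
#' @export
sktFeatures <- function(x) {
  if (length(x) == 0L) stop("empty SKT window")
  c(MeanSKT = mean(x), SDSKT = sampleSD(x))
}

#' Split an EDA window into tonic and phasic components
#'
#' The window is cubic-spline resampled to 32 Hz, decomposed with a db3
#' discrete wavelet transform to level 10, and the tonic component (skin
#' conductance level) is reconstructed from the level-10 approximation band
#' alone (0 to 32 / 2^11 = 0.015625 Hz). The phasic component (skin
#' conductance responses) is the resampled signal minus the tonic, so
#' tonic + phasic reconstructs the working signal exactly by construction.
#'
#' @param x numeric EDA samples of one window.
#' @param fs sampling rate of `x` in Hz.
#' @param level decomposition depth (default 10).
#' @param workFs working rate the signal is resampled to before the
#'   transform (default 32 Hz, which makes the approximation band match the
#'   stated 0-0.015625 Hz tonic bandwidth).
#' @return List with `tonic`, `phasic` (numeric, at `workFs`) and `fs`.
#' @export
edaDecompose <- function(x, fs, level = 10L, workFs = 32) {
  if (length(x) < 2L) stop("EDA window too short")
  t <- (seq_along(x) - 1L) / fs
  v <- if (abs(fs - workFs) < 1e-9) x else resampleUniform(t, x, workFs)$v
  if (length(v) < 2L^level)
    stop(sprintf("window too short for a level-%d decomposition (need >= %d samples at %g Hz)",
                 level, 2L^level, workFs))
  dec <- db3Wavedec(v, level)
  tonic <- db3Waverec(dec, zeroDetails = TRUE)
  list(tonic = tonic, phasic = v - tonic, fs = workFs)
}

# Strict sign changes. Zero samples attach to the previous sign (and leading
# zeros carry no sign), so a transition can only occur between consecutive
# nonzero signs.
countSignChanges <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(diff(s) != 0)
}

#' Electrodermal features from the tonic/phasic split
#'
#' Zero crossings (strict sign changes) and sample SD of the phasic
#' component; mean, sample SD, and amplitude (max minus min) of the tonic
#' component.
#'
#' @param tonic,phasic numeric components from [edaDecompose()], or a single
#'   list argument `tonic` with elements `tonic` and `phasic`.
#' @return Named numeric vector: ZC_EDAP, SD_EDAP, Mean_EDAT, SD_EDAT,
#'   Amp_EDAT.
#' @export
edaFeatures <- function(tonic, phasic = NULL) {
  if (is.list(tonic) && is.null(phasic)) {
    phasic <- tonic$phasic; tonic <- tonic$tonic
  }
  if (length(tonic) == 0L || length(tonic) != length(phasic))
    stop("tonic and phasic must be non-empty and equal length")
  c(ZC_EDAP = as.numeric(countSignChanges(phasic)),
    SD_EDAP = sampleSD(phasic),
    Mean_EDAT = mean(tonic),
    SD_EDAT = sampleSD(tonic),
    Amp_EDAT = max(tonic) - min(tonic))
}

windowFeatureRow <- function(rr, skt50, eda50, start, end) {
  inWin <- rr@times >= start & rr@times < end
  rrWin <- new("RRSeries", intervals = rr@intervals[inWin],
               times = rr@times[inWin], usable = rr@usable[inWin])
  if (sum(rrWin@usable) < 2L) stop("too few usable RR intervals in window")
  ht <- hrvTimeFeatures(rrWin)
  hf <- hrvFreqFeatures(rrWin)
  fs <- skt50@fs
  i0 <- floor(start * fs) + 1L
  i1 <- min(length(skt50@samples), ceiling(end * fs))
  sk <- sktFeatures(skt50@samples[i0:i1])
  fsE <- eda50@fs
  j0 <- floor(start * fsE) + 1L
  j1 <- min(length(eda50@samples), ceiling(end * fsE))
  ed <- edaFeatures(edaDecompose(eda50@samples[j0:j1], fsE))
  c(ht, hf, sk, ed)[featureNames()]
}

#' Build the per-subject feature matrix from a pair of recordings
#'
#' Runs the full conditioning chain on each condition's recording (QRS
#' detection and RR series for the ECG; downsampling to 50 Hz plus 1-Hz
#' low-pass for SKT and EDA), slides the windows, and computes the 16
#' features per retained window. Windows whose spectral features are
#' undefined (zero HF power) or that contain too few usable beats are
#' dropped with a warning.
#'
#' @param recordings named list with elements `basic` and `negative`, each a
#'   list with `ecg`, `skt`, `eda` [SignalRecord-class] objects (the shape
#'   returned by [simulateRecording()]).
#' @param spec a [windowSpec()].
#' @return A raw (unnormalized) [FeatureMatrix-class]; labels are implied by
#'   the `condition` column of `windowInfo()` (basic = 0, negative = 1).
#' @export
buildFeatureMatrix <- function(recordings, spec = windowSpec()) {
  if (!all(CONDITIONS %in% names(recordings)))
    stop("recordings must have both 'basic' and 'negative' conditions")
  rows <- list(); info <- list()
  for (cond in CONDITIONS) {
    rec <- recordings[[cond]]
    for (ch in c("ecg", "skt", "eda"))
      if (!methods::is(rec[[ch]], "SignalRecord"))
        stop(sprintf("recordings$%s$%s must be a SignalRecord", cond, ch))
    rr <- rrFromPeaks(detectRPeaks(rec$ecg))
    skt50 <- downsampleLowpass(rec$skt, 50, 1)
    eda50 <- downsampleLowpass(rec$eda, 50, 1)
    durationS <- length(rec$ecg@samples) / rec$ecg@fs
    wins <- slideWindows(durationS, spec)
    for (k in seq_len(nrow(wins))) {
      row <- tryCatch(
        windowFeatureRow(rr, skt50, eda50, wins$start[k], wins$end[k]),
        error = function(e) {
          warning(sprintf("dropping %s window %d: %s", cond,
                          wins$window_index[k], conditionMessage(e)),
                  call. = FALSE)
          NULL
        })
      if (is.null(row)) next
      rows[[length(rows) + 1L]] <- row
      info[[length(info) + 1L]] <- data.frame(
        subject_id = rec$ecg@subjectId, condition = cond,
        window_index = wins$window_index[k])
    }
  }
  vals <- do.call(rbind, rows)
  colnames(vals) <- featureNames()
  new("FeatureMatrix", values = vals, windowInfo = do.call(rbind, info))
}

#' Min-max normalize a feature matrix to \[0, 1\]
#'
#' Per feature, over all rows of both conditions pooled (per subject):
#' x' = (x - min) / (max - min). The bounds are stored on the returned
#' object for inverse mapping. A constant feature cannot be scaled and is
#' set to 0.5 everywhere with a warning.
#'
#' @param fm a raw [FeatureMatrix-class].
#' @return A normalized [FeatureMatrix-class] with `normBounds` set.
#' @export
normalizeMinmax <- function(fm) {
  stopifnot(methods::is(fm, "FeatureMatrix"))
  v <- fm@values
  lo <- apply(v, 2, min); hi <- apply(v, 2, max)
  out <- v
  for (j in seq_len(ncol(v))) {
    if (hi[j] > lo[j]) {
      out[, j] <- (v[, j] - lo[j]) / (hi[j] - lo[j])
    } else {
      warning(sprintf("feature '%s' is constant; normalized value set to 0.5",
                      colnames(v)[j]), call. = FALSE)
      out[, j] <- 0.5
    }
  }
  bounds <- rbind(min = lo, max = hi)
  colnames(bounds) <- colnames(v)
  methods::initialize(fm, values = out, normBounds = bounds)
}

#' Numeric class labels of a feature matrix
#'
#' @param fm a [FeatureMatrix-class].
#' @return Integer vector, basic = 0, negative = 1.
#' @export
conditionLabels <- function(fm) {
  as.integer(windowInfo(fm)$condition == "negative")
}
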