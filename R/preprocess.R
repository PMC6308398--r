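#' @include utils.R AllClasses.R
NULL

#' Detect R peaks in an ECG channel
#'
#' Pan-Tompkins-style QRS detection: zero-phase band-pass (5-15 Hz),
#' differentiation, squaring, 150-ms moving-window integration, then an
#' adaptive signal/noise threshold on the integrated envelope. Accepted
#' detections are refined to the local maximum of the raw ECG and a 200-ms
#' refractory period is enforced (of two candidates closer than 200 ms the
#' larger raw peak wins).
#'
#' @param ecg a [SignalRecord-class] with `channel = "ECG"`.
#' @param refractoryS refractory period in seconds (default 0.2).
#' @return An [RPeakSeries-class] with peak times in seconds.
#' @export
detectRPeaks <- function(ecg, refractoryS = 0.2) {
  stopifnot(methods::is(ecg, "SignalRecord"))
  if (ecg@channel != "ECG") stop("detectRPeaks expects an ECG channel")
  fs <- ecg@fs
  if (fs < 100) stop("sampling rate must be >= 100 Hz for QRS detection")
  x <- ecg@samples
  if (length(x) < fs) stop("ECG too short for QRS detection")
  if (stats::sd(x) == 0) stop("no QRS detected: flat signal")

  bp <- zeroPhaseFilter(x, signal::butter(2, c(5, 15) / (fs / 2), type = "pass"))
  d <- c(0, diff(bp)) * fs
  sq <- d^2
  w <- max(1L, round(0.150 * fs))
  integ <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  integ[is.na(integ)] <- 0

  # local maxima of the envelope, at least `refractoryS` apart
  n <- length(integ)
  isMax <- c(FALSE, integ[2:(n - 1)] >= integ[1:(n - 2)] &
                    integ[2:(n - 1)] > integ[3:n], FALSE)
  cand <- which(isMax)
  if (length(cand) == 0L) stop("no QRS detected")
  # collapse maxima closer than the refractory period (keep the larger)
  cand <- cand[order(cand)]
  minGap <- round(refractoryS * fs)
  keep <- integer(0)
  for (i in cand) {
    if (length(keep) && i - keep[length(keep)] < minGap) {
      if (integ[i] > integ[keep[length(keep)]]) keep[length(keep)] <- i
    } else keep <- c(keep, i)
  }
  cand <- keep

  # adaptive signal/noise levels (Pan-Tompkins running estimates)
  spk <- max(integ[seq_len(min(n, 2 * fs))])
  npk <- mean(integ[seq_len(min(n, 2 * fs))]) / 2
  accepted <- integer(0)
  for (i in cand) {
    thr <- npk + 0.25 * (spk - npk)
    if (integ[i] >= thr) {
      spk <- 0.125 * integ[i] + 0.875 * spk
      accepted <- c(accepted, i)
    } else {
      npk <- 0.125 * integ[i] + 0.875 * npk
    }
  }
  if (length(accepted) == 0L) stop("no QRS detected")

  # refine to the raw R-wave maximum near each envelope peak
  half <- round(0.10 * fs)
  peaks <- vapply(accepted, function(i) {
    lo <- max(1L, i - half); hi <- min(length(x), i + half)
    as.integer(lo + which.max(x[lo:hi]) - 1L)
  }, integer(1))
  peaks <- sort(unique(peaks))
  # refractory on refined peaks, larger raw amplitude wins (tie: earlier)
  keep <- integer(0)
  for (i in peaks) {
    if (length(keep) && i - keep[length(keep)] < minGap) {
      if (x[i] > x[keep[length(keep)]]) keep[length(keep)] <- i
    } else keep <- c(keep, i)
  }
  new("RPeakSeries", peakTimes = keep / fs, fs = fs)
}

#' Build the RR-interval series from detected R peaks
#'
#' RR_i = (t_{i+1} - t_i) * 1000 ms, stamped at the midpoint of the two
#' peaks. Intervals outside the physiologic band (300, 2000) ms are flagged
#' unusable (artifact rejection) but retained for bookkeeping.
#'
#' @param peaks an [RPeakSeries-class].
#' @return An [RRSeries-class].
#' @export
rrFromPeaks <- function(peaks) {
  stopifnot(methods::is(peaks, "RPeakSeries"))
  t <- peaks@peakTimes
  if (length(t) < 2L) stop("need at least 2 peaks to form RR intervals")
  rr <- diff(t) * 1000
  mid <- (t[-1] + t[-length(t)]) / 2
  ok <- rr > 0 & rr < 5000
  if (!all(ok)) {  # beyond any physiology; drop outright
    rr <- rr[ok]; mid <- mid[ok]
  }
  new("RRSeries", intervals = rr, times = mid,
      usable = rr > 300 & rr < 2000)
}

#' Downsample and low-pass filter a slow channel (SKT / EDA)
#'
#' Anti-alias filters (zero-phase Butterworth at 80% of the target Nyquist),
#' decimates to `targetFs`, then applies the noise-removal low-pass
#' (2nd-order Butterworth at `cutoffHz`, forward-backward so the result is
#' zero-phase).
#'
#' @param record a [SignalRecord-class].
#' @param targetFs target sampling rate in Hz (must divide `fs`).
#' @param cutoffHz low-pass cutoff in Hz (must be below `targetFs / 2`).
#' @return A [SignalRecord-class] at `targetFs`.
#' @export
downsampleLowpass <- function(record, targetFs = 50, cutoffHz = 1) {
  stopifnot(methods::is(record, "SignalRecord"))
  fs <- record@fs
  if (targetFs >= fs) stop("targetFs must be below the source rate")
  if (cutoffHz >= targetFs / 2) stop("cutoff must be below the target Nyquist frequency")
  fac <- fs / targetFs
  if (abs(fac - round(fac)) > 1e-9) stop("fs must be an integer multiple of targetFs")
  fac <- as.integer(round(fac))
  x <- record@samples
  aa <- signal::butter(4, 0.8 * (targetFs / 2) / (fs / 2), type = "low")
  x <- zeroPhaseFilter(x, aa)
  x <- x[seq.int(1L, length(x), by = fac)]
  lp <- signal::butter(2, cutoffHz / (targetFs / 2), type = "low")
  x <- zeroPhaseFilter(x, lp)
  methods::initialize(record, fs = targetFs, samples = x)
}
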