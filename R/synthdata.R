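#' @include utils.R AllClasses.R
NULL

#' Simulation parameters for two-condition synthetic recordings
#'
#' Builds the parameter set for [simulateRecording()]. Each per-condition
#' argument is a named numeric vector with elements `basic` and `negative`.
#' The default effect directions follow the expected autonomic response to
#' negative emotion: heart rate up (shorter RR), skin conductance responses
#' more frequent and tonic level higher, skin temperature lower. The default
#' magnitudes are deliberate, clearly separable choices (no quantitative
#' effect sizes exist to emulate) and are documented in the methods vignette.
#'
#' @param durationS recording length in seconds (default 3600, one hour).
#' @param ecgFs,sktFs,edaFs channel sampling rates in Hz (default 1000).
#' @param rrMeanMs mean RR interval (ms) per condition.
#' @param rrSdMs RR standard deviation (ms) per condition; 0 gives a
#'   metronomic heart.
#' @param scrRatePerMin skin-conductance-response event rate (events/min).
#' @param scrAmplitudeUS SCR event amplitude (microsiemens).
#' @param tonicLevelUS tonic skin-conductance level (microsiemens).
#' @param tonicDriftUSPerMin linear tonic drift (microsiemens/min).
#' @param sktBaseC baseline skin temperature (degrees C).
#' @param sktDriftCPerMin linear skin-temperature drift (degrees C/min).
#' @param noiseSd named numeric vector of additive Gaussian noise SDs for
#'   `ECG` (mV), `SKT` (degC) and `EDA` (uS).
#' @param seed default integer seed for [simulateRecording()].
#' @return A validated named list of parameters.
#' @examples
#' p <- simParams(durationS = 600)
#' rr <- simulateRRSeries(p, "negative", seed = 1)
#' mean(rr)
#' @export
simParams <- function(durationS = 3600,
                      ecgFs = 1000, sktFs = 1000, edaFs = 1000,
                      rrMeanMs = c(basic = 850, negative = 750),
                      rrSdMs = c(basic = 50, negative = 40),
                      scrRatePerMin = c(basic = 2, negative = 6),
                      scrAmplitudeUS = c(basic = 0.3, negative = 0.6),
                      tonicLevelUS = c(basic = 4, negative = 8),
                      tonicDriftUSPerMin = c(basic = 0.005, negative = 0.02),
                      sktBaseC = c(basic = 33.5, negative = 33.0),
                      sktDriftCPerMin = c(basic = 0, negative = -0.01),
                      noiseSd = c(ECG = 0.02, SKT = 0.01, EDA = 0.01),
                      seed = 1L) {
  p <- list(durationS = durationS, ecgFs = ecgFs, sktFs = sktFs, edaFs = edaFs,
            rrMeanMs = rrMeanMs, rrSdMs = rrSdMs,
            scrRatePerMin = scrRatePerMin, scrAmplitudeUS = scrAmplitudeUS,
            tonicLevelUS = tonicLevelUS, tonicDriftUSPerMin = tonicDriftUSPerMin,
            sktBaseC = sktBaseC, sktDriftCPerMin = sktDriftCPerMin,
            noiseSd = noiseSd, seed = as.integer(seed))
  validateSimParams(p)
  p
}

validateSimParams <- function(p) {
  assertScalar(p$durationS, "durationS")
  for (f in c("ecgFs", "sktFs", "edaFs")) assertScalar(p[[f]], f)
  perCond <- c("rrMeanMs", "rrSdMs", "scrRatePerMin", "scrAmplitudeUS",
               "tonicLevelUS", "tonicDriftUSPerMin", "sktBaseC",
               "sktDriftCPerMin")
  for (f in perCond) {
    v <- p[[f]]
    if (!all(CONDITIONS %in% names(v)))
      stop(sprintf("'%s' must be named with basic and negative", f), call. = FALSE)
  }
  if (any(p$rrMeanMs < 300 | p$rrMeanMs > 2000))
    stop("rrMeanMs must lie in [300, 2000] ms", call. = FALSE)
  if (any(p$rrSdMs < 0)) stop("rrSdMs must be non-negative", call. = FALSE)
  if (any(p$scrRatePerMin < 0)) stop("scrRatePerMin must be non-negative", call. = FALSE)
  if (any(p$scrAmplitudeUS < 0)) stop("scrAmplitudeUS must be non-negative", call. = FALSE)
  if (any(p$tonicLevelUS < 0)) stop("tonic level must be non-negative", call. = FALSE)
  if (any(p$sktBaseC <= 0)) stop("sktBaseC must be positive", call. = FALSE)
  if (!all(CHANNEL_KINDS %in% names(p$noiseSd)) || any(p$noiseSd < 0))
    stop("noiseSd must be named ECG/SKT/EDA and non-negative", call. = FALSE)
  invisible(TRUE)
}

condParam <- function(p, field, condition) unname(p[[field]][condition])

#' Simulate an RR-interval series
#'
#' Draws i.i.d. normal RR intervals with the condition's mean and SD,
#' truncated (by rejection) to the physiologic band \[300, 2000\] ms, until
#' their cumulative sum covers the recording duration.
#'
#' @param params a [simParams()] list.
#' @param condition `"basic"` or `"negative"`.
#' @param seed integer seed (defaults to `params$seed`).
#' @return Numeric vector of RR intervals in ms.
#' @export
simulateRRSeries <- function(params, condition = "basic", seed = params$seed) {
  validateSimParams(params)
  condition <- match.arg(condition, CONDITIONS)
  m <- condParam(params, "rrMeanMs", condition)
  s <- condParam(params, "rrSdMs", condition)
  durMs <- params$durationS * 1000
  withSeed(seed, {
    rr <- numeric(0)
    total <- 0
    while (total < durMs) {
      nDraw <- max(16L, ceiling((durMs - total) / m * 1.2))
      draw <- stats::rnorm(nDraw, m, s)
      bad <- draw < 300 | draw > 2000
      while (any(bad)) {  # truncation by rejection
        draw[bad] <- stats::rnorm(sum(bad), m, s)
        bad <- draw < 300 | draw > 2000
      }
      rr <- c(rr, draw)
      total <- total + sum(draw)
    }
    cs <- cumsum(rr)
    rr[cs <= durMs]
  })
}

# Gaussian R-wave template with peak value 1, sd `sigma` seconds.
ecgTemplate <- function(fs, sigma = 0.008, halfWidth = 0.04) {
  k <- round(halfWidth * fs)
  t <- (-k:k) / fs
  exp(-t^2 / (2 * sigma^2))
}

#' Simulate an ECG channel from an RR series
#'
#' Places a narrow Gaussian R-wave template (peak 1 mV) at each cumulative
#' RR time and adds white Gaussian noise. With zero noise the maximum of
#' beat k falls exactly on sample `round(cumsum(rr)[k] * fs / 1000)`.
#'
#' @param rrSeries numeric RR intervals in ms.
#' @param fs sampling rate in Hz (>= 100).
#' @param noiseSd additive noise SD in mV; the R amplitude (1 mV) should stay
#'   at least 5x above it.
#' @param seed integer seed for the noise.
#' @param subjectId,condition metadata carried on the returned record.
#' @return A [SignalRecord-class] with `channel = "ECG"`.
#' @export
simulateECG <- function(rrSeries, fs = 1000, noiseSd = 0.02, seed = 1L,
                        subjectId = "S1", condition = "basic") {
  if (length(rrSeries) == 0L) stop("rrSeries must be non-empty")
  if (fs < 100) stop("fs too low to resolve the QRS spike (need >= 100 Hz)")
  if (noiseSd < 0) stop("noiseSd must be non-negative")
  if (noiseSd > 0.2) stop("R amplitude must be at least 5x noiseSd")
  peakIdx <- round(cumsum(rrSeries) * fs / 1000)
  n <- max(peakIdx) + round(0.5 * fs)
  x <- numeric(n)
  tmpl <- ecgTemplate(fs)
  k <- (length(tmpl) - 1L) %/% 2L
  for (pk in peakIdx) {
    lo <- max(1L, pk - k); hi <- min(n, pk + k)
    x[lo:hi] <- x[lo:hi] + tmpl[(lo - pk + k + 1L):(hi - pk + k + 1L)]
  }
  if (noiseSd > 0) x <- x + withSeed(seed, stats::rnorm(n, 0, noiseSd))
  new("SignalRecord", channel = "ECG", fs = fs, samples = x, units = "mV",
      subjectId = subjectId, condition = condition)
}

# Biexponential SCR kernel (fast rise, slow decay), normalized to peak 1.
scrKernel <- function(fs, tauRise = 0.75, tauDecay = 4, support = 30) {
  t <- seq(0, support, by = 1 / fs)
  k <- exp(-t / tauDecay) - exp(-t / tauRise)
  k / max(k)
}

#' Simulate an electrodermal activity (EDA) channel
#'
#' Signal = tonic component (level plus linear drift) + phasic component
#' (skin-conductance responses at Poisson event times, each a fast-rise /
#' slow-decay biexponential kernel) + Gaussian noise, clipped at zero
#' (conductance is non-negative).
#'
#' @inheritParams simulateRRSeries
#' @param fs sampling rate in Hz.
#' @param subjectId subject identifier.
#' @return A [SignalRecord-class] with `channel = "EDA"`, units uS.
#' @export
simulateEDA <- function(params, condition = "basic", fs = params$edaFs,
                        seed = params$seed, subjectId = "S1") {
  validateSimParams(params)
  condition <- match.arg(condition, CONDITIONS)
  level <- condParam(params, "tonicLevelUS", condition)
  if (level < 0) stop("tonic level must be non-negative")
  drift <- condParam(params, "tonicDriftUSPerMin", condition)
  rate <- condParam(params, "scrRatePerMin", condition)
  amp <- condParam(params, "scrAmplitudeUS", condition)
  noiseSd <- unname(params$noiseSd["EDA"])
  n <- round(params$durationS * fs)
  tMin <- (seq_len(n) - 1L) / fs / 60
  tonic <- level + drift * tMin
  x <- withSeed(seed, {
    phasic <- numeric(n)
    nEv <- stats::rpois(1L, rate * params$durationS / 60)
    if (nEv > 0) {
      evIdx <- sort(1L + floor(stats::runif(nEv) * n))
      kern <- amp * scrKernel(fs)
      for (i0 in evIdx) {
        hi <- min(n, i0 + length(kern) - 1L)
        phasic[i0:hi] <- phasic[i0:hi] + kern[seq_len(hi - i0 + 1L)]
      }
    }
    y <- tonic + phasic
    if (noiseSd > 0) y <- y + stats::rnorm(n, 0, noiseSd)
    pmax(y, 0)
  })
  new("SignalRecord", channel = "EDA", fs = fs, samples = x, units = "uS",
      subjectId = subjectId, condition = condition)
}

#' Simulate a skin-temperature (SKT) channel
#'
#' Baseline plus linear drift plus low-amplitude Gaussian noise; under the
#' default parameters the negative condition has a lower baseline and a
#' negative drift.
#'
#' @inheritParams simulateEDA
#' @return A [SignalRecord-class] with `channel = "SKT"`, units degC.
#' @export
simulateSKT <- function(params, condition = "basic", fs = params$sktFs,
                        seed = params$seed, subjectId = "S1") {
  validateSimParams(params)
  condition <- match.arg(condition, CONDITIONS)
  base <- condParam(params, "sktBaseC", condition)
  drift <- condParam(params, "sktDriftCPerMin", condition)
  noiseSd <- unname(params$noiseSd["SKT"])
  n <- round(params$durationS * fs)
  tMin <- (seq_len(n) - 1L) / fs / 60
  x <- base + drift * tMin
  if (noiseSd > 0) x <- x + withSeed(seed, stats::rnorm(n, 0, noiseSd))
  new("SignalRecord", channel = "SKT", fs = fs, samples = x, units = "degC",
      subjectId = subjectId, condition = condition)
}

#' Simulate a complete three-channel recording
#'
#' Generates ECG, SKT and EDA channels for one (subject, condition) pair.
#' Channel seeds are derived deterministically from `seed`, so the same
#' (params, seed) always yields bit-identical recordings.
#'
#' @inheritParams simulateRRSeries
#' @param subjectId subject identifier.
#' @return Named list with elements `ecg`, `skt`, `eda`
#'   ([SignalRecord-class]) and `rr` (the programmed RR series, ms).
#' @examples
#' p <- simParams(durationS = 320)
#' rec <- simulateRecording(p, condition = "negative", seed = 7)
#' rec$eda
#' @export
simulateRecording <- function(params, condition = "basic", seed = params$seed,
                              subjectId = "S1") {
  condition <- match.arg(condition, CONDITIONS)
  condOff <- if (condition == "basic") 0L else 50L
  rr <- simulateRRSeries(params, condition, seed = seed * 100L + condOff + 1L)
  ecg <- simulateECG(rr, fs = params$ecgFs, noiseSd = unname(params$noiseSd["ECG"]),
                     seed = seed * 100L + condOff + 2L,
                     subjectId = subjectId, condition = condition)
  skt <- simulateSKT(params, condition, seed = seed * 100L + condOff + 3L,
                     subjectId = subjectId)
  eda <- simulateEDA(params, condition, seed = seed * 100L + condOff + 4L,
                     subjectId = subjectId)
  list(ecg = ecg, skt = skt, eda = eda, rr = rr)
}
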