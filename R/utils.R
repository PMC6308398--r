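#' @include AllClasses.R
NULL

# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

assertScalar <- function(x, name, positive = TRUE) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be strictly positive", name), call. = FALSE)
  invisible(x)
}

# Zero-phase Butterworth filtering with reflected edge padding.
# signal::filtfilt alone leaves startup transients (zero initial conditions)
# that break the DC-identity invariant; odd reflection at both ends keeps the
# signal continuous across the pad so the transient dies inside the pad.
zeroPhaseFilter <- function(x, filt) {
  n <- length(x)
  np <- min(n - 1L, 2000L)
  if (np < 1L) return(as.numeric(signal::filter(filt, x)))
  left <- 2 * x[1] - x[(np + 1L):2L]
  right <- 2 * x[n] - x[(n - 1L):(n - np)]
  y <- as.numeric(signal::filter(filt, c(left, x, right)))
  y <- rev(as.numeric(signal::filter(filt, rev(y))))
  y[(np + 1L):(np + n)]
}

# Sample standard deviation (n - 1 denominator); 0 for length-1 input.
sampleSD <- function(x) if (length(x) < 2L) 0 else stats::sd(x)

# Cubic-spline resampling of (t, v) onto a uniform grid at rate fs.
resampleUniform <- function(t, v, fs, t0 = min(t), t1 = max(t)) {
  grid <- seq(t0, t1, by = 1 / fs)
  list(t = grid, v = stats::spline(t, v, xout = grid, method = "natural")$y)
}

# Welch power spectral density, one-sided, Hann window.
# Returns freq (Hz) and psd (input-units^2 per Hz). Segments shorter than
# `nperseg` fall back to the largest power of two that fits.
welchPsd <- function(x, fs, nperseg = 256L, overlap = 0.5) {
  n <- length(x)
  if (n < 8L) stop("signal too short for spectral estimation")
  if (n < nperseg) nperseg <- 2L^floor(log2(n))
  step <- max(1L, floor(nperseg * (1 - overlap)))
  starts <- seq.int(1L, n - nperseg + 1L, by = step)
  k <- seq_len(nperseg) - 1L
  win <- 0.5 * (1 - cos(2 * pi * k / (nperseg - 1L)))
  scale <- fs * sum(win^2)
  acc <- numeric(nperseg)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- seg - mean(seg)
    acc <- acc + Mod(stats::fft(seg * win))^2 / scale
  }
  acc <- acc / length(starts)
  half <- nperseg %/% 2L
  psd <- acc[1:(half + 1L)]
  psd[2:half] <- 2 * psd[2:half]  # fold negative frequencies
  list(freq = (0:half) * fs / nperseg, psd = psd)
}

# Integrate a PSD over [lo, hi] (trapezoidal on the discrete grid).
bandPower <- function(freq, psd, lo, hi) {
  keep <- freq >= lo & freq <= hi
  if (sum(keep) < 2L) return(0)
  pracma::trapz(freq[keep], psd[keep])
}
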