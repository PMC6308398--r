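test_that("RR simulation honours the programmed distribution", {
  p <- simParams(durationS = 600)

  # degenerate noise: metronomic heart
  p0 <- simParams(durationS = 60, rrMeanMs = c(basic = 800, negative = 800),
                  rrSdMs = c(basic = 0, negative = 0))
  rr0 <- simulateRRSeries(p0, "basic", seed = 1)
  expect_true(all(rr0 == 800))

  # Monte-Carlo check: sample mean within 3 SE of the programmed mean
  pLong <- simParams(durationS = 3600,
                     rrMeanMs = c(basic = 800, negative = 750),
                     rrSdMs = c(basic = 50, negative = 40))
  rr <- simulateRRSeries(pLong, "basic", seed = 2)
  se <- 50 / sqrt(length(rr))
  expect_lt(abs(mean(rr) - 800), 3 * se)

  # interval count ~ duration / mean
  expect_lt(abs(length(rr) - 4500), 0.05 * 4500)

  # cumulative sum covers (almost) the whole duration
  expect_gt(sum(rr), 3600 * 1000 - 2000)

  expect_error(simParams(durationS = 60, rrSdMs = c(basic = -1, negative = 1)),
               "non-negative")
  expect_error(simParams(durationS = 60, rrMeanMs = c(basic = 100, negative = 800)),
               "300")
})

test_that("ECG synthesis places R peaks exactly and round-trips detection", {
  rr <- c(800, 820, 790, 805, 810, 800, 795, 815, 790, 800)
  ecg <- simulateECG(rr, fs = 1000, noiseSd = 0, seed = 1)
  x <- samples(ecg)
  expected <- round(cumsum(rr) * 1000 / 1000)
  for (idx in expected) {
    lo <- max(1, idx - 100); hi <- min(length(x), idx + 100)
    expect_equal(lo + which.max(x[lo:hi]) - 1L, idx)
  }
  expect_error(simulateECG(numeric(0)), "non-empty")
  expect_error(simulateECG(rr, fs = 50), "100 Hz")

  # default noise: detection recovers >= 99% of beats within 10 ms
  p <- simParams(durationS = 300)
  rrLong <- simulateRRSeries(p, "basic", seed = 3)
  noisy <- simulateECG(rrLong, noiseSd = 0.02, seed = 4)
  found <- peakTimes(detectRPeaks(noisy))
  truth <- cumsum(rrLong) / 1000
  hits <- vapply(truth, function(tt) min(abs(found - tt)) < 0.010, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("EDA synthesis has the stated tonic/phasic structure", {
  # constant signal when the phasic process and noise are off
  pFlat <- simParams(durationS = 60,
                     scrRatePerMin = c(basic = 0, negative = 0),
                     tonicDriftUSPerMin = c(basic = 0, negative = 0),
                     noiseSd = c(ECG = 0, SKT = 0, EDA = 0))
  eda <- simulateEDA(pFlat, "basic", seed = 1)
  expect_equal(samples(eda), rep(4, 60 * 1000))

  # Poisson event count: 6/min over 60 min -> 360 +- 3*sqrt(360). The event
  # count is recovered from the total phasic mass divided by one SCR
  # kernel's integral (noise and drift off, so signal - level = phasic sum).
  fsE <- 20
  p6 <- simParams(durationS = 3600, edaFs = fsE,
                  scrRatePerMin = c(basic = 6, negative = 6),
                  tonicDriftUSPerMin = c(basic = 0, negative = 0),
                  noiseSd = c(ECG = 0, SKT = 0, EDA = 0))
  eda6 <- samples(simulateEDA(p6, "basic", seed = 11))
  kernelMass <- sum(0.3 * physioaffect:::scrKernel(fsE)) / fsE
  nEvents <- sum(eda6 - 4) / fsE / kernelMass
  expect_lt(abs(nEvents - 360), 3 * sqrt(360))

  expect_error(simParams(tonicLevelUS = c(basic = -1, negative = 8)),
               "non-negative")

  # all samples non-negative even with noise
  pN <- simParams(durationS = 30, edaFs = 100)
  expect_true(all(samples(simulateEDA(pN, "negative", seed = 2)) >= 0))
})

test_that("SKT synthesis follows base + drift and the condition effect directions hold", {
  pD <- simParams(durationS = 3600, sktFs = 10,
                  sktDriftCPerMin = c(basic = 0, negative = -0.01),
                  noiseSd = c(ECG = 0, SKT = 0, EDA = 0))
  skt <- simulateSKT(pD, "negative", seed = 1)
  x <- samples(skt)
  expect_equal(x[1], 33.0)
  expect_equal(x[length(x)], 33.0 - 0.01 * (length(x) - 1) / 10 / 60,
               tolerance = 1e-12)

  pFlat <- simParams(durationS = 60, sktFs = 100,
                     noiseSd = c(ECG = 0, SKT = 0, EDA = 0))
  expect_true(all(samples(simulateSKT(pFlat, "basic", seed = 1)) == 33.5))

  # negative condition: lower SKT, higher EDA window means (default params)
  p <- simParams(durationS = 600, sktFs = 50, edaFs = 50)
  sktB <- samples(simulateSKT(p, "basic", seed = 5))
  sktN <- samples(simulateSKT(p, "negative", seed = 5))
  expect_lt(mean(sktN), mean(sktB))
  edaB <- samples(simulateEDA(p, "basic", seed = 5))
  edaN <- samples(simulateEDA(p, "negative", seed = 5))
  win <- function(x) colMeans(matrix(x[1:(50 * 590)], nrow = 50 * 10))
  expect_gte(mean(win(edaN) > win(edaB)), 0.95)
  expect_gte(mean(win(sktN) < win(sktB)), 0.95)
})

test_that("simulation is bit-identical under a fixed seed", {
  p <- simParams(durationS = 120)
  a <- simulateRecording(p, "negative", seed = 9)
  b <- simulateRecording(p, "negative", seed = 9)
  expect_identical(samples(a$ecg), samples(b$ecg))
  expect_identical(samples(a$eda), samples(b$eda))
  expect_identical(samples(a$skt), samples(b$skt))
  expect_identical(a$rr, b$rr)
  c1 <- simulateRecording(p, "negative", seed = 10)
  expect_false(identical(samples(a$ecg), samples(c1$ecg)))
})

test_that("noiseless round trip recovers the programmed quantities", {
  p <- simParams(durationS = 1500,
                 rrSdMs = c(basic = 20, negative = 20),
                 scrRatePerMin = c(basic = 0, negative = 0),
                 tonicDriftUSPerMin = c(basic = 0, negative = 0),
                 sktDriftCPerMin = c(basic = 0, negative = 0),
                 noiseSd = c(ECG = 0, SKT = 0, EDA = 0))
  rec <- simulateRecording(p, "basic", seed = 2)
  rr <- rrFromPeaks(detectRPeaks(rec$ecg))
  expect_lt(abs(mean(rrIntervals(rr)) - 850), 1)  # within 1 ms of rr_mean
  eda50 <- downsampleLowpass(rec$eda, 50, 1)
  d <- edaDecompose(samples(eda50)[1:(300 * 50)], 50)
  expect_lt(abs(mean(d$tonic) - 4) / 4, 0.01)     # within 1% of tonic level
})
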