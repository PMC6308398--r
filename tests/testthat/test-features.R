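test_that("window sliding yields the documented counts", {
  expect_equal(nrow(slideWindows(3600, windowSpec(), select = FALSE)), 111)
  w <- slideWindows(3600, windowSpec())
  expect_equal(nrow(w), 100)
  expect_equal(w$window_index, 12:111)    # the last 100 of 111
  expect_equal(w$end[nrow(w)], 3600)
  expect_equal(nrow(slideWindows(300, windowSpec(selectionCount = 1))), 1)
  expect_error(slideWindows(200, windowSpec()), "shorter")
  expect_error(slideWindows(400, windowSpec()), "exceeds")
})

test_that("time-domain HRV features match hand-computed values", {
  f <- hrvTimeFeatures(c(800, 810, 790, 805, 795))
  expect_equal(unname(f["MeanHRV"]), 800, tolerance = 1e-9)
  expect_equal(unname(f["SDNN"]), sqrt(250 / 4), tolerance = 1e-9)
  expect_equal(unname(f["RMSSD"]), sqrt(825 / 4), tolerance = 1e-9)
  expect_equal(unname(f["NN50"]), 0)
  expect_equal(unname(f["pNN50"]), 0)

  g <- hrvTimeFeatures(c(700, 760, 700))
  expect_equal(unname(g["NN50"]), 2)
  expect_equal(unname(g["pNN50"]), 200 / 3, tolerance = 1e-9)

  h <- hrvTimeFeatures(rep(812, 10))
  expect_equal(unname(h["SDNN"]), 0)
  expect_equal(unname(h["RMSSD"]), 0)

  # shift invariance: SDNN/RMSSD/NN50 unchanged, MeanHRV shifts
  base <- c(812, 840, 795, 830, 801, 825)
  a <- hrvTimeFeatures(base); b <- hrvTimeFeatures(base + 100)
  expect_equal(unname(b["MeanHRV"] - a["MeanHRV"]), 100, tolerance = 1e-9)
  expect_equal(b[c("SDNN", "RMSSD", "NN50")], a[c("SDNN", "RMSSD", "NN50")],
               tolerance = 1e-9)

  expect_error(hrvTimeFeatures(800), "at least 2")
})

test_that("frequency-domain HRV features localize band power", {
  lf <- hrvFreqFeatures(sineRRSeries(0.1))
  expect_gte(unname(lf["nLF"]), 0.95)
  hf <- hrvFreqFeatures(sineRRSeries(0.25))
  expect_gte(unname(hf["nHF"]), 0.95)
  # normalization identity
  expect_equal(unname(lf["nLF"] + lf["nHF"]), 1, tolerance = 1e-9)
  expect_gt(unname(lf["TP"]), 0)
})

test_that("SKT features are mean and sample SD", {
  expect_equal(unname(sktFeatures(rep(33, 100))), c(33, 0))
  f <- sktFeatures(c(32, 34))
  expect_equal(unname(f["MeanSKT"]), 33)
  expect_equal(unname(f["SDSKT"]), sqrt(2), tolerance = 1e-9)
  ramp <- seq(32, 33, length.out = 15000)
  expect_equal(unname(sktFeatures(ramp)["MeanSKT"]), 32.5, tolerance = 0.01)
  expect_error(sktFeatures(numeric(0)), "empty")
})

test_that("EDA features count crossings and summarize the components", {
  zero <- edaFeatures(tonic = rep(5, 100), phasic = rep(0, 100))
  expect_equal(unname(zero["ZC_EDAP"]), 0)
  expect_equal(unname(zero["SD_EDAP"]), 0)
  expect_equal(unname(zero["Mean_EDAT"]), 5)
  expect_equal(unname(zero["SD_EDAT"]), 0)
  expect_equal(unname(zero["Amp_EDAT"]), 0)

  # one full period of a sinusoid crosses zero twice
  t <- seq(0, 10, by = 1 / 32)
  cyc <- cos(2 * pi * 0.1 * t)
  f <- edaFeatures(tonic = rep(1, length(cyc)), phasic = cyc)
  expect_equal(unname(f["ZC_EDAP"]), 2)

  # zeros attach to the previous sign: +,0,- is one change, not two
  expect_equal(physioaffect:::countSignChanges(c(1, 0, -1)), 1)
  expect_equal(physioaffect:::countSignChanges(c(0, 0, 1, -1, 0, -1)), 1)
})

test_that("feature matrices have the documented shape and normalize to [0,1]", {
  p <- simParams(durationS = 660)
  recs <- list(basic = simulateRecording(p, "basic", seed = 21),
               negative = simulateRecording(p, "negative", seed = 21))
  spec <- windowSpec(selectionCount = 5)
  fm <- buildFeatureMatrix(recs, spec)
  v <- featureValues(fm)
  expect_equal(dim(v), c(10L, 16L))
  expect_identical(colnames(v), featureNames())
  expect_equal(sum(windowInfo(fm)$condition == "negative"), 5L)
  # 9 ECG / 2 SKT / 5 EDA grouping
  expect_identical(featureNames()[1:9],
                   c("MeanHRV", "SDNN", "RMSSD", "NN50", "pNN50",
                     "LF_HF", "TP", "nHF", "nLF"))
  expect_identical(featureNames()[10:11], c("MeanSKT", "SDSKT"))
  expect_identical(featureNames()[12:16],
                   c("ZC_EDAP", "SD_EDAP", "Mean_EDAT", "SD_EDAT", "Amp_EDAT"))
  expect_equal(unname(v[, "nHF"] + v[, "nLF"]), rep(1, 10), tolerance = 1e-9)

  nm <- normalizeMinmax(fm)
  nv <- featureValues(nm)
  expect_true(all(nv >= 0 & nv <= 1))
  expect_equal(unname(apply(nv, 2, min)), rep(0, 16))
  expect_equal(unname(apply(nv, 2, max)), rep(1, 16))
  expect_equal(dim(normBounds(nm)), c(2L, 16L))

  expect_error(buildFeatureMatrix(recs["basic"], spec), "both")
})

test_that("min-max normalization handles its documented cases", {
  v <- cbind(A = c(2, 4, 6), B = c(0, 0.5, 1), C = c(7, 7, 7))
  fm <- new("FeatureMatrix", values = v,
            windowInfo = data.frame(subject_id = "S1",
                                    condition = c("basic", "basic", "negative"),
                                    window_index = 1:3))
  expect_warning(nm <- normalizeMinmax(fm), "constant")
  nv <- featureValues(nm)
  expect_equal(unname(nv[, "A"]), c(0, 0.5, 1))
  expect_equal(unname(nv[, "B"]), c(0, 0.5, 1))  # already [0,1]: identity
  expect_equal(unname(nv[, "C"]), c(0.5, 0.5, 0.5))
})
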