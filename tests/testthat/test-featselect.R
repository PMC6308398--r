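test_that("histogram estimation applies pseudo-count smoothing", {
  d <- estimateDistribution(rep(0.55, 7), nBins = 10, pseudoCount = 0)
  expect_equal(d$prob[6], 1)
  expect_equal(sum(d$prob), 1)

  u <- estimateDistribution(seq(0.05, 0.95, by = 0.1), nBins = 10,
                            pseudoCount = 0)
  expect_equal(u$prob, rep(0.1, 10))

  s <- estimateDistribution(c(0.1, 0.1, 0.2, 0.6), nBins = 2, pseudoCount = 1)
  expect_equal(s$prob, c(4 / 6, 2 / 6))

  # boundary values land in the outermost bins
  b <- estimateDistribution(c(0, 1), nBins = 4, pseudoCount = 0)
  expect_equal(b$counts, c(1L, 0L, 0L, 1L))

  expect_error(estimateDistribution(numeric(0)), "empty")
  expect_error(estimateDistribution(c(0.2, 1.4)), "0, 1")
})

test_that("KLD matches hand-computed values and its defining properties", {
  expect_equal(kld(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(kld(c(0.5, 0.5), c(0.25, 0.75)), 1 - 0.5 * log2(3),
               tolerance = 1e-9)  # 0.20752 bits
  expect_equal(kld(c(1, 0), c(0.5, 0.5)), 1, tolerance = 1e-9)

  # non-negativity and identity of indiscernibles on random distributions
  set.seed(4)
  for (i in 1:20) {
    p <- rgamma(8, 1); p <- p / sum(p)
    q <- rgamma(8, 1); q <- q / sum(q)
    expect_gte(kld(p, q), 0)
    expect_equal(kld(p, p), 0, tolerance = 1e-12)
  }

  # asymmetry is real: D(p||q) != D(q||p) on an asymmetric pair
  p <- c(0.9, 0.1); q <- c(0.5, 0.5)
  expect_false(isTRUE(all.equal(kld(p, q), kld(q, p))))

  expect_error(kld(c(0.5, 0.5), c(1, 0)), "strictly positive")
  expect_error(kld(c(0.5, 0.5), c(0.2, 0.3, 0.5)), "length")
})

test_that("label entropy matches hand-computed values", {
  expect_equal(labelEntropy(rep(c(0, 1), 50)), 1)
  expect_equal(labelEntropy(c(rep(0, 25), rep(1, 75))),
               -(0.25 * log2(0.25) + 0.75 * log2(0.75)), tolerance = 1e-9)
  expect_equal(labelEntropy(rep("a", 10)), 0)
  expect_error(labelEntropy(integer(0)), "empty")
})

test_that("cumulative information gain matches a brute-force partition oracle", {
  set.seed(6)
  for (rep in 1:5) {
    n <- sample(10:30, 1)
    d <- sample(1:3, 1)
    x <- matrix(runif(n * d), n, d)
    colnames(x) <- paste0("F", 1:d)
    y <- sample(0:1, n, replace = TRUE)
    if (length(unique(y)) < 2) y[1] <- 1 - y[1]
    for (k in 1:d) {
      expect_equal(cumulativeIG(x, y, colnames(x), k),
                   bruteForceIG(x, y, colnames(x)[1:k]), tolerance = 1e-12)
    }
  }
})

test_that("the IG curve is monotone, bounded, and saturates on separable data", {
  # perfectly separating feature: IG = H(S) = 1 bit at k = 1
  x1 <- cbind(F1 = c(seq(0, 0.4, length.out = 10), seq(0.6, 1, length.out = 10)))
  y1 <- rep(0:1, each = 10)
  expect_equal(cumulativeIG(x1, y1, "F1", 1), 1, tolerance = 1e-12)

  # label-independent feature: IG near zero at n = 200
  set.seed(8)
  x0 <- cbind(F1 = runif(200))
  y0 <- rep(0:1, each = 100)
  expect_lte(cumulativeIG(x0, y0, "F1", 1), 0.05)

  # monotone non-decreasing in k, bounded by H(S)
  m <- plantedSignalMatrix(3)
  ig <- vapply(1:16, function(k) cumulativeIG(m$x, m$y, featureNames(), k),
               numeric(1))
  expect_true(all(diff(ig) >= -1e-12))
  expect_true(all(ig <= 1 + 1e-12))

  expect_error(cumulativeIG(m$x, m$y, featureNames(), 0), "out of range")
  expect_error(cumulativeIG(m$x, m$y, featureNames(), 17), "out of range")
})

test_that("the convergence rule reproduces its worked examples", {
  cv <- convergencePoint(c(0.2, 0.6, 0.9, 0.95, 0.96, 0.96))
  expect_equal(cv@kStar, 3L)
  expect_equal(cv@cp, 0.19, tolerance = 1e-12)

  flat <- convergencePoint(rep(0.7, 6))
  expect_equal(flat@kStar, 1L)
  expect_equal(flat@cp, 0)

  # all forward differences equal: never converges, keep all features
  lin <- convergencePoint(seq(0.1, 0.6, by = 0.1))
  expect_equal(lin@kStar, 6L)

  expect_error(convergencePoint(numeric(0)), "empty")
})

test_that("selection ranks planted signal above noise and reports diagnostics", {
  m <- plantedSignalMatrix(1)
  sel <- selectFeatures(m$x, m$y)
  rk <- featureRanking(sel)
  # the three signal features out-rank every noise feature
  expect_setequal(rk@feature[1:3], featureNames()[1:3])
  # nothing outside the signal set is selected on this strong effect
  expect_true(all(selectedFeatures(sel) %in% featureNames()[1:3]))
  expect_s4_class(igCurve(sel), "IGCurve")
  expect_true(all(rk@kld >= 0))
  expect_equal(sort(rk@feature), sort(featureNames()))

  # pure-noise matrix: diagnostics still valid, selection well-defined
  set.seed(12)
  xN <- matrix(runif(200 * 4), 200, 4)
  colnames(xN) <- paste0("N", 1:4)
  selN <- selectFeatures(xN, rep(0:1, 100))
  expect_gte(igCurve(selN)@kStar, 1L)
  expect_true(all(featureRanking(selN)@kld < 0.3))

  # single-feature matrix selects that feature
  x1 <- matrix(c(runif(50, 0, 0.4), runif(50, 0.6, 1)), ncol = 1,
               dimnames = list(NULL, "only"))
  sel1 <- selectFeatures(x1, rep(0:1, each = 50))
  expect_identical(selectedFeatures(sel1), "only")

  expect_error(selectFeatures(m$x, rep(1, 200)), "both classes")
})
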