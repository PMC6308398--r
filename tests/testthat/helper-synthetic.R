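# Shared fixture builders; everything is generated in code at test time.

# An RRSeries whose tachogram is rrMean + amp * sin(2*pi*f*t), beats ~0.8 s apart.
sineRRSeries <- function(f, durationS = 320, rrMean = 800, amp = 50) {
  t <- cumsum(rep(0.8, round(durationS / 0.8)))
  iv <- rrMean + amp * sin(2 * pi * f * t)
  new("RRSeries", intervals = iv, times = t, usable = rep(TRUE, length(iv)))
}

# FeatureMatrix of multivariate-normal rows (d = 16), split into two
# conditions; used for outlier calibration.
gaussianFeatureMatrix <- function(n, mean = 0.5, sd = 0.08, seed = 1) {
  set.seed(seed)
  v <- matrix(rnorm(n * 16, mean, sd), n, 16)
  colnames(v) <- featureNames()
  new("FeatureMatrix", values = v,
      windowInfo = data.frame(
        subject_id = "S1",
        condition = rep(c("basic", "negative"), length.out = n),
        window_index = seq_len(n)))
}

# Planted-signal design: features 1..3 shifted by `shiftSD` class SDs in the
# negative class, 13 pure-noise features; min-max normalized.
plantedSignalMatrix <- function(seed, n = 200, shiftSD = 3) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  x <- matrix(rnorm(n * 16), n, 16)
  x[y == 1, 1:3] <- x[y == 1, 1:3] + shiftSD
  x <- apply(x, 2, function(col) (col - min(col)) / (max(col) - min(col)))
  colnames(x) <- featureNames()
  list(x = x, y = y)
}

# Independent oracle for the cumulative information gain: explicit
# enumeration of all 2^k binary cells (nested loops over cell codes), written
# without the package's partition machinery.
bruteForceIG <- function(x, y, cols) {
  k <- length(cols)
  med <- vapply(cols, function(j) median(x[, j]), numeric(1))
  ent <- function(lab) {
    if (length(lab) == 0) return(0)
    p <- c(mean(lab == 0), mean(lab == 1))
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  total <- 0
  for (code in 0:(2^k - 1)) {
    inCell <- rep(TRUE, nrow(x))
    for (j in seq_len(k)) {
      bit <- (code %/% 2^(j - 1)) %% 2
      above <- x[, cols[j]] > med[j]
      inCell <- inCell & (above == (bit == 1))
    }
    if (any(inCell)) total <- total + mean(inCell) * ent(y[inCell])
  }
  ent(y) - total
}

# Two well-separated Gaussian blobs in [0,1]^d with labels 0/1.
blobData <- function(n, d = 2, gapSD = 3, sd = 0.05, seed = 1) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  X <- matrix(rnorm(n * d, 0.4, sd), n, d)
  X[y == 1, ] <- X[y == 1, ] + gapSD * sd
  list(X = X, y = y)
}
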