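#' @include utils.R
NULL

# Daubechies-3 (db3) analysis low-pass filter; the other three filters follow
# from the standard quadrature-mirror relations.
DB3_DEC_LO <- c(0.03522629188570953, -0.08544127388202666,
                -0.13501102001025458, 0.45987750211849154,
                0.80689150931109257, 0.33267055295008263)
DB3_DEC_HI <- rev(DB3_DEC_LO) * rep(c(-1, 1), 3)
DB3_REC_LO <- rev(DB3_DEC_LO)
DB3_REC_HI <- DB3_DEC_LO * rep(c(1, -1), 3)
DB3_LEN <- 6L

# Half-point symmetric extension by p samples on both sides (edge repeated).
symExtend <- function(x, p) {
  n <- length(x)
  if (p > n) stop("signal too short for symmetric extension")
  c(x[p:1], x, x[n:(n - p + 1L)])
}

# One analysis step: returns approximation and detail coefficients, each of
# length floor((n + 5) / 2), matching symmetric-extension DWT conventions.
dwtStep <- function(x) {
  p <- DB3_LEN - 1L
  ext <- symExtend(x, p)
  nc <- (length(x) + DB3_LEN - 1L) %/% 2L
  idx <- seq.int(DB3_LEN + 1L, by = 2L, length.out = nc)
  cA <- stats::convolve(ext, rev(DB3_DEC_LO), type = "open")[idx]
  cD <- stats::convolve(ext, rev(DB3_DEC_HI), type = "open")[idx]
  list(cA = cA, cD = cD)
}

# One synthesis step back to a signal of length nOut.
idwtStep <- function(cA, cD, nOut) {
  up <- function(cf) {
    u <- numeric(2L * length(cf))
    u[seq.int(1L, by = 2L, length.out = length(cf))] <- cf
    u
  }
  y <- stats::convolve(up(cA), rev(DB3_REC_LO), type = "open") +
       stats::convolve(up(cD), rev(DB3_REC_HI), type = "open")
  y <- y[-seq_len(DB3_LEN - 2L)]  # drop synthesis boundary samples
  y[seq_len(nOut)]
}

# Multi-level db3 decomposition: list with approximation at `level`, details
# per level, and the signal lengths needed to invert.
db3Wavedec <- function(x, level) {
  lengths <- integer(level)
  details <- vector("list", level)
  cur <- x
  for (l in seq_len(level)) {
    lengths[l] <- length(cur)
    st <- dwtStep(cur)
    details[[l]] <- st$cD
    cur <- st$cA
  }
  list(cA = cur, details = details, lengths = lengths)
}

# Reconstruction; detail coefficients can be zeroed to obtain the
# approximation-band (tonic) signal.
db3Waverec <- function(dec, zeroDetails = FALSE) {
  cur <- dec$cA
  for (l in rev(seq_along(dec$details))) {
    cD <- if (zeroDetails) numeric(length(dec$details[[l]])) else dec$details[[l]]
    cur <- idwtStep(cur, cD, dec$lengths[l])
  }
  cur
}
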