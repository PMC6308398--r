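#' @include AllClasses.R features.R
NULL

#' Histogram estimate of a feature's distribution on \[0, 1\]
#'
#' Equal-width bins with additive (pseudo-count) smoothing:
#' probability = (count + pseudoCount) / (n + nBins * pseudoCount). The
#' smoothing keeps every bin strictly positive so the divergence in
#' [kld()] is always finite.
#'
#' @param values numeric vector in \[0, 1\].
#' @param nBins number of bins (default 10).
#' @param pseudoCount smoothing pseudo-count per bin (default 1).
#' @return List with `edges` (length nBins + 1), `counts` and `prob`.
#' @export
estimateDistribution <- function(values, nBins = 10L, pseudoCount = 1) {
  if (length(values) == 0L) stop("empty input")
  if (nBins < 2L) stop("need at least 2 bins")
  if (any(values < -1e-9 | values > 1 + 1e-9))
    stop("values must lie in [0, 1]; normalize first")
  edges <- seq(0, 1, length.out = nBins + 1L)
  bin <- pmin(pmax(findInterval(values, edges, rightmost.closed = TRUE), 1L),
              nBins)
  counts <- tabulate(bin, nbins = nBins)
  prob <- (counts + pseudoCount) / (length(values) + nBins * pseudoCount)
  list(edges = edges, counts = counts, prob = prob)
}

#' Kullback-Leibler divergence between two binned distributions
#'
#' D_KL(p || q) = sum p(x) log2(p(x) / q(x)), in bits; non-negative and zero
#' iff p = q. The divergence is asymmetric: in the feature ranking, p is the
#' negative-emotion class and q the basic class.
#'
#' @param p,q distributions from [estimateDistribution()] (same bin edges),
#'   or bare probability vectors of equal length.
#' @return Divergence in bits.
#' @examples
#' kld(c(0.5, 0.5), c(0.25, 0.75))  # 0.20752 bits
#' @export
kld <- function(p, q) {
  pp <- if (is.list(p)) p$prob else p
  qq <- if (is.list(q)) q$prob else q
  if (is.list(p) && is.list(q) && !isTRUE(all.equal(p$edges, q$edges)))
    stop("p and q must share bin edges")
  if (length(pp) != length(qq)) stop("p and q must have the same length")
  if (any(qq <= 0 & pp > 0)) stop("q must be strictly positive where p > 0 (smooth q)")
  nz <- pp > 0
  sum(pp[nz] * log2(pp[nz] / qq[nz]))
}

#' Shannon entropy of a label set
#'
#' H(S) = -sum p log2 p over the class proportions, with 0 log 0 = 0.
#'
#' @param labels vector of class labels (any type).
#' @return Entropy in bits.
#' @export
labelEntropy <- function(labels) {
  if (length(labels) == 0L) stop("empty label set")
  p <- table(labels) / length(labels)
  p <- as.numeric(p[p > 0])
  -sum(p * log2(p))
}

# Cell membership of the joint median-split partition of the top-k features.
medianSplitCells <- function(x, ranking, k) {
  x <- as.matrix(x)
  cols <- ranking[seq_len(k)]
  bits <- vapply(cols, function(j) as.integer(x[, j] > stats::median(x[, j])),
                 integer(nrow(x)))
  if (nrow(x) == 1L) bits <- matrix(bits, nrow = 1L)
  apply(bits, 1L, paste, collapse = "")
}

#' Cumulative information gain of the top-k ranked features
#'
#' Each of the top-k features is binarized at its pooled median; the
#' "lower nodes" are the nonempty cells of the joint binarization, and
#' IG = H(S) - sum_t p(t) H(t). Adding a feature refines the partition, so
#' the curve is non-decreasing in k and bounded by H(S).
#'
#' @param x numeric feature matrix (normalized).
#' @param labels class labels aligned with rows.
#' @param ranking feature order (column names or indices), most important
#'   first.
#' @param k number of leading ranked features to use.
#' @return Information gain in bits.
#' @export
cumulativeIG <- function(x, labels, ranking, k) {
  x <- as.matrix(x)
  if (k < 1L || k > length(ranking)) stop("k out of range")
  if (length(labels) != nrow(x)) stop("labels must match rows")
  cells <- medianSplitCells(x, ranking, k)
  n <- length(labels)
  hCond <- 0
  for (cell in unique(cells)) {
    idx <- cells == cell
    hCond <- hCond + sum(idx) / n * labelEntropy(labels[idx])
  }
  labelEntropy(labels) - hCond
}

#' Convergence point of an information-gain curve
#'
#' Let CP = (max IG - min IG) / 4. The selected size k* is the smallest k
#' whose forward difference IG(k+1) - IG(k) falls strictly below half the
#' maximum forward difference, provided IG(k) has already climbed to at
#' least min IG + CP. A flat curve (maximum forward difference 0) selects
#' k* = 1; if no k qualifies, all features are kept (k* = d).
#'
#' @param ig numeric cumulative information-gain curve (k = 1..d).
#' @param hS label entropy H(S) in bits (for the returned object; defaults
#'   to max(ig) when unknown).
#' @return An [IGCurve-class] with slots `cp` and `kStar`.
#' @export
convergencePoint <- function(ig, hS = max(ig)) {
  if (length(ig) < 1L) stop("empty IG curve")
  cp <- (max(ig) - min(ig)) / 4
  kStar <- length(ig)
  if (length(ig) == 1L) {
    kStar <- 1L
  } else {
    dif <- diff(ig)
    if (max(dif) <= 0) {
      kStar <- 1L  # flat curve: converged immediately
    } else {
      half <- max(dif) / 2
      hit <- which(dif < half & ig[-length(ig)] >= min(ig) + cp)
      if (length(hit)) kStar <- hit[1L]
    }
  }
  new("IGCurve", ig = ig, hS = hS, cp = cp, kStar = as.integer(kStar))
}

#' Rank features by KLD and cut at the information-gain convergence point
#'
#' Per feature, the class-conditional distributions are estimated by smoothed
#' histograms and the features ranked by descending D_KL(negative || basic).
#' Features are then added one by one in that order, the cumulative
#' information gain of the joint median-split partition computed, and the
#' set cut at the convergence point.
#'
#' @param fm a normalized [FeatureMatrix-class], or a numeric matrix in
#'   \[0, 1\] (then `labels` is required).
#' @param labels 0/1 labels (1 = negative emotion); taken from the
#'   `condition` column when `fm` is a [FeatureMatrix-class].
#' @param nBins,pseudoCount histogram settings, see [estimateDistribution()].
#' @return A [SelectedFeatureSet-class].
#' @export
selectFeatures <- function(fm, labels = NULL, nBins = 10L, pseudoCount = 1) {
  if (methods::is(fm, "FeatureMatrix")) {
    labels <- conditionLabels(fm)
    x <- featureValues(fm)
  } else {
    x <- as.matrix(fm)
    if (is.null(labels)) stop("labels required for a bare matrix")
  }
  if (length(unique(labels)) < 2L)
    stop("both classes must be present to rank features")
  if (is.null(colnames(x))) colnames(x) <- paste0("F", seq_len(ncol(x)))
  kldVals <- vapply(seq_len(ncol(x)), function(j) {
    p <- estimateDistribution(x[labels == 1, j], nBins, pseudoCount)
    q <- estimateDistribution(x[labels == 0, j], nBins, pseudoCount)
    kld(p, q)
  }, numeric(1))
  ord <- order(kldVals, decreasing = TRUE)
  ranking <- new("FeatureRanking", feature = colnames(x)[ord],
                 kld = kldVals[ord])
  ig <- vapply(seq_len(ncol(x)),
               function(k) cumulativeIG(x, labels, ranking@feature, k),
               numeric(1))
  curve <- convergencePoint(ig, hS = labelEntropy(labels))
  new("SelectedFeatureSet", ranking = ranking, igCurve = curve,
      selected = ranking@feature[seq_len(curve@kStar)])
}
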