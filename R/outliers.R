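#' @include AllClasses.R
NULL

#' Fit a multivariate normal to the rows of one emotion class
#'
#' Sample mean and sample covariance with a small ridge
#' (lambda * trace(Sigma) / d added to the diagonal) so the covariance is
#' invertible even when rows are few relative to the 16 features.
#'
#' @param x numeric matrix, rows of a single class.
#' @param ridge ridge coefficient lambda (default 1e-6).
#' @return A [ClassGaussian-class].
#' @export
fitClassGaussian <- function(x, ridge = 1e-6) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 rows to fit a class Gaussian")
  mu <- colMeans(x)
  S <- stats::cov(x)
  d <- ncol(x)
  tr <- sum(diag(S))
  # a flat class (all rows identical) still needs an invertible covariance
  lam <- ridge * if (tr > 0) tr / d else 1
  S <- S + diag(lam, d)
  new("ClassGaussian", center = mu, covariance = S, ridge = ridge,
      n = nrow(x))
}

#' Squared Mahalanobis distance to a fitted class Gaussian
#'
#' @param x numeric vector or matrix of row vectors.
#' @param g a [ClassGaussian-class].
#' @return Numeric vector of squared distances
#'   (x - mu)' Sigma^-1 (x - mu), all >= 0.
#' @export
mahalanobisSq <- function(x, g) {
  stopifnot(methods::is(g, "ClassGaussian"))
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  if (ncol(x) != length(g@center)) stop("dimension mismatch")
  stats::mahalanobis(x, g@center, g@covariance)
}

#' Remove outlying windows by per-class Mahalanobis distance
#'
#' Each class (basic, negative) is fit separately under a multivariate
#' normal assumption; rows whose squared Mahalanobis distance to their own
#' class exceeds the chi-square quantile threshold (df = number of features)
#' are removed. Both classes are processed independently in one pass.
#'
#' @param fm a normalized [FeatureMatrix-class].
#' @param quantile chi-square quantile in (0, 1) defining the threshold
#'   (default 0.975). Lower values clean more aggressively.
#' @param pooled fit one Gaussian on all rows instead of one per class
#'   (default FALSE: per class).
#' @param ridge ridge passed to [fitClassGaussian()].
#' @return List with `matrix` (the cleaned [FeatureMatrix-class]) and
#'   `mask` (an [OutlierMask-class] aligned with the input rows).
#' @export
removeOutliers <- function(fm, quantile = 0.975, pooled = FALSE,
                           ridge = 1e-6) {
  stopifnot(methods::is(fm, "FeatureMatrix"))
  if (quantile <= 0 || quantile >= 1) stop("quantile must lie in (0, 1)")
  v <- fm@values
  labels <- windowInfo(fm)$condition
  d2 <- numeric(nrow(v))
  if (pooled) {
    g <- fitClassGaussian(v, ridge)
    d2 <- mahalanobisSq(v, g)
  } else {
    for (cond in unique(labels)) {
      rows <- labels == cond
      g <- fitClassGaussian(v[rows, , drop = FALSE], ridge)
      d2[rows] <- mahalanobisSq(v[rows, , drop = FALSE], g)
    }
  }
  thr <- stats::qchisq(quantile, df = ncol(v))
  keep <- d2 <= thr
  mask <- new("OutlierMask", keep = keep, distanceSq = d2, threshold = thr,
              quantile = quantile)
  cleaned <- methods::initialize(fm,
    values = v[keep, , drop = FALSE],
    windowInfo = fm@windowInfo[keep, , drop = FALSE])
  rownames(cleaned@windowInfo) <- NULL
  list(matrix = cleaned, mask = mask)
}
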