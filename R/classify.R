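#' @include utils.R outliers.R AllClasses.R
NULL

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Configuration of the one-hidden-layer perceptron
#'
#' The network has one hidden layer with (input feature count - 1) sigmoid
#' units (minimum 1, so a single-input network still has one hidden unit),
#' a sigmoid output unit, and is trained by full-batch gradient descent on
#' the summed binary cross-entropy with a constant learning rate of 0.01 for
#' exactly 2000 iterations. Weights are initialized uniform(-0.5, 0.5) from
#' `seed`, so training is deterministic given (X, y, config).
#'
#' @param nInputs number of input features.
#' @param hiddenNodes hidden-layer width; default `max(1, nInputs - 1)`.
#' @param learningRate gradient-descent step size (default 0.01).
#' @param iterations number of full-batch updates (default 2000).
#' @param seed integer seed for weight initialization.
#' @return A validated list.
#' @export
mlpConfig <- function(nInputs, hiddenNodes = max(1L, nInputs - 1L),
                      learningRate = 0.01, iterations = 2000L, seed = 1L) {
  assertScalar(nInputs, "nInputs"); assertScalar(hiddenNodes, "hiddenNodes")
  assertScalar(learningRate, "learningRate")
  assertScalar(iterations, "iterations")
  list(nInputs = as.integer(nInputs), hiddenNodes = as.integer(hiddenNodes),
       learningRate = learningRate, iterations = as.integer(iterations),
       seed = as.integer(seed))
}

#' Train the perceptron by full-batch backpropagation
#'
#' @param X numeric matrix in \[0, 1\] (rows = samples).
#' @param y 0/1 labels (1 = negative emotion).
#' @param config an [mlpConfig()]; its `nInputs` must match `ncol(X)`.
#' @return An [MLPModel-class].
#' @export
trainMLP <- function(X, y, config = mlpConfig(ncol(X))) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) stop("training labels contain a single class")
  if (config$nInputs != ncol(X)) stop("config nInputs must match ncol(X)")
  d <- ncol(X); h <- config$hiddenNodes; n <- nrow(X)
  init <- withSeed(config$seed, stats::runif(d * h + h + h + 1L, -0.5, 0.5))
  W1 <- matrix(init[seq_len(d * h)], d, h)
  b1 <- init[d * h + seq_len(h)]
  W2 <- matrix(init[d * h + h + seq_len(h)], h, 1L)
  b2 <- init[d * h + 2L * h + 1L]
  lr <- config$learningRate
  for (it in seq_len(config$iterations)) {
    H <- sigmoid(sweep(X %*% W1, 2L, b1, "+"))
    p <- sigmoid(as.numeric(H %*% W2) + b2)
    delta2 <- (p - y)                   # d(summed BCE)/d(logit), per sample
    gW2 <- crossprod(H, delta2)
    gb2 <- sum(delta2)
    delta1 <- (delta2 %*% t(W2)) * H * (1 - H)
    gW1 <- crossprod(X, delta1)
    gb1 <- colSums(delta1)
    W1 <- W1 - lr * gW1; b1 <- b1 - lr * gb1
    W2 <- W2 - lr * gW2; b2 <- b2 - lr * gb2
  }
  new("MLPModel", W1 = W1, b1 = b1, W2 = W2, b2 = b2, config = config,
      featureNames = if (is.null(colnames(X))) character(0) else colnames(X))
}

mlpForward <- function(model, X) {
  H <- sigmoid(sweep(X %*% model@W1, 2L, model@b1, "+"))
  sigmoid(as.numeric(H %*% model@W2) + model@b2)
}

#' Predict labels (or probabilities) from a trained model
#'
#' Output-unit values >= 0.5 are called negative emotion (label 1); the
#' exact tie goes to the positive class.
#'
#' @param object an [MLPModel-class] or [GaussianClassifier-class].
#' @param newdata numeric matrix with the training feature count.
#' @param type `"class"` (default) for 0/1 labels, `"prob"` for the
#'   positive-class probability.
#' @return Numeric vector of labels or probabilities.
#' @export
setMethod("predict", "MLPModel", function(object, newdata,
                                          type = c("class", "prob")) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  if (ncol(X) != nrow(object@W1)) stop("feature count does not match training")
  p <- mlpForward(object, X)
  if (type == "prob") p else as.numeric(p >= 0.5)
})

gaussianLogDensity <- function(x, g) {
  d <- length(g@center)
  ch <- chol(g@covariance)
  z <- backsolve(ch, t(x) - g@center, transpose = TRUE)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * d * log(2 * pi)
}

trainGaussianDiscriminant <- function(X, y, pooled, ridge = 1e-6) {
  X <- as.matrix(X); y <- as.numeric(y)
  if (sum(y == 0) < 2L || sum(y == 1) < 2L)
    stop("need at least 2 samples per class")
  g0 <- fitClassGaussian(X[y == 0, , drop = FALSE], ridge)
  g1 <- fitClassGaussian(X[y == 1, , drop = FALSE], ridge)
  if (pooled) {
    n0 <- g0@n; n1 <- g1@n
    Sp <- ((n0 - 1) * g0@covariance + (n1 - 1) * g1@covariance) / (n0 + n1 - 2)
    g0 <- methods::initialize(g0, covariance = Sp)
    g1 <- methods::initialize(g1, covariance = Sp)
  }
  new("GaussianClassifier", class0 = g0, class1 = g1, pooled = pooled,
      featureNames = if (is.null(colnames(X))) character(0) else colnames(X))
}

#' Linear and quadratic discriminant comparators
#'
#' Equal-prior Gaussian discriminants with a small covariance ridge (shared
#' with the outlier module). LDA pools the class covariances; QDA keeps one
#' covariance per class, so it can separate classes that differ only in
#' spread.
#'
#' @param X numeric matrix (rows = samples).
#' @param y 0/1 labels.
#' @param ridge covariance ridge coefficient.
#' @return A [GaussianClassifier-class].
#' @export
trainLDA <- function(X, y, ridge = 1e-6) trainGaussianDiscriminant(X, y, TRUE, ridge)

#' @rdname trainLDA
#' @export
trainQDA <- function(X, y, ridge = 1e-6) trainGaussianDiscriminant(X, y, FALSE, ridge)

#' @rdname predict-MLPModel-method
#' @export
setMethod("predict", "GaussianClassifier", function(object, newdata,
                                                    type = c("class", "prob")) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  if (ncol(X) != length(object@class0@center))
    stop("feature count does not match training")
  l0 <- gaussianLogDensity(X, object@class0)
  l1 <- gaussianLogDensity(X, object@class1)
  p1 <- 1 / (1 + exp(l0 - l1))  # equal priors
  if (type == "prob") p1 else as.numeric(p1 >= 0.5)
})

#' Classification metrics from a confusion table
#'
#' Accuracy = (TP + TN) / (TP + FN + FP + TN), sensitivity = TP / (TP + FN),
#' specificity = TN / (FP + TN), PPV = TP / (TP + FP), NPV = TN / (FN + TN).
#' The positive class is negative emotion. A zero denominator yields NaN
#' with a warning.
#'
#' @param counts named vector or list with TP, FN, FP, TN.
#' @return Named numeric vector: accuracy, sensitivity, specificity, ppv,
#'   npv (fractions).
#' @examples
#' metricsFromConfusion(c(TP = 45, FN = 5, FP = 3, TN = 47))
#' @export
metricsFromConfusion <- function(counts) {
  counts <- unlist(counts)
  need <- c("TP", "FN", "FP", "TN")
  if (!all(need %in% names(counts))) stop("counts must name TP, FN, FP, TN")
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  tp <- counts["TP"]; fn <- counts["FN"]; fp <- counts["FP"]; tn <- counts["TN"]
  total <- tp + fn + fp + tn
  if (total == 0) stop("empty confusion table")
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator)", what), call. = FALSE)
      return(NaN)
    }
    num / den
  }
  c(accuracy = unname((tp + tn) / total),
    sensitivity = unname(safe(tp, tp + fn, "sensitivity")),
    specificity = unname(safe(tn, fp + tn, "specificity")),
    ppv = unname(safe(tp, tp + fp, "PPV")),
    npv = unname(safe(tn, fn + tn, "NPV")))
}

#' Leave-one-out cross-validation
#'
#' n folds; fold i trains on all rows but i (with fold seed = `seed + i` for
#' the perceptron, so folds are reproducible but not weight-identical) and
#' predicts row i. Confusion counts are aggregated over folds and the five
#' metrics computed. If a fold's training labels collapse to one class, that
#' fold predicts the training majority class with a warning.
#'
#' @param X numeric matrix in \[0, 1\].
#' @param y 0/1 labels (1 = negative emotion).
#' @param method `"mlp"`, `"lda"` or `"qda"`.
#' @param config an [mlpConfig()] for `method = "mlp"` (its seed is the
#'   LOOCV base seed).
#' @param ridge covariance ridge for the discriminant methods.
#' @return An [EvaluationReport-class].
#' @export
loocv <- function(X, y, method = c("mlp", "lda", "qda"),
                  config = NULL, ridge = 1e-6) {
  method <- match.arg(method)
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 samples for LOOCV")
  if (length(y) != n) stop("labels must match rows")
  if (method == "mlp" && is.null(config)) config <- mlpConfig(ncol(X))
  pred <- numeric(n)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]; ytr <- y[-i]
    if (length(unique(ytr)) < 2L) {
      warning(sprintf("fold %d has single-class training labels; predicting the majority class", i),
              call. = FALSE)
      pred[i] <- as.numeric(mean(ytr) >= 0.5)
      next
    }
    model <- switch(method,
      mlp = trainMLP(Xtr, ytr, config = within(config, seed <- seed + i)),
      lda = trainLDA(Xtr, ytr, ridge),
      qda = trainQDA(Xtr, ytr, ridge))
    pred[i] <- predict(model, X[i, , drop = FALSE])
  }
  confusion <- c(TP = sum(pred == 1 & y == 1), FN = sum(pred == 0 & y == 1),
                 FP = sum(pred == 1 & y == 0), TN = sum(pred == 0 & y == 0))
  new("EvaluationReport", classifier = method,
      confusion = stats::setNames(as.integer(confusion), names(confusion)),
      metrics = metricsFromConfusion(confusion), folds = as.integer(n),
      config = if (is.null(config)) list(ridge = ridge) else config)
}
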