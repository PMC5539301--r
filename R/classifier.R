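#' @importFrom stats predict glm binomial coef quantile sd var
NULL

# Standardise training features and apply the same transform to the test
# portion. Columns with zero training variance are left on their original
# scale (matching the behaviour of e1071::svm, which skips scaling for
# constant columns).
.scalePair <- function(xtr, xte) {
  mu <- colMeans(xtr)
  n <- nrow(xtr)
  v <- (colMeans(xtr * xtr) - mu * mu) * n / (n - 1)
  s <- sqrt(pmax(v, 0))
  use <- s > 0
  if (any(use)) {
    f <- ifelse(use, 1 / s, 1)
    off <- ifelse(use, mu * f, 0)
    xtr <- xtr * rep(f, each = n) - rep(off, each = n)
    xte <- xte * rep(f, each = nrow(xte)) - rep(off, each = nrow(xte))
  }
  list(train = xtr, test = xte)
}

.resolveGamma <- function(spec, nfeat) {
  if (is.character(spec@gamma)) 1 / nfeat else spec@gamma
}

# Fit on one training portion, return test accuracy. X matrices are
# samples x features.
.fitPredictAcc <- function(xtr, ytr, xte, yte, spec) {
  if (length(unique(as.character(ytr))) < 2L)
    stop("training fold contains a single class")
  fam <- spec@family
  if (fam %in% c("svm_rbf", "svm_linear")) {
    if (spec@scale) {
      sc <- .scalePair(xtr, xte)
      xtr <- sc$train; xte <- sc$test
    }
    fit <- e1071::svm(xtr, ytr, type = "C-classification",
                      kernel = if (fam == "svm_rbf") "radial" else "linear",
                      cost = spec@cost,
                      gamma = .resolveGamma(spec, ncol(xtr)),
                      scale = FALSE, fitted = FALSE)
    mean(predict(fit, xte) == yte)
  } else if (fam == "random_forest") {
    fit <- withr::with_seed(spec@seed,
      randomForest::randomForest(xtr, ytr))
    mean(predict(fit, xte) == yte)
  } else { # logistic
    df <- data.frame(.y = as.integer(ytr == levels(ytr)[1L]), xtr)
    fit <- suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
    p <- suppressWarnings(predict(fit, data.frame(xte), type = "response"))
    pred <- ifelse(p > 0.5, levels(ytr)[1L], levels(ytr)[2L])
    mean(pred == yte)
  }
}

# Internal CV engine: X is samples x features, y a two-level factor,
# fold an integer portion assignment. Returns per-fold accuracies in
# rotation order.
.cvAccuracyCore <- function(X, y, fold, k, spec) {
  vapply(foldRotation(k), function(f) {
    te <- fold == f
    .fitPredictAcc(X[!te, , drop = FALSE], y[!te],
                   X[te, , drop = FALSE], y[te], spec)
  }, numeric(1))
}

#' Cross-validated classification accuracy
#'
#' Fits the configured classifier on the training portions of each fold and
#' reports the fraction of correct class predictions on the held-out
#' portion, iterating over folds in rotation order (first training fold
#' tests portion \code{k}, the second portion 1, and so on). Deterministic
#' for a fixed \code{spec} seed.
#'
#' @param features numeric F x S matrix (features in rows, samples in
#'   columns).
#' @param labels per-sample conditions (length S).
#' @param folds a \linkS4class{FoldPlan} over the same samples.
#' @param spec a \linkS4class{ClassifierSpec}.
#' @return a \linkS4class{CVResult}.
#' @examples
#' x <- matrix(c(rep(10, 12), rep(0, 12)), nrow = 1)
#' folds <- stratifiedFolds(rep(c("cancer", "normal"), each = 12), k = 4)
#' cvAccuracy(x, rep(c("cancer", "normal"), each = 12), folds,
#'            classifierSpec())
#' @export
cvAccuracy <- function(features, labels, folds, spec = classifierSpec()) {
  features <- as.matrix(features)
  y <- factor(tolower(as.character(labels)), levels = c("cancer", "normal"))
  if (ncol(features) != length(y))
    stop("features and labels disagree on the sample count")
  if (length(y) != length(folds@assignment))
    stop("fold plan covers a different number of samples")
  acc <- .cvAccuracyCore(t(features), y, folds@assignment, folds@k, spec)
  new("CVResult", perFoldAccuracy = acc, meanAccuracy = mean(acc))
}
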