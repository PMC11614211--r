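# Per-contact PCA + linear-SVM decoding with an exact binomial null and the
# one-sample t power analysis of the study design.

#' Construct a binomial null specification
#'
#' The null distribution for decoding accuracy is Binomial(nObs, p0) with
#' p0 = 0.5; by the study design nObs matches the number of presentations of
#' each number modality (40), regardless of the pooled test count.
#'
#' @param p0 chance probability (default 0.5).
#' @param nObs null observation count (default 40).
#' @param alpha significance level (default 0.01).
#' @return a [NullSpec-class].
#' @export
nullSpec <- function(p0 = 0.5, nObs = 40L, alpha = 0.01) {
  new("NullSpec", p0 = as.numeric(p0), nObs = as.integer(nObs),
      alpha = as.numeric(alpha))
}

#' Exact binomial upper-tail probability of a decoding accuracy
#'
#' Returns `P(X >= nCorrect)` for `X ~ Binomial(nObs, p0)`. When the
#' accuracy was estimated on a different number of test observations,
#' rescale first: `nCorrect = round(accuracy * nObs)`.
#'
#' @param nCorrect number of correct classifications (`<= nObs`).
#' @param null a [NullSpec-class].
#' @return the exact upper-tail probability.
#' @export
#' @examples
#' binomialP(20, nullSpec(nObs = 40))   # ~0.5627
#' binomialP(28, nullSpec(nObs = 40))   # < 0.01
binomialP <- function(nCorrect, null = nullSpec()) {
  stopifnot(is(null, "NullSpec"))
  validObject(null)
  nCorrect <- as.integer(round(nCorrect))
  if (nCorrect < 0 || nCorrect > null@nObs)
    stopf("'nCorrect' must lie in [0, %d]", null@nObs)
  stats::pbinom(nCorrect - 1L, null@nObs, null@p0, lower.tail = FALSE)
}

#' Smallest decoding accuracy significant under the binomial null
#'
#' @param null a [NullSpec-class].
#' @return the smallest `k/nObs` with exact upper tail below `alpha`.
#' @export
#' @examples
#' binomialCriticalAccuracy(nullSpec(nObs = 40, alpha = 0.01))  # 0.70
binomialCriticalAccuracy <- function(null = nullSpec()) {
  stopifnot(is(null, "NullSpec"))
  validObject(null)
  tails <- stats::pbinom(0:null@nObs - 1L, null@nObs, null@p0, lower.tail = FALSE)
  k <- which(tails < null@alpha)
  if (!length(k))
    stopf("no accuracy on %d observations reaches alpha = %g", null@nObs, null@alpha)
  (min(k) - 1L) / null@nObs
}

#' Power of the one-sample t-test
#'
#' `P(T' > t_crit)` with `T'` noncentral t, `df = n - 1`, noncentrality
#' `d * sqrt(n)`, and `t_crit` the `1 - alpha` (one-tailed) or `1 - alpha/2`
#' (two-tailed) quantile of the central t distribution. With the study's
#' design values (`d = 0.4`, `n = 40`, one-tailed `alpha = 0.05`) this gives
#' 79.97%.
#'
#' @param d standardized effect size (Cohen's d).
#' @param n number of observations (>= 2).
#' @param alpha significance level.
#' @param tails `"one"` (default) or `"two"`.
#' @return the power as a fraction.
#' @export
#' @examples
#' powerOneSampleT(0.4, 40)             # 0.7997...
powerOneSampleT <- function(d, n, alpha = 0.05, tails = c("one", "two")) {
  tails <- match.arg(tails)
  if (!isNum(d)) stopf("'d' must be a number")
  n <- as.integer(n)
  if (is.na(n) || n < 2) stopf("'n' must be >= 2")
  if (!isNum(alpha) || alpha <= 0 || alpha >= 1) stopf("'alpha' must be in (0, 1)")
  q <- if (tails == "one") 1 - alpha else 1 - alpha / 2
  tcrit <- stats::qt(q, df = n - 1)
  stats::pt(tcrit, df = n - 1, ncp = d * sqrt(n), lower.tail = FALSE)
}

# stratified fold assignment: per class, shuffled round-robin
stratifiedFolds <- function(y, k, seed) {
  fold <- integer(length(y))
  withSeed(childSeed(seed, "folds"), {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# linear-SVM weight vector in input space, oriented so positive decision
# values mean "stimulus"
linearSvmWeights <- function(model, Z, y) {
  w <- drop(crossprod(model$coefs, model$SV))
  b <- -model$rho
  dv <- drop(Z %*% w) + b
  pred <- stats::predict(model, Z)
  agree <- mean((dv > 0) == (pred == "stimulus"))
  if (agree < 0.5) { w <- -w; b <- -b }
  list(w = w, b = b)
}

#' Cross-validated PCA + linear-SVM decoding for one contact
#'
#' Stratified k-fold cross-validation of a stimulus-vs-ITI contrast. Within
#' each fold, per-feature standardization and PCA are fit on the training
#' epochs only; the first `nComponents` principal axes are retained, a
#' linear SVM is fit on the training component weights, and the held-out
#' epochs are scored. Accuracy pools all held-out predictions; significance
#' is the exact binomial tail of the accuracy rescaled to the null's
#' observation count.
#'
#' @param features an [EpochFeatureSet-class] with balanced classes.
#' @param nComponents number of principal components (default 50; reduced
#'   with a warning when the training set cannot support it).
#' @param kFolds cross-validation folds (default 6).
#' @param seed integer seed (fold assignment); identical seeds give
#'   identical results.
#' @param cost linear-SVM regularization parameter C (default 1).
#' @param null a [NullSpec-class] (default `nullSpec()`).
#' @param format label recorded on the result (`"all"` or a modality).
#' @return a [ContactResult-class].
#' @export
crossvalClassify <- function(features, nComponents = 50L, kFolds = 6L,
                             seed = 1L, cost = 1, null = nullSpec(),
                             format = "all") {
  stopifnot(is(features, "EpochFeatureSet"), is(null, "NullSpec"))
  y <- features@condition
  counts <- table(factor(y, levels = c("stimulus", "iti")))
  if (counts[1] != counts[2])
    stopf("class imbalance: %d stimulus vs %d iti epochs", counts[1], counts[2])
  n <- length(y)
  if (n <= kFolds) stopf("need more epochs (%d) than folds (%d)", n, kFolds)
  if (min(counts) < kFolds)
    stopf("each class needs at least %d epochs for %d-fold stratification",
          kFolds, kFolds)
  X <- features@features
  fold <- stratifiedFolds(y, kFolds, seed)
  pred <- character(n)
  folds <- vector("list", kFolds)
  for (f in seq_len(kFolds)) {
    tr <- which(fold != f)
    te <- which(fold == f)
    std <- standardizeFeatures(X, tr)
    kUse <- min(nComponents, length(tr) - 1L, ncol(X))
    if (kUse < nComponents)
      warnf("reducing components from %d to %d (training size %d)",
            nComponents, kUse, length(tr))
    sv <- svd(std$X[tr, , drop = FALSE], nu = 0, nv = kUse)
    V <- sv$v[, seq_len(kUse), drop = FALSE]
    Ztr <- std$X[tr, , drop = FALSE] %*% V
    Zte <- std$X[te, , drop = FALSE] %*% V
    model <- e1071::svm(x = Ztr, y = factor(y[tr], levels = c("iti", "stimulus")),
                        kernel = "linear", cost = cost, scale = FALSE)
    wb <- linearSvmWeights(model, Ztr, y[tr])
    dvTe <- drop(Zte %*% wb$w) + wb$b
    pred[te] <- ifelse(dvTe > 0, "stimulus", "iti")
    folds[[f]] <- list(foldId = f, testIdx = te, center = std$center,
                       scale = std$scale, basis = V,
                       explained = (sv$d[seq_len(kUse)]^2) / (length(tr) - 1L),
                       svmW = wb$w, svmB = wb$b, pred = pred[te],
                       decision = dvTe)
  }
  nCorrect <- sum(pred == y)
  acc <- nCorrect / n
  p <- binomialP(round(acc * null@nObs), null)
  new("ContactResult", contact = features@channel, format = format,
      nTest = as.integer(n), nCorrect = as.integer(nCorrect), accuracy = acc,
      pValue = p, significant = p < null@alpha, null = null, folds = folds,
      freqsHz = features@freqsHz, timesS = features@timesS)
}
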