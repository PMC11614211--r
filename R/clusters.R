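# Classifier interpretation: eigenspectrogram back-projection and the
# one-sample sign-flip cluster permutation test.

#' Back-project a fold's SVM weights into time-frequency space
#'
#' The "eigenspectrogram": the fold's linear-SVM weight vector over
#' principal-component scores is composed with the fold's PCA basis,
#' `w_feature = V w`, and unflattened into the (nFreqs + 1) x nTimes grid.
#' Because PCA is fit on standardized training features (zero training
#' mean), the component-space decision value is exactly
#' `sum(grid * standardizedFeatureGrid) + effectiveIntercept` for every
#' epoch.
#'
#' @param result a [ContactResult-class].
#' @param fold fold index (1..kFolds).
#' @return a list of class `CoefMap`: `grid` (signed coefficient matrix),
#'   `effectiveIntercept`, `foldId`.
#' @export
eigenspectrogram <- function(result, fold) {
  stopifnot(is(result, "ContactResult"))
  if (fold < 1 || fold > length(result@folds)) stopf("no fold %d", fold)
  f <- result@folds[[fold]]
  wFeat <- drop(f$basis %*% f$svmW)
  grid <- unflattenGrid(wFeat, length(result@freqsHz) + 1L)
  structure(list(grid = grid, effectiveIntercept = f$svmB, foldId = f$foldId),
            class = "CoefMap")
}

#' Per-epoch signed contribution maps
#'
#' For every epoch, the element-wise product of the coefficient grid of the
#' fold in which the epoch was held out with the epoch's standardized
#' feature grid (that fold's training statistics), signed by class
#' (+1 stimulus, -1 ITI). Summing a map plus the class-signed intercept
#' reproduces the signed SVM decision value. These maps are the one-sample
#' observations of the cluster permutation test.
#'
#' @param result a [ContactResult-class] from [crossvalClassify()].
#' @param features the [EpochFeatureSet-class] the result was fit on.
#' @return an epochs x (nFreqs + 1) x nTimes array.
#' @export
contributionMaps <- function(result, features) {
  stopifnot(is(result, "ContactResult"), is(features, "EpochFeatureSet"))
  X <- features@features
  n <- nrow(X)
  if (n < 2) stopf("need at least 2 epochs")
  nr <- length(result@freqsHz) + 1L
  nt <- length(result@timesS)
  if (ncol(X) != nr * nt) stopf("feature width does not match the result's grid")
  maps <- array(NA_real_, dim = c(n, nr, nt))
  covered <- logical(n)
  sgn <- ifelse(features@condition == "stimulus", 1, -1)
  for (f in result@folds) {
    coef <- drop(f$basis %*% f$svmW)
    for (e in f$testIdx) {
      xstd <- (X[e, ] - f$center) / f$scale
      maps[e, , ] <- matrix(coef * xstd * sgn[e], nr, nt)
      covered[e] <- TRUE
    }
  }
  if (!all(covered))
    stopf("epoch(s) never held out: %s",
          paste(utils::head(which(!covered)), collapse = ", "))
  maps
}

# 4-connected component labelling; the final (voltage) row can be kept as a
# separate connectivity domain
#' Label 4-connected clusters in a grid mask
#'
#' @param mask logical matrix.
#' @param separateLastRow treat the final row as its own connectivity domain
#'   (the appended voltage row is not frequency-adjacent to the power rows).
#' @return integer matrix of cluster labels (0 = background).
#' @export
labelClusters <- function(mask, separateLastRow = FALSE) {
  stopifnot(is.matrix(mask))
  cpp_label_clusters(mask, isTRUE(separateLastRow))
}

# vectorized one-sample t maps for sign-flip permutations: signs is
# nPerm x n of +/-1, X is n x p; returns nPerm x p
permTMaps <- function(signs, X) {
  n <- nrow(X)
  M <- (signs %*% X) / n
  SS <- matrix(colSums(X^2), nrow(signs), ncol(X), byrow = TRUE)
  V <- (SS - n * M^2) / (n - 1)
  t <- M / sqrt(V / n)
  t[!is.finite(t)] <- 0
  t
}

#' One-sample cluster permutation test on contribution maps
#'
#' Computes the per-point one-sample t statistic of the maps against zero,
#' forms positive and negative clusters separately at the `1 - alpha`
#' quantile of the central t distribution (df = n - 1, "99% of a
#' T-distribution" at the default alpha = 0.01), takes cluster mass as the
#' sum of t values over each 4-connected component, and compares observed
#' masses with the permutation distribution of the maximum absolute cluster
#' mass under random sign flips of whole observations. A cluster is
#' significant when its mass exceeds the `1 - alpha` percentile of the
#' permutation maxima. The appended voltage row is a separate connectivity
#' domain.
#'
#' @param maps observations x (nFreqs + 1) x nTimes array (e.g. from
#'   [contributionMaps()]); at least 10 observations.
#' @param alpha cluster-forming and family-wise level (default 0.01).
#' @param nPerm number of sign-flip permutations (default 1000; a warning is
#'   issued below `99/alpha`).
#' @param seed integer seed for the sign flips.
#' @param separateVoltageRow keep the final row as its own connectivity
#'   domain (default TRUE).
#' @return a [ClusterSet-class].
#' @export
oneSampleClusterPerm <- function(maps, alpha = 0.01, nPerm = 1000L, seed = 1L,
                                 separateVoltageRow = TRUE) {
  d <- dim(maps)
  if (length(d) != 3) stopf("'maps' must be observations x rows x times")
  n <- d[1]
  if (n < 10) stopf("cluster permutation needs at least 10 observations (got %d)", n)
  nPerm <- as.integer(nPerm)
  if (nPerm < 99 / alpha)
    warnf("nPerm = %d gives coarse resolution for alpha = %g (recommend >= %d)",
          nPerm, alpha, ceiling(99 / alpha))
  nr <- d[2]; nt <- d[3]
  X <- matrix(maps, n, nr * nt)
  thr <- stats::qt(1 - alpha, df = n - 1)
  tObs <- drop(permTMaps(matrix(1, 1, n), X))
  tMap <- matrix(tObs, nr, nt)

  sep <- isTRUE(separateVoltageRow)
  clusters <- list()
  for (sgn in c(1, -1)) {
    lab <- cpp_label_clusters(sgn * tMap > thr, sep)
    for (id in seq_len(max(lab))) {
      cells <- which(lab == id)
      clusters[[length(clusters) + 1L]] <-
        list(cells = cells, mass = sum(tMap[cells]),
             sign = if (sgn > 0) "positive" else "negative")
    }
  }
  signs <- withSeed(childSeed(seed, "signflip"),
                    matrix(sample(c(-1, 1), nPerm * n, replace = TRUE), nPerm, n))
  permT <- permTMaps(signs, X)
  permMax <- cpp_perm_max_mass(permT, thr, nr, nt, sep)
  critMass <- sort(permMax)[max(1L, ceiling((1 - alpha) * nPerm))]
  clusters <- lapply(clusters, function(cl) {
    cl$pValue <- (1 + sum(permMax >= abs(cl$mass))) / (nPerm + 1)
    cl$significant <- abs(cl$mass) > critMass
    cl
  })
  new("ClusterSet", clusters = clusters, tMap = tMap, threshold = thr,
      permMax = permMax, alpha = alpha, nPerm = nPerm)
}
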