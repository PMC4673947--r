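#' Root mean squared error
#'
#' `sqrt(mean((observed - predicted)^2))`.
#'
#' @param observed,predicted numeric vectors of equal, nonzero length
#' @return scalar RMSE (same units as the inputs)
#' @export
rmse <- function(observed, predicted) {
  if (!length(observed) || length(observed) != length(predicted))
    stop("observed and predicted must have equal nonzero length")
  sqrt(mean((observed - predicted)^2))
}

#' Coefficient of determination
#'
#' `1 - SS_residual / SS_total` about the observed mean; may be negative
#' for predictors worse than the mean.  `pearson = TRUE` instead returns
#' the squared Pearson correlation between observed and predicted.
#'
#' @inheritParams rmse
#' @param pearson use the squared-correlation variant (default FALSE)
#' @return scalar R-squared
#' @export
rSquared <- function(observed, predicted, pearson = FALSE) {
  if (!length(observed) || length(observed) != length(predicted))
    stop("observed and predicted must have equal nonzero length")
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) stop("observed values are constant; R^2 undefined")
  if (pearson) return(stats::cor(observed, predicted)^2)
  1 - sum((observed - predicted)^2) / sst
}

#' Stratified train/test split of a BIS matrix
#'
#' Within every dose group a seeded random choice of `trainPerDose`
#' training and `testPerDose` testing rows; with 8 exposed doses and 7
#' replicates the defaults give the 40/16 split of the evaluation
#' protocol.  Deterministic given `seed`.
#'
#' @param bis a [BISMatrix]
#' @param trainPerDose,testPerDose rows per dose group (defaults 5 and 2)
#' @param seed integer seed
#' @return list with disjoint integer vectors `train` and `test`
#' @export
stratifiedSplit <- function(bis, trainPerDose = 5L, testPerDose = 2L, seed = 1L) {
  stopifnot(methods::is(bis, "BISMatrix"), trainPerDose >= 1L, testPerDose >= 1L)
  d <- bis@dose
  .with_seed(seed, {
    train <- integer(); test <- integer()
    for (dd in sort(unique(d))) {
      idx <- which(d == dd)
      if (length(idx) < trainPerDose + testPerDose)
        stop(sprintf("dose group %g has %d rows; %d needed",
                     dd, length(idx), trainPerDose + testPerDose))
      pick <- sample(idx, trainPerDose + testPerDose)
      train <- c(train, pick[seq_len(trainPerDose)])
      test <- c(test, pick[trainPerDose + seq_len(testPerDose)])
    }
    list(train = sort(train), test = sort(test))
  })
}

#' Cross-validated latent-variable selection curve
#'
#' Seeded k-fold cross-validation (folds stratified by `strata` when
#' given): for each fold a PLS model with `maxLV` components is fitted on
#' the remaining rows and the held-out rows are predicted with 1..maxLV
#' components; `mseByLV[j]` pools the squared errors at j components over
#' all folds.  The selected count is the argmin (smallest j on ties).
#'
#' @param X predictor matrix (or [BISMatrix])
#' @param y response vector
#' @param maxLV largest component count to examine
#' @param kFolds number of folds (default 7)
#' @param seed integer seed for the fold assignment
#' @param strata optional labels (e.g. doses) to stratify folds
#' @return list with `mseByLV` (length `maxLV`) and `selectedLV`
#' @export
cvLVCurve <- function(X, y, maxLV, kFolds = 7L, seed = 1L, strata = NULL) {
  if (methods::is(X, "BISMatrix")) {
    if (is.null(strata)) strata <- X@dose
    X <- X@X
  }
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(y) == n, kFolds >= 2L, kFolds <= n, maxLV >= 1L)
  folds <- .with_seed(seed, {
    f <- integer(n)
    if (is.null(strata)) {
      f <- sample(rep_len(seq_len(kFolds), n))
    } else {
      for (g in unique(strata)) {
        idx <- which(strata == g)
        f[idx] <- sample(rep_len(sample(kFolds), length(idx)))
      }
    }
    f
  })
  biggest_fold <- max(tabulate(folds, kFolds))
  cap <- min(maxLV, n - biggest_fold - 1L, ncol(X))
  if (cap < 1L) stop("folds too small for even one latent variable")
  sse <- numeric(cap)
  for (k in seq_len(kFolds)) {
    hold <- folds == k
    if (!any(hold)) next
    fit <- fitPLS(X[!hold, , drop = FALSE], y[!hold], nLV = cap)
    for (j in seq_len(cap)) {
      pred <- predict(fit, X[hold, , drop = FALSE], nLV = j)
      sse[j] <- sse[j] + sum((y[hold] - pred)^2)
    }
  }
  mse <- sse / n
  list(mseByLV = mse, selectedLV = which.min(mse))
}

#' Default spectral windows of the evaluation protocol
#'
#' The full working range plus its four 500 cm^-1 segments:
#' 1000--3000, 2500--3000, 2000--2500, 1500--2000 and 1000--1500 cm^-1.
#'
#' @return list of `c(lo, hi)` pairs
#' @export
defaultWindows <- function() {
  list(c(1000, 3000), c(2500, 3000), c(2000, 2500),
       c(1500, 2000), c(1000, 1500))
}

#' Evaluate dose prediction over spectral windows
#'
#' The full evaluation protocol: compute BIS from a preprocessed
#' collection; for each window restrict the BIS matrix, draw `nModels`
#' stratified 40/16 splits (shared across windows, seeded), select the
#' latent-variable count on each training set by [cvLVCurve()], fit the
#' final model and record train/test RMSE and R-squared.
#'
#' @param x a preprocessed [SpectrumCollection]
#' @param windows list of `c(lo, hi)` pairs (default [defaultWindows()])
#' @param nModels number of random splits per window (default 20)
#' @param maxLV largest latent-variable count examined (default 15)
#' @param kFolds cross-validation folds (default 7)
#' @param seed root seed; split m uses a sub-seed derived from `(seed, m)`
#' @param controlDose reference dose for the BIS (default 0)
#' @param trainPerDose,testPerDose split sizes per dose group
#' @return data.frame with one row per (window, model): `window`, `lo`,
#'   `hi`, `model`, `selectedLV`, `r2Train`, `rmseTrain`, `r2Test`,
#'   `rmseTest`
#' @seealso [summarizeEvaluation()]
#' @export
evaluateWindows <- function(x, windows = defaultWindows(), nModels = 20L,
                            maxLV = 15L, kFolds = 7L, seed = 1L,
                            controlDose = 0, trainPerDose = 5L,
                            testPerDose = 2L) {
  stopifnot(methods::is(x, "SpectrumCollection"), nModels >= 1L)
  bis <- computeBIS(x, controlDose)
  splits <- lapply(seq_len(nModels), function(m)
    stratifiedSplit(bis, trainPerDose, testPerDose,
                    seed = .stage_seed(seed, sprintf("split%d", m))))
  rows <- list()
  for (wi in seq_along(windows)) {
    win <- windows[[wi]]
    sub <- extractWindow(bis, win[1L], win[2L])
    X <- sub@X; y <- sub@dose
    for (m in seq_len(nModels)) {
      tr <- splits[[m]]$train; te <- splits[[m]]$test
      cv <- cvLVCurve(X[tr, , drop = FALSE], y[tr], maxLV = maxLV,
                      kFolds = kFolds,
                      seed = .stage_seed(seed, sprintf("cv%d", m)),
                      strata = y[tr])
      fit <- fitPLS(X[tr, , drop = FALSE], y[tr], nLV = cv$selectedLV)
      predTr <- predict(fit, X[tr, , drop = FALSE])
      predTe <- predict(fit, X[te, , drop = FALSE])
      rows[[length(rows) + 1L]] <- data.frame(
        window = sprintf("%g-%g", win[1L], win[2L]),
        lo = win[1L], hi = win[2L], model = m, selectedLV = cv$selectedLV,
        r2Train = rSquared(y[tr], predTr), rmseTrain = rmse(y[tr], predTr),
        r2Test = rSquared(y[te], predTe), rmseTest = rmse(y[te], predTe))
    }
  }
  do.call(rbind, rows)
}

#' Summarize an evaluation table per window
#'
#' Mean and standard deviation of the test and train R-squared and RMSE
#' across the random splits of each window.
#'
#' @param records output of [evaluateWindows()]
#' @return data.frame, one row per window
#' @export
summarizeEvaluation <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) > 0L)
  out <- lapply(split(records, factor(records$window, levels = unique(records$window))),
    function(r) data.frame(
      window = r$window[1L], nModels = nrow(r),
      meanR2Test = mean(r$r2Test), sdR2Test = stats::sd(r$r2Test),
      meanRmseTest = mean(r$rmseTest), sdRmseTest = stats::sd(r$rmseTest),
      meanR2Train = mean(r$r2Train), sdR2Train = stats::sd(r$r2Train),
      meanRmseTrain = mean(r$rmseTrain), sdRmseTrain = stats::sd(r$rmseTrain),
      meanSelectedLV = mean(r$selectedLV)))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
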