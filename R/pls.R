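#' Fit univariate partial least squares regression (NIPALS)
#'
#' Centers `X` column-wise and `y`, then extracts `nLV` components
#' sequentially: weight `w = X'y / ||X'y||`, score `t = Xw`, X-loading
#' `p = X't / t't`, y-loading `q = y't / t't`, followed by deflation
#' `X <- X - t p'`, `y <- y - q t`.  For a univariate response each
#' component is closed-form, so the fit is deterministic.  The collapsed
#' regression vector is `b = W (P'W)^-1 q`; `P'W` is unit upper-triangular
#' in exact arithmetic and is inverted by triangular back-substitution,
#' guarded by a conditioning check.  Predictors are centered but not
#' variance-scaled (set `scale = TRUE` for autoscaling).
#'
#' @param X numeric matrix, n x p
#' @param y numeric response, length n, non-constant
#' @param nLV number of latent variables, `1 <= nLV <= min(n - 1, p)`
#' @param scale autoscale predictor columns to unit variance (default FALSE)
#' @return a [PLSModel-class]
#' @examples
#' X <- matrix(rnorm(80), 10, 8)
#' y <- X[, 1] - 2 * X[, 2] + rnorm(10, sd = 0.1)
#' m <- fitPLS(X, y, nLV = 2)
#' predict(m, X)
#' @export
fitPLS <- function(X, y, nLV, scale = FALSE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (n < 2L) stop("need at least 2 observations")
  if (stats::var(y) == 0) stop("y has zero variance; nothing to regress on")
  nLV <- as.integer(nLV)
  if (nLV < 1L || nLV > min(n - 1L, p))
    stop(sprintf("nLV must be in [1, %d]", min(n - 1L, p)))
  xm <- colMeans(X)
  xs <- rep(1, p)
  if (scale) {
    xs <- apply(X, 2L, stats::sd)
    xs[xs == 0] <- 1
  }
  Xc <- sweep(sweep(X, 2L, xm), 2L, xs, "/")
  ym <- mean(y)
  yc <- y - ym
  ssx <- sum(Xc^2); ssy <- sum(yc^2)
  W <- matrix(0, p, nLV); P <- matrix(0, p, nLV); Tm <- matrix(0, n, nLV)
  q <- numeric(nLV)
  for (k in seq_len(nLV)) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12 * sqrt(ssx * ssy) || nw == 0)
      stop(sprintf("X is exhausted after %d component(s); lower nLV", k - 1L))
    w <- w / nw
    tk <- drop(Xc %*% w)
    tt <- sum(tk^2)
    if (tt < .Machine$double.eps)
      stop(sprintf("degenerate score at component %d", k))
    pk <- drop(crossprod(Xc, tk)) / tt
    qk <- sum(yc * tk) / tt
    Xc <- Xc - tcrossprod(tk, pk)
    yc <- yc - qk * tk
    W[, k] <- w; P[, k] <- pk; Tm[, k] <- tk; q[k] <- qk
  }
  M <- crossprod(P, W)   # unit upper-triangular in exact arithmetic
  dM <- abs(diag(M))
  if (max(dM) / min(dM) > 1e10)
    stop("ill-conditioned P'W (condition estimate > 1e10); lower nLV")
  Minv <- backsolve(M, diag(nLV))
  R <- W %*% Minv
  b <- drop(R %*% q) / xs
  methods::new("PLSModel", xMean = xm, yMean = ym, W = W, T = Tm, P = P,
               q = q, R = sweep(R, 1L, xs, "/"), b = b, nLV = nLV,
               ssx = ssx, ssy = ssy)
}

#' Predict doses from a fitted PLS model
#'
#' Computes `(Xnew - xMean) b + yMean`.  `nLV` may be lowered to predict
#' with a leading subset of the fitted components (used by the
#' cross-validated latent-variable selection).
#'
#' @param object a [PLSModel-class]
#' @param newdata numeric matrix m x p (or a [BISMatrix])
#' @param nLV number of components to use, `<= nLatent(object)`
#' @param ... ignored
#' @return numeric vector of m predictions
#' @export
setMethod("predict", "PLSModel", function(object, newdata, nLV = object@nLV, ...) {
  X <- if (methods::is(newdata, "BISMatrix")) newdata@X else as.matrix(newdata)
  if (ncol(X) != length(object@xMean))
    stop(sprintf("newdata has %d columns; model expects %d",
                 ncol(X), length(object@xMean)))
  nLV <- as.integer(nLV)
  if (nLV < 1L || nLV > object@nLV)
    stop(sprintf("nLV must be in [1, %d]", object@nLV))
  # leading block of the triangular inverse = inverse of the leading block,
  # so truncating R and q yields the exact k-component regression vector
  b <- drop(object@R[, seq_len(nLV), drop = FALSE] %*% object@q[seq_len(nLV)])
  drop(sweep(X, 2L, object@xMean) %*% b) + object@yMean
})

#' Per-component explained variance
#'
#' Fraction of the centered training sum of squares of `X` and of `y`
#' captured by each latent variable; fractions lie in `[0, 1]` and their
#' cumulative sums are non-decreasing.
#'
#' @param model a fitted [PLSModel-class]
#' @return list with numeric vectors `x` and `y`, one fraction per component
#' @export
explainedVariance <- function(model) {
  stopifnot(methods::is(model, "PLSModel"))
  tt <- colSums(model@T^2)
  list(x = tt * colSums(model@P^2) / model@ssx,
       y = model@q^2 * tt / model@ssy)
}
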