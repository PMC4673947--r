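# Asymmetric least squares (ALS) baseline: penalized least squares with a
# second-difference smoothness penalty and asymmetric residual weights, so
# the fit hugs the lower envelope of the spectrum and ignores bands.
.als_baseline <- function(y, lambda = 1e7, p = 0.01, iters = 10L) {
  m <- length(y)
  D <- Matrix::bandSparse(m - 2L, m, k = 0:2,
                          diagonals = list(rep(1, m - 2L), rep(-2, m - 2L),
                                           rep(1, m - 2L)))
  DtD <- lambda * Matrix::crossprod(D)
  w <- rep(1, m)
  z <- y
  for (i in seq_len(iters)) {
    z <- as.numeric(Matrix::solve(Matrix::Diagonal(m, w) + DtD, w * y))
    w <- ifelse(y > z, p, 1 - p)
  }
  z
}

#' Baseline-correct spectra
#'
#' Subtracts an asymmetric-least-squares baseline estimated per spectrum:
#' a smooth curve (second-difference penalty `lambda`) fitted with small
#' weight `p` on points above it and `1 - p` below, iterated `iters` times.
#' Tiny numerical negatives (above -1e-6) are clipped to zero; genuine
#' undershoot is kept.
#'
#' @param x a [SpectrumCollection] with >= 10 grid points
#' @param lambda smoothness weight, > 0 (default 1e7)
#' @param p asymmetry weight in (0, 1) (default 0.01)
#' @param iters reweighting iterations, >= 1 (default 10)
#' @return a baseline-corrected [SpectrumCollection]
#' @export
baselineCorrect <- function(x, lambda = 1e7, p = 0.01, iters = 10L) {
  stopifnot(methods::is(x, "SpectrumCollection"),
            lambda > 0, p > 0, p < 1, iters >= 1L)
  a <- absorbance(x)
  if (nrow(a) < 10L) stop("baseline correction needs spectra of length >= 10")
  if (any(!is.finite(a))) stop("non-finite absorbance values")
  out <- apply(a, 2L, function(col) {
    r <- col - .als_baseline(col, lambda, p, iters)
    r[r < 0 & r > -1e-6] <- 0
    r
  })
  SpectrumCollection(matrix(out, nrow = nrow(a)), wavenumbers(x),
                     dose = doses(x), replicate = replicateIds(x),
                     label = SummarizedExperiment::colData(x)$label)
}

#' Normalize each spectrum to the range 0--1
#'
#' Per spectrum affine map `(a - min) / (max - min)`; the output minimum is
#' exactly 0 and the maximum exactly 1.  Applied over the full recorded
#' grid, before any windowing.
#'
#' @param x a [SpectrumCollection]
#' @return a normalized [SpectrumCollection]
#' @export
normalize01 <- function(x) {
  stopifnot(methods::is(x, "SpectrumCollection"))
  a <- absorbance(x)
  out <- apply(a, 2L, function(col) {
    rng <- range(col)
    if (rng[2L] <= rng[1L]) stop("constant spectrum cannot be 0-1 normalized")
    (col - rng[1L]) / (rng[2L] - rng[1L])
  })
  SpectrumCollection(matrix(out, nrow = nrow(a)), wavenumbers(x),
                     dose = doses(x), replicate = replicateIds(x),
                     label = SummarizedExperiment::colData(x)$label)
}

#' Preprocess a collection: baseline correction then 0--1 normalization
#'
#' The fixed order mirrors standard acquisition pipelines: each spectrum is
#' baseline corrected, then (optionally) range-normalized over the full grid.
#'
#' @inheritParams baselineCorrect
#' @param normalize apply [normalize01()] after baseline correction
#' @return a preprocessed [SpectrumCollection]
#' @export
preprocessSpectra <- function(x, lambda = 1e7, p = 0.01, iters = 10L,
                              normalize = TRUE) {
  out <- baselineCorrect(x, lambda = lambda, p = p, iters = iters)
  if (normalize) out <- normalize01(out)
  out
}
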