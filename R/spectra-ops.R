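.window_index <- function(w, lo, hi) {
  if (!is.numeric(lo) || !is.numeric(hi) || lo >= hi)
    stop("window bounds must satisfy lo < hi")
  keep <- which(w >= lo & w <= hi)
  if (!length(keep))
    stop(sprintf("window [%g, %g] has no overlap with the grid %g-%g cm^-1",
                 lo, hi, w[1L], w[length(w)]))
  keep
}

#' @describeIn SpectrumCollection restrict to the closed window `[lo, hi]`
#' @param lo,hi window bounds in cm^-1
#' @export
setMethod("extractWindow", "SpectrumCollection", function(x, lo, hi) {
  x[.window_index(wavenumbers(x), lo, hi), ]
})

#' @describeIn BISMatrix restrict to the closed window `[lo, hi]`
#' @param lo,hi window bounds in cm^-1
#' @export
setMethod("extractWindow", "BISMatrix", function(x, lo, hi) {
  keep <- .window_index(x@wavenumber, lo, hi)
  methods::initialize(x, X = x@X[, keep, drop = FALSE],
                      wavenumber = x@wavenumber[keep])
})

#' Resample spectra onto a new wavenumber grid
#'
#' Linear interpolation between bracketing grid points; values at grid points
#' shared by source and target are reproduced exactly.  Extrapolation outside
#' the source grid is refused.
#'
#' @param x a [SpectrumCollection]
#' @param wavenumber target grid (strictly increasing, uniform spacing)
#' @return a [SpectrumCollection] on the target grid
#' @export
resampleSpectra <- function(x, wavenumber) {
  stopifnot(methods::is(x, "SpectrumCollection"))
  g <- .check_grid(wavenumber)
  if (!is.null(g)) stop(g)
  w <- wavenumbers(x)
  if (wavenumber[1L] < w[1L] || wavenumber[length(wavenumber)] > w[length(w)])
    stop("target grid extends beyond the source grid: extrapolation refused")
  a <- apply(absorbance(x), 2L, function(col)
    stats::approx(w, col, xout = wavenumber, method = "linear")$y)
  a <- matrix(a, nrow = length(wavenumber))
  SpectrumCollection(a, wavenumber, dose = doses(x),
                     replicate = replicateIds(x),
                     label = SummarizedExperiment::colData(x)$label)
}
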