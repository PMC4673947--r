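#' @describeIn SpectrumCollection wavenumber grid
#' @param x object
#' @export
setMethod("wavenumbers", "SpectrumCollection", function(x)
  SummarizedExperiment::rowData(x)$wavenumber)

#' @describeIn SpectrumCollection per-spectrum doses
#' @export
setMethod("doses", "SpectrumCollection", function(x)
  SummarizedExperiment::colData(x)$dose)

#' @describeIn SpectrumCollection per-spectrum replicate ids
#' @export
setMethod("replicateIds", "SpectrumCollection", function(x)
  SummarizedExperiment::colData(x)$replicate)

#' @describeIn SpectrumCollection absorbance matrix (wavenumbers x spectra)
#' @export
setMethod("absorbance", "SpectrumCollection", function(x)
  SummarizedExperiment::assay(x, "absorbance"))

setMethod("show", "SpectrumCollection", function(object) {
  w <- wavenumbers(object)
  cat(sprintf("SpectrumCollection: %d spectra on %d-point grid %g-%g cm^-1 (spacing %g)\n",
              ncol(object), length(w), w[1L], w[length(w)],
              if (length(w) > 1L) w[2L] - w[1L] else NA_real_))
  d <- doses(object)
  cat(sprintf("doses (ug/mL): %s\n",
              paste(sprintf("%g (n=%d)", sort(unique(d)),
                            tabulate(match(d, sort(unique(d))))), collapse = ", ")))
  invisible(NULL)
})

#' @describeIn BISMatrix wavenumber grid
#' @param x object
#' @export
setMethod("wavenumbers", "BISMatrix", function(x) x@wavenumber)

#' @describeIn BISMatrix dose per BIS row
#' @export
setMethod("doses", "BISMatrix", function(x) x@dose)

#' @describeIn BISMatrix replicate id per BIS row
#' @export
setMethod("replicateIds", "BISMatrix", function(x) x@replicate)

#' Coerce a BISMatrix to its plain predictor matrix
#'
#' @param x a [BISMatrix]
#' @param ... ignored
#' @return numeric matrix, rows = BIS spectra, columns = wavenumbers
#' @export
as.matrix.BISMatrix <- function(x, ...) x@X

setMethod("show", "BISMatrix", function(object) {
  w <- object@wavenumber
  cat(sprintf("BISMatrix: %d difference spectra x %d wavenumbers (%g-%g cm^-1), control dose %g\n",
              nrow(object@X), ncol(object@X), w[1L], w[length(w)], object@controlDose))
  invisible(NULL)
})

#' @describeIn PLSModel number of latent variables
#' @param x object
#' @export
setMethod("nLatent", "PLSModel", function(x) x@nLV)

setMethod("show", "PLSModel", function(object) {
  cat(sprintf("PLSModel: %d latent variable(s), %d predictors, fitted on n = %d\n",
              object@nLV, length(object@xMean), nrow(object@T)))
  ev <- explainedVariance(object)
  cat(sprintf("cumulative y-variance explained: %.4f\n", sum(ev$y)))
  invisible(NULL)
})

setMethod("show", "HillFit", function(object) {
  cat(sprintf("HillFit: EC50 = %.4g ug/mL, slope = %.4g, residual SS = %.4g%s\n",
              object@ec50, object@slope, object@residualSS,
              if (object@converged) "" else "  [NOT CONVERGED]"))
  invisible(NULL)
})
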