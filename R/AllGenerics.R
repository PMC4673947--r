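#' @title Generics for cytoIR containers
#' @name cytoIR-generics
#' @keywords internal
NULL

#' Wavenumber grid accessor
#'
#' Returns the wavenumber grid (cm^-1) of a spectral container.
#'
#' @param x a [SpectrumCollection] or [BISMatrix]
#' @return numeric vector of wavenumbers, strictly increasing, uniform spacing
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' Dose accessor
#'
#' Per-spectrum (or per-BIS-row) cisplatin concentration in ug/mL.
#'
#' @param x a [SpectrumCollection] or [BISMatrix]
#' @return numeric vector of doses
#' @export
setGeneric("doses", function(x) standardGeneric("doses"))

#' Replicate-id accessor
#'
#' @param x a [SpectrumCollection] or [BISMatrix]
#' @return integer vector of replicate ids (>= 1)
#' @export
setGeneric("replicateIds", function(x) standardGeneric("replicateIds"))

#' Absorbance matrix accessor
#'
#' @param x a [SpectrumCollection]
#' @return numeric matrix, rows = wavenumbers, columns = spectra
#' @export
setGeneric("absorbance", function(x) standardGeneric("absorbance"))

#' Extract a contiguous wavenumber window
#'
#' Keeps every grid point g with `lo <= g <= hi` (closed interval).
#'
#' @param x a [SpectrumCollection] or [BISMatrix]
#' @param lo,hi window bounds in cm^-1, `lo < hi`
#' @return an object of the same class restricted to the window
#' @export
setGeneric("extractWindow", function(x, lo, hi) standardGeneric("extractWindow"))

#' Number of latent variables of a fitted PLS model
#'
#' @param x a [PLSModel]
#' @return integer
#' @export
setGeneric("nLatent", function(x) standardGeneric("nLatent"))
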