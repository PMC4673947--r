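#' SpectrumCollection: FTIR absorbance spectra on a shared wavenumber grid
#'
#' A thin wrapper around [SummarizedExperiment::SummarizedExperiment] holding
#' one assay `"absorbance"` (rows = wavenumbers, columns = individual spectra)
#' with per-spectrum metadata in `colData`: `dose` (ug/mL, >= 0),
#' `replicate` (integer >= 1, unique within each dose group) and `label`.
#' The wavenumber grid lives in `rowData()$wavenumber` and must be strictly
#' increasing with uniform spacing inside the instrument range 400--4000 cm^-1.
#'
#' @slot .ignore see SummarizedExperiment; no extra slots are added
#' @seealso [SpectrumCollection()] for the constructor, [wavenumbers()],
#'   [doses()], [absorbance()], [extractWindow()]
#' @export
setClass("SpectrumCollection", contains = "SummarizedExperiment")

.check_grid <- function(w) {
  if (length(w) < 2L) return("wavenumber grid needs at least 2 points")
  if (any(!is.finite(w))) return("wavenumber grid contains non-finite values")
  d <- diff(w)
  if (any(d <= 0)) return("wavenumbers must be strictly increasing")
  if ((max(d) - min(d)) > 1e-9 * mean(d))
    return("wavenumber grid spacing is not uniform")
  if (w[1L] < 400 || w[length(w)] > 4000)
    return("wavenumber grid outside the instrument range 400-4000 cm^-1")
  NULL
}

setValidity("SpectrumCollection", function(object) {
  msgs <- character()
  if (!"absorbance" %in% SummarizedExperiment::assayNames(object))
    msgs <- c(msgs, "assay 'absorbance' is missing")
  rd <- SummarizedExperiment::rowData(object)
  if (!"wavenumber" %in% colnames(rd)) {
    msgs <- c(msgs, "rowData column 'wavenumber' is missing")
  } else {
    g <- .check_grid(rd$wavenumber)
    if (!is.null(g)) msgs <- c(msgs, g)
  }
  cd <- SummarizedExperiment::colData(object)
  for (col in c("dose", "replicate"))
    if (!col %in% colnames(cd)) msgs <- c(msgs, sprintf("colData column '%s' is missing", col))
  if (all(c("dose", "replicate") %in% colnames(cd)) && ncol(object) > 0L) {
    if (any(cd$dose < 0)) msgs <- c(msgs, "doses must be >= 0")
    if (any(cd$replicate < 1)) msgs <- c(msgs, "replicate ids must be >= 1")
    if (anyDuplicated(paste(cd$dose, cd$replicate)))
      msgs <- c(msgs, "replicate ids must be unique within each dose group")
  }
  a <- SummarizedExperiment::assay(object, "absorbance")
  if (any(!is.finite(a))) msgs <- c(msgs, "absorbance contains non-finite values")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SpectrumCollection
#'
#' @param absorbance numeric matrix, rows = wavenumbers, columns = spectra
#' @param wavenumber numeric vector of wavenumbers (cm^-1), length `nrow(absorbance)`
#' @param dose numeric vector of doses (ug/mL), length `ncol(absorbance)`
#' @param replicate integer vector of replicate ids, length `ncol(absorbance)`
#' @param label optional character vector of free-text labels
#' @return a validated [SpectrumCollection-class] object
#' @examples
#' w <- seq(1000, 1010, by = 1)
#' a <- cbind(runif(11), runif(11))
#' sc <- SpectrumCollection(a, w, dose = c(0, 1), replicate = c(1L, 1L))
#' wavenumbers(sc)
#' @export
SpectrumCollection <- function(absorbance, wavenumber, dose, replicate,
                               label = rep("", length(dose))) {
  absorbance <- as.matrix(absorbance)
  if (nrow(absorbance) != length(wavenumber))
    stop("nrow(absorbance) must equal length(wavenumber)")
  if (ncol(absorbance) != length(dose) || length(dose) != length(replicate))
    stop("dose and replicate must have one entry per spectrum")
  colnames(absorbance) <- sprintf("%g:%d", dose, as.integer(replicate))
  rownames(absorbance) <- sprintf("%g", wavenumber)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(absorbance = absorbance),
    rowData = S4Vectors::DataFrame(wavenumber = as.numeric(wavenumber)),
    colData = S4Vectors::DataFrame(dose = as.numeric(dose),
                                   replicate = as.integer(replicate),
                                   label = as.character(label)))
  methods::new("SpectrumCollection", se)
}

#' BISMatrix: Biochemical Index Spectra as a predictor block
#'
#' Rows are exposed-minus-control difference spectra (one per exposed
#' replicate), columns are wavenumber grid points.  `dose` is the response
#' vector used by PLS; no row carries the control dose.
#'
#' @slot X numeric matrix, rows = BIS vectors, columns = grid points
#' @slot dose numeric, one dose per row (ug/mL)
#' @slot replicate integer, replicate id per row
#' @slot wavenumber numeric, shared grid (cm^-1)
#' @slot controlDose scalar, the dose consumed as reference
#' @seealso [computeBIS()]
#' @export
setClass("BISMatrix",
  representation(X = "matrix", dose = "numeric", replicate = "integer",
                 wavenumber = "numeric", controlDose = "numeric"))

setValidity("BISMatrix", function(object) {
  msgs <- character()
  if (nrow(object@X) != length(object@dose))
    msgs <- c(msgs, "one dose per BIS row required")
  if (nrow(object@X) != length(object@replicate))
    msgs <- c(msgs, "one replicate id per BIS row required")
  if (ncol(object@X) != length(object@wavenumber))
    msgs <- c(msgs, "one wavenumber per BIS column required")
  g <- .check_grid(object@wavenumber)
  if (!is.null(g)) msgs <- c(msgs, g)
  if (any(object@dose == object@controlDose))
    msgs <- c(msgs, "BIS rows must not carry the control dose")
  if (length(msgs)) msgs else TRUE
})

#' PLSModel: univariate partial least squares regression fit
#'
#' Holds the NIPALS decomposition of a centered predictor block `X` and
#' response `y`: weights `W` (p x k, unit-norm columns), scores `T`
#' (n x k, the latent variables, mutually orthogonal), X-loadings `P`
#' (p x k), y-loadings `q` (length k) and the collapsed regression vector
#' `b` (length p) so that predictions are `(Xnew - xMean) b + yMean`.
#'
#' @slot xMean column means of the training predictors
#' @slot yMean mean of the training response
#' @slot W,T,P NIPALS weights, scores and loadings
#' @slot q y-loadings (regression coefficients for the scores)
#' @slot R rotation `W (P'W)^-1` used to form regression vectors
#' @slot b regression vector at the full number of components
#' @slot nLV number of latent variables
#' @slot ssx,ssy total centered sums of squares of X and y (diagnostics)
#' @seealso [fitPLS()], [predict,PLSModel-method], [explainedVariance()]
#' @export
setClass("PLSModel",
  representation(xMean = "numeric", yMean = "numeric",
                 W = "matrix", T = "matrix", P = "matrix",
                 q = "numeric", R = "matrix", b = "numeric",
                 nLV = "integer", ssx = "numeric", ssy = "numeric"))

#' HillFit: two-parameter Hill (log-logistic) dose-response fit
#'
#' Mortality model `100 c^h / (ec50^h + c^h)` with asymptotes fixed at
#' 0 and 100 percent.
#'
#' @slot ec50 half-maximal-effect concentration (ug/mL)
#' @slot slope Hill coefficient h (dimensionless)
#' @slot residualSS residual sum of squares (percent^2)
#' @slot converged logical; FALSE flags a degenerate or untrustworthy fit
#' @seealso [fitHill()], [predictMortality()]
#' @export
setClass("HillFit",
  representation(ec50 = "numeric", slope = "numeric",
                 residualSS = "numeric", converged = "logical"))
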