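.hill_mortality <- function(dose, ec50, slope) {
  ifelse(dose <= 0, 0, 100 * dose^slope / (ec50^slope + dose^slope))
}

#' Clonogenic mortality of HepG2 cells under cisplatin
#'
#' The published nine-point mortality-vs-concentration table from the
#' 24-hour clonogenic assay the package models (control 0% at 0 ug/mL up
#' to 100% at 4 ug/mL).
#'
#' @return data.frame with columns `dose` (ug/mL) and `mortality` (percent)
#' @export
cisplatinMortality <- function() {
  data.frame(dose = c(0, 0.125, 0.25, 0.5, 1, 1.5, 2, 3, 4),
             mortality = c(0, 24, 40, 67, 88, 92, 95, 98, 100))
}

#' Fit a two-parameter Hill mortality curve
#'
#' Least-squares fit of `mortality% = 100 c^h / (ec50^h + c^h)` over the
#' nonzero concentrations, with asymptotes fixed at 0 and 100.  The fit is
#' a deterministic BFGS minimization on log-parameters, multi-started over
#' slopes {0.5, 1, 2, 4}; the best start wins.  A fit to data without an
#' increasing dose-mortality trend, or whose EC50 escapes the dosed range
#' by more than a decade, is flagged `converged = FALSE` rather than
#' returned silently.
#'
#' @param table data.frame with columns `dose` (ug/mL) and `mortality`
#'   (percent, in `[0, 100]`)
#' @return a [HillFit-class]
#' @examples
#' fit <- fitHill(cisplatinMortality())
#' round(fit@ec50, 1)
#' @export
fitHill <- function(table) {
  stopifnot(is.data.frame(table), all(c("dose", "mortality") %in% colnames(table)))
  d <- table$dose[table$dose > 0]
  m <- table$mortality[table$dose > 0]
  if (length(d) < 3L) stop("need >= 3 nonzero concentrations")
  if (any(m < 0 | m > 100)) stop("mortality must lie in [0, 100] percent")
  if (all(m == 0) || all(m == 100))
    stop("degenerate mortality data: all 0% or all 100%")
  ss <- function(par) {
    pred <- .hill_mortality(d, exp(par[1L]), exp(par[2L]))
    sum((m - pred)^2)
  }
  # start EC50 at the dose bracketing 50% mortality (median dose fallback)
  ec0 <- if (any(m >= 50) && any(m < 50))
    sqrt(max(d[m < 50]) * min(d[m >= 50])) else stats::median(d)
  best <- NULL
  for (h0 in c(0.5, 1, 2, 4)) {
    opt <- stats::optim(log(c(ec0, h0)), ss, method = "BFGS",
                        control = list(maxit = 1000L, reltol = 1e-12))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  ec50 <- exp(best$par[1L]); slope <- exp(best$par[2L])
  trend <- stats::cor(d, m, method = "spearman")
  converged <- best$convergence == 0 && is.finite(trend) && trend > 0 &&
    ec50 > min(d) / 10 && ec50 < max(d) * 10 && slope > 1e-3
  methods::new("HillFit", ec50 = ec50, slope = slope,
               residualSS = best$value, converged = converged)
}

#' Predicted mortality at a dose
#'
#' Evaluates the fitted Hill curve: 0% at dose 0, 50% at the EC50,
#' approaching 100% at saturating dose; strictly increasing in dose.
#'
#' @param fit a [HillFit-class]
#' @param dose concentrations in ug/mL, >= 0
#' @return mortality in percent
#' @export
predictMortality <- function(fit, dose) {
  stopifnot(methods::is(fit, "HillFit"), all(dose >= 0))
  .hill_mortality(dose, fit@ec50, fit@slope)
}

#' Mortality table from colony counts
#'
#' `mortality% = 100 (1 - colonies / colonies_control)`, clipped to
#' `[0, 100]`, referenced to the control-dose well.
#'
#' @param counts data.frame with columns `dose` and `colonies`
#' @param controlDose reference dose (default 0)
#' @return data.frame with columns `dose`, `mortality`
#' @export
survivalFromColonies <- function(counts, controlDose = 0) {
  stopifnot(is.data.frame(counts), all(c("dose", "colonies") %in% colnames(counts)))
  ctrl <- counts$colonies[counts$dose == controlDose]
  if (!length(ctrl)) stop(sprintf("no control row at dose %g", controlDose))
  ref <- mean(ctrl)
  if (ref <= 0) stop("control colony count must be > 0")
  data.frame(dose = counts$dose,
             mortality = pmin(pmax(100 * (1 - counts$colonies / ref), 0), 100))
}
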