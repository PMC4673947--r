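#' Compute Biochemical Index Spectra (exposed minus control)
#'
#' Each exposed spectrum minus the pointwise mean of all control-dose
#' spectra.  Control spectra are consumed as the reference only and never
#' appear as rows; under the default 9-concentration x 7-replicate design
#' this yields 8 x 7 = 56 BIS rows.  Input should be preprocessed
#' (see [preprocessSpectra()]).
#'
#' @param x a [SpectrumCollection] containing the control dose
#' @param controlDose the reference dose (default 0 ug/mL)
#' @return a [BISMatrix]
#' @export
computeBIS <- function(x, controlDose = 0) {
  stopifnot(methods::is(x, "SpectrumCollection"))
  d <- doses(x)
  ctrl <- which(d == controlDose)
  if (!length(ctrl)) stop(sprintf("no spectra at the control dose %g", controlDose))
  if (length(ctrl) == ncol(x)) stop("no exposed spectra: all doses equal the control dose")
  a <- absorbance(x)
  ref <- rowMeans(a[, ctrl, drop = FALSE])
  exposed <- setdiff(seq_len(ncol(x)), ctrl)
  X <- t(a[, exposed, drop = FALSE] - ref)
  rownames(X) <- sprintf("%g:%d", d[exposed], replicateIds(x)[exposed])
  methods::new("BISMatrix", X = X, dose = d[exposed],
               replicate = replicateIds(x)[exposed],
               wavenumber = wavenumbers(x), controlDose = controlDose)
}

#' Detect peaks in a spectral trace
#'
#' Finds local extrema of the requested sign inside the closed window
#' `[lo, hi]` (negative peaks are found as maxima of the negated trace),
#' filters them by topographic prominence, refines each apex by three-point
#' parabolic interpolation and reports centers rounded to the nearest
#' integer cm^-1 (the exact apex is kept in `centerExact`).  Peaks are
#' ordered by `|height|` descending.
#'
#' @param values numeric trace (e.g. one BIS row or one spectrum column)
#' @param wavenumber grid of the trace
#' @param lo,hi search window in cm^-1, `lo < hi`
#' @param sign `"positive"` or `"negative"`
#' @param minProminence minimum prominence (intensity units)
#' @return data.frame with columns `center` (integer cm^-1), `centerExact`,
#'   `height` (signed intensity at the apex), `prominence`, `sign`
#' @export
detectPeaks <- function(values, wavenumber, lo, hi,
                        sign = c("positive", "negative"), minProminence = 0) {
  sign <- match.arg(sign)
  stopifnot(length(values) == length(wavenumber))
  keep <- .window_index(wavenumber, lo, hi)
  w <- wavenumber[keep]
  y0 <- values[keep]
  y <- if (sign == "negative") -y0 else y0
  n <- length(y)
  empty <- data.frame(center = integer(), centerExact = numeric(),
                      height = numeric(), prominence = numeric(),
                      sign = character())
  if (n < 3L) return(empty)
  i <- which(y[-c(1L, n)] > y[-c(n - 1L, n)] & y[-c(1L, n)] >= y[-c(1L, 2L)]) + 1L
  # keep only extrema of the requested sign
  i <- i[y[i] > 0]
  if (!length(i)) return(empty)
  prom <- vapply(i, function(k) {
    lmin <- y[k]; j <- k
    while (j > 1L && y[j - 1L] <= y[k]) { j <- j - 1L; lmin <- min(lmin, y[j]) }
    if (j == 1L) lmin <- min(y[1L:k])
    rmin <- y[k]; j <- k
    while (j < n && y[j + 1L] <= y[k]) { j <- j + 1L; rmin <- min(rmin, y[j]) }
    if (j == n) rmin <- min(y[k:n])
    y[k] - max(lmin, rmin)
  }, 0)
  ok <- prom >= minProminence
  i <- i[ok]; prom <- prom[ok]
  if (!length(i)) return(empty)
  spacing <- w[2L] - w[1L]
  refine <- vapply(i, function(k) {
    denom <- y[k - 1L] - 2 * y[k] + y[k + 1L]
    delta <- if (abs(denom) < .Machine$double.eps) 0 else
      0.5 * (y[k - 1L] - y[k + 1L]) / denom
    apex <- y[k] - 0.25 * (y[k - 1L] - y[k + 1L]) * delta
    c(w[k] + delta * spacing, apex)
  }, c(0, 0))
  s <- if (sign == "negative") -1 else 1
  out <- data.frame(center = as.integer(round(refine[1L, ])),
                    centerExact = refine[1L, ],
                    height = s * refine[2L, ],
                    prominence = prom, sign = sign)
  out[order(-abs(out$height)), , drop = FALSE]
}

#' Per-dose peak trajectory
#'
#' Tracks the strongest peak of one band window across the dose series:
#' for every dose group the top [detectPeaks()] hit of each spectrum is
#' taken and centers/heights are averaged over the replicates in which a
#' peak was found.  Doses where no spectrum shows a peak are reported as
#' absent (dropped), never interpolated.
#'
#' @param x a [SpectrumCollection]
#' @param lo,hi band window in cm^-1
#' @param sign `"positive"` or `"negative"`
#' @param minProminence minimum prominence passed to [detectPeaks()]
#' @return data.frame with columns `dose`, `n` (replicates with a peak),
#'   `meanCenter`, `meanHeight`
#' @export
peakTrajectory <- function(x, lo, hi, sign = c("positive", "negative"),
                           minProminence = 0) {
  sign <- match.arg(sign)
  stopifnot(methods::is(x, "SpectrumCollection"))
  a <- absorbance(x)
  w <- wavenumbers(x)
  d <- doses(x)
  rows <- lapply(sort(unique(d)), function(dd) {
    hits <- lapply(which(d == dd), function(j) {
      pk <- detectPeaks(a[, j], w, lo, hi, sign, minProminence)
      if (nrow(pk)) pk[1L, ] else NULL
    })
    hits <- do.call(rbind, hits)
    if (is.null(hits) || !nrow(hits)) return(NULL)
    data.frame(dose = dd, n = nrow(hits),
               meanCenter = mean(hits$centerExact),
               meanHeight = mean(hits$height))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) data.frame(dose = numeric(), n = integer(),
                               meanCenter = numeric(), meanHeight = numeric())
  else out
}
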