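#' Read spectra from delimited text
#'
#' Two CSV dialects are supported.  `wide`: first column `wavenumber`, one
#' column per spectrum with header `dose:replicate` (e.g. `0.125:3`).
#' `long`: columns `wavenumber, absorbance, dose, replicate`.  All spectra
#' must share one uniform, strictly increasing wavenumber grid.
#'
#' @param path file path
#' @param dialect `"wide"` or `"long"`
#' @return a [SpectrumCollection]
#' @seealso [writeSpectra()] for the inverse operation
#' @export
readSpectra <- function(path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE)
  if (dialect == "wide") {
    if (!identical(colnames(df)[1L], "wavenumber") || ncol(df) < 2L)
      stop("wide dialect requires a leading 'wavenumber' column plus >= 1 spectrum column")
    w <- df[[1L]]
    g <- .check_grid(w)
    if (!is.null(g)) stop(g)
    hdr <- colnames(df)[-1L]
    parts <- strsplit(hdr, ":", fixed = TRUE)
    if (any(lengths(parts) != 2L))
      stop("wide dialect spectrum headers must be 'dose:replicate'")
    dose <- as.numeric(vapply(parts, `[`, "", 1L))
    repl <- as.integer(vapply(parts, `[`, "", 2L))
    if (any(is.na(dose)) || any(is.na(repl)))
      stop("could not parse 'dose:replicate' headers")
    SpectrumCollection(as.matrix(df[, -1L, drop = FALSE]), w, dose, repl)
  } else {
    need <- c("wavenumber", "absorbance", "dose", "replicate")
    if (!all(need %in% colnames(df)))
      stop(sprintf("long dialect requires columns: %s", paste(need, collapse = ", ")))
    key <- paste(df$dose, df$replicate)
    groups <- split(df, factor(key, levels = unique(key)))
    w <- groups[[1L]]$wavenumber
    g <- .check_grid(w)
    if (!is.null(g)) stop(g)
    same <- vapply(groups, function(gr)
      length(gr$wavenumber) == length(w) && all(gr$wavenumber == w), TRUE)
    if (!all(same)) stop("all spectra must share one wavenumber grid (ragged input)")
    a <- vapply(groups, function(gr) gr$absorbance, numeric(length(w)))
    a <- matrix(a, nrow = length(w))
    SpectrumCollection(a, w,
                       dose = vapply(groups, function(gr) gr$dose[1L], 0),
                       replicate = vapply(groups, function(gr) as.integer(gr$replicate[1L]), 0L))
  }
}

.fmt_num <- function(x) {
  # >= 12 significant digits so read(write(x)) round-trips within 1e-12
  sub("e([+-])0*(\\d)", "e\\1\\2", formatC(x, digits = 15, format = "g"))
}

#' Write spectra to delimited text
#'
#' Serializes a [SpectrumCollection] in either dialect accepted by
#' [readSpectra()]; numbers carry at least 12 significant digits so a
#' round-trip reproduces absorbances to within 1e-12 and doses exactly.
#'
#' @param x a non-empty [SpectrumCollection]
#' @param path output file path
#' @param dialect `"wide"` or `"long"`
#' @return `invisible(path)`
#' @export
writeSpectra <- function(x, path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  stopifnot(methods::is(x, "SpectrumCollection"))
  if (ncol(x) == 0L) stop("refusing to write an empty SpectrumCollection")
  w <- wavenumbers(x)
  a <- absorbance(x)
  if (dialect == "wide") {
    df <- data.frame(wavenumber = .fmt_num(w), check.names = FALSE)
    hdr <- sprintf("%s:%d", vapply(doses(x), .fmt_num, ""), replicateIds(x))
    for (j in seq_len(ncol(a))) df[[hdr[j]]] <- .fmt_num(a[, j])
  } else {
    n <- length(w)
    df <- data.frame(
      wavenumber = .fmt_num(rep(w, ncol(a))),
      absorbance = .fmt_num(as.vector(a)),
      dose = vapply(rep(doses(x), each = n), .fmt_num, ""),
      replicate = rep(replicateIds(x), each = n))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
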