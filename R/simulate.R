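# Dose-structured synthetic FTIR spectra: sums of Gaussian vibrational bands
# whose centers/amplitudes respond to drug dose, plus replicate-level noise.

.logistic <- function(z) 1 / (1 + exp(-z))

# Magnitude decay of the difference-spectrum marker bands: full strength at
# the lowest exposed dose (0.125 ug/mL), declining linearly to 20% at 4 ug/mL.
.bis_decay <- function(dose) pmax(0.2, 1 - 0.8 * (dose - 0.125) / (4 - 0.125))

#' Default vibrational band table
#'
#' Band model for a cisplatin-exposed hepatocyte film.  DNA base bands:
#' guanine 1725 -> 1713 cm^-1 and thymine 1665 -> 1657 cm^-1 (platinum
#' adduct shifts switching on near 1.5 ug/mL), adenine 1613 and cytosine
#' 1499 cm^-1 unshifted; protein amide I beta-sheet 1639 -> 1624 cm^-1
#' (threshold 2 ug/mL); phosphate asymmetric/symmetric stretches 1228 and
#' 1087 cm^-1 unshifted; difference-spectrum marker components at 1648
#' (positive) and 1490 cm^-1 (negative) whose magnitude decays with dose;
#' and C-H stretch bands at 2852/2923/2958 cm^-1 so the upper window is
#' populated.
#'
#' Columns: `name`, `centerLow`/`centerHigh` (cm^-1 at zero/saturating
#' dose), `ampLow`/`ampHigh` (absorbance), `sigma` (Gaussian width, cm^-1),
#' `threshold` (ug/mL, logistic midpoint of the shift), `steepness`
#' ((ug/mL)^-1), `mode` (`fixed`, `shift` or `bis_decay`) and `excess`
#' (signed absorbance added at the lowest exposed dose, `bis_decay` only).
#'
#' @return a data.frame, one row per band
#' @export
defaultBandTable <- function() {
  tab <- rbind(
    data.frame(name = "guanine",        centerLow = 1725, centerHigh = 1713, ampLow = 0.30, sigma = 4, threshold = 1.5, steepness = 8, mode = "shift",     excess = 0),
    data.frame(name = "thymine",        centerLow = 1665, centerHigh = 1657, ampLow = 0.35, sigma = 4, threshold = 1.5, steepness = 8, mode = "shift",     excess = 0),
    data.frame(name = "adenine",        centerLow = 1613, centerHigh = 1613, ampLow = 0.30, sigma = 4, threshold = 0,   steepness = 8, mode = "fixed",     excess = 0),
    data.frame(name = "cytosine",       centerLow = 1499, centerHigh = 1499, ampLow = 0.25, sigma = 4, threshold = 0,   steepness = 8, mode = "fixed",     excess = 0),
    data.frame(name = "amide_beta",     centerLow = 1639, centerHigh = 1624, ampLow = 0.55, sigma = 4, threshold = 2.0, steepness = 8, mode = "shift",     excess = 0),
    data.frame(name = "bis_marker_pos", centerLow = 1648, centerHigh = 1648, ampLow = 0.10, sigma = 4, threshold = 0,   steepness = 8, mode = "bis_decay", excess = 0.10),
    data.frame(name = "bis_marker_neg", centerLow = 1490, centerHigh = 1490, ampLow = 0.20, sigma = 4, threshold = 0,   steepness = 8, mode = "bis_decay", excess = -0.10),
    data.frame(name = "phosphate_asym", centerLow = 1228, centerHigh = 1228, ampLow = 0.45, sigma = 4, threshold = 0,   steepness = 8, mode = "fixed",     excess = 0),
    data.frame(name = "phosphate_sym",  centerLow = 1087, centerHigh = 1087, ampLow = 0.50, sigma = 4, threshold = 0,   steepness = 8, mode = "fixed",     excess = 0),
    data.frame(name = "ch2_sym",        centerLow = 2852, centerHigh = 2852, ampLow = 0.35, sigma = 4, threshold = 0,   steepness = 8, mode = "fixed",     excess = 0),
    data.frame(name = "ch2_asym",       centerLow = 2923, centerHigh = 2923, ampLow = 0.65, sigma = 4, threshold = 0,   steepness = 8, mode = "fixed",     excess = 0),
    data.frame(name = "ch3_asym",       centerLow = 2958, centerHigh = 2958, ampLow = 0.40, sigma = 4, threshold = 0,   steepness = 8, mode = "fixed",     excess = 0))
  tab$ampHigh <- tab$ampLow
  tab[, c("name", "centerLow", "centerHigh", "ampLow", "ampHigh", "sigma",
          "threshold", "steepness", "mode", "excess")]
}

#' Band center at a given dose
#'
#' Shifted bands move from `centerLow` to `centerHigh` along a logistic
#' transition: `centerLow + (centerHigh - centerLow) *
#' logistic(steepness * (dose - threshold))`.  Unshifted and marker bands
#' stay at `centerLow`.
#'
#' @param band one row of a band table (data.frame or list)
#' @param dose concentration in ug/mL, >= 0
#' @return center in cm^-1
#' @export
bandCenterAtDose <- function(band, dose) {
  if (any(dose < 0)) stop("dose must be >= 0")
  if (identical(band$mode, "shift"))
    band$centerLow + (band$centerHigh - band$centerLow) *
      .logistic(band$steepness * (dose - band$threshold))
  else
    rep(band$centerLow, length(dose))
}

#' Band amplitude at a given dose
#'
#' `shift` bands interpolate `ampLow -> ampHigh` with the same logistic as
#' the center; `bis_decay` bands add a signed excess at exposed doses whose
#' magnitude decays linearly from full strength at 0.125 ug/mL to 20% at
#' 4 ug/mL; `fixed` bands are constant.
#'
#' @inheritParams bandCenterAtDose
#' @return amplitude in absorbance units
#' @export
bandAmplitudeAtDose <- function(band, dose) {
  if (any(dose < 0)) stop("dose must be >= 0")
  switch(band$mode,
    shift = band$ampLow + (band$ampHigh - band$ampLow) *
      .logistic(band$steepness * (dose - band$threshold)),
    bis_decay = band$ampLow + ifelse(dose > 0, band$excess * .bis_decay(dose), 0),
    rep(band$ampLow, length(dose)))
}

#' Generator configuration
#'
#' Collects everything that defines the simulated experiment: the band
#' table, the working grid (1000--3000 cm^-1 at 1 cm^-1), replicate-level
#' noise (additive Gaussian `noiseSD`, random linear baseline with offset /
#' slope standard deviations `baselineSD`, multiplicative `scaleJitterSD`),
#' the nine design concentrations and seven replicates of the assay, and
#' the generator seed.
#'
#' @param bands band table as from [defaultBandTable()]
#' @param wavenumber working grid in cm^-1
#' @param noiseSD additive noise standard deviation (absorbance units);
#'   default 0.0033, i.e. 0.5% of the tallest default band
#' @param baselineSD length-2: standard deviations of the random baseline
#'   offset (absorbance) and slope (absorbance per cm^-1)
#' @param scaleJitterSD relative multiplicative jitter
#' @param concentrations design doses in ug/mL
#' @param nReplicates replicates per concentration
#' @param seed generator seed
#' @return an object of class `GeneratorConfig` (a validated list)
#' @export
generatorConfig <- function(bands = defaultBandTable(),
                            wavenumber = seq(1000, 3000, by = 1),
                            noiseSD = 0.0033,
                            baselineSD = c(offset = 0.02, slope = 1e-5),
                            scaleJitterSD = 0.02,
                            concentrations = c(0, 0.125, 0.25, 0.5, 1, 1.5, 2, 3, 4),
                            nReplicates = 7L,
                            seed = 1L) {
  g <- .check_grid(wavenumber)
  if (!is.null(g)) stop(g)
  stopifnot(is.data.frame(bands), all(bands$sigma > 0),
            all(bands$ampLow >= 0), all(bands$threshold >= 0),
            length(baselineSD) == 2L, noiseSD >= 0, scaleJitterSD >= 0,
            all(concentrations >= 0), nReplicates >= 1L)
  structure(list(bands = bands, wavenumber = wavenumber, noiseSD = noiseSD,
                 baselineSD = unname(baselineSD), scaleJitterSD = scaleJitterSD,
                 concentrations = concentrations,
                 nReplicates = as.integer(nReplicates), seed = as.integer(seed)),
            class = "GeneratorConfig")
}

#' Noise-free generator configuration
#'
#' Convenience wrapper setting every replicate-level noise term to zero, so
#' generation is deterministic and independent of the seed.
#'
#' @param ... passed to [generatorConfig()]
#' @export
noiseFreeConfig <- function(...) {
  generatorConfig(noiseSD = 0, baselineSD = c(0, 0), scaleJitterSD = 0, ...)
}

# Deterministic band-sum spectrum at one dose (no noise terms).
.pure_spectrum <- function(dose, config) {
  w <- config$wavenumber
  a <- numeric(length(w))
  for (i in seq_len(nrow(config$bands))) {
    band <- config$bands[i, ]
    ctr <- bandCenterAtDose(band, dose)
    amp <- bandAmplitudeAtDose(band, dose)
    a <- a + amp * exp(-0.5 * ((w - ctr) / band$sigma)^2)
  }
  a
}

#' Generate one synthetic spectrum
#'
#' Sum of Gaussian bands at dose-adjusted centers and amplitudes, plus a
#' random linear baseline, multiplicative scale jitter and i.i.d. Gaussian
#' noise.  With all noise terms zero the result is the deterministic
#' noise-free spectrum.  Draws from the current RNG state unless `seed` is
#' given.
#'
#' @param dose concentration in ug/mL, >= 0
#' @param config a [generatorConfig()]
#' @param replicate replicate id stored in the metadata
#' @param seed optional seed for this one draw
#' @return a one-column [SpectrumCollection]
#' @export
generateSpectrum <- function(dose, config = generatorConfig(), replicate = 1L,
                             seed = NULL) {
  stopifnot(inherits(config, "GeneratorConfig"))
  if (dose < 0) stop("dose must be >= 0")
  draw <- function() {
    a <- .pure_spectrum(dose, config)
    scale <- 1 + stats::rnorm(1L, sd = config$scaleJitterSD)
    base <- stats::rnorm(1L, sd = config$baselineSD[1L]) +
      stats::rnorm(1L, sd = config$baselineSD[2L]) *
        (config$wavenumber - config$wavenumber[1L])
    a <- pmax(a * scale + base +
                stats::rnorm(length(a), sd = config$noiseSD), 0)
    SpectrumCollection(matrix(a, ncol = 1L), config$wavenumber,
                       dose = dose, replicate = replicate)
  }
  if (is.null(seed)) draw() else .with_seed(seed, draw())
}

#' Generate the full designed experiment
#'
#' `nReplicates` spectra at each design concentration (9 x 7 = 63 under the
#' defaults), deterministic given the config seed.
#'
#' @param config a [generatorConfig()]
#' @return a [SpectrumCollection]
#' @export
generateDesign <- function(config = generatorConfig()) {
  stopifnot(inherits(config, "GeneratorConfig"))
  .with_seed(config$seed, {
    cols <- list()
    dose <- rep(config$concentrations, each = config$nReplicates)
    repl <- rep(seq_len(config$nReplicates), times = length(config$concentrations))
    for (i in seq_along(dose))
      cols[[i]] <- absorbance(generateSpectrum(dose[i], config, repl[i]))
    SpectrumCollection(do.call(cbind, cols), config$wavenumber, dose, repl)
  })
}

#' Simulate a clonogenic assay
#'
#' Seeds `nCells` per well; colony survival follows a binomial law with
#' survival probability `1 - Hill(dose)` where `Hill` is the two-parameter
#' mortality curve with `ec50` and `slope` and asymptotes 0/100.  Mortality
#' is referenced to the control well: `100 (1 - colonies / colonies_at_0)`.
#'
#' @param doses concentrations in ug/mL (the control dose 0 should be included)
#' @param nCells cells seeded per well
#' @param ec50 half-lethal concentration of the generating truth (ug/mL)
#' @param slope Hill coefficient of the generating truth
#' @param seed optional seed
#' @return data.frame with columns `dose`, `colonies`, `mortality` (percent)
#' @export
simulateClonogenic <- function(doses = c(0, 0.125, 0.25, 0.5, 1, 1.5, 2, 3, 4),
                               nCells = 100L, ec50 = 0.3, slope = 1.6,
                               seed = NULL) {
  stopifnot(nCells >= 1L, ec50 > 0, slope > 0, all(doses >= 0))
  draw <- function() {
    surv <- 1 - .hill_mortality(doses, ec50, slope) / 100
    colonies <- stats::rbinom(length(doses), nCells, surv)
    ref <- if (any(doses == 0)) colonies[match(0, doses)] else nCells
    if (ref <= 0) stop("control well produced no colonies; cannot reference mortality")
    data.frame(dose = doses, colonies = colonies,
               mortality = pmin(pmax(100 * (1 - colonies / ref), 0), 100))
  }
  if (is.null(seed)) draw() else .with_seed(seed, draw())
}
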