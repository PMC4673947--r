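test_that("default band table carries the assigned bands", {
  tab <- defaultBandTable()
  g <- tab[tab$name == "guanine", ]
  expect_equal(g$centerLow, 1725)
  expect_equal(g$centerHigh, 1713)
  t <- tab[tab$name == "thymine", ]
  expect_equal(c(t$centerLow, t$centerHigh), c(1665, 1657))
  # unshifted phosphate stretches
  expect_equal(sort(tab$centerLow[grepl("phosphate", tab$name)]), c(1087, 1228))
  expect_true(all(tab$mode[grepl("phosphate", tab$name)] == "fixed"))
  # every no-shift band keeps one center
  noshift <- tab[tab$mode != "shift", ]
  expect_equal(noshift$centerLow, noshift$centerHigh)
  expect_true(all(tab$sigma > 0) && all(tab$ampLow >= 0))
})

test_that("band centers follow the logistic dose transition", {
  tab <- defaultBandTable()
  g <- tab[tab$name == "guanine", ]
  # at the threshold dose the center sits at the midpoint
  expect_equal(bandCenterAtDose(g, 1.5), (1725 + 1713) / 2)
  # far above threshold: logistic(8 * 1.5) evaluated independently
  expected <- 1725 + (1713 - 1725) / (1 + exp(-8 * (3 - 1.5)))
  expect_equal(bandCenterAtDose(g, 3), expected, tolerance = 1e-12)
  expect_lt(abs(bandCenterAtDose(g, 3) - 1713), 0.01)
  # no-shift band pinned at centerLow for any dose
  a <- tab[tab$name == "adenine", ]
  expect_equal(bandCenterAtDose(a, c(0, 1, 4)), rep(1613, 3))
  expect_error(bandCenterAtDose(g, -1), ">= 0")
})

test_that("shifted band centers are monotone in dose and bounded", {
  tab <- defaultBandTable()
  dd <- seq(0, 4, by = 0.05)
  for (nm in tab$name[tab$mode == "shift"]) {
    band <- tab[tab$name == nm, ]
    ctr <- bandCenterAtDose(band, dd)
    expect_true(all(diff(ctr) < 0))  # all default shifts go downfield
    expect_true(all(ctr <= max(band$centerLow, band$centerHigh) &
                    ctr >= min(band$centerLow, band$centerHigh)))
  }
})

test_that("noise-free spectra place the band apices where assigned", {
  tr0 <- nf_trace(0); tr3 <- nf_trace(3)
  win <- tr0$w >= 1690 & tr0$w <= 1740
  expect_equal(tr0$w[win][which.max(tr0$a[win])], 1725)
  expect_equal(tr3$w[win][which.max(tr3$a[win])], 1713)
})

test_that("noise-free generation is deterministic and seed-independent", {
  a1 <- absorbance(generateSpectrum(2, noiseFreeConfig(), seed = 1L))
  a2 <- absorbance(generateSpectrum(2, noiseFreeConfig(), seed = 999L))
  expect_identical(a1, a2)
})

test_that("same seed reproduces a noisy spectrum; different seed does not", {
  cfg <- generatorConfig()
  a1 <- absorbance(generateSpectrum(1, cfg, seed = 42L))
  a2 <- absorbance(generateSpectrum(1, cfg, seed = 42L))
  a3 <- absorbance(generateSpectrum(1, cfg, seed = 43L))
  expect_identical(a1, a2)
  expect_false(identical(a1, a3))
})

test_that("the designed experiment has the right layout and determinism", {
  cfg <- generatorConfig(seed = 5L)
  x <- generateDesign(cfg)
  expect_identical(ncol(x), 63L)               # 9 concentrations x 7 replicates
  expect_identical(sum(doses(x) == 0), 7L)
  expect_identical(absorbance(x), absorbance(generateDesign(cfg)))
  y <- generateDesign(generatorConfig(seed = 6L))
  expect_false(identical(absorbance(x), absorbance(y)))
  small <- generateDesign(generatorConfig(concentrations = c(0, 1),
                                          nReplicates = 1L))
  expect_identical(ncol(small), 2L)
})

test_that("the 2000-2500 region is silent by construction", {
  for (dose in c(0, 0.5, 2, 4)) {
    tr <- nf_trace(dose)
    silent <- tr$w >= 2000 & tr$w <= 2500
    expect_lt(max(tr$a[silent]), 0.01 * max(tr$a))
  }
})

test_that("simulated clonogenic mortality behaves like the Hill truth", {
  # control is always 0% (survival probability 1 at dose 0)
  tab <- simulateClonogenic(seed = 1L)
  expect_equal(tab$mortality[tab$dose == 0], 0)
  expect_true(all(tab$mortality >= 0 & tab$mortality <= 100))
  # binomial concentration: at the EC50 with a huge well, mortality ~ 50%
  big <- simulateClonogenic(doses = c(0, 0.3), nCells = 1e6L,
                            ec50 = 0.3, slope = 1.6, seed = 2L)
  expect_lt(abs(big$mortality[big$dose == 0.3] - 50), 0.5)
  # saturating dose kills everything in expectation
  sat <- simulateClonogenic(doses = c(0, 1e6), nCells = 1e4L, seed = 3L)
  expect_gt(sat$mortality[sat$dose == 1e6], 99)
  # non-decreasing in dose in expectation: average many runs
  reps <- sapply(1:30, function(s)
    simulateClonogenic(nCells = 1000L, seed = s)$mortality)
  expect_true(all(diff(rowMeans(reps)) > -0.5))
})

test_that("marker-band magnitude decays with dose in the generator", {
  tab <- defaultBandTable()
  pos <- tab[tab$name == "bis_marker_pos", ]
  dd <- c(0.125, 0.25, 0.5, 1, 1.5, 2, 3, 4)
  amp <- bandAmplitudeAtDose(pos, dd)
  expect_true(all(diff(amp) < 0))
  # floor at 20% of the lowest-dose excess
  expect_equal(amp[length(amp)] - pos$ampLow, 0.2 * pos$excess)
})
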