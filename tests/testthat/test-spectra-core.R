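test_that("constructor validates the wavenumber grid and metadata", {
  w <- seq(1000, 1004, by = 1)
  a <- matrix(runif(10), 5)
  expect_s4_class(SpectrumCollection(a, w, dose = c(0, 1), replicate = c(1L, 1L)),
                  "SpectrumCollection")
  # non-uniform spacing
  expect_error(SpectrumCollection(matrix(runif(3)), c(1000, 1002, 1003), 0, 1L),
               "uniform")
  # non-monotone
  expect_error(SpectrumCollection(matrix(runif(3)), c(1000, 999, 1001), 0, 1L),
               "increasing")
  # outside instrument range
  expect_error(SpectrumCollection(matrix(runif(3)), c(100, 101, 102), 0, 1L),
               "400-4000")
  # duplicate replicate within a dose group
  expect_error(SpectrumCollection(a, w, dose = c(1, 1), replicate = c(2L, 2L)),
               "unique")
})

test_that("wide and long dialects round-trip exactly", {
  x <- toy_collection(n_points = 15L, n_spec = 4L)
  for (dialect in c("wide", "long")) {
    path <- withr::local_tempfile(fileext = ".csv")
    writeSpectra(x, path, dialect)
    y <- readSpectra(path, dialect)
    expect_identical(doses(y), doses(x))
    expect_identical(replicateIds(y), replicateIds(x))
    expect_equal(wavenumbers(y), wavenumbers(x), tolerance = 1e-12)
    expect_lt(max(abs(absorbance(y) - absorbance(x))), 1e-12)
  }
})

test_that("wide reader enforces its format", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wn,0:1", "1000,0.5", "1001,0.6"), path)
  expect_error(readSpectra(path, "wide"), "wavenumber")
  writeLines(c("wavenumber,spec1", "1000,0.5", "1001,0.6"), path)
  expect_error(readSpectra(path, "wide"), "dose:replicate")
  writeLines(c("wavenumber,0:1", "1000,0.5", "1002,0.6", "1003,0.7"), path)
  expect_error(readSpectra(path, "wide"), "uniform")
  expect_error(readSpectra(file.path(tempdir(), "absent.csv"), "wide"),
               "not found")
})

test_that("long reader rejects ragged grids and missing columns", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavenumber,absorbance,dose", "1000,0.5,0"), path)
  expect_error(readSpectra(path, "long"), "requires columns")
  writeLines(c("wavenumber,absorbance,dose,replicate",
               "1000,0.5,0,1", "1001,0.6,0,1",
               "1000,0.4,1,1"), path)
  expect_error(readSpectra(path, "long"), "ragged")
})

test_that("writing an empty collection errors", {
  x <- toy_collection()[, 0]
  expect_error(writeSpectra(x, tempfile(), "wide"), "empty")
})

test_that("a wide file with one spectrum over 3 points has 4 lines", {
  x <- SpectrumCollection(matrix(c(0.1, 0.2, 0.3)), c(1500, 1501, 1502), 0.5, 1L)
  path <- withr::local_tempfile(fileext = ".csv")
  writeSpectra(x, path, "wide")
  expect_length(readLines(path), 4L)
})

test_that("extractWindow keeps the closed interval and is idempotent", {
  x <- generateSpectrum(0, noiseFreeConfig())
  # closed-interval point count on the 1 cm^-1 grid, counted independently
  w <- wavenumbers(x)
  expect_identical(sum(w >= 2500 & w <= 3000), 501L)
  win <- extractWindow(x, 2500, 3000)
  expect_identical(nrow(win), 501L)
  expect_equal(range(wavenumbers(win)), c(2500, 3000))
  # identity window and idempotence
  expect_equal(absorbance(extractWindow(x, 1000, 3000)), absorbance(x))
  expect_equal(absorbance(extractWindow(win, 2500, 3000)), absorbance(win))
  # metadata preserved
  expect_identical(doses(win), doses(x))
  # empty overlap and bad bounds
  expect_error(extractWindow(x, 100, 200), "no overlap")
  expect_error(extractWindow(x, 2000, 1500), "lo < hi")
})

test_that("resampling is exact on shared points and linear in between", {
  w <- seq(1000, 1010, by = 1)
  vals <- c(0.3, 1, 0.2, 0.8, 0.5, 0.9, 0.1, 0.6, 0.4, 0.7, 0.2)
  x <- SpectrumCollection(matrix(vals), w, 0, 1L)
  # own grid -> identical
  expect_equal(absorbance(resampleSpectra(x, w)), absorbance(x))
  # interior half-step grid: expected values from the linear-interpolation
  # closed form, computed independently of the implementation
  tgt <- seq(1000.5, 1009.5, by = 1)
  expected <- (vals[1:10] + vals[2:11]) / 2
  got <- absorbance(resampleSpectra(x, tgt))[, 1L]
  expect_equal(got, expected, tolerance = 1e-14, ignore_attr = TRUE)
  # midpoint worked example
  x2 <- SpectrumCollection(matrix(c(0, 2)), c(1000, 1002), 0, 1L)
  # grid of length 2 with spacing 1 overlapping: query 1001 via 3-point grid
  x3 <- resampleSpectra(x2, c(1000, 1001, 1002))
  expect_equal(absorbance(x3)[2L, 1L], 1)
  # extrapolation refused
  expect_error(resampleSpectra(x, seq(999, 1009, by = 1)), "extrapolation")
})

test_that("resampling recovers piecewise-linear signals at random interior grids", {
  w <- seq(1200, 1240, by = 2)
  for (seed in 1:5) {
    vals <- .with_toy_seed(seed, runif(length(w)))
    x <- SpectrumCollection(matrix(vals), w, 0, 1L)
    off <- .with_toy_seed(seed + 100, runif(1, 0.1, 1.9))
    tgt <- seq(1200 + off, 1238 + off, by = 2)
    lin <- stats::approxfun(w, vals)   # same closed form, reference path
    manual <- vapply(tgt, function(q) {
      i <- findInterval(q, w)
      vals[i] + (vals[i + 1L] - vals[i]) * (q - w[i]) / (w[i + 1L] - w[i])
    }, 0)
    expect_equal(absorbance(resampleSpectra(x, tgt))[, 1L], manual,
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(manual, lin(tgt), tolerance = 1e-12)
  }
})
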