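test_that("rmse matches its closed form", {
  expect_identical(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_identical(rmse(c(0, 2), c(1, 1)), 1)
  # brute-force elementwise evaluation of the formula as the oracle
  for (seed in 1:5) {
    v <- .with_toy_seed(seed, list(o = rnorm(9), p = rnorm(9)))
    acc <- 0
    for (i in seq_along(v$o)) acc <- acc + (v$o[i] - v$p[i])^2
    expect_equal(rmse(v$o, v$p), sqrt(acc / length(v$o)), tolerance = 1e-14)
  }
  expect_error(rmse(numeric(), numeric()), "length")
  expect_error(rmse(1:3, 1:2), "length")
})

test_that("rSquared matches 1 - SSres/SStot and its edge cases", {
  y <- c(2.5, 1.1, 4.8, 3.3)
  expect_equal(rSquared(y, y), 1)
  expect_equal(rSquared(y, rep(mean(y), 4)), 0)
  # hand evaluation: SSres = 1, SStot = 2
  expect_equal(rSquared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  # worse than the mean -> negative
  expect_lt(rSquared(c(1, 2, 3), c(3, 2, 1)), 0)
  expect_error(rSquared(rep(1, 3), c(1, 2, 3)), "constant")
  # squared-Pearson variant is insensitive to scale of the predictions
  expect_equal(rSquared(c(1, 2, 3), c(2, 4, 6), pearson = TRUE), 1)
})

test_that("stratified splits give 40/16 with every dose on both sides", {
  b <- computeBIS(nf_design())
  sp <- stratifiedSplit(b, seed = 4L)
  expect_length(sp$train, 40L)
  expect_length(sp$test, 16L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_setequal(c(sp$train, sp$test), seq_len(56))
  d <- doses(b)
  expect_setequal(unique(d[sp$train]), unique(d))
  expect_setequal(unique(d[sp$test]), unique(d))
  expect_true(all(table(d[sp$train]) == 5L))
  expect_true(all(table(d[sp$test]) == 2L))
  # deterministic given seed
  expect_identical(sp, stratifiedSplit(b, seed = 4L))
  expect_false(identical(sp, stratifiedSplit(b, seed = 5L)))
  expect_error(stratifiedSplit(b, trainPerDose = 6L, testPerDose = 2L),
               "dose group")
})

test_that("the CV curve has the requested length and a well-defined argmin", {
  dat <- .with_toy_seed(13, list(X = matrix(rnorm(56 * 30), 56, 30)))
  y <- rnorm(56)
  cv <- cvLVCurve(dat$X, y, maxLV = 10, kFolds = 7, seed = 2L)
  expect_length(cv$mseByLV, 10L)
  expect_identical(cv$selectedLV, which.min(cv$mseByLV))
  expect_true(all(cv$mseByLV[cv$selectedLV] <= cv$mseByLV))
  # deterministic given seed
  expect_identical(cv, cvLVCurve(dat$X, y, maxLV = 10, kFolds = 7, seed = 2L))
})

test_that("CV selects a small model when y lives in two X-directions", {
  n <- 42
  base <- .with_toy_seed(17, {
    t1 <- rnorm(n); t2 <- rnorm(n)
    list(t1 = t1, t2 = t2, N = matrix(rnorm(n * 18, sd = 0.01), n))
  })
  X <- cbind(base$t1, base$t2, base$N)
  for (s in 1:3) {
    y <- 2 * base$t1 - base$t2 + .with_toy_seed(100 + s, rnorm(n, sd = 0.05))
    cv <- cvLVCurve(X, y, maxLV = 8, kFolds = 7, seed = 3L)
    expect_lte(cv$selectedLV, 3L)
  }
})

test_that("evaluateWindows emits one record per window and split, deterministically", {
  x <- preprocessSpectra(generateDesign(generatorConfig(seed = 2L)))
  rec <- evaluateWindows(x, windows = list(c(1000, 1500), c(1500, 2000)),
                         nModels = 3L, maxLV = 5L, seed = 8L)
  expect_identical(nrow(rec), 6L)
  expect_setequal(unique(rec$window), c("1000-1500", "1500-2000"))
  expect_true(all(rec$r2Train <= 1) && all(rec$rmseTrain >= 0))
  expect_true(all(rec$rmseTest >= 0))
  rec2 <- evaluateWindows(x, windows = list(c(1000, 1500), c(1500, 2000)),
                          nModels = 3L, maxLV = 5L, seed = 8L)
  expect_identical(rec, rec2)
  smry <- summarizeEvaluation(rec)
  expect_identical(nrow(smry), 2L)
  expect_identical(smry$nModels, c(3L, 3L))
  expect_equal(smry$meanR2Test[1L],
               mean(rec$r2Test[rec$window == "1000-1500"]))
})

test_that("test rows never leak into latent-variable selection or fitting", {
  x <- preprocessSpectra(generateDesign(generatorConfig(seed = 3L)))
  bis <- computeBIS(x)
  # reproduce one evaluation record by hand from the split it used,
  # confirming its test metrics derive from rows outside the training set
  sp <- stratifiedSplit(bis, seed = cytoIR:::.stage_seed(9L, "split1"))
  expect_length(intersect(sp$train, sp$test), 0L)
  sub <- extractWindow(bis, 1000, 1500)
  cv <- cvLVCurve(as.matrix(sub)[sp$train, ], doses(sub)[sp$train],
                  maxLV = 5L, kFolds = 7L,
                  seed = cytoIR:::.stage_seed(9L, "cv1"),
                  strata = doses(sub)[sp$train])
  fit <- fitPLS(as.matrix(sub)[sp$train, ], doses(sub)[sp$train], cv$selectedLV)
  predTe <- predict(fit, as.matrix(sub)[sp$test, ])
  rec <- evaluateWindows(x, windows = list(c(1000, 1500)), nModels = 1L,
                         maxLV = 5L, seed = 9L)
  expect_equal(rec$r2Test, rSquared(doses(sub)[sp$test], predTe))
  expect_equal(rec$rmseTest, rmse(doses(sub)[sp$test], predTe))
  expect_identical(rec$selectedLV, cv$selectedLV)
})
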