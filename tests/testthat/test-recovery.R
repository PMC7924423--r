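test_that("operator application agrees with the dense contraction oracle", {
  set.seed(4)
  X <- matrix(rnorm(80), 8, 10)
  ms <- ksparseMeasurements(X, k = 3, p = 100, seed = 9)
  dense <- vapply(seq_len(100), function(i)
    sum(denseSensingMatrix(ms, i) * X), numeric(1))
  expect_equal(applyOperator(ms, X), dense, tolerance = 1e-12)

  # factored evaluation agrees with the densified one
  b <- drawBias(8, 10, 3, seed = 2)
  expect_equal(applyOperator(ms, b), applyOperator(ms, as.matrix(b)),
               tolerance = 1e-12)
  expect_error(applyOperator(ms, matrix(0, 3, 3)), "dimensions")
})

test_that("relative error behaves as a normalized Frobenius distance", {
  set.seed(5)
  X <- matrix(rnorm(25), 5, 5)
  expect_equal(relativeError(X, X), 0)
  expect_equal(relativeError(matrix(0, 5, 5), X), 1)
  expect_equal(relativeError(2 * X, X), 1)
  expect_error(relativeError(X, matrix(0, 5, 5)), "zero norm")
})

test_that("full entry observation recovers a low-rank matrix exactly", {
  X <- as.matrix(drawBias(10, 10, 2, seed = 3))
  pos <- as.matrix(expand.grid(row = 1:10, col = 1:10))
  ms <- entryMeasurements(pos, X[pos], dims = c(10, 10))
  fit <- recoverBias(ms, 2, quietSolver(seed = 1))
  expect_lt(relativeError(fit, X), 1e-6)
})

test_that("full observation of a general matrix yields its truncated SVD", {
  # Eckart-Young: with every entry measured, the rank-1 minimizer is the
  # leading singular component -- an independent closed-form oracle
  set.seed(12)
  `T` <- matrix(rnorm(36), 6, 6)
  pos <- as.matrix(expand.grid(row = 1:6, col = 1:6))
  ms <- entryMeasurements(pos, `T`[pos], dims = c(6, 6))
  fit <- recoverBias(ms, 1, quietSolver(seed = 2, maxIterations = 2000,
                                        gradientTolerance = 1e-10))
  sv <- svd(`T`)
  best1 <- sv$d[1] * tcrossprod(sv$u[, 1], sv$v[, 1])
  expect_lt(max(abs(as.matrix(fit) - best1)), 1e-6)
})

test_that("solver objective is monotone along accepted iterates", {
  db <- assembleDatabase(smallPairedConfig(seed = 8))
  ms <- blindMeasurements(observedMatrix(db), oracleRedundancies(db),
                          center = FALSE)
  fit <- suppressWarnings(recoverBias(ms, 2, solverSettings(restarts = 1,
                                                            seed = 3)))
  tr <- solverDiagnostics(fit)$objectiveTrace
  expect_gte(length(tr), 2L)
  expect_true(all(diff(tr) <= 1e-12))
})

test_that("recovery from noiseless 2-sparse measurements is accurate", {
  db <- assembleDatabase(evaluationConfig(biasRank = 2, seed = 17))
  X <- biasMatrix(db)
  ms <- ksparseMeasurements(X, k = 2, p = 1000, seed = 4)
  fit <- suppressWarnings(recoverBias(ms, 2, quietSolver(seed = 5)))
  expect_lt(relativeError(fit, X), 1e-3)
})

test_that("non-convergence is reported, never silent", {
  db <- assembleDatabase(smallPairedConfig(seed = 19))
  ms <- blindMeasurements(observedMatrix(db), oracleRedundancies(db),
                          center = FALSE)
  expect_warning(
    recoverBias(ms, 2, solverSettings(restarts = 1, maxIterations = 3,
                                      seed = 1)),
    "tolerance not reached")
})

test_that("measurement subsampling cap is honored", {
  db <- assembleDatabase(evaluationConfig(seed = 23))
  ms <- blindMeasurements(observedMatrix(db), oracleRedundancies(db),
                          center = FALSE)
  fit <- suppressWarnings(
    recoverBias(ms, 2, quietSolver(seed = 2, maxMeasurements = 800)))
  expect_equal(solverDiagnostics(fit)$measurements, 800L)
})

test_that("hold-out rank selection identifies the true rank", {
  picks <- vapply(1:5, function(s) {
    db <- assembleDatabase(evaluationConfig(biasRank = 2, n = 30, m = 30,
                                            seed = s))
    ms <- blindMeasurements(observedMatrix(db), oracleRedundancies(db),
                            center = FALSE)
    ms <- sampleMeasurements(ms, 700, seed = s)
    selectRank(ms, 1:4, settings = quietSolver(), seed = s)$rank
  }, integer(1))
  expect_gte(mean(picks == 2L), 0.8)

  # single candidate returned unconditionally; ties break to smaller rank
  db <- assembleDatabase(smallPairedConfig(seed = 31))
  ms <- blindMeasurements(observedMatrix(db), oracleRedundancies(db),
                          center = FALSE)
  expect_equal(selectRank(ms, 3L)$rank, 3L)
})

test_that("bias subtraction restores the signal and preserves missingness", {
  cfg <- simulationConfig(20, 20, biasRank = 2,
                          featureBlockSizes = rep(2L, 10),
                          sampleBlockSizes = rep(2L, 10),
                          missingMechanism = "MAR", missingRate = 0.15,
                          seed = 44)
  db <- assembleDatabase(cfg)
  O <- observedMatrix(db)
  # zero estimate: identity
  zero <- matrix(0, 20, 20)
  expect_identical(subtractBias(O, zero), O)
  # oracle estimate: recovers the signal exactly at observed entries
  corrected <- subtractBias(O, db@bias)
  keep <- !missingMask(db)
  expect_lt(max(abs(corrected[keep] - signalMatrix(db)[keep])), 1e-8)
  expect_identical(is.na(corrected), missingMask(db))
})
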