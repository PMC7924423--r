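test_that("covariance factors reproduce D C D for the block design", {
  # independence: rho = 0 gives a diagonal covariance of variances
  cfg0 <- simulationConfig(4, 4, biasRank = 1, featureBlockSizes = c(2L, 2L),
                           withinBlockCorrelation = 0, seed = 7)
  f0 <- buildCovarianceFactors(cfg0)
  A0 <- as.matrix(f0$feature)
  expect_equal(A0 %*% t(A0), diag(f0$featureStd^2), tolerance = 1e-12)

  # perfect correlation: 2-block of AA^T is the rank-1 [[s1^2, s1 s2], ...]
  cfg1 <- simulationConfig(2, 2, biasRank = 1, featureBlockSizes = 2L,
                           withinBlockCorrelation = 1, seed = 7)
  f1 <- buildCovarianceFactors(cfg1)
  s <- f1$featureStd
  cov1 <- as.matrix(f1$feature %*% Matrix::t(f1$feature))
  expect_equal(cov1, outer(s, s), tolerance = 1e-12)
  expect_equal(qr(cov1)$rank, 1L)

  # rho = 0.7, block of 3: brute-force D C D oracle
  cfg7 <- simulationConfig(3, 3, biasRank = 1, featureBlockSizes = 3L,
                           withinBlockCorrelation = 0.7, seed = 7)
  f7 <- buildCovarianceFactors(cfg7)
  C <- matrix(0.7, 3, 3); diag(C) <- 1
  D <- diag(f7$featureStd)
  expect_equal(as.matrix(f7$feature %*% Matrix::t(f7$feature)),
               D %*% C %*% D, tolerance = 1e-12)
})

test_that("signal draw honors the covariance structure", {
  # identity factors: i.i.d. standard normal entries
  cfg <- simulationConfig(4, 4, biasRank = 1, seed = 5)
  ident <- list(feature = Matrix::Diagonal(4), sample = Matrix::Diagonal(4),
                featureStd = rep(1, 4), sampleStd = rep(1, 4))
  s1 <- drawSignal(cfg, ident, seed = 99)
  set.seed(99)
  expect_equal(s1$S, matrix(rnorm(16), 4, 4))

  # rho = 1 pair: rows exactly proportional with slope sdB/sdA
  cfgP <- simulationConfig(2, 50, biasRank = 1, featureBlockSizes = 2L,
                           withinBlockCorrelation = 1, seed = 3)
  fP <- buildCovarianceFactors(cfgP)
  sP <- drawSignal(cfgP, fP)
  ratio <- fP$featureStd[2] / fP$featureStd[1]
  expect_lt(max(abs(sP$S[2, ] - ratio * sP$S[1, ])), 1e-12)

  # rho = 0.7 pair: Monte-Carlo correlation over many columns
  cfgC <- simulationConfig(2, 100000, biasRank = 1, featureBlockSizes = 2L,
                           withinBlockCorrelation = 0.7, seed = 3)
  fC <- buildCovarianceFactors(cfgC)
  sC <- drawSignal(cfgC, fC)
  expect_equal(cor(sC$S[1, ], sC$S[2, ]), 0.7, tolerance = 0.01)
})

test_that("bias draw lies on the Stiefel manifold at the requested rank", {
  b <- drawBias(50, 50, 5, seed = 2)
  expect_lt(max(abs(crossprod(b@U) - diag(5))), 1e-10)
  expect_lt(max(abs(crossprod(b@V) - diag(5))), 1e-10)
  expect_equal(sum(svd(as.matrix(b))$d > 1e-10), 5L)
  expect_true(all(b@sigma > 0 & b@sigma < 1))
  expect_false(is.unsorted(rev(b@sigma)))

  # rank 1: every 2x2 minor vanishes
  b1 <- as.matrix(drawBias(6, 6, 1, seed = 4))
  minors <- outer(1:5, 1:5, Vectorize(function(i, j)
    b1[i, j] * b1[i + 1, j + 1] - b1[i, j + 1] * b1[i + 1, j]))
  expect_lt(max(abs(minors)), 1e-12)

  # determinism and backend-stable sign convention
  expect_identical(as.matrix(drawBias(10, 8, 3, seed = 11)),
                   as.matrix(drawBias(10, 8, 3, seed = 11)))
  expect_error(drawBias(5, 5, 6), "rank")
})

test_that("bias scaling hits the requested bias-to-signal ratio exactly", {
  set.seed(1)
  S <- matrix(rnorm(100), 10, 10)
  b <- drawBias(10, 10, 2, seed = 1)
  for (snr in c(0.5, 1, 2)) {
    Xs <- scaleBiasToSnr(b, S, snr)
    expect_equal(sqrt(sum(as.matrix(Xs)^2)) / sqrt(sum(S^2)), snr,
                 tolerance = 1e-10)
  }
  # doubling snr doubles the norm; matrix input path agrees with factored
  X1 <- scaleBiasToSnr(as.matrix(b), S, 1)
  X2 <- scaleBiasToSnr(as.matrix(b), S, 2)
  expect_equal(sqrt(sum(X2^2)), 2 * sqrt(sum(X1^2)), tolerance = 1e-12)
  expect_equal(X1, as.matrix(scaleBiasToSnr(b, S, 1)), tolerance = 1e-12)
  expect_error(scaleBiasToSnr(matrix(0, 2, 2), S, 1), "zero")
})

test_that("missingness mechanisms mask at the requested rate", {
  set.seed(2)
  V <- matrix(rnorm(2500), 50, 50)
  expect_identical(applyMissingness(V, "none", 0.5), matrix(FALSE, 50, 50))
  expect_identical(applyMissingness(V, "MAR", 0), matrix(FALSE, 50, 50))

  # MAR: binomial Monte-Carlo over 100 seeds
  fr <- vapply(1:100, function(s)
    mean(applyMissingness(V, "MAR", 0.2, seed = s)), numeric(1))
  expect_equal(mean(fr), 0.2, tolerance = 0.02)

  # MNAR at steepness 0 reduces to MAR (uniform masking probability)
  frm <- vapply(1:100, function(s)
    mean(applyMissingness(V, "MNAR", 0.2, steepness = 0, seed = s)),
    numeric(1))
  expect_equal(mean(frm), 0.2, tolerance = 0.02)
  lowHi <- vapply(1:50, function(s) {
    mk <- applyMissingness(V, "MNAR", 0.2, steepness = 0, seed = s)
    mean(V[mk]) - mean(V[!mk])
  }, numeric(1))
  expect_equal(mean(lowHi), 0, tolerance = 0.05)

  # steep MNAR preferentially masks low values
  mk <- applyMissingness(V, "MNAR", 0.3, steepness = 5, seed = 9)
  expect_lt(mean(V[mk]), mean(V[!mk]))
  expect_equal(mean(mk), 0.3, tolerance = 0.05)
})

test_that("assembled databases satisfy the ground-truth invariants", {
  cfg <- smallPairedConfig(seed = 21, biasRank = 3, n = 30, m = 30,
                           snr = 1.5)
  db <- assembleDatabase(cfg)
  X <- biasMatrix(db); S <- signalMatrix(db); O <- observedMatrix(db)
  expect_lt(max(abs(O - X - S), na.rm = TRUE), 1e-12)
  expect_equal(sqrt(sum(X^2)) / sqrt(sum(S^2)), 1.5, tolerance = 1e-10)
  expect_equal(db@bias@rank, 3L)
  expect_equal(sum(svd(X)$d > 1e-10), 3L)

  # identical seed, bit-identical database
  db2 <- assembleDatabase(smallPairedConfig(seed = 21, biasRank = 3,
                                            n = 30, m = 30, snr = 1.5))
  expect_identical(observedMatrix(db2), O)
  expect_identical(as.matrix(db2@bias), X)

  # missingness plumbed through: NA pattern equals the mask
  cfgM <- simulationConfig(20, 20, biasRank = 2,
                           featureBlockSizes = rep(2L, 10),
                           missingMechanism = "MAR", missingRate = 0.2,
                           seed = 4)
  dbM <- assembleDatabase(cfgM)
  expect_identical(is.na(observedMatrix(dbM)), missingMask(dbM))
  expect_equal(mean(missingMask(dbM)), 0.2, tolerance = 0.15)
})

test_that("configuration validation rejects malformed inputs", {
  expect_error(simulationConfig(10, 10, biasRank = 11), "biasRank")
  expect_error(simulationConfig(10, 10, snr = 0), "snr")
  expect_error(simulationConfig(10, 10, withinBlockCorrelation = 1.2),
               "withinBlockCorrelation")
  expect_error(simulationConfig(10, 10, missingRate = 1), "missingRate")
  expect_error(simulationConfig(10, 10, featureBlockSizes = c(6L, 6L)),
               "featureBlockSizes")
  expect_error(simulationConfig(10, 10, meanModel = "group_design",
                                groupA = 1:2, groupB = 2:3), "disjoint")
})
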