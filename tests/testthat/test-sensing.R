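test_that("entry measurements are 1-sparse probes of single cells", {
  X <- matrix(rnorm(12), 3, 4)
  ms <- entryMeasurements(rbind(c(2, 3), c(1, 1)), c(X[2, 3], X[1, 1]),
                          dims = c(3, 4))
  expect_equal(applyOperator(ms, X), c(X[2, 3], X[1, 1]))
  expect_error(entryMeasurements(rbind(c(4, 1)), 0, dims = c(3, 4)),
               "out of range")
  expect_error(entryMeasurements(rbind(c(1, 1), c(1, 1)), c(0, 0),
                                 dims = c(3, 4)), "distinct")
})

test_that("k-sparse measurements match the dense Frobenius inner product", {
  set.seed(8)
  X <- matrix(rnorm(100), 10, 10)
  ms <- ksparseMeasurements(X, k = 3, p = 100, seed = 5)
  dense <- vapply(1:100, function(i) sum(denseSensingMatrix(ms, i) * X),
                  numeric(1))
  expect_equal(measurementTargets(ms), dense, tolerance = 1e-12)

  # k = 1 with unit coefficients reduces to entry sensing
  m1 <- ksparseMeasurements(X, k = 1, p = 50, seed = 5, unitCoeff = TRUE)
  e <- measurementEntries(m1)
  expect_true(all(e$coeff == 1))
  expect_equal(measurementTargets(m1), X[cbind(e$row, e$col)])

  # noisy targets: mean squared perturbation ~ noiseSd^2
  mClean <- ksparseMeasurements(X, k = 2, p = 10000, seed = 6)
  mNoisy <- ksparseMeasurements(X, k = 2, p = 10000, seed = 6, noiseSd = 0.1)
  expect_equal(mean((measurementTargets(mNoisy) -
                     measurementTargets(mClean))^2), 0.01, tolerance = 0.15)
})

test_that("k-sparse position sampling is uniform over cells", {
  X <- matrix(0, 20, 20)
  ms <- ksparseMeasurements(X, k = 2, p = 5000, seed = 13)
  e <- measurementEntries(ms)
  counts <- tabulate((e$col - 1L) * 20L + e$row, nbins = 400L)
  gof <- chisq.test(counts)
  expect_gt(gof$p.value, 1e-3)
})

test_that("measurement operator is linear", {
  set.seed(10)
  X <- matrix(rnorm(64), 8, 8); Y <- matrix(rnorm(64), 8, 8)
  ms <- ksparseMeasurements(X, k = 4, p = 60, seed = 3)
  for (i in 1:5) {
    a <- rnorm(1); b <- rnorm(1)
    expect_equal(applyOperator(ms, a * X + b * Y),
                 a * applyOperator(ms, X) + b * applyOperator(ms, Y),
                 tolerance = 1e-10)
  }
})

test_that("blind constraints vanish for on-line points and recover offsets", {
  # zero bias, perfectly correlated pair, oracle sd: every y is 0
  cfg <- simulationConfig(2, 30, biasRank = 1, featureBlockSizes = 2L,
                          withinBlockCorrelation = 1, seed = 2)
  f <- buildCovarianceFactors(cfg)
  S <- drawSignal(cfg, f)$S
  pairs <- new("RedundancySet",
               pairs = data.frame(space = "feature", a = 1L, b = 2L,
                                  rho = 1, sdA = sd(S[1, ]), sdB = sd(S[2, ]),
                                  nOverlap = 30L),
               mode = "oracle", threshold = NA_real_)
  ms0 <- blindMeasurements(S, pairs, center = FALSE)
  expect_lt(max(abs(measurementTargets(ms0))), 1e-10)

  # constructive oracle: known bias added to a proportional signal is
  # reproduced exactly by the constraint targets, over random draws
  for (rep in 1:100) {
    set.seed(rep)
    s1 <- rnorm(25); sds <- runif(2, 0.2, 3)
    S2 <- rbind(sds[1] * s1, sds[2] * s1)
    Xstar <- matrix(rnorm(50), 2, 25)
    prs <- new("RedundancySet",
               pairs = data.frame(space = "feature", a = 1L, b = 2L,
                                  rho = 1, sdA = sds[1] * sd(s1),
                                  sdB = sds[2] * sd(s1), nOverlap = 25L),
               mode = "oracle", threshold = NA_real_)
    ms <- blindMeasurements(S2 + Xstar, prs, center = FALSE)
    expect_lt(max(abs(measurementTargets(ms) - applyOperator(ms, Xstar))),
              1e-10)
  }
})

test_that("blind coefficient vectors are unit normals to the pair line", {
  db <- assembleDatabase(smallPairedConfig(seed = 14))
  ms <- blindMeasurements(observedMatrix(db), oracleRedundancies(db),
                          center = FALSE)
  e <- measurementEntries(ms)
  for (i in sample(measurementCount(ms), 20)) {
    ei <- e[e$measurement == i, ]
    expect_equal(sum(ei$coeff^2), 1, tolerance = 1e-12)
    # orthogonal to the line direction implied by the coefficients
    u <- c(ei$coeff[2], -ei$coeff[1])
    expect_lt(abs(sum(u * ei$coeff)), 1e-12)
  }
})

test_that("negative correlations are handled by the signed line direction", {
  db <- assembleDatabase(smallPairedConfig(seed = 15))
  O <- observedMatrix(db); X <- biasMatrix(db)
  pr <- redundancyPairs(oracleRedundancies(db))
  pr <- pr[pr$space == "feature", ][1, , drop = FALSE]
  b <- pr$b
  # negate one row of the pair everywhere: rho flips to -1
  O2 <- O; O2[b, ] <- -O2[b, ]
  X2 <- X; X2[b, ] <- -X2[b, ]
  pr$rho <- -1
  rs <- new("RedundancySet", pairs = pr, mode = "oracle",
            threshold = NA_real_)
  ms <- blindMeasurements(O2, rs, center = FALSE)
  expect_lt(max(abs(measurementTargets(ms) - applyOperator(ms, X2))), 1e-10)
})

test_that("measurement availability counting honors the missingness mask", {
  db <- assembleDatabase(evaluationConfig(seed = 5))
  pairs <- oracleRedundancies(db)
  expect_equal(countAvailableMeasurements(pairs, dims = c(50L, 50L)), 2500L)
  noPairs <- new("RedundancySet",
                 pairs = redundancyPairs(pairs)[0, ], mode = "oracle",
                 threshold = NA_real_)
  expect_equal(countAvailableMeasurements(noPairs, dims = c(50L, 50L)), 0L)

  # with missingness: equals the number of constraints actually built
  O <- observedMatrix(db)
  mask <- applyMissingness(O, "MAR", 0.2, seed = 3)
  O[mask] <- NA
  cnt <- countAvailableMeasurements(pairs, missingMask = mask)
  ms <- blindMeasurements(O, pairs, center = FALSE)
  expect_equal(cnt, measurementCount(ms))
  expect_lt(cnt, 2500L)
})

test_that("corruption perturbs targets and shuffling reassigns pairs", {
  db <- assembleDatabase(evaluationConfig(seed = 6))
  ms <- blindMeasurements(observedMatrix(db), oracleRedundancies(db),
                          center = FALSE)
  # identity corruption
  ms0 <- corruptMeasurements(ms, 0, 0, seed = 1)
  expect_equal(measurementTargets(ms0), measurementTargets(ms))
  expect_equal(measurementEntries(ms0), measurementEntries(ms))

  # variance oracle for target noise
  msN <- corruptMeasurements(sampleMeasurements(ms, 2000, seed = 1),
                             yNoiseSd = 0.1, seed = 2)
  d <- measurementTargets(msN) -
       measurementTargets(sampleMeasurements(ms, 2000, seed = 1))
  expect_equal(mean(d^2), 0.01, tolerance = 0.2)

  # full shuffling destroys the information: recovery no better than zero
  msS <- corruptMeasurements(ms, 0, shuffleFraction = 1, seed = 3)
  fit <- suppressWarnings(recoverBias(msS, 2, quietSolver(seed = 1)))
  expect_gte(relativeError(fit, biasMatrix(db)), 1)
})

test_that("spike-in entry constraints merge into a blind set", {
  db <- assembleDatabase(smallPairedConfig(seed = 30))
  O <- observedMatrix(db); X <- biasMatrix(db)
  ms <- blindMeasurements(O, oracleRedundancies(db), center = FALSE)
  p0 <- measurementCount(ms)
  tf <- tempfile(fileext = ".tsv")
  picks <- cbind(c(1L, 3L, 5L, 7L, 9L), c(2L, 4L, 6L, 8L, 10L))
  write.table(data.frame(feature_id = rownames(O)[picks[, 1]],
                         sample_id = colnames(O)[picks[, 2]],
                         bias_value = X[picks]),
              tf, sep = "\t", quote = FALSE, row.names = FALSE)
  spikes <- readSpikeIns(tf, O)
  merged <- mergeMeasurements(ms, spikes)
  expect_equal(measurementCount(merged), p0 + 5L)
  expect_equal(applyOperator(merged, X)[p0 + seq_len(5)], X[picks])
})
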