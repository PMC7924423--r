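# Shared fixtures: small, fast configurations used across test files.

smallPairedConfig <- function(seed = 1L, rho = 1, biasRank = 2L,
                              n = 20L, m = 20L, snr = 1) {
  simulationConfig(n, m, biasRank = biasRank, snr = snr,
                   featureBlockSizes = rep(2L, n %/% 2L),
                   sampleBlockSizes = rep(2L, m %/% 2L),
                   withinBlockCorrelation = rho, seed = seed)
}

# dense sensing matrix of one measurement, for brute-force oracles
denseSensingMatrix <- function(mset, i) {
  e <- measurementEntries(mset)
  e <- e[e$measurement == i, , drop = FALSE]
  A <- matrix(0, mset@nRows, mset@nCols)
  A[cbind(e$row, e$col)] <- e$coeff
  A
}

quietSolver <- function(...) solverSettings(restarts = 2L, ...)
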