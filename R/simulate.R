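#' Configuration for the confounded-database simulator
#'
#' Bundles and validates all parameters of the generative model: a
#' matrix-normal signal \eqn{S = M + A N B} with block-structured feature and
#' sample correlations, an additive random low-rank bias \eqn{X = U\Sigma V^T}
#' scaled to a target bias-to-signal Frobenius ratio, and optional MAR/MNAR
#' missingness. Blocks occupy consecutive leading indices; remaining features
#' and samples are mutually uncorrelated background.
#'
#' @param nFeatures,nSamples matrix dimensions (features x samples).
#' @param biasRank rank of the bias matrix (>= 1, <= min(n, m)).
#' @param snr target ratio \eqn{\|X\|_F / \|S\|_F} (> 0).
#' @param featureBlockSizes,sampleBlockSizes integer vectors of correlated
#'   block sizes; each must sum to at most the corresponding dimension.
#' @param withinBlockCorrelation correlation \eqn{\rho \in [0, 1]} shared by
#'   all within-block pairs.
#' @param stdDistribution distribution of feature/sample standard deviations:
#'   "half_normal" (|N(0,1)| * stdScale) or "uniform" (U(0,1) * stdScale),
#'   floored at `stdFloor` to avoid degeneracy.
#' @param stdScale scale of the standard-deviation distribution.
#' @param stdFloor lower floor on drawn standard deviations.
#' @param meanModel "zero" or "group_design". With a group design, features
#'   acquire a per-feature mean shift in the group-B samples.
#' @param groupA,groupB sample indices of the two replicate groups
#'   (group_design only).
#' @param effectSize per-feature group shift as a multiple of the feature's
#'   standard deviation: \eqn{\Delta_g =} `effectSize` \eqn{\times \sigma_g}.
#'   Proportionality to \eqn{\sigma_g} keeps correlated features exactly
#'   proportional across samples, so the shift is itself part of the redundant
#'   signal rather than a violation of it.
#' @param replicateSamples if TRUE, all sample standard deviations are fixed
#'   at 1 so that perfectly correlated sample blocks are exact replicate
#'   columns (used by the differential-expression benchmark).
#' @param missingMechanism "none", "MAR" or "MNAR".
#' @param missingRate expected fraction of masked entries, in \[0, 1).
#' @param mnarSteepness steepness of the logistic value-dependence of MNAR
#'   masking; 0 reduces to MAR.
#' @param seed integer seed; every stage of [assembleDatabase()] uses a
#'   deterministic substream derived from it.
#' @return a validated list of class "SimulationConfig".
#' @examples
#' cfg <- simulationConfig(50, 50, biasRank = 2,
#'                         featureBlockSizes = rep(2, 25),
#'                         sampleBlockSizes = rep(2, 25))
#' @export
simulationConfig <- function(nFeatures, nSamples, biasRank = 2L, snr = 1,
                             featureBlockSizes = integer(),
                             sampleBlockSizes = integer(),
                             withinBlockCorrelation = 1,
                             stdDistribution = c("half_normal", "uniform"),
                             stdScale = 1, stdFloor = 0.05,
                             meanModel = c("zero", "group_design"),
                             groupA = integer(), groupB = integer(),
                             effectSize = 1,
                             replicateSamples = FALSE,
                             missingMechanism = c("none", "MAR", "MNAR"),
                             missingRate = 0, mnarSteepness = 1,
                             seed = 1L) {
  stdDistribution <- match.arg(stdDistribution)
  meanModel <- match.arg(meanModel)
  missingMechanism <- match.arg(missingMechanism)
  nFeatures <- as.integer(nFeatures); nSamples <- as.integer(nSamples)
  biasRank <- as.integer(biasRank)
  if (nFeatures < 1L || nSamples < 1L)
    stop("nFeatures and nSamples must be positive")
  if (biasRank < 1L || biasRank > min(nFeatures, nSamples))
    stop("biasRank must be between 1 and min(nFeatures, nSamples)")
  if (!is.finite(snr) || snr <= 0) stop("snr must be positive")
  if (withinBlockCorrelation < 0 || withinBlockCorrelation > 1)
    stop("withinBlockCorrelation must lie in [0, 1]")
  if (missingRate < 0 || missingRate >= 1)
    stop("missingRate must lie in [0, 1)")
  featureBlockSizes <- as.integer(featureBlockSizes)
  sampleBlockSizes <- as.integer(sampleBlockSizes)
  if (any(featureBlockSizes < 1L) || sum(featureBlockSizes) > nFeatures)
    stop("featureBlockSizes must be positive and sum to at most nFeatures")
  if (any(sampleBlockSizes < 1L) || sum(sampleBlockSizes) > nSamples)
    stop("sampleBlockSizes must be positive and sum to at most nSamples")
  if (meanModel == "group_design") {
    groupA <- as.integer(groupA); groupB <- as.integer(groupB)
    if (length(groupA) < 2L || length(groupB) < 2L)
      stop("group_design requires at least two samples per group")
    if (length(intersect(groupA, groupB)))
      stop("groupA and groupB must be disjoint")
    if (any(c(groupA, groupB) < 1L) || any(c(groupA, groupB) > nSamples))
      stop("group indices out of range")
  }
  if (stdFloor <= 0) stop("stdFloor must be positive")
  structure(list(
    nFeatures = nFeatures, nSamples = nSamples, biasRank = biasRank,
    snr = snr, featureBlockSizes = featureBlockSizes,
    sampleBlockSizes = sampleBlockSizes,
    withinBlockCorrelation = withinBlockCorrelation,
    stdDistribution = stdDistribution, stdScale = stdScale,
    stdFloor = stdFloor, meanModel = meanModel,
    groupA = groupA, groupB = groupB, effectSize = effectSize,
    replicateSamples = replicateSamples,
    missingMechanism = missingMechanism, missingRate = missingRate,
    mnarSteepness = mnarSteepness, seed = as.integer(seed)),
    class = "SimulationConfig")
}

.blockAssignment <- function(nTotal, blockSizes) {
  blocks <- integer(nTotal)
  at <- 1L
  for (b in seq_along(blockSizes)) {
    blocks[at:(at + blockSizes[b] - 1L)] <- b
    at <- at + blockSizes[b]
  }
  blocks
}

.drawStds <- function(n, config) {
  x <- switch(config$stdDistribution,
    half_normal = abs(rnorm(n)) * config$stdScale,
    uniform = runif(n) * config$stdScale)
  pmax(x, config$stdFloor)
}

# Symmetric square root of D C D for one equicorrelated block; eigenvalues
# clipped at zero (rho = 1 blocks are rank-1 and exactly at the boundary).
.blockFactor <- function(sds, rho) {
  k <- length(sds)
  C <- matrix(rho, k, k); diag(C) <- 1
  cov <- sds * t(sds * C)  # D C D
  e <- eigen(cov, symmetric = TRUE)
  # rho = 1 blocks are exactly rank-1: clip eigenvalues that are numerical
  # noise relative to the largest, not just negative ones, so perfectly
  # correlated rows come out exactly proportional
  vals <- ifelse(e$values < max(e$values) * 1e-12, 0, e$values)
  e$vectors %*% (sqrt(vals) * t(e$vectors))
}

#' Covariance factors for the matrix-normal signal
#'
#' Builds the feature- and sample-space factors of the signal covariances:
#' sparse block-diagonal symmetric square roots \eqn{A} and \eqn{B} with
#' \eqn{AA^T = D_f C_f D_f} and \eqn{B^T B = D_s C_s D_s}, where \eqn{C} is 1
#' on the diagonal, \eqn{\rho} within blocks and 0 elsewhere, and \eqn{D} is
#' the diagonal of drawn standard deviations. Returned factors are symmetric,
#' so the transpose convention of the sampling formula is immaterial.
#'
#' @param config a [simulationConfig()].
#' @param seed integer seed for the standard-deviation draws (defaults to a
#'   substream of `config$seed`).
#' @return list with sparse factor matrices `feature` (n x n) and `sample`
#'   (m x m), the drawn `featureStd`/`sampleStd`, and the
#'   `featureBlocks`/`sampleBlocks` assignments (0 = background).
#' @export
buildCovarianceFactors <- function(config, seed = config$seed + 101L) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(seed)
  fStd <- .drawStds(config$nFeatures, config)
  sStd <- .drawStds(config$nSamples, config)
  if (isTRUE(config$replicateSamples)) sStd[] <- 1
  fBlocks <- .blockAssignment(config$nFeatures, config$featureBlockSizes)
  sBlocks <- .blockAssignment(config$nSamples, config$sampleBlockSizes)
  rho <- config$withinBlockCorrelation
  makeFactor <- function(sds, blocks, blockSizes) {
    if (!length(blockSizes))
      return(Diagonal(x = sds))
    inBlock <- sum(blockSizes)
    parts <- lapply(seq_along(blockSizes), function(b)
      .blockFactor(sds[blocks == b], rho))
    if (inBlock < length(sds))
      parts <- c(parts, list(as.matrix(Diagonal(x = sds[(inBlock + 1L):length(sds)]))))
    methods::as(bdiag(parts), "CsparseMatrix")
  }
  list(feature = makeFactor(fStd, fBlocks, config$featureBlockSizes),
       sample = makeFactor(sStd, sBlocks, config$sampleBlockSizes),
       featureStd = fStd, sampleStd = sStd,
       featureBlocks = fBlocks, sampleBlocks = sBlocks)
}

.meanMatrix <- function(config, featureStd) {
  M <- matrix(0, config$nFeatures, config$nSamples)
  if (config$meanModel == "group_design")
    M[, config$groupB] <- config$effectSize * featureStd
  M
}

#' Draw a matrix-normal signal
#'
#' Samples \eqn{S = M + A N B} where \eqn{N} has i.i.d. standard-normal
#' entries and \eqn{A}, \eqn{B} are the covariance factors from
#' [buildCovarianceFactors()]. The mean matrix \eqn{M} is zero or the
#' group-design shift defined by the configuration.
#'
#' @param config a [simulationConfig()].
#' @param factors output of [buildCovarianceFactors()].
#' @param seed integer seed for the normal draw.
#' @return list with the signal matrix `S` and the mean matrix `M`.
#' @export
drawSignal <- function(config, factors, seed = config$seed + 202L) {
  stopifnot(inherits(config, "SimulationConfig"))
  n <- config$nFeatures; m <- config$nSamples
  if (!all(dim(factors$feature) == c(n, n)) ||
      !all(dim(factors$sample) == c(m, m)))
    stop("factor dimensions do not match the configuration")
  set.seed(seed)
  N <- matrix(rnorm(n * m), n, m)
  M <- .meanMatrix(config, factors$featureStd)
  S <- M + as.matrix(factors$feature %*% N %*% factors$sample)
  list(S = S, M = M)
}

#' Draw an unscaled random low-rank bias matrix
#'
#' Generates \eqn{X = U \Sigma V^T} with \eqn{U} and \eqn{V} drawn uniformly
#' from Stiefel manifolds via the QR decomposition of standard-normal
#' matrices (sign-fixed so the R factor has a positive diagonal, making the
#' draw reproducible across linear-algebra backends) and singular values
#' drawn from Uniform(0, 1), sorted descending.
#'
#' @param n,m matrix dimensions.
#' @param rank bias rank (<= min(n, m)).
#' @param seed integer seed.
#' @return a [LowRankEstimate-class].
#' @export
drawBias <- function(n, m, rank, seed = 1L) {
  rank <- as.integer(rank)
  if (rank > min(n, m)) stop("rank must not exceed min(n, m)")
  set.seed(seed)
  stiefel <- function(d) {
    qrd <- qr(matrix(rnorm(d * rank), d, rank))
    Q <- qr.Q(qrd)
    sweep(Q, 2L, sign(diag(qr.R(qrd))), "*")
  }
  U <- stiefel(n)
  V <- stiefel(m)
  sig <- runif(rank)
  ord <- order(sig, decreasing = TRUE)
  new("LowRankEstimate", U = U[, ord, drop = FALSE], sigma = sig[ord],
      V = V[, ord, drop = FALSE], rank = rank, diagnostics = list())
}

#' Scale a bias matrix to a target bias-to-signal ratio
#'
#' Rescales so that \eqn{\|X\|_F / \|S\|_F} equals `snr` exactly.
#'
#' @param bias a [LowRankEstimate-class] or numeric matrix.
#' @param S the signal matrix.
#' @param snr target Frobenius-norm ratio (> 0).
#' @return the rescaled bias, same representation as the input.
#' @export
scaleBiasToSnr <- function(bias, S, snr) {
  if (!is.finite(snr) || snr <= 0) stop("snr must be positive")
  normX <- if (is(bias, "LowRankEstimate")) sqrt(sum(bias@sigma^2))
           else sqrt(sum(bias^2))
  if (normX == 0) stop("cannot scale a zero bias matrix")
  c0 <- snr * sqrt(sum(S^2)) / normX
  if (is(bias, "LowRankEstimate")) {
    bias@sigma <- bias@sigma * c0
    bias
  } else {
    bias * c0
  }
}

#' Generate a missingness mask
#'
#' MAR masks each entry independently with probability `rate`. MNAR masks
#' entry \eqn{(i,j)} with probability proportional to
#' \eqn{\mathrm{logistic}(-\mathrm{steepness} \cdot (v_{ij} - q))} (q = matrix
#' median; low values more likely missing), multiplicatively rescaled so the
#' expected overall rate equals `rate`. Steepness 0 reduces MNAR to MAR.
#'
#' @param values numeric matrix the mask applies to.
#' @param mechanism "none", "MAR" or "MNAR".
#' @param rate expected masked fraction in \[0, 1).
#' @param steepness MNAR logistic steepness.
#' @param seed integer seed.
#' @return logical matrix, TRUE = missing.
#' @export
applyMissingness <- function(values, mechanism = c("none", "MAR", "MNAR"),
                             rate = 0, steepness = 1, seed = 1L) {
  mechanism <- match.arg(mechanism)
  if (rate < 0 || rate >= 1) stop("rate must lie in [0, 1)")
  n <- nrow(values); m <- ncol(values)
  if (mechanism == "none" || rate == 0)
    return(matrix(FALSE, n, m))
  set.seed(seed)
  prob <- switch(mechanism,
    MAR = matrix(rate, n, m),
    MNAR = {
      p0 <- plogis(-steepness * (values - median(values)))
      pmin(p0 * rate / mean(p0), 1)
    })
  matrix(runif(n * m) < prob, n, m)
}

#' Assemble a complete synthetic confounded database
#'
#' Orchestrates the full generative model: draws covariance factors and
#' standard deviations, the matrix-normal signal, the random low-rank bias
#' (scaled so \eqn{\|X\|_F/\|S\|_F} equals the configured ratio exactly),
#' combines them additively into \eqn{O = X + S}, and applies the configured
#' missingness. Each stage uses its own deterministic seed substream, so
#' identical configurations yield bit-identical databases.
#'
#' @param config a [simulationConfig()].
#' @return a [SyntheticDatabase-class].
#' @examples
#' db <- assembleDatabase(simulationConfig(20, 20, biasRank = 2,
#'   featureBlockSizes = rep(2, 10), sampleBlockSizes = rep(2, 10)))
#' db
#' @export
assembleDatabase <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  factors <- buildCovarianceFactors(config)
  sig <- drawSignal(config, factors)
  bias <- drawBias(config$nFeatures, config$nSamples, config$biasRank,
                   seed = config$seed + 303L)
  bias <- scaleBiasToSnr(bias, sig$S, config$snr)
  X <- as.matrix(bias)
  O <- X + sig$S
  mask <- applyMissingness(O, config$missingMechanism, config$missingRate,
                           config$mnarSteepness, seed = config$seed + 404L)
  O[mask] <- NA_real_
  rownames(O) <- sprintf("f%04d", seq_len(config$nFeatures))
  colnames(O) <- sprintf("s%04d", seq_len(config$nSamples))
  dimnames(mask) <- dimnames(O)
  labels <- character(0)
  if (config$meanModel == "group_design") {
    labels <- rep("", config$nSamples)
    labels[config$groupA] <- "A"
    labels[config$groupB] <- "B"
  }
  new("SyntheticDatabase", observed = O, signal = sig$S, bias = bias,
      mean = sig$M, missingMask = mask,
      featureStd = factors$featureStd, sampleStd = factors$sampleStd,
      featureBlocks = factors$featureBlocks,
      sampleBlocks = factors$sampleBlocks,
      groupLabels = labels, config = unclass(config))
}

#' Preset: worst-case evaluation database
#'
#' The 50 x 50 evaluation layout used throughout the recovery sweeps: all
#' features form 25 disjoint correlated pairs and all samples form 25
#' disjoint correlated pairs (the worst-case redundancy structure, yielding
#' maximally 2,500 blind measurements), with a rank-`biasRank` bias at the
#' given bias-to-signal ratio.
#'
#' @param biasRank bias rank (default 2).
#' @param rho within-block correlation.
#' @param snr bias-to-signal Frobenius ratio.
#' @param n,m dimensions (blocks of 2 must tile both).
#' @param seed integer seed.
#' @return a [simulationConfig()].
#' @export
evaluationConfig <- function(biasRank = 2L, rho = 1, snr = 1,
                             n = 50L, m = 50L, seed = 1L) {
  simulationConfig(n, m, biasRank = biasRank, snr = snr,
                   featureBlockSizes = rep(2L, n %/% 2L),
                   sampleBlockSizes = rep(2L, m %/% 2L),
                   withinBlockCorrelation = rho, seed = seed)
}
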