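#' Quantile normalization
#'
#' Classic column quantile normalization: every column's order statistics are
#' replaced by the across-column mean of order statistics, so all columns
#' share one empirical distribution; ties receive the mean of their ranks'
#' reference values. The standard comparator for unsupervised normalization
#' of expression matrices; delegated to the limma implementation.
#'
#' @param values numeric matrix without missing values.
#' @return the quantile-normalized matrix (dimnames preserved).
#' @export
quantileNormalize <- function(values) {
  if (anyNA(values))
    stop("quantileNormalize requires a complete matrix (no missing values)")
  out <- limma::normalizeQuantiles(values, ties = TRUE)
  dimnames(out) <- dimnames(values)
  out
}

#' Average per-feature two-sample t-test p-value
#'
#' Runs an equal-variance (Student) two-sided t-test per feature between two
#' sample groups and returns the arithmetic mean of the p-values, the summary
#' statistic of the differential-expression benchmark. A feature whose
#' within-group variance is zero in both groups is degenerate: its p-value is
#' set to 0 when the group means differ and 1 when they coincide (noted via
#' message).
#'
#' @param values numeric feature-by-sample matrix (complete).
#' @param groupA,groupB disjoint sample index vectors, each of size >= 2.
#' @return mean p-value across features.
#' @export
ttestAvgP <- function(values, groupA, groupB) {
  groupA <- as.integer(groupA); groupB <- as.integer(groupB)
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("both groups need at least two samples")
  A <- values[, groupA, drop = FALSE]
  B <- values[, groupB, drop = FALSE]
  nA <- length(groupA); nB <- length(groupB)
  mA <- rowMeans(A); mB <- rowMeans(B)
  vA <- rowSums((A - mA)^2) / (nA - 1L)
  vB <- rowSums((B - mB)^2) / (nB - 1L)
  sp2 <- ((nA - 1L) * vA + (nB - 1L) * vB) / (nA + nB - 2L)
  se <- sqrt(sp2 * (1 / nA + 1 / nB))
  degen <- se == 0
  p <- numeric(nrow(values))
  if (any(degen)) {
    message(sprintf(
      "%d feature(s) with zero within-group variance: p set to 0/1 by mean difference",
      sum(degen)))
    p[degen] <- ifelse(mA[degen] != mB[degen], 0, 1)
  }
  ok <- !degen
  tstat <- (mA[ok] - mB[ok]) / se[ok]
  p[ok] <- 2 * pt(-abs(tstat), df = nA + nB - 2L)
  mean(p)
}

#' Benchmark database configuration
#'
#' The differential-expression benchmark layout: 40 genes x 30 samples with
#' two 5-replicate groups (samples 1-5 and 6-10) forming perfect-correlation
#' sample blocks of exact replicate columns, 10 background sample blocks of
#' 2 over the remaining 20 samples, all genes in 20 correlated feature
#' blocks of 2, and a per-gene group-B mean shift proportional to the gene's
#' standard deviation. Redundancy estimation is forced accurate downstream
#' via [oracleRedundancies()].
#'
#' @param seed integer seed.
#' @param effectSize group shift as a multiple of each gene's standard
#'   deviation.
#' @return a [simulationConfig()].
#' @export
benchmarkConfig <- function(seed = 1L, effectSize = 1) {
  simulationConfig(40L, 30L, biasRank = 2L, snr = 1,
                   featureBlockSizes = rep(2L, 20L),
                   sampleBlockSizes = c(5L, 5L, rep(2L, 10L)),
                   withinBlockCorrelation = 1,
                   stdDistribution = "half_normal", stdScale = 0.1,
                   meanModel = "group_design",
                   groupA = 1:5, groupB = 6:10,
                   effectSize = effectSize,
                   replicateSamples = TRUE, seed = seed)
}

.bcnCorrect <- function(O, db, rank = 2L, settings) {
  pairs <- oracleRedundancies(db)
  mset <- blindMeasurements(O, pairs, center = FALSE)
  fit <- suppressWarnings(recoverBias(mset, rank, settings))
  subtractBias(O, fit)
}

#' Differential-expression benchmark across noise conditions
#'
#' Reproduces the benchmark comparing blind compressive normalization (BCN,
#' with oracle redundancies at rank 2), quantile normalization (QN) and no
#' correction (NC) on the [benchmarkConfig()] database under three noise
#' conditions: i.i.d. N(0,1) random noise, systematic rank-2 low-rank noise
#' at matched Frobenius amplitude (\eqn{\|X\|_F = \sqrt{nm}}, the expected
#' norm of the random-noise matrix), and no noise. For every condition and
#' method the average per-gene t-test p-value between the two replicate
#' groups is reported, with a +/- call at the 0.05 significance level.
#'
#' @param seed integer seed; replicate r uses substream `seed + r`.
#' @param nReps number of independently simulated replications.
#' @param settings a [solverSettings()] for the BCN recovery.
#' @return list with `results` (one row per condition x method x replicate)
#'   and `summary` (median avg p per cell and its sign at 0.05).
#' @export
runTable1 <- function(seed = 1L, nReps = 10L,
                      settings = solverSettings(restarts = 2L)) {
  rows <- list()
  for (r in seq_len(nReps)) {
    cfg <- benchmarkConfig(seed = seed + r)
    db <- assembleDatabase(cfg)
    S <- signalMatrix(db)
    n <- nrow(S); m <- ncol(S)
    set.seed(seed + r + 500L)
    E <- matrix(rnorm(n * m), n, m)
    Xsys <- scaleBiasToSnr(drawBias(n, m, 2L, seed = seed + r + 600L),
                           S, snr = sqrt(n * m) / sqrt(sum(S^2)))
    observed <- list(random = S + E,
                     systematic = S + as.matrix(Xsys),
                     none = S)
    st <- settings; st$seed <- seed + r
    for (cond in names(observed)) {
      O <- observed[[cond]]
      corrected <- list(
        BCN = .bcnCorrect(O, db, rank = 2L, settings = st),
        QN = quantileNormalize(O),
        NC = O)
      for (meth in names(corrected)) {
        p <- suppressMessages(
          ttestAvgP(corrected[[meth]], cfg$groupA, cfg$groupB))
        rows[[length(rows) + 1L]] <-
          data.frame(condition = cond, method = meth, rep = r, avgP = p)
      }
    }
  }
  results <- do.call(rbind, rows)
  agg <- stats::aggregate(avgP ~ condition + method, data = results, median)
  names(agg)[names(agg) == "avgP"] <- "medianAvgP"
  agg$call <- ifelse(agg$medianAvgP <= 0.05, "+", "-")
  list(results = results, summary = agg)
}

#' One recovery experiment on the worst-case evaluation layout
#'
#' Simulates an [evaluationConfig()] database, builds either blind (oracle
#' redundancies) or k-sparse Gaussian measurements of its bias, optionally
#' subsamples to `p` measurements and corrupts them, recovers the bias at
#' the true rank and returns the relative Frobenius error. The worker behind
#' [sweepRecovery()] and the robustness evaluations.
#'
#' @param rank bias rank.
#' @param p number of measurements used.
#' @param method "blind" or "ksparse".
#' @param k sparsity for the k-sparse operator.
#' @param rho within-block correlation of the signal redundancies.
#' @param n,m matrix dimensions.
#' @param snr bias-to-signal Frobenius ratio.
#' @param yNoiseSd additive target noise, as an absolute sd, applied via
#'   [corruptMeasurements()].
#' @param relativeYNoise if TRUE, `yNoiseSd` is interpreted as a fraction of
#'   the root-mean-square target value.
#' @param shuffleFraction fraction of measurements reassigned to wrong pairs.
#' @param seed integer seed.
#' @param settings a [solverSettings()].
#' @return list with `error`, the measurement count `p`, and the fit.
#' @export
recoveryExperiment <- function(rank = 2L, p = 1500L,
                               method = c("blind", "ksparse"), k = 2L,
                               rho = 1, n = 50L, m = 50L, snr = 1,
                               yNoiseSd = 0, relativeYNoise = FALSE,
                               shuffleFraction = 0, seed = 1L,
                               settings = solverSettings(restarts = 2L)) {
  method <- match.arg(method)
  db <- assembleDatabase(evaluationConfig(biasRank = rank, rho = rho,
                                          snr = snr, n = n, m = m,
                                          seed = seed))
  X <- biasMatrix(db)
  if (method == "blind") {
    mset <- blindMeasurements(observedMatrix(db), oracleRedundancies(db),
                              center = FALSE)
    if (p < measurementCount(mset))
      mset <- sampleMeasurements(mset, p, seed = seed + 71L)
  } else {
    mset <- ksparseMeasurements(X, k = k, p = p, seed = seed + 72L)
  }
  if (yNoiseSd > 0 || shuffleFraction > 0) {
    sdAbs <- if (relativeYNoise)
      yNoiseSd * sqrt(mean(measurementTargets(mset)^2)) else yNoiseSd
    mset <- corruptMeasurements(mset, yNoiseSd = sdAbs,
                                shuffleFraction = shuffleFraction,
                                seed = seed + 73L)
  }
  st <- settings; st$seed <- seed
  fit <- suppressWarnings(recoverBias(mset, rank, st))
  list(error = relativeError(fit, X), p = measurementCount(mset), fit = fit)
}

#' Grid of recovery experiments
#'
#' Runs [recoveryExperiment()] over the cross product of the supplied axes
#' with `nSeeds` replicate seeds per cell and summarizes the relative error
#' per cell. Covers the sparsity, measurement-fraction, rank and redundancy
#' sweeps of the performance and robustness evaluations.
#'
#' @param ranks,pValues,ks,rhos,yNoiseSds,shuffleFractions axis values.
#' @param method "blind" or "ksparse".
#' @param n,m matrix dimensions.
#' @param nSeeds replicate seeds per cell.
#' @param seed base seed; replicate i of a cell uses `seed + i`.
#' @param relativeYNoise interpret `yNoiseSds` as fractions of rms(y).
#' @param settings a [solverSettings()].
#' @return list with `runs` (every experiment) and `summary` (median and
#'   quartiles of error per cell).
#' @export
sweepRecovery <- function(ranks = 2L, pValues = 1500L, ks = 2L,
                          rhos = 1, yNoiseSds = 0, shuffleFractions = 0,
                          method = c("blind", "ksparse"),
                          n = 50L, m = 50L, nSeeds = 5L, seed = 1L,
                          relativeYNoise = FALSE,
                          settings = solverSettings(restarts = 2L)) {
  method <- match.arg(method)
  grid <- expand.grid(rank = ranks, p = pValues, k = ks, rho = rhos,
                      yNoiseSd = yNoiseSds,
                      shuffleFraction = shuffleFractions,
                      seedRep = seq_len(nSeeds))
  grid$error <- NA_real_
  for (i in seq_len(nrow(grid))) {
    res <- recoveryExperiment(
      rank = grid$rank[i], p = grid$p[i], method = method, k = grid$k[i],
      rho = grid$rho[i], n = n, m = m,
      yNoiseSd = grid$yNoiseSd[i], relativeYNoise = relativeYNoise,
      shuffleFraction = grid$shuffleFraction[i],
      seed = seed + grid$seedRep[i], settings = settings)
    grid$error[i] <- res$error
  }
  summary <- stats::aggregate(
    error ~ rank + p + k + rho + yNoiseSd + shuffleFraction, data = grid,
    FUN = function(e) c(median = median(e),
                        q25 = unname(quantile(e, 0.25)),
                        q75 = unname(quantile(e, 0.75))))
  summary <- do.call(data.frame, summary)
  names(summary) <- sub("^error\\.", "", names(summary))
  list(runs = grid, summary = summary)
}

#' Degrees-of-freedom scaling model
#'
#' The parameter-count overlay \eqn{c_0 \, r \, (n + m)} for measurement
#' requirements of rank-r recovery at matrix size n x m.
#'
#' @param c0 oversampling constant.
#' @param r rank.
#' @param n,m matrix dimensions.
#' @return required measurement count under the model.
#' @export
scalingModel <- function(c0, r, n, m) c0 * r * (n + m)
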