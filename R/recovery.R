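#' Solver settings for fixed-rank recovery
#'
#' @param maxIterations iteration cap per solver run.
#' @param gradientTolerance stopping tolerance on the Riemannian gradient
#'   norm, relative to \eqn{\max(1, \|y\|_2)}.
#' @param init "random" (small-norm random rank-r point) or "spectral"
#'   (truncated SVD of the adjoint applied to the targets).
#' @param seed integer seed for initialization and restarts.
#' @param restarts number of independent runs; the best final objective wins.
#' @param maxMeasurements optional cap: larger measurement sets are randomly
#'   subsampled to this size before solving, a guard against conjugate
#'   gradient instability in heavily overdetermined settings.
#' @param verbose print per-iteration progress.
#' @return a validated list of class "SolverSettings".
#' @export
solverSettings <- function(maxIterations = 500L, gradientTolerance = 1e-7,
                           init = c("random", "spectral"), seed = 1L,
                           restarts = 3L, maxMeasurements = Inf,
                           verbose = FALSE) {
  init <- match.arg(init)
  if (gradientTolerance <= 0) stop("gradientTolerance must be positive")
  if (maxIterations < 1L) stop("maxIterations must be positive")
  if (restarts < 1L) stop("restarts must be positive")
  structure(list(maxIterations = as.integer(maxIterations),
                 gradientTolerance = gradientTolerance, init = init,
                 seed = as.integer(seed), restarts = as.integer(restarts),
                 maxMeasurements = maxMeasurements, verbose = verbose),
            class = "SolverSettings")
}

# -- operator application -----------------------------------------------------

#' @rdname applyOperator
setMethod("applyOperator", signature("MeasurementSet", "matrix"),
  function(mset, X) {
    if (nrow(X) != mset@nRows || ncol(X) != mset@nCols)
      stop("matrix dimensions do not match the measurement set")
    e <- mset@entries
    vals <- e$coeff * X[cbind(e$row, e$col)]
    out <- numeric(measurementCount(mset))
    agg <- rowsum(vals, e$measurement)
    out[as.integer(rownames(agg))] <- agg
    out
  })

#' @rdname applyOperator
setMethod("applyOperator", signature("MeasurementSet", "LowRankEstimate"),
  function(mset, X) {
    if (nrow(X@U) != mset@nRows || nrow(X@V) != mset@nCols)
      stop("estimate dimensions do not match the measurement set")
    e <- mset@entries
    xv <- rowSums(X@U[e$row, , drop = FALSE] *
                  sweep(X@V[e$col, , drop = FALSE], 2L, X@sigma, "*"))
    out <- numeric(measurementCount(mset))
    agg <- rowsum(e$coeff * xv, e$measurement)
    out[as.integer(rownames(agg))] <- agg
    out
  })

#' Relative Frobenius error
#'
#' \eqn{\|\hat X - X\|_F / \|X\|_F}, the error measure used throughout the
#' recovery evaluations.
#'
#' @param Xhat estimate (matrix or [LowRankEstimate-class]).
#' @param Xtrue ground truth (matrix or [LowRankEstimate-class]).
#' @return non-negative scalar.
#' @export
relativeError <- function(Xhat, Xtrue) {
  A <- if (is(Xhat, "LowRankEstimate")) as.matrix(Xhat) else Xhat
  B <- if (is(Xtrue, "LowRankEstimate")) as.matrix(Xtrue) else Xtrue
  if (!all(dim(A) == dim(B))) stop("dimension mismatch")
  nB <- sqrt(sum(B^2))
  if (nB == 0) stop("reference matrix has zero norm")
  sqrt(sum((A - B)^2)) / nB
}

# -- Riemannian conjugate gradient on the fixed-rank manifold -----------------

# Tangent-space projection at X = U S V': P(M) = UU'M + MVV' - UU'MVV'
.projectTangent <- function(M, U, V) {
  UtM <- crossprod(U, M)
  MV <- M %*% V
  U %*% UtM + MV %*% t(V) - U %*% (UtM %*% V) %*% t(V)
}

.svdTruncate <- function(X, r) {
  sv <- svd(X, nu = r, nv = r)
  s <- sv$d[seq_len(r)]
  # guard against boundary of the manifold (numerically rank-deficient point)
  floor <- max(s[1L], .Machine$double.xmin) * 1e-14
  s <- pmax(s, floor)
  list(U = sv$u, s = s, V = sv$v)
}

.initialPoint <- function(Aop, y, n, m, r, init, seed) {
  set.seed(seed)
  if (init == "spectral") {
    G <- matrix(as.numeric(Matrix::crossprod(Aop, y)), n, m)
    if (sum(G^2) > 0) {
      f <- .svdTruncate(G, r)
      # scale so the operator image of the init roughly matches y
      X0 <- f$U %*% (f$s * t(f$V))
      ax <- as.numeric(Aop %*% as.numeric(X0))
      sc <- sum(ax * y) / max(sum(ax^2), .Machine$double.eps)
      return(.svdTruncate(X0 * sc, r))
    }
  }
  scale <- 1e-2 * max(median(abs(y)), 1e-8)
  qrQ <- function(d) qr.Q(qr(matrix(rnorm(d * r), d, r)))
  U <- qrQ(n); V <- qrQ(m)
  s <- sort(runif(r, 0.5, 1), decreasing = TRUE)
  s <- s * scale / sqrt(sum(s^2))
  list(U = U, s = s, V = V)
}

.fixedRankCG <- function(Aop, y, n, m, r, settings, runSeed) {
  pt <- .initialPoint(Aop, y, n, m, r, settings$init, runSeed)
  X <- pt$U %*% (pt$s * t(pt$V))
  tol <- settings$gradientTolerance * max(1, sqrt(sum(y^2)))
  objective <- function(M) {
    rv <- as.numeric(Aop %*% as.numeric(M)) - y
    0.5 * sum(rv^2)
  }
  rv <- as.numeric(Aop %*% as.numeric(X)) - y
  f <- 0.5 * sum(rv^2)
  trace <- f
  PGprev <- NULL; etaPrev <- NULL; gnormPrev <- NA_real_
  gnorm <- NA_real_; converged <- FALSE; it <- 0L
  while (it < settings$maxIterations) {
    it <- it + 1L
    G <- matrix(as.numeric(Matrix::crossprod(Aop, rv)), n, m)
    PG <- .projectTangent(G, pt$U, pt$V)
    gnorm <- sqrt(sum(PG^2))
    if (settings$verbose)
      message(sprintf("  iter %d: f = %.6g, |grad| = %.3g", it, f, gnorm))
    if (gnorm <= tol) { converged <- TRUE; break }
    if (is.null(PGprev)) {
      eta <- -PG
    } else {
      PGprevT <- .projectTangent(PGprev, pt$U, pt$V)
      beta <- max(0, sum(PG * (PG - PGprevT)) / gnormPrev^2)
      eta <- -PG + beta * .projectTangent(etaPrev, pt$U, pt$V)
      if (sum(eta * PG) > -1e-12 * gnorm * sqrt(sum(eta^2)))
        eta <- -PG  # restart when the CG direction loses descent
    }
    slope <- sum(PG * eta)
    Aeta <- as.numeric(Aop %*% as.numeric(eta))
    denom <- sum(Aeta^2)
    t0 <- if (denom > 0) -sum(rv * Aeta) / denom else 1
    if (!is.finite(t0) || t0 <= 0) { eta <- -PG; slope <- -gnorm^2
      Aeta <- as.numeric(Aop %*% as.numeric(eta))
      denom <- sum(Aeta^2)
      t0 <- if (denom > 0) -sum(rv * Aeta) / denom else 1 }
    stepped <- FALSE
    tt <- t0
    for (ls in 1:30) {
      cand <- .svdTruncate(X + tt * eta, r)
      Xc <- cand$U %*% (cand$s * t(cand$V))
      fc <- objective(Xc)
      if (fc <= f + 1e-4 * tt * slope) { stepped <- TRUE; break }
      tt <- tt / 2
    }
    if (!stepped) break  # no further progress possible at this precision
    PGprev <- PG; etaPrev <- eta; gnormPrev <- gnorm
    pt <- cand; X <- Xc
    rv <- as.numeric(Aop %*% as.numeric(X)) - y
    f <- 0.5 * sum(rv^2)
    trace <- c(trace, f)
  }
  list(U = pt$U, s = pt$s, V = pt$V, objective = f, gradNorm = gnorm,
       iterations = it, converged = converged, objectiveTrace = trace)
}

#' Recover a low-rank bias matrix from sparse measurements
#'
#' Solves the matrix recovery problem: minimize
#' \eqn{\tfrac12\|y - \mathcal{A}(X)\|_2^2} over the manifold of rank-`rank`
#' \eqn{n \times m} matrices, by Riemannian conjugate gradient on the
#' embedded fixed-rank manifold with truncated-SVD retraction. The Euclidean
#' gradient \eqn{\mathcal{A}^*(\mathcal{A}(X) - y)} is assembled analytically
#' from the sparse measurement entries (no automatic differentiation, no
#' dense operator storage), projected onto the tangent space at the current
#' iterate; conjugate directions use Polak-Ribiere with projection transport
#' and an Armijo backtracking line search seeded by the exact minimizer of
#' the linearized objective. The best of `restarts` independently
#' initialized runs (by final objective) is returned.
#'
#' @param mset a [MeasurementSet-class].
#' @param rank target rank r >= 1.
#' @param settings a [solverSettings()].
#' @return a [LowRankEstimate-class]; `solverDiagnostics()` carries the final
#'   objective, Riemannian gradient norm, iteration count, convergence flag
#'   and the objective trace of the winning run. A warning (never a silent
#'   result) is issued when no run reached the gradient tolerance.
#' @export
recoverBias <- function(mset, rank, settings = solverSettings()) {
  stopifnot(is(mset, "MeasurementSet"))
  rank <- as.integer(rank)
  n <- mset@nRows; m <- mset@nCols
  if (rank < 1L || rank > min(n, m))
    stop("rank must lie in [1, min(n, m)]")
  p <- measurementCount(mset)
  if (p < 1L) stop("at least one measurement is required")
  if (is.finite(settings$maxMeasurements) && p > settings$maxMeasurements)
    mset <- sampleMeasurements(mset, as.integer(settings$maxMeasurements),
                               seed = settings$seed + 9901L)
  e <- mset@entries
  Aop <- sparseMatrix(i = e$measurement, j = (e$col - 1L) * n + e$row,
                      x = e$coeff, dims = c(measurementCount(mset), n * m))
  best <- NULL
  for (run in seq_len(settings$restarts)) {
    fit <- .fixedRankCG(Aop, mset@y, n, m, rank, settings,
                        runSeed = settings$seed + 131L * (run - 1L))
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (!best$converged)
    warning(sprintf(paste0(
      "recoverBias: gradient tolerance not reached ",
      "(final |grad| = %.3g, objective = %.4g after %d iterations)"),
      best$gradNorm, best$objective, best$iterations))
  new("LowRankEstimate", U = best$U, sigma = best$s, V = best$V,
      rank = rank,
      diagnostics = list(objective = best$objective,
                         gradNorm = best$gradNorm,
                         iterations = best$iterations,
                         converged = best$converged,
                         objectiveTrace = best$objectiveTrace,
                         measurements = measurementCount(mset),
                         restarts = settings$restarts))
}

#' Select the recovery rank by measurement hold-out
#'
#' Withholds a random fraction of the measurements, fits each candidate rank
#' on the remainder, and selects the rank with the smallest held-out squared
#' residual \eqn{\|y_{held} - \mathcal{A}_{held}(\hat X)\|_2^2}. Ties break
#' toward the smaller rank.
#'
#' @param mset a [MeasurementSet-class].
#' @param candidateRanks integer vector of ranks to try.
#' @param holdoutFraction fraction of measurements withheld, in (0, 0.5\].
#' @param settings a [solverSettings()].
#' @param seed integer seed for the split.
#' @return list with `rank` (the selection) and `diagnostics` (a data.frame
#'   of candidate ranks and held-out residuals).
#' @export
selectRank <- function(mset, candidateRanks, holdoutFraction = 0.25,
                       settings = solverSettings(), seed = 1L) {
  stopifnot(is(mset, "MeasurementSet"))
  if (holdoutFraction <= 0 || holdoutFraction > 0.5)
    stop("holdoutFraction must lie in (0, 0.5]")
  candidateRanks <- sort(unique(as.integer(candidateRanks)))
  if (length(candidateRanks) == 1L)
    return(list(rank = candidateRanks,
                diagnostics = data.frame(rank = candidateRanks,
                                         holdoutResidual = NA_real_)))
  p <- measurementCount(mset)
  nHold <- round(holdoutFraction * p)
  if (nHold < 1L || p - nHold < 1L)
    stop("too few measurements to split")
  set.seed(seed)
  held <- sort(sample.int(p, nHold))
  train <- subsetMeasurements(mset, setdiff(seq_len(p), held))
  test <- subsetMeasurements(mset, held)
  res <- vapply(candidateRanks, function(r) {
    fit <- suppressWarnings(recoverBias(train, r, settings))
    sum((measurementTargets(test) - applyOperator(test, fit))^2)
  }, numeric(1L))
  # candidates are sorted ascending, which.min takes the first minimum:
  # exact ties resolve to the smaller rank
  list(rank = candidateRanks[which.min(res)],
       diagnostics = data.frame(rank = candidateRanks,
                                holdoutResidual = res))
}

#' Subtract a recovered bias from the observed matrix
#'
#' Returns the normalized matrix \eqn{O - \hat X}: the recovered bias,
#' densified, subtracted from the observed values. Missing entries remain
#' missing; dimension names are preserved. When constraints were built from
#' centered data the estimate is the correspondingly centered bias, so the
#' observed row/column means pass through unchanged.
#'
#' @param observed numeric matrix with NA for missing entries.
#' @param estimate a [LowRankEstimate-class] or numeric matrix.
#' @return the corrected matrix.
#' @export
subtractBias <- function(observed, estimate) {
  X <- if (is(estimate, "LowRankEstimate")) as.matrix(estimate) else estimate
  if (!all(dim(observed) == dim(X))) stop("dimension mismatch")
  out <- observed - X
  dimnames(out) <- dimnames(observed)
  out
}
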