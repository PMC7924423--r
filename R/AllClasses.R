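#' @import methods
#' @importFrom stats rnorm runif sd cor median pt plogis quantile
#' @importFrom Matrix sparseMatrix bdiag Diagonal crossprod t
NULL

#' Low-rank matrix estimate in factored form
#'
#' Represents a rank-\eqn{r} matrix \eqn{X = U \Sigma V^T} with
#' column-orthonormal \code{U} (\eqn{n \times r}) and \code{V}
#' (\eqn{m \times r}) and positive singular values in descending order.
#' Produced by [drawBias()] (ground-truth bias in simulations) and by
#' [recoverBias()] (the recovered bias), whose convergence diagnostics are
#' stored in \code{diagnostics}.
#'
#' @slot U numeric matrix, left singular vectors (column-orthonormal).
#' @slot sigma numeric vector of singular values, descending, positive.
#' @slot V numeric matrix, right singular vectors (column-orthonormal).
#' @slot rank integer rank \eqn{r}.
#' @slot diagnostics list of solver diagnostics (objective, gradient norm,
#'   iterations, convergence flag, objective trace) or empty for exact
#'   constructions.
#'
#' @seealso [recoverBias()], [drawBias()], [relativeError()]
#' @export
setClass("LowRankEstimate",
  slots = c(U = "matrix", sigma = "numeric", V = "matrix",
            rank = "integer", diagnostics = "list"))

setValidity("LowRankEstimate", function(object) {
  r <- object@rank
  msg <- character()
  if (length(r) != 1L || r < 1L)
    msg <- c(msg, "rank must be a single positive integer")
  if (ncol(object@U) != r || ncol(object@V) != r || length(object@sigma) != r)
    msg <- c(msg, "U, V and sigma must all have 'rank' columns/elements")
  if (any(object@sigma < 0))
    msg <- c(msg, "singular values must be non-negative")
  if (is.unsorted(rev(object@sigma)))
    msg <- c(msg, "singular values must be in descending order")
  if (length(msg) == 0L) {
    du <- max(abs(crossprod(object@U) - diag(r)))
    dv <- max(abs(crossprod(object@V) - diag(r)))
    if (du > 1e-8 || dv > 1e-8)
      msg <- c(msg, "U and V must have orthonormal columns (tolerance 1e-8)")
  }
  if (length(msg)) msg else TRUE
})

#' Set of correlated feature or sample pairs
#'
#' Detected (or ground-truth) redundancies: pairs of features or samples whose
#' profiles are correlated, together with the correlation estimate, the two
#' standard-deviation estimates, and the number of overlapping observations.
#' These seed the construction of blind bias measurements
#' (see [blindMeasurements()]).
#'
#' @slot pairs data.frame with columns \code{space} ("feature"/"sample"),
#'   \code{a}, \code{b} (1-based indices, \code{a < b}), \code{rho}
#'   (signed correlation in \[-1, 1\]), \code{sdA}, \code{sdB} (positive),
#'   \code{nOverlap} (integer).
#' @slot mode "estimated" or "oracle".
#' @slot threshold absolute-correlation threshold used for detection
#'   (\code{NA} in oracle mode).
#'
#' @seealso [estimateCorrelations()], [oracleRedundancies()]
#' @export
setClass("RedundancySet",
  slots = c(pairs = "data.frame", mode = "character", threshold = "numeric"))

setValidity("RedundancySet", function(object) {
  p <- object@pairs
  need <- c("space", "a", "b", "rho", "sdA", "sdB", "nOverlap")
  msg <- character()
  if (!all(need %in% names(p)))
    return(paste("pairs must have columns:", paste(need, collapse = ", ")))
  if (!object@mode %in% c("estimated", "oracle"))
    msg <- c(msg, "mode must be 'estimated' or 'oracle'")
  if (nrow(p)) {
    if (!all(p$space %in% c("feature", "sample")))
      msg <- c(msg, "space must be 'feature' or 'sample'")
    if (any(p$a >= p$b))
      msg <- c(msg, "pair indices must satisfy a < b")
    if (any(abs(p$rho) > 1 + 1e-12, na.rm = TRUE))
      msg <- c(msg, "|rho| must not exceed 1")
    if (any(p$sdA <= 0 | p$sdB <= 0))
      msg <- c(msg, "standard deviations must be positive")
    if (anyDuplicated(p[c("space", "a", "b")]))
      msg <- c(msg, "duplicate (space, a, b) pairs are not allowed")
  }
  if (length(msg)) msg else TRUE
})

#' Sparse linear measurement operator with targets
#'
#' A set of \eqn{p} sparse sensing matrices \eqn{A_i} together with targets
#' \eqn{y_i}, representing the linear operator
#' \eqn{\mathcal{A}(X)_i = \langle A_i, X\rangle} (Frobenius inner product)
#' whose measurements constrain the unknown bias matrix. Entries are stored
#' columnar: one row of \code{entries} per nonzero coefficient.
#'
#' @slot entries data.frame with columns \code{measurement} (1..p),
#'   \code{row}, \code{col} (1-based positions) and \code{coeff}.
#' @slot y numeric vector of measurement targets, length p.
#' @slot nRows,nCols integer dimensions of the sensed matrix.
#' @slot provenance character vector, length p: one of "entry", "ksparse",
#'   "blind_feature", "blind_sample", "spikein".
#' @slot corruption list recording applied corruption
#'   (\code{yNoiseSd}, \code{shuffleFraction}), empty if none.
#'
#' @seealso [blindMeasurements()], [ksparseMeasurements()],
#'   [entryMeasurements()], [applyOperator()], [recoverBias()]
#' @export
setClass("MeasurementSet",
  slots = c(entries = "data.frame", y = "numeric",
            nRows = "integer", nCols = "integer",
            provenance = "character", corruption = "list"))

setValidity("MeasurementSet", function(object) {
  e <- object@entries
  p <- length(object@y)
  msg <- character()
  if (!all(c("measurement", "row", "col", "coeff") %in% names(e)))
    return("entries must have columns measurement, row, col, coeff")
  if (length(object@provenance) != p)
    msg <- c(msg, "provenance must have one element per measurement")
  if (nrow(e)) {
    if (min(e$row) < 1L || max(e$row) > object@nRows ||
        min(e$col) < 1L || max(e$col) > object@nCols)
      msg <- c(msg, "entry positions out of matrix bounds")
    if (min(e$measurement) < 1L || max(e$measurement) > p)
      msg <- c(msg, "measurement ids out of range")
    if (anyDuplicated(e[c("measurement", "row", "col")]))
      msg <- c(msg, "duplicate positions within a measurement")
    if (length(unique(e$measurement)) != p)
      msg <- c(msg, "every measurement must have at least one entry")
  } else if (p > 0L) {
    msg <- c(msg, "non-empty y with no entries")
  }
  if (length(msg)) msg else TRUE
})

#' Simulated confounded database with full ground truth
#'
#' The output of [assembleDatabase()]: an observed matrix \eqn{O = X + S}
#' (low-rank bias plus matrix-normal signal) with missingness applied, plus
#' every ground-truth component needed to evaluate recovery: the signal, the
#' bias in factored form, the mean matrix, the missingness mask, the true
#' feature/sample standard deviations, the correlation block assignments and
#' optional group labels.
#'
#' Missing entries of \code{observed} are \code{NA}; the same pattern is
#' recorded in \code{missingMask} (\code{TRUE} = missing).
#'
#' @slot observed numeric feature-by-sample matrix with NA for missing.
#' @slot signal numeric matrix S (complete).
#' @slot bias [LowRankEstimate-class] ground-truth bias X.
#' @slot mean numeric mean matrix M of the signal model.
#' @slot missingMask logical matrix, TRUE where masked.
#' @slot featureStd,sampleStd numeric vectors of true standard deviations.
#' @slot featureBlocks,sampleBlocks integer block ids (0 = unblocked
#'   background).
#' @slot groupLabels character sample labels ("A"/"B"/"" when a group design
#'   is present, otherwise empty).
#' @slot config the [simulationConfig()] list that produced the database.
#'
#' @seealso [assembleDatabase()], [oracleRedundancies()]
#' @export
setClass("SyntheticDatabase",
  slots = c(observed = "matrix", signal = "matrix", bias = "LowRankEstimate",
            mean = "matrix", missingMask = "matrix",
            featureStd = "numeric", sampleStd = "numeric",
            featureBlocks = "integer", sampleBlocks = "integer",
            groupLabels = "character", config = "list"))

setValidity("SyntheticDatabase", function(object) {
  n <- nrow(object@observed); m <- ncol(object@observed)
  msg <- character()
  if (!all(dim(object@signal) == c(n, m)) ||
      !all(dim(object@mean) == c(n, m)) ||
      !all(dim(object@missingMask) == c(n, m)))
    msg <- c(msg, "signal, mean and missingMask dimensions must match observed")
  if (length(object@featureStd) != n || length(object@sampleStd) != m)
    msg <- c(msg, "standard-deviation vectors must match dimensions")
  if (length(object@featureBlocks) != n || length(object@sampleBlocks) != m)
    msg <- c(msg, "block assignments must match dimensions")
  if (length(msg) == 0L) {
    X <- biasMatrix(object)
    keep <- !object@missingMask
    dev <- max(abs(object@observed[keep] - X[keep] - object@signal[keep]))
    if (!is.finite(dev) || dev > 1e-9)
      msg <- c(msg, "observed must equal bias + signal at non-missing entries")
    if (any(!is.na(object@observed[object@missingMask])))
      msg <- c(msg, "masked entries must be NA in observed")
  }
  if (length(msg)) msg else TRUE
})
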