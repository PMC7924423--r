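.newMeasurementSet <- function(entries, y, nRows, nCols, provenance,
                               corruption = list()) {
  rownames(entries) <- NULL
  new("MeasurementSet",
      entries = entries, y = as.numeric(y),
      nRows = as.integer(nRows), nCols = as.integer(nCols),
      provenance = provenance, corruption = corruption)
}

#' Entry (1-sparse) measurements
#'
#' One 1-sparse sensing matrix per position with unit coefficient and the
#' given target: \eqn{\langle A_i, X\rangle = X_{jk}}. This is the path by
#' which absolute constraints such as spike-in controls enter the recovery
#' problem.
#'
#' @param positions two-column matrix (row, col) of 1-based positions.
#' @param values numeric targets, one per position.
#' @param dims integer dimensions c(n, m) of the sensed matrix.
#' @param provenance provenance label, "entry" or "spikein".
#' @return a [MeasurementSet-class].
#' @export
entryMeasurements <- function(positions, values, dims,
                              provenance = c("entry", "spikein")) {
  provenance <- match.arg(provenance)
  positions <- matrix(as.integer(positions), ncol = 2L)
  if (nrow(positions) != length(values))
    stop("one value per position required")
  if (anyDuplicated(positions))
    stop("positions must be distinct")
  if (any(positions[, 1L] < 1L) || any(positions[, 1L] > dims[1L]) ||
      any(positions[, 2L] < 1L) || any(positions[, 2L] > dims[2L]))
    stop("position out of range")
  p <- nrow(positions)
  entries <- data.frame(measurement = seq_len(p),
                        row = positions[, 1L], col = positions[, 2L],
                        coeff = rep(1, p))
  .newMeasurementSet(entries, values, dims[1L], dims[2L],
                     rep(provenance, p))
}

#' k-sparse Gaussian measurements of a known matrix
#'
#' For each of `p` measurements, `k` distinct positions are chosen uniformly
#' at random and given i.i.d. standard-normal coefficients; the target is the
#' Frobenius inner product with `XTrue` plus optional Gaussian noise. Used in
#' simulation mode as the non-blind reference against which blind recovery is
#' compared (entry sensing is the k = 1 special case with unit coefficients).
#'
#' @param XTrue the matrix being sensed (ground truth).
#' @param k sparsity of each sensing matrix (number of nonzeros).
#' @param p number of measurements (> 0).
#' @param seed integer seed.
#' @param noiseSd standard deviation of additive target noise.
#' @param unitCoeff use coefficient 1 instead of Gaussian draws (with k = 1
#'   this reduces exactly to entry sensing).
#' @return a [MeasurementSet-class].
#' @export
ksparseMeasurements <- function(XTrue, k, p, seed = 1L, noiseSd = 0,
                                unitCoeff = FALSE) {
  n <- nrow(XTrue); m <- ncol(XTrue)
  k <- as.integer(k); p <- as.integer(p)
  if (p < 1L) stop("p must be positive")
  if (k < 1L || k > n * m) stop("k must lie in [1, n*m]")
  set.seed(seed)
  cells <- vapply(seq_len(p), function(i) sample.int(n * m, k),
                  integer(k))
  cells <- as.integer(cells)  # column-major: k entries per measurement
  rows <- ((cells - 1L) %% n) + 1L
  cols <- ((cells - 1L) %/% n) + 1L
  coeff <- if (unitCoeff) rep(1, k * p) else rnorm(k * p)
  meas <- rep(seq_len(p), each = k)
  vals <- coeff * XTrue[cbind(rows, cols)]
  y <- as.numeric(rowsum(vals, meas))
  if (noiseSd > 0) y <- y + rnorm(p, sd = noiseSd)
  entries <- data.frame(measurement = meas, row = rows, col = cols,
                        coeff = coeff)
  .newMeasurementSet(entries, y, n, m, rep("ksparse", p))
}

#' Remove row then column means of the observed entries
#'
#' Double-centers a matrix with missing values: subtracts each row's mean
#' over its observed entries, then each column's mean of the row-centered
#' values. The removed components are attached as attributes `rowMeans` and
#' `colMeans`. For real data this is applied before blind constraint
#' construction, so that the perfect-correlation line of each pair passes
#' through the origin; the recovered bias is then the correspondingly
#' centered bias.
#'
#' @param values numeric matrix with NA for missing.
#' @return centered matrix with attributes `rowMeans`, `colMeans`.
#' @export
doubleCenter <- function(values) {
  rm <- rowMeans(values, na.rm = TRUE)
  v <- values - rm
  cm <- colMeans(v, na.rm = TRUE)
  v <- sweep(v, 2L, cm)
  attr(v, "rowMeans") <- rm
  attr(v, "colMeans") <- cm
  v
}

# Unit direction of the perfect-correlation line and its unit normal for one
# pair: u = (sdA, sign(rho) * sdB) / ||.||, w = (-u2, u1).
.pairNormal <- function(sdA, sdB, rho) {
  u <- c(sdA, sign(rho) * sdB)
  u <- u / sqrt(sum(u^2))
  c(-u[2L], u[1L])
}

#' Blind measurements from detected redundancies
#'
#' Converts every (correlated pair, observation index) combination into one
#' 2-sparse linear constraint on the bias matrix. For a feature pair
#' \eqn{(s_1, s_2)} with standard deviations \eqn{(\sigma_1, \sigma_2)} and a
#' column \eqn{x} where both entries are observed, the unit direction of the
#' perfect-correlation line in the pair's plane is
#' \eqn{u = (\sigma_1, \mathrm{sign}(\hat\rho)\,\sigma_2)/\|\cdot\|} and its
#' unit normal is \eqn{w = (-u_2, u_1)}. The emitted sensing matrix carries
#' coefficients \eqn{w_1} at \eqn{(s_1, x)} and \eqn{w_2} at \eqn{(s_2, x)},
#' with target \eqn{y = w_1 O_{s_1 x} + w_2 O_{s_2 x}}: the signed orthogonal
#' offset of the observed point from the line. If the pair's (centered)
#' signal lies exactly on the line, the offset is caused entirely by the
#' bias, so \eqn{\langle A_i, X\rangle = y_i} exactly at the true bias.
#' Sample pairs are handled identically on the transpose.
#'
#' @param observed numeric matrix with NA for missing entries.
#' @param pairs a [RedundancySet-class].
#' @param center double-center `observed` first (see [doubleCenter()]).
#'   Use FALSE when the signal model is already origin-proportional, e.g. the
#'   zero-mean simulations and the oracle benchmark, where raw constraints
#'   are exact at the true bias.
#' @param coeffScale "unit" (default) scales each measurement's coefficient
#'   vector to unit norm so all pairs weigh equally in the least-squares
#'   objective; "sigma" uses the raw \eqn{(\sigma_1, \sigma_2)}-scaled form.
#' @return a [MeasurementSet-class] with provenance "blind_feature" /
#'   "blind_sample".
#' @export
blindMeasurements <- function(observed, pairs, center = TRUE,
                              coeffScale = c("unit", "sigma")) {
  coeffScale <- match.arg(coeffScale)
  stopifnot(is(pairs, "RedundancySet"))
  V <- if (center) doubleCenter(observed) else observed
  n <- nrow(V); m <- ncol(V)
  obs <- !is.na(V)
  pr <- redundancyPairs(pairs)
  rowsL <- colsL <- coefL <- yL <- provL <- vector("list", nrow(pr))
  for (i in seq_len(nrow(pr))) {
    sdA <- pr$sdA[i]; sdB <- pr$sdB[i]
    if (!is.finite(sdA) || !is.finite(sdB) || sdA <= 0 || sdB <= 0) {
      message(sprintf("skipping pair %s (%d, %d): non-positive sd",
                      pr$space[i], pr$a[i], pr$b[i]))
      next
    }
    w <- .pairNormal(sdA, sdB, pr$rho[i])
    if (coeffScale == "sigma") w <- w * sqrt(sdA^2 + sdB^2)
    a <- pr$a[i]; b <- pr$b[i]
    if (pr$space[i] == "feature") {
      idx <- which(obs[a, ] & obs[b, ])
      if (!length(idx)) next
      rowsL[[i]] <- rep(c(a, b), each = length(idx))
      colsL[[i]] <- c(idx, idx)
      yL[[i]] <- w[1L] * V[a, idx] + w[2L] * V[b, idx]
      provL[[i]] <- rep("blind_feature", length(idx))
    } else {
      idx <- which(obs[, a] & obs[, b])
      if (!length(idx)) next
      rowsL[[i]] <- c(idx, idx)
      colsL[[i]] <- rep(c(a, b), each = length(idx))
      yL[[i]] <- w[1L] * V[idx, a] + w[2L] * V[idx, b]
      provL[[i]] <- rep("blind_sample", length(idx))
    }
    coefL[[i]] <- rep(w, each = length(idx))
  }
  counts <- lengths(provL)
  if (sum(counts) == 0L) {
    entries <- data.frame(measurement = integer(), row = integer(),
                          col = integer(), coeff = numeric())
    return(.newMeasurementSet(entries, numeric(), n, m, character()))
  }
  # entries come pair-blocked: for each pair, first-entry block then second
  measIds <- unlist(lapply(seq_along(counts), function(i) {
    if (!counts[i]) return(integer())
    base <- sum(counts[seq_len(i - 1L)])
    rep(base + seq_len(counts[i]), times = 2L)
  }))
  entries <- data.frame(measurement = measIds,
                        row = unlist(rowsL), col = unlist(colsL),
                        coeff = unlist(coefL))
  entries <- entries[order(entries$measurement), , drop = FALSE]
  .newMeasurementSet(entries, unlist(yL), n, m, unlist(provL))
}

#' Count available blind measurements
#'
#' Number of (pair, observation index) combinations with both pair entries
#' observed, summed over feature- and sample-space pairs. For the worst-case
#' 50 x 50 layout of 25 disjoint feature pairs and 25 disjoint sample pairs
#' with no missing values this is 2,500.
#'
#' @param pairs a [RedundancySet-class].
#' @param missingMask logical matrix (TRUE = missing), or NULL for complete
#'   data with dimensions `dims`.
#' @param dims dimensions c(n, m), needed only when `missingMask` is NULL.
#' @return integer count.
#' @export
countAvailableMeasurements <- function(pairs, missingMask = NULL,
                                       dims = NULL) {
  stopifnot(is(pairs, "RedundancySet"))
  pr <- redundancyPairs(pairs)
  if (is.null(missingMask)) {
    if (is.null(dims)) stop("dims required when missingMask is NULL")
    nf <- sum(pr$space == "feature") * dims[2L]
    ns <- sum(pr$space == "sample") * dims[1L]
    return(as.integer(nf + ns))
  }
  obs <- !missingMask
  total <- 0L
  for (i in seq_len(nrow(pr))) {
    total <- total + if (pr$space[i] == "feature")
      sum(obs[pr$a[i], ] & obs[pr$b[i], ])
    else
      sum(obs[, pr$a[i]] & obs[, pr$b[i]])
  }
  as.integer(total)
}

#' Corrupt a measurement set
#'
#' Adds Gaussian noise to the targets and/or reassigns a fraction of the
#' measurements to random wrong positions, mimicking noisy constraint
#' estimation and falsely detected redundancies respectively. Shuffling keeps
#' each measurement's coefficients and target but redraws its pair identity:
#' feature-space constraints get a random wrong feature pair (same column),
#' sample-space constraints a random wrong sample pair (same row), and other
#' provenances fully random positions.
#'
#' @param mset a [MeasurementSet-class].
#' @param yNoiseSd standard deviation of additive target noise.
#' @param shuffleFraction fraction of measurements to reassign, in \[0, 1\].
#' @param seed integer seed.
#' @return the corrupted [MeasurementSet-class].
#' @export
corruptMeasurements <- function(mset, yNoiseSd = 0, shuffleFraction = 0,
                                seed = 1L) {
  stopifnot(is(mset, "MeasurementSet"))
  if (shuffleFraction < 0 || shuffleFraction > 1)
    stop("shuffleFraction must lie in [0, 1]")
  set.seed(seed)
  p <- measurementCount(mset)
  y <- mset@y
  if (yNoiseSd > 0) y <- y + rnorm(p, sd = yNoiseSd)
  entries <- mset@entries
  if (shuffleFraction > 0 && p > 0L) {
    nShuffle <- round(shuffleFraction * p)
    pick <- sample.int(p, nShuffle)
    n <- mset@nRows; m <- mset@nCols
    for (i in pick) {
      sel <- which(entries$measurement == i)
      k <- length(sel)
      prov <- mset@provenance[i]
      if (prov == "blind_feature" && k == 2L) {
        entries$row[sel] <- sample.int(n, 2L)
      } else if (prov == "blind_sample" && k == 2L) {
        entries$col[sel] <- sample.int(m, 2L)
      } else {
        cells <- sample.int(n * m, k)
        entries$row[sel] <- ((cells - 1L) %% n) + 1L
        entries$col[sel] <- ((cells - 1L) %/% n) + 1L
      }
    }
  }
  .newMeasurementSet(entries, y, mset@nRows, mset@nCols, mset@provenance,
                     corruption = list(yNoiseSd = yNoiseSd,
                                       shuffleFraction = shuffleFraction))
}

#' Subset or sample a measurement set
#'
#' `subsetMeasurements` keeps the measurements at `idx` (re-indexed);
#' `sampleMeasurements` draws `p` of them uniformly at random.
#'
#' @param mset a [MeasurementSet-class].
#' @param idx integer indices of measurements to keep.
#' @return a [MeasurementSet-class].
#' @export
subsetMeasurements <- function(mset, idx) {
  stopifnot(is(mset, "MeasurementSet"))
  idx <- as.integer(idx)
  p <- measurementCount(mset)
  if (any(idx < 1L) || any(idx > p) || anyDuplicated(idx))
    stop("idx must be distinct measurement indices")
  keep <- mset@entries$measurement %in% idx
  entries <- mset@entries[keep, , drop = FALSE]
  newId <- integer(p)
  newId[idx] <- seq_along(idx)
  entries$measurement <- newId[entries$measurement]
  entries <- entries[order(entries$measurement), , drop = FALSE]
  .newMeasurementSet(entries, mset@y[idx], mset@nRows, mset@nCols,
                     mset@provenance[idx], mset@corruption)
}

#' @rdname subsetMeasurements
#' @param p number of measurements to draw.
#' @param seed integer seed.
#' @export
sampleMeasurements <- function(mset, p, seed = 1L) {
  total <- measurementCount(mset)
  if (p > total) stop("cannot sample more measurements than available")
  set.seed(seed)
  subsetMeasurements(mset, sort(sample.int(total, p)))
}

#' Merge measurement sets
#'
#' Concatenates measurements over the same matrix dimensions, e.g. to add
#' spike-in entry constraints to a blind set.
#'
#' @param ... [MeasurementSet-class] objects with identical dimensions.
#' @return a [MeasurementSet-class].
#' @export
mergeMeasurements <- function(...) {
  sets <- list(...)
  stopifnot(length(sets) >= 1L, all(vapply(sets, is, TRUE, "MeasurementSet")))
  dims <- vapply(sets, function(s) c(s@nRows, s@nCols), integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
    stop("all measurement sets must share the same matrix dimensions")
  offset <- 0L
  entries <- list(); y <- list(); prov <- list()
  for (s in sets) {
    e <- s@entries
    e$measurement <- e$measurement + offset
    entries[[length(entries) + 1L]] <- e
    y[[length(y) + 1L]] <- s@y
    prov[[length(prov) + 1L]] <- s@provenance
    offset <- offset + measurementCount(s)
  }
  .newMeasurementSet(do.call(rbind, entries), unlist(y),
                     sets[[1L]]@nRows, sets[[1L]]@nCols, unlist(prov))
}
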