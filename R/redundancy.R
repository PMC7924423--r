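#' Per-feature or per-sample standard deviations under missingness
#'
#' Sample standard deviation of each row (feature space) or column (sample
#' space) over its non-missing entries. Rows/columns with fewer than three
#' observations or zero spread are returned as NA with a warning; they are
#' excluded from pair detection.
#'
#' @param observed numeric matrix with NA for missing entries.
#' @param space "feature" (rows) or "sample" (columns).
#' @return numeric vector of standard deviations (NA where degenerate).
#' @export
estimateStds <- function(observed, space = c("feature", "sample")) {
  space <- match.arg(space)
  M <- if (space == "feature") observed else t(observed)
  nObs <- rowSums(!is.na(M))
  sds <- apply(M, 1L, sd, na.rm = TRUE)
  bad <- nObs < 3L | is.na(sds) | sds == 0
  if (any(bad)) {
    warning(sprintf(
      "%d %s(s) with < 3 observations or zero spread excluded from pairing",
      sum(bad), space))
    sds[bad] <- NA_real_
  }
  sds
}

.spacePairs <- function(observed, space, threshold, minOverlap) {
  M <- if (space == "feature") observed else t(observed)
  sds <- suppressWarnings(estimateStds(observed, space))
  obs <- !is.na(M)
  ov <- tcrossprod(obs * 1)
  C <- suppressWarnings(cor(t(M), use = "pairwise.complete.obs"))
  keep <- which(upper.tri(C) & !is.na(C) & abs(C) >= threshold &
                ov >= minOverlap, arr.ind = TRUE)
  if (nrow(keep)) {
    ok <- !is.na(sds[keep[, 1L]]) & !is.na(sds[keep[, 2L]])
    keep <- keep[ok, , drop = FALSE]
  }
  data.frame(space = rep(space, nrow(keep)),
             a = as.integer(keep[, 1L]), b = as.integer(keep[, 2L]),
             rho = C[keep], sdA = sds[keep[, 1L]], sdB = sds[keep[, 2L]],
             nOverlap = as.integer(ov[keep]),
             stringsAsFactors = FALSE)
}

#' Detect correlated feature/sample pairs from the observed matrix
#'
#' Pearson correlation on pairwise-complete entries; pairs with
#' \eqn{|\hat\rho| \ge \tau} and at least `minOverlap` shared observations
#' are retained, with the signed correlation and the two standard-deviation
#' estimates. High thresholds give the high-specificity, low-sensitivity
#' detection regime in which blind recovery operates: false pairs are far more
#' damaging than missed ones, and large databases offer an overabundance of
#' candidate measurements.
#'
#' @param observed numeric matrix with NA for missing entries.
#' @param space "feature", "sample" or "both".
#' @param threshold detection threshold \eqn{\tau \in (0, 1]} on
#'   \eqn{|\hat\rho|}.
#' @param minOverlap minimum number of shared non-missing positions.
#' @return a [RedundancySet-class] with mode "estimated".
#' @export
estimateCorrelations <- function(observed,
                                 space = c("both", "feature", "sample"),
                                 threshold = 0.9, minOverlap = 10L) {
  space <- match.arg(space)
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  spaces <- if (space == "both") c("feature", "sample") else space
  pairs <- do.call(rbind, lapply(spaces, .spacePairs, observed = observed,
                                 threshold = threshold,
                                 minOverlap = minOverlap))
  rownames(pairs) <- NULL
  new("RedundancySet", pairs = pairs, mode = "estimated",
      threshold = threshold)
}

#' Ground-truth redundancies from a synthetic database
#'
#' Emits every within-block feature and sample pair of the simulator's block
#' structure with the configured correlation and the true signal standard
#' deviations (computed from the noiseless signal matrix), reproducing the
#' forced-accurate-estimation setting used in the recovery benchmarks, where
#' correlations and standard deviations are supplied rather than estimated.
#'
#' @param db a [SyntheticDatabase-class].
#' @return a [RedundancySet-class] with mode "oracle".
#' @export
oracleRedundancies <- function(db) {
  stopifnot(is(db, "SyntheticDatabase"))
  rho <- db@config$withinBlockCorrelation
  S <- signalMatrix(db)
  blockPairs <- function(blocks, space) {
    sds <- if (space == "feature") apply(S, 1L, sd) else apply(S, 2L, sd)
    out <- lapply(setdiff(unique(blocks), 0L), function(b) {
      idx <- which(blocks == b)
      if (length(idx) < 2L) return(NULL)
      cmb <- utils::combn(idx, 2L)
      data.frame(space = space, a = cmb[1L, ], b = cmb[2L, ],
                 rho = rho, sdA = sds[cmb[1L, ]], sdB = sds[cmb[2L, ]],
                 nOverlap = if (space == "feature") ncol(S) else nrow(S),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }
  pairs <- rbind(blockPairs(featureBlocks(db), "feature"),
                 blockPairs(sampleBlocks(db), "sample"))
  if (is.null(pairs))
    pairs <- data.frame(space = character(), a = integer(), b = integer(),
                        rho = numeric(), sdA = numeric(), sdB = numeric(),
                        nOverlap = integer(), stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  pairs$nOverlap <- as.integer(pairs$nOverlap)
  new("RedundancySet", pairs = pairs, mode = "oracle", threshold = NA_real_)
}
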