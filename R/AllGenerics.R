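#' Accessors for bcnorm containers
#'
#' Small accessor generics for the package's S4 containers, so downstream code
#' never touches slots directly.
#'
#' @param x a bcnorm S4 object.
#' @return `observedMatrix`, `signalMatrix`, `biasMatrix`, `meanMatrix` return
#'   numeric matrices; `missingMask` a logical matrix; `featureBlocks`,
#'   `sampleBlocks` integer block-id vectors; `groupLabels` a character
#'   vector; `redundancyPairs` and `measurementEntries` data.frames;
#'   `measurementTargets` a numeric vector; `measurementCount` an integer;
#'   `solverDiagnostics` a list.
#'
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("observedMatrix", function(x) standardGeneric("observedMatrix"))
#' @rdname accessors
#' @export
setGeneric("signalMatrix", function(x) standardGeneric("signalMatrix"))
#' @rdname accessors
#' @export
setGeneric("biasMatrix", function(x) standardGeneric("biasMatrix"))
#' @rdname accessors
#' @export
setGeneric("meanMatrix", function(x) standardGeneric("meanMatrix"))
#' @rdname accessors
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))
#' @rdname accessors
#' @export
setGeneric("featureBlocks", function(x) standardGeneric("featureBlocks"))
#' @rdname accessors
#' @export
setGeneric("sampleBlocks", function(x) standardGeneric("sampleBlocks"))
#' @rdname accessors
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))
#' @rdname accessors
#' @export
setGeneric("redundancyPairs", function(x) standardGeneric("redundancyPairs"))
#' @rdname accessors
#' @export
setGeneric("measurementEntries", function(x) standardGeneric("measurementEntries"))
#' @rdname accessors
#' @export
setGeneric("measurementTargets", function(x) standardGeneric("measurementTargets"))
#' @rdname accessors
#' @export
setGeneric("measurementCount", function(x) standardGeneric("measurementCount"))
#' @rdname accessors
#' @export
setGeneric("solverDiagnostics", function(x) standardGeneric("solverDiagnostics"))

#' Apply a sparse measurement operator
#'
#' Evaluates \eqn{\mathcal{A}(X)}: the vector of Frobenius inner products
#' \eqn{\langle A_i, X\rangle} of the sparse sensing matrices with \code{X}.
#' Computed sparsely from the stored nonzeros; for a [LowRankEstimate-class]
#' the needed entries \eqn{X_{jk} = \sum_l U_{jl}\sigma_l V_{kl}} are
#' evaluated without densifying the matrix.
#'
#' @param mset a [MeasurementSet-class].
#' @param X a numeric matrix or a [LowRankEstimate-class] with dimensions
#'   matching `mset`.
#' @return numeric vector of length `measurementCount(mset)`.
#' @examples
#' ms <- entryMeasurements(cbind(1, 2), 5, dims = c(3, 3))
#' X <- matrix(0, 3, 3); X[1, 2] <- 7
#' applyOperator(ms, X)  # 7
#' @export
setGeneric("applyOperator", function(mset, X) standardGeneric("applyOperator"))

# -- methods ------------------------------------------------------------------

#' @rdname accessors
setMethod("observedMatrix", "SyntheticDatabase", function(x) x@observed)
#' @rdname accessors
setMethod("signalMatrix", "SyntheticDatabase", function(x) x@signal)
#' @rdname accessors
setMethod("biasMatrix", "SyntheticDatabase", function(x) as.matrix(x@bias))
#' @rdname accessors
setMethod("meanMatrix", "SyntheticDatabase", function(x) x@mean)
#' @rdname accessors
setMethod("missingMask", "SyntheticDatabase", function(x) x@missingMask)
#' @rdname accessors
setMethod("featureBlocks", "SyntheticDatabase", function(x) x@featureBlocks)
#' @rdname accessors
setMethod("sampleBlocks", "SyntheticDatabase", function(x) x@sampleBlocks)
#' @rdname accessors
setMethod("groupLabels", "SyntheticDatabase", function(x) x@groupLabels)
#' @rdname accessors
setMethod("redundancyPairs", "RedundancySet", function(x) x@pairs)
#' @rdname accessors
setMethod("measurementEntries", "MeasurementSet", function(x) x@entries)
#' @rdname accessors
setMethod("measurementTargets", "MeasurementSet", function(x) x@y)
#' @rdname accessors
setMethod("measurementCount", "MeasurementSet", function(x) length(x@y))
#' @rdname accessors
setMethod("solverDiagnostics", "LowRankEstimate", function(x) x@diagnostics)

#' Densify a factored low-rank estimate
#'
#' @param x a [LowRankEstimate-class].
#' @param ... ignored.
#' @return the dense numeric matrix \eqn{U \Sigma V^T}.
#' @method as.matrix LowRankEstimate
#' @export
as.matrix.LowRankEstimate <- function(x, ...) {
  x@U %*% (x@sigma * t(x@V))
}

setMethod("show", "LowRankEstimate", function(object) {
  cat(sprintf("LowRankEstimate: %d x %d, rank %d\n",
              nrow(object@U), nrow(object@V), object@rank))
  cat("  singular values:",
      paste(signif(utils::head(object@sigma, 5), 4), collapse = ", "),
      if (object@rank > 5) "..." else "", "\n")
  d <- object@diagnostics
  if (length(d)) {
    cat(sprintf("  solver: objective %.4g, grad norm %.3g, %d iterations, %s\n",
                d$objective, d$gradNorm, d$iterations,
                if (isTRUE(d$converged)) "converged" else "NOT converged"))
  }
})

setMethod("show", "RedundancySet", function(object) {
  p <- object@pairs
  cat(sprintf("RedundancySet (%s): %d pairs (%d feature, %d sample)",
              object@mode, nrow(p), sum(p$space == "feature"),
              sum(p$space == "sample")))
  if (!is.na(object@threshold))
    cat(sprintf(", |rho| >= %g", object@threshold))
  cat("\n")
})

setMethod("show", "MeasurementSet", function(object) {
  cat(sprintf("MeasurementSet: %d measurements on a %d x %d matrix\n",
              length(object@y), object@nRows, object@nCols))
  tab <- table(object@provenance)
  cat("  provenance:", paste(sprintf("%s (%d)", names(tab), tab),
                             collapse = ", "), "\n")
  if (length(object@corruption))
    cat(sprintf("  corrupted: y noise sd %g, shuffle fraction %g\n",
                object@corruption$yNoiseSd, object@corruption$shuffleFraction))
})

setMethod("show", "SyntheticDatabase", function(object) {
  cat(sprintf("SyntheticDatabase: %d features x %d samples\n",
              nrow(object@observed), ncol(object@observed)))
  cat(sprintf("  bias rank %d, snr %.3g, missing %.1f%%\n",
              object@bias@rank, object@config$snr,
              100 * mean(object@missingMask)))
  cat(sprintf("  feature blocks: %d, sample blocks: %d, rho = %g\n",
              max(object@featureBlocks), max(object@sampleBlocks),
              object@config$withinBlockCorrelation))
})
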