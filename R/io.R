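#' Read a feature-by-sample matrix from TSV
#'
#' Expects a header row of sample ids, a first column of feature ids, and
#' `NA` for missing values. Validates rectangularity, numeric content and id
#' uniqueness, naming the offending line or id on failure.
#'
#' @param path TSV file path.
#' @return numeric matrix with dimnames and NA for missing values.
#' @export
readMatrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("matrix file needs a header and >= 1 row")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  width <- lengths(cells)
  if (any(width != width[1L]))
    stop(sprintf("ragged row at line %d (%d fields, expected %d)",
                 which(width != width[1L])[1L], width[width != width[1L]][1L],
                 width[1L]))
  sampleIds <- cells[[1L]][-1L]
  featureIds <- vapply(cells[-1L], `[`, character(1L), 1L)
  if (anyDuplicated(featureIds))
    stop(sprintf("duplicated feature id: %s",
                 featureIds[duplicated(featureIds)][1L]))
  if (anyDuplicated(sampleIds))
    stop(sprintf("duplicated sample id: %s",
                 sampleIds[duplicated(sampleIds)][1L]))
  body <- lapply(cells[-1L], `[`, -1L)
  vals <- suppressWarnings(vapply(body, as.numeric,
                                  numeric(length(sampleIds))))
  vals <- matrix(vals, ncol = length(sampleIds), byrow = TRUE)
  raw <- matrix(unlist(body), ncol = length(sampleIds), byrow = TRUE)
  badNum <- is.na(vals) & !(raw %in% c("NA", "nan", ""))
  if (any(badNum)) {
    at <- which(badNum, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric value '%s' at line %d, column %d",
                 raw[badNum][1L], at[1L] + 1L, at[2L] + 1L))
  }
  dimnames(vals) <- list(featureIds, sampleIds)
  vals
}

#' Write a feature-by-sample matrix to TSV
#'
#' Inverse of [readMatrix()]: header row of sample ids, first column of
#' feature ids, `NA` for missing, 17 significant digits so finite values
#' round-trip bit-identically.
#'
#' @param values numeric matrix with dimnames.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeMatrix <- function(values, path) {
  if (!is.matrix(values) || nrow(values) == 0L || ncol(values) == 0L)
    stop("values must be a non-empty matrix")
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("f%04d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%04d", seq_len(ncol(values)))
  fmt <- matrix(vapply(values, function(v)
    if (is.na(v)) "NA" else sprintf("%.17g", v), character(1L)),
    nrow(values), ncol(values))
  out <- c(paste(c("feature_id", colnames(values)), collapse = "\t"),
           vapply(seq_len(nrow(values)), function(i)
             paste(c(rownames(values)[i], fmt[i, ]), collapse = "\t"),
             character(1L)))
  writeLines(out, path)
  invisible(path)
}

#' Read or write a redundancy-pair table
#'
#' TSV with columns space, id_a, id_b, rho_hat, sd_a, sd_b, n_overlap
#' (1-based indices in files).
#'
#' @param pairs a [RedundancySet-class].
#' @param path file path.
#' @return `writePairs` returns `path` invisibly; `readPairs` a
#'   [RedundancySet-class] (mode "estimated", unknown threshold).
#' @export
writePairs <- function(pairs, path) {
  stopifnot(is(pairs, "RedundancySet"))
  p <- redundancyPairs(pairs)
  out <- data.frame(space = p$space, id_a = p$a, id_b = p$b,
                    rho_hat = p$rho, sd_a = p$sdA, sd_b = p$sdB,
                    n_overlap = p$nOverlap)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writePairs
#' @export
readPairs <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  pairs <- data.frame(space = d$space, a = as.integer(d$id_a),
                      b = as.integer(d$id_b), rho = d$rho_hat,
                      sdA = d$sd_a, sdB = d$sd_b,
                      nOverlap = as.integer(d$n_overlap),
                      stringsAsFactors = FALSE)
  new("RedundancySet", pairs = pairs, mode = "estimated",
      threshold = NA_real_)
}

#' Write a measurement set for inspection
#'
#' One row per sensing-matrix nonzero: measurement_id, row, col, coeff, y
#' (the target repeated for each of its measurement's entries).
#'
#' @param mset a [MeasurementSet-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeMeasurements <- function(mset, path) {
  stopifnot(is(mset, "MeasurementSet"))
  e <- mset@entries
  out <- data.frame(measurement_id = e$measurement, row = e$row,
                    col = e$col, coeff = e$coeff,
                    y = mset@y[e$measurement])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read spike-in constraints as entry measurements
#'
#' TSV with columns feature_id, sample_id, bias_value; ids are matched
#' against the observed matrix's dimnames. Each row becomes one 1-sparse
#' entry measurement of the bias.
#'
#' @param path TSV path.
#' @param observed the observed matrix whose dimnames define the id space.
#' @return a [MeasurementSet-class] with provenance "spikein".
#' @export
readSpikeIns <- function(path, observed) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  rows <- match(d$feature_id, rownames(observed))
  cols <- match(d$sample_id, colnames(observed))
  if (anyNA(rows) || anyNA(cols))
    stop("spike-in ids not found in the observed matrix")
  entryMeasurements(cbind(rows, cols), d$bias_value, dim(observed),
                    provenance = "spikein")
}

#' Read a flat key-value configuration file
#'
#' Lines of `key = value` (or `key: value`); blank lines and `#` comments
#' ignored. Values are parsed as numeric where possible, comma-separated
#' values as vectors.
#'
#' @param path file path.
#' @return named list.
#' @export
readConfigFile <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "[=:]", perl = TRUE)[[1L]]
    if (length(kv) < 2L) stop(sprintf("cannot parse config line: '%s'", ln))
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = ":"))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1L]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (anyNA(num)) parts else num
  }
  out
}
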