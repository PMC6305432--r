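#' Construct an abundance matrix
#'
#' The universal currency between pipeline stages: a non-negative numeric
#' matrix of features (genes, taxa, or functional features) by samples,
#' explicitly flagged as holding relative abundances or raw counts.
#'
#' @param values Numeric matrix with unique rownames (feature ids) and
#'   unique colnames (sample ids). No negative entries, no `NA`.
#' @param units Either `"relative"` (each column sums to at most 1) or
#'   `"counts"`.
#' @return A numeric matrix of class `abundance_matrix` with a `units`
#'   attribute.
#' @examples
#' m <- matrix(c(0.5, 0.5, 0.2, 0.8), nrow = 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' abundance_matrix(m, "relative")
#' @export
abundance_matrix <- function(values, units = c("relative", "counts")) {
  units <- match.arg(units)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("abundance matrix needs rownames (features) and colnames (samples)")
  if (anyDuplicated(rownames(values)))
    stop("duplicate row ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids")
  if (anyNA(values)) stop("abundance matrix contains NA")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative abundance at row '%s', sample '%s'",
                 rownames(values)[bad[1]], colnames(values)[bad[2]]))
  }
  if (units == "relative") {
    cs <- colSums(values)
    if (any(cs > 1 + 1e-9))
      stop("column sums exceed 1 for a relative-abundance matrix: ",
           paste(colnames(values)[cs > 1 + 1e-9], collapse = ", "))
  }
  structure(values, units = units, class = c("abundance_matrix", "matrix",
                                             "array"))
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("<abundance_matrix> %d features x %d samples (%s)\n",
              nrow(x), ncol(x), attr(x, "units")))
  invisible(x)
}

#' Units flag of an abundance matrix
#' @param x An `abundance_matrix`.
#' @return `"relative"` or `"counts"`.
#' @export
abundance_units <- function(x) attr(x, "units")

#' Read an abundance matrix from TSV
#'
#' Expects a tab-separated file whose header row holds sample ids and whose
#' first column holds feature (row) ids. Lines starting with `#` are
#' comments. Parsing is strict: duplicate row ids, ragged rows, negative or
#' non-numeric values are rejected with the offending location named.
#'
#' @param path Path to the TSV file.
#' @param relative_flag If `TRUE` the matrix is flagged as relative
#'   abundances and its column sums are validated; otherwise it is treated
#'   as raw counts. Counts are never silently renormalized.
#' @return An [abundance_matrix()].
#' @export
read_abundance_matrix <- function(path, relative_flag = TRUE) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("abundance TSV needs a header and data rows")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  ncol_expected <- length(header)
  samples <- header[-1L]
  body <- fields[-1L]
  nf <- lengths(body)
  if (any(nf != ncol_expected)) {
    bad <- which(nf != ncol_expected)[1L]
    stop(sprintf("ragged row at line %d: %d fields, expected %d",
                 bad + 1L, nf[bad], ncol_expected))
  }
  row_ids <- vapply(body, `[[`, character(1), 1L)
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1L]), numeric(length(samples))))
  vals <- matrix(vals, nrow = length(samples))  # columns = rows of file
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric value at row '%s', sample '%s'",
                 row_ids[bad[2]], samples[bad[1]]))
  }
  if (any(vals < 0)) {
    bad <- which(vals < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative value at row '%s', sample '%s'",
                 row_ids[bad[2]], samples[bad[1]]))
  }
  m <- t(vals)
  dimnames(m) <- list(row_ids, samples)
  abundance_matrix(m, if (relative_flag) "relative" else "counts")
}

#' Write an abundance matrix to TSV
#'
#' Inverse of [read_abundance_matrix()]: `read(write(x))` reproduces `x` up
#' to floating-point representation (values are written with full
#' `%.17g` precision).
#'
#' @param x An [abundance_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_abundance_matrix <- function(x, path) {
  stopifnot(inherits(x, "abundance_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("feature_id", colnames(x)), collapse = "\t"), con)
  body <- apply(x, 1L, function(v)
    paste(sprintf("%.17g", v), collapse = "\t"))
  writeLines(paste(rownames(x), body, sep = "\t"), con)
  invisible(path)
}

#' Column-normalize a counts matrix to relative abundances
#'
#' @param x An [abundance_matrix()] (any units).
#' @return An [abundance_matrix()] flagged relative; all-zero columns stay
#'   zero.
#' @export
to_relative <- function(x) {
  stopifnot(inherits(x, "abundance_matrix"))
  cs <- colSums(x)
  cs[cs == 0] <- 1
  abundance_matrix(sweep(unclass(x), 2L, cs, "/"), "relative")
}
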