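#' Binned spectrum dataset
#'
#' A spectrum is a set of ordered bins (channels or times). Two statistical
#' modes are supported, mirroring the two plain-text data dialects: counting
#' data `(channel, counts)` analysed with a Poisson likelihood, and
#' measurements with stated uncertainties `(channel, y, y uncertainty)`
#' analysed with a Gaussian likelihood.
#'
#' @param x Strictly increasing numeric vector of bin centers.
#' @param counts Nonnegative integer counts (Poisson mode).
#' @param y,sigma Measured values and strictly positive uncertainties
#'   (Gaussian mode). Supply either `counts` or `y` + `sigma`, not both.
#' @return An object of class `spectrum_data` with elements `x`, `mode`
#'   (`"poisson"` or `"gaussian"`) and the relevant response columns.
#' @examples
#' spectrum_data(1:5, counts = c(0, 2, 5, 1, 0))
#' spectrum_data(1:3, y = c(0.2, 1.4, 0.1), sigma = c(0.1, 0.2, 0.1))
#' @export
spectrum_data <- function(x, counts = NULL, y = NULL, sigma = NULL) {
  x <- as.numeric(x)
  if (length(x) < 1) stop("data error: empty spectrum")
  if (any(diff(x) <= 0)) stop("data error: 'x' must be strictly increasing")
  if (!is.null(counts)) {
    if (!is.null(y) || !is.null(sigma))
      stop("supply either 'counts' (poisson) or 'y'+'sigma' (gaussian)")
    counts <- as.numeric(counts)
    if (length(counts) != length(x))
      stop("data error: length mismatch between 'x' and 'counts'")
    if (any(counts < 0) || any(counts != round(counts)))
      stop("data error: counts must be nonnegative integers")
    out <- list(x = x, mode = "poisson", counts = counts)
  } else {
    if (is.null(y) || is.null(sigma))
      stop("supply either 'counts' (poisson) or 'y'+'sigma' (gaussian)")
    y <- as.numeric(y); sigma <- as.numeric(sigma)
    if (length(y) != length(x) || length(sigma) != length(x))
      stop("data error: length mismatch between 'x', 'y' and 'sigma'")
    if (any(sigma <= 0)) stop("data error: 'sigma' must be strictly positive")
    out <- list(x = x, mode = "gaussian", y = y, sigma = sigma)
  }
  structure(out, class = "spectrum_data")
}

#' @export
print.spectrum_data <- function(x, ...) {
  cat(sprintf("Spectrum: %d bins, %s mode, x in [%g, %g]\n",
              length(x$x), x$mode, min(x$x), max(x$x)))
  if (x$mode == "poisson")
    cat(sprintf("  total counts: %g\n", sum(x$counts)))
  invisible(x)
}

#' Read a plain-text spectrum file
#'
#' Whitespace-delimited columns; `#` comments and blank lines are skipped.
#' Two columns are read as `(channel, counts)` and give a Poisson-mode
#' dataset; three columns as `(channel, y, y uncertainty)` give a
#' Gaussian-mode dataset. Any other column count, a ragged row or a
#' non-numeric field is a parse error reported with its line number.
#'
#' @param path Path to the text file.
#' @return A [spectrum_data] object.
#' @seealso [write_spectrum()]
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) stop("data file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0) stop("parse error: no data rows in ", path)
  rows <- lapply(keep, function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v))
      stop(sprintf("parse error at line %d of %s: non-numeric field", i, path))
    v
  })
  ncols <- unique(vapply(rows, length, integer(1)))
  if (length(ncols) != 1) {
    bad <- keep[which(vapply(rows, length, integer(1)) != ncols[1])[1]]
    stop(sprintf("parse error at line %d of %s: ragged row", bad, path))
  }
  m <- do.call(rbind, rows)
  if (ncols == 2) {
    if (any(m[, 2] < 0)) {
      bad <- keep[which(m[, 2] < 0)[1]]
      stop(sprintf("parse error at line %d of %s: negative counts", bad, path))
    }
    spectrum_data(m[, 1], counts = m[, 2])
  } else if (ncols == 3) {
    spectrum_data(m[, 1], y = m[, 2], sigma = m[, 3])
  } else {
    bad <- keep[1]
    stop(sprintf(
      "parse error at line %d of %s: expected 2 or 3 columns, found %d",
      bad, path, ncols))
  }
}

#' Write a spectrum to the plain-text exchange format
#'
#' @param data A [spectrum_data] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(data, path) {
  if (!inherits(data, "spectrum_data")) stop("'data' must be a spectrum_data")
  if (data$mode == "poisson") {
    m <- cbind(data$x, data$counts)
  } else {
    m <- cbind(data$x, data$y, data$sigma)
  }
  utils::write.table(format(m, digits = 17, scientific = FALSE, trim = TRUE),
                     path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
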