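# Plain-text raster serialization (Esri ASCII grid). Grids are integer or
# numeric matrices; NA encodes nodata. Row 1 of the matrix is the top row of
# the grid, as in image coordinates.

#' Write a matrix as an Esri ASCII grid
#'
#' @param mat Numeric or integer matrix; `NA` cells become the nodata value.
#' @param path Output file path.
#' @param cellsize Cell edge length in map units (default 15 m pixels).
#' @param nodata Nodata sentinel written to the file.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(mat, path, cellsize = 15, nodata = -9999) {
  if (!is.matrix(mat)) stop("'mat' must be a matrix", call. = FALSE)
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) {
    stop("cannot open raster file for writing: ", path, call. = FALSE)
  }
  on.exit(close(con))
  header <- c(
    paste("ncols", ncol(mat)),
    paste("nrows", nrow(mat)),
    "xllcorner 0",
    "yllcorner 0",
    paste("cellsize", cellsize),
    paste("NODATA_value", nodata)
  )
  writeLines(header, con)
  m <- mat
  m[is.na(m)] <- nodata
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an Esri ASCII grid into a matrix
#'
#' @param path File written by [write_ascii_grid()] (or any conformant grid).
#' @return A numeric matrix with `NA` for nodata cells; the `cellsize` header
#'   value is attached as attribute `"cellsize"`.
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path, call. = FALSE)
  lines <- readLines(path, n = 6)
  header <- strsplit(trimws(lines), "\\s+")
  keys <- tolower(vapply(header, `[`, "", 1L))
  vals <- as.numeric(vapply(header, `[`, "", 2L))
  names(vals) <- keys
  body <- utils::read.table(path, skip = 6)
  m <- as.matrix(body)
  dimnames(m) <- NULL
  if (nrow(m) != vals[["nrows"]] || ncol(m) != vals[["ncols"]]) {
    stop("grid body does not match header dimensions in ", path, call. = FALSE)
  }
  m[m == vals[["nodata_value"]]] <- NA
  attr(m, "cellsize") <- vals[["cellsize"]]
  m
}
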