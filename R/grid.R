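#' Regular raster grid
#'
#' A minimal single-band raster: a numeric matrix plus an affine placement
#' (lower-left corner and square cell size). Rows run north to south, columns
#' west to east, so `values[1, 1]` is the north-west cell. Missing cells are
#' `NA`. This is the container every raster-producing function in the package
#' returns; [write_ascii_grid()] / [read_ascii_grid()] round-trip it through
#' the plain-text ESRI ASCII grid format.
#'
#' @param values numeric matrix (rows = north to south).
#' @param xmin,ymin coordinates of the lower-left (south-west) corner, m.
#' @param res cell size in metres (square cells).
#' @return An object of class `ysz_grid`.
#' @export
ysz_grid <- function(values, xmin = 0, ymin = 0, res = 2) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(res) || length(res) != 1L || !is.finite(res) || res <= 0) {
    stop("`res` must be a single positive number", call. = FALSE)
  }
  structure(
    list(values = values, xmin = xmin, ymin = ymin, res = res),
    class = "ysz_grid"
  )
}

#' @export
dim.ysz_grid <- function(x) dim(x$values)

#' @export
print.ysz_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<ysz_grid> %d rows x %d cols @ %g m (extent %g x %g m, origin %g, %g)\n",
    d[1], d[2], x$res, d[2] * x$res, d[1] * x$res, x$xmin, x$ymin
  ))
  v <- x$values[is.finite(x$values)]
  if (length(v)) {
    cat(sprintf("  values: [%g, %g], %d NA\n",
                min(v), max(v), sum(is.na(x$values))))
  } else {
    cat("  values: all NA\n")
  }
  invisible(x)
}

grid_nrow <- function(g) nrow(g$values)
grid_ncol <- function(g) ncol(g$values)
grid_ymax <- function(g) g$ymin + grid_nrow(g) * g$res

#' Cell-centre coordinates of a grid
#'
#' @param g a [ysz_grid()].
#' @return data.frame with `row`, `col`, `x`, `y` for every cell (row-major).
#' @export
grid_cell_centers <- function(g) {
  nr <- grid_nrow(g); nc <- grid_ncol(g)
  col <- rep(seq_len(nc), each = nr)
  row <- rep(seq_len(nr), times = nc)
  data.frame(
    row = row, col = col,
    x = g$xmin + (col - 0.5) * g$res,
    y = grid_ymax(g) - (row - 0.5) * g$res
  )
}

#' Map point coordinates to grid row/col indices (nearest cell)
#'
#' @param g a [ysz_grid()].
#' @param x,y point coordinates, m.
#' @return data.frame with `row` and `col`; points outside the extent error.
#' @export
grid_locate <- function(g, x, y) {
  col <- floor((x - g$xmin) / g$res) + 1L
  row <- floor((grid_ymax(g) - y) / g$res) + 1L
  # points exactly on the top/right edge belong to the last cell
  col[x == g$xmin + grid_ncol(g) * g$res] <- grid_ncol(g)
  row[y == g$ymin] <- grid_nrow(g)
  bad <- col < 1L | col > grid_ncol(g) | row < 1L | row > grid_nrow(g)
  if (any(bad)) {
    stop(sprintf(
      "%d point(s) outside the raster extent (first offenders: %s)",
      sum(bad),
      paste(utils::head(sprintf("(%.1f, %.1f)", x[bad], y[bad]), 3L),
            collapse = ", ")
    ), call. = FALSE)
  }
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Extract grid values at point locations (nearest cell)
#'
#' @inheritParams grid_locate
#' @return numeric vector of cell values.
#' @export
grid_extract <- function(g, x, y) {
  rc <- grid_locate(g, x, y)
  g$values[cbind(rc$row, rc$col)]
}

#' Write a grid as an ESRI ASCII raster
#'
#' Plain-text raster interchange format readable by GDAL, QGIS and ArcGIS.
#'
#' @param g a [ysz_grid()].
#' @param path output file path (conventionally `.asc`).
#' @param nodata value written for `NA` cells (default -9999).
#' @param digits significant digits written (default 17, round-trip safe).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(g, path, nodata = -9999, digits = 17) {
  stopifnot(inherits(g, "ysz_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", grid_ncol(g)),
    sprintf("nrows %d", grid_nrow(g)),
    sprintf("xllcorner %.10g", g$xmin),
    sprintf("yllcorner %.10g", g$ymin),
    sprintf("cellsize %.10g", g$res),
    sprintf("NODATA_value %.10g", nodata)
  ), con)
  v <- g$values
  v[is.na(v)] <- nodata
  rows <- apply(v, 1L, function(r) {
    paste(formatC(r, digits = digits, format = "g"), collapse = " ")
  })
  writeLines(rows, con)
  invisible(path)
}

#' Read an ESRI ASCII raster
#'
#' @param path file written by [write_ascii_grid()] or any conforming tool.
#' @return a [ysz_grid()]; nodata cells become `NA`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("malformed ASCII grid header in ", path, call. = FALSE)
  }
  body <- scan(text = lines[i:length(lines)], quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(body) != nr * nc) {
    stop("ASCII grid body does not match header dimensions", call. = FALSE)
  }
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  ysz_grid(m, xmin = hdr$xllcorner, ymin = hdr$yllcorner, res = hdr$cellsize)
}
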