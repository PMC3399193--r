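#' Define a regular analysis grid
#'
#' All rasters in one analysis share a single grid: `n_rows` x `n_cols` square
#' cells of side `cell_size_km`. Coordinates are Euclidean kilometres; the cell
#' in row 1, column 1 has its centre at `(origin_x + cell/2, origin_y +
#' cell/2)` and the y ("northing") coordinate increases with the row index.
#' Working in kilometres keeps all buffering and distance logic Euclidean;
#' geographic (degree) data should be converted to a km grid via a mean cell
#' size before use.
#'
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param cell_size_km Cell side length in km (default 5, i.e. roughly a
#'   0.05 degree cell).
#' @param origin_x,origin_y Coordinates (km) of the grid's lower-left corner.
#' @return A `grid_spec` object.
#' @examples
#' g <- grid_spec(4, 5)
#' cell_centers(g)
#' @export
grid_spec <- function(n_rows, n_cols, cell_size_km = 5,
                      origin_x = 0, origin_y = 0) {
  if (n_rows < 1 || n_cols < 1) {
    stop("`n_rows` and `n_cols` must be >= 1", call. = FALSE)
  }
  if (cell_size_km <= 0) {
    stop("`cell_size_km` must be > 0", call. = FALSE)
  }
  structure(
    list(
      n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
      cell_size_km = as.numeric(cell_size_km),
      origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y)
    ),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> %d x %d cells of %.3g km (%.4g x %.4g km extent)\n",
    x$n_rows, x$n_cols, x$cell_size_km,
    x$n_cols * x$cell_size_km, x$n_rows * x$cell_size_km
  ))
  invisible(x)
}

n_cells <- function(grid) grid$n_rows * grid$n_cols

#' Cell centre coordinates of a grid
#'
#' @param grid A [grid_spec()].
#' @return A tibble with one row per cell: `cell` (linear index, column-major
#'   as in R matrices), `row`, `col`, `x`, `y` (km).
#' @export
cell_centers <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  row <- rep(seq_len(grid$n_rows), times = grid$n_cols)
  col <- rep(seq_len(grid$n_cols), each = grid$n_rows)
  tibble::tibble(
    cell = seq_len(n_cells(grid)),
    row = row,
    col = col,
    x = grid$origin_x + (col - 0.5) * grid$cell_size_km,
    y = grid$origin_y + (row - 0.5) * grid$cell_size_km
  )
}

#' Convert x/y coordinates to linear cell indices
#'
#' Points outside the grid extent map to `NA`.
#'
#' @param grid A [grid_spec()].
#' @param x,y Coordinate vectors in km.
#' @return Integer vector of linear (column-major) cell indices.
#' @export
xy_to_cell <- function(grid, x, y) {
  col <- floor((x - grid$origin_x) / grid$cell_size_km) + 1
  row <- floor((y - grid$origin_y) / grid$cell_size_km) + 1
  ok <- row >= 1 & row <= grid$n_rows & col >= 1 & col <= grid$n_cols &
    !is.na(row) & !is.na(col)
  out <- rep(NA_integer_, length(x))
  out[ok] <- as.integer((col[ok] - 1) * grid$n_rows + row[ok])
  out
}

#' Convert a raster matrix to a long tibble
#'
#' @param m Matrix with `n_rows` x `n_cols` dimensions matching `grid`.
#' @param grid A [grid_spec()].
#' @param name Column name for the values.
#' @return Tibble `cell, row, col, x, y, <name>`.
#' @export
raster_to_tibble <- function(m, grid, name = "value") {
  out <- cell_centers(grid)
  out[[name]] <- as.vector(m)
  out
}

new_raster <- function(values, grid) {
  matrix(values, nrow = grid$n_rows, ncol = grid$n_cols)
}

check_same_grid <- function(a, b) {
  if (!identical(unclass(a), unclass(b))) {
    stop("rasters do not share the same grid specification", call. = FALSE)
  }
  invisible(TRUE)
}

#' Write / read a raster as a plain-text TSV
#'
#' The file carries the grid specification in `#!` header lines followed by a
#' tab-separated matrix (one line per row, row 1 first); `NA` encodes nodata.
#'
#' @param m Raster matrix.
#' @param grid A [grid_spec()].
#' @param path Output file path.
#' @return `path`, invisibly ([write_raster_tsv()]); a list with elements
#'   `values` (matrix) and `grid` ([read_raster_tsv()]).
#' @export
write_raster_tsv <- function(m, grid, path) {
  hdr <- sprintf(
    "#! grid n_rows=%d n_cols=%d cell_size_km=%.10g origin_x=%.10g origin_y=%.10g",
    grid$n_rows, grid$n_cols, grid$cell_size_km, grid$origin_x, grid$origin_y
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(m, con,
    sep = "\t", row.names = FALSE, col.names = FALSE,
    quote = FALSE, na = "NA"
  )
  invisible(path)
}

#' @rdname write_raster_tsv
#' @export
read_raster_tsv <- function(path) {
  hdr <- readLines(path, n = 1)
  if (!startsWith(hdr, "#! grid")) {
    stop("not a raster TSV: missing '#! grid' header in ", path, call. = FALSE)
  }
  kv <- strsplit(strsplit(sub("^#! grid ", "", hdr), " ")[[1]], "=")
  vals <- stats::setNames(
    vapply(kv, function(p) as.numeric(p[2]), numeric(1)),
    vapply(kv, `[`, character(1), 1)
  )
  grid <- grid_spec(
    vals[["n_rows"]], vals[["n_cols"]], vals[["cell_size_km"]],
    vals[["origin_x"]], vals[["origin_y"]]
  )
  m <- as.matrix(utils::read.table(path, sep = "\t", skip = 1, header = FALSE))
  dimnames(m) <- NULL
  stopifnot(nrow(m) == grid$n_rows, ncol(m) == grid$n_cols)
  list(values = m, grid = grid)
}

# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed %% .Machine$integer.max), code)
}

# Deterministically derive a stream-specific sub-seed from a master seed.
derive_seed <- function(seed, ...) {
  parts <- unlist(list(...))
  h <- as.numeric(seed) %% 2147483629
  for (p in parts) {
    bytes <- utf8ToInt(paste0(as.character(p), "|"))
    for (b in bytes) h <- (h * 131 + b) %% 2147483629
  }
  as.integer(h + 1)
}
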