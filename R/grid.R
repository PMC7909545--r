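#' Define a regular analysis grid
#'
#' The grid is the spatial frame every other computation hangs off: a regular
#' lattice of square cells in a planar (projected) coordinate system.  Cell
#' ids are 0-based, row-major from the lower-left corner, i.e.
#' `id = row * n_cols + col`.  Geographic (lon/lat) coordinates must be
#' projected before use; the grid carries only a free-text `crs_label`.
#'
#' @param origin_x,origin_y Coordinates of the grid's lower-left corner, in
#'   projected units (metres for a national-scale study).
#' @param cell_size Side length of a square cell (same units; the study
#'   analogue is ~5000 m).
#' @param n_rows,n_cols Positive integer grid dimensions.
#' @param crs_label Free-text identifier of the planar reference system.
#'
#' @return A `grid_spec` object.
#' @examples
#' g <- grid_spec(0, 0, 10, 2, 2)
#' cell_of_xy(c(5, 10), c(5, 10), g)
#' @export
grid_spec <- function(origin_x, origin_y, cell_size, n_rows, n_cols,
                      crs_label = "planar") {
  stopifnot(is.numeric(origin_x), is.numeric(origin_y),
            length(origin_x) == 1L, length(origin_y) == 1L)
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("`cell_size` must be a single positive number", call. = FALSE)
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L)
    stop("`n_rows` and `n_cols` must be positive integers", call. = FALSE)
  structure(
    list(origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
         cell_size = as.numeric(cell_size),
         n_rows = n_rows, n_cols = n_cols, crs_label = crs_label),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells of %g units, origin (%g, %g), crs '%s'\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y,
              x$crs_label))
  invisible(x)
}

n_cells <- function(grid) grid$n_rows * grid$n_cols

#' Map planar coordinates to 0-based cell ids
#'
#' Points on an interior upper/right cell boundary belong to the next cell;
#' the outermost top/right boundary is clamped inward so the grid's bounding
#' box is fully covered.  Points outside the bounding box get `NA`.
#'
#' @param x,y Numeric coordinate vectors (recycled to common length).
#' @param grid A [grid_spec()].
#' @return Integer vector of 0-based cell ids (`NA` outside the grid).
#' @export
cell_of_xy <- function(x, y, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  n <- max(length(x), length(y))
  x <- rep_len(as.numeric(x), n); y <- rep_len(as.numeric(y), n)
  xmax <- grid$origin_x + grid$n_cols * grid$cell_size
  ymax <- grid$origin_y + grid$n_rows * grid$cell_size
  inside <- x >= grid$origin_x & x <= xmax & y >= grid$origin_y & y <= ymax
  col <- floor((x - grid$origin_x) / grid$cell_size)
  row <- floor((y - grid$origin_y) / grid$cell_size)
  col <- pmin(pmax(col, 0), grid$n_cols - 1L)  # clamp outer boundary inward
  row <- pmin(pmax(row, 0), grid$n_rows - 1L)
  out <- as.integer(row * grid$n_cols + col)
  out[!inside] <- NA_integer_
  out
}

#' Cell centre coordinates
#'
#' @param cell_id Integer vector of 0-based cell ids (default: all cells).
#' @param grid A [grid_spec()].
#' @return A tibble with columns `cell`, `x`, `y`.
#' @export
cell_centers <- function(grid, cell_id = seq_len(n_cells(grid)) - 1L) {
  stopifnot(inherits(grid, "grid_spec"))
  cell_id <- as.integer(cell_id)
  if (any(cell_id < 0L | cell_id >= n_cells(grid)))
    stop("cell ids out of range", call. = FALSE)
  row <- cell_id %/% grid$n_cols
  col <- cell_id %% grid$n_cols
  tibble::tibble(
    cell = cell_id,
    x = grid$origin_x + (col + 0.5) * grid$cell_size,
    y = grid$origin_y + (row + 0.5) * grid$cell_size
  )
}

#' Cell bounding boxes
#'
#' @inheritParams cell_centers
#' @return A tibble with columns `cell`, `xmin`, `ymin`, `xmax`, `ymax`.
#' @export
cell_bounds <- function(grid, cell_id = seq_len(n_cells(grid)) - 1L) {
  ctr <- cell_centers(grid, cell_id)
  h <- grid$cell_size / 2
  tibble::tibble(cell = ctr$cell,
                 xmin = ctr$x - h, ymin = ctr$y - h,
                 xmax = ctr$x + h, ymax = ctr$y + h)
}

#' Assign occurrence records to grid cells
#'
#' Fills the `cell` column from `x`/`y` where missing.  Records already
#' carrying a `cell` id are passed through untouched (the operation is
#' idempotent).  Records whose coordinates fall outside the grid bounding
#' box are never silently dropped: they are split off into a `rejects`
#' tibble.
#'
#' @param records A data frame with columns `taxon`, `endemic`, and either
#'   `x` + `y` or `cell`.
#' @param grid A [grid_spec()].
#' @return A list with tibbles `records` (with `cell` filled) and `rejects`.
#' @export
assign_cells <- function(records, grid) {
  stopifnot(is.data.frame(records), inherits(grid, "grid_spec"))
  records <- tibble::as_tibble(records)
  if (!"taxon" %in% names(records))
    stop("`records` must have a `taxon` column", call. = FALSE)
  if (!"cell" %in% names(records)) records$cell <- NA_integer_
  need <- is.na(records$cell)
  if (any(need)) {
    if (!all(c("x", "y") %in% names(records)))
      stop("records without `cell` need `x` and `y` columns", call. = FALSE)
    records$cell[need] <- cell_of_xy(records$x[need], records$y[need], grid)
  }
  bad <- is.na(records$cell)
  list(records = records[!bad, , drop = FALSE],
       rejects = records[bad, , drop = FALSE])
}
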