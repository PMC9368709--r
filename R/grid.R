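#' Grid geometry shared by all raster layers
#'
#' A `grid_spec` records the common geometry every layer in an analysis must
#' share: grid shape, cell size, the planar coordinate of the upper-left
#' corner, which side of the grid faces the open sea, and the nodata sentinel
#' used on disk. Row 0 (R index 1) is the northernmost row; cell `(r, c)`
#' covers the half-open square starting at
#' `(origin_x + (c-1)*cell_size, origin_y - (r-1)*cell_size)`.
#'
#' @param n_rows,n_cols Grid shape; both at least 1.
#' @param cell_size Cell side length in metres (> 0). At the default 100 m
#'   each cell is exactly 1 ha.
#' @param origin Numeric length-2, planar `(x, y)` of the upper-left corner.
#' @param sea_side Which edge faces open water: `"east"`, `"west"`,
#'   `"north"` or `"south"`.
#' @param nodata_value Sentinel written for invalid cells in raster files.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(210, 214)
#' cell_area_ha(g)  # 1 ha per cell at 100 m
#' @export
grid_spec <- function(n_rows, n_cols, cell_size = 100,
                      origin = c(0, 0), sea_side = "east",
                      nodata_value = -9999) {
  stopifnot(length(n_rows) == 1, length(n_cols) == 1, length(cell_size) == 1)
  if (n_rows < 1 || n_cols < 1) {
    stop("grid must have at least one row and one column", call. = FALSE)
  }
  if (cell_size <= 0) stop("cell_size must be positive", call. = FALSE)
  sea_side <- match.arg(sea_side, c("east", "west", "north", "south"))
  stopifnot(is.numeric(origin), length(origin) == 2)
  structure(
    list(
      n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
      cell_size = as.numeric(cell_size),
      origin = as.numeric(origin), sea_side = sea_side,
      nodata_value = as.numeric(nodata_value)
    ),
    class = "grid_spec"
  )
}

#' @rdname grid_spec
#' @param grid A `grid_spec`.
#' @export
cell_area_ha <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  grid$cell_size^2 / 1e4
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> %d x %d cells of %g m (%g ha), origin (%g, %g), sea to the %s\n",
    x$n_rows, x$n_cols, x$cell_size, cell_area_ha(x),
    x$origin[1], x$origin[2], x$sea_side
  ))
  invisible(x)
}

grids_equal <- function(a, b) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    isTRUE(all.equal(a$origin, b$origin)) &&
    a$sea_side == b$sea_side
}

#' Raster layer on a shared grid
#'
#' A `wx_layer` couples a value matrix to its [grid_spec()]. Invalid (nodata)
#' cells are stored as `NA` and excluded from every statistic and every
#' propagation update. Categorical layers hold integer class codes.
#'
#' @param grid A [grid_spec()].
#' @param values Numeric matrix of shape `(n_rows, n_cols)`; `NA` marks
#'   invalid cells.
#' @param kind `"continuous"` or `"categorical"`.
#' @return An object of class `wx_layer`.
#' @export
wx_layer <- function(grid, values, kind = c("continuous", "categorical")) {
  stopifnot(inherits(grid, "grid_spec"), is.matrix(values))
  kind <- match.arg(kind)
  if (nrow(values) != grid$n_rows || ncol(values) != grid$n_cols) {
    stop(sprintf(
      "values matrix is %d x %d but grid is %d x %d",
      nrow(values), ncol(values), grid$n_rows, grid$n_cols
    ), call. = FALSE)
  }
  storage.mode(values) <- "double"
  if (kind == "categorical") {
    v <- values[!is.na(values)]
    if (length(v) && any(v != round(v))) {
      stop("categorical layer contains non-integer values", call. = FALSE)
    }
  }
  structure(list(grid = grid, values = values, kind = kind),
            class = "wx_layer")
}

#' @rdname wx_layer
#' @param x A `wx_layer`.
#' @export
layer_mask <- function(x) {
  stopifnot(inherits(x, "wx_layer"))
  !is.na(x$values)
}

#' @export
print.wx_layer <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf(
    "<wx_layer:%s> %d x %d, %d valid cells, range [%g, %g]\n",
    x$kind, x$grid$n_rows, x$grid$n_cols, length(v),
    if (length(v)) min(v) else NA, if (length(v)) max(v) else NA
  ))
  invisible(x)
}

# Build a layer quickly from a constant or matrix (internal convenience).
as_layer <- function(grid, values, kind = "continuous") {
  if (length(values) == 1) {
    values <- matrix(values, grid$n_rows, grid$n_cols)
  }
  wx_layer(grid, values, kind)
}

#' Check that a set of layers shares one grid geometry
#'
#' Returns `TRUE` only when every layer has an identical [grid_spec()]
#' (shape, cell size, origin and sea side). Downstream stages treat a
#' `FALSE` as fatal: statistics and propagation across misaligned rasters
#' are meaningless.
#'
#' @param layers A list of [wx_layer()] objects (at least two).
#' @return Logical scalar.
#' @export
align_check <- function(layers) {
  stopifnot(is.list(layers), length(layers) >= 2)
  if (!all(vapply(layers, inherits, logical(1), "wx_layer"))) {
    stop("align_check expects a list of wx_layer objects", call. = FALSE)
  }
  g0 <- layers[[1]]$grid
  all(vapply(layers[-1], function(l) grids_equal(g0, l$grid), logical(1)))
}

require_aligned <- function(...) {
  layers <- list(...)
  if (length(layers) >= 2 && !align_check(layers)) {
    stop("input layers are not aligned on a common grid", call. = FALSE)
  }
  invisible(TRUE)
}
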