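#' Read a single-band raster layer
#'
#' Reads an ESRI ASCII grid (`.asc`) into a [wx_layer()]. The header's
#' `ncols`/`nrows`/`cellsize`/corner coordinates populate the [grid_spec()];
#' cells equal to the file's `NODATA_value` are masked (`NA`). The format
#' carries no sea-side orientation, so that is supplied by the caller.
#'
#' @param path Path to an existing `.asc` file.
#' @param expected_kind `"continuous"` or `"categorical"`; a categorical read
#'   of non-integer values is a validation error.
#' @param sea_side Sea-facing edge to record in the grid spec.
#' @return A [wx_layer()].
#' @export
read_layer <- function(path, expected_kind = c("continuous", "categorical"),
                       sea_side = "east") {
  expected_kind <- match.arg(expected_kind)
  if (!file.exists(path)) {
    stop(sprintf("raster file not found: %s", path), call. = FALSE)
  }
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    stop("GeoTIFF input is not supported; supply an ESRI ASCII grid (.asc)",
         call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  body_start <- 1L
  for (i in seq_along(lines)) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) == 2 && is.na(suppressWarnings(as.numeric(parts[1])))) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      body_start <- i + 1L
    } else {
      break
    }
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop(sprintf("not a valid ESRI ASCII grid header in %s", path),
         call. = FALSE)
  }
  nr <- as.integer(hdr$nrows)
  nc <- as.integer(hdr$ncols)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[body_start:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nr * nc) {
    stop(sprintf("expected %d values, found %d in %s", nr * nc,
                 length(vals), path), call. = FALSE)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  if (expected_kind == "categorical") {
    v <- m[!is.na(m)]
    if (length(v) && any(v != round(v))) {
      stop("categorical read found non-integer cell values", call. = FALSE)
    }
  }
  # llcorner is the lower-left; our origin convention is the upper-left
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else 0
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else 0
  grid <- grid_spec(nr, nc, cell_size = hdr$cellsize,
                    origin = c(xll, yll + nr * hdr$cellsize),
                    sea_side = sea_side, nodata_value = nodata)
  wx_layer(grid, m, kind = expected_kind)
}

#' Write a layer as an ESRI ASCII grid
#'
#' Inverse of [read_layer()]: masked cells are written as the grid's nodata
#' sentinel. Values are printed with 15 significant digits so continuous
#' round-trips are lossless to double precision.
#'
#' @param layer A [wx_layer()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_layer <- function(layer, path) {
  stopifnot(inherits(layer, "wx_layer"))
  g <- layer$grid
  m <- layer$values
  m[is.na(m)] <- g$nodata_value
  hdr <- c(
    sprintf("ncols %d", g$n_cols),
    sprintf("nrows %d", g$n_rows),
    sprintf("xllcorner %.10g", g$origin[1]),
    sprintf("yllcorner %.10g", g$origin[2] - g$n_rows * g$cell_size),
    sprintf("cellsize %.10g", g$cell_size),
    sprintf("NODATA_value %.10g", g$nodata_value)
  )
  rows <- apply(m, 1, function(r) paste(format(r, digits = 15, trim = TRUE,
                                               scientific = FALSE),
                                        collapse = " "))
  ok <- tryCatch({
    writeLines(c(hdr, rows), path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop(sprintf("cannot write raster to %s", path), call. = FALSE)
  invisible(path)
}
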