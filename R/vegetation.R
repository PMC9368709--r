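#' Wetland vegetation class codes
#'
#' Integer codes for the categorical vegetation-type layer. The codes are
#' stable across years within a study: `SEA` = 0, `MUDFLAT` = 1,
#' `SUAEDA_SALSA` = 2 (short pioneer halophyte), `PHRAGMITES_AUSTRALIS` = 3
#' (tall reed of the landward belt), `SPARTINA_ALTERNIFLORA` = 4 (tall
#' invasive cordgrass of the seaward flat), `OTHER_LAND` = 5 (reclaimed
#' land, roads, ditches).
#'
#' @return Named integer vector of class codes.
#' @export
wetland_classes <- function() {
  c(SEA = 0L, MUDFLAT = 1L, SUAEDA_SALSA = 2L,
    PHRAGMITES_AUSTRALIS = 3L, SPARTINA_ALTERNIFLORA = 4L,
    OTHER_LAND = 5L)
}

veg_code <- function(name) unname(wetland_classes()[name])

#' Coverage bin codes
#'
#' Fractional vegetation cover is discretised into three bins:
#' `LOW` (< 50 %), `MID` (50-75 %), `HIGH` (>= 75 %). Codes are
#' `LOW` = 0, `MID` = 1, `HIGH` = 2.
#'
#' @return Named integer vector of bin codes.
#' @export
coverage_bins <- function() c(LOW = 0L, MID = 1L, HIGH = 2L)

#' NDVI stretch parameters for fractional vegetation cover
#'
#' Parameters of the dimidiate pixel model stretch that converts NDVI to
#' fractional vegetation cover (VFC). With `stretch_mode = "exact_extrema"`
#' the scene minimum maps to 0 and the scene maximum to 1; the
#' `"percentile"` mode substitutes robust percentiles (default 2 %/98 %)
#' because scene extrema are outlier-sensitive. Explicit `ndvi_min`/
#' `ndvi_max` override the scene statistics entirely.
#'
#' @param ndvi_min,ndvi_max Optional fixed stretch endpoints
#'   (`ndvi_max > ndvi_min`).
#' @param stretch_mode `"exact_extrema"` or `"percentile"`.
#' @param percentile_pair Low/high probabilities used in percentile mode.
#' @return An object of class `ndvi_params`.
#' @export
ndvi_params <- function(ndvi_min = NULL, ndvi_max = NULL,
                        stretch_mode = c("exact_extrema", "percentile"),
                        percentile_pair = c(0.02, 0.98)) {
  stretch_mode <- match.arg(stretch_mode)
  if (!is.null(ndvi_min) && !is.null(ndvi_max) && ndvi_max <= ndvi_min) {
    stop("ndvi_max must exceed ndvi_min", call. = FALSE)
  }
  structure(list(ndvi_min = ndvi_min, ndvi_max = ndvi_max,
                 stretch_mode = stretch_mode,
                 percentile_pair = percentile_pair),
            class = "ndvi_params")
}

#' Normalised difference vegetation index
#'
#' Per-cell `NDVI = (NIR - R) / (NIR + R)` from co-registered near-infrared
#' and red reflectance layers. Cells where both bands are zero are masked.
#'
#' @param nir,red Aligned reflectance [wx_layer()]s, values >= 0.
#' @return Continuous [wx_layer()] with values in `[-1, 1]`.
#' @export
compute_ndvi <- function(nir, red) {
  require_aligned(nir, red)
  if (any(nir$values < 0, na.rm = TRUE) || any(red$values < 0, na.rm = TRUE)) {
    stop("reflectance values must be non-negative", call. = FALSE)
  }
  s <- nir$values + red$values
  ndvi <- (nir$values - red$values) / s
  ndvi[!is.na(s) & s == 0] <- NA_real_
  wx_layer(nir$grid, ndvi, "continuous")
}

#' Fractional vegetation cover from NDVI
#'
#' Dimidiate pixel model: `VFC = (NDVI - NDVImin) / (NDVImax - NDVImin)`,
#' clipped to `[0, 1]`. Stretch endpoints come from `params` (fixed values,
#' scene extrema, or scene percentiles).
#'
#' @param ndvi NDVI [wx_layer()].
#' @param params An [ndvi_params()].
#' @return Continuous [wx_layer()] with values in `[0, 1]`.
#' @export
compute_vfc <- function(ndvi, params = ndvi_params()) {
  stopifnot(inherits(ndvi, "wx_layer"), inherits(params, "ndvi_params"))
  v <- ndvi$values[!is.na(ndvi$values)]
  if (!length(v)) stop("NDVI layer is fully masked", call. = FALSE)
  if (!is.null(params$ndvi_min) && !is.null(params$ndvi_max)) {
    lo <- params$ndvi_min; hi <- params$ndvi_max
  } else if (params$stretch_mode == "exact_extrema") {
    lo <- min(v); hi <- max(v)
  } else {
    q <- stats::quantile(v, params$percentile_pair, names = FALSE, type = 7)
    lo <- q[1]; hi <- q[2]
  }
  if (hi <= lo) {
    stop("degenerate NDVI stretch: ndvi_max equals ndvi_min", call. = FALSE)
  }
  vfc <- pmin(1, pmax(0, (ndvi$values - lo) / (hi - lo)))
  wx_layer(ndvi$grid, matrix(vfc, nrow(ndvi$values), ncol(ndvi$values)),
           "continuous")
}

#' Discretise vegetation cover into the three coverage bins
#'
#' `VFC < 0.50` is `LOW`; `0.50 <= VFC < 0.75` is `MID`; `VFC >= 0.75` is
#' `HIGH`. The partition is total over `[0, 1]`: 0.50 falls in `MID` and
#' 0.75 in `HIGH`.
#'
#' @param vfc VFC [wx_layer()] with values in `[0, 1]`.
#' @return Categorical [wx_layer()] of [coverage_bins()] codes.
#' @export
bin_coverage <- function(vfc) {
  stopifnot(inherits(vfc, "wx_layer"))
  v <- vfc$values
  if (any(v < 0 | v > 1, na.rm = TRUE)) {
    stop("VFC values must lie in [0, 1]", call. = FALSE)
  }
  bins <- matrix(NA_real_, nrow(v), ncol(v))
  bins[!is.na(v) & v < 0.50] <- 0
  bins[!is.na(v) & v >= 0.50 & v < 0.75] <- 1
  bins[!is.na(v) & v >= 0.75] <- 2
  wx_layer(vfc$grid, bins, "categorical")
}
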