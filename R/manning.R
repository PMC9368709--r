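#' Manning roughness lookup table
#'
#' The per-cell Manning roughness of an intertidal flat is composed
#' additively from three contributions, `n = nbase + ntopo + nvege`:
#' a bare-soil background, a micro-topography term, and a vegetation term
#' that depends on growth form and coverage bin. Defaults are the standard
#' muddy-tidal-flat assignments used throughout the analysis:
#'
#' * `nbase`: 0.025 for bare wetland soil, 0.030 where more than 25 % of the
#'   cell is covered by gravel and broken shells;
#' * `ntopo`: 0.001 for a typical flat surface without micro-landforms; a
#'   non-flat value is a configurable extension (`ntopo_non_flat`, unset by
#'   default);
#' * `nvege`: short-stemmed soft-leaf vegetation (Suaeda salsa)
#'   0.025/0.030/0.035 for LOW/MID/HIGH coverage; tall-stemmed soft-leaf
#'   vegetation (Phragmites australis, Spartina alterniflora)
#'   0.050/0.060/0.070; unvegetated classes contribute 0.
#'
#' All entries are overridable for sensitivity analysis.
#'
#' @param nbase_default,nbase_shelly Base-soil values.
#' @param shelly_fraction_threshold Shell/gravel cover fraction above which
#'   `nbase_shelly` applies.
#' @param ntopo_flat Micro-topography value for flat cells.
#' @param ntopo_non_flat Optional value for non-flat cells (`NULL` = not
#'   configured; requesting a non-flat lookup then errors).
#' @param nvege_short,nvege_tall Named vectors `c(LOW=, MID=, HIGH=)`.
#' @param nvege_none Vegetation term for unvegetated classes.
#' @return An object of class `roughness_table`.
#' @export
roughness_table <- function(nbase_default = 0.025, nbase_shelly = 0.030,
                            shelly_fraction_threshold = 0.25,
                            ntopo_flat = 0.001, ntopo_non_flat = NULL,
                            nvege_short = c(LOW = 0.025, MID = 0.030, HIGH = 0.035),
                            nvege_tall = c(LOW = 0.050, MID = 0.060, HIGH = 0.070),
                            nvege_none = 0.0) {
  stopifnot(all(c("LOW", "MID", "HIGH") %in% names(nvege_short)),
            all(c("LOW", "MID", "HIGH") %in% names(nvege_tall)))
  vals <- c(nbase_default, nbase_shelly, ntopo_flat, ntopo_non_flat,
            nvege_short, nvege_tall, nvege_none)
  if (any(vals < 0)) stop("roughness entries must be >= 0", call. = FALSE)
  if (is.unsorted(nvege_short[c("LOW", "MID", "HIGH")]) ||
      is.unsorted(nvege_tall[c("LOW", "MID", "HIGH")])) {
    stop("nvege must be monotone non-decreasing in coverage bin",
         call. = FALSE)
  }
  structure(list(
    nbase_default = nbase_default, nbase_shelly = nbase_shelly,
    shelly_fraction_threshold = shelly_fraction_threshold,
    ntopo_flat = ntopo_flat, ntopo_non_flat = ntopo_non_flat,
    nvege_short = nvege_short[c("LOW", "MID", "HIGH")],
    nvege_tall = nvege_tall[c("LOW", "MID", "HIGH")],
    nvege_none = nvege_none
  ), class = "roughness_table")
}

#' Base-soil roughness contribution
#'
#' @param shelly Logical (vectorised): is more than the threshold fraction of
#'   the cell covered by gravel and broken shells?
#' @param table A [roughness_table()].
#' @return Numeric, `nbase` per input.
#' @export
nbase_for <- function(shelly, table = roughness_table()) {
  ifelse(shelly, table$nbase_shelly, table$nbase_default)
}

#' Micro-topography roughness contribution
#'
#' @param terrain_class `"flat"` or `"non_flat"` (vectorised).
#' @param table A [roughness_table()].
#' @return Numeric, `ntopo` per input.
#' @export
ntopo_for <- function(terrain_class, table = roughness_table()) {
  bad <- setdiff(unique(terrain_class[!is.na(terrain_class)]),
                 c("flat", "non_flat"))
  if (length(bad)) {
    stop(sprintf("unknown terrain class: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  if (isTRUE(any(terrain_class == "non_flat", na.rm = TRUE)) &&
      is.null(table$ntopo_non_flat)) {
    stop("non-flat cells present but no ntopo_non_flat value configured",
         call. = FALSE)
  }
  out <- rep(table$ntopo_flat, length(terrain_class))
  nf <- !is.na(terrain_class) & terrain_class == "non_flat"
  out[nf] <- table$ntopo_non_flat
  out[is.na(terrain_class)] <- NA_real_
  out
}

#' Vegetation roughness contribution
#'
#' Suaeda salsa uses the short-vegetation column; Phragmites australis and
#' Spartina alterniflora use the tall-vegetation column; sea, mudflat and
#' other land contribute `nvege_none`.
#'
#' @param veg Vegetation class code(s), see [wetland_classes()].
#' @param bin Coverage bin code(s), see [coverage_bins()]. Ignored for
#'   unvegetated classes.
#' @param table A [roughness_table()].
#' @return Numeric, `nvege` per input.
#' @export
nvege_for <- function(veg, bin, table = roughness_table()) {
  cls <- wetland_classes()
  bad <- setdiff(unique(veg[!is.na(veg)]), cls)
  if (length(bad)) {
    stop(sprintf("unknown vegetation class code: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  out <- rep(table$nvege_none, length(veg))
  short <- !is.na(veg) & veg == cls[["SUAEDA_SALSA"]]
  tall <- !is.na(veg) & veg %in% cls[c("PHRAGMITES_AUSTRALIS",
                                       "SPARTINA_ALTERNIFLORA")]
  bin_name <- names(coverage_bins())[match(bin, coverage_bins())]
  if (any((short | tall) & is.na(bin_name))) {
    stop("vegetated cells require a valid coverage bin", call. = FALSE)
  }
  out[short] <- table$nvege_short[bin_name[short]]
  out[tall] <- table$nvege_tall[bin_name[tall]]
  out[is.na(veg)] <- NA_real_
  out
}

#' Classify micro-relief from an elevation layer
#'
#' Optional helper for the `ntopo` extension point: a cell is `non_flat`
#' when the elevation range within its 3x3 neighbourhood exceeds
#' `threshold` (default 0.5 m).
#'
#' @param elevation Elevation [wx_layer()] in metres.
#' @param threshold Relief threshold in metres.
#' @return Character matrix of `"flat"`/`"non_flat"`.
#' @export
classify_relief <- function(elevation, threshold = 0.5) {
  stopifnot(inherits(elevation, "wx_layer"))
  e <- elevation$values
  lo <- e; hi <- e
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    s <- shift_matrix(e, dr, dc, fill = NA_real_)
    lo <- pmin(lo, s, na.rm = TRUE)
    hi <- pmax(hi, s, na.rm = TRUE)
  }
  out <- matrix("flat", nrow(e), ncol(e))
  out[(hi - lo) > threshold] <- "non_flat"
  out[is.na(e)] <- NA_character_
  out
}

#' Compose the per-cell Manning roughness raster
#'
#' Sums the three lookup contributions per cell. Open-sea cells receive
#' `n = 0` so that water never attenuates the exchange signal; masked cells
#' stay masked.
#'
#' @param veg Categorical vegetation [wx_layer()] of [wetland_classes()]
#'   codes.
#' @param bins Categorical coverage-bin [wx_layer()] ([bin_coverage()]).
#' @param terrain Optional character matrix (`"flat"`/`"non_flat"`, e.g.
#'   from [classify_relief()]); default all flat.
#' @param shelly Optional logical matrix flagging shell/gravel covered
#'   cells; default all `FALSE` (muddy flat).
#' @param table A [roughness_table()].
#' @return Continuous [wx_layer()] of Manning `n`.
#' @export
compose_manning <- function(veg, bins, terrain = NULL, shelly = NULL,
                            table = roughness_table()) {
  require_aligned(veg, bins)
  g <- veg$grid
  if (is.null(terrain)) terrain <- matrix("flat", g$n_rows, g$n_cols)
  if (is.null(shelly)) shelly <- matrix(FALSE, g$n_rows, g$n_cols)
  stopifnot(identical(dim(terrain), dim(veg$values)),
            identical(dim(shelly), dim(veg$values)))
  vveg <- as.vector(veg$values)
  n <- nbase_for(as.vector(shelly), table) +
    ntopo_for(as.vector(terrain), table) +
    nvege_for(vveg, as.vector(bins$values), table)
  n[!is.na(vveg) & vveg == wetland_classes()[["SEA"]]] <- 0
  n[is.na(vveg)] <- NA_real_
  wx_layer(g, matrix(n, g$n_rows, g$n_cols), "continuous")
}
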