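#' Paths to bundled example tables
#'
#' The package ships the reported summary tables of the Yancheng intertidal
#' wetland study series (1980-2017) as plain CSV, for worked-example
#' arithmetic and as format fixtures:
#'
#' * `yancheng_zonal_elevation.csv` — reported per-year zonal elevation
#'   min/max/mean (m) by vegetation belt;
#' * `yancheng_capacity_summary.csv` — reported first/last-year mean
#'   exchange capacity and the areas (km²) above/below the 0.7/0.4
#'   capacity thresholds;
#' * `yancheng_capacity_bin_areas.csv` — reported per-year per-belt areas
#'   (ha) by exchange-capacity bin.
#'
#' @param file File name, or `NULL` to list the available files.
#' @return A file path (or a vector of file names).
#' @examples
#' elev <- read.csv(tideflux_example("yancheng_zonal_elevation.csv"))
#' zonal_delta(elev, "SUAEDA_SALSA", 1980, 2017)  # +0.30 m
#' @export
tideflux_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "tideflux")))
  }
  p <- system.file("extdata", file, package = "tideflux")
  if (p == "") stop(sprintf("no bundled file named %s", file), call. = FALSE)
  p
}
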