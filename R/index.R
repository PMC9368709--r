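#' Material-exchange-function index against a reference year
#'
#' Per-cell `Hi = ln(Ex_i / Ex_0)`: the natural log of the ratio of a
#' year's exchange capacity to the reference year's (by convention the last
#' pre-disturbance year). `Hi = 0` means unchanged, negative means the cell
#' exchanges less material with the sea than it did in the reference state.
#' Cells where either capacity is zero (unreachable) are masked, with a
#' warning when any such cell exists.
#'
#' @param ex_year,ex_reference `exchange_capacity` objects on one grid.
#' @param year_label,reference_label Text labels carried in the result.
#' @return An `exchange_index` object: `$layer` (Hi), the two labels, and
#'   the two capacity layers (kept for arithmetic-difference change maps).
#' @export
exchange_index <- function(ex_year, ex_reference, year_label = "year",
                           reference_label = "reference") {
  stopifnot(inherits(ex_year, "exchange_capacity"),
            inherits(ex_reference, "exchange_capacity"))
  require_aligned(ex_year$layer, ex_reference$layer)
  a <- ex_year$layer$values
  b <- ex_reference$layer$values
  bad <- (!is.na(a) & a <= 0) | (!is.na(b) & b <= 0)
  hi <- log(a / b)
  hi[bad] <- NA_real_
  if (any(bad)) {
    warning(sprintf("%d cells with non-positive capacity masked in index",
                    sum(bad)), call. = FALSE)
  }
  if (all(is.na(hi) | ex_year$seed_mask)) {
    stop("exchange index is fully masked", call. = FALSE)
  }
  structure(list(
    layer = wx_layer(ex_year$layer$grid, hi, "continuous"),
    year_label = year_label, reference_label = reference_label,
    seed_mask = ex_year$seed_mask,
    ex_year = ex_year$layer, ex_reference = ex_reference$layer
  ), class = "exchange_index")
}

#' Aggregate exchange index over the wetland
#'
#' Default aggregation is the spatial mean of the per-cell log-ratios over
#' valid non-sea cells (`"mean_of_logs"`). The alternative
#' (`"log_of_means"`) takes the log of the ratio of mean capacities; by
#' Jensen's inequality the default is always the smaller (more negative)
#' of the two.
#'
#' @param hi An [exchange_index()].
#' @param mode `"mean_of_logs"` or `"log_of_means"`.
#' @return Numeric scalar.
#' @export
aggregate_index <- function(hi, mode = c("mean_of_logs", "log_of_means")) {
  stopifnot(inherits(hi, "exchange_index"))
  mode <- match.arg(mode)
  sel <- !is.na(hi$layer$values) & !hi$seed_mask
  if (mode == "mean_of_logs") {
    mean(hi$layer$values[sel])
  } else {
    log(mean(hi$ex_year$values[sel]) / mean(hi$ex_reference$values[sel]))
  }
}

#' Change map relative to the reference year
#'
#' In the default log-ratio mode this is the Hi surface itself (Hi already
#' encodes difference-from-reference in log space). The arithmetic mode
#' returns the plain capacity difference `Ex_i - Ex_0`.
#'
#' @param hi An [exchange_index()].
#' @param mode `"log_ratio"` or `"difference"`.
#' @return A [wx_layer()].
#' @export
change_map <- function(hi, mode = c("log_ratio", "difference")) {
  stopifnot(inherits(hi, "exchange_index"))
  mode <- match.arg(mode)
  if (mode == "log_ratio") return(hi$layer)
  wx_layer(hi$layer$grid, hi$ex_year$values - hi$ex_reference$values,
           "continuous")
}

#' Zonal statistics of a continuous layer by vegetation class
#'
#' Per-class minimum, maximum, mean and cell count of `target` over valid
#' cells; classes with no cells are omitted.
#'
#' @param target Continuous [wx_layer()].
#' @param veg Categorical vegetation [wx_layer()] of [wetland_classes()]
#'   codes.
#' @param classes Optional subset of class names to report.
#' @return A data.frame with columns `class`, `min`, `max`, `mean`,
#'   `n_cells`.
#' @export
zonal_stats <- function(target, veg, classes = NULL) {
  require_aligned(target, veg)
  cls <- wetland_classes()
  if (!is.null(classes)) cls <- cls[classes]
  rows <- lapply(names(cls), function(nm) {
    sel <- !is.na(veg$values) & veg$values == cls[[nm]] &
      !is.na(target$values)
    if (!any(sel)) return(NULL)
    v <- target$values[sel]
    data.frame(class = nm, min = min(v), max = max(v), mean = mean(v),
               n_cells = sum(sel))
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Area of each vegetation class by capacity bin
#'
#' Cross-tabulates exchange capacity into bins per vegetation class and
#' converts cell counts to areas. Bins are half-open `[lo, hi)` except the
#' last, which is closed, so a capacity exactly on an interior edge falls
#' in the upper bin and the maximum capacity 1 is kept. Capacities below
#' the first edge are reported in an `underflow` column rather than
#' dropped, so per-class areas are conserved.
#'
#' @param ex An `exchange_capacity`.
#' @param veg Categorical vegetation [wx_layer()].
#' @param bin_edges Strictly increasing edges, default `0.1, 0.2, ..., 1`.
#' @param units `"ha"` or `"km2"`.
#' @return A data.frame: one row per class present, one column per bin plus
#'   `underflow`.
#' @export
bin_area_table <- function(ex, veg, bin_edges = seq(0.1, 1, by = 0.1),
                           units = c("ha", "km2")) {
  stopifnot(inherits(ex, "exchange_capacity"))
  require_aligned(ex$layer, veg)
  units <- match.arg(units)
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    stop("bin edges must be strictly increasing", call. = FALSE)
  }
  per_cell <- cell_area_ha(ex$layer$grid) / if (units == "km2") 100 else 1
  nb <- length(bin_edges) - 1
  labs <- sprintf("%g-%g", bin_edges[-length(bin_edges)], bin_edges[-1])
  cls <- wetland_classes()
  land <- setdiff(names(cls), "SEA")
  rows <- lapply(land, function(nm) {
    sel <- !is.na(veg$values) & veg$values == cls[[nm]] &
      !is.na(ex$layer$values) & !ex$seed_mask
    if (!any(sel)) return(NULL)
    v <- ex$layer$values[sel]
    counts <- vapply(seq_len(nb), function(i) {
      if (i < nb) {
        sum(v >= bin_edges[i] & v < bin_edges[i + 1])
      } else {
        sum(v >= bin_edges[i] & v <= bin_edges[i + 1])
      }
    }, numeric(1))
    out <- data.frame(class = nm, underflow = sum(v < bin_edges[1]) * per_cell)
    out[labs] <- as.list(counts * per_cell)
    out
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  attr(out, "units") <- units
  out
}

#' Headline change metrics between the first and last year
#'
#' From per-year capacity summaries ([summarize_capacity()] rows bound
#' together in year order):
#' * `capacity_drop_fraction` — `(mean_first - mean_last) / mean_first`;
#' * `high_area_reduction_fraction` — relative loss of area with capacity
#'   above the high threshold;
#' * `low_area_fold_increase` — `(A_low_last - A_low_first) / A_low_first`.
#'
#' @param summaries A data.frame whose first and last rows are the first
#'   and last years, with columns `mean_ex`, `area_high_km2`,
#'   `area_low_km2`.
#' @return A one-row data.frame of the three metrics.
#' @export
headline_metrics <- function(summaries) {
  stopifnot(is.data.frame(summaries), nrow(summaries) >= 2,
            all(c("mean_ex", "area_high_km2", "area_low_km2") %in%
                  names(summaries)))
  a <- summaries[1, ]; b <- summaries[nrow(summaries), ]
  if (a$mean_ex == 0 || a$area_high_km2 == 0 || a$area_low_km2 == 0) {
    stop("degenerate first-year summary (zero denominator)", call. = FALSE)
  }
  data.frame(
    capacity_drop_fraction = (a$mean_ex - b$mean_ex) / a$mean_ex,
    high_area_reduction_fraction =
      (a$area_high_km2 - b$area_high_km2) / a$area_high_km2,
    low_area_fold_increase =
      (b$area_low_km2 - a$area_low_km2) / a$area_low_km2
  )
}

#' Difference of a zonal statistic between two years
#'
#' Utility over a long-format zonal summary table (columns `year`, `class`,
#' and the statistic columns): the change in one statistic for one class
#' between two years. Used, e.g., to derive per-belt elevation gains from
#' reported zonal elevation tables.
#'
#' @param summary_df Data.frame with `year`, `class` and `stat` columns.
#' @param class Class name to select.
#' @param from_year,to_year Years to difference (`to - from`).
#' @param stat Statistic column, default `"mean"`.
#' @return Numeric scalar.
#' @export
zonal_delta <- function(summary_df, class, from_year, to_year,
                        stat = "mean") {
  pick <- function(y) {
    r <- summary_df[summary_df$year == y & summary_df$class == class, stat]
    if (length(r) != 1) {
      stop(sprintf("no unique row for class %s, year %s", class, y),
           call. = FALSE)
    }
    r
  }
  pick(to_year) - pick(from_year)
}

#' Grand means of yearly zonal statistics
#'
#' Mean over years of each statistic, per class — the "Mean" row of a
#' yearly zonal summary table.
#'
#' @param summary_df Data.frame with `year`, `class` and statistic columns.
#' @param stats Statistic columns to average.
#' @return Data.frame, one row per class.
#' @export
zonal_grand_means <- function(summary_df, stats = c("min", "max", "mean")) {
  stats <- intersect(stats, names(summary_df))
  out <- lapply(split(summary_df, summary_df$class), function(d) {
    cbind(data.frame(class = d$class[1]),
          as.data.frame(lapply(d[stats], mean)))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
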