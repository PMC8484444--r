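#' @title Regional runs and favorability mapping
#' @description Multi-year per-cell simulations aggregated into annual
#'   cumulative pupal production and a map-normalized favorability index.
#' @name regional
NULL

#' Run one lattice cell over a multi-year weather series
#'
#' A single continuous simulation (no annual reset) driven by the series;
#' the annual value is the sum over each calendar year of the daily flux of
#' individuals entering the pupal stage ("new pupae").
#'
#' @param series A `weather_series` covering at least 2 calendar years.
#' @param sp A `species_params` object.
#' @param n0 Initial adults (default 10).
#' @param quiescence Passed to [initialize_population()].
#' @return Named numeric vector of cumulative new pupae per calendar year.
#' @export
run_cell <- function(series, sp, n0 = 10, quiescence = TRUE) {
  yrs <- format(series$date, "%Y")
  if (length(unique(yrs)) < 2)
    stop("run_cell: weather series must span at least 2 calendar years",
         call. = FALSE)
  pop <- initialize_population(sp, n0, quiescence = quiescence)
  res <- run_population(pop, series, sp)
  tab <- tapply(res$trace$new_pupae, yrs, sum)
  annual <- as.numeric(tab[unique(yrs)])
  names(annual) <- unique(yrs)
  annual
}

#' Multi-year summary statistics omitting the burn-in year
#'
#' Mean, standard deviation (sample, n-1 denominator), and coefficient of
#' variation of annual values, omitting the first year during which the model
#' is assumed to be equilibrating from its arbitrary initial condition.
#'
#' @param annual Numeric vector of per-year values (length >= 2).
#' @return Named vector `c(mean =, sd =, cv =)`.
#' @examples
#' summarize_years(c(100, 200, 300))  # mean 250
#' @export
summarize_years <- function(annual) {
  if (length(annual) < 2)
    stop("summarize_years: need at least 2 annual values", call. = FALSE)
  v <- annual[-1]
  m <- mean(v)
  s <- if (length(v) > 1) stats::sd(v) else 0
  c(mean = m, sd = s, cv = if (m > 0) s / m else NA_real_)
}

#' Run a whole lattice of cells
#'
#' Cells are independent; any execution order yields identical results.
#'
#' @param cells A data.frame with columns `cell_id`, `lon`, `lat`, `elev_m`,
#'   and either a `weather_path` column (files read with [read_weather()]) or
#'   a list-column `series` of `weather_series` objects.
#' @param sp A `species_params` object.
#' @param n0 Initial adults per cell.
#' @param elev_cutoff Elevation mask threshold, m (default 2000).
#' @param quiescence Passed to [run_cell()].
#' @param verbose Print per-cell progress lines.
#' @return A `cell_summary` data.frame (one row per cell) with per-cell
#'   mean/sd/cv of annual pupae, the mask flag, and the favorability index
#'   (see [favorability_map()]).
#' @export
run_lattice <- function(cells, sp, n0 = 10, elev_cutoff = 2000,
                        quiescence = TRUE, verbose = FALSE) {
  stopifnot(all(c("cell_id", "lon", "lat", "elev_m") %in% names(cells)))
  n <- nrow(cells)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    series <- if (!is.null(cells$series)) cells$series[[i]]
              else read_weather(cells$weather_path[i], cell_id = cells$cell_id[i])
    annual <- run_cell(series, sp, n0 = n0, quiescence = quiescence)
    stats <- summarize_years(annual)
    if (verbose)
      message(sprintf("cell %s: mean annual pupae %.3g (cv %.2f)",
                      cells$cell_id[i], stats[["mean"]], stats[["cv"]]))
    out[[i]] <- data.frame(cell_id = cells$cell_id[i], lon = cells$lon[i],
                           lat = cells$lat[i], elev_m = cells$elev_m[i],
                           mean_pupae = stats[["mean"]], sd_pupae = stats[["sd"]],
                           cv_pupae = stats[["cv"]],
                           years = length(annual))
  }
  summary <- do.call(rbind, out)
  favorability_map(summary, elev_cutoff = elev_cutoff)
}

#' Normalize per-cell abundance into a favorability index
#'
#' `FI = mean_pupae / max(mean_pupae)` over unmasked cells (elevation at or
#' below the cutoff), giving a qualitative index in \[0, 1\]: `FI <= 0.5`
#' low/decreasing favorability, `FI > 0.5` increasing favorability and
#' potential for establishment. Cells above the cutoff are masked: excluded
#' from the map maximum and assigned `FI = NA`.
#'
#' @param summary A data.frame with `mean_pupae` and `elev_m` columns.
#' @param elev_cutoff Elevation mask threshold, m (default 2000).
#' @return The input with `masked` and `fi` columns, class `cell_summary`.
#' @export
favorability_map <- function(summary, elev_cutoff = 2000) {
  stopifnot(all(c("mean_pupae", "elev_m") %in% names(summary)))
  masked <- summary$elev_m > elev_cutoff
  if (all(masked))
    stop("favorability_map: all cells masked by the elevation cutoff", call. = FALSE)
  mx <- max(summary$mean_pupae[!masked])
  if (!is.finite(mx) || mx <= 0)
    stop("favorability_map: no unmasked cell with positive mean pupae", call. = FALSE)
  summary$masked <- masked
  summary$fi <- ifelse(masked, NA_real_, summary$mean_pupae / mx)
  class(summary) <- c("cell_summary", "data.frame")
  summary
}

#' Export a cell summary as CSV and, for regular lattices, an ESRI ASCII grid
#'
#' The CSV always carries the full per-cell table. When `format = "asc"` the
#' cells must form a complete regular lon/lat lattice; the favorability index
#' is written as an ESRI ASCII grid (`ncols/nrows/xllcorner/yllcorner/
#' cellsize/NODATA_value` header, rows north to south) with masked cells as
#' nodata. The grid round-trips bit-exactly through [read_esri_ascii()].
#'
#' @param cells A `cell_summary`.
#' @param path Output path (extension added per format).
#' @param format `"csv"` or `"asc"`.
#' @param value Column to grid (default `"fi"`).
#' @param digits Significant digits written to the grid (default 17, enough
#'   to round-trip doubles bit-exactly).
#' @return The path written, invisibly.
#' @export
export_grid <- function(cells, path, format = c("csv", "asc"), value = "fi",
                        digits = 17) {
  format <- match.arg(format)
  if (identical(format, "csv")) {
    utils::write.csv(as.data.frame(cells), path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  lons <- sort(unique(cells$lon))
  lats <- sort(unique(cells$lat))
  step_ok <- function(v) length(v) == 1 || diff(range(diff(v))) < 1e-9
  if (nrow(cells) != length(lons) * length(lats) || !step_ok(lons) || !step_ok(lats))
    stop("export_grid: cells do not form a complete regular lattice; ",
         "use format = 'csv' for a table export", call. = FALSE)
  cs_x <- if (length(lons) > 1) lons[2] - lons[1] else 1
  cs_y <- if (length(lats) > 1) lats[2] - lats[1] else cs_x
  if (abs(cs_x - cs_y) > 1e-9)
    stop("export_grid: lon and lat spacing differ; ESRI ASCII needs square cells",
         call. = FALSE)
  nodata <- -9999
  m <- matrix(nodata, nrow = length(lats), ncol = length(lons))
  ri <- match(cells$lat, lats)
  ci <- match(cells$lon, lons)
  v <- cells[[value]]
  v[is.na(v)] <- nodata
  m[cbind(ri, ci)] <- v
  hdr <- c(paste("ncols", length(lons)),
           paste("nrows", length(lats)),
           paste("xllcorner", format(lons[1] - cs_x / 2, digits = 15)),
           paste("yllcorner", format(lats[1] - cs_x / 2, digits = 15)),
           paste("cellsize", format(cs_x, digits = 15)),
           paste("NODATA_value", nodata))
  body <- apply(m[rev(seq_len(nrow(m))), , drop = FALSE], 1L, function(r)
    paste(formatC(r, digits = digits, format = "g"), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path Path to a grid written by [export_grid()] (or any conformant
#'   ESRI ASCII raster).
#' @return List with `values` (matrix, row 1 = northernmost), `xllcorner`,
#'   `yllcorner`, `cellsize`, `nodata`; nodata cells are `NA`.
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- tolower(vapply(hdr, `[[`, "", 1L))
  vals <- as.numeric(vapply(hdr, `[[`, "", 2L))
  names(vals) <- keys
  ncols <- as.integer(vals[["ncols"]]); nrows <- as.integer(vals[["nrows"]])
  body <- lapply(lines[7:(6 + nrows)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  m <- do.call(rbind, body)
  stopifnot(ncol(m) == ncols)
  m[m == vals[["nodata_value"]]] <- NA_real_
  list(values = m, xllcorner = vals[["xllcorner"]],
       yllcorner = vals[["yllcorner"]], cellsize = vals[["cellsize"]],
       nodata = vals[["nodata_value"]])
}

#' Read a lattice description table
#'
#' CSV with columns `cell_id`, `lon`, `lat`, `elev_m`, and optionally
#' `weather_path` (resolved relative to the table's directory).
#'
#' @param path Path to the CSV.
#' @return data.frame suitable for [run_lattice()].
#' @export
read_lattice <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "lon", "lat", "elev_m")
  if (!all(need %in% names(df)))
    stop("lattice file '", path, "' must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  if ("weather_path" %in% names(df)) {
    rel <- !file.exists(df$weather_path)
    df$weather_path[rel] <- file.path(dirname(path), df$weather_path[rel])
  }
  df
}
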