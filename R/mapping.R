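# Gridded effect maps: per-location mean effects interpolated onto a 5 km
# grid by inverse distance weighting with a 20 km search radius and a
# minimum support of 5 survey locations per cell.

#' Per-location mean annual effect for mapping
#'
#' Averages a practice's effect over the assessment years (1995-2015 by
#' default, the 21-year map average) for each location; locations without
#' full year coverage are excluded with a warning.
#'
#' @param effects data.frame `location_id`, `year`, `effect`
#' @param frame a `survey_frame` providing coordinates
#' @param years years that must all be present per location
#' @return data.frame `location_id`, `x_km`, `y_km`, `value`
#' @export
average_effect_map <- function(effects, frame, years = 1995:2015) {
  e <- effects[effects$year %in% years & !is.na(effects$effect), ]
  cnt <- tapply(e$year, e$location_id, length)
  keep <- as.integer(names(cnt))[cnt == length(years)]
  if (length(keep) < length(cnt))
    warning(length(cnt) - length(keep),
            " location(s) excluded from the map: incomplete year coverage")
  e <- e[e$location_id %in% keep, ]
  mv <- tapply(e$effect, e$location_id, mean)
  ids <- as.integer(names(mv))
  li <- match(ids, frame$locations$location_id)
  data.frame(location_id = ids,
             x_km = frame$locations$x_km[li],
             y_km = frame$locations$y_km[li],
             value = as.numeric(mv))
}

#' Default grid specification covering the survey domain
#'
#' @param frame a `survey_frame`
#' @param cell_size_km grid cell size (default 5 km)
#' @return list `(origin, cell_size_km, nx, ny)`; `origin` is the lower-left
#'   corner
#' @export
default_grid <- function(frame, cell_size_km = 5) {
  list(origin = c(0, 0), cell_size_km = cell_size_km,
       nx = ceiling(frame$domain_km[1] / cell_size_km),
       ny = ceiling(frame$domain_km[2] / cell_size_km))
}

#' Inverse-distance-weighted interpolation onto a grid
#'
#' Each cell value is the distance-weighted mean (`w_i = d_i^-power`) of the
#' point values within `radius_km` of the cell centroid. Cells with fewer
#' than `min_points` points in radius are null. A point within 1 m of the
#' centroid short-circuits to its own value. Interpolated values are convex
#' combinations of contributing point values.
#'
#' @param points data.frame with `x_km`, `y_km`, `value`
#' @param grid_spec as from [default_grid()]
#' @param radius_km search radius (default 20 km)
#' @param min_points minimum supporting points per cell (default 5)
#' @param power inverse-distance exponent (default 2)
#' @param scenario optional label stored on the grid
#' @return object of class `effect_grid`: list with `values` (ny x nx matrix,
#'   row 1 = southern edge; `NA` = null), `origin`, `cell_size_km`, `scenario`
#' @export
idw_interpolate <- function(points, grid_spec, radius_km = 20, min_points = 5,
                            power = 2, scenario = NULL) {
  check_that(radius_km > 0, "radius must be positive")
  check_that(min_points >= 1, "min_points must be >= 1")
  nx <- grid_spec$nx; ny <- grid_spec$ny; cs <- grid_spec$cell_size_km
  cx <- grid_spec$origin[1] + (seq_len(nx) - 0.5) * cs
  cy <- grid_spec$origin[2] + (seq_len(ny) - 0.5) * cs
  vals <- matrix(NA_real_, ny, nx)
  if (nrow(points) > 0) {
    px <- points$x_km; py <- points$y_km; pv <- points$value
    r2 <- radius_km^2
    for (iy in seq_len(ny)) {
      dy2 <- (py - cy[iy])^2
      near_y <- dy2 <= r2
      if (!any(near_y)) next
      pxn <- px[near_y]; pvn <- pv[near_y]; dy2n <- dy2[near_y]
      for (ix in seq_len(nx)) {
        d2 <- (pxn - cx[ix])^2 + dy2n
        sel <- d2 <= r2
        if (sum(sel) < min_points) next
        d <- sqrt(d2[sel])
        if (any(d < 0.001)) {               # within 1 m of the centroid
          vals[iy, ix] <- pvn[sel][which.min(d)]
        } else {
          wgt <- d^(-power)
          vals[iy, ix] <- sum(wgt * pvn[sel]) / sum(wgt)
        }
      }
    }
  }
  structure(list(values = vals, origin = grid_spec$origin,
                 cell_size_km = cs, scenario = scenario),
            class = "effect_grid")
}

#' @export
print.effect_grid <- function(x, ...) {
  cat("effect_grid:", nrow(x$values), "x", ncol(x$values), "cells of",
      x$cell_size_km, "km;", sum(!is.na(x$values)), "non-null\n")
  invisible(x)
}

#' Write an effect grid as an ESRI ASCII raster
#'
#' Writes the standard `.asc` header (`NCOLS`, `NROWS`, `XLLCORNER`,
#' `YLLCORNER`, `CELLSIZE`, `NODATA_VALUE`) followed by rows north to south,
#' plus a companion `.meta.txt` naming the scenario and units.
#'
#' @param grid an `effect_grid`
#' @param path output path (conventionally ending in `.asc`)
#' @param nodata value written for null cells (default -9999)
#' @return `path`, invisibly
#' @export
write_effect_grid <- function(grid, path, nodata = -9999) {
  v <- grid$values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("NCOLS", ncol(v)),
    paste("NROWS", nrow(v)),
    paste("XLLCORNER", grid$origin[1]),
    paste("YLLCORNER", grid$origin[2]),
    paste("CELLSIZE", grid$cell_size_km),
    paste("NODATA_VALUE", nodata)), con)
  for (iy in rev(seq_len(nrow(v))))        # north to south
    writeLines(paste(format(v[iy, ], trim = TRUE), collapse = " "), con)
  meta <- paste0(sub("\\.asc$", "", path), ".meta.txt")
  writeLines(c(paste("scenario:", grid$scenario %||% "unspecified"),
               "units: t C ha-1 yr-1 (mean annual SOC stock-change effect)",
               paste("cell_size_km:", grid$cell_size_km)), meta)
  invisible(path)
}
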