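#' Systematic ROI grid over an image
#'
#' Tiles an image extent with square sampling windows placed at fixed
#' center-to-center intervals from an origin (defaults: 89.51 um windows
#' every 100 um, the systematic-sampling geometry for confocal montages
#' of the midline thalamus). Windows that would extend beyond the image
#' are generated but marked excluded.
#'
#' @param image_extent_um c(x, y) extent of the image, um.
#' @param spacing_um center-to-center window interval, um.
#' @param window_um window side, um.
#' @param origin c(x, y) of the first window's upper-left corner, um.
#' @return data frame of class `RoiGrid` with one row per window:
#'   `window_id`, `ix`, `iy` (grid indices), `x_um`, `y_um` (window
#'   origin), `included`, `region`. Attributes `window_um`, `spacing_um`,
#'   `origin` carry the geometry.
#' @export
build_grid <- function(image_extent_um, spacing_um = 100,
                       window_um = 89.51, origin = c(0, 0)) {
  if (spacing_um <= 0 || window_um <= 0)
    stop("spacing and window side must be positive")
  stopifnot(length(image_extent_um) == 2L, length(origin) == 2L)
  xs <- seq(origin[1], image_extent_um[1], by = spacing_um)
  ys <- seq(origin[2], image_extent_um[2], by = spacing_um)
  xs <- xs[xs < image_extent_um[1]]
  ys <- ys[ys < image_extent_um[2]]
  g <- expand.grid(ix = seq_along(xs), iy = seq_along(ys))
  g$x_um <- xs[g$ix]; g$y_um <- ys[g$iy]
  g$included <- g$x_um >= 0 & g$y_um >= 0 &
    g$x_um + window_um <= image_extent_um[1] &
    g$y_um + window_um <= image_extent_um[2]
  g$region <- NA_character_
  g$window_id <- sprintf("w%02d_%02d", g$ix, g$iy)
  g <- g[, c("window_id", "ix", "iy", "x_um", "y_um", "included", "region")]
  attr(g, "window_um") <- window_um
  attr(g, "spacing_um") <- spacing_um
  attr(g, "origin") <- origin
  class(g) <- c("RoiGrid", "data.frame")
  g
}

# pixel index ranges (rows = y, cols = x) whose centers fall in a window
window_pixels <- function(x0, y0, window_um, pixel_size_um, nrow, ncol) {
  cols <- which((seq_len(ncol) - 0.5) * pixel_size_um >= x0 &
                  (seq_len(ncol) - 0.5) * pixel_size_um <= x0 + window_um)
  rows <- which((seq_len(nrow) - 0.5) * pixel_size_um >= y0 &
                  (seq_len(nrow) - 0.5) * pixel_size_um <= y0 + window_um)
  list(rows = rows, cols = cols)
}

#' Assign anatomical regions to grid windows
#'
#' Labels every included window with the majority region
#' (MDm / transition / core / none) of the pixels it covers. Windows
#' whose majority label is `none`, or whose top labels tie exactly, are
#' excluded — ambiguous windows do not enter region comparisons.
#'
#' @param grid a [build_grid()] result.
#' @param field a `RegionField` from [generate_region_field()], or any
#'   list with `labels` (character matrix, rows = y) and `pixel_size_um`.
#' @return the grid with `region` filled and `included` updated.
#' @export
assign_regions <- function(grid, field) {
  stopifnot(inherits(grid, "RoiGrid"))
  if (is.null(field$labels) || is.null(field$pixel_size_um))
    stop("`field` must carry a label map and a pixel size")
  labs <- field$labels
  ps <- field$pixel_size_um
  w <- attr(grid, "window_um")
  for (i in seq_len(nrow(grid))) {
    if (!grid$included[i]) next
    px <- window_pixels(grid$x_um[i], grid$y_um[i], w, ps,
                        nrow(labs), ncol(labs))
    if (!length(px$rows) || !length(px$cols)) {
      grid$included[i] <- FALSE
      next
    }
    tab <- sort(table(labs[px$rows, px$cols]), decreasing = TRUE)
    tie <- length(tab) > 1L && tab[1] == tab[2]
    if (tie || names(tab)[1] == "none") {
      grid$included[i] <- FALSE
    } else {
      grid$region[i] <- names(tab)[1]
    }
  }
  grid
}

#' Mean fluorescence intensity inside one window
#'
#' Arithmetic mean of the pixel intensities whose centers fall in the
#' window; raw arbitrary units, no background subtraction.
#'
#' @param image numeric matrix (rows = y, cols = x).
#' @param x_um,y_um window origin (upper-left), um.
#' @param window_um window side, um.
#' @param pixel_size_um physical pixel size, um.
#' @return mean intensity (AU).
#' @export
roi_mean_intensity <- function(image, x_um, y_um, window_um,
                               pixel_size_um) {
  px <- window_pixels(x_um, y_um, window_um, pixel_size_um,
                      nrow(image), ncol(image))
  if (!length(px$rows) || !length(px$cols))
    stop("window covers no pixels")
  mean(image[px$rows, px$cols])
}

#' Measure a per-window image statistic over a grid
#'
#' Fills one column of the grid with the per-window mean intensity of an
#' image channel (or any per-window statistic supplied via `fun`).
#'
#' @param grid a [build_grid()] (optionally region-assigned) grid.
#' @param image numeric matrix (rows = y, cols = x).
#' @param pixel_size_um physical pixel size, um.
#' @param name column name for the measurement.
#' @param fun function(matrix) -> scalar; default `mean`.
#' @return the grid with the new column (NA for excluded windows).
#' @export
measure_grid <- function(grid, image, pixel_size_um,
                         name = "mean_intensity", fun = mean) {
  stopifnot(inherits(grid, "RoiGrid"))
  w <- attr(grid, "window_um")
  vals <- rep(NA_real_, nrow(grid))
  for (i in seq_len(nrow(grid))) {
    if (!grid$included[i]) next
    px <- window_pixels(grid$x_um[i], grid$y_um[i], w, pixel_size_um,
                        nrow(image), ncol(image))
    if (!length(px$rows) || !length(px$cols)) next
    vals[i] <- fun(image[px$rows, px$cols])
  }
  grid[[name]] <- vals
  grid
}

# nearest-pixel lookup at world coordinates (x_um, y_um); NA outside
pixel_at <- function(image, x_um, y_um, pixel_size_um) {
  j <- ceiling(x_um / pixel_size_um)
  i <- ceiling(y_um / pixel_size_um)
  ok <- i >= 1 & i <= nrow(image) & j >= 1 & j <= ncol(image)
  out <- rep(NA_real_, length(x_um))
  out[ok] <- image[cbind(i[ok], j[ok])]
  out
}

#' Line intensity profile with perpendicular band averaging
#'
#' Samples the image along a polyline at fixed arc-length steps; at every
#' sample point the intensity is averaged over a band of `band_width_um`
#' perpendicular to the local direction (nearest-pixel samples spaced one
#' pixel apart across the band). A band no wider than one pixel
#' degenerates to plain sampling along the line.
#'
#' @param image numeric matrix (rows = y, cols = x).
#' @param polyline_um n x 2 matrix of (x, y) points, um; must lie inside
#'   the image.
#' @param band_width_um perpendicular averaging width, um.
#' @param step_um arc-length sampling step, um.
#' @param pixel_size_um physical pixel size, um.
#' @return data frame of class `LineProfile` (distance_um, intensity).
#' @export
line_profile <- function(image, polyline_um, band_width_um = 1,
                         step_um = 1, pixel_size_um = 1) {
  polyline_um <- as.matrix(polyline_um)
  stopifnot(ncol(polyline_um) == 2L)
  seg <- sqrt(rowSums(diff(polyline_um)^2))
  total <- sum(seg)
  if (nrow(polyline_um) < 2L || total == 0)
    stop("polyline has zero length")
  s <- c(0, cumsum(seg))
  t_out <- seq(0, total, by = step_um)
  x <- stats::approx(s, polyline_um[, 1], xout = t_out)$y
  y <- stats::approx(s, polyline_um[, 2], xout = t_out)$y
  # local tangent by central differences, then perpendicular
  dx <- c(diff(x)[1], diff(x)); dy <- c(diff(y)[1], diff(y))
  nrm <- sqrt(dx^2 + dy^2); nrm[nrm == 0] <- 1
  px <- -dy / nrm; py <- dx / nrm
  noff <- max(1L, floor(band_width_um / pixel_size_um))
  offs <- if (noff <= 1L) 0 else
    seq(-band_width_um / 2, band_width_um / 2, length.out = noff)
  vals <- vapply(seq_along(t_out), function(i) {
    v <- pixel_at(image, x[i] + offs * px[i], y[i] + offs * py[i],
                  pixel_size_um)
    mean(v, na.rm = TRUE)
  }, numeric(1))
  if (anyNA(vals) || any(is.nan(vals)))
    stop("polyline (or its band) leaves the image")
  out <- data.frame(distance_um = t_out, intensity = vals)
  class(out) <- c("LineProfile", "data.frame")
  out
}

#' Per-region summary of grid measurements
#'
#' Convenience aggregation: mean and SEM of a measured column per
#' assigned region, for included windows.
#'
#' @param grid a measured, region-assigned [build_grid()] grid.
#' @param column measurement column name.
#' @return data frame (region, n, mean, sem).
#' @export
grid_region_summary <- function(grid, column = "mean_intensity") {
  g <- grid[grid$included & !is.na(grid$region), , drop = FALSE]
  out <- do.call(rbind, lapply(split(g, g$region), function(d)
    data.frame(region = d$region[1], n = nrow(d),
               mean = mean(d[[column]]),
               sem = stats::sd(d[[column]]) / sqrt(nrow(d)))))
  rownames(out) <- NULL
  out
}
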