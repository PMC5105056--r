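#' Height-map container
#'
#' A `heightmap` holds a rectangular grid of surface heights in nanometres
#' together with the lateral pixel sizes. Rows are scan lines along the fast
#' axis (the column index moves along the fast axis, the row index along the
#' slow axis), matching the usual AFM raster convention. All heights are in nm
#' internally; loaders convert from file units.
#'
#' @param heights Numeric matrix of heights (nm); rows = slow axis,
#'   columns = fast axis. Must be finite everywhere.
#' @param pixel_size Pixel size in nm per pixel; either a single value or
#'   `c(x, y)` for the fast- and slow-axis spacing.
#' @param meta Optional named list of free-form scan metadata (scan rate,
#'   setpoint, label, ...).
#' @return An object of class `heightmap`.
#' @examples
#' hm <- heightmap(matrix(0, 8, 8), pixel_size = 10)
#' rms_roughness(hm)
#' @export
heightmap <- function(heights, pixel_size, meta = list()) {
  if (!is.matrix(heights) || !is.numeric(heights))
    stop("heights must be a numeric matrix")
  if (nrow(heights) < 1L || ncol(heights) < 1L)
    stop("heights must have at least one pixel")
  if (!all(is.finite(heights)))
    stop("heights must be finite everywhere (no NaN/NA/Inf); ",
         "use fill_nonfinite() or the loader fill option first")
  pixel_size <- as.numeric(pixel_size)
  if (length(pixel_size) == 1L) pixel_size <- c(pixel_size, pixel_size)
  if (length(pixel_size) != 2L || any(!is.finite(pixel_size)) ||
      any(pixel_size <= 0))
    stop("pixel_size must be one or two positive finite values (nm/px)")
  structure(
    list(heights = unname(heights),
         pixel_size_x = pixel_size[[1L]],
         pixel_size_y = pixel_size[[2L]],
         meta = meta),
    class = "heightmap")
}

#' @export
print.heightmap <- function(x, ...) {
  cat(sprintf("<%s> %d x %d px, %.4g x %.4g nm/px\n",
              class(x)[[1L]], nrow(x$heights), ncol(x$heights),
              x$pixel_size_x, x$pixel_size_y))
  cat(sprintf("  height range [%.4g, %.4g] nm, R_rms %.4g nm\n",
              min(x$heights), max(x$heights), rms_roughness(x)))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.heightmap <- function(x) dim(x$heights)

is_heightmap <- function(x) inherits(x, "heightmap")

stopifnot_heightmap <- function(x) {
  if (!is_heightmap(x)) stop("expected a heightmap object")
  invisible(x)
}

#' Root-mean-square roughness
#'
#' R_rms of a height map: the root mean square of the height deviations from
#' the mean height, `sqrt(mean((y_i - mean(y))^2))` over all pixels. This is
#' the population form (divide by N), invariant under adding a constant to all
#' heights and under transposing the grid.
#'
#' @param map A [heightmap].
#' @return Roughness in nm (>= 0).
#' @export
rms_roughness <- function(map) {
  stopifnot_heightmap(map)
  y <- map$heights
  sqrt(mean((y - mean(y))^2))
}

#' Scan geometry descriptor
#'
#' Describes the raster kinematics of a contact-mode scan: number of lines,
#' line width, and scan rate (lines per second).
#'
#' @param n_lines Number of scan lines (>= 0).
#' @param line_width Width of one scan line in nm (>= 0).
#' @param scan_rate Line rate in Hz (>= 0).
#' @param retrace_included Logical; whether the tip retraces each line
#'   (doubling the slid distance).
#' @return An object of class `scan_geometry`.
#' @export
scan_geometry <- function(n_lines, line_width, scan_rate,
                          retrace_included = TRUE) {
  if (n_lines < 0 || line_width < 0 || scan_rate < 0)
    stop("n_lines, line_width and scan_rate must be non-negative")
  structure(list(n_lines = n_lines, line_width = line_width,
                 scan_rate = scan_rate,
                 retrace_included = isTRUE(retrace_included)),
            class = "scan_geometry")
}

#' Sliding distance and velocity of a raster scan
#'
#' Total sliding distance is `n_lines * line_width`, doubled when the retrace
#' is included. The sliding velocity is `scan_rate * line_width`, i.e. the
#' one-way convention: with trace and retrace, a line of width w is traversed
#' twice per period so the instantaneous speed equals `2 * rate * w`, but
#' instrument software customarily reports the one-way value. Both conventions
#' are deliberately mixed here (distance counts the retrace, velocity does
#' not) so that printed instrument numbers are reproduced exactly.
#'
#' @param geom A [scan_geometry].
#' @return A list with `total_sliding_distance_nm` and
#'   `sliding_velocity_nm_s`.
#' @examples
#' g <- scan_geometry(1024, 2500, 0.2)
#' scan_kinematics(g)  # ~5.1 mm, 500 nm/s
#' @export
scan_kinematics <- function(geom) {
  if (!inherits(geom, "scan_geometry")) stop("expected a scan_geometry")
  passes <- if (geom$retrace_included) 2 else 1
  list(total_sliding_distance_nm = geom$n_lines * geom$line_width * passes,
       sliding_velocity_nm_s = geom$scan_rate * geom$line_width)
}

#' Replace non-finite pixels by their line median
#'
#' Loaders reject non-finite data by default because silent interpolation
#' corrupts roughness statistics; this explicit repair replaces each
#' non-finite pixel by the median of the finite pixels in its scan line.
#'
#' @param heights Numeric matrix possibly containing NA/NaN/Inf.
#' @return A finite matrix.
#' @export
fill_nonfinite <- function(heights) {
  for (i in seq_len(nrow(heights))) {
    row <- heights[i, ]
    bad <- !is.finite(row)
    if (any(bad)) {
      if (all(bad)) stop("line ", i, " has no finite pixels to fill from")
      heights[i, bad] <- stats::median(row[!bad])
    }
  }
  heights
}
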