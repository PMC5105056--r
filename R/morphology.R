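#' Tip model
#'
#' A tip model is a height map restricted to a single apex-centred protrusion,
#' normalized so the apex height is 0 and the rest of the grid is negative.
#' If several pixels tie for the maximum, the one nearest the grid centre is
#' taken as the apex (deterministic tie-break). The object records the apex
#' index in `apex` (row, col).
#'
#' @param heights Numeric matrix (nm); will be apex-normalized.
#' @param pixel_size Pixel size in nm (scalar or `c(x, y)`).
#' @param meta Optional metadata list.
#' @return An object of class `c("tipmodel", "heightmap")`.
#' @export
tip_model <- function(heights, pixel_size, meta = list()) {
  hm <- heightmap(heights, pixel_size, meta)
  h <- hm$heights - max(hm$heights)
  top <- which(h == 0, arr.ind = TRUE)
  ctr <- (dim(h) + 1) / 2
  d2 <- (top[, 1] - ctr[[1]])^2 + (top[, 2] - ctr[[2]])^2
  apex <- top[which.min(d2), ]
  hm$heights <- h
  hm$apex <- c(row = unname(apex[[1]]), col = unname(apex[[2]]))
  class(hm) <- c("tipmodel", "heightmap")
  hm
}

check_compatible <- function(surface, tip) {
  stopifnot_heightmap(surface)
  if (!inherits(tip, "tipmodel")) stop("tip must be a tipmodel")
  rel <- function(a, b) abs(a - b) / max(a, b)
  if (rel(surface$pixel_size_x, tip$pixel_size_x) > 1e-9 ||
      rel(surface$pixel_size_y, tip$pixel_size_y) > 1e-9)
    stop("pixel-size mismatch between surface/image and tip")
  if (nrow(tip$heights) > nrow(surface$heights) ||
      ncol(tip$heights) > ncol(surface$heights))
    stop("tip grid must be no larger than the surface grid")
}

#' Image formation: grayscale dilation of a surface by a tip
#'
#' The recorded AFM image is the grayscale dilation of the sample by the tip:
#' `image(x) = max over tip offsets u of [surface(x + u) + tip(u)]`, with tip
#' offsets measured from the apex and the apex height 0. This is the
#' non-penetration contact condition of a down-pointing tip, so a delta-spike
#' sample images the tip shape reflected through its apex. Near the grid
#' border the tip support is truncated to in-grid offsets; the affected margin
#' (half the tip size) is recorded in the `border_px` attribute.
#'
#' @param surface A [heightmap].
#' @param tip A [tip_model()] with the same pixel size.
#' @return The simulated image as a [heightmap] (pointwise >= surface).
#' @seealso [erode()], [blind_tip_reconstruction()]
#' @export
dilate <- function(surface, tip) {
  check_compatible(surface, tip)
  out <- surface
  out$heights <- dilate_cpp(surface$heights, tip$heights,
                            tip$apex[[1]] - 1L, tip$apex[[2]] - 1L)
  attr(out, "border_px") <- (dim(tip$heights) - 1L) %/% 2L
  out
}

#' Surface recovery: grayscale erosion of an image by a tip
#'
#' The adjoint of [dilate()]: `erosion(x) = min over tip offsets u of
#' [image(x - u) - tip(u)]`. Eroding an image with the tip that formed it
#' gives an upper-bound surface reconstruction: `erode(dilate(S, T), T) >= S`
#' pointwise, with equality wherever the tip apex touched the sample.
#'
#' @param image A [heightmap].
#' @param tip A [tip_model()] with the same pixel size.
#' @return The recovered surface as a [heightmap].
#' @export
erode <- function(image, tip) {
  check_compatible(image, tip)
  out <- image
  out$heights <- erode_cpp(image$heights, tip$heights,
                           tip$apex[[1]] - 1L, tip$apex[[2]] - 1L)
  attr(out, "border_px") <- (dim(tip$heights) - 1L) %/% 2L
  out
}

#' Blind tip reconstruction
#'
#' Estimates the least upper bound on the tip shape consistent with an image
#' of an unknown rough surface. Starting from the bluntest candidate (a flat
#' tip at height 0), each image pixel's neighbourhood iteratively carves the
#' estimate down: a candidate contact offset `v` at image pixel `x` is
#' admissible only when the apex constraint `T(v) >= I(x) - I(x+v) - threshold`
#' holds for the current estimate, and each admissible contact bounds every
#' tip pixel `p` by `T(p) <= T(v) + I(x+v-p) - I(x) + threshold`. The
#' threshold absorbs pixel noise. Iteration stops when no tip pixel changes
#' by more than `tol` nm. The result is an outer bound: it never lies below
#' the true tip (at threshold 0 on a noiseless image), and re-imaging the
#' eroded surface with it reproduces the image within the threshold.
#'
#' An image border of half the tip-grid width is excluded from the updates to
#' avoid edge artifacts. A constant (featureless) image yields a flat tip,
#' returned with a warning and `attr(, "uninformative") = TRUE`.
#'
#' @param image A flattened [heightmap].
#' @param tip_grid Tip grid size in pixels, `c(rows, cols)` or a scalar; both
#'   must be odd.
#' @param threshold_nm Noise slack in nm (>= 0).
#' @param tol Convergence tolerance in nm (default 1e-3).
#' @param max_iter Maximum refinement sweeps.
#' @return A [tip_model()] (apex-normalized reconstruction).
#' @export
blind_tip_reconstruction <- function(image, tip_grid, threshold_nm = 0,
                                     tol = 1e-3, max_iter = 50L) {
  stopifnot_heightmap(image)
  tip_grid <- as.integer(rep_len(tip_grid, 2L))
  if (any(tip_grid %% 2L == 0L)) stop("tip_grid dimensions must be odd")
  if (any(tip_grid > dim(image$heights)))
    stop("tip grid larger than image")
  if (threshold_nm < 0) stop("threshold_nm must be >= 0")
  est <- btr_cpp(image$heights, tip_grid[[1]], tip_grid[[2]],
                 threshold_nm, tol, as.integer(max_iter))
  tip <- tip_model(est, c(image$pixel_size_x, image$pixel_size_y),
                   meta = list(threshold_nm = threshold_nm))
  if (all(est == est[[1]])) {
    warning("image carries no tip information (constant or featureless); ",
            "returning a flat tip")
    attr(tip, "uninformative") <- TRUE
  }
  tip
}

#' Crop the invalid border of a simulated image
#'
#' [dilate()] computes boundary pixels with a truncated tip support, so a
#' simulated image's border (half the tip width, recorded in `border_px`) is
#' lower than a physical scan would measure there. Crop it before feeding a
#' simulated image to [blind_tip_reconstruction()] or peak analysis; real
#' instrument images need no cropping.
#'
#' @param map A [heightmap] (typically from [dilate()] or
#'   [simulate_image()]).
#' @param margin Rows/columns to remove on each side, `c(rows, cols)` or a
#'   scalar; default the map's `border_px` attribute.
#' @return The cropped [heightmap].
#' @export
crop_border <- function(map, margin = NULL) {
  stopifnot_heightmap(map)
  if (is.null(margin)) margin <- attr(map, "border_px")
  if (is.null(margin)) stop("no border_px attribute; pass margin explicitly")
  margin <- as.integer(rep_len(margin, 2L))
  h <- map$heights
  if (2L * margin[[1L]] >= nrow(h) || 2L * margin[[2L]] >= ncol(h))
    stop("margin leaves no pixels")
  map$heights <- h[(margin[[1L]] + 1L):(nrow(h) - margin[[1L]]),
                   (margin[[2L]] + 1L):(ncol(h) - margin[[2L]]), drop = FALSE]
  attr(map, "border_px") <- NULL
  map
}

#' Robust spike and discontinuity rejection
#'
#' Replaces implausible pixels before tip estimation. Spike rejection flags
#' pixels deviating from their scan-line median by more than `spike_sigma`
#' times the line's robust standard deviation (median absolute deviation,
#' Gaussian-consistent). Discontinuity rejection flags pixels whose fast-axis
#' gradient magnitude exceeds `discont_sigma` times the global robust
#' standard deviation of the gradient. Flagged pixels are replaced by their
#' line median; all others are untouched. Infinite multipliers disable the
#' corresponding rule.
#'
#' @param image A [heightmap].
#' @param spike_sigma Spike rejection multiplier (> 0; default 7).
#' @param discont_sigma Discontinuity rejection multiplier (> 0; default 3).
#' @return The cleaned [heightmap]; the number of replaced pixels is recorded
#'   in `attr(, "n_rejected")`.
#' @export
reject_outliers <- function(image, spike_sigma = 7, discont_sigma = 3) {
  stopifnot_heightmap(image)
  if (spike_sigma <= 0 || discont_sigma <= 0)
    stop("sigma multipliers must be positive")
  h <- image$heights
  flag <- matrix(FALSE, nrow(h), ncol(h))
  meds <- apply(h, 1L, stats::median)
  if (is.finite(spike_sigma)) {
    for (i in seq_len(nrow(h))) {
      s <- stats::mad(h[i, ])
      if (s > 0) flag[i, ] <- abs(h[i, ] - meds[[i]]) > spike_sigma * s
    }
  }
  if (is.finite(discont_sigma) && ncol(h) >= 2L) {
    g <- h[, -1L, drop = FALSE] - h[, -ncol(h), drop = FALSE]
    s <- stats::mad(g)
    if (s > 0) {
      bad <- abs(g) > discont_sigma * s
      # a steep gradient implicates whichever of its two endpoints sits
      # farther from the line median (so a spike's neighbours survive)
      dev <- abs(h - meds[row(h)])
      left_worse <- dev[, -ncol(h), drop = FALSE] >= dev[, -1L, drop = FALSE]
      flag[, -ncol(h)] <- flag[, -ncol(h)] | (bad & left_worse)
      flag[, -1L] <- flag[, -1L] | (bad & !left_worse)
    }
  }
  for (i in seq_len(nrow(h)))
    if (any(flag[i, ])) h[i, flag[i, ]] <- meds[[i]]
  image$heights <- h
  attr(image, "n_rejected") <- sum(flag)
  image
}
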