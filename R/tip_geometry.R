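#' Apex end radius by circle + sphere fit
#'
#' Extracts the closed height contour `depth` nm below the apex by sub-pixel
#' linear interpolation, fits a circle to it (algebraic Kasa least squares),
#' and returns the radius of the sphere through that circle and the apex:
#' `R_t = (r_c^2 + depth^2) / (2 * depth)`. For a spherical apex this
#' recovers the sphere radius for any depth below the apex; for a paraboloid
#' of apex curvature radius R it gives `R + depth/2`.
#'
#' @param tip A [tip_model()].
#' @param depth Contour depth below the apex in nm (default 15).
#' @return End radius in nm.
#' @export
end_radius <- function(tip, depth = 15) {
  if (!inherits(tip, "tipmodel")) stop("tip must be a tipmodel")
  if (depth <= 0) stop("depth must be positive")
  if (min(tip$heights) > -depth)
    stop("tip does not extend ", depth, " nm below its apex")
  ring <- apex_contour(tip, depth)
  fit <- kasa_circle(ring$x, ring$y)
  (fit$r^2 + depth^2) / (2 * depth)
}

## Closed contour at apex - depth enclosing the apex, coordinates in nm.
apex_contour <- function(tip, depth) {
  h <- tip$heights
  xs <- (seq_len(nrow(h)) - 1) * tip$pixel_size_y   # slow axis position
  ys <- (seq_len(ncol(h)) - 1) * tip$pixel_size_x   # fast axis position
  cl <- grDevices::contourLines(xs, ys, h, levels = -depth)
  if (!length(cl))
    stop("no contour found ", depth, " nm below the apex")
  ax <- xs[[tip$apex[["row"]]]]
  ay <- ys[[tip$apex[["col"]]]]
  px <- max(tip$pixel_size_x, tip$pixel_size_y)
  loops <- stitch_contours(cl, eps = px / 2)
  enclosing <- NULL
  n_closed <- 0L
  for (lp in loops) {
    if (!lp$closed) next
    n_closed <- n_closed + 1L
    if (is.null(enclosing) && point_in_polygon(ax, ay, lp$x, lp$y))
      enclosing <- lp
  }
  if (is.null(enclosing)) {
    open_near <- any(vapply(loops, function(lp)
      !lp$closed && point_in_polygon(ax, ay, c(lp$x, lp$x[[1]]),
                                     c(lp$y, lp$y[[1]])), logical(1)))
    if (open_near)
      stop("contour at ", depth,
           " nm below the apex is open (tip touches the grid edge)")
    stop("no closed contour enclosing the apex at ", depth,
         " nm below the apex")
  }
  if (n_closed > 1L)
    warning("multiple contours at the requested depth; ",
            "using the one enclosing the apex")
  list(x = enclosing$x, y = enclosing$y)
}

## contourLines() splits a single level loop into several polylines; chain
## segments whose endpoints coincide (within eps) back into loops.
stitch_contours <- function(cl, eps) {
  segs <- lapply(cl, function(cc) list(x = cc$x, y = cc$y))
  used <- rep(FALSE, length(segs))
  loops <- list()
  near <- function(x1, y1, x2, y2) sqrt((x1 - x2)^2 + (y1 - y2)^2) <= eps
  for (i in seq_along(segs)) {
    if (used[[i]]) next
    used[[i]] <- TRUE
    cx <- segs[[i]]$x; cy <- segs[[i]]$y
    repeat {
      n <- length(cx)
      if (near(cx[[n]], cy[[n]], cx[[1]], cy[[1]]) && n > 2L) break
      found <- FALSE
      for (j in seq_along(segs)) {
        if (used[[j]]) next
        sx <- segs[[j]]$x; sy <- segs[[j]]$y
        m <- length(sx)
        if (near(cx[[n]], cy[[n]], sx[[1]], sy[[1]])) {
          cx <- c(cx, sx[-1L]); cy <- c(cy, sy[-1L])
          used[[j]] <- TRUE; found <- TRUE; break
        }
        if (near(cx[[n]], cy[[n]], sx[[m]], sy[[m]])) {
          cx <- c(cx, rev(sx)[-1L]); cy <- c(cy, rev(sy)[-1L])
          used[[j]] <- TRUE; found <- TRUE; break
        }
      }
      if (!found) break
    }
    n <- length(cx)
    closed <- n > 2L && near(cx[[n]], cy[[n]], cx[[1]], cy[[1]])
    loops[[length(loops) + 1L]] <- list(x = cx, y = cy, closed = closed)
  }
  loops
}

point_in_polygon <- function(px, py, xs, ys) {
  n <- length(xs)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if ((ys[[i]] > py) != (ys[[j]] > py) &&
        px < (xs[[j]] - xs[[i]]) * (py - ys[[i]]) / (ys[[j]] - ys[[i]]) + xs[[i]])
      inside <- !inside
    j <- i
  }
  inside
}

## Algebraic (Kasa) circle fit: minimizes sum of (r^2 residuals), linear.
kasa_circle <- function(x, y) {
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- stats::lm.fit(A, b)$coefficients
  list(cx = sol[[1]], cy = sol[[2]],
       r = sqrt(sol[[3]] + sol[[1]]^2 + sol[[2]]^2))
}

#' Open sphericity of a tip apex
#'
#' `Psi_o = (18*pi)^(1/3) * V^(2/3) / A`, where V is the volume between the
#' apex and the plane `depth` below it (trapezoidal integration of horizontal
#' cross-section areas) and A is the lateral surface area of the same region
#' (triangulation of the height grid). Psi_o equals 1 for an open hemisphere
#' measured over its full depth, and ~0.94 for a paraboloid measured down to
#' its apex radius of curvature; it is invariant under uniform scaling.
#'
#' The default depth is the tip's own end radius ([end_radius()] at its
#' default 15 nm contour depth), i.e. the region from the apex to R_t below
#' it. Cross sections use a strict height comparison, so a plateau exactly at
#' the cutoff level (e.g. the surround of a hemispherical cap) contributes
#' neither volume nor area.
#'
#' @param tip A [tip_model()].
#' @param depth Integration depth below the apex in nm; `NULL` (default) uses
#'   the tip's end radius.
#' @param n_levels Number of cross-section levels for the trapezoidal volume.
#' @return A number in (0, 1] up to discretization error, with attributes
#'   `volume_nm3`, `area_nm2` and `depth_nm`.
#' @export
open_sphericity <- function(tip, depth = NULL, n_levels = 256L) {
  if (!inherits(tip, "tipmodel")) stop("tip must be a tipmodel")
  if (is.null(depth)) depth <- end_radius(tip)
  if (depth <= 0) stop("depth must be positive")
  if (min(tip$heights) > -depth)
    stop("tip does not extend ", depth, " nm below its apex")
  V <- region_volume(tip, depth, n_levels)
  A <- region_area(tip, depth)
  psi <- (18 * pi)^(1 / 3) * V^(2 / 3) / A
  structure(psi, volume_nm3 = V, area_nm2 = A, depth_nm = depth)
}

region_volume <- function(tip, depth, n_levels) {
  h <- tip$heights
  pxa <- tip$pixel_size_x * tip$pixel_size_y
  levels <- seq(0, depth, length.out = n_levels + 1L)
  areas <- vapply(levels, function(d) sum(h > -d) * pxa, numeric(1))
  sum((areas[-1L] + areas[-length(areas)]) / 2 * diff(levels))
}

region_area <- function(tip, depth) {
  h <- tip$heights
  px <- tip$pixel_size_x
  py <- tip$pixel_size_y
  cutoff <- -depth
  nr <- nrow(h); nc <- ncol(h)
  z00 <- h[-nr, -nc]; z10 <- h[-1L, -nc]
  z01 <- h[-nr, -1L]; z11 <- h[-1L, -1L]
  # two triangles per cell; area of the 3-D triangle over each half-cell
  tri_area <- function(dz1, dz2) {
    # vertices (0,0,0), (py,0,dz1), (0,px,dz2): cross product norm / 2
    0.5 * sqrt((dz1 * px)^2 + (dz2 * py)^2 + (px * py)^2)
  }
  a1 <- tri_area(z10 - z00, z01 - z00)
  a2 <- tri_area(z01 - z11, z10 - z11)
  in1 <- (z00 + z10 + z01) / 3 > cutoff
  in2 <- (z11 + z10 + z01) / 3 > cutoff
  sum(a1[in1]) + sum(a2[in2])
}

#' Closed sphericity
#'
#' `Psi = pi^(1/3) * (6 V)^(2/3) / A`: the surface area of a sphere with the
#' same volume as the body, divided by the body's surface area. Equals 1 for
#' a full sphere and can exceed 1 for open shapes, which is what motivates
#' [open_sphericity()].
#'
#' @param volume Volume in nm^3 (> 0).
#' @param area Surface area in nm^2 (> 0).
#' @return Dimensionless sphericity.
#' @export
closed_sphericity <- function(volume, area) {
  if (volume <= 0 || area <= 0) stop("volume and area must be positive")
  pi^(1 / 3) * (6 * volume)^(2 / 3) / area
}

#' Disc-method volume from a width-vs-depth profile
#'
#' Treats each depth slice as a disc of diameter equal to the profile width
#' at that depth and integrates `pi * (w/2)^2` over depth (trapezoidal rule).
#'
#' @param widths Profile widths in nm at each depth.
#' @param depths Monotone increasing depths below the apex in nm (same
#'   length); the first entry is the shallowest.
#' @return Volume in nm^3.
#' @export
disc_volume <- function(widths, depths) {
  if (length(widths) != length(depths))
    stop("widths and depths must have the same length")
  if (length(depths) < 2L) return(0)
  if (any(diff(depths) <= 0)) stop("depth grid must be strictly increasing")
  a <- pi * (widths / 2)^2
  sum((a[-1L] + a[-length(a)]) / 2 * diff(depths))
}

#' Apex line profiles of a tip
#'
#' Extracts the fast-axis and slow-axis line profiles through the tip apex,
#' with lateral positions in nm centred on the apex.
#'
#' @param tip A [tip_model()].
#' @return An object of class `tip_profile_pair`: a list with `fast` and
#'   `slow` components, each `list(position, height)`.
#' @export
tip_profiles <- function(tip) {
  if (!inherits(tip, "tipmodel")) stop("tip must be a tipmodel")
  i <- tip$apex[["row"]]; j <- tip$apex[["col"]]
  fast <- list(position = (seq_len(ncol(tip$heights)) - j) * tip$pixel_size_x,
               height = tip$heights[i, ])
  slow <- list(position = (seq_len(nrow(tip$heights)) - i) * tip$pixel_size_y,
               height = tip$heights[, j])
  structure(list(fast = fast, slow = slow,
                 pixel_size = c(tip$pixel_size_x, tip$pixel_size_y)),
            class = "tip_profile_pair")
}

## Width of a profile at given depths below its own apex: distance between
## the outermost crossings of the level on each side of the apex (linear
## interpolation). NA where a side never crosses within the profile.
profile_width <- function(position, height, depths) {
  apex_h <- max(height)
  k <- which.max(height)
  vapply(depths, function(d) {
    if (d <= 0) return(0)
    level <- apex_h - d
    right <- NA_real_
    for (idx in rev(seq(k, length(height) - 1L))) {
      if (height[[idx]] >= level && height[[idx + 1L]] < level) {
        f <- (height[[idx]] - level) / (height[[idx]] - height[[idx + 1L]])
        right <- position[[idx]] + f * (position[[idx + 1L]] - position[[idx]])
        break
      }
    }
    left <- NA_real_
    for (idx in seq_len(k - 1L)) {
      if (height[[idx]] < level && height[[idx + 1L]] >= level) {
        f <- (height[[idx + 1L]] - level) / (height[[idx + 1L]] - height[[idx]])
        left <- position[[idx + 1L]] - f * (position[[idx + 1L]] - position[[idx]])
        break
      }
    }
    if (is.na(left) || is.na(right)) return(NA_real_)
    right - left
  }, numeric(1))
}

#' Worn volume from before/after profile pairs
#'
#' Overlays the worn tip's profiles on the unworn tip's by searching the
#' vertical offset (worn apex at or below the unworn apex) that maximizes the
#' occupied area subject to the containment constraint that the worn width
#' never exceeds the unworn width at any height. Because the overlap is
#' monotone in the offset, the maximizer is the smallest feasible offset; the
#' coarse 0.1 nm scan is refined by bisection. The volume difference is then
#' measured with the disc method down to the depth where the two widths first
#' become equal, and averaged over the fast and slow profiles.
#'
#' @param before,after [tip_profiles()] of the unworn and worn tip.
#' @param step Depth/offset grid step in nm (default 0.1).
#' @param tol_width Width-equality tolerance in nm; default one pixel.
#' @param slack Containment slack in nm absorbing interpolation noise.
#' @return Worn volume in nm^3 (>= 0), with per-axis values in
#'   `attr(, "per_axis")` and the fitted offsets in `attr(, "offset_nm")`.
#' @export
worn_volume <- function(before, after, step = 0.1, tol_width = NULL,
                        slack = 0.01) {
  if (!inherits(before, "tip_profile_pair") ||
      !inherits(after, "tip_profile_pair"))
    stop("before and after must be tip_profile_pair objects")
  if (is.null(tol_width)) tol_width <- max(before$pixel_size)
  res <- lapply(c("fast", "slow"), function(axis) {
    worn_volume_1d(before[[axis]], after[[axis]], step, tol_width, slack)
  })
  vols <- vapply(res, `[[`, numeric(1), "volume")
  structure(max(mean(vols), 0),
            per_axis = stats::setNames(vols, c("fast", "slow")),
            offset_nm = vapply(res, `[[`, numeric(1), "offset"),
            depth_nm = vapply(res, `[[`, numeric(1), "depth"))
}

worn_volume_1d <- function(unworn, worn, step, tol_width, slack) {
  d_max_u <- max(unworn$height) -
    max(unworn$height[[1L]], unworn$height[[length(unworn$height)]])
  d_max_w <- max(worn$height) -
    max(worn$height[[1L]], worn$height[[length(worn$height)]])
  depths <- seq(0, d_max_u, by = step)
  w_u <- profile_width(unworn$position, unworn$height, depths)
  if (anyNA(w_u)) {              # trim depths the unworn profile cannot span
    keep <- seq_len(min(which(is.na(w_u))) - 1L)
    depths <- depths[keep]; w_u <- w_u[keep]
  }
  if (length(depths) < 3L)
    stop("unworn profile too shallow for the disc overlay")
  wfun_w <- function(d) profile_width(worn$position, worn$height, d)

  feasible <- function(s) {
    sel <- depths - s >= 0 & depths - s <= d_max_w
    dd <- depths[sel]
    ww <- if (length(dd)) wfun_w(dd - s) else numeric(0)
    wu <- w_u[sel]
    # also pin the worn profile's deepest (widest) point, which the step
    # grid can straddle
    d_end <- s + d_max_w
    if (d_end > max(depths) - 1e-9) d_end <- max(depths)
    if (d_end > s) {
      ww <- c(ww, wfun_w(max(d_end - s, step / 10) - 1e-6))
      wu <- c(wu, stats::approx(depths, w_u, d_end, rule = 2)$y)
    }
    all(is.na(ww) | is.na(wu) | (ww <= wu + slack))
  }
  s_grid <- seq(0, d_max_u, by = step)
  s_star <- NA_real_
  for (s in s_grid) if (feasible(s)) { s_star <- s; break }
  if (is.na(s_star))
    stop("containment infeasible: worn profile wider than unworn ",
         "at every tested vertical offset")
  if (s_star > 0) {           # refine the feasibility boundary by bisection
    lo <- s_star - step; hi <- s_star
    for (it in 1:20) {
      mid <- (lo + hi) / 2
      if (feasible(mid)) hi <- mid else lo <- mid
    }
    s_star <- hi
  }

  ww_shift <- ifelse(depths - s_star >= 0 & depths - s_star <= d_max_w,
                     wfun_w(pmax(depths - s_star, 0)), 0)
  ww_shift[is.na(ww_shift)] <- 0
  eq <- which(depths > s_star & ww_shift > 0 &
              !is.na(w_u) & abs(w_u - ww_shift) <= tol_width)
  if (!length(eq)) {
    if (s_star == 0 &&
        all(abs(w_u - ww_shift) <= tol_width, na.rm = TRUE))
      return(list(volume = 0, offset = 0, depth = 0))  # identical profiles
    stop("worn and unworn widths never become equal within the profiles")
  }
  k <- eq[[1L]]
  dd <- depths[seq_len(k)]
  wu <- w_u[seq_len(k)]; wu[is.na(wu)] <- 0
  ww <- ww_shift[seq_len(k)]
  list(volume = disc_volume(wu, dd) - disc_volume(ww, dd),
       offset = s_star, depth = depths[[k]])
}

#' All apex metrics of a tip
#'
#' Convenience wrapper computing the end radius, the open sphericity at the
#' default depth (the end radius itself), and the volume/area of the measured
#' region.
#'
#' @param tip A [tip_model()].
#' @param contour_depth Depth for the end-radius contour (nm, default 15).
#' @param depth Sphericity depth; `NULL` (default) uses the end radius.
#' @return A list of class `tip_metrics` with fields `end_radius_Rt`,
#'   `open_sphericity`, `volume`, `surface_area`, `depth_used`.
#' @export
tip_metrics <- function(tip, contour_depth = 15, depth = NULL) {
  rt <- end_radius(tip, contour_depth)
  if (is.null(depth)) depth <- rt
  psi <- open_sphericity(tip, depth)
  structure(list(end_radius_Rt = rt,
                 open_sphericity = as.numeric(psi),
                 volume = attr(psi, "volume_nm3"),
                 surface_area = attr(psi, "area_nm2"),
                 depth_used = depth),
            class = "tip_metrics")
}

#' @export
print.tip_metrics <- function(x, ...) {
  cat(sprintf("Tip metrics (depth used %.3g nm):\n", x$depth_used))
  cat(sprintf("  end radius R_t    %8.3g nm\n", x$end_radius_Rt))
  cat(sprintf("  open sphericity   %8.3f\n", x$open_sphericity))
  cat(sprintf("  volume            %8.4g nm^3\n", x$volume))
  cat(sprintf("  lateral area      %8.4g nm^2\n", x$surface_area))
  invisible(x)
}
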