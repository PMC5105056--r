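#' Detect peaks in a line profile by prominence
#'
#' A peak is a local maximum that rises by at least `min_prominence` above
#' BOTH of its nearest flanking local minima (true topographic prominence on
#' both sides). Profile endpoints are never peaks; where no interior minimum
#' exists between a maximum and the profile end, the minimum height over that
#' stretch is used. Plateau maxima report their centre sample.
#'
#' @param height Numeric vector of profile heights (nm), length >= 3.
#' @param min_prominence Minimum height difference to both flanking minima
#'   (nm, default 20).
#' @return Integer vector of peak indices (possibly empty).
#' @export
detect_peaks <- function(height, min_prominence = 20) {
  n <- length(height)
  if (n < 3L) stop("profile must have at least 3 samples")
  d <- diff(height)
  # run-length collapse so plateaus count once
  sgn <- sign(d)
  keep <- sgn != 0
  idx <- which(keep)
  s <- sgn[keep]
  if (!length(s)) return(integer(0))
  peaks <- integer(0)
  for (k in seq_len(length(s) - 1L)) {
    if (s[[k]] == 1 && s[[k + 1L]] == -1) {
      i0 <- idx[[k]] + 1L            # plateau start
      i1 <- idx[[k + 1L]]            # plateau end
      peaks <- c(peaks, (i0 + i1) %/% 2L)
    }
  }
  if (!length(peaks)) return(integer(0))
  ok <- vapply(peaks, function(p) {
    left_min <- min(height[flank_left(height, p)])
    right_min <- min(height[flank_right(height, p)])
    height[[p]] - left_min >= min_prominence &&
      height[[p]] - right_min >= min_prominence
  }, logical(1))
  peaks[ok]
}

## indices from p leftwards down to (and including) the nearest local
## minimum, or the profile start
flank_left <- function(height, p) {
  i <- p
  while (i > 1L && height[[i - 1L]] <= height[[i]]) i <- i - 1L
  i:p
}

flank_right <- function(height, p) {
  n <- length(height)
  i <- p
  while (i < n && height[[i + 1L]] <= height[[i]]) i <- i + 1L
  p:i
}

#' Parabolic fit of a single profile peak
#'
#' Least-squares fit of `y = a x^2 + b x + c` (x in nm, centred on the apex
#' sample for conditioning; the radius is origin-invariant) to the contiguous
#' samples around the peak lying within `depth` nm below the apex. The window
#' is truncated at an intervening minimum so a neighbouring peak's flank is
#' never included. The apex radius of curvature is `1 / (2 |a|)`.
#'
#' Fits with fewer than 3 in-window samples or a non-concave coefficient
#' (`a >= 0`) are rejected: the function returns a `peak_reject` object
#' carrying the reason rather than raising an error, so that callers can
#' keep QC statistics.
#'
#' @param position Lateral positions (nm) of the profile samples.
#' @param height Profile heights (nm).
#' @param peak_index Index of the peak sample (e.g. from [detect_peaks()]).
#' @param depth Vertical fit window below the apex in nm (default 15).
#' @return A list of class `peak_fit` (`apex_position`, `apex_height`, `a`,
#'   `b`, `c`, `radius`, `n_points`), or a `peak_reject` object with a
#'   `reason` field.
#' @export
fit_peak <- function(position, height, peak_index, depth = 15) {
  n <- length(height)
  apex_h <- height[[peak_index]]
  cutoff <- apex_h - depth
  lo <- peak_index
  while (lo > 1L && height[[lo - 1L]] >= cutoff &&
         height[[lo - 1L]] <= height[[lo]]) lo <- lo - 1L
  hi <- peak_index
  while (hi < n && height[[hi + 1L]] >= cutoff &&
         height[[hi + 1L]] <= height[[hi]]) hi <- hi + 1L
  reject <- function(why)
    structure(list(reason = why), class = "peak_reject")
  if (hi - lo + 1L < 3L) return(reject("too_few_points"))
  x <- position[lo:hi] - position[[peak_index]]
  y <- height[lo:hi]
  co <- stats::lm.fit(cbind(1, x, x^2), y)$coefficients
  a <- co[[3L]]
  if (!is.finite(a) || a >= 0) return(reject("non_concave"))
  structure(list(apex_position = position[[peak_index]],
                 apex_height = apex_h,
                 a = a, b = co[[2L]], c = co[[1L]],
                 radius = 1 / (2 * abs(a)),
                 n_points = hi - lo + 1L),
            class = "peak_fit")
}

#' Collect peak radii over image sections
#'
#' Runs [detect_peaks()] + [fit_peak()] on every fast-axis line (matrix row)
#' of an image, with the rows partitioned into `n_sections` contiguous blocks
#' along the slow axis (the first `n_sections - 1` blocks take
#' `floor(rows / n_sections)` rows, the last the remainder). Each section's
#' radii are annotated with the cumulative sliding distance at the section's
#' middle row, computed from the scan kinematics (trace + retrace).
#'
#' @param image A flattened, filtered [heightmap].
#' @param n_sections Number of slow-axis sections (default 6).
#' @param min_prominence Peak prominence threshold in nm (default 20).
#' @param depth Parabolic fit window in nm (default 15).
#' @param scan_rate Line rate in Hz used for the kinematics annotation.
#' @return A list of class `radius_samples`; each element has `radii`,
#'   `section_index`, `sliding_distance_nm`, `n_rows`, and QC counts
#'   (`n_peaks`, `n_rejected`). The accept rate over all sections is in
#'   `attr(, "accept_rate")`.
#' @export
collect_radii <- function(image, n_sections = 6L, min_prominence = 20,
                          depth = 15, scan_rate = 0.2) {
  stopifnot_heightmap(image)
  h <- image$heights
  nr <- nrow(h)
  n_sections <- as.integer(n_sections)
  if (nr < n_sections)
    stop("image has fewer rows (", nr, ") than sections (", n_sections, ")")
  base <- nr %/% n_sections
  sizes <- c(rep(base, n_sections - 1L), nr - base * (n_sections - 1L))
  starts <- cumsum(c(0L, sizes[-n_sections]))
  pos <- (seq_len(ncol(h)) - 1L) * image$pixel_size_x
  line_width <- ncol(h) * image$pixel_size_x
  total_pk <- 0L; total_rej <- 0L
  out <- vector("list", n_sections)
  for (s in seq_len(n_sections)) {
    rows <- starts[[s]] + seq_len(sizes[[s]])
    radii <- numeric(0)
    n_pk <- 0L; n_rej <- 0L
    for (i in rows) {
      pks <- detect_peaks(h[i, ], min_prominence)
      n_pk <- n_pk + length(pks)
      for (p in pks) {
        fit <- fit_peak(pos, h[i, ], p, depth)
        if (inherits(fit, "peak_fit")) radii <- c(radii, fit$radius)
        else n_rej <- n_rej + 1L
      }
    }
    mid_rows <- starts[[s]] + sizes[[s]] / 2
    out[[s]] <- structure(
      list(radii = radii, section_index = s,
           sliding_distance_nm = 2 * mid_rows * line_width,
           n_rows = sizes[[s]], n_peaks = n_pk, n_rejected = n_rej),
      class = "radius_sample")
    total_pk <- total_pk + n_pk; total_rej <- total_rej + n_rej
  }
  structure(out, class = "radius_samples",
            accept_rate = if (total_pk > 0) 1 - total_rej / total_pk else NA_real_)
}

#' @export
print.radius_samples <- function(x, ...) {
  cat(sprintf("<radius_samples> %d sections, %d radii, accept rate %.2f\n",
              length(x), sum(lengths(lapply(x, `[[`, "radii"))),
              attr(x, "accept_rate")))
  invisible(x)
}
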