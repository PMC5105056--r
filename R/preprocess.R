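#' Flattening configuration
#'
#' Parameters for line-by-line background removal. Each fast-axis line is
#' fitted with a polynomial baseline by least squares, using only the lowest
#' `1 - exclude_fraction` quantile of the line's pixels so that tall surface
#' peaks do not drag the baseline upwards (which would bias the peak shapes
#' the downstream parabolic fits depend on).
#'
#' @param poly_order Polynomial order of the baseline (>= 0; default 1).
#' @param exclude_fraction Fraction of the highest pixels per line excluded
#'   from the baseline fit (in `[0, 1)`; default 0.2).
#' @return An object of class `flatten_config`.
#' @export
flatten_config <- function(poly_order = 1L, exclude_fraction = 0.2) {
  poly_order <- as.integer(poly_order)
  if (poly_order < 0L) stop("poly_order must be >= 0")
  if (exclude_fraction < 0 || exclude_fraction >= 1)
    stop("exclude_fraction must be in [0, 1)")
  structure(list(poly_order = poly_order,
                 exclude_fraction = exclude_fraction),
            class = "flatten_config")
}

#' Line-by-line flattening
#'
#' Subtracts an independently fitted polynomial baseline from every fast-axis
#' line (matrix row). After flattening, the mean residual of the included
#' (non-excluded) pixels of each line is ~0.
#'
#' @param map A [heightmap].
#' @param cfg A [flatten_config()].
#' @return The flattened [heightmap].
#' @export
flatten_lines <- function(map, cfg = flatten_config()) {
  stopifnot_heightmap(map)
  if (!inherits(cfg, "flatten_config")) stop("cfg must be a flatten_config")
  h <- map$heights
  nc <- ncol(h)
  x <- seq_len(nc) * map$pixel_size_x
  x <- x - mean(x)                      # centred abscissa: well-conditioned
  X <- stats::poly(x, degree = max(cfg$poly_order, 1L), raw = FALSE)
  for (i in seq_len(nrow(h))) {
    row <- h[i, ]
    keep <- row <= stats::quantile(row, 1 - cfg$exclude_fraction,
                                   names = FALSE, type = 7)
    if (sum(keep) < cfg$poly_order + 2L)
      stop("line ", i, " has too few pixels (", sum(keep),
           ") for a baseline of order ", cfg$poly_order)
    if (cfg$poly_order == 0L) {
      h[i, ] <- row - mean(row[keep])
    } else {
      fit <- stats::lm.fit(cbind(1, X[, seq_len(cfg$poly_order), drop = FALSE])[keep, , drop = FALSE],
                           row[keep])
      baseline <- cbind(1, X[, seq_len(cfg$poly_order), drop = FALSE]) %*% fit$coefficients
      h[i, ] <- row - baseline
    }
  }
  map$heights <- h
  map
}

#' Gaussian low-pass filter
#'
#' Separable Gaussian smoothing with standard deviation `sigma_px` pixels and
#' reflective boundary handling. The kernel is normalized, so the mean height
#' is preserved and the output never exceeds the input's global extrema.
#' `sigma_px = 0` is the identity.
#'
#' @param map A [heightmap].
#' @param sigma_px Kernel standard deviation in pixels (>= 0; default 1).
#' @return The smoothed [heightmap].
#' @export
lowpass <- function(map, sigma_px = 1) {
  stopifnot_heightmap(map)
  if (!is.finite(sigma_px) || sigma_px < 0)
    stop("sigma_px must be a non-negative number")
  if (sigma_px == 0) return(map)
  k <- gaussian_kernel(sigma_px)
  h <- map$heights
  h <- apply_kernel_rows(h, k)       # along fast axis
  h <- t(apply_kernel_rows(t(h), k)) # along slow axis
  map$heights <- h
  map
}

gaussian_kernel <- function(sigma_px) {
  r <- max(1L, ceiling(4 * sigma_px))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_px^2))
  k / sum(k)
}

## 1-D convolution of every row with kernel k, reflective padding.
apply_kernel_rows <- function(h, k) {
  r <- (length(k) - 1L) / 2L
  nc <- ncol(h)
  idx <- c(pmin(pmax(seq_len(r), 1L), nc)[r:1],   # reflect left: r, ..., 1
           seq_len(nc),
           nc + 1L - seq_len(r))                  # reflect right
  hp <- h[, idx, drop = FALSE]
  out <- matrix(0, nrow(h), nc)
  for (j in seq_along(k))
    out <- out + k[[j]] * hp[, (j - 1L) + seq_len(nc), drop = FALSE]
  out
}
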