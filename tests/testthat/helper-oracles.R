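# Independent oracles and small builders used across the suite.

# Brute-force max-plus dilation: for every tip offset, shift the surface and
# take the pointwise maximum. Independent of the per-pixel C++ kernels.
oracle_dilate <- function(S, T, ai, aj) {
  nr <- nrow(S); nc <- ncol(S)
  out <- matrix(-Inf, nr, nc)
  for (i in seq_len(nrow(T))) for (j in seq_len(ncol(T))) {
    di <- i - ai; dj <- j - aj
    xs <- seq_len(nr) + di; ys <- seq_len(nc) + dj
    okx <- xs >= 1 & xs <= nr; oky <- ys >= 1 & ys <= nc
    if (!any(okx) || !any(oky)) next
    out[okx, oky] <- pmax(out[okx, oky], S[xs[okx], ys[oky]] + T[i, j])
  }
  out
}

# Brute-force min-plus erosion (adjoint): out(x) = min_u I(x-u) - T(u).
oracle_erode <- function(I, T, ai, aj) {
  nr <- nrow(I); nc <- ncol(I)
  out <- matrix(Inf, nr, nc)
  for (i in seq_len(nrow(T))) for (j in seq_len(ncol(T))) {
    di <- i - ai; dj <- j - aj
    xs <- seq_len(nr) - di; ys <- seq_len(nc) - dj
    okx <- xs >= 1 & xs <= nr; oky <- ys >= 1 & ys <= nc
    if (!any(okx) || !any(oky)) next
    out[okx, oky] <- pmin(out[okx, oky], I[xs[okx], ys[oky]] - T[i, j])
  }
  out
}

# Hemispherical cap tip on a flat surround at -R.
make_hemisphere_tip <- function(R, px) {
  xs <- seq(-R - 2 * px, R + 2 * px, by = px)
  r2 <- outer(xs^2, xs^2, `+`)
  z <- ifelse(r2 <= R^2, sqrt(pmax(R^2 - r2, 0)) - R, -R)
  tip_model(z, px)
}

make_paraboloid_tip <- function(R, px, half_extent) {
  xs <- seq(-half_extent, half_extent, by = px)
  r2 <- outer(xs^2, xs^2, `+`)
  tip_model(-r2 / (2 * R), px)
}

# NLN sampler used as the generative truth in fitting tests.
draw_nln <- function(n, mu_tip, sigma_tip, mu_log, sigma_log, seed) {
  set.seed(seed)
  stats::rnorm(n, mu_tip, sigma_tip) + stats::rlnorm(n, mu_log, sigma_log)
}

# Shared end-to-end pipeline: rough surface imaged with a spherical-cap tip;
# returns the cropped image and aligned truth.
sim_surface_image <- function(R_true, seed, size_px = 108, px = 4,
                              tip_px = 21, grain_density = 250,
                              grain_radius_logmu = log(15),
                              grain_height_range = c(20, 90)) {
  s <- generate_surface(surface_spec(size_px = size_px, pixel_size = px,
                                     grain_density = grain_density,
                                     grain_radius_logmu = grain_radius_logmu,
                                     grain_height_range = grain_height_range,
                                     seed = seed))
  tp <- generate_tip(tip_spec("sphere_cone", R_true, size_px = tip_px,
                              pixel_size = px))
  list(surface = s, tip = tp, image = crop_border(dilate(s, tp)))
}

all_radii <- function(image)
  unlist(lapply(collect_radii(image, n_sections = 1L), `[[`, "radii"))

# Reference-anchored surface calibration, the synthetic analogue of
# calibrating on images taken with new tips of known nominal radius: the
# lognormal scale comes from the reference radii minus the known tip
# radius, and the location is solved (bisection) so the fixed-surface fit
# returns the reference radius itself. This fixes the gauge of the
# tip/surface decomposition; transfers to other radii are then genuine.
calibrate_surface_anchored <- function(R0, seeds, ...) {
  ref <- unlist(lapply(seeds, function(sd)
    all_radii(sim_surface_image(R0, sd, ...)$image)))
  s <- ref - R0
  s <- s[s > 0.5]
  sigl <- stats::sd(log(s))
  m <- mean(log(s))
  g <- function(mu) fit_nln_tip(ref, c(mu, sigl))$mu_tip - R0
  lo <- m - 1.5; hi <- m + 1.5
  for (i in 1:12) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  c((lo + hi) / 2, sigl)
}

# Dense, tall, sharp-grained imaging conditions used for the NLN
# end-to-end fixtures (occludes off-apex line slices of each bump).
dense_conditions <- list(grain_density = 1000, grain_radius_logmu = log(8),
                         grain_height_range = c(30, 120))
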