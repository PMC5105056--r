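#' Synthetic rough-surface specification
#'
#' Describes a polycrystalline surface built from spherical-cap grains:
#' Poisson-distributed grain centres, apex radii drawn from a lognormal
#' distribution (the standard model for grain sizes in crystalline
#' materials), and grain apex heights uniform over a range. Overlaps are
#' resolved by pointwise maximum over a flat base plane at 0.
#'
#' The defaults emulate a hard, high-roughness polycrystalline surface of the
#' kind used for tip wear and blind reconstruction (R_rms in the low tens of
#' nm, sharp grain apices a few tens of nm in radius) at the instrument-like
#' sampling of 2.44 nm/px.
#'
#' @param size_px Grid size `c(rows, cols)` (default 256 x 256).
#' @param pixel_size Pixel size in nm (default 2.44).
#' @param grain_density Grains per square micron (default 250).
#' @param grain_radius_logmu Lognormal location of grain apex radii, log-nm
#'   (default `log(15)`).
#' @param grain_radius_logsigma Lognormal scale (default 0.5).
#' @param grain_height_range Grain apex heights, uniform over this range in
#'   nm (default `c(20, 90)`).
#' @param seed Integer seed fixing the full output.
#' @return An object of class `surface_spec`.
#' @export
surface_spec <- function(size_px = c(256L, 256L), pixel_size = 2.44,
                         grain_density = 250,
                         grain_radius_logmu = log(15),
                         grain_radius_logsigma = 0.5,
                         grain_height_range = c(20, 90), seed = 1L) {
  size_px <- as.integer(rep_len(size_px, 2L))
  if (any(size_px < 2L) || pixel_size <= 0 || grain_density <= 0 ||
      grain_radius_logsigma <= 0 ||
      any(grain_height_range <= 0) || diff(grain_height_range) < 0)
    stop("invalid surface specification")
  structure(list(size_px = size_px, pixel_size = pixel_size,
                 grain_density = grain_density,
                 grain_radius_logmu = grain_radius_logmu,
                 grain_radius_logsigma = grain_radius_logsigma,
                 grain_height_range = grain_height_range,
                 seed = as.integer(seed)),
            class = "surface_spec")
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic polycrystalline surface
#'
#' @param spec A [surface_spec()].
#' @return A [heightmap]; bit-reproducible for a given `spec$seed`.
#' @export
generate_surface <- function(spec) {
  if (!inherits(spec, "surface_spec")) stop("spec must be a surface_spec")
  nr <- spec$size_px[[1L]]; nc <- spec$size_px[[2L]]
  px <- spec$pixel_size
  area_um2 <- (nr * px) * (nc * px) * 1e-6
  with_seed(spec$seed, {
    margin <- stats::qlnorm(0.999, spec$grain_radius_logmu,
                            spec$grain_radius_logsigma)
    full_um2 <- ((nr * px) + 2 * margin) * ((nc * px) + 2 * margin) * 1e-6
    n <- stats::rpois(1L, spec$grain_density * full_um2)
    if (n > 1e6) stop("grain density too high: ", n, " grains requested")
    gx <- stats::runif(n, -margin, nr * px + margin)
    gy <- stats::runif(n, -margin, nc * px + margin)
    gr <- stats::rlnorm(n, spec$grain_radius_logmu,
                        spec$grain_radius_logsigma)
    gh <- stats::runif(n, spec$grain_height_range[[1L]],
                       spec$grain_height_range[[2L]])
    h <- matrix(0, nr, nc)
    xs <- (seq_len(nr) - 1) * px
    ys <- (seq_len(nc) - 1) * px
    for (g in seq_len(n)) {
      i0 <- max(1L, ceiling((gx[[g]] - gr[[g]]) / px))
      i1 <- min(nr, floor((gx[[g]] + gr[[g]]) / px) + 1L)
      j0 <- max(1L, ceiling((gy[[g]] - gr[[g]]) / px))
      j1 <- min(nc, floor((gy[[g]] + gr[[g]]) / px) + 1L)
      if (i0 > i1 || j0 > j1) next
      r2 <- outer((xs[i0:i1] - gx[[g]])^2, (ys[j0:j1] - gy[[g]])^2, `+`)
      cap <- gh[[g]] - gr[[g]] + sqrt(pmax(gr[[g]]^2 - r2, 0))
      cap[r2 > gr[[g]]^2] <- 0
      h[i0:i1, j0:j1] <- pmax(h[i0:i1, j0:j1], cap)
    }
    heightmap(h, px, meta = list(generator = "spherical_cap_grains",
                                 n_grains = n, grain_radii = gr,
                                 seed = spec$seed))
  })
}

#' Parametric tip specification
#'
#' @param shape `"paraboloid"` (z = -r^2 / (2 R)) or `"sphere_cone"`
#'   (spherical cap of the apex radius blended tangentially into a cone).
#' @param apex_radius Apex radius of curvature in nm (> 0).
#' @param cone_half_angle Cone half-angle from the axis in degrees
#'   (sphere_cone only; 0 < angle < 90; default 25).
#' @param size_px Tip grid size (odd; scalar or `c(rows, cols)`).
#' @param pixel_size Pixel size in nm.
#' @return An object of class `tip_spec`.
#' @export
tip_spec <- function(shape = c("paraboloid", "sphere_cone"),
                     apex_radius, cone_half_angle = 25,
                     size_px = 41L, pixel_size = 2.44) {
  shape <- match.arg(shape)
  size_px <- as.integer(rep_len(size_px, 2L))
  if (apex_radius <= 0) stop("apex_radius must be positive")
  if (shape == "sphere_cone" &&
      (cone_half_angle <= 0 || cone_half_angle >= 90))
    stop("cone_half_angle must be in (0, 90) degrees")
  if (any(size_px %% 2L == 0L)) stop("tip grid size must be odd")
  structure(list(shape = shape, apex_radius = apex_radius,
                 cone_half_angle = cone_half_angle,
                 size_px = size_px, pixel_size = pixel_size),
            class = "tip_spec")
}

#' Generate a parametric tip model
#'
#' @param spec A [tip_spec()].
#' @return A [tip_model()] with the apex at the grid centre (height 0).
#' @export
generate_tip <- function(spec) {
  if (!inherits(spec, "tip_spec")) stop("spec must be a tip_spec")
  nr <- spec$size_px[[1L]]; nc <- spec$size_px[[2L]]
  px <- spec$pixel_size
  if (min(nr - 1L, nc - 1L) * px < 2 * spec$apex_radius)
    stop("tip grid too small to contain a 2 x apex_radius footprint")
  ci <- (nr + 1L) / 2; cj <- (nc + 1L) / 2
  r <- sqrt(outer(((seq_len(nr) - ci) * px)^2,
                  ((seq_len(nc) - cj) * px)^2, `+`))
  R <- spec$apex_radius
  z <- if (spec$shape == "paraboloid") {
    -r^2 / (2 * R)
  } else {
    a <- spec$cone_half_angle * pi / 180
    rt <- R * cos(a)
    zc <- ifelse(r <= rt, sqrt(pmax(R^2 - r^2, 0)) - R,
                 R * (sin(a) - 1) - (r - rt) / tan(a))
    zc
  }
  tip_model(z, px, meta = list(shape = spec$shape, apex_radius = R))
}

#' Simulate a contact-mode AFM image
#'
#' Dilation of the surface by the tip ([dilate()]) plus optional per-pixel
#' Gaussian noise and per-line height drift; deterministic per seed.
#'
#' @param surface A [heightmap].
#' @param tip A [tip_model()] with the same pixel size.
#' @param noise_sd Per-pixel Gaussian noise sd in nm (default 0).
#' @param line_drift_sd Per-line random offset sd in nm (default 0).
#' @param seed Integer seed.
#' @return The simulated image as a [heightmap].
#' @export
simulate_image <- function(surface, tip, noise_sd = 0, line_drift_sd = 0,
                           seed = 1L) {
  img <- dilate(surface, tip)
  if (noise_sd > 0 || line_drift_sd > 0) {
    img$heights <- with_seed(seed, {
      h <- img$heights
      if (noise_sd > 0)
        h <- h + matrix(stats::rnorm(length(h), 0, noise_sd),
                        nrow(h), ncol(h))
      if (line_drift_sd > 0)
        h <- h + stats::rnorm(nrow(h), 0, line_drift_sd)
      h
    })
  }
  img
}

#' Simulate a gradually wearing tip
#'
#' Returns tips whose apex radius grows linearly, each the same cone (or
#' paraboloid family) with a progressively blunter spherical apex. In a
#' common frame sharing the far-field cone flanks, a larger apex radius sits
#' strictly inside the sharper tip, so material is only ever removed and the
#' worn volume between any two steps is positive.
#'
#' @param spec A [tip_spec()] describing the initial tip.
#' @param n_steps Number of tips in the sequence (>= 1).
#' @param radius_growth_per_step Apex radius increment per step in nm (> 0
#'   unless `n_steps` is 1).
#' @return A list of [tip_model()]s.
#' @export
simulate_wear <- function(spec, n_steps, radius_growth_per_step) {
  if (!inherits(spec, "tip_spec")) stop("spec must be a tip_spec")
  n_steps <- as.integer(n_steps)
  if (n_steps < 1L) stop("n_steps must be >= 1")
  if (n_steps > 1L && radius_growth_per_step <= 0)
    stop("radius growth must be positive")
  radii <- spec$apex_radius + (seq_len(n_steps) - 1L) * radius_growth_per_step
  grid_cap <- (min(spec$size_px) - 1L) * spec$pixel_size / 2
  if (max(radii) > grid_cap)
    stop("final radius ", max(radii), " nm exceeds the grid capacity ",
         grid_cap, " nm")
  lapply(radii, function(R) {
    s <- spec; s$apex_radius <- R
    generate_tip(s)
  })
}
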