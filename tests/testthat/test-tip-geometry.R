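test_that("end radius recovers spherical, parabolic and conical apices", {
  hemi <- make_hemisphere_tip(20, 0.2)
  expect_equal(end_radius(hemi, 15), 20, tolerance = 0.01)
  # depth independence for a sphere
  for (d in c(5, 10, 18)) expect_equal(end_radius(hemi, d), 20, tolerance = 0.01)
  # paraboloid R: closed form gives R + depth/2
  par <- make_paraboloid_tip(15, 0.1, 25)
  expect_equal(end_radius(par, 15), 22.5, tolerance = 0.01)
  # pure cone, 45 degrees: contour radius = depth -> R_t = depth
  xs <- seq(-25, 25, by = 0.1)
  cone <- tip_model(-sqrt(outer(xs^2, xs^2, `+`)), 0.1)
  expect_equal(end_radius(cone, 15), 15, tolerance = 0.01)
})

test_that("end radius demands a closed contour and enough depth", {
  shallow <- make_hemisphere_tip(10, 0.2)
  expect_error(end_radius(shallow, 15), "does not extend")
  # paraboloid clipped so the 15 nm contour exits the grid
  par <- make_paraboloid_tip(15, 0.5, 15)
  expect_error(end_radius(par, 15), "contour")
})

test_that("open sphericity matches closed-form solids", {
  hemi <- make_hemisphere_tip(20, 0.2)
  expect_equal(as.numeric(open_sphericity(hemi, 20)), 1, tolerance = 0.02)
  # paraboloid to its apex radius of curvature: 18^(1/3)*1.5/(3*sqrt(3)-1)
  par <- make_paraboloid_tip(15, 0.1, 25)
  psi_exact <- 18^(1 / 3) * 1.5 / (3 * sqrt(3) - 1)
  expect_equal(as.numeric(open_sphericity(par, 15)), psi_exact,
               tolerance = 0.005)
  # spherical cap R = 20 to depth 10: V = pi d^2 (3R - d)/3, A = 2 pi R d
  cap <- make_hemisphere_tip(20, 0.1)
  V <- pi * 100 * 50 / 3; A <- 2 * pi * 20 * 10
  psi_cap <- (18 * pi)^(1 / 3) * V^(2 / 3) / A
  expect_equal(as.numeric(open_sphericity(cap, 10)), psi_cap,
               tolerance = 0.01)
  expect_error(open_sphericity(hemi, -1), "positive")
})

test_that("open sphericity is scale invariant", {
  base <- make_paraboloid_tip(15, 0.2, 25)
  psi0 <- as.numeric(open_sphericity(base, 15))
  for (f in c(0.5, 2, 5)) {
    scaled <- tip_model(base$heights * f, 0.2 * f)
    expect_equal(as.numeric(open_sphericity(scaled, 15 * f)), psi0,
                 tolerance = 1e-6)
  }
})

test_that("closed sphericity has its textbook values", {
  R <- 7
  expect_equal(closed_sphericity(4 / 3 * pi * R^3, 4 * pi * R^2), 1)
  s <- 3
  expect_equal(closed_sphericity(s^3, 6 * s^2), (pi / 6)^(1 / 3),
               tolerance = 1e-12)
  # open hemisphere exceeds 1, which is what motivates the open variant
  expect_gt(closed_sphericity(2 / 3 * pi * R^3, 2 * pi * R^2), 1)
  expect_error(closed_sphericity(0, 1), "positive")
})

test_that("disc volumes integrate widths correctly", {
  d <- seq(0, 12, by = 0.1)
  expect_equal(disc_volume(rep(6, length(d)), d), pi * 9 * 12,
               tolerance = 1e-9)                       # cylinder exact
  R <- 20
  dh <- seq(0, R, by = 0.1)
  w <- 2 * sqrt(pmax(R^2 - (R - dh)^2, 0))
  expect_equal(disc_volume(w, dh), 2 / 3 * pi * R^3, tolerance = 0.02)
  expect_equal(disc_volume(numeric(1), 0), 0)
  expect_error(disc_volume(c(1, 2), c(1, 1)), "increasing")
  # order-1 convergence: halving the step roughly halves the error
  err <- sapply(c(0.2, 0.1, 0.05), function(h) {
    dd <- seq(0, R, by = h)
    abs(disc_volume(2 * sqrt(pmax(R^2 - (R - dd)^2, 0)), dd) -
          2 / 3 * pi * R^3)
  })
  expect_true(all(diff(err) < 0))
})

test_that("worn volume matches the solid-of-revolution oracle", {
  mkpair <- function(R, dmax) {
    xm <- sqrt(2 * R * dmax)
    x <- seq(-xm, xm, by = 0.05)
    pr <- list(position = x, height = -x^2 / (2 * R))
    structure(list(fast = pr, slow = pr, pixel_size = c(0.05, 0.05)),
              class = "tip_profile_pair")
  }
  # paraboloid R = 15 worn to R = 30, profiles truncated at width 40
  before <- mkpair(15, 400 / 30)
  after <- mkpair(30, 400 / 60)
  wv <- worn_volume(before, after)
  # oracle: V = int pi/4 (w_u^2 - w_w^2) dh with the exact offset 20/3
  oracle <- 4000 / 3 * pi
  expect_equal(as.numeric(wv), oracle, tolerance = 0.02)
  expect_equal(unname(attr(wv, "offset_nm")[1]), 20 / 3, tolerance = 0.02)
  # no wear -> zero volume; swapped roles cannot satisfy the overlay
  expect_equal(as.numeric(worn_volume(before, before)), 0)
  expect_error(worn_volume(after, before), "never become equal|infeasible")
})
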