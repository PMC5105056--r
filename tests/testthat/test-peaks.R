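test_that("peak detection applies true two-sided prominence", {
  x <- seq(0, 500, by = 2.44)
  bump <- function(c0, h, w = 200) h * exp(-(x - c0)^2 / w)
  expect_length(detect_peaks(bump(250, 25)), 1L)       # clear prominence
  expect_length(detect_peaks(bump(250, 10)), 0L)       # sub-threshold
  # three bumps with prominences ~30, ~15, ~40 over a shared baseline
  y <- bump(100, 30) + bump(250, 15) + bump(400, 40)
  pks <- detect_peaks(y, 20)
  # brute-force oracle: prominence of every strict local maximum
  oracle <- Filter(function(p) {
    lm_ <- min(y[1:p]); rm_ <- min(y[p:length(y)])
    lo <- p; while (lo > 1 && y[lo - 1] <= y[lo]) lo <- lo - 1
    hi <- p; while (hi < length(y) && y[hi + 1] <= y[hi]) hi <- hi + 1
    y[p] - min(y[lo:p]) >= 20 && y[p] - min(y[p:hi]) >= 20
  }, which(diff(sign(diff(y))) == -2) + 1L)
  expect_equal(pks, as.integer(oracle))
  expect_equal(length(pks), 2L)
  expect_equal(sort(abs(x[pks] - c(100, 400))) < 3, c(TRUE, TRUE))
})

test_that("peak counts are monotone in the prominence threshold and avoid endpoints", {
  set.seed(31)
  y <- cumsum(rnorm(400)) + 30 * sin(seq(0, 12 * pi, length.out = 400))
  counts <- sapply(c(5, 10, 20, 40, 80), function(pr)
    length(detect_peaks(y, pr)))
  expect_true(all(diff(counts) <= 0))
  for (pr in c(5, 20)) {
    pk <- detect_peaks(y, pr)
    expect_false(1L %in% pk || length(y) %in% pk)
  }
})

test_that("parabolic fits recover curvature radii", {
  x <- seq(0, 500, by = 2.44)
  y <- -(x - 250)^2 / 50
  f <- fit_peak(x, y, which.max(y), 15)
  expect_equal(f$radius, 25, tolerance = 1e-9)
  expect_equal(f$a, -0.02, tolerance = 1e-9)
  # circular arc radius 30 at instrument sampling: the parabola
  # underestimates the circle over a 15 nm window; frozen oracle value from
  # the closed-form least-squares fit of the analytic arc is 24.27
  xa <- seq(-25, 25, by = 2.44)
  ya <- sqrt(pmax(30^2 - xa^2, 0)) - 30
  fa <- fit_peak(xa, ya, which.min(abs(xa)), 15)
  expect_equal(fa$radius, 24.27, tolerance = 0.01)
  # radius is invariant to height offset and profile reversal
  f2 <- fit_peak(xa, ya + 123, which.min(abs(xa)), 15)
  f3 <- fit_peak(rev(-xa), rev(ya), which.min(abs(xa)), 15)
  expect_equal(f2$radius, fa$radius, tolerance = 1e-9)
  expect_equal(f3$radius, fa$radius, tolerance = 1e-9)
})

test_that("unusable fits are rejected with a reason, not an error", {
  x <- c(0, 2.44, 4.88)
  f <- fit_peak(x, c(-20, 0, -20), 2L, 15)   # only 1 in-window point
  expect_s3_class(f, "peak_reject")
  expect_equal(f$reason, "too_few_points")
  conv <- fit_peak(seq(0, 24, 2.44), rep(0, 10), 5L, 15)
  expect_s3_class(conv, "peak_reject")
  expect_equal(conv$reason, "non_concave")
})

test_that("radius collection partitions rows and annotates distance", {
  img <- heightmap(matrix(0, 1024, 16), 2.44)
  rs <- collect_radii(img, 6)
  expect_equal(sapply(rs, `[[`, "n_rows"), c(170, 170, 170, 170, 170, 174))
  expect_equal(sapply(rs, `[[`, "radii"), rep(list(numeric(0)), 6)) # flat
  # distance at section midpoints: 2 * rows_so_far * line width
  lw <- 16 * 2.44
  expect_equal(rs[[1]]$sliding_distance_nm, 2 * 85 * lw)
  expect_equal(rs[[6]]$sliding_distance_nm, 2 * (850 + 87) * lw)
  expect_error(collect_radii(heightmap(matrix(0, 4, 8), 1), 6), "fewer rows")
})

test_that("collected radii see the tip as a curvature floor", {
  # the tip adds its radius to every grain apex, so against the bare
  # surface the whole distribution of measured radii shifts up by ~R_true
  # (parabola-vs-arc bias affects both samples alike)
  sim <- sim_surface_image(R_true = 25, seed = 77, size_px = 140, px = 4,
                           tip_px = 17)
  rs <- collect_radii(sim$image, n_sections = 1L)
  radii <- rs[[1]]$radii
  expect_gt(length(radii), 80)
  bare <- unlist(lapply(collect_radii(sim$surface, n_sections = 1L),
                        `[[`, "radii"))
  expect_gt(quantile(radii, 0.25) - quantile(bare, 0.25), 0.5 * 25)
  expect_gt(quantile(radii, 0.05), quantile(bare, 0.05))
  # offset invariance of the whole chain
  img2 <- sim$image; img2$heights <- img2$heights + 55
  rs2 <- collect_radii(img2, n_sections = 1L)
  expect_equal(rs2[[1]]$radii, radii, tolerance = 1e-9)
})
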