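test_that("segmentation recovers phantom masks with high Dice overlap", {
  dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

  flat <- make_spheroid_image(diameter_um = 120, profile_shape = "flat",
                              peak_intensity = 200, background = 10,
                              noise_sd = 0)
  mask <- segment_mask(flat$image)
  expect_gte(dice(mask, flat$truth$mask), 0.99)

  # bright rim with a dark interior hole: the hole must be filled
  holed <- make_spheroid_image(
    diameter_um = 120, profile_shape = "custom",
    radial_fn = function(r) ifelse(r < 0.35, 0, 1),
    peak_intensity = 200, background = 10, noise_sd = 0)
  mask_h <- segment_mask(holed$image)
  expect_gte(dice(mask_h, holed$truth$mask), 0.98)

  expect_error(segment_mask(image_grid(matrix(0, 50, 50), 1)),
               "no foreground")
})

test_that("the centroid is the coordinate mean and is checked for interiority", {
  ctr_mask <- disk_mask(200, c(100, 100), 40)
  ctr <- compute_centroid(ctr_mask)
  expect_lt(max(abs(ctr - c(100, 100))), 0.5)
  expect_true(attr(ctr, "inside"))

  off_mask <- disk_mask(200, c(60, 140), 30)
  off <- compute_centroid(off_mask)
  # brute-force coordinate mean oracle
  idx <- which(off_mask, arr.ind = TRUE)
  expect_equal(as.numeric(off), c(mean(idx[, 1]), mean(idx[, 2])))
  expect_lt(max(abs(off - c(60, 140))), 0.5)

  # C-shaped mask whose coordinate mean falls in the central hole
  cshape <- disk_mask(200, c(100, 100), 50) &
    !disk_mask(200, c(100, 100), 35)
  cshape[, 106:200] <- FALSE   # open the ring toward +col
  cres_ctr <- compute_centroid(cshape)
  expect_false(attr(cres_ctr, "inside"))
  img <- image_grid(matrix(1, 200, 200), 1)
  expect_error(cast_profiles(img, cshape, cres_ctr),
               "inside the mask")

  expect_error(compute_centroid(matrix(FALSE, 5, 5)), "empty mask")
})

test_that("geometry metrics match analytic shapes", {
  disk <- disk_mask(201, c(101, 101), 50.5)
  g <- measure_geometry(disk, pixel_size_um = 1)
  expect_lt(abs(g$diameter_um - 101), 2)
  expect_gte(g$circularity, 0.95)
  expect_lte(g$circularity, 1)

  sq <- matrix(FALSE, 60, 60); sq[6:55, 6:55] <- TRUE
  g_sq <- measure_geometry(sq, 1)
  expect_lt(abs(g_sq$circularity - pi / 4), 0.05)

  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  g_one <- measure_geometry(one, 2)
  expect_equal(g_one$diameter_um, 2 * 2 / sqrt(pi))
  expect_lte(g_one$circularity, 1)

  expect_error(measure_geometry(matrix(FALSE, 4, 4), 1), "empty mask")
})

test_that("radial profiles recover analytic fields on noiseless phantoms", {
  cases <- list(
    list(f = function(r) 1 - r, a = function(d) 200 * (1 - d)),
    list(f = function(r) (1 - r)^2, a = function(d) 200 * (1 - d)^2))
  for (cs in cases) {
    sim <- make_spheroid_image(diameter_um = 150, profile_shape = "custom",
                               radial_fn = cs$f, peak_intensity = 200,
                               background = 0, noise_sd = 0,
                               center = c(100, 100))
    ps <- cast_profiles(sim$image, sim$truth$mask, sim$truth$centroid)
    expect_equal(dim(ps$profiles), c(20, 80))
    expect_lte(max(abs(ps$mean_profile - cs$a(ps$normalized_distance))), 2)
    # every ray ends on the mask boundary
    expect_true(all(abs(ps$ray_length_px - sim$truth$radius_px) <= 1))
  }
})

test_that("profile sampling respects shape, constants, and the distance axis", {
  mask <- disk_mask(120, c(60, 60), 40)
  const <- image_grid(matrix(5, 120, 120), 1)
  ps <- cast_profiles(const, mask, K = 12, M = 40)
  expect_true(all(abs(ps$profiles - 5) < 1e-9))
  expect_equal(ps$normalized_distance[1], 0)
  expect_equal(ps$normalized_distance[40], 1)
  expect_true(all(diff(ps$normalized_distance) > 0))
  expect_true(is_degenerate_profile(ps$normalized_profile))

  expect_error(cast_profiles(const, mask, K = 2), "at least 3")
  expect_error(cast_profiles(const, mask, M = 4), "at least 8")
})

test_that("rotating an angular phantom cyclically permutes the rays", {
  K <- 20
  mkimg <- function(shift) {
    n <- 200; ctr <- c(100.5, 100.5); R <- 75
    rows <- matrix(1:n, n, n); cols <- t(rows)
    rad <- sqrt((rows - ctr[1])^2 + (cols - ctr[2])^2)
    th <- atan2(-(rows - ctr[1]), cols - ctr[2])
    v <- matrix(0, n, n)
    inside <- rad <= R
    rn <- rad[inside] / R
    # azimuthal modulation vanishing at centre and rim keeps the
    # gradient bounded everywhere
    v[inside] <- 100 + 50 * cos(th[inside] - shift) * rn * (1 - rn)
    list(img = image_grid(v, 1, "ang", "float"), mask = inside, ctr = ctr)
  }
  a <- mkimg(0); b <- mkimg(2 * pi / K)
  pa <- cast_profiles(a$img, a$mask, a$ctr, K = K)
  pb <- cast_profiles(b$img, b$mask, b$ctr, K = K)
  shifted <- pa$profiles[c(K, 1:(K - 1)), ]
  expect_lt(max(abs(pb$profiles - shifted)), 1)
})

test_that("mean_profile is the column mean", {
  expect_equal(mean_profile(rbind(c(0, 2, 4), c(2, 2, 4))), c(1, 2, 4))
  same <- rbind(c(1, 5, 9), c(1, 5, 9), c(1, 5, 9))
  expect_equal(mean_profile(same), c(1, 5, 9))
  set.seed(4)
  m <- matrix(rnorm(20 * 80), 20, 80)
  oracle <- vapply(seq_len(80), function(j) {
    s <- 0
    for (i in 1:20) s <- s + m[i, j]
    s / 20
  }, numeric(1))
  expect_equal(mean_profile(m), oracle)
})

test_that("min-max normalization matches the closed form and its invariances", {
  expect_equal(as.numeric(normalize_profile(c(0, 5, 10))), c(0, 0.5, 1))

  const <- normalize_profile(c(7, 7, 7))
  expect_equal(as.numeric(const), c(0, 0, 0))
  expect_true(is_degenerate_profile(const))

  set.seed(8)
  for (rep in 1:20) {
    x <- rnorm(80)
    got <- as.numeric(normalize_profile(x))
    expect_equal(got, (x - min(x)) / (max(x) - min(x)), tolerance = 1e-14)
    expect_equal(min(got), 0)
    expect_equal(max(got), 1)
    # affine invariance for positive scalings
    a <- runif(1, 0.1, 10); b <- rnorm(1, 0, 5)
    expect_equal(as.numeric(normalize_profile(a * x + b)), got,
                 tolerance = 1e-12)
  }
  expect_error(normalize_profile(c(1, NA, 3)), "non-finite")
  expect_error(normalize_profile(1), "at least 2")
})

test_that("profile_spheroid composes the stages and classifies size", {
  sim <- make_spheroid_image(diameter_um = 150, profile_shape = "edge_high",
                             peak_intensity = 180, background = 8,
                             noise_sd = 2, seed = 12)
  rec <- profile_spheroid(sim$image)
  expect_s3_class(rec, "spheroid_record")
  expect_lt(abs(rec$diameter_um - 150), 8)
  expect_equal(rec$size_class, "small")
  expect_gte(rec$circularity, 0.9)
  # the normalized profile of an edge-high marker rises outward
  np <- as.numeric(rec$profile_set$normalized_profile)
  expect_lt(np[5], np[75])
})
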