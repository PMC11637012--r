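test_that("the biexponential model matches its closed form", {
  # t = 0 gives I0 when amplitudes are normalized
  expect_equal(biexp_model(0, 100, 0.7, 0.4, 0.3, 2.5), 100)
  # mono-exponential at t = tau1
  expect_equal(biexp_model(0.4, 100, 0.8, 0.4, 0, 2.5), 100 * 0.8 / exp(1))
  # scalar-loop oracle on random parameters
  set.seed(19)
  for (rep in 1:5) {
    t <- seq(0, 12.5, length.out = 64)
    I0 <- runif(1, 10, 1000); a1 <- runif(1); a2 <- runif(1)
    t1 <- runif(1, 0.1, 1); t2 <- runif(1, 1, 5)
    got <- biexp_model(t, I0, a1, t1, a2, t2)
    for (i in seq_along(t))
      expect_equal(got[i], I0 * (a1 * exp(-t[i] / t1) + a2 * exp(-t[i] / t2)))
  }
  expect_error(biexp_model(0:10, 1, 0.5, -0.4, 0.5, 2.5), "positive")
  expect_error(biexp_model(-1, 1, 0.5, 0.4, 0.5, 2.5), "non-negative")
})

test_that("noiseless decays are recovered to high precision (inverse crime)", {
  truth <- list(A1 = 0.8, tau1 = 0.4, A2 = 0.2, tau2 = 2.5)
  h <- expected_decay_curve(truth$A1, truth$tau1, truth$A2, truth$tau2,
                            photons = 5000)
  fit <- fit_pixel_decay(h, 12.5 / 256)
  expect_true(fit$valid)
  expect_lt(abs(fit$A1 - truth$A1) / truth$A1, 1e-3)
  expect_lt(abs(fit$tau1_ns - truth$tau1) / truth$tau1, 1e-3)
  expect_lt(abs(fit$tau2_ns - truth$tau2) / truth$tau2, 1e-3)
  expect_equal(fit$A1 + fit$A2, 1)
  # the fitted model reproduces the histogram
  t <- (seq_along(h) - 1) * 12.5 / 256
  model <- fit$background +
    biexp_model(t, fit$I0, fit$A1, fit$tau1_ns, fit$A2, fit$tau2_ns)
  chi2 <- sum((model - h)^2 / pmax(h, 1)) / (length(h) - 5)
  expect_lt(chi2, 1e-6)
})

test_that("a mono-exponential decay is absorbed without bias", {
  h <- expected_decay_curve(1, 1.2, 0, 2.5, photons = 10000)
  fit <- fit_pixel_decay(h, 12.5 / 256)
  expect_true(fit$valid)
  expect_lt(abs(mean_lifetime(fit) - 1.2), 0.05)
})

test_that("mean lifetime is the amplitude-weighted average", {
  mk <- function(A1, t1, A2, t2)
    structure(list(I0 = 1, A1 = A1, A2 = A2, tau1_ns = t1, tau2_ns = t2,
                   background = 0, chi2_reduced = 0, n_photons = 1e4,
                   valid = TRUE, converged = TRUE), class = "biexp_fit")
  expect_equal(mean_lifetime(mk(1, 0.4, 0, 2.5)), 0.4)
  expect_equal(mean_lifetime(mk(0.8, 0.4, 0.2, 2.5)), 0.82)
  expect_equal(mean_lifetime(mk(0.5, 0.3, 0.5, 1.9)), (0.3 + 1.9) / 2)
  # intensity weighting emphasises the long component
  expect_gt(mean_lifetime(mk(0.8, 0.4, 0.2, 2.5), "intensity"), 0.82)
})

test_that("photon-starved and empty histograms are skipped, not errors", {
  dim_fit <- fit_pixel_decay(rep(0.2, 64), 0.05)
  expect_false(dim_fit$valid)
  zero_fit <- fit_pixel_decay(rep(0, 64), 0.05)
  expect_false(zero_fit$valid)
  expect_error(fit_pixel_decay(c(-1, rep(1, 63)), 0.05), "non-negative")
})

test_that("Poisson-noise fits recover amplitude ratios and lifetimes", {
  set.seed(101)
  truth <- list(A1 = 0.8, tau1 = 0.4, A2 = 0.2, tau2 = 2.5)
  lambda <- expected_decay_curve(truth$A1, truth$tau1, truth$A2,
                                 truth$tau2, photons = 5000)
  ratios <- taus <- numeric(60)
  for (i in seq_along(ratios)) {
    fit <- fit_pixel_decay(rpois(length(lambda), lambda), 12.5 / 256)
    ratios[i] <- fit$A1 / fit$A2
    taus[i] <- mean_lifetime(fit)
  }
  expect_lte(median(abs(ratios - 4) / 4), 0.10)
  expect_lte(abs(mean(taus) - 0.82), 0.03)
})

test_that("fitted mean lifetime rises with the true bound fraction", {
  taus <- vapply(c(0.1, 0.2, 0.3, 0.4), function(a2) {
    h <- expected_decay_curve(1 - a2, 0.4, a2, 2.5, photons = 8000)
    mean_lifetime(fit_pixel_decay(h, 12.5 / 256))
  }, numeric(1))
  expect_true(all(diff(taus) > 0))
})

test_that("stack fitting maps a uniform phantom within 2 percent", {
  sim <- make_decay_stack(shape = c(8, 8), photons_per_pixel = 5000,
                          seed = 7)
  maps <- fit_stack(sim$stack, spatial_bin = 3)
  expect_gte(mean(maps$valid), 0.99)
  expect_lt(abs(mean(maps$a1a2_ratio[maps$valid]) - 4) / 4, 0.02)
  expect_lt(abs(mean(maps$mean_tau_ns[maps$valid]) - 0.82) / 0.82, 0.02)

  zero <- decay_stack(array(0L, c(4, 4, 32)), 0.05, 1)
  maps0 <- fit_stack(zero)
  expect_false(any(maps0$valid))
  expect_true(all(is.na(maps0$mean_tau_ns)))
})

test_that("core/edge amplitude-ratio contrast separates in two-region stacks", {
  # inner A1/A2 = 4.9, outer 4.3 - a core/edge-like metabolic contrast
  a1_of <- function(r) r / (1 + r)
  sim <- make_decay_stack(
    shape = c(16, 16), photons_per_pixel = 5000, seed = 3,
    two_region = list(
      inner = list(A1 = a1_of(4.9), tau1_ns = 0.4,
                   A2 = 1 - a1_of(4.9), tau2_ns = 2.5),
      outer = list(A1 = a1_of(4.3), tau1_ns = 0.4,
                   A2 = 1 - a1_of(4.3), tau2_ns = 2.5),
      radius_frac = 0.5))
  maps <- fit_stack(sim$stack, spatial_bin = 1)
  inner <- sim$truth$region_map == 1L & maps$valid
  outer <- sim$truth$region_map == 2L & maps$valid
  m_in <- mean(maps$a1a2_ratio[inner]); m_out <- mean(maps$a1a2_ratio[outer])
  pooled_sd <- sqrt((stats::var(maps$a1a2_ratio[inner]) +
                     stats::var(maps$a1a2_ratio[outer])) / 2)
  expect_gt(m_in, m_out)
  expect_gt((m_in - m_out) / (pooled_sd / sqrt(min(sum(inner), sum(outer)))),
            3)
})

test_that("gain/power normalization follows the calibration curve", {
  img <- image_grid(matrix(200, 10, 10), 1)
  flat_curve <- data.frame(gain = c(0, 500), sensitivity = c(1, 1))
  out <- normalize_intensity(img, 250, 1, flat_curve)
  expect_equal(out$values, img$values)

  # doubling the power at a fixed scene quadruples the raw signal;
  # normalization must cancel it (two-photon exponent 2)
  raw1 <- image_grid(matrix(100, 5, 5), 1)
  raw2 <- image_grid(matrix(400, 5, 5), 1)
  n1 <- normalize_intensity(raw1, 250, 5, flat_curve)
  n2 <- normalize_intensity(raw2, 250, 10, flat_curve)
  expect_equal(n1$values, n2$values)

  # log-linear interpolation on a decade-per-100 curve
  curve <- data.frame(gain = seq(0, 300, by = 50),
                      sensitivity = 10^(seq(0, 300, by = 50) / 100))
  out2 <- normalize_intensity(img, 200, 2, curve)
  expect_equal(out2$values, img$values / 400)
  # interpolation at an off-grid gain stays on the exponential curve
  out3 <- normalize_intensity(img, 225, 1, curve)
  expect_equal(out3$values, img$values / 10^(2.25), tolerance = 1e-10)

  expect_error(normalize_intensity(img, 400, 1, curve), "outside")
  expect_error(normalize_intensity(img, 200, 0, curve), "positive")
})

test_that("the redox ratio is bounded, symmetric, and scale invariant", {
  mk <- function(m) image_grid(m, 1)
  n <- matrix(50, 8, 8)
  same <- redox_map(mk(n), mk(n), floor = 1)
  expect_true(all(same$ratio[same$valid] == 0.5))

  zero_nadh <- redox_map(mk(matrix(0, 8, 8)), mk(n), floor = 1)
  expect_true(all(zero_nadh$ratio[zero_nadh$valid] == 1))

  set.seed(23)
  a <- matrix(runif(64, 1, 100), 8, 8)
  b <- matrix(runif(64, 1, 100), 8, 8)
  rm1 <- redox_map(mk(a), mk(b), floor = 0.5)
  # scalar-loop oracle
  for (i in 1:8) for (j in 1:8)
    expect_equal(rm1$ratio[i, j], b[i, j] / (a[i, j] + b[i, j]))
  expect_true(all(rm1$ratio[rm1$valid] >= 0 & rm1$ratio[rm1$valid] <= 1))
  # scale invariance
  rm2 <- redox_map(mk(3 * a), mk(3 * b), floor = 1.5)
  expect_equal(rm2$ratio, rm1$ratio, tolerance = 1e-12)

  # floor marks weak-signal pixels invalid
  dim_img <- a; dim_img[1, 1] <- 0.01
  dim_fad <- b; dim_fad[1, 1] <- 0.01
  rm3 <- redox_map(mk(dim_img), mk(dim_fad), floor = 1)
  expect_false(rm3$valid[1, 1])
  expect_true(is.na(rm3$ratio[1, 1]))

  expect_error(redox_map(mk(a), mk(matrix(1, 4, 4))), "same shape")
})

test_that("radial profiling applies unchanged to fitted lifetime maps", {
  a1_of <- function(r) r / (1 + r)
  sim <- make_decay_stack(
    shape = c(24, 24), photons_per_pixel = 4000, seed = 9,
    two_region = list(
      inner = list(A1 = a1_of(4.9), tau1_ns = 0.4,
                   A2 = 1 - a1_of(4.9), tau2_ns = 2.5),
      outer = list(A1 = a1_of(4.3), tau1_ns = 0.4,
                   A2 = 1 - a1_of(4.3), tau2_ns = 2.5),
      radius_frac = 0.9))
  maps <- fit_stack(sim$stack, spatial_bin = 3)
  vals <- maps$a1a2_ratio
  vals[!maps$valid] <- 0
  map_img <- image_grid(vals, sim$stack$pixel_size_um, "a1a2", "float")
  mask <- sim$truth$region_map == 1L
  ps <- cast_profiles(map_img, mask, compute_centroid(mask), K = 12, M = 16)
  expect_equal(dim(ps$profiles), c(12, 16))
  expect_true(all(is.finite(ps$profiles)))
  np <- as.numeric(ps$normalized_profile)
  expect_equal(range(np), c(0, 1))
})
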