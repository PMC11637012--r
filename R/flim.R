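#' Biexponential fluorescence decay model
#'
#' Evaluates `I(t) = I0 * (A1 * exp(-t / tau1) + A2 * exp(-t / tau2))`,
#' the standard two-component model for NADH fluorescence-lifetime
#' decays: `tau1` is the short (free NADH) and `tau2` the long
#' (protein-bound NADH) lifetime component, and `A1`, `A2` their
#' relative contributions.
#'
#' @param t Time vector in ns (>= 0).
#' @param I0 Amplitude scale (>= 0).
#' @param A1,A2 Component amplitudes (>= 0).
#' @param tau1_ns,tau2_ns Lifetimes in ns (> 0).
#' @return Numeric vector `I(t)`.
#' @export
biexp_model <- function(t, I0, A1, tau1_ns, A2, tau2_ns) {
  if (tau1_ns <= 0 || tau2_ns <= 0)
    stop("lifetimes must be positive")
  if (I0 < 0 || A1 < 0 || A2 < 0)
    stop("amplitudes must be non-negative")
  if (any(t < 0)) stop("`t` must be non-negative")
  I0 * (A1 * exp(-t / tau1_ns) + A2 * exp(-t / tau2_ns))
}

new_invalid_fit <- function(n_photons) {
  structure(
    list(I0 = NA_real_, A1 = NA_real_, A2 = NA_real_,
         tau1_ns = NA_real_, tau2_ns = NA_real_, background = NA_real_,
         chi2_reduced = NA_real_, n_photons = n_photons,
         valid = FALSE, converged = FALSE),
    class = "biexp_fit")
}

#' Fit a biexponential decay to one pixel's histogram
#'
#' Constrained weighted least squares (Levenberg-Marquardt) of the
#' biexponential model plus a constant background term, with
#' Poisson-motivated weights `1 / max(expected count, 1)`: the fit is
#' seeded with data-based weights and then iteratively re-weighted by
#' the fitted model, which removes the amplitude bias that observed-
#' count weights introduce at moderate photon counts. Several starting
#' points are tried and the best (Pearson chi-square) kept, so nearly
#' mono-exponential decays do not strand the optimizer in a local
#' minimum. Bins before the
#' histogram peak are discarded and the time axis re-zeroed at the peak
#' (no instrument-response deconvolution is attempted). Amplitudes are
#' reported normalized to `A1 + A2 = 1`, the raw scale being carried by
#' `I0`. Bounds: `tau1` in `[0.05, 1]` ns, `tau2` in `[1, 6]` ns,
#' amplitudes and background >= 0.
#'
#' Histograms below `photon_threshold` total counts, and fits that fail
#' to converge, return an invalid fit (`valid = FALSE`) rather than an
#' error, so map-level code can simply skip them.
#'
#' @param counts Numeric vector of bin counts (>= 0; need not be
#'   integer, so noiseless model curves can be fitted too).
#' @param bin_width_ns Bin width in ns.
#' @param init Optional named list overriding the starting values
#'   `tau1 = 0.4`, `tau2 = 2.5`, `a1 = 0.7` (free/bound NADH literature
#'   priors).
#' @param photon_threshold Minimum total counts to attempt a fit
#'   (default 100).
#' @return A `biexp_fit`: list with `I0`, `A1`, `A2`, `tau1_ns`,
#'   `tau2_ns`, `background`, `chi2_reduced`, `n_photons`, `valid`,
#'   `converged`.
#' @export
fit_pixel_decay <- function(counts, bin_width_ns, init = NULL,
                            photon_threshold = 100) {
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total < photon_threshold) return(new_invalid_fit(total))
  peak <- which.max(counts)
  y <- counts[peak:length(counts)]
  if (length(y) < 8L) return(new_invalid_fit(total))
  t <- (seq_along(y) - 1) * bin_width_ns
  bg0 <- max(mean(utils::tail(y, max(3L, length(y) %/% 20L))), 0)
  model <- function(p)
    p[5] + p[1] * (p[2] * exp(-t / p[3]) + (1 - p[2]) * exp(-t / p[4]))
  lower <- c(0, 0, 0.05, 1.0, 0)
  upper <- c(Inf, 1, 1.0, 6.0, Inf)
  # several starting points guard against the valley between nearly
  # mono-exponential solutions and genuine two-component mixtures
  starts <- list(c(a1 = 0.7, tau1 = 0.4, tau2 = 2.5),
                 c(a1 = 0.3, tau1 = 0.3, tau2 = 1.5),
                 c(a1 = 0.9, tau1 = 0.6, tau2 = 3.5),
                 c(a1 = 0.05, tau1 = 0.2, tau2 = 1.2))
  if (!is.null(init))
    starts <- c(list(c(a1 = init$a1 %||% 0.7, tau1 = init$tau1 %||% 0.4,
                       tau2 = init$tau2 %||% 2.5)), starts)
  best <- NULL
  for (s in starts) {
    par0 <- c(I0 = max(y[1] - bg0, 1e-6), a1 = unname(s["a1"]),
              tau1 = unname(s["tau1"]), tau2 = unname(s["tau2"]),
              bg = bg0)
    w <- 1 / pmax(y, 1)
    res <- tryCatch(
      minpack.lm::nls.lm(
        par = par0, fn = function(p) (model(p) - y) * sqrt(w),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(res) || !(res$info %in% 1:4)) next
    # re-weight by the fitted model rather than the noisy data: data
    # weights systematically over-trust downward-fluctuated bins and
    # bias the amplitudes (Neyman chi-square bias)
    for (it in 1:2) {
      w <- 1 / pmax(model(res$par), 1)
      res2 <- tryCatch(
        minpack.lm::nls.lm(
          par = res$par, fn = function(p) (model(p) - y) * sqrt(w),
          lower = lower, upper = upper,
          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (is.null(res2) || !(res2$info %in% 1:4)) break
      res <- res2
    }
    ss <- sum(((model(res$par) - y)^2) / pmax(model(res$par), 1))
    if (is.null(best) || ss < best$ss) best <- list(res = res, ss = ss)
  }
  if (is.null(best)) return(new_invalid_fit(total))
  p <- best$res$par
  npar <- 5L
  chi2 <- best$ss / max(length(y) - npar, 1L)
  structure(
    list(I0 = unname(p[1]), A1 = unname(p[2]), A2 = unname(1 - p[2]),
         tau1_ns = unname(p[3]), tau2_ns = unname(p[4]),
         background = unname(p[5]),
         chi2_reduced = chi2, n_photons = total,
         valid = TRUE, converged = TRUE),
    class = "biexp_fit")
}

#' @export
print.biexp_fit <- function(x, ...) {
  if (!x$valid) {
    cat(sprintf("<biexp_fit> invalid (%.0f photons)\n", x$n_photons))
    return(invisible(x))
  }
  cat(sprintf(
    "<biexp_fit> A1 = %.3f tau1 = %.3f ns | A2 = %.3f tau2 = %.3f ns\n",
    x$A1, x$tau1_ns, x$A2, x$tau2_ns))
  cat(sprintf("  mean lifetime %.3f ns, A1/A2 = %.3f, reduced chi2 = %.3g\n",
              mean_lifetime(x), x$A1 / x$A2, x$chi2_reduced))
  invisible(x)
}

#' Mean fluorescence lifetime of a fit
#'
#' The default is the amplitude-weighted mean
#' `(A1 tau1 + A2 tau2) / (A1 + A2)` (the SPCImage convention);
#' `weighting = "intensity"` gives the intensity-weighted mean
#' `(A1 tau1^2 + A2 tau2^2) / (A1 tau1 + A2 tau2)`.
#'
#' @param fit A valid `biexp_fit`.
#' @param weighting `"amplitude"` (default) or `"intensity"`.
#' @return Mean lifetime in ns.
#' @export
mean_lifetime <- function(fit, weighting = c("amplitude", "intensity")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(fit, "biexp_fit"))
  if (!fit$valid) return(NA_real_)
  if (weighting == "amplitude") {
    (fit$A1 * fit$tau1_ns + fit$A2 * fit$tau2_ns) / (fit$A1 + fit$A2)
  } else {
    (fit$A1 * fit$tau1_ns^2 + fit$A2 * fit$tau2_ns^2) /
      (fit$A1 * fit$tau1_ns + fit$A2 * fit$tau2_ns)
  }
}

# 3x3 (or bin x bin) neighbourhood summation of histograms, the
# SPCImage-style spatial binning that trades resolution for photons.
spatial_bin_counts <- function(counts, bin) {
  if (bin <= 1L) return(counts)
  half <- (bin - 1L) %/% 2L
  d <- dim(counts)
  out <- array(0, d)
  for (dr in -half:half) {
    rs <- pmin(pmax(seq_len(d[1]) + dr, 1L), d[1])
    for (dc in -half:half) {
      cs <- pmin(pmax(seq_len(d[2]) + dc, 1L), d[2])
      out <- out + counts[rs, cs, , drop = FALSE]
    }
  }
  out
}

#' Fit a biexponential model at every pixel of a decay stack
#'
#' Optionally sums each pixel's histogram with its
#' `spatial_bin x spatial_bin` neighbourhood (default 3, edge pixels
#' replicate the border), then runs [fit_pixel_decay()] per pixel and
#' assembles lifetime maps. Pixels below the photon threshold or with
#' non-converged fits are marked invalid and carry `NA`.
#'
#' @param stack A [decay_stack].
#' @param photon_threshold Minimum (binned) photons per pixel.
#' @param spatial_bin Neighbourhood side for histogram summation
#'   (1 = none).
#' @param init Optional starting values, see [fit_pixel_decay()].
#' @return A `lifetime_maps`: list of matrices `mean_tau_ns`,
#'   `a1a2_ratio`, `a1`, `tau1_ns`, `tau2_ns`, `chi2_reduced`, logical
#'   `valid`, plus `pixel_size_um`.
#' @export
fit_stack <- function(stack, photon_threshold = 100, spatial_bin = 3,
                      init = NULL) {
  stopifnot(inherits(stack, "decay_stack"))
  counts <- spatial_bin_counts(stack$counts, as.integer(spatial_bin))
  d <- dim(counts)
  mk <- function() matrix(NA_real_, d[1], d[2])
  maps <- list(mean_tau_ns = mk(), a1a2_ratio = mk(), a1 = mk(),
               tau1_ns = mk(), tau2_ns = mk(), chi2_reduced = mk(),
               valid = matrix(FALSE, d[1], d[2]),
               pixel_size_um = stack$pixel_size_um)
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      fit <- fit_pixel_decay(counts[i, j, ], stack$bin_width_ns,
                             init = init,
                             photon_threshold = photon_threshold)
      if (!fit$valid) next
      maps$valid[i, j] <- TRUE
      maps$mean_tau_ns[i, j] <- mean_lifetime(fit)
      maps$a1a2_ratio[i, j] <- if (fit$A2 > 0) fit$A1 / fit$A2 else Inf
      maps$a1[i, j] <- fit$A1
      maps$tau1_ns[i, j] <- fit$tau1_ns
      maps$tau2_ns[i, j] <- fit$tau2_ns
      maps$chi2_reduced[i, j] <- fit$chi2_reduced
    }
  }
  structure(maps, class = "lifetime_maps")
}

#' @export
print.lifetime_maps <- function(x, ...) {
  nv <- sum(x$valid)
  cat(sprintf("<lifetime_maps> %d x %d px, %d valid (%.1f%%)\n",
              nrow(x$valid), ncol(x$valid), nv,
              100 * nv / length(x$valid)))
  if (nv) cat(sprintf("  mean tau %.3f ns, A1/A2 %.3f (map means)\n",
                      mean(x$mean_tau_ns[x$valid]),
                      mean(x$a1a2_ratio[x$valid])))
  invisible(x)
}

#' Normalize an intensity image by detector gain and laser power
#'
#' Divides the raw intensities by `g(pmt_gain) * laser_power^exponent`,
#' where `g` is a detector sensitivity curve measured against
#' fluorescein standards and interpolated log-linearly between
#' calibration points. The default power exponent of 2 reflects
#' two-photon excitation (signal scales with the square of the
#' excitation power); set it to 1 for one-photon data. Gains outside
#' the calibration table are an error - the curve is steep and
#' extrapolation is unsafe.
#'
#' @param image An [image_grid] of raw intensities.
#' @param pmt_gain Detector gain at acquisition.
#' @param laser_power_mW Laser power at acquisition (> 0).
#' @param gain_curve Data frame with columns `gain` and `sensitivity`
#'   (both positive, at least 2 rows).
#' @param power_exponent Power-law exponent (default 2).
#' @return An [image_grid] of normalized intensities.
#' @export
normalize_intensity <- function(image, pmt_gain, laser_power_mW,
                                gain_curve, power_exponent = 2) {
  stopifnot(is_image_grid(image))
  if (!all(c("gain", "sensitivity") %in% names(gain_curve)) ||
      nrow(gain_curve) < 2L)
    stop("`gain_curve` needs columns gain and sensitivity (>= 2 rows)")
  if (any(gain_curve$sensitivity <= 0))
    stop("sensitivities must be positive")
  if (laser_power_mW <= 0) stop("`laser_power_mW` must be positive")
  gc <- gain_curve[order(gain_curve$gain), ]
  if (pmt_gain < min(gc$gain) || pmt_gain > max(gc$gain))
    stop(sprintf(
      "gain %g is outside the calibration range [%g, %g]; no extrapolation",
      pmt_gain, min(gc$gain), max(gc$gain)))
  g <- 10^stats::approx(gc$gain, log10(gc$sensitivity), xout = pmt_gain)$y
  image_grid(image$values / (g * laser_power_mW^power_exponent),
             image$pixel_size_um, image$channel_name, "float")
}

#' Pixel-wise optical redox ratio map
#'
#' Computes `FAD / (FAD + NADH)` from co-registered, gain/power
#' normalized channel images - a label-free readout of cellular
#' metabolic state bounded in `[0, 1]`. Pixels whose total signal
#' `FAD + NADH` falls below `floor` (default: 1 percent of the summed
#' image's 99th percentile) are background and marked invalid (`NA` in
#' the ratio).
#'
#' @param nadh_norm,fad_norm [image_grid]s of equal shape.
#' @param floor Denominator floor; `NULL` for the default.
#' @return A `redox_map`: list with `ratio` (matrix, `NA` where
#'   invalid), `valid` (logical matrix), `nadh_norm`, `fad_norm`,
#'   `floor`, `pixel_size_um`.
#' @export
redox_map <- function(nadh_norm, fad_norm, floor = NULL) {
  stopifnot(is_image_grid(nadh_norm), is_image_grid(fad_norm))
  if (!all(dim(nadh_norm$values) == dim(fad_norm$values)))
    stop("NADH and FAD images must have the same shape")
  denom <- fad_norm$values + nadh_norm$values
  if (is.null(floor))
    floor <- 0.01 * stats::quantile(denom, 0.99, names = FALSE)
  valid <- denom >= floor & denom > 0
  ratio <- matrix(NA_real_, nrow(denom), ncol(denom))
  ratio[valid] <- fad_norm$values[valid] / denom[valid]
  structure(
    list(ratio = ratio, valid = valid,
         nadh_norm = nadh_norm, fad_norm = fad_norm,
         floor = floor, pixel_size_um = nadh_norm$pixel_size_um),
    class = "redox_map")
}

#' @export
print.redox_map <- function(x, ...) {
  nv <- sum(x$valid)
  cat(sprintf("<redox_map> %d x %d px, %d valid (%.1f%%)\n",
              nrow(x$ratio), ncol(x$ratio), nv, 100 * nv / length(x$valid)))
  if (nv) cat(sprintf("  mean redox ratio %.3f\n", mean(x$ratio[x$valid])))
  invisible(x)
}
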