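# Phantom generators with known ground truth. Every generator is a pure
# function of its arguments plus a seed, and returns a truth manifest
# alongside the data so downstream tests never re-derive truth from
# pixels.

radial_shape_fn <- function(profile_shape, radial_fn) {
  switch(profile_shape,
    core_high = function(r) 1 - r,
    edge_high = ,
    linear_ramp = function(r) r,
    flat = function(r) rep(1, length(r)),
    custom = {
      if (!is.function(radial_fn))
        stop("profile_shape = \"custom\" needs a `radial_fn`")
      radial_fn
    },
    stop(sprintf("unknown profile shape '%s'", profile_shape)))
}

#' Generate a single-spheroid phantom image
#'
#' Draws a disk of the requested diameter whose intensity follows a
#' chosen function of normalized radius - `core_high`
#' (`peak * (1 - r)`, brightest at the centre, like hypoxia or
#' apoptosis markers), `edge_high` / `linear_ramp` (`peak * r`, like
#' proliferation markers), `flat`, or a `custom` function - plus a
#' constant background and additive Gaussian noise (read-noise
#' dominated widefield model). The disk must fit inside the field with
#' enough margin to survive QC (padded crop box plus border margin).
#'
#' @param diameter_um Spheroid diameter in micrometres.
#' @param pixel_size_um Pixel size (default 1).
#' @param field_px Square field side in pixels (default 200).
#' @param profile_shape One of `"core_high"`, `"edge_high"`,
#'   `"linear_ramp"`, `"flat"`, `"custom"`.
#' @param peak_intensity Intensity amplitude above background.
#' @param background Background level.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed Integer seed; same spec + seed gives identical output.
#' @param center Optional `c(row, col)` of the disk centre; defaults to
#'   the field centre.
#' @param radial_fn Function of normalized radius in `[0, 1]` for
#'   `profile_shape = "custom"`.
#' @return List with `image` (an [image_grid]) and `truth` (list:
#'   `mask`, `centroid`, `radius_px`, `diameter_um`, `profile_shape`,
#'   and `radial_intensity`, the noise-free intensity as a function of
#'   normalized radius).
#' @export
make_spheroid_image <- function(diameter_um = 150, pixel_size_um = 1,
                                field_px = 200,
                                profile_shape = "core_high",
                                peak_intensity = 200, background = 10,
                                noise_sd = 2, seed = 1, center = NULL,
                                radial_fn = NULL) {
  stopifnot(diameter_um > 0, pixel_size_um > 0, field_px >= 16,
            noise_sd >= 0)
  r_px <- diameter_um / (2 * pixel_size_um)
  if (is.null(center)) center <- c(field_px, field_px) / 2 + 0.5
  # the padded square crop reaches 1.3 * r from the centre; leave 2 px
  # of breathing room beyond it on every side
  need <- 1.3 * r_px + 2
  if (center[1] - need < -0.5 || center[2] - need < -0.5 ||
      center[1] + need > field_px + 0.5 ||
      center[2] + need > field_px + 0.5)
    stop(sprintf(
      "a %g um spheroid does not fit a %d px field with QC margin",
      diameter_um, field_px))
  f <- radial_shape_fn(profile_shape, radial_fn)
  rows <- matrix(seq_len(field_px), field_px, field_px)
  cols <- t(rows)
  r_norm <- sqrt((rows - center[1])^2 + (cols - center[2])^2) / r_px
  inside <- r_norm <= 1
  values <- matrix(background, field_px, field_px)
  values[inside] <- background + peak_intensity * f(r_norm[inside])
  if (noise_sd > 0) {
    set.seed(seed)
    values <- values + matrix(stats::rnorm(field_px^2, sd = noise_sd),
                              field_px, field_px)
  }
  values <- pmax(values, 0)
  list(
    image = image_grid(values, pixel_size_um, "phantom", "float"),
    truth = list(mask = inside,
                 centroid = center,
                 radius_px = r_px,
                 diameter_um = diameter_um,
                 profile_shape = profile_shape,
                 radial_intensity = function(r) background +
                   peak_intensity * f(r)))
}

place_disk <- function(values, center, r_px, level) {
  field <- nrow(values)
  rows <- matrix(seq_len(field), field, field)
  cols <- t(rows)
  inside <- (rows - center[1])^2 + (cols - center[2])^2 <= r_px^2
  values[inside] <- level
  values
}

#' Generate a multi-spheroid QC test field
#'
#' Builds a field of flat-intensity disks according to a layout, each
#' disk carrying a truth status: `"ok"` (interior, isolated, croppable),
#' `"clipped"` (crosses the image border), or `"touching"` (the row
#' expands into a pair of disks separated by a 2-px boundary gap).
#' Overlapping `"ok"` disks are a layout error.
#'
#' @param layout Data frame with columns `row`, `col`, `diameter_um`,
#'   `status`.
#' @param field_px Field side in pixels.
#' @param pixel_size_um Pixel size.
#' @param peak_intensity,background,noise_sd Intensity model as in
#'   [make_spheroid_image()].
#' @param seed Integer seed.
#' @return List with `image` (an [image_grid]) and `truth`, a data
#'   frame with one row per generated disk: `disk_id`, `row`, `col`,
#'   `radius_px`, `status`, `expected_accept`.
#' @export
make_qc_field <- function(layout, field_px = 200, pixel_size_um = 2,
                          peak_intensity = 200, background = 10,
                          noise_sd = 2, seed = 1) {
  need <- c("row", "col", "diameter_um", "status")
  if (nrow(layout) > 0 && !all(need %in% names(layout)))
    stop("`layout` needs columns row, col, diameter_um, status")
  disks <- data.frame(row = numeric(0), col = numeric(0),
                      radius_px = numeric(0), status = character(0))
  for (i in seq_len(nrow(layout))) {
    r_px <- layout$diameter_um[i] / (2 * pixel_size_um)
    st <- layout$status[i]
    disks <- rbind(disks, data.frame(row = layout$row[i],
                                     col = layout$col[i],
                                     radius_px = r_px, status = st))
    if (st == "touching") {
      # partner disk 2 px beyond tangency along +col
      disks <- rbind(disks,
                     data.frame(row = layout$row[i],
                                col = layout$col[i] + 2 * r_px + 2,
                                radius_px = r_px, status = "touching"))
    }
  }
  # ok disks must not overlap anything
  ok_idx <- which(disks$status == "ok")
  for (i in ok_idx) {
    for (j in seq_len(nrow(disks))) {
      if (i == j) next
      d <- sqrt((disks$row[i] - disks$row[j])^2 +
                (disks$col[i] - disks$col[j])^2)
      if (d < disks$radius_px[i] + disks$radius_px[j])
        stop("layout error: an 'ok' spheroid overlaps another spheroid")
    }
  }
  values <- matrix(background, field_px, field_px)
  for (i in seq_len(nrow(disks)))
    values <- place_disk(values, c(disks$row[i], disks$col[i]),
                         disks$radius_px[i], background + peak_intensity)
  if (noise_sd > 0) {
    set.seed(seed)
    values <- values + matrix(stats::rnorm(field_px^2, sd = noise_sd),
                              field_px, field_px)
  }
  values <- pmax(values, 0)
  truth <- data.frame(disk_id = seq_len(nrow(disks)),
                      row = disks$row, col = disks$col,
                      radius_px = disks$radius_px,
                      status = disks$status,
                      expected_accept = disks$status == "ok")
  list(image = image_grid(values, pixel_size_um, "qc_field", "float"),
       truth = truth)
}

#' Random QC field layout
#'
#' Draws a layout for [make_qc_field()]: 1-3 isolated croppable
#' spheroids, plus optionally one border-clipped spheroid and one
#' touching pair. Diameters follow a lognormal spread (median 150 um,
#' log-sd 0.3) clamped so every disk fits the field, echoing the size
#' dispersion of a real spheroid harvest.
#'
#' @param seed Integer seed.
#' @param field_px Field side in pixels.
#' @param pixel_size_um Pixel size.
#' @return Layout data frame for [make_qc_field()].
#' @export
random_qc_layout <- function(seed, field_px = 200, pixel_size_um = 2) {
  set.seed(seed)
  draw_d <- function(n, dmax)
    pmin(pmax(stats::rlnorm(n, log(150), 0.3), 60), dmax)
  placed <- data.frame(row = numeric(0), col = numeric(0),
                       r = numeric(0))
  can_place <- function(row, col, r, clearance = 10) {
    if (!nrow(placed)) return(TRUE)
    d <- sqrt((placed$row - row)^2 + (placed$col - col)^2)
    all(d > placed$r + r + clearance)
  }
  layout <- data.frame(row = numeric(0), col = numeric(0),
                       diameter_um = numeric(0), status = character(0))
  add <- function(row, col, d_um, status, extra_r = 0) {
    layout <<- rbind(layout, data.frame(row = row, col = col,
                                        diameter_um = d_um,
                                        status = status))
    placed <<- rbind(placed, data.frame(row = row, col = col,
                                        r = d_um / (2 * pixel_size_um) +
                                          extra_r))
  }
  n_ok <- sample(1:3, 1)
  for (i in seq_len(n_ok)) {
    d_um <- draw_d(1, 0.55 * field_px * pixel_size_um)
    r <- d_um / (2 * pixel_size_um)
    m <- ceiling(0.3 * r) + 5
    for (try in 1:200) {
      row <- stats::runif(1, r + m, field_px - r - m)
      col <- stats::runif(1, r + m, field_px - r - m)
      if (can_place(row, col, r)) { add(row, col, d_um, "ok"); break }
    }
  }
  if (sample(c(TRUE, FALSE), 1)) {   # one clipped spheroid
    d_um <- draw_d(1, 0.4 * field_px * pixel_size_um)
    r <- d_um / (2 * pixel_size_um)
    for (try in 1:200) {
      row <- r - 3                      # crosses the top border
      col <- stats::runif(1, r + 5, field_px - r - 5)
      if (can_place(row, col, r)) { add(row, col, d_um, "clipped"); break }
    }
  }
  if (sample(c(TRUE, FALSE), 1)) {   # one touching pair
    d_um <- draw_d(1, 0.35 * field_px * pixel_size_um)
    r <- d_um / (2 * pixel_size_um)
    m <- r + 8
    for (try in 1:200) {
      row <- stats::runif(1, m, field_px - m)
      col <- stats::runif(1, m, field_px - (3 * r + m + 2))
      if (can_place(row, col, r, clearance = 14) &&
          can_place(row, col + 2 * r + 2, r, clearance = 14)) {
        add(row, col, d_um, "touching", extra_r = 2 * r + 2)
        break
      }
    }
  }
  layout
}

#' Expected (noise-free) biexponential decay histogram
#'
#' The biexponential model evaluated on the TCSPC time axis
#' (`t_i = i * bin_width`) and scaled so the bins sum to `photons`.
#'
#' @param A1,A2 Component amplitudes.
#' @param tau1_ns,tau2_ns Lifetimes in ns.
#' @param photons Total expected photon count.
#' @param nbins Number of time bins (default 256).
#' @param window_ns Measurement window in ns (default 12.5).
#' @return Numeric vector of expected counts per bin.
#' @export
expected_decay_curve <- function(A1, tau1_ns, A2, tau2_ns,
                                 photons = 5000, nbins = 256,
                                 window_ns = 12.5) {
  t <- (seq_len(nbins) - 1) * window_ns / nbins
  curve <- biexp_model(t, 1, A1, tau1_ns, A2, tau2_ns)
  photons * curve / sum(curve)
}

#' Generate a Poisson TCSPC decay-stack phantom
#'
#' Every pixel's histogram is an independent Poisson sample of the
#' expected biexponential curve (photon counting is Poisson by
#' physics). With `two_region`, a central disk and the surrounding
#' annulus carry different truth parameters, mimicking a core/edge
#' metabolic contrast.
#'
#' @param A1,A2,tau1_ns,tau2_ns Truth parameters (defaults: free/bound
#'   NADH-like, A1 = 0.8, tau1 = 0.4 ns, A2 = 0.2, tau2 = 2.5 ns).
#' @param photons_per_pixel Expected photons per pixel (0 gives an
#'   all-zero stack).
#' @param nbins,window_ns Histogram geometry (256 bins over 12.5 ns).
#' @param shape `c(rows, cols)` of the stack.
#' @param two_region Optional list with elements `inner` and `outer`
#'   (each a list of A1, tau1_ns, A2, tau2_ns) and `radius_frac`
#'   (default 0.5): pixels within `radius_frac * min(shape)/2` of the
#'   centre use `inner`, the rest `outer`.
#' @param pixel_size_um Pixel size.
#' @param seed Integer seed.
#' @return List with `stack` (a [decay_stack]) and `truth` (list:
#'   `params` per region, `region_map` matrix of 1 = inner, 2 = outer,
#'   `expected_curves`).
#' @export
make_decay_stack <- function(A1 = 0.8, tau1_ns = 0.4, A2 = 0.2,
                             tau2_ns = 2.5, photons_per_pixel = 5000,
                             nbins = 256, window_ns = 12.5,
                             shape = c(16, 16), two_region = NULL,
                             pixel_size_um = 1, seed = 1) {
  stopifnot(photons_per_pixel >= 0, nbins >= 8, window_ns > 0)
  params <- list(list(A1 = A1, tau1_ns = tau1_ns, A2 = A2,
                      tau2_ns = tau2_ns))
  region_map <- matrix(1L, shape[1], shape[2])
  if (!is.null(two_region)) {
    rf <- if (is.null(two_region$radius_frac)) 0.5 else two_region$radius_frac
    params <- list(two_region$inner, two_region$outer)
    ctr <- (shape + 1) / 2
    rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
    cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
    inner <- sqrt((rows - ctr[1])^2 + (cols - ctr[2])^2) <=
      rf * min(shape) / 2
    region_map[!inner] <- 2L
  }
  curves <- lapply(params, function(p)
    expected_decay_curve(p$A1, p$tau1_ns, p$A2, p$tau2_ns,
                         photons_per_pixel, nbins, window_ns))
  counts <- array(0, c(shape[1], shape[2], nbins))
  set.seed(seed)
  if (photons_per_pixel > 0) {
    for (i in seq_len(shape[1]))
      for (j in seq_len(shape[2]))
        counts[i, j, ] <- stats::rpois(nbins, curves[[region_map[i, j]]])
  }
  list(stack = decay_stack(counts, window_ns / nbins, pixel_size_um),
       truth = list(params = params, region_map = region_map,
                    expected_curves = curves))
}

#' Microregion effect sizes for macrophage markers
#'
#' Per-region means and standard deviations of normalized CD80 (M1
#' macrophage) and CD206 (M2 macrophage) intensities in small
#' (0-200 um) and large (201-400 um) spheroids, used as generator
#' inputs for cohort simulations: CD80 rises from core to proliferative
#' edge in both size classes, while CD206 is core-high in small and
#' quiescent-peaked in large spheroids.
#'
#' @return Data frame with columns `marker`, `size_class`, `region`,
#'   `mean`, `sd`.
#' @export
macrophage_marker_effects <- function() {
  data.frame(
    marker = rep(c("CD80", "CD206"), each = 6),
    size_class = rep(rep(c("small", "large"), each = 3), 2),
    region = rep(c("core", "quiescent", "edge"), 4),
    mean = c(0.189, 0.364, 0.767,  0.212, 0.494, 0.801,
             0.826, 0.874, 0.521,  0.420, 0.786, 0.620),
    sd   = c(0.212, 0.214, 0.089,  0.123, 0.151, 0.184,
             0.156, 0.085, 0.123,  0.266, 0.139, 0.208),
    stringsAsFactors = FALSE)
}

#' Simulate a cohort of per-region marker values
#'
#' Draws normalized regional marker values from normal distributions
#' with the requested per-(marker, size class, region) means and
#' standard deviations, and spheroid diameters uniformly within each
#' size class's bounds (small: 50-200 um, large: 201-400 um). Output
#' feeds [compare_regions()] and [diameter_correlation()] directly.
#'
#' @param n_small,n_large Spheroids per size class (>= 2).
#' @param marker_effects Effects table as from
#'   [macrophage_marker_effects()].
#' @param seed Integer seed.
#' @return List with `data` (long data frame: `spheroid_id`,
#'   `size_class`, `diameter_um`, `marker`, `region`, `value`) and
#'   `truth` (the effects table).
#' @export
make_cohort <- function(n_small = 30, n_large = 30,
                        marker_effects = macrophage_marker_effects(),
                        seed = 1) {
  stopifnot(n_small >= 2, n_large >= 2)
  set.seed(seed)
  sph <- data.frame(
    spheroid_id = sprintf("sph%03d", seq_len(n_small + n_large)),
    size_class = rep(c("small", "large"), c(n_small, n_large)),
    diameter_um = c(stats::runif(n_small, 50, 200),
                    stats::runif(n_large, 201, 400)),
    stringsAsFactors = FALSE)
  out <- list()
  for (m in unique(marker_effects$marker)) {
    for (reg in c("core", "quiescent", "edge")) {
      eff <- marker_effects[marker_effects$marker == m &
                            marker_effects$region == reg, ]
      mu <- stats::setNames(eff$mean, eff$size_class)
      sdv <- stats::setNames(eff$sd, eff$size_class)
      out[[length(out) + 1L]] <- data.frame(
        spheroid_id = sph$spheroid_id,
        size_class = sph$size_class,
        diameter_um = sph$diameter_um,
        marker = m, region = reg,
        value = stats::rnorm(nrow(sph),
                             mu[sph$size_class], sdv[sph$size_class]),
        stringsAsFactors = FALSE)
    }
  }
  list(data = do.call(rbind, out), truth = marker_effects)
}
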