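#' Segment a single-spheroid crop
#'
#' Otsu threshold, hole filling, largest 8-connected component, then one
#' 3x3 binary closing. Intended for crops containing exactly one
#' spheroid on a darker background.
#'
#' @param image An [image_grid] crop.
#' @return Logical matrix (the binary mask).
#' @export
segment_mask <- function(image) {
  stopifnot(is_image_grid(image))
  fg <- otsu_foreground(image$values)
  if (!any(fg))
    stop("segmentation failed: no foreground found in channel \"",
         image$channel_name, "\"")
  fg <- fill_holes(fg)
  lab <- label_components8(fg)
  sizes <- tabulate(lab[lab > 0L])
  mask <- lab == which.max(sizes)
  kern <- EBImage::makeBrush(3, "box")
  mask <- EBImage::closing(EBImage::Image(mask * 1), kern)
  matrix(as.numeric(mask) > 0.5, nrow(fg), ncol(fg))
}

#' Centroid of a binary mask
#'
#' Unweighted mean of the foreground pixel coordinates, at sub-pixel
#' precision. For non-convex masks the mean can fall outside the
#' foreground; the result then carries attribute `inside = FALSE` and
#' should be rejected by callers, since a radial profile anchored
#' outside the spheroid is meaningless.
#'
#' @param mask Logical matrix.
#' @return Numeric `c(row, col)` (1-based) with attribute `inside`.
#' @export
compute_centroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("cannot compute the centroid of an empty mask")
  ctr <- c(row = mean(idx[, 1]), col = mean(idx[, 2]))
  nearest <- pmin(pmax(round(ctr), 1), dim(mask))
  attr(ctr, "inside") <- mask[nearest[1], nearest[2]]
  ctr
}

#' Diameter and circularity of a mask
#'
#' The diameter is the equivalent-circle diameter
#' `2 * pixel_size_um * sqrt(area / pi)`; circularity is
#' `4 pi A / P^2` with `P` the outer-contour perimeter (see
#' `mask_perimeter`), clipped to `[0, 1]`.
#'
#' @param mask Logical matrix (non-empty).
#' @param pixel_size_um Pixel size in micrometres.
#' @return List with `diameter_um` and `circularity`.
#' @export
measure_geometry <- function(mask, pixel_size_um) {
  area <- sum(mask)
  if (area == 0L) stop("cannot measure an empty mask")
  per <- mask_perimeter(mask)
  circ <- if (per > 0) 4 * pi * area / per^2 else 1
  list(diameter_um = 2 * pixel_size_um * sqrt(area / pi),
       circularity = min(max(circ, 0), 1))
}

#' Cast radial intensity profiles from the centroid
#'
#' Casts `K` rays from the centroid at angles `2 pi k / K`
#' (k = 0..K-1; angle 0 points along the +column axis and angles turn
#' counterclockwise). Each ray is marched outward in 0.25-px steps and
#' ends at its own mask-boundary crossing - the first sample whose
#' nearest pixel is background (or outside the image). `M` sample points
#' are placed equally spaced over `[0, 1]` of each ray's length, and
#' intensities are read by bilinear interpolation, so the shared
#' `normalized_distance` axis runs from the centroid (0) to the boundary
#' (1) for every ray regardless of its physical length.
#'
#' @param image An [image_grid].
#' @param mask Logical matrix, same shape; the centroid must be inside.
#' @param centroid Numeric `c(row, col)`; defaults to
#'   [compute_centroid()] of the mask.
#' @param K Number of rays (>= 3; default 20).
#' @param M Samples per ray (>= 8; default 80).
#' @param angle_offset Angle of the first ray in radians (default 0).
#' @return A `radial_profile_set`: list with `profiles` (K x M),
#'   `normalized_distance` (length M), `mean_profile`,
#'   `normalized_profile`, `ray_length_px` (length K), `K`, `M`,
#'   `angles`, and `pixel_size_um`.
#' @export
cast_profiles <- function(image, mask, centroid = compute_centroid(mask),
                          K = 20, M = 80, angle_offset = 0) {
  stopifnot(is_image_grid(image), is.logical(mask),
            all(dim(mask) == dim(image$values)))
  if (K < 3) stop("`K` must be at least 3")
  if (M < 8) stop("`M` must be at least 8")
  nr <- nrow(mask); nc <- ncol(mask)
  ctr <- as.numeric(centroid)
  nearest <- pmin(pmax(round(ctr), 1), dim(mask))
  if (!mask[nearest[1], nearest[2]])
    stop("centroid does not lie inside the mask")
  angles <- angle_offset + 2 * pi * (seq_len(K) - 1) / K
  step <- 0.25
  ray_len <- numeric(K)
  profiles <- matrix(NA_real_, K, M)
  u <- seq(0, 1, length.out = M)
  max_len <- sqrt(nr^2 + nc^2)
  for (k in seq_len(K)) {
    # +col axis at angle 0, counterclockwise on screen (rows point down)
    dc <- cos(angles[k]); dr <- -sin(angles[k])
    s <- step
    repeat {
      r <- ctr[1] + s * dr; c <- ctr[2] + s * dc
      ri <- round(r); ci <- round(c)
      outside <- ri < 1 || ri > nr || ci < 1 || ci > nc
      if (outside || !mask[ri, ci]) break
      s <- s + step
      if (s > max_len) break
    }
    if (s <= step)
      stop("ray of zero length: centroid lies on the mask boundary")
    # the crossing is the first sample whose nearest pixel is
    # background; bisect between the last inside and first outside
    # march samples to locate the flip point at sub-step precision
    lo <- s - step; hi <- min(s, max_len)
    for (it in 1:6) {
      mid <- (lo + hi) / 2
      ri <- round(ctr[1] + mid * dr); ci <- round(ctr[2] + mid * dc)
      inside <- ri >= 1 && ri <= nr && ci >= 1 && ci <= nc && mask[ri, ci]
      if (inside) lo <- mid else hi <- mid
    }
    len <- lo
    ray_len[k] <- len
    profiles[k, ] <- bilinear_sample(image$values,
                                     ctr[1] + u * len * dr,
                                     ctr[2] + u * len * dc,
                                     mask = mask)
  }
  mp <- mean_profile(profiles)
  np <- normalize_profile(mp)
  structure(
    list(profiles = profiles,
         normalized_distance = u,
         mean_profile = mp,
         normalized_profile = np,
         ray_length_px = ray_len,
         K = as.integer(K), M = as.integer(M),
         angles = angles,
         pixel_size_um = image$pixel_size_um),
    class = "radial_profile_set")
}

#' @export
print.radial_profile_set <- function(x, ...) {
  cat(sprintf(
    "<radial_profile_set> %d rays x %d points, ray length %.1f-%.1f px\n",
    x$K, x$M, min(x$ray_length_px), max(x$ray_length_px)))
  if (isTRUE(attr(x$normalized_profile, "degenerate")))
    cat("  profile is constant (degenerate after normalization)\n")
  invisible(x)
}

#' Mean radial profile
#'
#' Column-wise arithmetic mean of a K x M profile matrix.
#'
#' @param profiles Numeric matrix, rays in rows.
#' @return Numeric vector of length `ncol(profiles)`.
#' @export
mean_profile <- function(profiles) {
  stopifnot(is.matrix(profiles), nrow(profiles) >= 1)
  colMeans(profiles)
}

#' Min-max normalize a mean profile
#'
#' Rescales a profile to `[0, 1]`:
#' `(x - min(x)) / (max(x) - min(x))`. A constant profile has no
#' min-max range; it maps to all zeros and the result carries attribute
#' `degenerate = TRUE` so downstream statistics can exclude it
#' deterministically.
#'
#' @param mean_profile Numeric vector (length >= 2, all finite).
#' @return Numeric vector in `[0, 1]` with attribute `degenerate`.
#' @export
normalize_profile <- function(mean_profile) {
  if (length(mean_profile) < 2L)
    stop("a profile needs at least 2 points")
  if (any(!is.finite(mean_profile)))
    stop("profile contains non-finite values")
  lo <- min(mean_profile); hi <- max(mean_profile)
  # ranges at floating-point noise level are constant in substance
  if (hi - lo <= 1e-12 * max(abs(hi), abs(lo), 1)) {
    out <- rep(0, length(mean_profile))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- (mean_profile - lo) / (hi - lo)
  attr(out, "degenerate") <- FALSE
  out
}

#' Is a normalized profile degenerate?
#'
#' @param profile Result of [normalize_profile()].
#' @return Logical.
#' @export
is_degenerate_profile <- function(profile) {
  isTRUE(attr(profile, "degenerate"))
}

#' Profile a single-spheroid crop end to end
#'
#' Convenience wrapper: segment, locate the centroid, measure geometry,
#' cast profiles, and classify the spheroid's size. Records whose
#' centroid falls outside the mask are rejected with an error.
#'
#' @param image An [image_grid] containing one spheroid.
#' @param K,M Profile resolution (defaults 20 rays x 80 points).
#' @param angle_offset First-ray angle in radians.
#' @return A `spheroid_record`: list with `image`, `mask`, `centroid`,
#'   `diameter_um`, `circularity`, `size_class`, and `profile_set`.
#' @export
profile_spheroid <- function(image, K = 20, M = 80, angle_offset = 0) {
  mask <- segment_mask(image)
  ctr <- compute_centroid(mask)
  if (!isTRUE(attr(ctr, "inside")))
    stop("record rejected: centroid falls outside the (non-convex) mask")
  geom <- measure_geometry(mask, image$pixel_size_um)
  ps <- cast_profiles(image, mask, ctr, K = K, M = M,
                      angle_offset = angle_offset)
  structure(
    list(image = image, mask = mask, centroid = ctr,
         diameter_um = geom$diameter_um,
         circularity = geom$circularity,
         size_class = classify_size(geom$diameter_um),
         profile_set = ps),
    class = "spheroid_record")
}

#' @export
print.spheroid_record <- function(x, ...) {
  cat(sprintf(
    "<spheroid_record> diameter %.1f um (%s), circularity %.3f\n",
    x$diameter_um, x$size_class, x$circularity))
  invisible(x)
}
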