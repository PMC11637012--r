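#' Quality-control configuration
#'
#' Numeric proxies for the visual triage of spheroid fields of view:
#' Otsu foreground detection, a border-margin test for "in full view", a
#' minimum inter-spheroid distance test for "touching", and a
#' padded-crop-fits plus circularity test for "croppable".
#'
#' @param min_area_px Smallest component kept as a candidate, in pixels.
#' @param border_margin_px A spheroid any of whose pixels lies within
#'   this many pixels of an image edge is rejected as clipped.
#' @param gap_px Minimum pixel-to-pixel distance at or below which two
#'   spheroids count as touching.
#' @param pad_fraction Padding added around the bounding box when
#'   cropping, as a fraction of the box side.
#' @param min_circularity Candidates below this circularity are rejected
#'   as fused or irregular blobs that would defeat centroid-based
#'   profiling.
#' @return A named list of class `qc_config`.
#' @export
qc_config <- function(min_area_px = 200, border_margin_px = 2,
                      gap_px = 3, pad_fraction = 0.15,
                      min_circularity = 0.4) {
  stopifnot(min_area_px >= 1, border_margin_px >= 0, gap_px >= 0,
            pad_fraction >= 0, min_circularity >= 0)
  structure(list(min_area_px = min_area_px,
                 border_margin_px = border_margin_px,
                 gap_px = gap_px,
                 pad_fraction = pad_fraction,
                 min_circularity = min_circularity),
            class = "qc_config")
}

new_candidate_region <- function(label, pixels) {
  structure(
    list(label = as.integer(label),
         pixels = pixels,  # n x 2 matrix of (row, col), 1-based
         bounding_box = c(row_min = min(pixels[, 1]),
                          row_max = max(pixels[, 1]),
                          col_min = min(pixels[, 2]),
                          col_max = max(pixels[, 2])),
         area_px = nrow(pixels)),
    class = "candidate_region")
}

#' Detect candidate spheroids in a field of view
#'
#' Foreground is the Otsu threshold of the grayscale image with holes
#' filled; candidates are its 8-connected components, largest first.
#' Components smaller than `min_area_px` are dropped and reported in the
#' `"too_small"` attribute of the result so QC accounting can log them.
#'
#' @param image An [image_grid] (single channel).
#' @param min_area_px Minimum component area in pixels.
#' @return List of `candidate_region` objects sorted by descending area,
#'   with attribute `too_small` holding the dropped regions.
#' @export
detect_candidates <- function(image, min_area_px = 200) {
  stopifnot(is_image_grid(image))
  fg <- otsu_foreground(image$values)
  if (!any(fg)) {
    out <- list()
    attr(out, "too_small") <- list()
    return(out)
  }
  fg <- fill_holes(fg)
  lab <- label_components8(fg)
  idx <- which(lab > 0L, arr.ind = TRUE)
  split_px <- split.data.frame(idx, lab[lab > 0L])
  regions <- lapply(split_px, as.matrix)
  regions <- regions[order(-vapply(regions, nrow, integer(1)))]
  regions <- mapply(new_candidate_region, seq_along(regions), regions,
                    SIMPLIFY = FALSE)
  small <- vapply(regions, function(r) r$area_px < min_area_px, logical(1))
  out <- regions[!small]
  attr(out, "too_small") <- regions[small]
  out
}

#' Is a candidate spheroid in full view?
#'
#' TRUE iff no pixel of the region lies within `border_margin_px` pixels
#' of any image edge (a pixel on the edge itself is at distance 0).
#'
#' @param region A `candidate_region`.
#' @param image_shape Integer vector `c(rows, cols)`.
#' @param border_margin_px Margin in pixels.
#' @return Logical.
#' @export
qc_full_view <- function(region, image_shape, border_margin_px = 2) {
  bb <- region$bounding_box
  # distance of a pixel to the nearest edge, in pixels (0 = on the edge)
  dmin <- min(bb["row_min"] - 1L, bb["col_min"] - 1L,
              image_shape[1] - bb["row_max"], image_shape[2] - bb["col_max"])
  dmin > border_margin_px
}

#' Is a candidate touching another spheroid?
#'
#' TRUE (reject) iff the minimum Euclidean pixel-to-pixel distance
#' between `region` and any region in `others` is at most `gap_px`.
#' Distances are evaluated on boundary pixels, where the set-to-set
#' minimum is attained.
#'
#' @param region A `candidate_region`.
#' @param others List of other `candidate_region`s (disjoint from
#'   `region`).
#' @param gap_px Distance threshold in pixels.
#' @return Logical.
#' @export
qc_touching <- function(region, others, gap_px = 3) {
  if (!length(others)) return(FALSE)
  a <- region_boundary(region)
  for (other in others) {
    b <- region_boundary(other)
    d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
    if (min(d2) <= gap_px^2) return(TRUE)
  }
  FALSE
}

region_boundary <- function(region) {
  bb <- region$bounding_box
  nr <- bb["row_max"] - bb["row_min"] + 1L
  nc <- bb["col_max"] - bb["col_min"] + 1L
  m <- matrix(FALSE, nr, nc)
  m[cbind(region$pixels[, 1] - bb["row_min"] + 1L,
          region$pixels[, 2] - bb["col_min"] + 1L)] <- TRUE
  b <- mask_boundary_pixels(m)
  cbind(b[, 1] + bb["row_min"] - 1L, b[, 2] + bb["col_min"] - 1L)
}

region_mask <- function(region) {
  bb <- region$bounding_box
  m <- matrix(FALSE,
              bb["row_max"] - bb["row_min"] + 1L,
              bb["col_max"] - bb["col_min"] + 1L)
  m[cbind(region$pixels[, 1] - bb["row_min"] + 1L,
          region$pixels[, 2] - bb["col_min"] + 1L)] <- TRUE
  m
}

# Square crop box used both by the croppability test and by run_qc:
# side = max(bounding box sides) * (1 + 2 * pad_fraction), centered on
# the bounding box center. Returns c(row_min, row_max, col_min, col_max).
crop_box <- function(region, pad_fraction) {
  bb <- region$bounding_box
  h <- bb["row_max"] - bb["row_min"] + 1L
  w <- bb["col_max"] - bb["col_min"] + 1L
  side <- ceiling(max(h, w) * (1 + 2 * pad_fraction))
  cr <- (bb["row_min"] + bb["row_max"]) / 2
  cc <- (bb["col_min"] + bb["col_max"]) / 2
  r0 <- floor(cr - side / 2) + 1L
  c0 <- floor(cc - side / 2) + 1L
  unname(c(r0, r0 + side - 1L, c0, c0 + side - 1L))
}

#' Can a candidate be cropped for profiling?
#'
#' TRUE iff the padded square crop box fits inside the image and the
#' region's circularity (4 pi A / P^2) reaches `min_circularity`. The
#' circularity test rejects fused or highly irregular blobs, for which a
#' centroid-anchored radial profile is meaningless.
#'
#' @param region A `candidate_region` that passed the full-view check.
#' @param image_shape Integer vector `c(rows, cols)`.
#' @param pad_fraction Padding fraction per side.
#' @param min_circularity Circularity floor (default 0.4).
#' @return Logical.
#' @export
qc_croppable <- function(region, image_shape, pad_fraction = 0.15,
                         min_circularity = 0.4) {
  box <- crop_box(region, pad_fraction)
  if (box[1] < 1 || box[3] < 1 ||
      box[2] > image_shape[1] || box[4] > image_shape[2]) return(FALSE)
  m <- region_mask(region)
  geom <- measure_geometry(m, pixel_size_um = 1)
  geom$circularity >= min_circularity
}

#' Run the full pre-processing flowchart on a field of view
#'
#' Applies detection, full-view, touching and croppability checks in
#' that order. Every detected component is accounted for exactly once:
#' either accepted with a square crop, or rejected with its first
#' failing reason (`too_small`, `not_full_view`, `touching`,
#' `not_croppable`).
#'
#' @param image An [image_grid] field of view.
#' @param config A [qc_config()].
#' @return List with `crops` (a list of `list(image, region, label)`,
#'   each crop a square [image_grid]) and `report` (a `qc_report` with
#'   `n_detected`, `n_accepted` and a `rejections` data frame).
#' @export
run_qc <- function(image, config = qc_config()) {
  stopifnot(is_image_grid(image), inherits(config, "qc_config"))
  shape <- dim(image$values)
  cand <- detect_candidates(image, config$min_area_px)
  small <- attr(cand, "too_small")
  rejections <- data.frame(label = integer(0), reason = character(0))
  for (r in small)
    rejections <- rbind(rejections,
                        data.frame(label = r$label, reason = "too_small"))
  crops <- list()
  for (i in seq_along(cand)) {
    region <- cand[[i]]
    reason <- NULL
    if (!qc_full_view(region, shape, config$border_margin_px)) {
      reason <- "not_full_view"
    } else if (qc_touching(region, cand[-i], config$gap_px)) {
      reason <- "touching"
    } else if (!qc_croppable(region, shape, config$pad_fraction,
                             config$min_circularity)) {
      reason <- "not_croppable"
    }
    if (is.null(reason)) {
      box <- crop_box(region, config$pad_fraction)
      crop <- image_grid(image$values[box[1]:box[2], box[3]:box[4]],
                         image$pixel_size_um, image$channel_name,
                         image$bit_depth)
      crops[[length(crops) + 1L]] <-
        list(image = crop, region = region, label = region$label)
    } else {
      rejections <- rbind(rejections,
                          data.frame(label = region$label, reason = reason))
    }
  }
  n_detected <- length(cand) + length(small)
  report <- structure(
    list(n_detected = n_detected,
         n_accepted = length(crops),
         rejections = rejections),
    class = "qc_report")
  stopifnot(report$n_accepted + nrow(report$rejections) == n_detected)
  list(crops = crops, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d detected, %d accepted, %d rejected\n",
              x$n_detected, x$n_accepted, nrow(x$rejections)))
  if (nrow(x$rejections)) {
    tab <- table(x$rejections$reason)
    for (nm in names(tab)) cat(sprintf("  %s: %d\n", nm, tab[[nm]]))
  }
  invisible(x)
}
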