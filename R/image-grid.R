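#' Image grid container
#'
#' A single-channel raster of non-negative intensities with isotropic
#' pixel-size metadata. `image_grid` is the unit every image operation in
#' the package consumes and returns.
#'
#' @param values Numeric matrix (rows x cols) of finite, non-negative
#'   intensities.
#' @param pixel_size_um Physical size of one pixel in micrometres (> 0).
#' @param channel_name Optional text label, e.g. `"CD80"` or `"NADH"`.
#' @param bit_depth Storage depth: 8, 16, or `"float"`.
#' @return An object of class `image_grid`.
#' @examples
#' img <- image_grid(matrix(1:12, 3, 4), pixel_size_um = 1.24)
#' dim(img$values)
#' @export
image_grid <- function(values, pixel_size_um, channel_name = "",
                       bit_depth = 16) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("image must have at least one row and one column")
  if (any(!is.finite(values)))
    stop("image values must all be finite")
  if (any(values < 0))
    stop("image values must be non-negative")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number")
  if (!(identical(bit_depth, 8) || identical(bit_depth, 16) ||
        identical(bit_depth, 8L) || identical(bit_depth, 16L) ||
        identical(bit_depth, "float")))
    stop("`bit_depth` must be 8, 16 or \"float\"")
  structure(
    list(values = unname(values),
         pixel_size_um = as.numeric(pixel_size_um),
         channel_name = as.character(channel_name),
         bit_depth = bit_depth),
    class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid> %d x %d px, %.4g um/px, channel \"%s\", %s-bit\n",
              nrow(x$values), ncol(x$values), x$pixel_size_um,
              x$channel_name, as.character(x$bit_depth)))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.matrix.image_grid <- function(x, ...) x$values

is_image_grid <- function(x) inherits(x, "image_grid")

#' Read a TIFF image
#'
#' Reads an 8-, 16- or 32-bit float TIFF. A multi-channel image (samples
#' per pixel > 1) is returned as a list of single-channel [image_grid]
#' objects in file channel order; a single-channel image is returned as
#' one `image_grid`.
#'
#' @param path Path to a TIFF file.
#' @param pixel_size_um Pixel size in micrometres (> 0); TIFF files carry
#'   no reliable physical calibration, so it must be supplied.
#' @param channel_name Optional channel label (single-channel input) or
#'   character vector recycled across channels.
#' @return An `image_grid`, or a list of them for multi-channel input.
#' @seealso [write_image()], [to_grayscale()]
#' @export
read_image <- function(path, pixel_size_um, channel_name = "") {
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number")
  if (!file.exists(path))
    stop(sprintf("cannot read image: file '%s' does not exist", path))
  raw <- tryCatch(
    tiff::readTIFF(path, as.is = TRUE, info = TRUE),
    error = function(e)
      stop(sprintf("cannot read image '%s': %s", path, conditionMessage(e)),
           call. = FALSE))
  bits <- attr(raw, "bits.per.sample")
  fmt <- attr(raw, "sample.format")
  depth <- if (!is.null(fmt) && identical(fmt, "float")) "float"
           else if (!is.null(bits) && bits == 8) 8 else 16
  strip <- function(m) matrix(as.numeric(m), nrow(m), ncol(m))
  if (length(dim(raw)) == 3L) {
    nch <- dim(raw)[3]
    nm <- rep_len(channel_name, nch)
    lapply(seq_len(nch), function(k)
      image_grid(strip(raw[, , k]), pixel_size_um, nm[k], depth))
  } else {
    image_grid(strip(raw), pixel_size_um, channel_name[1], depth)
  }
}

#' Write an image grid to TIFF
#'
#' Writes 8- or 16-bit integer TIFFs losslessly (`read_image()` recovers
#' the values exactly). Grids with `bit_depth = "float"` or non-integer
#' values are quantized to 16 bits over `[0, max]`; lossless float export
#' is not supported.
#'
#' @param image An [image_grid].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(is_image_grid(image))
  v <- image$values
  b <- if (identical(image$bit_depth, "float")) 16L else as.integer(image$bit_depth)
  top <- 2^b - 1
  if (any(v > top) || any(v != round(v))) {
    # quantize out-of-range / fractional data onto the 16-bit scale
    b <- 16L; top <- 2^b - 1
    v <- round(v / max(v, 1e-12) * top)
  }
  tiff::writeTIFF(v / top, path, bits.per.sample = b)
  invisible(path)
}

#' Convert a multi-channel image to grayscale
#'
#' A single channel passes through unchanged. Three channels (assumed
#' R, G, B in order) are combined with ITU-R BT.601 luma weights
#' 0.299 R + 0.587 G + 0.114 B; `method = "mean"` uses the unweighted
#' channel mean instead.
#'
#' @param image An [image_grid] or a list of 1 or 3 of them.
#' @param method `"bt601"` (default) or `"mean"`.
#' @return A single-channel [image_grid].
#' @export
to_grayscale <- function(image, method = c("bt601", "mean")) {
  method <- match.arg(method)
  if (is_image_grid(image)) return(image)
  if (!is.list(image) || !all(vapply(image, is_image_grid, logical(1))))
    stop("`image` must be an image_grid or a list of image_grid channels")
  if (length(image) == 1L) return(image[[1]])
  if (length(image) != 3L)
    stop(sprintf("grayscale conversion needs 1 or 3 channels, got %d",
                 length(image)))
  dims <- vapply(image, function(g) dim(g$values), integer(2))
  if (!all(dims == dims[, 1]))
    stop("all channels must have identical dimensions")
  w <- if (method == "bt601") c(0.299, 0.587, 0.114) else rep(1 / 3, 3)
  v <- w[1] * image[[1]]$values + w[2] * image[[2]]$values +
       w[3] * image[[3]]$values
  image_grid(v, image[[1]]$pixel_size_um, "gray", image[[1]]$bit_depth)
}

# Overlap weights mapping n_in samples onto n_out equal intervals.
# Row j of the returned (n_out x n_in) matrix averages the input pixels
# covered by output cell j, with fractional pixels weighted by overlap,
# so every row sums to 1 and the global mean is conserved.
area_weights_1d <- function(n_in, n_out) {
  w <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  for (j in seq_len(n_out)) {
    a <- (j - 1) * scale
    b <- j * scale
    i0 <- floor(a) + 1
    i1 <- ceiling(b)
    for (i in i0:min(i1, n_in)) {
      lo <- max(a, i - 1)
      hi <- min(b, i)
      if (hi > lo) w[j, i] <- (hi - lo) / scale
    }
  }
  w
}

#' Downsample an image by area averaging
#'
#' Resamples to a `target` x `target` grid using exact rectangular area
#' averaging (anti-aliased box resampling), the scheme under which a
#' constant image stays constant and the global mean is conserved. An
#' input already at the target size is returned unchanged. Non-square
#' inputs are forced to `target` x `target`; the pixel size is rescaled
#' per axis and recorded as the geometric mean of the two axis scales.
#'
#' @param image An [image_grid].
#' @param target Output side length in pixels (default 200).
#' @return An [image_grid] of size `target` x `target`.
#' @export
downsample <- function(image, target = 200) {
  stopifnot(is_image_grid(image))
  target <- as.integer(target)
  if (is.na(target) || target < 2L)
    stop("`target` must be an integer >= 2")
  nr <- nrow(image$values); nc <- ncol(image$values)
  if (nr == target && nc == target) return(image)
  wr <- area_weights_1d(nr, target)
  wc <- area_weights_1d(nc, target)
  v <- wr %*% image$values %*% t(wc)
  px <- image$pixel_size_um * sqrt((nr / target) * (nc / target))
  image_grid(v, px, image$channel_name, "float")
}
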