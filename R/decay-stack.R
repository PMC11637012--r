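#' TCSPC decay stack container
#'
#' Per-pixel photon-arrival histograms from time-correlated single-photon
#' counting: a rows x cols x nbins array of non-negative integer counts.
#' The time axis is `t_i = (i - 1) * bin_width_ns` for bin index `i`.
#'
#' @param counts 3-D numeric array (rows x cols x nbins) of non-negative
#'   integers.
#' @param bin_width_ns Width of one time bin in nanoseconds (> 0).
#' @param pixel_size_um Pixel size in micrometres (> 0).
#' @return An object of class `decay_stack`.
#' @export
decay_stack <- function(counts, bin_width_ns, pixel_size_um) {
  if (!is.array(counts) || length(dim(counts)) != 3L)
    stop("`counts` must be a 3-D array (rows x cols x nbins)")
  if (dim(counts)[3] < 8L)
    stop("a decay stack needs at least 8 time bins")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("decay counts must be finite and non-negative")
  if (any(counts != round(counts)))
    stop("decay counts must be integers")
  if (!is.numeric(bin_width_ns) || length(bin_width_ns) != 1L ||
      bin_width_ns <= 0)
    stop("`bin_width_ns` must be a single positive number")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number")
  structure(
    list(counts = counts,
         bin_width_ns = as.numeric(bin_width_ns),
         pixel_size_um = as.numeric(pixel_size_um)),
    class = "decay_stack")
}

#' @export
print.decay_stack <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf(
    "<decay_stack> %d x %d px, %d bins of %.4g ns (window %.4g ns)\n",
    d[1], d[2], d[3], x$bin_width_ns, d[3] * x$bin_width_ns))
  cat(sprintf("  total photons %.4g, median per pixel %.4g\n",
              sum(x$counts), stats::median(apply(x$counts, c(1, 2), sum))))
  invisible(x)
}

#' Time axis of a decay stack
#'
#' @param stack A [decay_stack].
#' @return Numeric vector of bin start times in ns.
#' @export
decay_time_axis <- function(stack) {
  stopifnot(inherits(stack, "decay_stack"))
  (seq_len(dim(stack$counts)[3]) - 1) * stack$bin_width_ns
}

#' Read a TCSPC decay stack
#'
#' Two plain on-disk layouts are supported: a multi-page TIFF whose pages
#' are time bins (page k = counts in bin k), and a CSV table with header
#' `row,col,bin,count` using 0-based indices; CSV cells not listed
#' default to 0.
#'
#' @param path `.tif`/`.tiff` or `.csv` file.
#' @param bin_width_ns Time-bin width in ns (> 0).
#' @param pixel_size_um Pixel size in micrometres (> 0).
#' @param axis_order For TIFF input: `"auto"` assumes pages are time bins
#'   but refuses a fully cubic stack (all three dimensions equal), where
#'   the layout cannot be inferred; pass `"pages"` to assert it.
#' @return A [decay_stack].
#' @export
read_decay_stack <- function(path, bin_width_ns, pixel_size_um,
                             axis_order = c("auto", "pages")) {
  axis_order <- match.arg(axis_order)
  if (!file.exists(path))
    stop(sprintf("cannot read decay stack: file '%s' does not exist", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    tab <- utils::read.csv(path)
    need <- c("row", "col", "bin", "count")
    if (!all(need %in% names(tab)))
      stop("decay CSV must have columns row,col,bin,count")
    if (any(tab$count < 0) || any(tab$count != round(tab$count)))
      stop("decay counts must be non-negative integers")
    dims <- c(max(tab$row) + 1, max(tab$col) + 1, max(max(tab$bin) + 1, 8))
    counts <- array(0, dims)
    counts[cbind(tab$row + 1, tab$col + 1, tab$bin + 1)] <- tab$count
  } else {
    pages <- tryCatch(
      tiff::readTIFF(path, all = TRUE, as.is = TRUE),
      error = function(e)
        stop(sprintf("cannot read decay stack '%s': %s",
                     path, conditionMessage(e)), call. = FALSE))
    if (!is.list(pages)) pages <- list(pages)
    d <- dim(pages[[1]])
    if (axis_order == "auto" && length(pages) == d[1] && d[1] == d[2])
      stop("stack is cubic; axis order is ambiguous - pass ",
           "axis_order = \"pages\" to assert that pages are time bins")
    counts <- array(0, c(d[1], d[2], length(pages)))
    for (k in seq_along(pages)) counts[, , k] <- pages[[k]]
  }
  decay_stack(counts, bin_width_ns, pixel_size_um)
}

#' Write a decay stack
#'
#' TIFF output stores one 16-bit page per time bin (counts must fit in
#' 16 bits); CSV output writes the sparse `row,col,bin,count` table with
#' 0-based indices, suitable for arbitrarily large counts.
#'
#' @param stack A [decay_stack].
#' @param path Output `.tif` or `.csv` path; the extension picks the
#'   format.
#' @return `path`, invisibly.
#' @export
write_decay_stack <- function(stack, path) {
  stopifnot(inherits(stack, "decay_stack"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    idx <- which(stack$counts > 0, arr.ind = TRUE)
    tab <- data.frame(row = idx[, 1] - 1, col = idx[, 2] - 1,
                      bin = idx[, 3] - 1,
                      count = stack$counts[idx])
    tab <- tab[order(tab$row, tab$col, tab$bin), ]
    utils::write.csv(tab, path, row.names = FALSE)
  } else {
    if (max(stack$counts) > 65535)
      stop("counts exceed 16-bit TIFF range; write as .csv instead")
    nb <- dim(stack$counts)[3]
    pages <- lapply(seq_len(nb),
                    function(k) stack$counts[, , k] / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  }
  invisible(path)
}
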