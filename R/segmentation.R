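# Low-level binary-mask primitives shared by QC and radial profiling.

# Global Otsu threshold; returns a logical foreground matrix. A constant
# image has no separable foreground and yields all-FALSE.
otsu_foreground <- function(values) {
  rng <- range(values)
  if (diff(rng) <= 0) return(matrix(FALSE, nrow(values), ncol(values)))
  v01 <- (values - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(v01), range = c(0, 1))
  v01 > th
}

fill_holes <- function(mask) {
  out <- EBImage::fillHull(EBImage::Image(mask * 1))
  matrix(as.numeric(out) > 0.5, nrow(mask), ncol(mask))
}

# 8-connected component labelling via a pixel-adjacency graph.
# EBImage's labeller is 4-connected, so diagonal bridges are wired up
# explicitly here.
label_components8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  n <- sum(mask)
  if (n == 0L) return(lab)
  id <- matrix(0L, nrow(mask), ncol(mask))
  id[mask] <- seq_len(n)
  nr <- nrow(mask); nc <- ncol(mask)
  edges <- integer(0)
  for (s in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
    dr <- s[1]; dc <- s[2]
    rows <- seq_len(nr - dr)
    cols <- seq.int(max(1L, 1L - dc), min(nc, nc - dc))
    a <- id[rows, cols, drop = FALSE]
    b <- id[rows + dr, cols + dc, drop = FALSE]
    keep <- a > 0L & b > 0L
    if (any(keep)) edges <- c(edges, rbind(a[keep], b[keep]))
  }
  if (length(edges)) {
    g <- igraph::make_empty_graph(n, directed = FALSE)
    g <- igraph::add_edges(g, edges)
    memb <- igraph::components(g)$membership
  } else {
    memb <- seq_len(n)
  }
  lab[mask] <- as.integer(memb)
  lab
}

# Pixels of `mask` adjacent (4-neighbourhood) to background or the image
# border; minimum set-to-set distances are attained on these.
mask_boundary_pixels <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  padded <- matrix(FALSE, nr + 2L, nc + 2L)
  padded[2:(nr + 1L), 2:(nc + 1L)] <- mask
  core <- padded[2:(nr + 1L), 2:(nc + 1L)]
  nb <- padded[1:nr, 2:(nc + 1L)] & padded[3:(nr + 2L), 2:(nc + 1L)] &
        padded[2:(nr + 1L), 1:nc] & padded[2:(nr + 1L), 3:(nc + 2L)]
  which(core & !nb, arr.ind = TRUE)
}

pad_matrix <- function(m, k, value = 0) {
  out <- matrix(value, nrow(m) + 2L * k, ncol(m) + 2L * k)
  out[(k + 1L):(k + nrow(m)), (k + 1L):(k + ncol(m))] <- m
  out
}

# Separable Gaussian smoothing with zero padding at the borders.
gaussian_smooth <- function(m, sigma) {
  radius <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(-radius:radius, sd = sigma)
  k <- k / sum(k)
  conv1 <- function(x) {
    # x is a matrix; convolve along rows (dimension 1)
    n <- nrow(x)
    out <- matrix(0, n, ncol(x))
    xp <- rbind(matrix(0, radius, ncol(x)), x, matrix(0, radius, ncol(x)))
    for (j in seq_along(k))
      out <- out + k[j] * xp[j:(j + n - 1L), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(m))))
}

# Perimeter of a binary mask: length of the 0.5 level set of the
# Gaussian-smoothed (sigma = 0.8 px) mask indicator, traced by marching
# squares. Smoothing removes the stair-step bias that makes raw digital
# contours overestimate smooth outlines; for masks too small to survive
# smoothing the raw binary contour is used instead.
mask_perimeter <- function(mask, sigma = 0.8) {
  if (sum(mask) == 0L) stop("cannot measure an empty mask")
  pm <- pad_matrix(mask * 1, 5L)
  contour_len <- function(z) {
    cl <- grDevices::contourLines(seq_len(nrow(z)), seq_len(ncol(z)),
                                  z, levels = 0.5)
    if (!length(cl)) return(0)
    sum(vapply(cl, function(p) {
      x <- p$x; y <- p$y
      len <- sum(sqrt(diff(x)^2 + diff(y)^2))
      # close the loop if the trace is not already closed
      if (x[1] != x[length(x)] || y[1] != y[length(y)])
        len <- len + sqrt((x[1] - x[length(x)])^2 + (y[1] - y[length(y)])^2)
      len
    }, numeric(1)))
  }
  p <- contour_len(gaussian_smooth(pm, sigma))
  if (p <= 0) p <- contour_len(pm)
  p
}

# Bilinear interpolation of matrix `values` at fractional (row, col)
# coordinates (1-based pixel centers); coordinates are clamped to the
# grid so samples marginally outside read the nearest edge pixel.
bilinear_sample <- function(values, r, c, mask = NULL) {
  nr <- nrow(values); nc <- ncol(values)
  r <- pmin(pmax(r, 1), nr)
  c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  if (nr == 1L) r0 <- rep(1L, length(r))
  if (nc == 1L) c0 <- rep(1L, length(c))
  fr <- r - r0; fc <- c - c0
  r1 <- pmin(r0 + 1L, nr); c1 <- pmin(c0 + 1L, nc)
  i00 <- cbind(r0, c0); i10 <- cbind(r1, c0)
  i01 <- cbind(r0, c1); i11 <- cbind(r1, c1)
  w00 <- (1 - fr) * (1 - fc); w10 <- fr * (1 - fc)
  w01 <- (1 - fr) * fc;       w11 <- fr * fc
  if (!is.null(mask)) {
    # restrict the interpolation support to in-mask pixels and
    # renormalize, so samples near the boundary are not diluted with
    # background; falls back to plain bilinear when no support remains
    w00 <- w00 * mask[i00]; w10 <- w10 * mask[i10]
    w01 <- w01 * mask[i01]; w11 <- w11 * mask[i11]
    tot <- w00 + w10 + w01 + w11
    bad <- tot <= 0
    if (any(bad)) {
      plain <- bilinear_sample(values, r[bad], c[bad])
      out <- numeric(length(r))
      ok <- !bad
      out[ok] <- (values[i00][ok] * w00[ok] + values[i10][ok] * w10[ok] +
                  values[i01][ok] * w01[ok] + values[i11][ok] * w11[ok]) /
                 tot[ok]
      out[bad] <- plain
      return(out)
    }
    return((values[i00] * w00 + values[i10] * w10 +
            values[i01] * w01 + values[i11] * w11) / tot)
  }
  values[i00] * w00 + values[i10] * w10 +
    values[i01] * w01 + values[i11] * w11
}
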