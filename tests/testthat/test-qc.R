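test_that("candidate detection finds disks, drops specks, handles blanks", {
  field <- make_qc_field(
    data.frame(row = c(60, 140), col = c(60, 140),
               diameter_um = c(80, 100), status = c("ok", "ok")),
    pixel_size_um = 2, noise_sd = 0, seed = 1)
  cand <- detect_candidates(field$image, min_area_px = 100)
  expect_length(cand, 2)
  # areas within 5% of pi r^2 (phantom truth radii 20 and 25 px)
  areas <- sort(vapply(cand, function(r) r$area_px, numeric(1)))
  expect_lt(abs(areas[1] - pi * 20^2) / (pi * 20^2), 0.05)
  expect_lt(abs(areas[2] - pi * 25^2) / (pi * 25^2), 0.05)
  # sorted by descending area
  expect_equal(vapply(cand, function(r) r$area_px, numeric(1)),
               rev(areas))

  blank <- image_grid(matrix(5, 100, 100), 1)
  expect_length(detect_candidates(blank, 100), 0)

  tiny <- image_grid(matrix(1, 100, 100), 1)
  tiny$values[48:52, 48:52] <- 200   # ~ disk of radius ~3
  out <- detect_candidates(tiny, min_area_px = 100)
  expect_length(out, 0)
  expect_length(attr(out, "too_small"), 1)
})

test_that("full-view test rejects regions within the border margin", {
  margin <- 2
  # disk whose top-most pixel sits exactly at 0-based row `margin`
  # must fail; one row lower must pass (boundary enumeration)
  mk_at <- function(min_row0) {
    v <- matrix(1, 120, 120)
    r <- 15; ctr_row <- min_row0 + 1 + r   # 1-based center
    for (i in 1:120) for (j in 1:120)
      if ((i - ctr_row)^2 + (j - 60)^2 <= r^2) v[i, j] <- 200
    detect_candidates(image_grid(v, 1), 50)[[1]]
  }
  shape <- c(120L, 120L)
  expect_false(qc_full_view(mk_at(margin), shape, margin))
  expect_true(qc_full_view(mk_at(margin + 1), shape, margin))
  # clipped at the border outright
  expect_false(qc_full_view(mk_at(0), shape, margin))
  # comfortably interior
  expect_true(qc_full_view(mk_at(40), shape, margin))
})

test_that("touching test agrees with brute-force all-pairs distances", {
  run_case <- function(c1, c2, r1, r2, gap_px) {
    v <- matrix(1, 150, 150)
    for (i in 1:150) for (j in 1:150) {
      if ((i - c1[1])^2 + (j - c1[2])^2 <= r1^2) v[i, j] <- 200
      if ((i - c2[1])^2 + (j - c2[2])^2 <= r2^2) v[i, j] <- 200
    }
    cand <- detect_candidates(image_grid(v, 1), 20)
    if (length(cand) != 2) return(NULL)   # merged: not a touching case
    # brute-force oracle over full pixel sets
    a <- cand[[1]]$pixels; b <- cand[[2]]$pixels
    d2min <- min(outer(a[, 1], b[, 1], "-")^2 +
                 outer(a[, 2], b[, 2], "-")^2)
    oracle <- sqrt(d2min) <= gap_px
    expect_identical(qc_touching(cand[[1]], cand[-1], gap_px), oracle)
    expect_identical(qc_touching(cand[[2]], cand[-2], gap_px), oracle)
    oracle
  }
  # far apart: clearly not touching
  expect_false(run_case(c(40, 40), c(110, 110), 15, 15, 3))
  # 1 px apart: forced touching
  expect_true(run_case(c(75, 40), c(75, 72), 15, 15, 3))
  # randomized placements vs the oracle
  set.seed(17)
  for (rep in 1:8) {
    c1 <- c(sample(30:70, 1), sample(30:70, 1))
    c2 <- c(sample(80:120, 1), sample(80:120, 1))
    run_case(c1, c2, sample(10:18, 1), sample(10:18, 1), 3)
  }
})

test_that("croppability requires a fitting padded box and circular shape", {
  shape <- c(200L, 200L)
  centered <- make_qc_field(
    data.frame(row = 100, col = 100, diameter_um = 120, status = "ok"),
    pixel_size_um = 2, noise_sd = 0)
  reg <- detect_candidates(centered$image, 100)[[1]]
  expect_true(qc_croppable(reg, shape, 0.15))

  # fused dumbbell: two disks joined by a thin bridge, circularity < 0.4
  v <- matrix(1, 200, 200)
  for (i in 1:200) for (j in 1:200) {
    if ((i - 100)^2 + (j - 55)^2 <= 625) v[i, j] <- 200
    if ((i - 100)^2 + (j - 145)^2 <= 625) v[i, j] <- 200
  }
  v[97:103, 55:146] <- 200
  fused <- detect_candidates(image_grid(v, 1), 100)[[1]]
  expect_false(qc_croppable(fused, shape, 0.15))

  # near the right edge: padded box spills out
  right <- make_qc_field(
    data.frame(row = 100, col = 172, diameter_um = 100, status = "clipped"),
    pixel_size_um = 2, noise_sd = 0)
  reg_r <- detect_candidates(right$image, 100)[[1]]
  expect_true(qc_full_view(reg_r, shape, 2))  # in view, but...
  expect_false(qc_croppable(reg_r, shape, 0.15))
})

test_that("the QC flowchart accounts for every candidate exactly once", {
  field <- make_qc_field(
    data.frame(row = c(50, 150, 100, 12, 160),
               col = c(50, 50, 130, 150, 150),
               diameter_um = c(70, 80, 60, 60, 60),
               status = c("ok", "ok", "touching", "clipped", "ok")),
    pixel_size_um = 2, seed = 3)
  res <- run_qc(field$image)
  expect_equal(res$report$n_detected, 6)
  expect_equal(res$report$n_accepted, 3)
  reasons <- table(res$report$rejections$reason)
  expect_equal(unname(reasons["not_full_view"]), 1)
  expect_equal(unname(reasons["touching"]), 2)
  expect_equal(res$report$n_accepted + nrow(res$report$rejections),
               res$report$n_detected)
  # crops are square
  for (cr in res$crops) {
    d <- dim(cr$image$values)
    expect_equal(d[1], d[2])
  }
  expect_true(qc_matches_truth(field, res))

  blank <- image_grid(matrix(3, 200, 200), 1)
  res_blank <- run_qc(blank)
  expect_equal(res_blank$report$n_detected, 0)
  expect_length(res_blank$crops, 0)

  single <- make_qc_field(
    data.frame(row = 100, col = 100, diameter_um = 100, status = "ok"),
    pixel_size_um = 2, seed = 5)
  res_single <- run_qc(single$image)
  expect_equal(res_single$report$n_accepted, 1)
})

test_that("QC decisions are geometry-, not order-, dependent", {
  field <- make_qc_field(
    data.frame(row = c(50, 150, 100, 12),
               col = c(50, 50, 130, 150),
               diameter_um = c(70, 80, 60, 60),
               status = c("ok", "ok", "touching", "clipped")),
    pixel_size_um = 2, seed = 7)
  res <- run_qc(field$image)
  # transposing the field permutes candidate enumeration order but
  # preserves geometry, hence all accept/reject decisions
  flipped <- image_grid(t(field$image$values), field$image$pixel_size_um)
  res_t <- run_qc(flipped)
  expect_equal(res_t$report$n_detected, res$report$n_detected)
  expect_equal(res_t$report$n_accepted, res$report$n_accepted)
  expect_equal(sort(table(res_t$report$rejections$reason)),
               sort(table(res$report$rejections$reason)))
})

test_that("widening the border margin never rescues a rejected region", {
  for (seed in c(2, 9, 23)) {
    field <- make_qc_field(random_qc_layout(seed), seed = seed + 500)
    res_tight <- run_qc(field$image, qc_config(border_margin_px = 2))
    res_wide <- run_qc(field$image, qc_config(border_margin_px = 12))
    lab_tight <- vapply(res_tight$crops, function(x) x$label, integer(1))
    lab_wide <- vapply(res_wide$crops, function(x) x$label, integer(1))
    expect_true(all(lab_wide %in% lab_tight))
  }
})
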