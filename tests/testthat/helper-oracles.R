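# Independent oracles used across the suite. These deliberately use
# naive scalar loops / textbook formulas, not the package's own code
# paths.

# Textbook balanced two-way fixed-effects ANOVA from cell means.
oracle_two_way_ss <- function(df) {
  a_lv <- unique(df$region); b_lv <- unique(df$size_class)
  a <- length(a_lv); b <- length(b_lv)
  n <- nrow(df) / (a * b)
  stopifnot(n == round(n))
  grand <- mean(df$value)
  cell <- tapply(df$value, list(df$region, df$size_class), mean)
  am <- tapply(df$value, df$region, mean)
  bm <- tapply(df$value, df$size_class, mean)
  ss_a <- b * n * sum((am - grand)^2)
  ss_b <- a * n * sum((bm - grand)^2)
  ss_cell <- n * sum((cell - grand)^2)
  ss_ab <- ss_cell - ss_a - ss_b
  ss_tot <- sum((df$value - grand)^2)
  ss_e <- ss_tot - ss_cell
  df_a <- a - 1; df_b <- b - 1; df_ab <- df_a * df_b
  df_e <- a * b * (n - 1)
  ms_e <- ss_e / df_e
  f <- c(region = (ss_a / df_a) / ms_e,
         size_class = (ss_b / df_b) / ms_e,
         interaction = (ss_ab / df_ab) / ms_e)
  p <- c(stats::pf(f[1], df_a, df_e, lower.tail = FALSE),
         stats::pf(f[2], df_b, df_e, lower.tail = FALSE),
         stats::pf(f[3], df_ab, df_e, lower.tail = FALSE))
  list(F = f, p = p,
       ss = c(region = ss_a, size_class = ss_b, interaction = ss_ab,
              residual = ss_e))
}

# Build a logical disk mask by scalar test.
disk_mask <- function(n, center, radius) {
  m <- matrix(FALSE, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      if ((i - center[1])^2 + (j - center[2])^2 <= radius^2)
        m[i, j] <- TRUE
  m
}

# Does the QC accept set match the generator truth, disk by disk?
# Truth disks are matched to detected regions by center membership.
qc_matches_truth <- function(field, qc_res) {
  accepted <- qc_res$crops
  covers <- function(region, row, col) {
    any(region$pixels[, 1] == round(row) & region$pixels[, 2] == round(col))
  }
  truth <- field$truth
  n_ok <- sum(truth$expected_accept)
  if (length(accepted) != n_ok) return(FALSE)
  for (i in seq_len(nrow(truth))) {
    hit <- any(vapply(accepted,
                      function(a) covers(a$region, truth$row[i], truth$col[i]),
                      logical(1)))
    if (hit != truth$expected_accept[i]) return(FALSE)
  }
  TRUE
}

# Region contrasts the reference cohort study found significant, with
# the sign of (first - second) region mean. Used by the direction-
# recovery study.
significant_region_contrasts <- function() {
  data.frame(
    marker = c(rep("CD80", 6), rep("CD206", 5)),
    size_class = c("small", "small", "small", "large", "large", "large",
                   "small", "small", "large", "large", "large"),
    first = c("quiescent", "edge", "edge", "quiescent", "edge", "edge",
              "core", "quiescent", "quiescent", "edge", "quiescent"),
    second = c("core", "core", "quiescent", "core", "core", "quiescent",
               "edge", "edge", "core", "core", "edge"),
    sign = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1),
    stringsAsFactors = FALSE)
}

# Estimated (first - second) region difference for one marker/size
# class from a fitted region_comparison, via the Tukey table.
contrast_estimate <- function(cmp, size_class, first, second) {
  tr <- cmp$tukey_region
  tr <- tr[tr$size_class == size_class, ]
  lab1 <- paste(first, "-", second)
  lab2 <- paste(second, "-", first)
  if (lab1 %in% tr$contrast) return(tr$estimate[tr$contrast == lab1])
  if (lab2 %in% tr$contrast) return(-tr$estimate[tr$contrast == lab2])
  NA_real_
}

# Wide region summary -> long format for compare_regions().
regions_long <- function(df) {
  do.call(rbind, lapply(c("core", "quiescent", "edge"), function(reg)
    data.frame(spheroid_id = df$spheroid_id, size_class = df$size_class,
               region = reg, value = df[[reg]],
               stringsAsFactors = FALSE)))
}
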