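#' Classify a spheroid into a size class
#'
#' Diameters up to 200 um (inclusive) are `"small"`, above 200 and up to
#' 400 um `"large"`. Larger spheroids fall outside the two-class design
#' and are flagged `"out_of_range"` with a warning; they are excluded
#' from regional statistics.
#'
#' @param diameter_um Spheroid diameter(s) in micrometres (> 0).
#' @param small_max_um,large_max_um Class boundaries (200 um inclusive
#'   to small, 400 um inclusive to large, by default).
#' @return Character vector over `"small"`, `"large"`,
#'   `"out_of_range"`.
#' @export
classify_size <- function(diameter_um, small_max_um = 200,
                          large_max_um = 400) {
  if (any(!is.finite(diameter_um)) || any(diameter_um <= 0))
    stop("`diameter_um` must be positive and finite")
  out <- ifelse(diameter_um <= small_max_um, "small",
                ifelse(diameter_um <= large_max_um, "large", "out_of_range"))
  if (any(out == "out_of_range"))
    warning("spheroid(s) larger than 400 um are out of range and will be ",
            "excluded from regional statistics")
  out
}

# Microregion fractions of radial-profile points per size class:
# small spheroids 25/50/25% (core/quiescent/edge), large 60/30/10%.
region_fractions <- function(size_class) {
  switch(size_class,
         small = c(core = 0.25, quiescent = 0.50, edge = 0.25),
         large = c(core = 0.60, quiescent = 0.30, edge = 0.10),
         stop(sprintf("unknown size class '%s'", size_class)))
}

#' Partition a radial profile into microregions
#'
#' Assigns the `M` profile points, ordered centroid to boundary, to
#' three contiguous blocks - necrotic core, quiescent region,
#' proliferative edge. Small spheroids (<= 200 um) use fractions
#' 25/50/25 percent; large spheroids (201-400 um) use 60/30/10 percent.
#' Core and edge block sizes are `round(fraction * M)`; the rounding
#' remainder goes to the middle (quiescent) block, which preserves the
#' core and edge fractions exactly at M = 80. Each block's
#' representative point is its midpoint index.
#'
#' @param size_class `"small"` or `"large"`.
#' @param M Number of profile points (>= 4).
#' @return A `region_partition`: list with `size_class`, `fractions`,
#'   `block_sizes`, `labels` (factor of length M), and
#'   `representative_idx` (named integer vector, 1-based).
#' @export
build_partition <- function(size_class, M = 80) {
  M <- as.integer(M)
  if (is.na(M) || M < 4L) stop("`M` must be an integer >= 4")
  fr <- region_fractions(size_class)
  n_core <- as.integer(round(fr["core"] * M))
  n_edge <- as.integer(round(fr["edge"] * M))
  n_quie <- M - n_core - n_edge
  if (n_core < 1L || n_quie < 1L || n_edge < 1L)
    stop("`M` is too small to give every microregion at least one point")
  sizes <- c(core = n_core, quiescent = n_quie, edge = n_edge)
  labels <- factor(rep(names(sizes), sizes),
                   levels = c("core", "quiescent", "edge"))
  starts <- c(core = 1L, quiescent = n_core + 1L,
              edge = n_core + n_quie + 1L)
  rep_idx <- starts + (sizes - 1L) %/% 2L
  structure(
    list(size_class = size_class,
         fractions = fr,
         block_sizes = sizes,
         labels = labels,
         representative_idx = rep_idx,
         M = M),
    class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  cat(sprintf("<region_partition> %s, M = %d: core %d | quiescent %d | edge %d\n",
              x$size_class, x$M,
              x$block_sizes["core"], x$block_sizes["quiescent"],
              x$block_sizes["edge"]))
  invisible(x)
}

#' Extract per-microregion values from a normalized profile
#'
#' `"midpoint"` mode (the default) reads the profile at each block's
#' representative midpoint index - one discrete point per microregion,
#' approximating its centralized location. `"block_mean"` averages over
#' each whole block. Profiles flagged degenerate by
#' [normalize_profile()] yield an excluded summary.
#'
#' @param profile Numeric vector of length `partition$M`, typically a
#'   normalized mean profile.
#' @param partition A [build_partition()] result.
#' @param mode `"midpoint"` or `"block_mean"`.
#' @param spheroid_id,marker Optional identifiers carried into the
#'   summary row.
#' @return One-row data frame: `spheroid_id`, `marker`, `size_class`,
#'   `core`, `quiescent`, `edge`, `mode`, `excluded`.
#' @export
extract_regions <- function(profile, partition,
                            mode = c("midpoint", "block_mean"),
                            spheroid_id = NA_character_,
                            marker = NA_character_) {
  mode <- match.arg(mode)
  stopifnot(inherits(partition, "region_partition"))
  if (length(profile) != partition$M)
    stop(sprintf("profile has %d points but the partition expects %d",
                 length(profile), partition$M))
  excluded <- is_degenerate_profile(profile)
  vals <- if (mode == "midpoint") {
    as.numeric(profile[partition$representative_idx])
  } else {
    as.numeric(tapply(as.numeric(profile), partition$labels, mean))
  }
  data.frame(spheroid_id = spheroid_id, marker = marker,
             size_class = partition$size_class,
             core = vals[1], quiescent = vals[2], edge = vals[3],
             mode = mode, excluded = excluded,
             stringsAsFactors = FALSE)
}

#' Compare microregions with two-way ANOVA and Tukey contrasts
#'
#' Fits the ordinary (fixed-effects) two-way model
#' `value ~ region * size_class` and reports the ANOVA table plus
#' Tukey-adjusted pairwise comparisons of regions within each size
#' class and of size classes within each region. Significance is judged
#' at `alpha` (default 0.05).
#'
#' @param data Data frame with columns `value`, `region` (3 levels:
#'   core, quiescent, edge) and `size_class` (2 levels: small, large).
#'   Rows flagged `excluded == TRUE`, if the column is present, are
#'   dropped first.
#' @param alpha Significance threshold.
#' @return A `region_comparison`: list with `anova` (data frame of
#'   term, df, sum_sq, mean_sq, F, p), `tukey_region`, `tukey_size`
#'   (data frames of contrast estimates and Tukey-adjusted p-values),
#'   `alpha`, `n_per_cell`, and `degenerate` (TRUE when all residual
#'   variance is zero, in which case no inference is attempted).
#' @export
compare_regions <- function(data, alpha = 0.05) {
  if (!all(c("value", "region", "size_class") %in% names(data)))
    stop("`data` needs columns value, region, size_class")
  if ("excluded" %in% names(data)) data <- data[!data$excluded, ]
  data$region <- factor(data$region, levels = c("core", "quiescent", "edge"))
  data$size_class <- factor(data$size_class, levels = c("small", "large"))
  data <- data[!is.na(data$region) & !is.na(data$size_class), ]
  cells <- table(data$region, data$size_class)
  if (any(cells < 2)) {
    bad <- which(cells < 2, arr.ind = TRUE)
    miss <- paste(sprintf("(%s, %s)", rownames(cells)[bad[, 1]],
                          colnames(cells)[bad[, 2]]), collapse = ", ")
    stop("need at least 2 observations per cell; short cells: ", miss)
  }
  fit <- stats::aov(value ~ region * size_class, data = data)
  an <- summary(fit)[[1]]
  anova_df <- data.frame(
    term = trimws(rownames(an)),
    df = an[["Df"]],
    sum_sq = an[["Sum Sq"]],
    mean_sq = an[["Mean Sq"]],
    F = an[["F value"]],
    p = an[["Pr(>F)"]],
    stringsAsFactors = FALSE)
  degenerate <- anova_df$mean_sq[anova_df$term == "Residuals"] <= .Machine$double.eps
  tuk_region <- NULL; tuk_size <- NULL
  if (!degenerate) {
    emm_r <- emmeans::emmeans(fit, ~ region | size_class)
    tuk_region <- as.data.frame(emmeans::contrast(emm_r, "pairwise",
                                                  adjust = "tukey"))
    emm_s <- emmeans::emmeans(fit, ~ size_class | region)
    tuk_size <- as.data.frame(emmeans::contrast(emm_s, "pairwise",
                                                adjust = "tukey"))
  }
  structure(
    list(anova = anova_df,
         tukey_region = tuk_region,
         tukey_size = tuk_size,
         alpha = alpha,
         n_per_cell = as.vector(cells),
         degenerate = degenerate),
    class = "region_comparison")
}

#' @export
print.region_comparison <- function(x, ...) {
  cat("<region_comparison> two-way ANOVA (region x size class)\n")
  if (x$degenerate) {
    cat("  degenerate: zero residual variance, no inference performed\n")
    return(invisible(x))
  }
  an <- x$anova
  for (i in seq_len(nrow(an))) {
    if (an$term[i] == "Residuals") next
    cat(sprintf("  %-20s F = %8.3f  p = %.4g%s\n", an$term[i], an$F[i],
                an$p[i], if (is.finite(an$p[i]) && an$p[i] < x$alpha) " *" else ""))
  }
  invisible(x)
}

#' Regress a metric on spheroid diameter
#'
#' Ordinary least-squares simple linear regression of a per-spheroid
#' metric on diameter, as used to relate marker intensity or metabolic
#' readouts to spheroid size.
#'
#' @param diameters Numeric vector of diameters (um).
#' @param values Numeric vector, same length.
#' @return List with `r_squared`, `p_value` (two-sided, on the slope),
#'   `slope`, `intercept`, and `n`.
#' @export
diameter_correlation <- function(diameters, values) {
  if (length(diameters) != length(values))
    stop("`diameters` and `values` must have the same length")
  keep <- is.finite(diameters) & is.finite(values)
  diameters <- diameters[keep]; values <- values[keep]
  if (length(diameters) < 3L)
    stop("need at least 3 finite observations")
  if (stats::var(diameters) == 0)
    stop("diameters have zero variance; the regression is undefined")
  fit <- stats::lm(values ~ diameters)
  sm <- summary(fit)
  co <- sm$coefficients
  p <- if (nrow(co) < 2L || sm$sigma == 0) {
    # perfect fit: slope p-value is below any representable threshold
    0
  } else co["diameters", "Pr(>|t|)"]
  list(r_squared = sm$r.squared,
       p_value = p,
       slope = unname(stats::coef(fit)["diameters"]),
       intercept = unname(stats::coef(fit)["(Intercept)"]),
       n = length(diameters))
}
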