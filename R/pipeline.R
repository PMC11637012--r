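#' Pipeline configuration
#'
#' Collects every tunable parameter of the analysis in one serializable
#' object. Defaults reproduce the reference workflow: 200 x 200 working
#' grid, 20 rays x 80 points, 200/400 um size-class bounds, midpoint
#' regional extraction.
#'
#' @param downsample_target Working grid side in pixels.
#' @param K,M Radial profile resolution.
#' @param angle_offset First-ray angle in radians.
#' @param qc A [qc_config()].
#' @param small_max_um,large_max_um Size-class boundaries.
#' @param extraction_mode `"midpoint"` or `"block_mean"`.
#' @param photon_threshold,spatial_bin FLIM fitting parameters.
#' @param power_exponent Laser-power normalization exponent.
#' @param alpha Significance threshold for regional statistics.
#' @param seed Seed recorded in run manifests.
#' @return A named list of class `spheroid_config`.
#' @export
spheroid_config <- function(downsample_target = 200, K = 20, M = 80,
                            angle_offset = 0, qc = qc_config(),
                            small_max_um = 200, large_max_um = 400,
                            extraction_mode = "midpoint",
                            photon_threshold = 100, spatial_bin = 3,
                            power_exponent = 2, alpha = 0.05,
                            seed = 1) {
  stopifnot(inherits(qc, "qc_config"),
            extraction_mode %in% c("midpoint", "block_mean"))
  structure(
    list(downsample_target = downsample_target, K = K, M = M,
         angle_offset = angle_offset, qc = qc,
         small_max_um = small_max_um, large_max_um = large_max_um,
         extraction_mode = extraction_mode,
         photon_threshold = photon_threshold, spatial_bin = spatial_bin,
         power_exponent = power_exponent, alpha = alpha, seed = seed),
    class = "spheroid_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are an error; missing keys keep their defaults.
#'
#' @param path YAML file.
#' @return A [spheroid_config()].
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  qc_keys <- names(formals(qc_config))
  top_keys <- setdiff(names(formals(spheroid_config)), "qc")
  unknown <- setdiff(names(raw), c(top_keys, "qc"))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  qc_args <- raw$qc %||% list()
  bad_qc <- setdiff(names(qc_args), qc_keys)
  if (length(bad_qc))
    stop("unknown qc config keys: ", paste(bad_qc, collapse = ", "))
  args <- raw[setdiff(names(raw), "qc")]
  args$qc <- do.call(qc_config, qc_args)
  do.call(spheroid_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_config <- function(config, path) {
  flat <- unclass(config)
  flat$qc <- unclass(flat$qc)
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' Run the full profiling pipeline on an image manifest
#'
#' For every manifest row the image is read, converted to grayscale,
#' QC-triaged, and each accepted spheroid is downsampled to the working
#' grid, segmented, profiled, size-classified, partitioned into
#' microregions and summarized. Cohort-level outputs (regional ANOVA /
#' Tukey tables and diameter correlations, per marker) are produced
#' when the surviving spheroids cover both size classes. Per-stage
#' failures are logged and the run continues; the exit status is
#' nonzero only when no spheroid at all survives QC. Re-running on the
#' same inputs and configuration reproduces identical tables.
#'
#' @param manifest Data frame, or path to a CSV, with columns
#'   `image_id`, `image_path`, `marker`, `pixel_size_um`.
#' @param output_dir Directory for the report bundle (created if
#'   needed).
#' @param config A [spheroid_config()].
#' @return Invisibly, a list with `status` (0 ok, 1 no spheroid
#'   survived), `region_summary`, `qc_reports`, `errors`, and the
#'   paths written.
#' @export
run_pipeline <- function(manifest, output_dir,
                         config = spheroid_config()) {
  if (is.character(manifest)) {
    if (!file.exists(manifest)) stop("manifest not found: ", manifest)
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  need <- c("image_id", "image_path", "marker", "pixel_size_um")
  if (!all(need %in% names(manifest)))
    stop("manifest needs columns ", paste(need, collapse = ", "))
  if (!nrow(manifest)) stop("manifest is empty: nothing to process")
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(output_dir, "profiles"), showWarnings = FALSE)

  qc_reports <- list()
  summaries <- list()
  errors <- list()
  log_error <- function(id, stage, e) {
    errors[[length(errors) + 1L]] <<-
      list(image_id = id, stage = stage, message = conditionMessage(e))
    message(sprintf("[%s] %s failed: %s", id, stage, conditionMessage(e)))
  }

  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    img <- tryCatch(to_grayscale(read_image(row$image_path,
                                            row$pixel_size_um)),
                    error = function(e) { log_error(row$image_id, "read", e); NULL })
    if (is.null(img)) next
    qc <- tryCatch(run_qc(img, config$qc),
                   error = function(e) { log_error(row$image_id, "qc", e); NULL })
    if (is.null(qc)) next
    qc_reports[[row$image_id]] <- list(
      image_id = row$image_id,
      n_detected = qc$report$n_detected,
      n_accepted = qc$report$n_accepted,
      rejections = qc$report$rejections)
    for (k in seq_along(qc$crops)) {
      sid <- sprintf("%s_sph%d", row$image_id, k)
      rec <- tryCatch({
        crop <- downsample(qc$crops[[k]]$image, config$downsample_target)
        profile_spheroid(crop, K = config$K, M = config$M,
                         angle_offset = config$angle_offset)
      }, error = function(e) { log_error(sid, "profile", e); NULL })
      if (is.null(rec)) next
      sz <- classify_size(rec$diameter_um, config$small_max_um,
                          config$large_max_um)
      prof_path <- file.path(output_dir, "profiles",
                             paste0(sid, "_profile.csv"))
      ps <- rec$profile_set
      utils::write.csv(
        data.frame(point_index = seq_len(ps$M) - 1L,
                   normalized_distance = ps$normalized_distance,
                   mean_intensity = ps$mean_profile,
                   normalized_intensity = as.numeric(ps$normalized_profile)),
        prof_path, row.names = FALSE)
      if (sz == "out_of_range") next
      part <- build_partition(sz, config$M)
      summ <- extract_regions(ps$normalized_profile, part,
                              mode = config$extraction_mode,
                              spheroid_id = sid, marker = row$marker)
      summ$diameter_um <- rec$diameter_um
      summ$circularity <- rec$circularity
      summaries[[sid]] <- summ
    }
  }

  region_summary <- if (length(summaries)) do.call(rbind, summaries)
                    else data.frame()
  utils::write.csv(region_summary,
                   file.path(output_dir, "region_summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(qc_reports,
                       file.path(output_dir, "qc_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  # cohort statistics per marker, when both size classes are populated
  stats_out <- list(); corr_rows <- list()
  if (nrow(region_summary)) {
    keep <- region_summary[!region_summary$excluded, ]
    for (m in unique(keep$marker)) {
      sub <- keep[keep$marker == m, ]
      long <- stats::reshape(
        sub[, c("spheroid_id", "size_class", "core", "quiescent", "edge")],
        varying = c("core", "quiescent", "edge"), v.names = "value",
        times = c("core", "quiescent", "edge"), timevar = "region",
        direction = "long")
      res <- tryCatch(compare_regions(long, alpha = config$alpha),
                      error = function(e) NULL)
      if (!is.null(res) && !res$degenerate) {
        stats_out[[m]] <- list(marker = m, anova = res$anova,
                               tukey_region = res$tukey_region,
                               tukey_size = res$tukey_size)
      }
      for (reg in c("core", "quiescent", "edge")) {
        cr <- tryCatch(diameter_correlation(sub$diameter_um, sub[[reg]]),
                       error = function(e) NULL)
        if (!is.null(cr))
          corr_rows[[paste(m, reg)]] <- data.frame(
            marker = m, region = reg, r_squared = cr$r_squared,
            p_value = cr$p_value, slope = cr$slope, n = cr$n)
      }
    }
  }
  if (length(stats_out)) {
    jsonlite::write_json(
      lapply(stats_out, function(s) list(marker = s$marker, anova = s$anova)),
      file.path(output_dir, "anova.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
    std_tukey <- function(df, family, marker, group_col) {
      data.frame(marker = marker, family = family,
                 group = as.character(df[[group_col]]),
                 contrast = as.character(df$contrast),
                 estimate = df$estimate, se = df$SE, df = df$df,
                 t = df$t.ratio, p = df$p.value)
    }
    tuk <- do.call(rbind, lapply(stats_out, function(s) rbind(
      std_tukey(s$tukey_region, "region_within_size", s$marker,
                "size_class"),
      std_tukey(s$tukey_size, "size_within_region", s$marker, "region"))))
    utils::write.csv(tuk, file.path(output_dir, "tukey.csv"),
                     row.names = FALSE)
  }
  if (length(corr_rows))
    utils::write.csv(do.call(rbind, corr_rows),
                     file.path(output_dir, "correlations.csv"),
                     row.names = FALSE)

  cfg_path <- file.path(output_dir, "config.yaml")
  write_config(config, cfg_path)
  run_manifest <- list(
    package_version = as.character(utils::packageVersion("spheroprofile")),
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_path)),
    n_images = nrow(manifest),
    n_detected = sum(vapply(qc_reports, `[[`, numeric(1), "n_detected")),
    n_accepted_spheroids = nrow(region_summary),
    inputs = manifest$image_path,
    errors = errors)
  jsonlite::write_json(run_manifest,
                       file.path(output_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  status <- if (nrow(region_summary) == 0L) 1L else 0L
  if (status != 0L)
    message("no spheroid survived QC and profiling; empty report bundle")
  invisible(list(status = status, region_summary = region_summary,
                 qc_reports = qc_reports, errors = errors,
                 output_dir = output_dir))
}
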