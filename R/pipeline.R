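#' Analyze a polarizer series over a set of regions of interest
#'
#' The core per-series chain: segment each ROI, fit the luminance sinusoid
#' per stripe class, derive degree of polarization, phase, fit quality,
#' the significance gate and the mean Michelson contrast. Excluded ROIs
#' (constant luminance, empty class, degenerate balance) are reported via
#' `message()` and the `exclusions` attribute, and the run continues —
#' mirroring field practice of dropping compromised regions while keeping
#' the rest of the animal.
#'
#' @param series A [polarizer_series]; must have exposure locked, otherwise
#'   luminances are not comparable across filter angles and the degree of
#'   polarization is invalid.
#' @param rois List of [roi()] objects.
#' @param zebra_id Identifier recorded in the output rows.
#' @param alpha Significance level for the phase gate.
#' @return A "study table" data.frame with one row per (ROI, stripe class):
#'   `zebra_id`, `roi_label`, `class`, `a`, `b`, `phase_deg`, `fit_r`, `d`,
#'   `significant`, `contrast`, plus any `illumination` flag found in the
#'   series metadata. Attribute `exclusions` is a data.frame of dropped
#'   ROIs with reasons.
#' @export
analyze_series <- function(series, rois, zebra_id = "subject", alpha = 0.05) {
  stopifnot(inherits(series, "polarizer_series"))
  if (!series$exposure_locked)
    stop("exposure not locked within the series: polarimetric ratios invalid")
  rows <- list(); excl <- list()
  illum <- series$metadata$illumination %||% NA_character_
  for (r in rois) {
    seg <- segment_roi(series, r)
    if (seg$excluded) {
      message(sprintf("ROI '%s' excluded: %s", r$label, seg$reason))
      excl[[length(excl) + 1L]] <- data.frame(roi_label = r$label,
                                              reason = seg$reason)
      next
    }
    pol <- roi_polarimetry(series, seg, alpha)
    for (cls in c("black", "white")) {
      f <- pol[[cls]]
      rows[[length(rows) + 1L]] <- data.frame(
        zebra_id = zebra_id, roi_label = r$label, class = cls,
        a = f$amplitude_a, b = f$baseline_b, phase_deg = f$phase_deg,
        fit_r = f$fit_r, d = f$degree_d, significant = pol$phase_pairable,
        contrast = pol$michelson_contrast, illumination = illum)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(zebra_id = character(), roi_label = character(),
               class = character(), a = numeric(), b = numeric(),
               phase_deg = numeric(), fit_r = numeric(), d = numeric(),
               significant = logical(), contrast = numeric(),
               illumination = character())
  attr(out, "exclusions") <- if (length(excl)) do.call(rbind, excl) else NULL
  out
}

#' Read a pipeline run configuration from YAML
#'
#' A run config drives the whole simulate / analyze / sweep workflow from
#' one file: exactly one of `scene` (a [scene_config()] field list) or
#' `manifest` (path to a series sidecar written by [write_series()]), plus
#' an optional `rois` list (label, row, col, height, width, optional
#' offsets), an `acuity` block, `alpha`, `seed` and `output_dir`. Values
#' given in the file override the package defaults; the seed is recorded in
#' every output.
#'
#' @param path YAML file path.
#' @return A `"run_config"` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  has_scene <- !is.null(cfg$scene)
  has_manifest <- !is.null(cfg$manifest)
  if (has_scene == has_manifest)
    stop("run config must contain exactly one of 'scene' or 'manifest'")
  cfg$alpha <- cfg$alpha %||% 0.05
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$output_dir <- cfg$output_dir %||% "."
  structure(cfg, class = "run_config")
}

run_config_rois <- function(cfg) {
  lapply(cfg$rois, function(r)
    roi(r$label, r$row, r$col, r$height, r$width,
        per_image_offsets = if (!is.null(r$offsets))
          matrix(unlist(r$offsets), ncol = 2, byrow = TRUE)))
}

run_config_series <- function(cfg) {
  if (!is.null(cfg$manifest)) return(read_series(cfg$manifest))
  sc <- cfg$scene
  sc$seed <- sc$seed %||% cfg$seed
  for (f in c("black_spec", "white_spec", "background_spec"))
    if (!is.null(sc[[f]])) sc[[f]] <- do.call(stripe_class_spec, sc[[f]])
  render_series(do.call(scene_config, sc))
}

#' Simulate: render a synthetic series to disk
#'
#' Renders the configured scene and writes per-angle 16-bit TIFFs plus the
#' YAML sidecar (including ground truth) under the config's output
#' directory. Identical config + seed gives byte-identical TIFFs.
#'
#' @param cfg A [read_run_config()] result (must contain a `scene`).
#' @return Invisibly, the sidecar path.
#' @export
run_simulate <- function(cfg) {
  if (is.null(cfg$scene)) stop("simulate requires a 'scene' block")
  series <- run_config_series(cfg)
  if (!dir.exists(cfg$output_dir)) dir.create(cfg$output_dir, recursive = TRUE)
  write_series(series, cfg$output_dir, prefix = cfg$prefix %||% "scene")
}

#' Analyze: per-ROI polarimetry of a configured series
#'
#' Loads (or renders) the configured series, runs [analyze_series()] over
#' the configured ROIs and writes `study_table.csv` to the output
#' directory, along with `exclusions.csv` when any ROI was dropped.
#'
#' @param cfg A [read_run_config()] result with an `rois` list.
#' @return The study table, invisibly.
#' @export
run_analyze <- function(cfg) {
  series <- run_config_series(cfg)
  rois <- run_config_rois(cfg)
  if (length(rois) == 0) stop("run config has no ROIs")
  tab <- analyze_series(series, rois, zebra_id = cfg$zebra_id %||% "subject",
                        alpha = cfg$alpha)
  tab$seed <- cfg$seed
  if (!dir.exists(cfg$output_dir)) dir.create(cfg$output_dir, recursive = TRUE)
  write.csv(tab, file.path(cfg$output_dir, "study_table.csv"),
            row.names = FALSE)
  ex <- attr(tab, "exclusions")
  if (!is.null(ex))
    write.csv(ex, file.path(cfg$output_dir, "exclusions.csv"),
              row.names = FALSE)
  invisible(tab)
}

#' Sweep: distance-visibility curves for every configured ROI
#'
#' Runs [visibility_sweep()] per ROI and writes one tidy CSV
#' (`visibility_curves.csv`: roi_label, distance_m, metric, class, value)
#' plus a PNG plot per ROI.
#'
#' @param cfg A [read_run_config()] result with `rois` and an optional
#'   `acuity` block.
#' @param plot Write PNG plots alongside the CSV.
#' @return Named list of visibility curves, invisibly.
#' @export
run_sweep <- function(cfg, plot = TRUE) {
  series <- run_config_series(cfg)
  rois <- run_config_rois(cfg)
  if (length(rois) == 0) stop("run config has no ROIs")
  acfg <- do.call(acuity_config, cfg$acuity %||% list())
  if (!dir.exists(cfg$output_dir)) dir.create(cfg$output_dir, recursive = TRUE)
  curves <- list(); tidy <- list()
  for (r in rois) {
    seg <- segment_roi(series, r)
    if (seg$excluded) {
      message(sprintf("ROI '%s' excluded from sweep: %s", r$label, seg$reason))
      next
    }
    cv <- visibility_sweep(series, r, seg, acfg)
    curves[[r$label]] <- cv
    tidy[[r$label]] <- cbind(roi_label = r$label, visibility_long(cv))
    if (plot) {
      grDevices::png(file.path(cfg$output_dir,
                               sprintf("visibility_%s.png", r$label)),
                     width = 600, height = 450)
      plot(cv, main = r$label)
      grDevices::dev.off()
    }
  }
  if (length(tidy) == 0) stop("no ROI survived segmentation")
  write.csv(do.call(rbind, tidy),
            file.path(cfg$output_dir, "visibility_curves.csv"),
            row.names = FALSE)
  invisible(curves)
}
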