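#' Construct a polarizer image series
#'
#' The unit of analysis: an ordered stack of co-registered single-scene
#' luminance images, one per linear-polarizer filter angle. Luminance is
#' linear and on an arbitrary scale (raw sensor counts are linearly related
#' to luminance by an unknown, exposure-dependent factor), which is fine
#' because every downstream statistic is a scale-invariant ratio — but only
#' within a series, hence the `exposure_locked` requirement.
#'
#' @param images List of numeric matrices, all the same dimensions,
#'   non-negative values.
#' @param filter_angles_deg Numeric vector of filter angles in degrees, one
#'   per image, in \[-90, 90\]. The standard protocol is seven angles from
#'   -90 to +90 in 30-degree steps: the two endpoints are the same physical
#'   filter orientation and serve as replicate observations.
#' @param pixels_per_degree Angular calibration at capture (px/deg).
#' @param capture_distance_m Camera-to-subject distance in metres.
#' @param exposure_locked Logical; must be `TRUE` for polarimetric analysis
#'   (exposure was not changed within the series).
#' @param metadata Free-form list (sun azimuth/elevation, illumination flags,
#'   body-axis angle, ...).
#' @return An object of class `"polarizer_series"`.
#' @export
polarizer_series <- function(images, filter_angles_deg,
                             pixels_per_degree = 89.5,
                             capture_distance_m = 50,
                             exposure_locked = TRUE,
                             metadata = list()) {
  if (!is.list(images) || length(images) == 0)
    stop("images must be a non-empty list of matrices")
  if (length(images) != length(filter_angles_deg))
    stop(sprintf("got %d images but %d filter angles",
                 length(images), length(filter_angles_deg)))
  dims <- lapply(images, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("all images in a series must have identical dimensions")
  images <- lapply(images, function(im) {
    storage.mode(im) <- "double"
    if (any(!is.finite(im)) || any(im < 0))
      stop("luminance values must be finite and non-negative")
    im
  })
  if (any(filter_angles_deg < -90 | filter_angles_deg > 90))
    stop("filter angles must lie in [-90, 90] degrees")
  structure(
    list(images = images,
         filter_angles_deg = as.numeric(filter_angles_deg),
         pixels_per_degree = pixels_per_degree,
         capture_distance_m = capture_distance_m,
         exposure_locked = isTRUE(exposure_locked),
         metadata = metadata),
    class = "polarizer_series")
}

#' @export
print.polarizer_series <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat(sprintf("Polarizer series: %d images of %d x %d px, angles [%s] deg\n",
              length(x$images), d[1], d[2],
              paste(x$filter_angles_deg, collapse = ", ")))
  cat(sprintf("  %.1f px/deg, captured at %g m, exposure %s\n",
              x$pixels_per_degree, x$capture_distance_m,
              if (x$exposure_locked) "locked" else "NOT LOCKED"))
  invisible(x)
}

#' Load a polarizer series from TIFF files
#'
#' Reads one grayscale or RGB TIFF per filter angle. 16-bit integer data are
#' promoted to double without rescaling (values are linear in luminance up
#' to an unknown scale factor, so rescaling would add nothing); RGB inputs
#' are converted to a luminance proxy with [rgb_to_luma()]. Raw camera
#' formats are out of scope: convert to TIFF first with a raw developer that
#' preserves linear sensor values.
#'
#' @param paths Character vector of TIFF paths, one per angle.
#' @param angles_deg Filter angle per file, in degrees.
#' @param ... Passed to [polarizer_series()] (calibration, metadata, ...).
#' @return A `"polarizer_series"`.
#' @export
load_series <- function(paths, angles_deg, ...) {
  if (length(paths) != length(angles_deg))
    stop(sprintf("got %d files but %d angles", length(paths), length(angles_deg)))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("unreadable file(s): ", paste(missing, collapse = ", "))
  images <- lapply(paths, function(p) {
    im <- tiff::readTIFF(p, as.is = TRUE, info = TRUE)
    if (is.double(im) && max(im) <= 1) {
      # multi-channel reads come back normalized to [0, 1]; restore the
      # integer sample counts from the file's bit depth
      bits <- attr(im, "bits.per.sample") %||% 16L
      im <- im * (2^bits - 1)
    }
    if (length(dim(im)) == 3) {
      if (dim(im)[3] == 4) im <- im[, , 1:3, drop = FALSE]  # drop alpha
      im <- rgb_to_luma(im)
    }
    im <- unclass(as.matrix(im))
    attributes(im)[setdiff(names(attributes(im)), "dim")] <- NULL
    storage.mode(im) <- "double"
    im
  })
  polarizer_series(images, angles_deg, ...)
}

#' Write a polarizer series as 16-bit grayscale TIFFs plus a YAML sidecar
#'
#' One TIFF per filter angle, values rounded to integer counts (must fit in
#' 0..65535), plus `<prefix>_series.yaml` recording filenames, angles,
#' calibration and — for synthetic series — the ground-truth generator
#' parameters. The integer write/read round trip is lossless.
#'
#' @param series A `"polarizer_series"`.
#' @param dir Output directory (created if absent).
#' @param prefix Filename prefix.
#' @return Invisibly, the sidecar path.
#' @export
write_series <- function(series, dir, prefix = "series") {
  stopifnot(inherits(series, "polarizer_series"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mx <- max(vapply(series$images, max, numeric(1)))
  if (mx > 65535)
    stop("luminance exceeds 16-bit range; rescale before writing")
  files <- character(length(series$images))
  for (i in seq_along(series$images)) {
    files[i] <- sprintf("%s_ang%+04d.tif", prefix, round(series$filter_angles_deg[i]))
    tiff::writeTIFF(round(series$images[[i]]) / 65535,
                    file.path(dir, files[i]), bits.per.sample = 16L)
  }
  sidecar <- list(
    files = files,
    filter_angles_deg = series$filter_angles_deg,
    pixels_per_degree = series$pixels_per_degree,
    capture_distance_m = series$capture_distance_m,
    exposure_locked = series$exposure_locked,
    metadata = series$metadata)
  gt <- attr(series, "ground_truth")
  if (!is.null(gt)) sidecar$ground_truth <- gt$params
  path <- file.path(dir, paste0(prefix, "_series.yaml"))
  yaml::write_yaml(sidecar, path)
  invisible(path)
}

#' Read a series previously written by [write_series()]
#'
#' @param sidecar_path Path to the `*_series.yaml` manifest.
#' @return A `"polarizer_series"`.
#' @export
read_series <- function(sidecar_path) {
  sc <- yaml::read_yaml(sidecar_path)
  load_series(file.path(dirname(sidecar_path), unlist(sc$files)),
              unlist(sc$filter_angles_deg),
              pixels_per_degree = sc$pixels_per_degree,
              capture_distance_m = sc$capture_distance_m,
              exposure_locked = sc$exposure_locked,
              metadata = sc$metadata %||% list())
}

#' Convert a linear RGB image to a luminance proxy
#'
#' Weighted channel sum with the Rec. 601 luma coefficients
#' (0.2989 R + 0.5870 G + 0.1140 B), the same weighting used by common
#' grayscale converters for CIE-luminance-like output. Linear in the input,
#' so the arbitrary exposure scale passes through unchanged.
#'
#' @param rgb_image Numeric array of dimension height x width x 3.
#' @return Numeric matrix of luminance values.
#' @export
rgb_to_luma <- function(rgb_image) {
  d <- dim(rgb_image)
  if (length(d) != 3 || d[3] != 3)
    stop("expected a height x width x 3 RGB array")
  0.2989 * rgb_image[, , 1] + 0.5870 * rgb_image[, , 2] + 0.1140 * rgb_image[, , 3]
}

#' Replicate-endpoint reliability check
#'
#' The first and last exposures of the protocol are taken at the same
#' physical filter orientation (-90 and +90 degrees), so any luminance
#' difference between them within a region of interest estimates the
#' within-series measurement repeatability (sensor noise, residual subject
#' motion, illumination drift). Reliability improves with ROI area as pixel
#' noise averages out.
#'
#' @param series A `"polarizer_series"` containing both -90 and +90 images.
#' @param roi A [roi()] region of interest.
#' @param segmentation Optional [segment_roi()] result; if supplied the
#'   report is additionally split by stripe class.
#' @return A data.frame with columns `class` ("all" plus "black"/"white"
#'   when a segmentation is given), `mean_lo`, `mean_hi` (endpoint ROI
#'   means), `abs_diff` and `rel_diff` (absolute difference over the pooled
#'   mean).
#' @export
replicate_endpoint_check <- function(series, roi, segmentation = NULL) {
  i_lo <- which(series$filter_angles_deg == -90)
  i_hi <- which(series$filter_angles_deg == 90)
  if (length(i_lo) < 1 || length(i_hi) < 1)
    stop("series must contain both -90 and +90 degree endpoint images")
  i_lo <- i_lo[1]; i_hi <- tail_idx(i_hi)
  p_lo <- extract_roi(series, roi, i_lo)
  p_hi <- extract_roi(series, roi, i_hi)
  row_for <- function(class, lo, hi) {
    m <- mean(c(lo, hi))
    data.frame(class = class, mean_lo = mean(lo), mean_hi = mean(hi),
               abs_diff = abs(mean(hi) - mean(lo)),
               rel_diff = if (m > 0) abs(mean(hi) - mean(lo)) / m else 0)
  }
  out <- row_for("all", p_lo, p_hi)
  if (!is.null(segmentation)) {
    m_lo <- segmentation$per_image[[i_lo]]$mask
    m_hi <- segmentation$per_image[[i_hi]]$mask
    out <- rbind(out,
                 row_for("white", p_lo[m_lo], p_hi[m_hi]),
                 row_for("black", p_lo[!m_lo], p_hi[!m_hi]))
  }
  out
}

tail_idx <- function(i) i[length(i)]
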