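#' Configuration of the compound-eye acuity model
#'
#' Models the low spatial acuity of a biting fly's compound eye as a
#' Gaussian blur of angular width `acuity_deg` (about 1 degree for large
#' calliphorid-like flies), applied to the captured images and rescaled
#' with the simulated observer distance. "Width" is interpreted as the full
#' width at half maximum of the Gaussian acceptance function by default —
#' the standard parameterization of an ommatidial acceptance angle — with a
#' switch to treat it as the Gaussian sigma instead, since either reading
#' is defensible.
#'
#' @param acuity_deg Angular blur width at the observer, degrees (> 0).
#' @param width_convention `"fwhm"` (default) or `"sigma"`.
#' @param distance_grid_m Ascending observer distances in metres (default
#'   1–50 m, the range over which fly host-seeking shifts from olfactory to
#'   visual guidance).
#' @param pixels_per_degree,capture_distance_m Capture calibration; default
#'   `NULL` means take them from the series at sweep time.
#' @return An `"acuity_config"` list.
#' @export
acuity_config <- function(acuity_deg = 1.0, width_convention = c("fwhm", "sigma"),
                          distance_grid_m = c(1, 2, 5, 10, 20, 30, 50),
                          pixels_per_degree = NULL, capture_distance_m = NULL) {
  width_convention <- match.arg(width_convention)
  if (acuity_deg <= 0) stop("acuity_deg must be positive")
  if (length(distance_grid_m) == 0) stop("distance grid must be non-empty")
  if (any(distance_grid_m <= 0)) stop("distances must be positive")
  if (is.unsorted(distance_grid_m, strictly = TRUE))
    stop("distance grid must be sorted ascending")
  structure(list(acuity_deg = acuity_deg,
                 width_convention = width_convention,
                 distance_grid_m = as.numeric(distance_grid_m),
                 pixels_per_degree = pixels_per_degree,
                 capture_distance_m = capture_distance_m),
            class = "acuity_config")
}

#' Gaussian blur sigma (in capture-image pixels) for an observer distance
#'
#' The observer's angular blur width maps onto the captured image as
#' `width_px = acuity_deg * pixels_per_degree * distance_m /
#' capture_distance_m`: an observer at the capture distance sees one
#' acuity-width per `acuity_deg * pixels_per_degree` pixels, and the
#' subtended blur scales linearly with distance. The width is converted to
#' a Gaussian sigma by `width / (2 sqrt(2 log 2))` (= width/2.3548) under
#' the FWHM convention, or taken as sigma directly.
#'
#' @param config An [acuity_config()] with calibration fields set.
#' @param distance_m Observer distance(s) in metres.
#' @return Gaussian sigma in pixels (vectorized over `distance_m`).
#' @export
blur_sigma_pixels <- function(config, distance_m) {
  ppd <- config$pixels_per_degree
  cap <- config$capture_distance_m
  if (is.null(ppd) || is.null(cap))
    stop("acuity config needs pixels_per_degree and capture_distance_m")
  width_px <- config$acuity_deg * ppd * distance_m / cap
  if (config$width_convention == "fwhm") width_px / (2 * sqrt(2 * log(2)))
  else width_px
}

# Mirror-pad a matrix by w pixels on every side (reflect without repeating
# the border pixel), handling w >= dim by repeated reflection.
pad_mirror <- function(m, w) {
  reflect_idx <- function(i, n) {
    if (n == 1) return(rep(1L, length(i)))
    p <- 2L * (n - 1L)
    j <- ((i - 1L) %% p + p) %% p
    as.integer(ifelse(j < n, j + 1L, p - j + 1L))
  }
  m[reflect_idx(seq(1 - w, nrow(m) + w), nrow(m)),
    reflect_idx(seq(1 - w, ncol(m) + w), ncol(m)), drop = FALSE]
}

#' Gaussian-blur a full image
#'
#' Isotropic Gaussian convolution applied to the *entire* frame (never to a
#' cropped ROI, which would bleed boundary artifacts into the region
#' means). The frame is mirror-padded by three sigma before filtering and
#' cropped back, so total luminance inside interior regions is conserved.
#' `sigma_px = 0` is the identity.
#'
#' @param image Numeric matrix.
#' @param sigma_px Gaussian sigma in pixels (>= 0).
#' @return Blurred matrix, same dimensions.
#' @export
blur_image <- function(image, sigma_px) {
  if (sigma_px < 0) stop("sigma_px must be >= 0")
  if (sigma_px == 0) return(image)
  w <- ceiling(3 * sigma_px)
  padded <- pad_mirror(image, w)
  blurred <- EBImage::gblur(padded, sigma = sigma_px, boundary = "replicate")
  blurred[w + seq_len(nrow(image)), w + seq_len(ncol(image)), drop = FALSE]
}

#' Visibility of polarization and stripe contrast versus observer distance
#'
#' For each distance in the grid: blur every filter-angle image of the
#' series by the distance-scaled acuity sigma, re-extract the stripe-class
#' mean luminances using the *original* (unblurred-image) segmentation
#' masks, refit the luminance sinusoid per class, and recompute the degree
#' of polarization for black and white stripes, the mean Michelson stripe
#' contrast, and the whole-ROI (mask-free) degree of polarization. Stripe
#' contrast collapses with distance as blur mixes the classes, while the
#' pooled polarization signal — the luminance-weighted mixture of the two
#' class sinusoids — survives, so a polarotactic insect loses the stripes
#' long before it loses the polarization cue.
#'
#' @param series A [polarizer_series].
#' @param roi A [roi()].
#' @param segmentation The [segment_roi()] result from the unblurred series.
#' @param config An [acuity_config()]; `NULL` calibration fields are filled
#'   from the series.
#' @return A data.frame of class `"visibility_curve"` with columns
#'   `distance_m`, `sigma_px`, `d_black`, `d_white`, `d_pooled`, `contrast`,
#'   and attribute `converged_d` (the pooled degree at the largest blur).
#' @export
visibility_sweep <- function(series, roi, segmentation,
                             config = acuity_config()) {
  stopifnot(inherits(series, "polarizer_series"),
            inherits(segmentation, "stripe_segmentation"))
  if (segmentation$excluded)
    stop("cannot sweep an excluded segmentation: ", segmentation$reason)
  if (is.null(config$pixels_per_degree))
    config$pixels_per_degree <- series$pixels_per_degree
  if (is.null(config$capture_distance_m))
    config$capture_distance_m <- series$capture_distance_m
  angles <- series$filter_angles_deg
  out <- lapply(config$distance_grid_m, function(dist) {
    sig <- blur_sigma_pixels(config, dist)
    blurred <- lapply(series$images, blur_image, sigma_px = sig)
    cm <- segmentation_class_means(series, segmentation, images = blurred)
    pooled <- vapply(seq_along(blurred), function(i)
      mean(extract_roi(series, roi, i, images = blurred)), numeric(1))
    fb <- fit_sinusoid(angles, cm$black)
    fw <- fit_sinusoid(angles, cm$white)
    fp <- fit_sinusoid(angles, pooled)
    denom <- cm$white + cm$black
    data.frame(distance_m = dist, sigma_px = sig,
               d_black = fb$degree_d, d_white = fw$degree_d,
               d_pooled = fp$degree_d,
               contrast = mean((cm$white - cm$black) / denom))
  })
  curve <- do.call(rbind, out)
  attr(curve, "converged_d") <- curve$d_pooled[nrow(curve)]
  class(curve) <- c("visibility_curve", "data.frame")
  curve
}

#' Tidy long format of a visibility curve
#'
#' @param curve A [visibility_sweep()] result.
#' @return A data.frame with columns `distance_m`, `metric`
#'   (`"d"`/`"contrast"`), `class` and `value`, ready for CSV export or
#'   plotting.
#' @export
visibility_long <- function(curve) {
  d <- as.data.frame(curve)
  rbind(
    data.frame(distance_m = d$distance_m, metric = "d", class = "black",
               value = d$d_black),
    data.frame(distance_m = d$distance_m, metric = "d", class = "white",
               value = d$d_white),
    data.frame(distance_m = d$distance_m, metric = "d", class = "pooled",
               value = d$d_pooled),
    data.frame(distance_m = d$distance_m, metric = "contrast", class = "both",
               value = d$contrast))
}

#' Plot a visibility curve
#'
#' Degree of polarization per stripe class and Michelson stripe contrast
#' against observer distance, on a shared unitless contrast axis.
#'
#' @param x A `"visibility_curve"`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.visibility_curve <- function(x, ...) {
  graphics::matplot(x$distance_m, cbind(x$d_black, x$d_white, x$contrast),
                    type = "b", pch = 19, lty = 1,
                    col = c("blue", "red", "black"),
                    xlab = "Distance (m)", ylab = "d / Michelson contrast",
                    ...)
  graphics::legend("topright", c("d black", "d white", "stripe contrast"),
                   col = c("blue", "red", "black"), lty = 1, pch = 19,
                   bty = "n")
  invisible(x)
}

#' Compare coat polarization against adjacent background patches
#'
#' For each (animal ROI, background ROI) pair imaged under the same
#' illumination: the coat degree of polarization is the mean of the black-
#' and white-class degrees from the segmented fit; the background degree
#' comes from a mask-free sinusoid fit of the patch mean luminance. Reports
#' the per-pair coat/background ratio, the median ratio, and a paired
#' t-test of the degrees.
#'
#' @param series A [polarizer_series] (or a list of one series per pair,
#'   matched by position).
#' @param roi_pairs List of `list(zebra = roi, background = roi)` pairs;
#'   pairs with a missing member are dropped with a warning.
#' @param alpha Significance level recorded with the fits.
#' @return A list: `pairs` (data.frame with `roi_label`, `d_zebra`,
#'   `d_background`, `ratio`), `median_ratio`, and `paired_t` (the
#'   [t.test()] result, `NULL` with fewer than 2 pairs).
#' @export
background_comparison <- function(series, roi_pairs, alpha = 0.05) {
  series_list <- if (inherits(series, "polarizer_series"))
    rep(list(series), length(roi_pairs)) else series
  rows <- list()
  for (i in seq_along(roi_pairs)) {
    pair <- roi_pairs[[i]]
    if (is.null(pair$zebra) || is.null(pair$background)) {
      warning("unpaired ROI at position ", i, ": excluded")
      next
    }
    s <- series_list[[i]]
    seg <- segment_roi(s, pair$zebra)
    if (seg$excluded) {
      warning(sprintf("pair %d excluded: %s", i, seg$reason))
      next
    }
    pol <- roi_polarimetry(s, seg, alpha)
    d_zebra <- mean(c(pol$black$degree_d, pol$white$degree_d))
    bg_means <- vapply(seq_along(s$images), function(j)
      mean(extract_roi(s, pair$background, j)), numeric(1))
    d_bg <- fit_sinusoid(s$filter_angles_deg, bg_means)$degree_d
    rows[[length(rows) + 1L]] <- data.frame(
      roi_label = pair$zebra$label, d_zebra = d_zebra, d_background = d_bg,
      ratio = d_zebra / d_bg)
  }
  pairs <- do.call(rbind, rows)
  if (is.null(pairs) || nrow(pairs) == 0) stop("no valid zebra/background pairs")
  paired_t <- if (nrow(pairs) >= 2)
    tryCatch(t.test(pairs$d_zebra, pairs$d_background, paired = TRUE),
             error = function(e) NULL) else NULL
  list(pairs = pairs, median_ratio = median(pairs$ratio), paired_t = paired_t)
}
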