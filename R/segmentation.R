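#' Define a tracked rectangular region of interest
#'
#' A body-region window analyzed across the whole series (e.g. shoulder,
#' flank, back, rump). The rectangle is given in the first image's frame as
#' 1-based inclusive (row, col, height, width); per-image integer offsets —
#' supplied manually or recovered by [track_roi()] — follow the subject
#' between exposures.
#'
#' @param label Body-region label (free text; the label set is a study
#'   convention, not fixed by the package).
#' @param row,col Top-left corner (1-based).
#' @param height,width Window size in pixels; at least 8 x 8 so the
#'   threshold has enough pixels to be stable.
#' @param per_image_offsets Optional integer matrix (n_images x 2) of
#'   (drow, dcol) per image; `NULL` means no motion.
#' @return An object of class `"roi"`.
#' @export
roi <- function(label, row, col, height, width, per_image_offsets = NULL) {
  if (height < 8 || width < 8) stop("ROI must be at least 8 x 8 px")
  if (row < 1 || col < 1) stop("ROI corner must be within the image")
  if (!is.null(per_image_offsets)) {
    per_image_offsets <- matrix(as.integer(per_image_offsets), ncol = 2)
  }
  structure(list(label = label, row = as.integer(row), col = as.integer(col),
                 height = as.integer(height), width = as.integer(width),
                 per_image_offsets = per_image_offsets),
            class = "roi")
}

# Offset of `roi` in image i (c(0, 0) when untracked)
roi_offset <- function(roi, i) {
  if (is.null(roi$per_image_offsets)) c(0L, 0L) else roi$per_image_offsets[i, ]
}

#' Extract the ROI pixel window from one image of a series
#'
#' @param series A [polarizer_series].
#' @param roi A [roi()].
#' @param i Image index.
#' @param images Optional replacement image list (e.g. blurred copies of the
#'   series frames); defaults to the series' own images.
#' @return Numeric matrix of ROI luminances.
#' @export
extract_roi <- function(series, roi, i, images = series$images) {
  off <- roi_offset(roi, i)
  rows <- roi$row + off[1] + seq_len(roi$height) - 1L
  cols <- roi$col + off[2] + seq_len(roi$width) - 1L
  d <- dim(images[[i]])
  if (rows[1] < 1 || cols[1] < 1 || rows[length(rows)] > d[1] ||
      cols[length(cols)] > d[2])
    stop(sprintf("ROI '%s' falls outside image %d after offset (%d, %d)",
                 roi$label, i, off[1], off[2]))
  images[[i]][rows, cols, drop = FALSE]
}

#' Otsu threshold over a 256-bin histogram
#'
#' Chooses the luminance cut that maximizes the between-class variance
#' \eqn{\omega_0 \omega_1 (\mu_0 - \mu_1)^2} over a 256-bin histogram of
#' the input range — equivalently, minimizes the within-stripe variance
#' relative to the black/white separation. The 256-bin granularity is used
#' regardless of bit depth, matching the behaviour of the classical
#' grayscale implementations; ties are broken toward the lower threshold.
#' Because the histogram is built on the input's own range, the threshold is
#' equivariant under positive affine rescaling of the luminances
#' (exposure-scale invariance of the segmentation).
#'
#' @param values Numeric vector (or matrix) of luminances with at least two
#'   distinct values.
#' @return The threshold, as a luminance value on the boundary between two
#'   histogram bins; pixels strictly above it form the brighter class.
#' @export
otsu_threshold <- function(values) {
  v <- as.numeric(values)
  v <- v[is.finite(v)]
  if (length(v) < 2) stop("need at least 2 values")
  lo <- min(v); hi <- max(v)
  if (lo == hi) stop("constant input: no bimodality to threshold")
  nbins <- 256L
  # bin index 1..256; right-closed cut after bin k at luminance lo + k*binw
  binw <- (hi - lo) / nbins
  idx <- pmin(floor((v - lo) / binw) + 1L, nbins)
  counts <- tabulate(idx, nbins)
  p <- counts / sum(counts)
  mids <- lo + (seq_len(nbins) - 0.5) * binw
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_tot <- mu0[nbins]
  k <- seq_len(nbins - 1L)
  valid <- w0[k] > 0 & w0[k] < 1
  bcv <- rep(-Inf, nbins - 1L)
  bcv[valid] <- (mu_tot * w0[k][valid] - mu0[k][valid])^2 /
    (w0[k][valid] * (1 - w0[k][valid]))
  kbest <- which.max(bcv)  # which.max returns the first (lowest) maximizer
  lo + kbest * binw
}

#' Segment a region of interest into black and white stripes
#'
#' Thresholds the ROI *independently in every image* of the series with
#' [otsu_threshold()] — the adaptivity that keeps the same stripes
#' identified even as their absolute luminances change with the polarizer
#' setting. The brighter class is labelled white; class identity is checked
#' for consistency against the reference image (the one with filter angle
#' closest to 0) so a class cannot swap labels between images. An ROI whose
#' threshold fails (constant luminance) or that yields an empty class in
#' any image is flagged excluded, mirroring the field practice of dropping
#' regions with luminance artifacts.
#'
#' @param series A [polarizer_series].
#' @param roi A [roi()].
#' @return An object of class `"stripe_segmentation"`: list with
#'   `per_image` (per image: `threshold`, `mask` — TRUE = white —,
#'   `frac_white`), `reference_index`, `excluded` flag and `reason`.
#' @export
segment_roi <- function(series, roi) {
  n <- length(series$images)
  ref <- which.min(abs(series$filter_angles_deg))
  per_image <- vector("list", n)
  excluded <- FALSE; reason <- NA_character_
  for (i in seq_len(n)) {
    vals <- extract_roi(series, roi, i)
    thr <- tryCatch(otsu_threshold(vals), error = function(e) NA_real_)
    if (is.na(thr)) { excluded <- TRUE; reason <- "constant luminance"; break }
    mask <- vals > thr
    if (!any(mask) || all(mask)) {
      excluded <- TRUE; reason <- "empty stripe class"; break
    }
    per_image[[i]] <- list(threshold = thr, mask = mask,
                           frac_white = mean(mask))
  }
  if (!excluded) {
    # a real striped ROI keeps a stable white fraction across the series;
    # a collapse to near-0/1 in some image signals a luminance artifact
    fw <- vapply(per_image, `[[`, numeric(1), "frac_white")
    if (any(fw < 0.05 | fw > 0.95)) {
      excluded <- TRUE; reason <- "degenerate class balance"
    }
  }
  structure(list(per_image = per_image, reference_index = ref,
                 roi = roi, excluded = excluded, reason = reason),
            class = "stripe_segmentation")
}

#' @export
print.stripe_segmentation <- function(x, ...) {
  if (x$excluded) {
    cat(sprintf("Stripe segmentation of '%s': EXCLUDED (%s)\n",
                x$roi$label, x$reason))
  } else {
    fw <- vapply(x$per_image, `[[`, numeric(1), "frac_white")
    cat(sprintf("Stripe segmentation of '%s': white fraction %.2f-%.2f across %d images\n",
                x$roi$label, min(fw), max(fw), length(x$per_image)))
  }
  invisible(x)
}

# Per-image class mean luminances for a segmented ROI. `images` may supply
# blurred frames: the *original* masks are reused verbatim, which is the
# procedure for distance-visibility analysis.
segmentation_class_means <- function(series, segmentation,
                                     images = series$images) {
  if (segmentation$excluded)
    stop("segmentation was excluded: ", segmentation$reason)
  n <- length(series$images)
  white <- numeric(n); black <- numeric(n)
  for (i in seq_len(n)) {
    vals <- extract_roi(series, segmentation$roi, i, images = images)
    m <- segmentation$per_image[[i]]$mask
    white[i] <- mean(vals[m])
    black[i] <- mean(vals[!m])
  }
  list(white = white, black = black)
}

#' Track a region of interest across the series by cross-correlation
#'
#' Recovers per-image integer offsets by maximizing the Pearson correlation
#' between the ROI patch in the first image and candidate windows within
#' `search_radius` pixels in each subsequent image — an automated stand-in
#' for matching fiduciary coat marks by hand. Manually supplied offsets in
#' the ROI remain authoritative; tracking is a convenience.
#'
#' @param series A [polarizer_series].
#' @param roi A [roi()] (its own offsets are ignored during tracking).
#' @param search_radius Maximum |offset| searched, in pixels (>= 0).
#' @return Integer matrix (n_images x 2) of recovered (drow, dcol) offsets;
#'   the first row is (0, 0). A warning is issued if any correlation peak
#'   lies on the search boundary (possible tracking failure).
#' @export
track_roi <- function(series, roi, search_radius = 5) {
  if (search_radius < 0) stop("search_radius must be >= 0")
  r <- as.integer(search_radius)
  base <- roi; base$per_image_offsets <- NULL
  template <- extract_roi(series, base, 1)
  n <- length(series$images)
  offsets <- matrix(0L, n, 2)
  at_boundary <- FALSE
  for (i in seq(2, length.out = n - 1)) {
    best <- -Inf; best_off <- c(0L, 0L)
    for (dr in -r:r) for (dc in -r:r) {
      cand <- base
      cand$per_image_offsets <- matrix(rep(c(dr, dc), each = n),
                                       n, 2)
      patch <- tryCatch(extract_roi(series, cand, i), error = function(e) NULL)
      if (is.null(patch)) next
      s <- if (sd(patch) == 0 || sd(template) == 0) -Inf
           else cor(as.numeric(template), as.numeric(patch))
      if (s > best) { best <- s; best_off <- c(dr, dc) }
    }
    offsets[i, ] <- best_off
    if (r > 0 && any(abs(best_off) == r)) at_boundary <- TRUE
  }
  if (at_boundary)
    warning("correlation peak at search boundary: possible tracking failure")
  offsets
}
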