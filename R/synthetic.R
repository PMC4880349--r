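#' Polarization specification for one surface class
#'
#' Per-pixel luminance of a surface class under the rotating polarizer
#' follows \eqn{L(\theta) = b (1 + d \sin(2(\theta + \phi)))}: mean
#' luminance `b`, degree of linear polarization `d` (the fractional
#' modulation depth) and polarization phase `phi` in the half-angle filter
#' convention (-45 degrees = horizontally polarized preponderance).
#'
#' @param mean_luminance Baseline luminance `b` (> 0, arbitrary linear units).
#' @param degree Degree of polarization `d` in \[0, 1\]. Values below 1 keep
#'   the minimum luminance positive; exactly 1 is allowed and produces a
#'   zero-luminance minimum.
#' @param phase_deg Polarization phase in \[-90, 90) degrees.
#' @return A `"stripe_class_spec"` list.
#' @export
stripe_class_spec <- function(mean_luminance, degree, phase_deg = 0) {
  if (!is.finite(mean_luminance) || mean_luminance <= 0)
    stop("mean_luminance must be positive")
  if (!is.finite(degree) || degree < 0 || degree > 1)
    stop("degree must be in [0, 1]")
  structure(list(mean_luminance = mean_luminance, degree = degree,
                 phase_deg = wrap_phase(phase_deg)),
            class = "stripe_class_spec")
}

#' Configuration of a synthetic striped scene
#'
#' Describes a striped target (hard-edged parallel black/white bands,
#' optionally feathered) centered on a vegetated background, imaged through
#' the rotating-polarizer protocol. Defaults follow the field protocol:
#' seven filter angles from -90 to +90 degrees in 30-degree steps with
#' replicated endpoints, 89.5 px/deg resolution.
#'
#' @param image_height,image_width Scene size in pixels.
#' @param stripe_period Full black+white cycle length in pixels (>= 2).
#' @param stripe_orientation_deg Stripe direction in degrees; 0 = vertical
#'   stripes (luminance varies along columns).
#' @param black_spec,white_spec,background_spec [stripe_class_spec()] for
#'   the two stripe classes and the background vegetation.
#' @param target_fraction Fraction of each image dimension covered by the
#'   centered striped target; the remainder is background.
#' @param filter_angles_deg Filter angles; must start at -90 and end at +90
#'   (the replicate endpoints).
#' @param noise_sd Additive Gaussian sensor-noise SD in luminance units,
#'   clipped at zero luminance.
#' @param feather_px Linear edge-feathering width at stripe boundaries in
#'   pixels (0 = hard edges).
#' @param pixels_per_degree,capture_distance_m Capture calibration.
#' @param seed Integer seed; identical configs render bit-identical series.
#' @return A `"scene_config"` list.
#' @export
scene_config <- function(image_height = 96, image_width = 96,
                         stripe_period = 16, stripe_orientation_deg = 0,
                         black_spec = stripe_class_spec(60, 0.3, -45),
                         white_spec = stripe_class_spec(180, 0.15, -45),
                         background_spec = stripe_class_spec(120, 0.1, -45),
                         target_fraction = 0.75,
                         filter_angles_deg = seq(-90, 90, by = 30),
                         noise_sd = 0, feather_px = 0,
                         pixels_per_degree = 89.5, capture_distance_m = 50,
                         seed = 1L) {
  if (stripe_period < 2) stop("stripe_period must be >= 2 px")
  if (stripe_period > image_width && stripe_period > image_height)
    stop("degenerate geometry: stripe_period exceeds image dimensions")
  n <- length(filter_angles_deg)
  if (n < 2 || filter_angles_deg[1] != -90 || filter_angles_deg[n] != 90)
    stop("filter_angles_deg must start at -90 and end at +90 (replicate endpoints)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (target_fraction <= 0 || target_fraction > 1)
    stop("target_fraction must be in (0, 1]")
  for (s in list(black_spec, white_spec, background_spec))
    stopifnot(inherits(s, "stripe_class_spec"))
  structure(
    list(image_height = as.integer(image_height),
         image_width = as.integer(image_width),
         stripe_period = stripe_period,
         stripe_orientation_deg = stripe_orientation_deg,
         black_spec = black_spec, white_spec = white_spec,
         background_spec = background_spec,
         target_fraction = target_fraction,
         filter_angles_deg = as.numeric(filter_angles_deg),
         noise_sd = noise_sd, feather_px = feather_px,
         pixels_per_degree = pixels_per_degree,
         capture_distance_m = capture_distance_m,
         seed = as.integer(seed)),
    class = "scene_config")
}

# Per-pixel class geometry of the scene: list with logical matrices
# `target`, `white` (within target) and the white-coverage weight map used
# for feathered edges.
scene_geometry <- function(config) {
  h <- config$image_height; w <- config$image_width
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  alpha <- deg2rad(config$stripe_orientation_deg)
  # stripe-normal coordinate; orientation 0 -> bands vary along columns
  u <- cols * cos(alpha) + rows * sin(alpha)
  p <- config$stripe_period
  s <- ((u %% p) + p) %% p
  white_hard <- s < p / 2
  f <- config$feather_px
  if (f > 0) {
    # signed distance to the nearest black/white boundary (at s = 0 and p/2)
    dist <- pmin(s, abs(s - p / 2), p - s)
    sgn <- ifelse(white_hard, 1, -1)
    wgt <- 0.5 + sgn * pmin(dist, f / 2) / f
  } else {
    wgt <- ifelse(white_hard, 1, 0)
  }
  r0 <- floor(h * (1 - config$target_fraction) / 2)
  c0 <- floor(w * (1 - config$target_fraction) / 2)
  target <- rows > r0 & rows <= h - r0 & cols > c0 & cols <= w - c0
  list(target = target, white = white_hard & target, weight = wgt)
}

# Noise-free expected luminance of a class spec at filter angle theta (deg)
class_luminance <- function(spec, theta_deg) {
  spec$mean_luminance *
    (1 + spec$degree * sin(2 * deg2rad(theta_deg + spec$phase_deg)))
}

#' Render a synthetic polarizer series with known ground truth
#'
#' Forward model: each pixel belongs to one of three classes (black stripe,
#' white stripe, background) and its expected luminance at filter angle
#' \eqn{\theta} is the class sinusoid \eqn{b(1 + d\sin(2(\theta+\phi)))};
#' additive Gaussian sensor noise (clipped at zero) is drawn independently
#' per pixel and image. Feathered stripe edges mix the two stripe sinusoids
#' linearly by boundary coverage. The returned series carries a
#' `ground_truth` attribute (class map, class specs, config) so downstream
#' stages can be tested by parameter recovery.
#'
#' @param config A [scene_config()].
#' @return A `"polarizer_series"` with attribute `ground_truth`: a list with
#'   `class_map` (character matrix, "black"/"white"/"background"),
#'   `white_mask`, `target_mask`, and `params` (the scalar generator
#'   parameters).
#' @export
render_series <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  geom <- scene_geometry(config)
  h <- config$image_height; w <- config$image_width
  set.seed(config$seed)
  images <- lapply(config$filter_angles_deg, function(theta) {
    Lb <- class_luminance(config$black_spec, theta)
    Lw <- class_luminance(config$white_spec, theta)
    Lbg <- class_luminance(config$background_spec, theta)
    im <- matrix(Lbg, h, w)
    im[geom$target] <- (geom$weight * Lw + (1 - geom$weight) * Lb)[geom$target]
    if (config$noise_sd > 0)
      im <- pmax(im + matrix(rnorm(h * w, sd = config$noise_sd), h, w), 0)
    im
  })
  class_map <- matrix("background", h, w)
  class_map[geom$target] <- "black"
  class_map[geom$white] <- "white"
  series <- polarizer_series(
    images, config$filter_angles_deg,
    pixels_per_degree = config$pixels_per_degree,
    capture_distance_m = config$capture_distance_m,
    metadata = list(synthetic = TRUE, seed = config$seed))
  attr(series, "ground_truth") <- list(
    class_map = class_map,
    white_mask = geom$white,
    target_mask = geom$target,
    params = list(
      black = unclass(config$black_spec),
      white = unclass(config$white_spec),
      background = unclass(config$background_spec),
      noise_sd = config$noise_sd, stripe_period = config$stripe_period,
      seed = config$seed))
  series
}

#' Translate each image of a series to emulate subject motion
#'
#' Shifts image `i` by integer `(drow, dcol)` offsets (content moves down /
#' right for positive offsets), replicating edge pixels into the vacated
#' margin. The injected offsets are recorded in the ground truth so that
#' [track_roi()] can be tested against them.
#'
#' @param series A `"polarizer_series"`.
#' @param offsets Integer matrix (n_images x 2) of (drow, dcol) per image.
#' @return A jittered `"polarizer_series"` with `ground_truth$offsets` set.
#' @export
render_motion_jitter <- function(series, offsets) {
  stopifnot(inherits(series, "polarizer_series"))
  offsets <- matrix(as.integer(offsets), ncol = 2)
  if (nrow(offsets) != length(series$images))
    stop("need one (drow, dcol) offset per image")
  d <- dim(series$images[[1]])
  if (any(abs(offsets[, 1]) >= d[1]) || any(abs(offsets[, 2]) >= d[2]))
    stop("offset exceeds image bounds")
  shifted <- lapply(seq_along(series$images), function(i)
    shift_matrix(series$images[[i]], offsets[i, 1], offsets[i, 2]))
  out <- series
  out$images <- shifted
  gt <- attr(series, "ground_truth") %||% list()
  gt$offsets <- offsets
  attr(out, "ground_truth") <- gt
  out
}

# Shift a matrix by (dr, dc), replicating edges into vacated margins.
shift_matrix <- function(m, dr, dc) {
  n <- nrow(m); p <- ncol(m)
  src_r <- pmin(pmax(seq_len(n) - dr, 1), n)
  src_c <- pmin(pmax(seq_len(p) - dc, 1), p)
  m[src_r, src_c, drop = FALSE]
}

#' Simulate a multi-animal cohort through the full pipeline
#'
#' Builds a cohort of synthetic zebras, each with several striped regions of
#' interest, renders every ROI's polarizer series, runs segmentation and
#' sinusoid fitting, and returns the study table — so cohort-level summary
#' statistics can be checked against the generator's ground truth. Per ROI,
#' the white-stripe degree of polarization is drawn log-normally and the
#' black-stripe degree is `d_ratio` times it (the black/white polarization
#' asymmetry); the two classes share a polarization phase up to
#' `phase_noise_sd`. For the first `n_background_pairs` zebras a paired
#' background patch with degree `zebra d / background_ratio` is analyzed
#' alongside, emulating the adjacent-vegetation comparison.
#'
#' @param n_zebras Number of animals (default 21).
#' @param rois_per_zebra Regions of interest per animal (default 7).
#' @param d_ratio Ground-truth black/white degree ratio (default 1.46).
#' @param d_white_meanlog,d_white_sdlog Log-normal parameters of the
#'   white-stripe degree across ROIs.
#' @param background_ratio Ground-truth zebra/background degree ratio
#'   (default 2).
#' @param n_background_pairs Number of zebra/background pairs (default 10).
#' @param noise_frac Sensor noise SD as a fraction of class mean luminance.
#' @param phase_noise_sd SD (degrees) of the white-minus-black phase offset.
#' @param seed Integer seed.
#' @return A list: `table` (study table data.frame, see [analyze_series()]),
#'   `background` (per-pair data.frame with zebra and background degrees),
#'   and `truth` (per-ROI generator parameters).
#' @export
simulate_cohort <- function(n_zebras = 21, rois_per_zebra = 7,
                            d_ratio = 1.46,
                            d_white_meanlog = log(0.12), d_white_sdlog = 0.4,
                            background_ratio = 2, n_background_pairs = 10,
                            noise_frac = 0.02, phase_noise_sd = 4,
                            seed = 1L) {
  set.seed(seed)
  rows <- list(); truth <- list(); bg_rows <- list()
  zebra_roi <- roi("flank", 25, 25, 24, 24)
  bg_roi <- roi("background", 1, 3, 8, 56)
  for (z in seq_len(n_zebras)) {
    for (k in seq_len(rois_per_zebra)) {
      dw <- min(exp(rnorm(1, d_white_meanlog, d_white_sdlog)), 0.6)
      db <- min(d_ratio * dw, 0.95)
      phi <- runif(1, -90, 90)
      phi_w <- phi + rnorm(1, 0, phase_noise_sd)
      bb <- 60 * exp(rnorm(1, 0, 0.1))
      bw <- 180 * exp(rnorm(1, 0, 0.1))
      d_bg <- mean(c(db, dw)) / background_ratio
      cfg <- scene_config(
        image_height = 64, image_width = 64, stripe_period = 12,
        black_spec = stripe_class_spec(bb, db, phi),
        white_spec = stripe_class_spec(bw, dw, phi_w),
        background_spec = stripe_class_spec(120, d_bg, phi),
        target_fraction = 0.72,
        noise_sd = noise_frac * mean(c(bb, bw)),
        seed = sample.int(.Machine$integer.max, 1))
      series <- render_series(cfg)
      lab <- sprintf("roi%02d", k)
      zr <- zebra_roi; zr$label <- lab
      tab <- analyze_series(series, list(zr), zebra_id = sprintf("zebra%02d", z))
      rows[[length(rows) + 1L]] <- tab
      truth[[length(truth) + 1L]] <- data.frame(
        zebra_id = sprintf("zebra%02d", z), roi_label = lab,
        d_black = db, d_white = dw, phase_black = phi,
        phase_white = wrap_phase(phi_w), d_background = d_bg)
      if (k == 1 && z <= n_background_pairs) {
        rep_bg <- background_comparison(series, list(list(zebra = zr,
                                                          background = bg_roi)))
        bg_rows[[length(bg_rows) + 1L]] <-
          cbind(zebra_id = sprintf("zebra%02d", z), rep_bg$pairs)
      }
    }
  }
  list(table = do.call(rbind, rows),
       background = do.call(rbind, bg_rows),
       truth = do.call(rbind, truth))
}
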