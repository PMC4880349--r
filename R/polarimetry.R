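#' Fit a 180-degree-period sinusoid of luminance against polarizer angle
#'
#' Fits \eqn{L(\theta) = b + a \sin(2(\theta + \phi))} by closed-form harmonic
#' regression on the basis \eqn{\{1, \sin 2\theta, \cos 2\theta\}}. The model
#' is linear in \eqn{(b, a\cos 2\phi, a\sin 2\phi)}, so the least-squares
#' optimum is exact, global and deterministic; no iterative optimizer is
#' involved.
#'
#' The phase \eqn{\phi} is reported in half-angle (polarization-angle) units
#' on \eqn{[-90, 90)} degrees with amplitude constrained non-negative: a sign
#' flip of the amplitude is equivalent to a +90 degree phase shift, which
#' makes the canonical form unique. Under the filter convention used here
#' (\eqn{\theta = \pm 90} degrees means the minimum-transmission axis of the
#' polarizer is vertical), a phase of \eqn{-45} degrees corresponds to
#' luminance peaks at \eqn{\theta = \pm 90} degrees, i.e. a preponderance of
#' horizontally polarized light; \eqn{+45} degrees indicates vertically
#' polarized light.
#'
#' `fit_r` is the Pearson correlation between fitted and observed luminances
#' (the fit-quality statistic used by the significance gate); it is 0 when
#' either the data or the fitted curve is constant.
#'
#' @param angles_deg Numeric vector of polarizer filter angles in degrees,
#'   typically the seven protocol angles `seq(-90, 90, by = 30)`.
#' @param luminances Numeric vector of luminances (linear, arbitrary scale),
#'   same length as `angles_deg`.
#' @return An object of class `"sinusoid_fit"`: a list with elements
#'   `amplitude_a`, `baseline_b`, `phase_deg`, `fit_r`, `n_points`,
#'   `degree_d` (amplitude/baseline, clipped to \[0, 1\] with a warning if the
#'   fitted minimum luminance is negative) and `clipped`.
#' @examples
#' th <- seq(-90, 90, by = 30)
#' L <- 100 + 30 * sin(2 * (th + 20) * pi / 180)
#' fit_sinusoid(th, L) # a = 30, b = 100, phi = 20, d = 0.3
#' @seealso [degree_of_polarization()], [critical_r()], [significance_gate()]
#' @export
fit_sinusoid <- function(angles_deg, luminances) {
  if (length(angles_deg) != length(luminances))
    stop("angles_deg and luminances must have the same length")
  ok <- is.finite(angles_deg) & is.finite(luminances)
  if (!all(ok)) stop("non-finite angles or luminances")
  n <- length(angles_deg)
  if (n < 4) stop("need at least 4 points to fit 3 parameters")
  X <- harmonic_design(angles_deg)
  qrX <- qr(X)
  if (qrX$rank < 3)
    stop("rank-deficient design: need at least 3 distinct filter angles (mod 180)")
  beta <- qr.coef(qrX, luminances)
  fitted <- drop(X %*% beta)
  a <- sqrt(beta[2]^2 + beta[3]^2)
  # raw sinusoid-argument phase psi in (-180, 180]; reported phase = psi / 2
  psi <- atan2(beta[3], beta[2]) * 180 / pi
  phi <- wrap_phase(psi / 2)
  r <- if (sd(fitted) == 0 || sd(luminances) == 0) 0 else cor(fitted, luminances)
  fit <- structure(
    list(amplitude_a = unname(a), baseline_b = unname(beta[1]),
         phase_deg = unname(phi), fit_r = unname(r), n_points = n,
         degree_d = NA_real_, clipped = FALSE),
    class = "sinusoid_fit")
  d <- degree_of_polarization(fit)
  fit$degree_d <- d
  fit$clipped <- attr(d, "clipped") %||% FALSE
  fit$degree_d <- as.numeric(d)
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Design matrix of the harmonic regression: columns {1, sin 2theta, cos 2theta}
harmonic_design <- function(angles_deg) {
  t2 <- 2 * deg2rad(angles_deg)
  cbind(1, sin(t2), cos(t2))
}

# Batch harmonic regression: one fit per row of Y (shared angle vector).
# Returns a data.frame with one row per series. Used by Monte-Carlo style
# parameter-recovery sweeps where thousands of 7-point fits are needed.
fit_sinusoid_batch <- function(angles_deg, Y) {
  Y <- as.matrix(Y)
  stopifnot(ncol(Y) == length(angles_deg))
  X <- harmonic_design(angles_deg)
  B <- t(solve(crossprod(X), crossprod(X, t(Y))))  # n_series x 3
  a <- sqrt(B[, 2]^2 + B[, 3]^2)
  phi <- wrap_phase(atan2(B[, 3], B[, 2]) * 180 / pi / 2)
  data.frame(amplitude_a = a, baseline_b = B[, 1], phase_deg = phi,
             degree_d = pmin(a / B[, 1], 1))
}

#' @export
print.sinusoid_fit <- function(x, ...) {
  cat(sprintf(
    "Sinusoid fit (n = %d): a = %.4g, b = %.4g, phase = %.2f deg, d = %.4f, r = %.3f\n",
    x$n_points, x$amplitude_a, x$baseline_b, x$phase_deg, x$degree_d, x$fit_r))
  invisible(x)
}

#' Degree of linear polarization from a fitted sinusoid
#'
#' Evaluates \eqn{d = (L_{max} - L_{min}) / (L_{max} + L_{min})} from the
#' extrema of the fitted curve. With \eqn{L_{max} = b + a} and
#' \eqn{L_{min} = b - a} this reduces to \eqn{d = a/b}. A value of 1 means
#' all reflected light is polarized in a single plane; 0 means the light
#' contains equal amounts of all polarization angles. The ratio is invariant
#' to global luminance scaling, so the unknown exposure scale factor cancels.
#'
#' @param fit A `"sinusoid_fit"` object (or any list with `amplitude_a` and
#'   `baseline_b`).
#' @return The degree of polarization in \[0, 1\]. If the fitted minimum
#'   luminance is negative (amplitude exceeds baseline, physically
#'   impossible), `d` is clipped to 1 with a warning and carries attribute
#'   `clipped = TRUE`.
#' @export
degree_of_polarization <- function(fit) {
  a <- fit$amplitude_a
  b <- fit$baseline_b
  if (!is.finite(b) || b <= 0) stop("baseline luminance must be positive")
  d <- a / b
  clipped <- FALSE
  if (d > 1) {
    # tolerate floating-point overshoot at exact full polarization
    if (d > 1 + 1e-9) {
      warning("fitted minimum luminance is negative; degree clipped to 1")
      clipped <- TRUE
    }
    d <- 1
  }
  structure(d, clipped = clipped)
}

#' Critical Pearson correlation for a two-tailed test
#'
#' The correlation threshold above which a Pearson r is significant at level
#' `alpha` (two-tailed) with `df` degrees of freedom, via the identity
#' \eqn{r = t / \sqrt{t^2 + df}} with \eqn{t} the upper \eqn{\alpha/2}
#' quantile of Student's t on `df`. The stripe-phase significance gate uses
#' `critical_r(0.05, 6)` = 0.707 for the seven-angle protocol.
#'
#' @param alpha Two-tailed significance level in (0, 1).
#' @param df Degrees of freedom (>= 1).
#' @return The critical correlation in (0, 1).
#' @examples
#' critical_r(0.05, 6) # 0.707
#' @export
critical_r <- function(alpha, df) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (!is.finite(df) || df < 1) stop("df must be >= 1")
  tcrit <- qt(1 - alpha / 2, df)
  tcrit / sqrt(tcrit^2 + df)
}

#' Significance gate for phase analyses
#'
#' A region of interest enters phase-based analyses only if the sinusoid fit
#' is significant for *both* stripe classes: each `fit_r` must strictly
#' exceed [critical_r()]. Phase estimates are unreliable when the degree of
#' polarization is low, which is the rationale for gating. Degrees of
#' freedom follow the printed field criterion `df = n_points - 1` (6 for the
#' seven-angle protocol); see the package vignette for a discussion of this
#' convention's calibration.
#'
#' @param black_fit,white_fit `"sinusoid_fit"` objects for the two stripe
#'   classes, fitted on the same number of points.
#' @param alpha Significance level (default 0.05).
#' @return Logical: `TRUE` if both fits pass.
#' @export
significance_gate <- function(black_fit, white_fit, alpha = 0.05) {
  if (black_fit$n_points != white_fit$n_points)
    stop("black and white fits must use the same number of points")
  rc <- critical_r(alpha, black_fit$n_points - 1)
  isTRUE(black_fit$fit_r > rc) && isTRUE(white_fit$fit_r > rc)
}

#' Circular difference between black- and white-stripe phases
#'
#' Phases live on a 180-degree-periodic domain, so the difference is the
#' shortest arc, reported in \[-90, 90) degrees. Requires both fits to pass
#' the significance gate, since low-amplitude phases are noise.
#'
#' @inheritParams significance_gate
#' @param alpha Significance level for the gate.
#' @return Signed phase difference (black minus white) in degrees.
#' @export
phase_difference <- function(black_fit, white_fit, alpha = 0.05) {
  if (!significance_gate(black_fit, white_fit, alpha))
    stop("phase difference requires both fits to pass the significance gate")
  wrap_phase(black_fit$phase_deg - white_fit$phase_deg)
}

# Ungated circular phase difference on the 180-degree domain (internal).
circ_phase_diff <- function(phi1, phi2) wrap_phase(phi1 - phi2)

#' Michelson contrast between stripe classes, averaged across filter angles
#'
#' Per image, computes \eqn{(L_{white} - L_{black}) / (L_{white} + L_{black})}
#' from the mean luminances of the two stripe classes, then averages the
#' per-image contrasts across the polarizer settings (unweighted) to give a
#' single contrast per region of interest.
#'
#' @param series A [polarizer_series] object.
#' @param segmentation A [segment_roi()] result for the region of interest.
#' @return Scalar mean Michelson contrast, with attribute `per_image` holding
#'   the contrast at each filter angle.
#' @export
michelson_contrast <- function(series, segmentation) {
  cm <- segmentation_class_means(series, segmentation)
  denom <- cm$white + cm$black
  if (any(denom == 0)) stop("zero class-mean sum: Michelson contrast undefined")
  per_image <- (cm$white - cm$black) / denom
  structure(mean(per_image), per_image = per_image)
}

#' Polarimetry of one region of interest
#'
#' Runs the full per-ROI chain: per-image class mean luminances from the
#' stripe segmentation, one sinusoid fit per stripe class across the filter
#' angles, the degree of polarization for each class, the mean Michelson
#' contrast, and the phase significance gate.
#'
#' @param series A [polarizer_series] object.
#' @param segmentation A [segment_roi()] result.
#' @param alpha Significance level for the phase gate.
#' @return A list of class `"roi_polarimetry"`: `black` and `white`
#'   `"sinusoid_fit"` objects, `michelson_contrast`, and `phase_pairable`
#'   (gate result).
#' @export
roi_polarimetry <- function(series, segmentation, alpha = 0.05) {
  cm <- segmentation_class_means(series, segmentation)
  black <- fit_sinusoid(series$filter_angles_deg, cm$black)
  white <- fit_sinusoid(series$filter_angles_deg, cm$white)
  structure(
    list(black = black, white = white,
         michelson_contrast = as.numeric(michelson_contrast(series, segmentation)),
         phase_pairable = significance_gate(black, white, alpha)),
    class = "roi_polarimetry")
}

#' @export
print.roi_polarimetry <- function(x, ...) {
  cat(sprintf("ROI polarimetry: d_black = %.4f, d_white = %.4f, contrast = %.4f, gated = %s\n",
              x$black$degree_d, x$white$degree_d, x$michelson_contrast,
              x$phase_pairable))
  invisible(x)
}
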