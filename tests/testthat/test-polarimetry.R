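test_that("harmonic regression recovers exact sinusoids to machine precision", {
  cases <- expand.grid(b = c(50, 100, 1234.5), d = c(0.05, 0.3, 0.999),
                       phi = c(-89, -45, 0, 20, 45, 89.5))
  for (i in seq_len(nrow(cases))) {
    b <- cases$b[i]; d <- cases$d[i]; phi <- cases$phi[i]
    f <- fit_sinusoid(protocol_angles, true_lum(b, d, phi))
    expect_equal(f$amplitude_a, d * b, tolerance = 1e-10)
    expect_equal(f$baseline_b, b, tolerance = 1e-10)
    expect_lt(abs(((f$phase_deg - phi + 90) %% 180) - 90), 1e-8)
    expect_equal(f$degree_d, d, tolerance = 1e-12)
    expect_equal(f$fit_r, 1, tolerance = 1e-8)
  }
})

test_that("constant luminance gives zero amplitude and d = 0", {
  f <- fit_sinusoid(protocol_angles, rep(50, 7))
  expect_equal(f$amplitude_a, 0, tolerance = 1e-12)
  expect_equal(f$baseline_b, 50)
  expect_equal(f$degree_d, 0, tolerance = 1e-12)
  expect_identical(f$fit_r, 0)
})

test_that("luminance peaking at filter +/-90 deg yields phase -45 deg", {
  L <- 100 - 30 * cos(2 * protocol_angles * pi / 180)
  expect_equal(which.max(L), c(1L))  # peaks at the endpoints
  f <- fit_sinusoid(protocol_angles, L)
  expect_equal(f$phase_deg, -45, tolerance = 1e-8)
})

test_that("fit rejects degenerate inputs", {
  expect_error(fit_sinusoid(c(0, 30), c(1, 2)), "at least 4")
  # angles 90 apart in the half-angle domain alias: only 2 distinct basis rows
  expect_error(fit_sinusoid(c(0, 0, 90, 90), c(1, 2, 1, 2)), "rank-deficient")
  expect_error(fit_sinusoid(protocol_angles, c(NA, rep(1, 6))), "non-finite")
})

test_that("degree of polarization follows the fitted-extrema formula", {
  # a = 30, b = 100: Lmax = 130, Lmin = 70, d = 60/200
  f <- fit_sinusoid(protocol_angles, true_lum(100, 0.3, 10))
  expect_equal(as.numeric(degree_of_polarization(f)), 0.3, tolerance = 1e-12)
  # Lmin = 0 (a = b): fully polarized
  f1 <- fit_sinusoid(protocol_angles, true_lum(80, 1, -30))
  expect_equal(f1$degree_d, 1, tolerance = 1e-10)
  # amplitude > baseline implies negative Lmin: warn and clip
  expect_warning(
    d <- degree_of_polarization(list(amplitude_a = 120, baseline_b = 100)),
    "clipped")
  expect_equal(as.numeric(d), 1)
  expect_error(degree_of_polarization(list(amplitude_a = 1, baseline_b = 0)),
               "positive")
})

test_that("degree of polarization is invariant to global luminance scaling", {
  set.seed(11)
  L <- true_lum(100, 0.25, 33) + rnorm(7, sd = 2)
  f1 <- fit_sinusoid(protocol_angles, L)
  f2 <- fit_sinusoid(protocol_angles, 7.3 * L)
  expect_equal(f1$degree_d, f2$degree_d, tolerance = 1e-12)
  expect_equal(f1$phase_deg, f2$phase_deg, tolerance = 1e-10)
  expect_equal(f1$fit_r, f2$fit_r, tolerance = 1e-12)
})

test_that("critical r matches the t-quantile closed form and is monotone in df", {
  expect_equal(round(critical_r(0.05, 6), 2), 0.71)
  expect_equal(critical_r(0.05, 6), 0.7067, tolerance = 1e-4)
  # direct oracle: solve P(|r| > rc) = alpha via the t transform
  t4 <- qt(0.975, 4)
  expect_equal(critical_r(0.05, 4), t4 / sqrt(t4^2 + 4))
  expect_gt(critical_r(0.05, 1), critical_r(0.05, 6))
  dfs <- c(2, 5, 10, 50, 500)
  expect_true(all(diff(sapply(dfs, critical_r, alpha = 0.05)) < 0))
  expect_lt(critical_r(0.05, 1e6), 0.01)
  expect_error(critical_r(1.2, 6), "alpha")
  expect_error(critical_r(0.05, 0), "df")
})

test_that("significance gate requires both classes to pass, strictly", {
  mkfit <- function(r) structure(list(fit_r = r, n_points = 7,
                                      phase_deg = 0), class = "sinusoid_fit")
  rc <- critical_r(0.05, 6)
  expect_true(significance_gate(mkfit(0.9), mkfit(0.8)))
  expect_false(significance_gate(mkfit(0.9), mkfit(0.5)))
  expect_false(significance_gate(mkfit(rc), mkfit(0.99)))  # at threshold fails
  expect_error(significance_gate(mkfit(0.9),
                                 structure(list(fit_r = 0.9, n_points = 5),
                                           class = "sinusoid_fit")),
               "same number")
})

test_that("phase difference is the shortest arc on the 180-degree domain", {
  mk <- function(phi) structure(list(fit_r = 0.95, n_points = 7,
                                     phase_deg = phi), class = "sinusoid_fit")
  expect_equal(phase_difference(mk(-45), mk(-45)), 0)
  # brute-force oracle: min over k of |phi_b - phi_w + 180 k|
  brute <- function(pb, pw) {
    cands <- pb - pw + 180 * (-2:2)
    cands[which.min(abs(cands))]
  }
  expect_equal(phase_difference(mk(80), mk(-80)), brute(80, -80))
  expect_equal(abs(phase_difference(mk(80), mk(-80))), 20)
  expect_equal(abs(phase_difference(mk(0), mk(90 - 1e-9))), 90,
               tolerance = 1e-6)  # antipodal: maximum possible difference
  set.seed(3)
  for (i in 1:25) {
    pb <- runif(1, -90, 90); pw <- runif(1, -90, 90)
    expect_equal(phase_difference(mk(pb), mk(pw)), brute(pb, pw),
                 tolerance = 1e-10)
  }
  lowr <- structure(list(fit_r = 0.3, n_points = 7, phase_deg = 0),
                    class = "sinusoid_fit")
  expect_error(phase_difference(mk(0), lowr), "gate")
})

test_that("harmonic regression agrees with multi-start nonlinear least squares", {
  skip_if_not_installed("minpack.lm")
  set.seed(42)
  n_cases <- 30
  for (i in seq_len(n_cases)) {
    b <- runif(1, 50, 200); d <- runif(1, 0.05, 0.8); phi <- runif(1, -90, 90)
    y <- true_lum(b, d, phi) + rnorm(7, sd = 0.02 * b)
    f <- fit_sinusoid(protocol_angles, y)
    best <- NULL; best_ss <- Inf
    for (phi0 in c(-67.5, -22.5, 22.5, 67.5)) {
      nl <- tryCatch(minpack.lm::nlsLM(
        y ~ b0 + a0 * sin(2 * (protocol_angles + p0) * pi / 180),
        start = list(b0 = mean(y), a0 = sd(y), p0 = phi0),
        control = minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15,
                                             maxiter = 500)),
        error = function(e) NULL)
      if (!is.null(nl) && sum(resid(nl)^2) < best_ss) {
        best_ss <- sum(resid(nl)^2); best <- coef(nl)
      }
    }
    expect_false(is.null(best))
    # canonicalize the NLS solution (a >= 0, phase in [-90, 90))
    a_nl <- best[["a0"]]; p_nl <- best[["p0"]]
    if (a_nl < 0) { a_nl <- -a_nl; p_nl <- p_nl + 90 }
    p_nl <- ((p_nl + 90) %% 180) - 90
    expect_equal(f$amplitude_a, a_nl, tolerance = 1e-7)
    expect_equal(f$baseline_b, best[["b0"]], tolerance = 1e-7)
    expect_lt(abs(((f$phase_deg - p_nl + 90) %% 180) - 90), 1e-5)
  }
})

test_that("pure-noise fit_r follows the Beta(1, 2) multiple-R law", {
  # fit_r is a multiple correlation with 2 harmonic regressors on n = 7
  # points, so under zero true amplitude r^2 ~ Beta(1, 2) and the printed
  # df = 6 single-class criterion passes with probability
  # (1 - 0.7067^2)^2 ~= 0.25, not alpha = 0.05; the both-classes gate
  # squares that to ~= 0.0625. The gate inherits its calibration from this
  # law, not from the nominal alpha.
  set.seed(99)
  nrep <- 4000
  Y <- matrix(rnorm(nrep * 7, mean = 100, sd = 5), nrep, 7)
  r <- apply(Y, 1, function(y) fit_sinusoid(protocol_angles, y)$fit_r)
  rc <- critical_r(0.05, 6)
  p_single <- mean(r > rc)
  p_theory <- (1 - rc^2)^2
  expect_equal(p_single, p_theory, tolerance = 0.1)
  se3 <- 3 * sqrt(p_theory * (1 - p_theory) / nrep)
  expect_lt(abs(p_single - p_theory), se3)
  # both-classes gate: pair independent replicates
  gate <- r[seq(1, nrep, 2)] > rc & r[seq(2, nrep, 2)] > rc
  expect_equal(mean(gate), p_theory^2, tolerance = 0.25)
})

test_that("Michelson contrast averages per-angle class contrasts", {
  s <- demo_scene()
  seg <- segment_roi(s, demo_roi())
  mc <- michelson_contrast(s, seg)
  # closed-form oracle from the generator parameters
  Lw <- true_lum(180, 0.15, -45); Lb <- true_lum(60, 0.3, -45)
  expect_equal(as.numeric(mc), mean((Lw - Lb) / (Lw + Lb)), tolerance = 1e-10)
  expect_length(attr(mc, "per_image"), 7)
  # equal classes -> zero contrast at every angle
  fake_seg <- seg
  s0 <- s; s0$images <- lapply(s0$images, function(im) im * 0 + 100)
  expect_equal(as.numeric(michelson_contrast(s0, fake_seg)), 0)
})

test_that("Monte-Carlo parameter recovery: d accurate, phase degrades as d -> 0", {
  set.seed(5)
  grid <- expand.grid(d = c(0.05, 0.1, 0.2, 0.4), phi = c(-90, -45, 0, 45))
  b <- 100; nrep <- 200
  med_d_err <- med_phi_err <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    mu <- true_lum(b, grid$d[i], grid$phi[i])
    Y <- matrix(rep(mu, each = nrep), nrep, 7) +
      matrix(rnorm(nrep * 7, sd = 0.02 * b), nrep, 7)
    fits <- polstripe:::fit_sinusoid_batch(protocol_angles, Y)
    med_d_err[i] <- median(abs(fits$degree_d - grid$d[i]))
    med_phi_err[i] <- median(abs(((fits$phase_deg - grid$phi[i] + 90) %% 180) - 90))
  }
  expect_true(all(med_d_err <= 0.02))
  expect_true(all(med_phi_err[grid$d >= 0.1] <= 5))
  # phase error inflates as d -> 0 (the rationale for the significance gate)
  for (phi in unique(grid$phi)) {
    sel <- grid$phi == phi
    expect_gt(med_phi_err[sel & grid$d == 0.05][1],
              med_phi_err[sel & grid$d == 0.4][1])
  }
})
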