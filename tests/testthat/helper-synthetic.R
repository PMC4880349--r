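# Shared fixtures built in code.

protocol_angles <- seq(-90, 90, by = 30)

# Noise-free expected class luminance at the protocol angles
true_lum <- function(b, d, phi_deg, angles = protocol_angles) {
  b * (1 + d * sin(2 * (angles + phi_deg) * pi / 180))
}

# A small noise-free striped scene with distinct class parameters
demo_scene <- function(noise_sd = 0, seed = 7, ...) {
  render_series(scene_config(
    image_height = 96, image_width = 96, stripe_period = 16,
    black_spec = stripe_class_spec(60, 0.3, -45),
    white_spec = stripe_class_spec(180, 0.15, -45),
    background_spec = stripe_class_spec(120, 0.1, -45),
    noise_sd = noise_sd, seed = seed, ...))
}

demo_roi <- function() roi("flank", 20, 20, 40, 40)

# Brute-force between-class-variance maximizer: bins values into the
# standard 256-level histogram (values represented by bin midpoints), then
# evaluates sigma_B^2 = w0 w1 (mu0 - mu1)^2 independently at every cut by
# direct group means — no cumulative-moment recursion shared with the
# implementation.
otsu_brute <- function(v) {
  v <- as.numeric(v)
  lo <- min(v); hi <- max(v)
  binw <- (hi - lo) / 256
  mid <- lo + (pmin(floor((v - lo) / binw), 255) + 0.5) * binw
  cuts <- lo + seq_len(255) * binw
  bcv <- vapply(cuts, function(ct) {
    g1 <- mid[mid < ct]; g2 <- mid[mid > ct]
    if (!length(g1) || !length(g2)) return(-Inf)
    w1 <- length(g1) / length(mid)
    w1 * (1 - w1) * (mean(g1) - mean(g2))^2
  }, numeric(1))
  cuts[which.max(bcv)]
}
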