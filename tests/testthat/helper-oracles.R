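# Independent oracles and small fixture builders shared across tests.
# Oracles deliberately re-derive quantities from first principles rather
# than calling the implementation under test.

# A straight, axis-aligned, noiseless, hard-edged tube.
straight_truth <- function(y0 = 50, radius = 5, tube = 100, bg = 10,
                           width = 200, height = 120, lesions = list(),
                           noise = 0, seed = 1L, bits = 8) {
  ground_truth(
    tube_model(image_height = height, image_width = width,
               centerline_coeffs = y0, tube_radius = radius,
               tube_intensity = tube, background_intensity = bg,
               edge_softness = 0, bit_depth = bits),
    lesions, noise_sigma = noise, seed = seed)
}

# Default 16-bit study-scale tube used by pipeline-level tests.
study_truth <- function(coeffs = 60, lesions = list(), noise = 0, seed = 1L,
                        soft = 0) {
  ground_truth(
    tube_model(centerline_coeffs = coeffs, edge_softness = soft),
    lesions, noise_sigma = noise, seed = seed)
}

# Brute-force bilinear interpolation, written independently of the package
# (different algebraic arrangement; explicit corner clamping).
oracle_bilinear <- function(img, x, y) {
  H <- nrow(img); W <- ncol(img)
  vapply(seq_along(x), function(i) {
    xa <- floor(x[i]); ya <- floor(y[i])
    xb <- min(xa + 1, W - 1); yb <- min(ya + 1, H - 1)
    u <- x[i] - xa; v <- y[i] - ya
    p00 <- img[ya + 1, xa + 1]; p01 <- img[ya + 1, xb + 1]
    p10 <- img[yb + 1, xa + 1]; p11 <- img[yb + 1, xb + 1]
    top <- p00 + u * (p01 - p00)
    bot <- p10 + u * (p11 - p10)
    top + v * (bot - top)
  }, numeric(1))
}

# Hand-written mid-rank Kruskal-Wallis H with tie correction.
oracle_kw_h <- function(values, groups) {
  g <- factor(groups)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, g, mean)
  n <- tabulate(g)
  h <- 12 / (N * (N + 1)) * sum(n * rbar^2) - 3 * (N + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Random polynomial centerline (degree <= 6) kept inside the valid band of
# the default 512 x 120 frame; coefficients constructed in u = x / W then
# converted to pixel units.
random_true_poly <- function(height = 120, width = 512, radius = 10) {
  repeat {
    a <- c(60 + runif(1, -5, 5), runif(6, -1, 1) * 8 / (1:6))
    coeffs <- a / width^(0:6)
    tb <- tube_model(image_height = height, image_width = width,
                     centerline_coeffs = coeffs, tube_radius = radius)
    xs <- seq(0, width - 1, by = 0.5)
    y <- vapply(xs, function(x) sum(coeffs * x^(0:6)), numeric(1))
    if (all(y >= radius) && all(y <= height - 1 - radius)) return(tb)
  }
}

# Build an nq_profile directly from a vector (for peak-caller tests that
# do not need an image).
as_profile <- function(v, step = 1) {
  structure(list(arc_positions = seq_along(v) - 1, intensities = as.numeric(v),
                 x = seq_along(v) - 1, y = rep(0, length(v)),
                 sampling_step = step, linewidth = 1L, n_dropped = 0L),
            class = "nq_profile")
}
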