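# Synthetic-data generator: notochord fluorescence images with known ground
# truth, RGB histology rasters, and skeletal count tables. The generator is
# the oracle for every downstream recovery test: each image is fully
# determined by its GroundTruth (tube geometry, lesion list, noise model,
# seed), so the pipeline's output can be compared with what was put in.

#' Describe the notochord tube of a synthetic image
#'
#' The notochord is modelled as a bright hard-edged tube on a dim
#' background: pixel (x, y) is inside the tube when `|y - f(x)| <= r`,
#' where `f` is a polynomial centerline (y as a function of x, pixel
#' units, 0-based coordinates) and `r` the tube radius. `edge_softness`
#' optionally blurs the noiseless image with a Gaussian kernel so the tube
#' edge falls off smoothly, as in real stereomicroscope images.
#'
#' Default intensities are on a 16-bit scale: background 500, tube 10000,
#' in a 512 x 120 frame with a straight centerline at mid-height.
#'
#' @param image_height,image_width frame size in pixels.
#' @param centerline_coeffs ascending polynomial coefficients of the
#'   centerline `y(x) = c0 + c1 x + ...` (pixel units).
#' @param tube_radius tube half-width in pixels (> 0).
#' @param tube_intensity,background_intensity grey values; tube must be
#'   brighter than background.
#' @param edge_softness Gaussian blur sigma (pixels, >= 0) applied to the
#'   noiseless image.
#' @param bit_depth 8 or 16; grey values are clipped to `[0, 2^bit_depth-1]`.
#' @return an object of class `nq_tube`.
#' @export
tube_model <- function(image_height = 120, image_width = 512,
                       centerline_coeffs = 60, tube_radius = 10,
                       tube_intensity = 10000, background_intensity = 500,
                       edge_softness = 0, bit_depth = 16) {
  stopifnot(image_height >= 3, image_width >= 3, tube_radius > 0,
            edge_softness >= 0, bit_depth %in% c(8L, 16L))
  if (tube_intensity <= background_intensity)
    nq_error("nq_value_error", "tube_intensity must exceed background_intensity")
  structure(list(image_height = as.integer(image_height),
                 image_width = as.integer(image_width),
                 centerline_coeffs = as.numeric(centerline_coeffs),
                 tube_radius = as.numeric(tube_radius),
                 tube_intensity = as.numeric(tube_intensity),
                 background_intensity = as.numeric(background_intensity),
                 edge_softness = as.numeric(edge_softness),
                 bit_depth = as.integer(bit_depth)),
            class = "nq_tube")
}

#' Describe one synthetic lesion
#'
#' A lesion is a localized intensity elevation inside the tube: it adds
#' `amplitude * exp(-(x - center_x)^2 / (2 * width_sigma^2))` to every
#' in-tube pixel at column x (lesions are a feature of the notochord, so
#' they never brighten the background), producing the "higher pixel
#' intensity and broader area under the peak" signature on the extracted
#' profile.
#'
#' @param center_x lesion center (pixels, along x).
#' @param amplitude added grey value at the center (> 0).
#' @param width_sigma Gaussian width in pixels (> 0).
#' @export
lesion_spec <- function(center_x, amplitude, width_sigma) {
  stopifnot(is.numeric(center_x), amplitude > 0, width_sigma > 0)
  structure(list(center_x = as.numeric(center_x),
                 amplitude = as.numeric(amplitude),
                 width_sigma = as.numeric(width_sigma)),
            class = "nq_lesion")
}

#' Full generating description of one synthetic fish image
#'
#' Bundles tube geometry, lesion list, additive Gaussian pixel noise
#' (sigma in grey values, applied after blurring, then rounded to integers
#' and clipped to the bit depth) and the RNG seed. Two identical ground
#' truths always render to bit-identical images.
#'
#' @param tube a [tube_model()].
#' @param lesions list of [lesion_spec()] objects (possibly empty).
#' @param noise_sigma grey-value standard deviation of the pixel noise.
#' @param seed integer seed for the noise draw.
#' @export
ground_truth <- function(tube, lesions = list(), noise_sigma = 0, seed = 1L) {
  stopifnot(inherits(tube, "nq_tube"), noise_sigma >= 0)
  if (inherits(lesions, "nq_lesion")) lesions <- list(lesions)
  for (l in lesions) {
    stopifnot(inherits(l, "nq_lesion"))
    if (l$center_x < 0 || l$center_x >= tube$image_width)
      nq_error("nq_value_error", "lesion center_x outside the image")
  }
  structure(list(tube = tube, lesions = lesions,
                 noise_sigma = as.numeric(noise_sigma),
                 seed = as.integer(seed)),
            class = "nq_truth")
}

check_geometry <- function(tube) {
  xs <- seq(0, tube$image_width - 1, by = 0.5)
  y <- poly_eval(tube$centerline_coeffs, xs)
  lo <- tube$tube_radius
  hi <- tube$image_height - 1 - tube$tube_radius
  if (any(!is.finite(y)) || any(y < lo) || any(y > hi))
    nq_error("nq_geometry_error", sprintf(
      "centerline leaves the valid band [%g, %g] (range [%g, %g])",
      lo, hi, min(y), max(y)))
  invisible(TRUE)
}

# Separable Gaussian blur, replicate padding; kernel radius 3*sigma.
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  blur1d <- function(v) {
    padded <- c(rep(v[1], r), v, rep(v[length(v)], r))
    out <- numeric(length(v))
    for (j in seq_along(k)) out <- out + k[j] * padded[j:(j + length(v) - 1)]
    out
  }
  m <- apply(m, 2, blur1d)
  t(apply(m, 1, blur1d))
}

#' Render a synthetic notochord image from its ground truth
#'
#' Renders background, paints in-tube pixels at the tube intensity, adds
#' each lesion's Gaussian bump to in-tube pixels, optionally blurs
#' (`edge_softness`), adds Gaussian pixel noise from the stored seed,
#' rounds to integer grey values and clips to the bit depth. Identical
#' ground truths give bit-identical images.
#'
#' @param truth a [ground_truth()].
#' @return integer matrix of class `nq_image` (rows = y, cols = x) with a
#'   `bit_depth` attribute.
#' @export
generate_notochord_image <- function(truth) {
  stopifnot(inherits(truth, "nq_truth"))
  tube <- truth$tube
  check_geometry(tube)
  H <- tube$image_height; W <- tube$image_width
  xs <- 0:(W - 1)
  f <- poly_eval(tube$centerline_coeffs, xs)
  yy <- matrix(0:(H - 1), nrow = H, ncol = W)
  cc <- matrix(f, nrow = H, ncol = W, byrow = TRUE)
  inside <- abs(yy - cc) <= tube$tube_radius
  img <- matrix(tube$background_intensity, H, W)
  img[inside] <- tube$tube_intensity
  if (length(truth$lesions)) {
    bump <- rep(0, W)
    for (l in truth$lesions)
      bump <- bump + l$amplitude * exp(-(xs - l$center_x)^2 / (2 * l$width_sigma^2))
    add <- matrix(bump, nrow = H, ncol = W, byrow = TRUE)
    img <- img + add * inside
  }
  img <- gaussian_blur(img, tube$edge_softness)
  if (truth$noise_sigma > 0)
    img <- img + with_seed(truth$seed, matrix(rnorm(H * W, 0, truth$noise_sigma), H, W))
  maxval <- 2^tube$bit_depth - 1
  img <- pmin(pmax(round(img), 0), maxval)
  structure(img, bit_depth = tube$bit_depth, class = c("nq_image", class(img)))
}

#' Enumerate the ground-truth tube pixels
#'
#' The set of (x, y) pixel coordinates inside the tube, the oracle against
#' which thresholded masks are compared.
#'
#' @param tube a [tube_model()] (or a [ground_truth()], whose tube is used).
#' @return data.frame with columns `x`, `y` (0-based).
#' @export
tube_pixels <- function(tube) {
  if (inherits(tube, "nq_truth")) tube <- tube$tube
  stopifnot(inherits(tube, "nq_tube"))
  xs <- 0:(tube$image_width - 1)
  f <- poly_eval(tube$centerline_coeffs, xs)
  out <- lapply(seq_along(xs), function(i) {
    ys <- seq(ceiling(f[i] - tube$tube_radius), floor(f[i] + tube$tube_radius))
    ys <- ys[ys >= 0 & ys < tube$image_height]
    if (!length(ys)) return(NULL)
    data.frame(x = xs[i], y = ys)
  })
  do.call(rbind, out)
}

# ---- distributions for cohort / count specs ---------------------------------

#' Distribution specifications for cohort generators
#'
#' Small tagged lists used wherever a cohort or count spec needs "a
#' distribution": a degenerate constant, a Poisson count, or a continuous
#' uniform range.
#'
#' @param value,lambda,lo,hi distribution parameters; `lambda >= 0`.
#' @return a list with a `dist` tag, consumed by [generate_cohort()] and
#'   [generate_skeletal_counts()].
#' @export
dist_constant <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1, value >= 0)
  list(dist = "constant", value = value)
}

#' @rdname dist_constant
#' @export
dist_poisson <- function(lambda) {
  if (!is.numeric(lambda) || lambda < 0)
    nq_error("nq_value_error", "Poisson rate must be nonnegative")
  list(dist = "poisson", lambda = lambda)
}

#' @rdname dist_constant
#' @export
dist_uniform <- function(lo, hi) {
  stopifnot(lo <= hi)
  list(dist = "uniform", lo = lo, hi = hi)
}

draw_dist <- function(d, n = 1) {
  switch(d$dist,
         constant = rep(d$value, n),
         poisson = rpois(n, d$lambda),
         uniform = runif(n, d$lo, d$hi),
         nq_error("nq_value_error", paste("unknown distribution:", d$dist)))
}

#' Describe one experimental group of a synthetic cohort
#'
#' @param label group label.
#' @param n_fish number of fish (>= 1).
#' @param n_lesions lesion-count distribution ([dist_constant()] or
#'   [dist_poisson()]).
#' @param amplitude lesion amplitude distribution (grey values).
#' @param width_sigma lesion width distribution (pixels).
#' @export
group_spec <- function(label, n_fish, n_lesions = dist_constant(0),
                       amplitude = dist_uniform(4000, 8000),
                       width_sigma = dist_constant(6)) {
  stopifnot(is.character(label), n_fish >= 1)
  list(label = label, n_fish = as.integer(n_fish), n_lesions = n_lesions,
       amplitude = amplitude, width_sigma = width_sigma)
}

#' Describe a synthetic multi-group cohort
#'
#' Groups share the frame, tube intensity and noise model; each fish gets
#' its own RNG stream derived deterministically from the cohort seed and
#' the fish index, so adding fish or groups never reshuffles earlier fish.
#' Per fish, the centerline is a gentle random cubic (bounded so the tube
#' stays in frame) and lesion centers are placed uniformly with a minimum
#' spacing and an edge margin.
#'
#' @param groups list of [group_spec()] objects (>= 1).
#' @param tube template [tube_model()]; its centerline is re-drawn per fish
#'   unless `jitter_centerline = FALSE`.
#' @param noise_sigma pixel-noise sigma (grey values).
#' @param min_spacing minimum distance between lesion centers (pixels).
#' @param margin lesion-free margin at either end of the frame (pixels).
#' @param jitter_centerline draw a random per-fish centerline?
#' @param seed cohort seed.
#' @export
cohort_spec <- function(groups, tube = tube_model(edge_softness = 1),
                        noise_sigma = 400, min_spacing = 40, margin = 30,
                        jitter_centerline = TRUE, seed = 1L) {
  if (!length(groups)) nq_error("nq_value_error", "empty group list")
  for (g in groups) stopifnot(is.list(g), !is.null(g$label))
  structure(list(groups = groups, tube = tube, noise_sigma = noise_sigma,
                 min_spacing = min_spacing, margin = margin,
                 jitter_centerline = isTRUE(jitter_centerline),
                 seed = as.integer(seed)),
            class = "nq_cohort_spec")
}

# Random gentle cubic centerline in the middle band of the frame, retried
# until the geometry invariant holds.
random_centerline <- function(tube, max_tries = 50) {
  H <- tube$image_height; W <- tube$image_width
  for (i in seq_len(max_tries)) {
    a <- runif(3, -1, 1) * c(8, 10, 8)
    # coefficients in u = x/W, converted to pixel units
    coeffs <- c(H / 2 + runif(1, -5, 5), a[1] / W, a[2] / W^2, a[3] / W^3)
    cand <- tube
    cand$centerline_coeffs <- coeffs
    ok <- tryCatch({ check_geometry(cand); TRUE },
                   nq_geometry_error = function(e) FALSE)
    if (ok) return(coeffs)
  }
  tube$centerline_coeffs
}

# Lesion centers with minimum spacing inside [margin, W-1-margin].
place_lesion_centers <- function(n, width, margin, min_spacing,
                                 max_tries = 200) {
  if (n == 0) return(numeric(0))
  lo <- margin; hi <- width - 1 - margin
  centers <- numeric(0)
  tries <- 0
  while (length(centers) < n && tries < max_tries) {
    cand <- runif(1, lo, hi)
    if (!length(centers) || min(abs(centers - cand)) >= min_spacing)
      centers <- c(centers, cand)
    tries <- tries + 1
  }
  sort(centers)
}

#' Generate a synthetic cohort of fish images with ground truth
#'
#' @param spec a [cohort_spec()].
#' @return list with one element per fish: `fish_id`, `group`, `image`
#'   (class `nq_image`) and `truth` (class `nq_truth`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "nq_cohort_spec"))
  out <- list()
  idx <- 0L
  for (g in spec$groups) {
    for (i in seq_len(g$n_fish)) {
      idx <- idx + 1L
      fish_seed <- derive_seed(spec$seed, idx)
      truth <- with_seed(fish_seed, {
        tube <- spec$tube
        if (spec$jitter_centerline)
          tube$centerline_coeffs <- random_centerline(tube)
        n_les <- draw_dist(g$n_lesions)
        centers <- place_lesion_centers(n_les, tube$image_width,
                                        spec$margin, spec$min_spacing)
        lesions <- lapply(centers, function(cx)
          lesion_spec(cx, draw_dist(g$amplitude), draw_dist(g$width_sigma)))
        ground_truth(tube, lesions, noise_sigma = spec$noise_sigma,
                     seed = derive_seed(fish_seed, 1L))
      })
      out[[idx]] <- list(
        fish_id = sprintf("%s_%03d", g$label, i),
        group = g$label,
        image = generate_notochord_image(truth),
        truth = truth)
    }
  }
  out
}

# ---- ground-truth serialisation ---------------------------------------------

#' Serialise / deserialise a ground truth as JSON
#'
#' Round-trippable: `truth_from_json(truth_to_json(t))` reproduces `t`
#' exactly (all fields are doubles or integers).
#'
#' @param truth a [ground_truth()].
#' @param path file path; for `truth_to_json` optional (returns the JSON
#'   string when `NULL`).
#' @export
truth_to_json <- function(truth, path = NULL) {
  stopifnot(inherits(truth, "nq_truth"))
  x <- list(
    tube = unclass(truth$tube),
    lesions = lapply(truth$lesions, unclass),
    noise_sigma = truth$noise_sigma,
    seed = truth$seed)
  js <- jsonlite::toJSON(x, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' @rdname truth_to_json
#' @export
truth_from_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  tube <- do.call(tube_model, x$tube)
  lesions <- lapply(x$lesions, function(l) do.call(lesion_spec, l))
  ground_truth(tube, lesions, noise_sigma = x$noise_sigma, seed = x$seed)
}

# ---- RGB histology ----------------------------------------------------------

#' Generate a synthetic RGB histology image
#'
#' Paints rectangular labelled regions with requested per-channel means on
#' a uniform background, optionally adding Gaussian channel noise; the
#' noiseless channel mean over each region equals the requested value
#' exactly. Stand-in for stained-section photographs used in channel-mean
#' quantification.
#'
#' @param regions data.frame with columns `x0`, `x1`, `y0`, `y1` (0-based,
#'   inclusive) and `red`, `green`, `blue` (grey values); regions must not
#'   overlap.
#' @param width,height image size.
#' @param background length-3 background RGB.
#' @param noise_sigma Gaussian channel-noise sigma (grey values).
#' @param seed RNG seed.
#' @param bit_depth 8 or 16.
#' @return numeric array `height x width x 3`.
#' @export
generate_rgb_histology <- function(regions, width = 128, height = 128,
                                   background = c(0, 0, 0), noise_sigma = 0,
                                   seed = 1L, bit_depth = 8) {
  stopifnot(is.data.frame(regions),
            all(c("x0", "x1", "y0", "y1", "red", "green", "blue") %in%
                  names(regions)))
  maxval <- 2^bit_depth - 1
  if (any(regions[c("red", "green", "blue")] < 0) ||
      any(regions[c("red", "green", "blue")] > maxval))
    nq_error("nq_value_error", "channel means outside bit depth")
  occ <- matrix(FALSE, height, width)
  img <- array(rep(background, each = height * width), c(height, width, 3))
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    rows <- (r$y0:r$y1) + 1; cols <- (r$x0:r$x1) + 1
    if (any(rows < 1) || any(rows > height) || any(cols < 1) || any(cols > width))
      nq_error("nq_value_error", sprintf("region %d out of bounds", i))
    if (any(occ[rows, cols]))
      nq_error("nq_value_error", sprintf("region %d overlaps another region", i))
    occ[rows, cols] <- TRUE
    img[rows, cols, 1] <- r$red
    img[rows, cols, 2] <- r$green
    img[rows, cols, 3] <- r$blue
  }
  if (noise_sigma > 0) {
    img <- img + with_seed(seed, array(rnorm(length(img), 0, noise_sigma), dim(img)))
    img <- pmin(pmax(round(img), 0), maxval)
  }
  structure(img, bit_depth = as.integer(bit_depth))
}

# ---- skeletal count tables --------------------------------------------------

#' Generate a synthetic table of per-fish fusion and cleft counts
#'
#' Fixture generator for the vertebral severity rubric: draws nonnegative
#' integer fusion and cleft counts per fish from the stated distributions.
#'
#' @param groups list of lists with `label`, `n_fish`, `fusions`, `clefts`
#'   (the last two are [dist_constant()] or [dist_poisson()] specs).
#' @param seed RNG seed.
#' @return data.frame (fish_id, group, fusions, clefts).
#' @export
generate_skeletal_counts <- function(groups, seed = 1L) {
  if (!length(groups)) nq_error("nq_value_error", "empty group list")
  rows <- with_seed(seed, {
    out <- list()
    for (g in groups) {
      fus <- draw_dist(g$fusions, g$n_fish)
      cle <- draw_dist(g$clefts, g$n_fish)
      out[[length(out) + 1]] <- data.frame(
        fish_id = sprintf("%s_%03d", g$label, seq_len(g$n_fish)),
        group = g$label,
        fusions = as.integer(fus), clefts = as.integer(cle))
    }
    out
  })
  do.call(rbind, rows)
}
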