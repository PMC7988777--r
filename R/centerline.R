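# Step two of the pipeline: model the notochord axis as a degree-6
# polynomial fitted to the segmented pixels, then sample the image along
# that curve at uniform arc-length spacing. The profile extractor is a
# profile-line sampler generalised from a straight segment to a polynomial
# path: bilinear interpolation at each arc-length sample, optionally
# averaged across the local normal.

#' Fit a polynomial centerline to a notochord mask
#'
#' Ordinary least squares of y on powers of x over all mask pixels
#' (unweighted, one term per pixel). For conditioning the fit is computed
#' on x rescaled to \[-1, 1\]; returned coefficients are in pixel units.
#'
#' @param mask an `nq_mask`.
#' @param degree polynomial degree (default 6).
#' @return object of class `nq_centerline`: `degree`, `coefficients`
#'   (ascending, pixel units), `x_domain` (range of mask x), `rms_residual`.
#' @export
fit_polynomial_centerline <- function(mask, degree = 6) {
  stopifnot(inherits(mask, "nq_mask"), degree >= 0)
  x <- mask$coords$x; y <- mask$coords$y
  ux <- unique(x)
  if (length(ux) < degree + 1)
    nq_error("nq_fit_error", sprintf(
      "under-determined fit: %d distinct x values for degree %d (need >= %d)",
      length(ux), degree, degree + 1))
  a <- min(x); b <- max(x)
  t <- (2 * x - (a + b)) / (b - a)
  V <- outer(t, 0:degree, "^")
  qrv <- qr(V)
  if (qrv$rank < degree + 1)
    nq_error("nq_fit_error", "rank-deficient design matrix in centerline fit")
  d <- qr.coef(qrv, y)
  # convert from t = alpha*x + beta back to pixel units
  alpha <- 2 / (b - a); beta <- -(a + b) / (b - a)
  coeffs <- poly_compose_affine(as.numeric(d), alpha, beta)
  fitted <- V %*% d
  structure(list(degree = as.integer(degree),
                 coefficients = coeffs,
                 coefficients_scaled = as.numeric(d),
                 x_domain = c(a, b),
                 rms_residual = sqrt(mean((y - fitted)^2))),
            class = "nq_centerline")
}

#' Evaluate a fitted centerline
#'
#' @param curve an `nq_centerline`.
#' @param x x coordinates (pixels).
#' @return predicted y (pixels). Evaluation uses the conditioned
#'   \[-1, 1\]-rescaled form of the fit.
#' @export
centerline_predict <- function(curve, x) {
  stopifnot(inherits(curve, "nq_centerline"))
  a <- curve$x_domain[1]; b <- curve$x_domain[2]
  poly_eval(curve$coefficients_scaled, (2 * x - (a + b)) / (b - a))
}

#' Uniform arc-length samples along a polynomial centerline
#'
#' Samples the curve y = f(x) over its x domain at uniform arc-length
#' spacing `step`: the curve is first discretised densely in x (`subdiv`
#' subdivisions per pixel), cumulative chord length gives arc length as a
#' function of x, and linear inversion places the samples. The unit
#' tangent comes from the analytic derivative.
#'
#' @param curve an `nq_centerline`.
#' @param step arc-length spacing in pixels (> 0).
#' @param subdiv dense subdivisions per pixel of x (>= 10).
#' @return data.frame (arc, x, y, tx, ty); `arc` starts at 0 and increases
#'   by `step`.
#' @export
arc_length_samples <- function(curve, step = 1, subdiv = 50) {
  stopifnot(inherits(curve, "nq_centerline"), step > 0, subdiv >= 10)
  a <- curve$x_domain[1]; b <- curve$x_domain[2]
  if (!(b > a)) nq_error("nq_value_error", "degenerate x domain")
  xs <- seq(a, b, length.out = max(2, ceiling((b - a) * subdiv)) + 1)
  ys <- centerline_predict(curve, xs)
  seg <- sqrt(diff(xs)^2 + diff(ys)^2)
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  targets <- seq(0, total, by = step)
  xt <- approx(s, xs, xout = targets, ties = "ordered")$y
  yt <- centerline_predict(curve, xt)
  # tangent from dy/dx in the rescaled coordinate (chain rule)
  alpha <- 2 / (b - a)
  dydx <- poly_eval(poly_deriv(curve$coefficients_scaled),
                    (2 * xt - (a + b)) / (b - a)) * alpha
  norm <- sqrt(1 + dydx^2)
  data.frame(arc = targets, x = xt, y = yt, tx = 1 / norm, ty = dydx / norm)
}

#' Total arc length of a centerline over its domain
#'
#' @inheritParams arc_length_samples
#' @export
arc_length_total <- function(curve, subdiv = 50) {
  a <- curve$x_domain[1]; b <- curve$x_domain[2]
  xs <- seq(a, b, length.out = max(2, ceiling((b - a) * subdiv)) + 1)
  ys <- centerline_predict(curve, xs)
  sum(sqrt(diff(xs)^2 + diff(ys)^2))
}

# Bilinear interpolation at 0-based (x, y); callers guarantee in-bounds.
bilinear_at <- function(image, x, y) {
  H <- nrow(image); W <- ncol(image)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  x1 <- pmin(x0 + 1, W - 1); y1 <- pmin(y0 + 1, H - 1)
  i00 <- image[cbind(y0 + 1, x0 + 1)]
  i01 <- image[cbind(y0 + 1, x1 + 1)]
  i10 <- image[cbind(y1 + 1, x0 + 1)]
  i11 <- image[cbind(y1 + 1, x1 + 1)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

#' Extract the intensity profile along a fitted centerline
#'
#' At each uniform arc-length sample the intensity is read by bilinear
#' interpolation at the curve point (`linewidth = 1`), or as the mean of
#' `linewidth` bilinear samples spaced 1 px along the local normal and
#' centered on the curve (`linewidth` must be odd). Samples falling outside
#' the image (any of their normal subsamples out of bounds) are dropped,
#' not clamped; the number dropped is recorded.
#'
#' @param image numeric matrix.
#' @param curve an `nq_centerline` whose x domain overlaps the image.
#' @param step arc-length sampling step in pixels (default 1).
#' @param linewidth odd number of normal samples averaged per point
#'   (default 1).
#' @return object of class `nq_profile`: `arc_positions`, `intensities`,
#'   `sampling_step`, `linewidth`, `n_dropped`, and the sampled `x`, `y`.
#' @export
extract_profile <- function(image, curve, step = 1, linewidth = 1) {
  stopifnot(is.matrix(image), inherits(curve, "nq_centerline"), step > 0)
  if (linewidth < 1 || linewidth %% 2 != 1)
    nq_error("nq_value_error", "linewidth must be odd and >= 1")
  H <- nrow(image); W <- ncol(image)
  pts <- arc_length_samples(curve, step = step)
  offs <- seq(-(linewidth - 1) / 2, (linewidth - 1) / 2)
  ok <- rep(TRUE, nrow(pts))
  acc <- matrix(NA_real_, nrow(pts), length(offs))
  for (j in seq_along(offs)) {
    sx <- pts$x - offs[j] * pts$ty   # unit normal is (-ty, tx)
    sy <- pts$y + offs[j] * pts$tx
    inb <- sx >= 0 & sx <= W - 1 & sy >= 0 & sy <= H - 1
    ok <- ok & inb
    acc[inb, j] <- bilinear_at(image, sx[inb], sy[inb])
  }
  if (!any(ok))
    nq_error("nq_profile_error", "all profile samples fall outside the image")
  vals <- rowMeans(acc)[ok]
  structure(list(arc_positions = pts$arc[ok],
                 intensities = as.numeric(vals),
                 x = pts$x[ok], y = pts$y[ok],
                 sampling_step = step, linewidth = as.integer(linewidth),
                 n_dropped = sum(!ok)),
            class = "nq_profile")
}

#' Export a profile as CSV / a centerline as JSON
#'
#' @param profile an `nq_profile`.
#' @param curve an `nq_centerline`.
#' @param path output path.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "nq_profile"))
  write.csv(data.frame(arc_position = profile$arc_positions,
                       intensity = profile$intensities),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
write_centerline <- function(curve, path) {
  stopifnot(inherits(curve, "nq_centerline"))
  writeLines(as.character(jsonlite::toJSON(
    list(degree = curve$degree, coefficients = curve$coefficients,
         x_domain = curve$x_domain),
    digits = NA, auto_unbox = TRUE)), path)
  invisible(path)
}
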