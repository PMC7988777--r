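# Centerline fitting, arc-length sampling and profile extraction.

test_that("a horizontal pixel row fits to a constant polynomial", {
  mask <- structure(list(coords = data.frame(x = 0:99, y = 5L),
                         dim = c(20L, 100L)), class = "nq_mask")
  cv <- fit_polynomial_centerline(mask, degree = 6)
  expect_equal(cv$coefficients[1], 5, tolerance = 1e-8)
  expect_true(all(abs(cv$coefficients[-1]) <= 1e-8))
  expect_equal(cv$x_domain, c(0, 99))
})

test_that("a rasterised quadratic band is recovered within 0.5 px", {
  f <- function(x) 0.001 * x^2 + 0.2 * x + 10
  xs <- 0:99
  coords <- do.call(rbind, lapply(xs, function(x)
    data.frame(x = x, y = seq(ceiling(f(x) - 3), floor(f(x) + 3)))))
  mask <- structure(list(coords = coords, dim = c(60L, 100L)),
                    class = "nq_mask")
  cv <- fit_polynomial_centerline(mask, degree = 6)
  expect_lt(max(abs(centerline_predict(cv, xs) - f(xs))), 0.5)
})

test_that("under-determined fits raise an informative error", {
  mask <- structure(list(coords = data.frame(x = 0:4, y = 2L),
                         dim = c(10L, 10L)), class = "nq_mask")
  expect_error(fit_polynomial_centerline(mask, degree = 6),
               class = "nq_fit_error")
})

test_that("arc-length sampling matches straight-line and diagonal geometry", {
  mask <- structure(list(coords = data.frame(x = 0:50, y = 7L),
                         dim = c(20L, 60L)), class = "nq_mask")
  cv <- fit_polynomial_centerline(mask, degree = 1)
  pts <- arc_length_samples(cv, step = 1)
  expect_equal(pts$x, 0:50, tolerance = 1e-9)
  expect_equal(pts$y, rep(7, 51), tolerance = 1e-9)
  # line y = x sampled at step sqrt(2): consecutive x differ by 1
  diag_mask <- structure(list(coords = data.frame(x = 0:40, y = 0:40),
                              dim = c(50L, 50L)), class = "nq_mask")
  cvd <- fit_polynomial_centerline(diag_mask, degree = 1)
  ptsd <- arc_length_samples(cvd, step = sqrt(2))
  expect_equal(diff(ptsd$x), rep(1, nrow(ptsd) - 1), tolerance = 1e-6)
})

test_that("arc length of a quadratic matches adaptive quadrature", {
  mask <- structure(list(coords = data.frame(
    x = rep(0:99, each = 3),
    y = as.vector(vapply(0:99, function(x)
      round(0.002 * x^2 + 20) + (-1:1), numeric(3)))),
    dim = c(60L, 100L)), class = "nq_mask")
  cv <- fit_polynomial_centerline(mask, degree = 2)
  dco <- cv$coefficients
  fprime <- function(x) dco[2] + 2 * dco[3] * x
  ref <- stats::integrate(function(x) sqrt(1 + fprime(x)^2),
                          cv$x_domain[1], cv$x_domain[2],
                          rel.tol = 1e-10)$value
  expect_lt(abs(arc_length_total(cv) - ref), 1e-3)
})

test_that("recovery meets the rasterisation bound on sloped tubes", {
  # per-column centroids of a rasterised band sit within 0.5 px of the true
  # centerline; when the centerline has enough slope the quantisation
  # pattern cycles faster than a degree-6 polynomial can follow, so the fit
  # tracks truth well inside that bound. Near-flat centerlines let the fit
  # absorb the slowly-varying quantisation bias, which can approach (and,
  # with end leverage, locally exceed) the 0.5 px centroid bound itself;
  # even then the fit error stays of order 1 px (regression bound 1.25).
  set.seed(33)
  for (i in 1:5) {
    drop <- runif(1, 25, 35) * sample(c(-1, 1), 1)
    tb <- tube_model(centerline_coeffs = c(60 - drop / 2, drop / 512))
    img <- generate_notochord_image(ground_truth(tb))
    cv <- fit_polynomial_centerline(largest_component(threshold_mask(img, 5000)))
    xs <- seq(cv$x_domain[1], cv$x_domain[2], by = 1)
    truth_y <- notoquant:::poly_eval(tb$centerline_coeffs, xs)
    expect_lt(max(abs(centerline_predict(cv, xs) - truth_y)), 0.5)
  }
  for (i in 1:5) {
    tb <- random_true_poly()  # gentle, notochord-like
    img <- generate_notochord_image(ground_truth(tb))
    cv <- fit_polynomial_centerline(largest_component(threshold_mask(img, 5000)))
    xs <- seq(cv$x_domain[1], cv$x_domain[2], by = 1)
    truth_y <- notoquant:::poly_eval(tb$centerline_coeffs, xs)
    expect_lt(max(abs(centerline_predict(cv, xs) - truth_y)), 1.25)
  }
})

test_that("profile of a constant tube is constant; of a ramp, the x coordinate", {
  truth <- straight_truth()
  img <- generate_notochord_image(truth)
  cv <- fit_polynomial_centerline(largest_component(threshold_mask(img, 50)))
  pr <- extract_profile(img, cv, step = 1, linewidth = 1)
  expect_true(all(abs(pr$intensities - 100) < 1e-9))
  # ramp field I(x, y) = x along a straight centerline
  ramp <- matrix(rep(0:199, each = 60), 60, 200)
  mask <- structure(list(coords = data.frame(x = 0:199, y = 30L),
                         dim = c(60L, 200L)), class = "nq_mask")
  cvr <- fit_polynomial_centerline(mask, degree = 1)
  prr <- extract_profile(ramp, cvr)
  expect_lt(max(abs(prr$intensities - prr$x)), 1e-9)
})

test_that("bilinear interpolation reproduces affine intensity fields exactly", {
  H <- 40; W <- 80
  aff <- outer(0:(H - 1), 0:(W - 1), function(y, x) 3 + 0.5 * x - 0.25 * y)
  set.seed(1)
  xs <- runif(200, 0, W - 1); ys <- runif(200, 0, H - 1)
  got <- notoquant:::bilinear_at(aff, xs, ys)
  expect_lt(max(abs(got - (3 + 0.5 * xs - 0.25 * ys))), 1e-9)
})

test_that("profile matches an independent brute-force sampler on a curved tube", {
  set.seed(21)
  tb <- random_true_poly()
  truth <- ground_truth(tb, list(lesion_spec(250, 6000, 6)), noise_sigma = 0)
  img <- generate_notochord_image(truth)
  cv <- fit_polynomial_centerline(largest_component(threshold_mask(img, 5000)))
  pr <- extract_profile(img, cv)
  oracle <- oracle_bilinear(img, pr$x, pr$y)
  expect_lt(max(abs(pr$intensities - oracle)), 1e-9)
})

test_that("profile spacing is uniform and wide linewidth averages the normal", {
  truth <- straight_truth()
  img <- generate_notochord_image(truth)
  cv <- fit_polynomial_centerline(largest_component(threshold_mask(img, 50)))
  pr <- extract_profile(img, cv, step = 0.5)
  expect_true(all(abs(diff(pr$arc_positions) - 0.5) < 1e-6))
  pr3 <- extract_profile(img, cv, step = 1, linewidth = 3)
  expect_true(all(abs(pr3$intensities - 100) < 1e-9))  # inside a radius-5 tube
  expect_error(extract_profile(img, cv, linewidth = 2),
               class = "nq_value_error")
})

test_that("halving the step leaves the mean of an affine profile unchanged", {
  ramp <- matrix(rep(seq(0, 99.5, by = 0.5), each = 60), 60, 200)
  mask <- structure(list(coords = data.frame(x = 0:199, y = 30L),
                         dim = c(60L, 200L)), class = "nq_mask")
  cv <- fit_polynomial_centerline(mask, degree = 1)
  m1 <- mean(extract_profile(ramp, cv, step = 1)$intensities)
  m2 <- mean(extract_profile(ramp, cv, step = 0.5)$intensities)
  expect_lt(abs(m1 - m2), 1e-3)
})

test_that("integer translation shifts the fit and leaves the profile unchanged", {
  truth <- straight_truth(y0 = 40, lesions = list(lesion_spec(90, 60, 5)),
                          width = 180, height = 100)
  img1 <- generate_notochord_image(truth)
  dx <- 7L; dy <- 9L
  img2 <- matrix(10, 100, 180)
  img2[(1 + dy):100, (1 + dx):180] <- img1[1:(100 - dy), 1:(180 - dx)]
  cv1 <- fit_polynomial_centerline(largest_component(threshold_mask(img1, 50)))
  cv2 <- fit_polynomial_centerline(largest_component(threshold_mask(img2, 50)))
  xs <- seq(cv1$x_domain[1], 180 - dx - 1, by = 1)
  expect_lt(max(abs(centerline_predict(cv2, xs + dx) -
                      (centerline_predict(cv1, xs) + dy))), 1e-6)
  p1 <- extract_profile(img1, cv1)
  p2 <- extract_profile(img2, cv2)
  n <- min(length(p1$intensities), length(p2$intensities))
  expect_lt(max(abs(p1$intensities[1:n] - p2$intensities[1:n])), 1e-6)
})
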