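# Synthetic-data generator: rendering model, determinism, ground-truth
# bookkeeping, histology and count fixtures.

test_that("noiseless hard-edge tube renders exact in/out intensities", {
  truth <- straight_truth()
  img <- generate_notochord_image(truth)
  expect_equal(img[50 + 1, 20 + 1], 100)   # in-tube pixel (x=20, y=50)
  expect_equal(img[5 + 1, 20 + 1], 10)     # background pixel (x=20, y=5)
  expect_equal(dim(img), c(120, 200))
  # mask of in-tube pixels matches the analytic band
  expect_true(all(img[abs(row(img) - 1 - 50) <= 5] == 100))
})

test_that("a lesion adds its amplitude at its center and nowhere far away", {
  truth <- straight_truth(lesions = list(lesion_spec(60, 80, 4)))
  img <- generate_notochord_image(truth)
  expect_equal(img[50 + 1, 60 + 1], 180)
  expect_equal(img[50 + 1, 190 + 1], 100)  # far from the lesion
  expect_equal(img[5 + 1, 60 + 1], 10)     # lesions never brighten background
})

test_that("identical ground truth gives bit-identical noisy images", {
  truth <- straight_truth(noise = 5, seed = 7)
  img1 <- generate_notochord_image(truth)
  img2 <- generate_notochord_image(truth)
  expect_identical(img1, img2)
  img3 <- generate_notochord_image(straight_truth(noise = 5, seed = 8))
  expect_false(identical(img1, img3))
})

test_that("adding a lesion never decreases any pixel", {
  base <- straight_truth(noise = 0)
  more <- straight_truth(noise = 0,
                         lesions = list(lesion_spec(100, 40, 10)))
  expect_true(all(generate_notochord_image(more) >=
                    generate_notochord_image(base)))
})

test_that("lesion intensities are clipped at the bit-depth maximum", {
  truth <- straight_truth(tube = 200, lesions = list(lesion_spec(60, 200, 4)))
  img <- generate_notochord_image(truth)
  expect_equal(max(img), 255)
})

test_that("a centerline leaving the frame is rejected with a geometry error", {
  tube <- tube_model(image_height = 40, image_width = 200,
                     centerline_coeffs = c(5, 0.5), tube_radius = 8,
                     tube_intensity = 100, background_intensity = 10,
                     bit_depth = 8)
  expect_error(generate_notochord_image(ground_truth(tube)),
               class = "nq_geometry_error")
})

test_that("cohort generation is reproducible and seed-sensitive", {
  spec <- cohort_spec(list(
    group_spec("ctrl", 4, n_lesions = dist_constant(0)),
    group_spec("ras", 6, n_lesions = dist_poisson(4))), seed = 11)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(lapply(c1, function(f) truth_to_json(f$truth)),
                   lapply(c2, function(f) truth_to_json(f$truth)))
  # degenerate control distribution: every truth lesion-free
  ctrl <- Filter(function(f) f$group == "ctrl", c1)
  expect_true(all(vapply(ctrl, function(f) length(f$truth$lesions),
                         integer(1)) == 0))
  spec2 <- cohort_spec(spec$groups, seed = 12)
  c3 <- generate_cohort(spec2)
  expect_false(identical(truth_to_json(c1[[5]]$truth),
                         truth_to_json(c3[[5]]$truth)))
  expect_error(cohort_spec(list()), class = "nq_value_error")
})

test_that("ground truth serialises to JSON and round-trips exactly", {
  truth <- straight_truth(lesions = list(lesion_spec(60.25, 80, 4)),
                          noise = 5, seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  truth_to_json(truth, path)
  back <- truth_from_json(path)
  expect_identical(truth_to_json(back), truth_to_json(truth))
  expect_identical(generate_notochord_image(back),
                   generate_notochord_image(truth))
})

test_that("synthetic histology regions hit their channel means exactly", {
  one <- data.frame(x0 = 0, x1 = 63, y0 = 0, y1 = 63,
                    red = 200, green = 30, blue = 80)
  img <- generate_rgb_histology(one, width = 64, height = 64)
  expect_true(all(img[, , 1] == 200) && all(img[, , 2] == 30) &&
                all(img[, , 3] == 80))
  # two equal-area regions, pure red and pure blue: whole-image red mean 127.5
  two <- data.frame(x0 = c(0, 32), x1 = c(31, 63), y0 = 0, y1 = 63,
                    red = c(255, 0), green = 0, blue = c(0, 255))
  img2 <- generate_rgb_histology(two, width = 64, height = 64)
  expect_equal(mean(img2[, , 1]), 127.5)
  expect_equal(mean(img2[, , 3]), 127.5)
  # overlapping regions are rejected
  bad <- data.frame(x0 = c(0, 10), x1 = c(31, 40), y0 = 0, y1 = 63,
                    red = 10, green = 10, blue = 10)
  expect_error(generate_rgb_histology(bad, 64, 64), class = "nq_value_error")
  # noise is reproducible under a fixed seed
  n1 <- generate_rgb_histology(one, 64, 64, noise_sigma = 5, seed = 9)
  n2 <- generate_rgb_histology(one, 64, 64, noise_sigma = 5, seed = 9)
  expect_identical(n1, n2)
})

test_that("skeletal count tables honour their distributions and seed", {
  zero <- list(list(label = "a", n_fish = 5, fusions = dist_constant(0),
                    clefts = dist_constant(0)))
  tab <- generate_skeletal_counts(zero, seed = 1)
  expect_true(all(tab$fusions == 0) && all(tab$clefts == 0))
  fixed <- list(list(label = "b", n_fish = 5, fusions = dist_constant(3),
                     clefts = dist_constant(2)))
  tab2 <- generate_skeletal_counts(fixed, seed = 1)
  expect_true(all(tab2$fusions == 3) && all(tab2$clefts == 2))
  pois <- list(list(label = "c", n_fish = 20, fusions = dist_poisson(2.5),
                    clefts = dist_poisson(1)))
  expect_identical(generate_skeletal_counts(pois, seed = 4),
                   generate_skeletal_counts(pois, seed = 4))
  expect_error(dist_poisson(-1), class = "nq_value_error")
})
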