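test_that("noise-free phantoms are exactly piecewise constant", {
  for (geom in c("concentric", "voronoi", "slice_like")) {
    ph <- generate_phantom(phantom_spec(shape = c(32, 32), geometry = geom,
                                        seed = 4))
    fg <- ph$truth$labels > 0
    expect_true(all(ph$truth$labels[fg] %in% 1:3))
    expect_true(all(tabulate(ph$truth$labels[fg], 3) > 0))
    expect_equal(ph$image$pixels[fg],
                 ph$spec$class_means[ph$truth$labels[fg]])
    expect_identical(ph$image$mask, fg)
  }
})

test_that("phantom generation is bit-identical under a fixed spec", {
  spec <- phantom_spec(shape = c(32, 32), geometry = "slice_like",
                       noise_model = "rician", noise_level = 10,
                       bias_field = 0.2, seed = 77)
  expect_identical(generate_phantom(spec), generate_phantom(spec))
  spec2 <- phantom_spec(shape = c(32, 32), geometry = "slice_like",
                        noise_model = "rician", noise_level = 10,
                        bias_field = 0.2, seed = 78)
  expect_false(identical(generate_phantom(spec2)$image,
                         generate_phantom(spec)$image))
})

test_that("gaussian noise level follows the brightest-class convention", {
  spec <- phantom_spec(shape = c(96, 96), n_classes = 4,
                       class_means = c(60, 120, 180, 240),
                       geometry = "concentric", noise_model = "gaussian",
                       noise_level = 7, seed = 12)
  ph <- generate_phantom(spec)
  resid <- ph$image$pixels - spec$class_means[ph$truth$labels]
  # interior pixels only (no clamping at these means); sd ~ 0.07 * 240
  expect_equal(sd(resid), 16.8, tolerance = 0.05 * 16.8)
})

test_that("salt-and-pepper and rician noise honor their contracts", {
  base <- generate_phantom(phantom_spec(shape = c(64, 64),
                                        geometry = "concentric", seed = 3))
  sp <- corrupt_image(base$image, "salt_pepper", 10, seed = 5)
  hit <- sp$pixels != base$image$pixels
  n_extreme <- sum(sp$pixels[hit] %in% range(base$image$pixels))
  expect_equal(sum(hit) / length(sp$pixels), 0.10, tolerance = 0.25)
  expect_equal(n_extreme, sum(hit))
  ric <- corrupt_image(base$image, "rician", 15, seed = 5)
  expect_true(all(ric$pixels >= 0))
  # level 0 and model "none" are identities
  expect_identical(corrupt_image(base$image, "rician", 0), base$image)
  expect_identical(corrupt_image(base$image, "none", 10), base$image)
  expect_identical(corrupt_image(base$image, "gaussian", 5, seed = 2),
                   corrupt_image(base$image, "gaussian", 5, seed = 2))
  expect_error(corrupt_image(base$image, "speckle", 5), "arg")
})

test_that("phantom spec validation catches inconsistencies", {
  expect_error(phantom_spec(n_classes = 1), ">= 2")
  expect_error(phantom_spec(class_means = c(1, 2)), "one value per class")
  expect_error(phantom_spec(class_means = c(5, 5, 6)), "distinct")
  expect_error(phantom_spec(n_classes = 4, class_means = 1:4,
                            geometry = "slice_like"), "exactly 3")
  expect_error(phantom_spec(noise_level = -1), ">= 0")
})

test_that("a perfect segmentation of the clean phantom scores JS 1", {
  ph <- generate_phantom(phantom_spec(shape = c(48, 48),
                                      geometry = "slice_like", seed = 21))
  js <- jaccard_scores(ph$truth$labels, ph$truth$labels)
  expect_equal(unname(js), rep(1, 4))
})
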