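test_that("LVC matches hand-computed values and conventions", {
  m <- matrix(2, 3, 3); m[2, 2] <- 11
  # window {2 x8, 11}: mean 3, sum of squared deviations 72, LVC = 72/81
  expect_equal(compute_lvc(gray_image(m))[2, 2], 72 / 81)
  expect_equal(compute_lvc(gray_image(matrix(5, 4, 4))), array(0, c(4, 4)))
  expect_equal(compute_lvc(gray_image(matrix(0, 4, 4))), array(0, c(4, 4)))
  neg <- matrix(c(-1, 1, -1, 1, -1, 1, -1, 1, -1), 3, 3)
  expect_warning(compute_lvc(neg), "negative")
})

test_that("phi takes the three branches with omega in (0, 1)", {
  const <- compute_phi(gray_image(matrix(7, 5, 5)))
  expect_equal(const$omega, array(1 / 9, c(5, 5)))
  expect_equal(const$phi, array(0, c(5, 5)))

  x <- random_image(9, 9, 42)
  img <- gray_image(x)
  reg <- compute_phi(img)
  mu <- local_mean(img)
  expect_true(all(reg$omega >= 0 & reg$omega <= 1))
  expect_true(all(reg$phi >= 0 & reg$phi <= 3))
  bright <- mu < x
  dark <- mu > x
  expect_true(all(reg$phi[bright] > 2 & reg$phi[bright] < 3))
  expect_true(all(reg$phi[dark] > 1 & reg$phi[dark] < 2))
  expect_equal(reg$phi[bright], 2 + reg$omega[bright])
  expect_equal(reg$phi[dark], 2 - reg$omega[dark])
})

test_that("phi is invariant under positive rescaling of the image", {
  x <- random_image(8, 8, 7)
  r1 <- compute_phi(gray_image(x))
  r2 <- compute_phi(gray_image(3.7 * x))
  expect_equal(r1$phi, r2$phi, tolerance = 1e-12)
  expect_equal(r1$omega, r2$omega, tolerance = 1e-12)
})

test_that("omega normalization never overflows on extreme LVC sums", {
  # a few huge spikes drive window LVC sums far beyond exp() range
  x <- matrix(1e-3, 8, 8)
  x[cbind(c(2, 5, 7), c(3, 5, 2))] <- 1e6
  reg <- compute_phi(gray_image(x))
  expect_true(all(is.finite(reg$omega)))
  expect_true(all(is.finite(reg$phi)))
  expect_true(all(reg$omega >= 0 & reg$omega <= 1))
})

test_that("weighted image blends center and neighbors convexly", {
  g <- gray_image(matrix(6.5, 5, 5))
  expect_equal(weighted_image(g)$values, array(6.5, c(5, 5)))
  # direct evaluation with max phi forced to 0: (9 + (1/8)*0)/2 = 4.5
  spike <- gray_image(matrix(c(0, 0, 0, 0, 9, 0, 0, 0, 0), 3, 3))
  zero_reg <- structure(list(lvc = array(0, c(3, 3)),
                             omega = array(1 / 9, c(3, 3)),
                             phi = array(0, c(3, 3)), base_constant = 2),
                        class = "regularizer_field")
  expect_equal(weighted_image(spike, zero_reg)$values[2, 2], 4.5)
  for (seed in 1:3) {
    x <- random_image(8, 8, seed)
    wi <- weighted_image(gray_image(x))
    expect_true(all(wi$values >= min(x) & wi$values <= max(x)))
  }
})

test_that("regularizer chain matches the per-pixel loop oracle", {
  for (seed in 1:3) {
    x <- random_image(8, 8, seed)
    img <- gray_image(x)
    or <- oracle_regularizer(x)
    reg <- compute_phi(img)
    expect_equal(compute_lvc(img), array(or$lvc, c(8, 8)), tolerance = 1e-13)
    expect_equal(reg$omega, array(or$omega, c(8, 8)), tolerance = 1e-13)
    expect_equal(reg$phi, array(or$phi, c(8, 8)), tolerance = 1e-13)
    expect_equal(weighted_image(img, reg)$values, array(or$xi, c(8, 8)),
                 tolerance = 1e-13)
  }
})
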