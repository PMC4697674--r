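test_that("objective and center update match nested-loop evaluation", {
  set.seed(11)
  x <- runif(40, 0, 100)
  xb <- runif(40, 0, 100)
  phi <- runif(40, 1, 3)
  v <- c(20, 60, 90)
  u <- matrix(runif(120), 40, 3); u <- u / rowSums(u)
  expect_equal(arkfcm_objective(x, xb, phi, u, v, 2, 25),
               oracle_objective(x, xb, phi, u, v, 2, 25), tolerance = 1e-12)
  expect_equal(update_centers(x, xb, phi, u, v, 2, 25),
               oracle_centers(x, xb, phi, u, v, 2, 25), tolerance = 1e-12)
  # fuzzifier other than 2
  expect_equal(arkfcm_objective(x, xb, phi, u, v, 2.6, 25),
               oracle_objective(x, xb, phi, u, v, 2.6, 25), tolerance = 1e-12)
})

test_that("membership update handles symmetry and singularities", {
  x <- c(0, 5, 10)
  phi <- c(0, 0, 0)
  # all centers identical -> uniform membership by symmetry
  u <- update_memberships(x, x, phi, c(4, 4, 4), 2, 3)
  expect_equal(u, matrix(1 / 3, 3, 3))
  # pixel exactly at a center with no regularization -> crisp membership
  u <- update_memberships(x, x, phi, c(0, 9), 2, 3)
  expect_equal(u[1, ], c(1, 0))
  expect_equal(rowSums(u), rep(1, 3))
  # zero dissimilarity split equally among tied centers
  u <- update_memberships(0, 0, 0, c(0, 0, 5), 2, 3)
  expect_equal(u[1, ], c(0.5, 0.5, 0))
})

test_that("center updates stay in data range and re-seed empty clusters", {
  g <- rep(7, 20)
  u <- matrix(runif(40), 20, 2); u <- u / rowSums(u)
  expect_equal(update_centers(g, g, rep(2, 20), u, c(3, 12), 2, 5),
               c(7, 7))
  # crisp partition of two constant regions with phi = 0 -> region means
  x <- c(rep(10, 10), rep(50, 10))
  u <- cbind(rep(c(1, 0), each = 10), rep(c(0, 1), each = 10))
  expect_equal(update_centers(x, x, rep(0, 20), u, c(10, 50), 2, 15),
               c(10, 50))
  # a cluster with all-zero membership weight underflows -> re-seeded
  u0 <- cbind(rep(1, 20), rep(0, 20))
  expect_warning(
    v <- update_centers(x, x, rep(0, 20), u0, c(30, 1e9), 2, 15),
    "re-seeded")
  expect_true(all(v >= 10 & v <= 50))
})

test_that("baseline FCM converges to the expected fixed points", {
  x <- matrix(c(rep(0, 8), rep(10, 8)), 4, 4)
  seg <- fcm_segment(gray_image(x), cluster_config(2))
  expect_true(seg$converged)
  expect_equal(seg$partition$centers, c(0, 10), tolerance = 1e-3)
  expect_equal(sort(unique(as.vector(seg$labels))), c(1L, 2L))
  # rows of u sum to 1
  expect_equal(rowSums(seg$partition$memberships), rep(1, 16),
               tolerance = 1e-9)
})

test_that("with phi disabled the pipeline reduces to kernelized FCM", {
  ph <- generate_phantom(phantom_spec(shape = c(16, 16),
                                      geometry = "concentric",
                                      noise_model = "gaussian",
                                      noise_level = 5, seed = 5))
  seg <- arkfcm_segment(ph$image, cluster_config(3, variant = "none"))
  x <- ph$image$pixels[ph$image$mask]
  or <- oracle_kfcm(x, 3, m = 2, sigma = seg$sigma)
  ord <- order(or$v)
  expect_equal(seg$partition$centers, or$v[ord], tolerance = 1e-6)
  expect_equal(seg$partition$memberships, or$u[, ord], tolerance = 1e-6)
})

test_that("segmentation is deterministic and label-order invariant", {
  ph <- generate_phantom(phantom_spec(shape = c(24, 24),
                                      geometry = "voronoi",
                                      noise_model = "gaussian",
                                      noise_level = 6, seed = 9))
  cfg <- cluster_config(3, variant = "weighted")
  a <- arkfcm_segment(ph$image, cfg)
  b <- arkfcm_segment(ph$image, cfg)
  expect_identical(a, b)
  # randomized initializations agree after ascending-center relabeling
  s1 <- arkfcm_segment(ph$image, cluster_config(3, variant = "average",
                                                init = "random_membership",
                                                seed = 1))
  s2 <- arkfcm_segment(ph$image, cluster_config(3, variant = "average",
                                                init = "random_membership",
                                                seed = 2))
  expect_identical(s1$labels, s2$labels)
  expect_equal(s1$partition$centers, s2$partition$centers, tolerance = 1e-4)
})

test_that("configuration and degenerate inputs are rejected", {
  expect_error(cluster_config(1), "n_clusters")
  expect_error(cluster_config(3, m = 1), "m must be")
  expect_error(cluster_config(3, epsilon = 0), "epsilon")
  tiny <- gray_image(matrix(c(1, 2), 1, 2))
  expect_error(arkfcm_segment(tiny, cluster_config(2)), "smaller than")
  expect_error(arkfcm_segment(gray_image(matrix(5, 4, 4)),
                              cluster_config(2)), "degenerate")
})
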