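# Standardization, UMAP embedding, and the from-scratch fuzzy c-means.

test_that("z-score standardization uses the population-sd convention", {
  z <- zscore_standardize(cbind(a = c(1, 2, 3), b = c(4, 0, 2)))
  expect_equal(z[, "a"], c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  expect_lt(max(abs(colMeans(z))), 1e-9)
  n <- nrow(z)
  expect_lt(max(abs(sqrt(colSums(z^2) / n) - 1)), 1e-9)

  expect_equal(unclass(zscore_standardize(z)), unclass(z),
               ignore_attr = TRUE, tolerance = 1e-9)    # idempotent
  expect_error(zscore_standardize(cbind(x = c(1, 1, 1), y = 1:3)),
               "constant column.*x")
})

test_that("the 2-D embedding is reproducible and separation-preserving", {
  withr::with_seed(5, {
    x <- rbind(matrix(rnorm(50 * 9), 50, 9),
               matrix(rnorm(50 * 9, mean = 10), 50, 9))
  })
  labels <- rep(1:2, each = 50)
  e1 <- embed_2d(x, seed = 3)
  e2 <- embed_2d(x, seed = 3)
  expect_equal(dim(e1$coords), c(100, 2))
  expect_true(all(is.finite(e1$coords)))
  expect_identical(e1$coords, e2$coords)

  # oracle: silhouette of the true labels on the embedded coordinates
  sil <- cluster::silhouette(labels, dist(e1$coords))
  expect_gt(mean(sil[, "sil_width"]), 0.5)

  expect_error(embed_2d(x[1:10, ], n_neighbors = 15), "n_neighbors")
})

test_that("FCM reproduces the closed-form membership equation", {
  # a point equidistant from two centroids
  pts <- rbind(c(0, 0), c(2, 0), c(1, 0), c(0.1, 0.2), c(1.9, -0.1),
               c(1, 0.01))
  fc <- fcm_cluster(pts, c = 2, seed = 1)
  d2 <- sapply(1:2, function(k) rowSums(sweep(pts, 2, fc$centroids[k, ])^2))
  u_closed <- (1 / d2) / rowSums(1 / d2)       # mu = 2 closed form
  expect_equal(unclass(fc$membership), unclass(u_closed),
               ignore_attr = TRUE, tolerance = 1e-6)

  # distances (1, 2) at mu = 2 -> memberships (0.8, 0.2)
  inv <- c(1, 2)^(-2)
  expect_equal(inv / sum(inv), c(0.8, 0.2))

  # blobs: hard labels recover the blob identity up to permutation
  withr::with_seed(2, {
    blobs <- rbind(matrix(rnorm(80, 0, 0.3), 40, 2),
                   matrix(rnorm(80, 6, 0.3), 40, 2))
  })
  fb <- fcm_cluster(blobs, c = 2, seed = 4)
  expect_equal(adjusted_rand_index(fb$hard_labels, rep(1:2, each = 40)), 1)
  expect_true(all(diff(fb$objective_trace) <= 1e-9))
  expect_lt(max(abs(rowSums(fb$membership) - 1)), 1e-9)

  expect_error(fcm_cluster(blobs[1:2, ], c = 3), "more points")
  expect_error(fcm_cluster(matrix(1, 10, 2), c = 2), "identical")
})

test_that("FCM agrees with an independent implementation on separated data", {
  skip_if_not_installed("e1071")
  withr::with_seed(6, {
    blobs <- rbind(matrix(rnorm(60, 0, 0.4), 30, 2),
                   matrix(rnorm(60, 5, 0.4), 30, 2),
                   matrix(rnorm(60, c(0, 8), 0.4), 30, 2))
  })
  init <- rbind(c(0.2, 0.1), c(5.2, 5.1), c(0.1, 8.2))
  ours <- fcm_cluster(blobs, c = 3, init = init)
  ref <- e1071::cmeans(blobs, centers = init, m = 2, iter.max = 100)
  expect_equal(adjusted_rand_index(ours$hard_labels, ref$cluster), 1)
  # same converged centroids up to cluster order
  o <- ours$centroids[order(ours$centroids[, 1] + ours$centroids[, 2]), ]
  r <- ref$centers[order(ref$centers[, 1] + ref$centers[, 2]), ]
  expect_equal(unclass(o), unclass(r), ignore_attr = TRUE, tolerance = 1e-3)
})

test_that("permuting the input permutes the clustering accordingly", {
  withr::with_seed(11, {
    blobs <- rbind(matrix(rnorm(60, 0, 0.4), 30, 2),
                   matrix(rnorm(60, 6, 0.4), 30, 2))
    perm <- sample(60)
  })
  a <- fcm_cluster(blobs, c = 2, seed = 3)
  b <- fcm_cluster(blobs[perm, ], c = 2, seed = 3)
  expect_equal(adjusted_rand_index(a$hard_labels[perm], b$hard_labels), 1)
})

test_that("hard assignment takes the argmax with lowest-index tie-breaks", {
  U <- rbind(c(0.7, 0.2, 0.1), c(0.5, 0.5, 0.0), c(0.2, 0.3, 0.5))
  labels <- suppressMessages(hard_assign(U))
  expect_equal(as.vector(labels), c(1, 1, 3))
  expect_equal(attr(labels, "ties"), 2L)
  expect_message(hard_assign(U), "tied")
  expect_error(hard_assign(rbind(c(0.9, 0.3))), "sum to 1")

  fc <- fcm_cluster(matrix(rnorm(40), 20, 2), c = 2, seed = 1)
  expect_equal(as.vector(fc$hard_labels),
               as.vector(suppressMessages(hard_assign(fc$membership))))
})
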