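test_that("fusion weights have unit peak, FWHM = patch side, and symmetry", {
  w <- gaussian_patch_weights(c(9, 9, 9))
  expect_equal(max(w), 1)
  expect_equal(unname(which(w == 1, arr.ind = TRUE)[1, ]), c(5, 5, 5))
  # per-axis log2 falloff is -4 d^2 / L^2, i.e. exactly -1 at d = L/2 (FWHM)
  for (k in 1:4) {
    expect_equal(log2(w[5 + k, 5, 5] / w[5, 5, 5]), -4 * k^2 / 81,
                 tolerance = 1e-12)
  }
  # separability across axes
  expect_equal(w[7, 8, 5], w[7, 5, 5] * w[5, 8, 5], tolerance = 1e-12)
  # reflection symmetry through the centre
  expect_equal(w, w[9:1, , ])
  expect_equal(w, w[, , 9:1])
  # even-sized patches: face voxels fall near half of the attained peak
  w2 <- gaussian_patch_weights(c(8, 8, 8))
  expect_equal(max(w2), 1)
  expect_equal(w2, w2[8:1, , ])
})

test_that("single-patch and identical-patch fusion return inputs exactly", {
  set.seed(1)
  p <- array(runif(6 * 6 * 4 * 3), c(6, 6, 4, 3))
  p <- p / array(rep(apply(p, 1:3, sum), 3), dim(p))
  single <- fuse_patches(list(list(probs = p, offset = c(0, 0, 0))),
                         c(6, 6, 4))
  expect_equal(single, p)  # weights cancel in the quotient
  two <- fuse_patches(list(list(probs = p[, , 1:2, ], offset = c(0, 0, 0)),
                           list(probs = p[, , 1:2, ], offset = c(0, 0, 0))),
                      c(6, 6, 2))
  expect_equal(two, p[, , 1:2, ])  # convexity fixed point
})

test_that("fusion is the weighted average, order-invariant, simplex-valued", {
  set.seed(2)
  shape <- c(4, 4, 8)
  mk <- function(const) {
    a <- array(0, c(4, 4, 4, 3))
    a[, , , 1] <- 1 - const; a[, , , 2] <- const
    a
  }
  patches <- list(list(probs = mk(1), offset = c(0, 0, 0)),
                  list(probs = mk(0), offset = c(0, 0, 2)),
                  list(probs = mk(0.5), offset = c(0, 0, 4)))
  fused <- fuse_patches(patches, shape)
  # independent computation of the quotient at an overlap voxel (z = 3 is
  # slice 3 of patch 1 and slice 1 of patch 2)
  w <- gaussian_patch_weights(c(4, 4, 4))
  v <- c(2, 3)
  expected <- (w[v[1], v[2], 3] * 1 + w[v[1], v[2], 1] * 0) /
    (w[v[1], v[2], 3] + w[v[1], v[2], 1])
  expect_equal(fused[v[1], v[2], 3, 2], expected, tolerance = 1e-12)
  # order invariance
  fused2 <- fuse_patches(patches[c(3, 1, 2)], shape)
  expect_equal(fused2, fused)
  # simplex everywhere and convex hull of inputs
  sums <- apply(fused, 1:3, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_true(all(fused[, , , 2] >= 0 & fused[, , , 2] <= 1))
  expect_error(fuse_patches(patches[1:2], c(4, 4, 9)), "cover")
})

test_that("ensemble averaging preserves the simplex and handles edge cases", {
  a <- array(0, c(2, 2, 2, 3)); a[, , , 1] <- 1
  b <- array(0, c(2, 2, 2, 3)); b[, , , 2] <- 1
  m <- ensemble_average(list(a, b))
  expect_equal(m[1, 1, 1, ], c(0.5, 0.5, 0))
  expect_equal(ensemble_average(list(a)), a)
  set.seed(3)
  maps <- lapply(1:5, function(i) {
    p <- array(runif(8 * 3), c(2, 2, 2, 3))
    p / array(rep(apply(p, 1:3, sum), 3), dim(p))
  })
  avg <- ensemble_average(maps)
  expect_true(all(abs(apply(avg, 1:3, sum) - 1) < 1e-12))
  expect_error(ensemble_average(list()), "empty")
  expect_error(ensemble_average(list(a, array(0, c(1, 1, 1, 3)))), "shape")
})

test_that("class assignment takes the argmax with ties toward background", {
  p <- array(0, c(1, 1, 3, 3))
  p[1, 1, 1, ] <- c(0.2, 0.5, 0.3)
  p[1, 1, 2, ] <- c(1, 1, 1) / 3
  p[1, 1, 3, ] <- c(0.1, 0.45, 0.45)
  lab <- assign_classes(p)
  expect_identical(as.vector(lab), c(1L, 0L, 1L))
  lm <- assign_classes(p, grid_geometry(c(1, 1, 3), c(2.5, 2.5, 2.5)))
  expect_s3_class(lm, "label_map")
})

test_that("connected components agree with a union-find oracle", {
  set.seed(11)
  for (rep in 1:8) {
    mask <- array(runif(16^3) < 0.12, c(16, 16, 16))
    for (conn in c(26L, 6L)) {
      got <- connected_components(mask, conn)
      want <- oracle_components(mask, conn)
      expect_identical(max(got), max(want))
      # same partition up to relabelling
      if (max(got) > 0) {
        tab <- table(got[mask], want[mask])
        expect_true(all(rowSums(tab > 0) == 1))
        expect_true(all(colSums(tab > 0) == 1))
      }
    }
  }
  expect_identical(max(connected_components(array(FALSE, c(4, 4, 4)))), 0L)
})

test_that("small regions are excluded strictly below 0.1 ml", {
  arr <- array(0L, c(20, 20, 8))
  arr[1:6, 1, 1] <- 1L                 # 6 voxels = 0.09375 ml -> removed
  arr[1:7, 5, 1] <- 2L                 # 7 voxels = 0.109 ml  -> kept
  arr[10:15, 10, 3:4] <- 1L            # 12 voxels -> kept
  lm <- lmap(arr)
  out <- filter_small_rois(lm)
  expect_identical(sum(out$labels[1:6, 1, 1]), 0L)
  expect_identical(sum(out$labels[1:7, 5, 1] == 2L), 7L)
  expect_identical(sum(out$labels == 1L), 12L)
  empty <- filter_small_rois(lmap(array(0L, c(4, 4, 4))))
  expect_true(all(empty$labels == 0L))
})

test_that("filtering respects the connectivity choice", {
  arr <- array(0L, c(10, 10, 4))
  # two diagonal runs touching only at corners: one component under 26-conn,
  # two under 6-conn
  for (i in 1:4) arr[i, i, 1] <- 1L
  for (i in 5:8) arr[i, i, 1] <- 1L
  lm <- lmap(arr)
  kept26 <- filter_small_rois(lm, min_ml = 0.1, connectivity = 26L)
  expect_identical(sum(kept26$labels == 1L), 8L)   # 8 voxels = 0.125 ml
  kept6 <- filter_small_rois(lm, min_ml = 0.1, connectivity = 6L)
  expect_identical(sum(kept6$labels == 1L), 0L)    # two 4-voxel components
})
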