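test_that("resampling a constant volume preserves the constant", {
  geom <- grid_geometry(c(10, 8, 6), c(3.1, 2.2, 4.7))
  vol <- scalar_volume(array(7, c(10, 8, 6)), geom, "CT_HU")
  out <- resample_to_common_grid(vol, c(2.5, 2.5, 2.5))
  expect_equal(out$geometry$spacing, c(2.5, 2.5, 2.5))
  expect_true(all(abs(out$values - 7) < 1e-12))
  # world extent preserved to within one voxel
  expect_equal(out$geometry$shape * 2.5, c(10, 8, 6) * geom$spacing,
               tolerance = 2.5 / min(c(10, 8, 6) * geom$spacing))
})

test_that("resampling at the target spacing is the identity", {
  geom <- geom25(c(6, 6, 6))
  vol <- scalar_volume(array(runif(216), c(6, 6, 6)), geom, "PET_SUV")
  out <- resample_to_common_grid(vol, 2.5)
  expect_identical(out$values, vol$values)
})

test_that("nearest-neighbour label resampling round-trips on aligned grids", {
  geom <- geom25(c(8, 8, 8))
  arr <- array(sample(0:2, 512, TRUE), c(8, 8, 8))
  lm <- label_map(arr, geom)
  up <- resample_to_common_grid(lm, 1.25)
  expect_identical(as.integer(up$geometry$shape), c(16L, 16L, 16L))
  down <- resample_to_common_grid(up, 2.5)
  expect_identical(down$labels, arr)
  expect_true(all(up$labels %in% 0:2))
})

test_that("trilinear resampling reproduces a linear ramp exactly", {
  geom <- grid_geometry(c(9, 9, 9), c(2, 2, 2))
  co <- (0:8) * 2
  ramp <- outer(outer(co, rep(1, 9)), rep(1, 9))
  vol <- scalar_volume(ramp, geom, "CT_HU")
  out <- resample_to_common_grid(vol, c(1, 1, 1))
  co2 <- (seq_len(out$geometry$shape[1]) - 1) * 1
  expected <- outer(outer(pmin(co2, max(co)), rep(1, out$geometry$shape[2])),
                    rep(1, out$geometry$shape[3]))
  expect_equal(out$values, expected, tolerance = 1e-12)
})

test_that("central transaxial crop records offsets and preserves the centre", {
  geom <- geom25(c(160, 160, 4))
  vol <- scalar_volume(array(seq_len(160 * 160 * 4), c(160, 160, 4)),
                       geom, "CT_HU")
  out <- central_crop_transaxial(vol, 128)
  expect_identical(dim(out$values)[1:2], c(128L, 128L))
  off <- attr(out, "source_offset")
  expect_identical(off, c(16L, 16L, 0L))
  expect_equal(out$values[1, 1, 1], vol$values[17, 17, 1])
  expect_equal(out$values[64, 64, 2], vol$values[80, 80, 2])
})

test_that("small inputs are padded with background", {
  geom <- geom25(c(100, 100, 4))
  lm <- label_map(array(1L, c(100, 100, 4)), geom)
  out <- central_crop_transaxial(lm, 128)
  expect_identical(dim(out$labels)[1:2], c(128L, 128L))
  expect_identical(attr(out, "source_offset"), c(-14L, -14L, 0L))
  expect_identical(out$labels[1, 1, 1], 0L)       # padded corner
  expect_identical(out$labels[15, 15, 1], 1L)     # original content
  same <- central_crop_transaxial(lm, 100)
  expect_identical(same$labels, lm$labels)
})

test_that("axial crop keeps the requested half-open slice range", {
  geom <- geom25(c(4, 4, 64))
  vol <- scalar_volume(array(rep(1:64, each = 16), c(4, 4, 64)), geom, "PET_SUV")
  full <- axial_crop(vol, c(0, 64))
  expect_identical(full$values, vol$values)
  part <- axial_crop(vol, c(0, 32))
  expect_identical(dim(part$values)[3], 32L)
  expect_identical(attr(part, "source_offset"), c(0L, 0L, 0L))
  mid <- axial_crop(vol, c(10, 20))
  expect_equal(unique(as.vector(mid$values[, , 1])), 11)
  expect_identical(attr(mid, "source_offset")[3], 10L)
  expect_error(axial_crop(vol, c(20, 10)), "invalid")
  expect_error(axial_crop(vol, c(0, 65)), "invalid")
})

test_that("crop offsets compose invertibly back to the original grid", {
  geom <- geom25(c(20, 20, 30))
  vol <- scalar_volume(array(runif(20 * 20 * 30), c(20, 20, 30)), geom, "PET_SUV")
  step1 <- central_crop_transaxial(vol, 12)
  step2 <- axial_crop(step1, c(5, 25))
  off <- attr(step2, "source_offset")
  for (v in list(c(1, 1, 1), c(5, 9, 3), c(12, 12, 20))) {
    expect_equal(step2$values[v[1], v[2], v[3]],
                 vol$values[v[1] + off[1], v[2] + off[2], v[3] + off[3]])
  }
})

test_that("CT windowing clips and both modalities scale to [0, 1]", {
  geom <- geom25(c(4, 4, 2))
  ctv <- array(-150, c(4, 4, 2)); ctv[1, 1, 1] <- 400; ctv[2, 1, 1] <- 0
  pet <- array(0, c(4, 4, 2)); pet[1, 1, 1] <- 20; pet[2, 1, 1] <- 5
  wn <- window_and_normalize(scalar_volume(pet, geom, "PET_SUV"),
                             scalar_volume(ctv, geom, "CT_HU"))
  expect_equal(wn$ct$values[1, 1, 1], 1)          # 400 HU clipped to 150
  expect_equal(wn$ct$values[2, 1, 1], 0.5)        # 0 HU mid-window
  expect_equal(wn$pet$values[1, 1, 1], 1)
  expect_equal(wn$pet$values[2, 1, 1], 0.25)      # (5 - 0) / 20
  expect_true(all(wn$pet$values >= 0 & wn$pet$values <= 1))
})

test_that("constant volumes normalize to all-zeros without error", {
  geom <- geom25(c(3, 3, 3))
  wn <- window_and_normalize(scalar_volume(array(2, c(3, 3, 3)), geom, "PET_SUV"),
                             scalar_volume(array(40, c(3, 3, 3)), geom, "CT_HU"))
  expect_true(all(wn$pet$values == 0))
  expect_true(all(wn$ct$values == 0))
})

test_that("one-hot encoding is exact and inverts by argmax", {
  arr <- array(sample(0:2, 4 * 4 * 4, TRUE), c(4, 4, 4))
  oh <- one_hot_encode(arr)
  expect_identical(dim(oh), c(4L, 4L, 4L, 3L))
  sums <- apply(oh, 1:3, sum)
  expect_true(all(sums == 1))
  expect_identical(assign_classes(oh), arr)
  all_bg <- one_hot_encode(array(0L, c(2, 2, 2)))
  expect_true(all(all_bg[, , , 1] == 1))
  v <- one_hot_encode(array(2L, c(1, 1, 1)))
  expect_equal(as.vector(v), c(0, 0, 1))
  expect_error(one_hot_encode(array(3L, c(2, 2, 2))), "range")
})

test_that("patch extraction strides, flush-aligns, and covers every slice", {
  mk <- function(depth) list(pet = array(runif(16 * 16 * depth), c(16, 16, depth)),
                             ct = array(0.5, c(16, 16, depth)))
  ps <- c(16L, 16L, 32L)
  one <- extract_patches(mk(32), ps)
  expect_length(one, 1)
  expect_identical(one[[1]]$offset, c(0L, 0L, 0L))

  five <- extract_patches(mk(64), ps)
  expect_identical(vapply(five, function(p) p$offset[3], integer(1)),
                   c(0L, 8L, 16L, 24L, 32L))
  # interior slices covered by at least 2 patches
  cover <- integer(64)
  for (p in five) cover[p$offset[3] + 1:32] <- cover[p$offset[3] + 1:32] + 1L
  expect_true(all(cover >= 1))
  expect_true(all(cover[9:56] >= 2))

  two <- extract_patches(mk(40), ps)
  expect_identical(vapply(two, function(p) p$offset[3], integer(1)), c(0L, 8L))
  expect_identical(two[[2]]$offset[3] + 32L, 40L)  # flush with last slice

  for (depth in c(33, 47, 55, 80)) {
    ps_small <- c(16L, 16L, 8L)
    patches <- extract_patches(mk(depth), ps_small)
    cov <- integer(depth)
    for (p in patches) cov[p$offset[3] + 1:8] <- cov[p$offset[3] + 1:8] + 1L
    expect_true(all(cov >= 1))
    # patch content matches the source volume at the recorded offset
    last <- patches[[length(patches)]]
    expect_identical(last$offset[3] + 8L, as.integer(depth))
  }
})

test_that("shallow volumes are padded and padding is background in targets", {
  stack <- list(pet = array(1, c(8, 8, 5)), ct = array(0, c(8, 8, 5)),
                target = one_hot_encode(array(1L, c(8, 8, 5))))
  patches <- extract_patches(stack, c(8L, 8L, 8L))
  expect_length(patches, 1)
  expect_identical(attr(patches, "source_depth"), 5L)
  tg <- patches[[1]]$target
  expect_true(all(tg[, , 6:8, 1] == 1))  # padded slices are background
  expect_true(all(tg[, , 1:5, 2] == 1))
})

test_that("degenerate patching parameters are rejected", {
  stack <- list(pet = array(0, c(8, 8, 16)), ct = array(0, c(8, 8, 16)))
  expect_error(extract_patches(stack, c(8L, 8L, 8L), axial_overlap = 1),
               "stride")
  expect_error(extract_patches(stack, c(16L, 16L, 8L)), "in-plane")
})
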