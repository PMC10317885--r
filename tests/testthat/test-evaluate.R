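test_that("DSC matches brute-force voxel counting", {
  a <- array(FALSE, c(4, 4, 2)); a[1:2, 1:2, 1] <- TRUE   # |A| = 4
  b <- array(FALSE, c(4, 4, 2)); b[2:3, 1:2, 1] <- TRUE   # |B| = 4, overlap 2
  expect_equal(dsc(a, b), 2 * 2 / 8)
  expect_equal(dsc(a, a), 1)
  expect_equal(dsc(a, !a & c(TRUE)), 0)
  expect_true(is.na(dsc(a & FALSE, b & FALSE)))
  expect_error(dsc(a, array(FALSE, c(2, 2, 2))), "grids")
  # |A| = |B| = 8 with |intersection| = 4 -> 0.5
  a2 <- array(FALSE, c(4, 4, 2)); a2[1:8] <- TRUE
  b2 <- array(FALSE, c(4, 4, 2)); b2[5:12] <- TRUE
  expect_equal(dsc(a2, b2), 0.5)
})

test_that("cohort DSC pools voxel counts before the ratio", {
  # patient 1: perfect prediction, patient 2: complete miss, equal sizes
  r1 <- array(0L, c(6, 6, 2)); r1[1:8] <- 1L
  p2 <- array(0L, c(6, 6, 2)); p2[20:27] <- 1L
  refs <- list(lmap(r1), lmap(r1))
  preds <- list(lmap(r1), lmap(p2))
  rep <- dsc_report(refs, preds)
  expect_equal(rep$primary$individual, c(1, 0))
  expect_equal(rep$primary$cohort, 0.5)  # (2*8) / (16 + 16)
  expect_equal(rep$primary$mean, 0.5)
  expect_identical(rep$primary$n_failed, 1L)
  # with n = 1, cohort equals the individual DSC
  rep1 <- dsc_report(refs[1], preds[2])
  expect_equal(rep1$primary$cohort, rep1$primary$individual[1])
})

test_that("a perfect cohort reports ones and no failures", {
  set.seed(8)
  maps <- lapply(1:4, function(i) lmap(random_label_map()))
  rep <- dsc_report(maps, maps)
  for (tg in c("primary", "ln", "union")) {
    if (rep[[tg]]$n_defined > 0) {
      expect_equal(rep[[tg]]$cohort, 1)
      expect_equal(rep[[tg]]$mean, 1)
      expect_equal(rep[[tg]]$median, 1)
      expect_equal(rep[[tg]]$ci50, c(1, 1))
      expect_identical(rep[[tg]]$n_failed, 0L)
    }
  }
  expect_error(dsc_report(maps, maps[1:2]), "length")
})

test_that("both-empty targets are excluded, empty predictions count as failed", {
  ref_a <- array(0L, c(4, 4, 2)); ref_a[1:6] <- 1L       # primary only
  refs <- list(lmap(ref_a))
  preds <- list(lmap(array(0L, c(4, 4, 2))))
  rep <- dsc_report(refs, preds)
  expect_identical(rep$primary$n_failed, 1L)
  expect_identical(rep$ln$n_defined, 0L)      # both empty for LN: excluded
  expect_identical(rep$ln$n_failed, 0L)
})

test_that("voxel classification reproduces published contingency rates", {
  # contingency proportions (t_pt, f_pt, t_ln, f_ln) per mille, as printed
  # for the two evaluation cohorts
  cases <- list(
    list(prop = c(608, 15, 372, 5), acc = 98.0, tpr_pt = 99.2, tpr_ln = 96.1),
    list(prop = c(670, 12, 309, 9), acc = 97.9, tpr_pt = 98.7, tpr_ln = 96.3))
  for (cs in cases) {
    ref <- array(0L, c(10, 10, 10))
    pred <- array(0L, c(10, 10, 10))
    n <- cs$prop
    ref[1:1000] <- rep(c(1L, 2L, 2L, 1L), times = n)   # t_pt, f_pt, t_ln, f_ln
    pred[1:1000] <- rep(c(1L, 1L, 2L, 2L), times = n)
    vc <- voxel_classification(lmap(ref), lmap(pred))
    expect_identical(unname(vc$counts), as.numeric(n))
    expect_equal(round(100 * vc$acc, 1), cs$acc)
    expect_equal(round(100 * vc$tpr_pt, 1), cs$tpr_pt)
    expect_equal(round(100 * vc$tpr_ln, 1), cs$tpr_ln)
  }
})

test_that("classification restricts to jointly delineated voxels and is exact", {
  ref <- array(0L, c(4, 4, 4)); pred <- array(0L, c(4, 4, 4))
  ref[1:10] <- 1L; pred[5:14] <- 2L  # overlap voxels 5:10 are ref 1 / pred 2
  vc <- voxel_classification(lmap(ref), lmap(pred))
  expect_identical(unname(vc$counts), c(0, 0, 0, 6))
  expect_identical(vc$n, 6)
  # identity prediction: perfect rates
  set.seed(2)
  full <- random_label_map()
  vc2 <- voxel_classification(lmap(full), lmap(full))
  expect_equal(vc2$acc, 1)
  expect_equal(vc2$tpr_pt, 1)
  expect_equal(vc2$tpr_ln, 1)
  # conservation: counts cover exactly the joint lesion voxels
  pred3 <- random_label_map()
  vc3 <- voxel_classification(lmap(full), lmap(pred3))
  expect_equal(vc3$n, sum(full > 0 & pred3 > 0))
})

test_that("structure matching applies the coverage rules at the boundary", {
  # one reference lesion of 8 voxels, prediction covers exactly 4 (50%)
  ref <- array(0L, c(12, 12, 4)); ref[1:8, 1, 1] <- 1L
  pred <- array(0L, c(12, 12, 4)); pred[1:4, 1, 1] <- 1L
  sm <- structure_match(lmap(ref), lmap(pred), target = "primary")
  expect_identical(sm$tp_man, 1L)   # >= 50% counts as detected
  expect_identical(sm$fn, 0L)
  # predicted structure of 8 voxels covered exactly 50% by reference: FP
  pred2 <- array(0L, c(12, 12, 4)); pred2[5:12, 1, 1] <- 1L
  sm2 <- structure_match(lmap(ref), lmap(pred2), target = "primary")
  expect_identical(sm2$tp_cnn, 0L)  # needs > 50%
  expect_identical(sm2$fp, 1L)
  # identical maps: no FN/FP and unit rates
  set.seed(5)
  m <- lmap(random_label_map())
  sm3 <- structure_match(m, m, target = "union")
  expect_identical(sm3$fn, 0L)
  expect_identical(sm3$fp, 0L)
  expect_equal(sm3$tpr_str, 1)
  expect_equal(sm3$ppv_str, 1)
})

test_that("union matching is classless while per-class matching is not", {
  ref <- array(0L, c(10, 10, 4)); ref[1:8, 1, 1] <- 1L
  pred <- array(0L, c(10, 10, 4)); pred[1:8, 1, 1] <- 2L  # right place, wrong class
  per_class <- structure_match(lmap(ref), lmap(pred), target = "primary")
  expect_identical(per_class$tp_man, 0L)
  union <- structure_match(lmap(ref), lmap(pred), target = "union")
  expect_identical(union$tp_man, 1L)
  expect_identical(union$fp, 0L)
})

test_that("published lesion-detection rates follow from the printed counts", {
  rows <- list(
    list(cnt = c(578, 592, 65, 44), tpr = 89.9, ppv = 93.1),
    list(cnt = c(849, 893, 229, 252), tpr = 78.8, ppv = 78.0),
    list(cnt = c(1427, 1485, 294, 296), tpr = 82.9, ppv = 83.4),
    list(cnt = c(164, 160, 11, 10), tpr = 93.7, ppv = 94.1),
    list(cnt = c(193, 198, 204, 53), tpr = 48.6, ppv = 78.9),
    list(cnt = c(357, 358, 215, 63), tpr = 62.4, ppv = 85.0))
  for (r in rows) {
    rates <- structure_rates(r$cnt[1], r$cnt[2], r$cnt[3], r$cnt[4])
    expect_equal(round(100 * rates$tpr_str, 1), r$tpr)
    expect_equal(round(100 * rates$ppv_str, 1), r$ppv)
  }
})

test_that("structure counts are conserved against component counts", {
  set.seed(13)
  for (i in 1:5) {
    ref <- random_label_map(n_blobs = 4)
    pred <- random_label_map(n_blobs = 4)
    for (tg in c("primary", "ln", "union")) {
      sm <- structure_match(lmap(ref), lmap(pred), target = tg)
      msk_r <- switch(tg, primary = ref == 1, ln = ref == 2, union = ref > 0)
      msk_p <- switch(tg, primary = pred == 1, ln = pred == 2, union = pred > 0)
      expect_identical(sm$tp_man + sm$fn, max(oracle_components(msk_r)))
      expect_identical(sm$tp_cnn + sm$fp, max(oracle_components(msk_p)))
    }
  }
})

test_that("TTB sums lesion volume in ml", {
  arr <- array(0L, c(8, 8, 4))
  expect_equal(ttb(lmap(arr)), 0)
  arr[1:40] <- 1L; arr[41:64] <- 2L
  expect_equal(ttb(lmap(arr)), voxels_to_ml(64, geom25()))
  only1 <- array(0L, c(8, 8, 4)); only1[1:10] <- 1L
  expect_equal(ttb(lmap(only1)), voxels_to_ml(10, geom25()))
})

test_that("TTB agreement fits, rejects outliers, and guards degeneracy", {
  set.seed(21)
  man <- runif(100, 1, 60)
  expect_equal(suppressWarnings(ttb_agreement(man, man))$r_squared, 1)
  expect_equal(suppressWarnings(ttb_agreement(man, man))$mean_abs_diff, 0)
  # noisy agreement with one gross outlier: rejection restores the clean fit
  cnn <- man + rnorm(100, 0, 1)
  cnn[17] <- man[17] + 300
  res <- suppressWarnings(ttb_agreement(man, cnn, outlier_fraction = 0.01))
  expect_false(res$retained[17])
  clean <- summary(stats::lm(cnn[-17] ~ man[-17]))$r.squared
  expect_equal(res$r_squared, clean, tolerance = 1e-12)
  expect_equal(res$slope, 1, tolerance = 0.05)
  expect_identical(res$n_used, 99L)
  expect_identical(nrow(res$prediction_interval), 99L)
  expect_true(all(res$prediction_interval$lwr < res$prediction_interval$fit))
  expect_error(ttb_agreement(rep(5, 20), rnorm(20, 5)), "degenerate")
  expect_error(ttb_agreement(man[1:5], cnn[1:5]), "at least")
})
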