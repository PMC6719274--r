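make_simple <- function() {
  # 11x8x6 toy volume with a 5x4x4 "brain" block at 30 HU
  a <- array(-1000, dim = c(11, 8, 6))
  a[4:8, 3:6, 2:5] <- 30
  vol <- ct_volume(a, spacing = c(2, 2, 2))
  mask <- brain_mask(a > -1000, vol$spacing)
  list(vol = vol, mask = mask)
}

test_that("difference map is input minus restored on the mask, zero outside", {
  s <- make_simple()
  # identity restoration
  d0 <- difference_map(s$vol, fake_iic(s$vol, s$vol$data), s$mask)
  expect_true(all(d0$values == 0))
  # constant +2 HU restoration on-mask
  r <- s$vol$data
  r[s$mask$mask] <- r[s$mask$mask] + 2
  d2 <- difference_map(s$vol, fake_iic(s$vol, r), s$mask)
  expect_true(all(d2$values[s$mask$mask] == -2))
  expect_true(all(d2$values[!s$mask$mask] == 0))
  # grid mismatch
  other <- ct_volume(array(0, dim = c(4, 4, 4)), c(1, 1, 1))
  expect_error(difference_map(other, fake_iic(s$vol, r), s$mask), "grids")
})

test_that("threshold is closed at the boundary value", {
  a <- array(-1000, dim = c(7, 3, 3))
  a[1:5, 2, 2] <- 30
  vol <- ct_volume(a, c(1, 1, 1))
  mask <- brain_mask(a > -1000, vol$spacing)
  r <- a
  r[1:5, 2, 2] <- 30 - c(-3.0, -1.6, -1.5, -1.4, 0)   # dmap values
  sel <- threshold_map(difference_map(vol, fake_iic(vol, r), mask), -1.5)
  expect_identical(sel[1:5, 2, 2], c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(sum(sel), 3)
  # all-zero map selects nothing
  sel0 <- threshold_map(difference_map(vol, fake_iic(vol, a), mask), -1.5)
  expect_equal(sum(sel0), 0)
  expect_error(threshold_map(difference_map(vol, fake_iic(vol, a), mask), 0),
               "negative")
})

test_that("selection volume arithmetic is exact", {
  sel <- array(FALSE, dim = c(20, 10, 10))
  sel[seq_len(2000)] <- TRUE
  expect_equal(masked_volume_cc(sel, c(1.875, 1.875, 5.0)), 35.15625)
  expect_equal(masked_volume_cc(sel & FALSE, c(1, 1, 1)), 0)
  one <- array(FALSE, dim = c(2, 2, 2)); one[1] <- TRUE
  expect_equal(masked_volume_cc(one, c(1, 1, 1)), 0.001)
  expect_error(masked_volume_cc(one, c(0, 1, 1)), "positive")
})

test_that("hemisphere split partitions the mask without bias", {
  truth <- make_head_phantom(small_spec(seed = 6))
  mask <- extract_brain(truth$image)
  split <- split_hemispheres(mask, truth$image)
  expect_false(any(split$left_mask & split$right_mask))
  n_l <- sum(split$left_mask); n_r <- sum(split$right_mask)
  expect_lt(abs(n_l - n_r) / mask$voxel_count, 0.02)   # symmetric phantom
  # centred cuboid mask on an odd grid: midline at the centre index
  a <- array(-1000, dim = c(21, 9, 5)); a[6:16, 3:7, 2:4] <- 30
  vol <- ct_volume(a, c(1, 1, 1))
  sp2 <- split_hemispheres(brain_mask(a > -1000, c(1, 1, 1)), vol)
  expect_equal(sp2$midline_index, 11)
  expect_false(any(sp2$left_mask[11, , ]))
  expect_false(any(sp2$right_mask[11, , ]))
  # one-sided mask: a hemisphere would be empty
  b <- array(-1000, dim = c(21, 9, 5)); b[3, 3:7, 2:4] <- 30
  expect_error(split_hemispheres(brain_mask(b > -1000, c(1, 1, 1)),
                                 ct_volume(b, c(1, 1, 1))),
               "empty")
})

test_that("infarct estimate equals the independently recomposed volumes", {
  truth <- insert_lesion(make_head_phantom(small_spec(seed = 3)),
                         small_lesion(f = 0.3))
  mask <- extract_brain(truth$image)
  res <- correct_em_seg(truth$image, mask)
  rep <- estimate_infarct_volume(truth$image, mask, res, "right")
  # oracle recomposition from the primitive operations
  dmap <- difference_map(truth$image, res, mask)
  split <- split_hemispheres(mask, truth$image, "right")
  sel <- threshold_map(dmap, -1.5)
  v_i <- masked_volume_cc(sel & split$ipsi_mask, truth$image$spacing)
  v_c <- masked_volume_cc(sel & split$contra_mask, truth$image$spacing)
  expect_equal(rep$vol_ipsi_cc, v_i)
  expect_equal(rep$vol_contra_cc, v_c)
  expect_equal(rep$infarct_cc, v_i - v_c)
  expect_equal(rep$infarct_cc, rep$vol_ipsi_cc - rep$vol_contra_cc)
})

test_that("volumes are monotone in the threshold", {
  truth <- insert_lesion(make_head_phantom(small_spec(seed = 3)),
                         small_lesion(f = 0.3))
  mask <- extract_brain(truth$image)
  res <- correct_em_seg(truth$image, mask)
  prev_i <- Inf; prev_c <- Inf
  for (thr in c(-1.0, -1.5, -2.5, -4.0)) {
    rep <- estimate_infarct_volume(truth$image, mask, res, "right",
                                   upper_hu = thr)
    expect_lte(rep$vol_ipsi_cc, prev_i)
    expect_lte(rep$vol_contra_cc, prev_c)
    prev_i <- rep$vol_ipsi_cc; prev_c <- rep$vol_contra_cc
  }
})

test_that("auto side selection finds the lesioned hemisphere", {
  truth <- insert_lesion(make_head_phantom(small_spec(seed = 4)),
                         small_lesion(f = 0.3))
  mask <- extract_brain(truth$image)
  res <- correct_em_seg(truth$image, mask)
  rep <- estimate_infarct_volume(truth$image, mask, res, "auto")
  expect_equal(rep$side_ipsi, "right")
  expect_gte(rep$infarct_cc, 0)
  # forcing the wrong side yields the negated estimate plus a warning
  wrong <- estimate_infarct_volume(truth$image, mask, res, "left")
  expect_equal(wrong$infarct_cc, -rep$infarct_cc)
  expect_match(wrong$warnings, "negative", all = FALSE)
})

test_that("noiseless high-contrast lesion selection overlaps the truth", {
  truth <- insert_lesion(make_head_phantom(small_spec(seed = 2, noise_sigma = 0)),
                         small_lesion(f = 0.3))
  mask <- extract_brain(truth$image)
  for (fun in list(correct_em_seg, correct_hist_sharpen)) {
    res <- fun(truth$image, mask)
    sel <- threshold_map(difference_map(truth$image, res, mask), -1.5)
    dice <- 2 * sum(sel & truth$lesion_mask_true) /
      (sum(sel) + sum(truth$lesion_mask_true))
    expect_gt(dice, 0.5)
  }
})
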