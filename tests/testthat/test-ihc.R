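test_that("despeckle removes isolated pixels and matches a direct 3x3 median", {
  m <- matrix(0, 11, 11); m[6, 6] <- 1
  expect_equal(sum(despeckle(m)), 0)
  # solid 5x5 square: compare interior/corner behaviour to the brute-force
  # 3x3 median (replicate-padded at borders)
  sq <- matrix(0, 11, 11); sq[4:8, 4:8] <- 1
  expect_equal(despeckle(sq)[5:7, 5:7], brute_median3(sq)[5:7, 5:7])
  # square corners have 4 of 9 foreground neighbours -> removed
  expect_equal(despeckle(sq)[4, 4], 0)
  expect_equal(despeckle(sq)[6, 6], 1)
  cst <- matrix(3, 7, 7)
  expect_equal(despeckle(cst), cst)
})

test_that("opening removes sub-element specks and never grows the mask", {
  speck <- matrix(FALSE, 20, 20); speck[5:6, 5:6] <- TRUE
  expect_false(any(morpho_clean(speck, 2)))
  sq <- matrix(FALSE, 40, 40); sq[10:29, 10:29] <- TRUE
  opened <- morpho_clean(sq, 2)
  expect_lte(sum(opened), sum(sq))
  expect_true(all(opened[12:27, 12:27]))          # interior intact
  expect_false(any(morpho_clean(matrix(FALSE, 10, 10), 2)))
  # opening property on arbitrary noisy masks
  set.seed(3)
  for (i in 1:5) {
    m <- matrix(runif(900) < 0.4, 30, 30)
    expect_lte(sum(morpho_clean(m, 2)), sum(m))
  }
})

test_that("isodata threshold splits bimodal maps at the intermeans fixed point", {
  set.seed(10)
  map <- matrix(c(rnorm(600, 0.1, 0.02), rnorm(400, 1.0, 0.05)), 25, 40)
  mask <- threshold_channel(map, "isodata")
  thr <- attr(mask, "threshold")
  expect_gt(thr, 0.2); expect_lt(thr, 0.9)        # strictly between modes
  oracle <- oracle_intermeans(map)
  expect_equal(mask > 0, map >= oracle)           # same classification
  expect_equal(thr, oracle, tolerance = 2e-3)
  # fixed mode covers exactly the supra-threshold pixels
  half <- matrix(rep(c(0.1, 0.5), each = 50), 10, 10)
  fm <- threshold_channel(half, "fixed", 0.3)
  expect_equal(sum(fm), 50)
  expect_equal(attr(fm, "method"), "fixed")
  expect_error(threshold_channel(matrix(1, 5, 5), "isodata"), "degenerate")
  expect_error(threshold_channel(matrix(0.2, 5, 5), "fixed"), "value")
  # otsu also lands between the modes
  om <- threshold_channel(map, "otsu")
  expect_gt(attr(om, "threshold"), 0.2)
  expect_lt(attr(om, "threshold"), 0.9)
})

test_that("percent positive area is the DAB/tissue ratio with intersection capping", {
  tissue <- matrix(FALSE, 20, 20); tissue[1:10, 1:20] <- TRUE  # 200 px
  none <- matrix(FALSE, 20, 20)
  expect_equal(quantify_cytoplasmic(tissue, none)$percent_positive, 0)
  expect_equal(quantify_cytoplasmic(tissue, tissue)$percent_positive, 100)
  dab <- matrix(FALSE, 20, 20); dab[1:5, 1:5] <- TRUE          # 25 px inside
  res <- quantify_cytoplasmic(tissue, dab)
  expect_equal(res$percent_positive, 12.5)
  # DAB outside tissue is artefact: intersection keeps the ratio <= 100
  dab_out <- matrix(TRUE, 20, 20)
  expect_equal(quantify_cytoplasmic(tissue, dab_out)$percent_positive, 100)
  expect_error(quantify_cytoplasmic(none, dab), "tissue")
  # calibrated areas
  expect_equal(quantify_cytoplasmic(tissue, dab, pixel_size = 2)$dab_area_um2,
               25 * 4)
})

test_that("flat-field correction recovers a flat scene from a known gain field", {
  flat <- array(180, c(40, 40, 3))
  blank <- array(200, c(40, 40, 3))
  expect_equal(correct_background(flat, blank), flat, ignore_attr = TRUE)
  # scene x smooth gain, corrected with the gain itself as blank
  gain <- outer(seq(0.7, 1, length.out = 40), seq(0.8, 1, length.out = 40))
  gain <- EBImage::imageData(EBImage::gblur(gain, 4))
  scene <- array(150, c(40, 40, 3))
  obs <- scene
  blank2 <- scene
  for (c in 1:3) {
    obs[, , c] <- scene[, , c] * gain
    blank2[, , c] <- 230 * gain
  }
  rec <- correct_background(obs, blank2, blank_sigma = 0)
  expect_lt(max(abs(rec - median(rec))), 1.5)
  zero_blank <- blank
  zero_blank[1:20, 1:20, ] <- 0
  expect_error(correct_background(flat, zero_blank), "degenerate")
})

test_that("self-estimated illumination correction flattens a vignetted field", {
  set.seed(5)
  base <- array(200, c(64, 64, 3))
  vign <- 1 - 0.3 * (outer((1:64 - 32.5)^2, (1:64 - 32.5)^2, `+`) /
                       (2 * 31.5^2))
  img <- base
  for (c in 1:3) img[, , c] <- base[, , c] * vign
  rec <- correct_background(img)
  # corrected interior varies far less than the vignetted input
  # (the Gaussian gain estimate is least reliable at the frame border)
  expect_lt(diff(range(rec[10:55, 10:55, 1])),
            0.5 * diff(range(img[10:55, 10:55, 1])))
})

test_that("content cropping finds the joint bounding box of dark content", {
  img <- array(255, c(60, 80, 3))
  disk <- simple_disk(60, 80, 30, 40, 10)
  for (c in 1:3) img[, , c][disk] <- 50
  rect <- crop_to_content(img)
  expect_equal(rect$rows, range(which(rowSums(disk) > 0)))
  expect_equal(rect$cols, range(which(colSums(disk) > 0)))
  expect_false(rect$warning)
  expect_equal(dim(apply_crop(img, rect))[1], diff(rect$rows) + 1)
  # all-white stack falls back to the full frame with a warning flag
  blank <- array(255, c(30, 30, 3))
  r2 <- crop_to_content(list(blank, blank))
  expect_true(r2$warning)
  expect_equal(r2$rows, c(1, 30))
  # two images with content in opposite corners -> spanning rectangle
  a <- array(255, c(50, 50, 3)); a[3:10, 3:10, ] <- 40
  b <- array(255, c(50, 50, 3)); b[40:48, 41:47, ] <- 40
  r3 <- crop_to_content(list(a, b))
  expect_equal(r3$rows, c(3, 48))
  expect_equal(r3$cols, c(3, 47))
})

test_that("QC overlays draw outer contours with magenta over green", {
  img <- array(128, c(30, 30, 3))
  none <- matrix(FALSE, 30, 30)
  expect_equal(make_qc_overlay(img, none, none), img)
  sq <- matrix(FALSE, 30, 30); sq[10:19, 10:19] <- TRUE
  ov <- make_qc_overlay(img, sq, none)
  green <- ov[, , 1] == 0 & ov[, , 2] == 255 & ov[, , 3] == 0
  # outer contour of a k x k square dilated by a 3x3 box has 4k + 4 pixels
  expect_equal(sum(green), 4 * 10 + 4)
  expect_false(any(green & sq))                  # contour lies outside
  # overlapping contours: the positive (magenta) outline wins
  ov2 <- make_qc_overlay(img, sq, sq)
  magenta <- ov2[, , 1] == 255 & ov2[, , 2] == 0 & ov2[, , 3] == 255
  expect_equal(sum(magenta), 44)
  expect_equal(sum(ov2[, , 2] == 255 & ov2[, , 1] == 0), 0)
})
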