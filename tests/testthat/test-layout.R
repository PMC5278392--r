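test_that("the default layout is a 66-well 6 x 11 grid with marker column 11", {
  lay <- array_layout()
  expect_equal(lay$n_rows, 6L)
  expect_equal(lay$n_cols, 11L)
  expect_equal(lay$capacity, 66L)
  expect_equal(lay$marker_columns, 11L)
  expect_error(array_layout(pitch = 0), "pitch")
  expect_error(array_layout(marker_columns = 12), "marker")
})

test_that("spots on the grid assign perfectly and jitter below tolerance is harmless", {
  lay <- array_layout(pitch = 2000)
  nodes <- expand.grid(col = 1:11, row = 1:6)
  cen <- cbind(x = (nodes$col - 1) * 2000, y = (nodes$row - 1) * 2000)
  a <- assign_spots(cen, lay, tolerance = 600)
  expect_equal(sum(!is.na(a$row)), 66)
  expect_equal(max(a$residual), 0)
  expect_equal(a$row, nodes$row)
  expect_equal(a$col, nodes$col)
  set.seed(30)
  jit <- cen + matrix(runif(132, -250, 250), ncol = 2)
  aj <- assign_spots(jit, lay, tolerance = 600)
  expect_equal(aj$row, a$row)
  expect_equal(aj$col, a$col)
  expect_true(all(aj$residual[!is.na(aj$row)] <= 600))
  expect_error(assign_spots(cen, lay, tolerance = 1500), "half the pitch")
})

test_that("well conflicts resolve by smallest residual and assignments stay injective", {
  lay <- array_layout(pitch = 2000)
  cen <- rbind(c(100, 0), c(300, 50))   # both nearest well (1, 1)
  a <- assign_spots(cen, lay, tolerance = 800)
  expect_equal(a$row[1], 1); expect_equal(a$col[1], 1)
  expect_true(is.na(a$row[2]))
  set.seed(31)
  cen2 <- cbind(runif(40, 0, 20000), runif(40, 0, 10000))
  a2 <- assign_spots(cen2, lay, tolerance = 700)
  keys <- paste(a2$row, a2$col)[!is.na(a2$row)]
  expect_equal(anyDuplicated(keys), 0)
  # permissive marker wells may hold several spots
  m <- rbind(c(20000, 0), c(20100, 80))  # both near well (1, 11)
  am <- assign_spots(m, lay, tolerance = 800, permissive_markers = TRUE)
  expect_equal(sum(!is.na(am$row)), 2)
})

test_that("assignment is invariant to global translation when the origin is re-estimated", {
  lay <- array_layout(pitch = 2000)
  set.seed(32)
  nodes <- expand.grid(col = 1:11, row = 1:6)
  cen <- cbind((nodes$col - 1) * 2000, (nodes$row - 1) * 2000) +
    matrix(runif(132, -150, 150), ncol = 2)
  a0 <- assign_spots(cen, lay, tolerance = 600, estimate_origin = TRUE)
  shift <- cbind(cen[, 1] + 12345, cen[, 2] - 6789)
  a1 <- assign_spots(shift, lay, tolerance = 600, estimate_origin = TRUE)
  expect_equal(a1$row, a0$row)
  expect_equal(a1$col, a0$col)
})

test_that("central-band section counts follow the floor formula and its monotonicity", {
  expect_equal(sections_in_center_band(500, 0.2, 4), 50L)
  expect_equal(sections_in_center_band(500, 0, 4), 0L)
  expect_equal(sections_in_center_band(300, 0.2, 4), 30L)
  expect_error(sections_in_center_band(500, 0.2, 0), "thickness")
  expect_error(sections_in_center_band(500, 0.7, 4), "band_fraction")
  diam <- seq(200, 1000, by = 100)
  expect_true(!is.unsorted(vapply(diam, sections_in_center_band,
                                  integer(1), band_fraction = 0.2,
                                  thickness = 4)))
  thick <- c(2, 4, 8, 12)
  expect_true(!is.unsorted(rev(vapply(thick, function(t)
    sections_in_center_band(500, 0.2, t), integer(1)))))
})

test_that("workflow economics reproduce the array-versus-separate arithmetic", {
  full <- plan_workflow(11, 6, 3)
  expect_equal(full$fold_saving, 11)
  expect_equal(full$blocks_array, 1L)
  dose <- plan_workflow(10, 6, 3)
  expect_equal(dose$blocks_separate, 10)        # samples per plate
  expect_equal(dose$slides_separate, 30)        # 3 slides per condition
  expect_equal(plan_workflow(1, 6, 3)$fold_saving, 1)
  expect_error(plan_workflow(12, 6, 3), "capacity")
})
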