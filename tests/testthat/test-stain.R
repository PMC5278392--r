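test_that("optical-density transform follows Beer-Lambert with the dark clamp", {
  px <- function(v) array(rep(v, each = 1), c(1, 1, 3))
  expect_equal(as.numeric(rgb_to_od(px(c(255, 255, 255)))), c(0, 0, 0))
  expect_equal(as.numeric(rgb_to_od(px(c(26, 26, 26)))),
               rep(-log10(26 / 255), 3), tolerance = 1e-12)
  # black pixels are clamped to intensity 1 to stay finite
  expect_equal(as.numeric(rgb_to_od(px(c(0, 0, 0)))),
               rep(log10(255), 3), tolerance = 1e-12)
  expect_error(rgb_to_od(px(c(10, 10, 10)), background_intensity = 0),
               "positive")
  # monotone decreasing in intensity
  ods <- vapply(c(10, 50, 100, 200, 255),
                function(i) rgb_to_od(px(rep(i, 3)))[1, 1, 1], numeric(1))
  expect_true(all(diff(ods) < 0))
})

test_that("stain systems are unit-norm, invertible, and reject collinear vectors", {
  ortho <- stain_system(c(1, 0, 0), c(0, 1, 0))
  expect_equal(ortho$vectors[3, ], c(r = 0, g = 0, b = 1))
  expect_equal(unname(ortho$inverse), diag(3), tolerance = 1e-12)
  sys <- stain_system()
  expect_equal(sqrt(rowSums(sys$vectors^2)), c(h = 1, dab = 1, residual = 1),
               tolerance = 1e-9)
  expect_equal(unname(sys$inverse %*% t(sys$vectors)), diag(3),
               tolerance = 1e-9)
  # residual orthogonal to both stains when auto-generated
  expect_equal(as.numeric(sys$vectors[3, ] %*% sys$vectors[1, ]), 0,
               tolerance = 1e-12)
  expect_error(stain_system(c(1, 1, 1), c(2, 2, 2)), "singular")
  expect_error(stain_system(c(0, 0, 0), c(1, 0, 0)), "singular")
})

test_that("deconvolution inverts the forward model on basis and synthetic inputs", {
  sys <- stain_system()
  # pure unit H density synthesised and deconvolved comes back as (1, 0, 0)
  maps <- array(0, c(1, 1, 3)); maps[1, 1, 1] <- 1
  od <- array(sys$vectors[1, ], c(1, 1, 3))
  expect_equal(as.numeric(deconvolve(od, sys)), c(1, 0, 0), tolerance = 1e-6)
  # 1x1 OD equal to the DAB row -> (0, 1, 0)
  od_dab <- array(sys$vectors[2, ], c(1, 1, 3))
  expect_equal(as.numeric(deconvolve(od_dab, sys)), c(0, 1, 0),
               tolerance = 1e-9)
  expect_equal(deconvolve(array(0, c(4, 5, 3)), sys), array(0, c(4, 5, 3)),
               ignore_attr = TRUE)
})

test_that("deconvolution is linear and equals projection for orthonormal systems", {
  sys <- stain_system()
  set.seed(42)
  a <- array(runif(2 * 3 * 3, 0, 1), c(2, 3, 3))
  b <- array(runif(2 * 3 * 3, 0, 1), c(2, 3, 3))
  expect_equal(deconvolve(a + b, sys), deconvolve(a, sys) + deconvolve(b, sys),
               tolerance = 1e-9)
  ortho <- stain_system(c(1, 0, 0), c(0, 1, 0))
  od <- array(runif(12), c(2, 2, 3))
  proj <- array(matrix(od, ncol = 3) %*% t(ortho$vectors), c(2, 2, 3))
  expect_equal(unname(deconvolve(od, ortho)), unname(proj), tolerance = 1e-12)
})

test_that("synthesis saturates, reconstructs OD exactly, and round-trips at 8-bit accuracy", {
  sys <- stain_system()
  expect_equal(unique(as.numeric(synthesize_rgb(array(0, c(2, 2, 3)), sys))),
               255)
  dark <- array(c(3, 3, 0), c(1, 1, 3))   # 3 OD of both stains
  expect_true(all(synthesize_rgb(dark, sys) <= 1))
  expect_error(synthesize_rgb(array(-1, c(1, 1, 3)), sys), "nonnegative")
  # ConcentrationMaps contract: maps %*% vectors reproduces the input OD
  set.seed(7)
  od <- array(runif(5 * 5 * 3, 0, 1.5), c(5, 5, 3))
  maps <- deconvolve(od, sys)
  back <- array(matrix(maps, ncol = 3) %*% sys$vectors, dim(od))
  expect_equal(back, od, tolerance = 1e-9, ignore_attr = TRUE)
  # 8-bit quantisation limit: fields kept below 0.6 OD per channel recover
  # within 0.01 per stain
  set.seed(8)
  for (i in 1:20) {
    m <- array(runif(8 * 8 * 3, 0, 0.3), c(8, 8, 3)); m[, , 3] <- 0
    rec <- deconvolve(rgb_to_od(synthesize_rgb(m, sys)), sys)
    expect_lt(max(abs(rec - m)), 0.01)
  }
})
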