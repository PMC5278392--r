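test_that("median absolute deviation matches the brute-force oracle and ignores outliers", {
  expect_equal(median_abs_deviation(c(5, 5, 5)), 0)
  expect_equal(median_abs_deviation(c(1, 2, 3), scale = 1), 1)
  expect_equal(median_abs_deviation(c(1, 2, 3, 100), scale = 1), 1)
  expect_error(median_abs_deviation(numeric(0)), "empty")
  # exhaustive agreement on short lists over a small value grid
  grid <- c(0, 2, 4, 6, 9)
  set.seed(14)
  for (i in 1:200) {
    x <- sample(grid, sample(2:6, 1), replace = TRUE)
    expect_equal(median_abs_deviation(x, 1), brute_mad(x, 1))
    expect_equal(median_abs_deviation(x, 1.4826), brute_mad(x, 1.4826))
  }
})

test_that("robust Z' follows its defining formula and rejects zero separation", {
  expect_equal(robust_z_prime(c(10, 10, 10), c(0, 0, 0)), 1)
  # medians 10 and 1 separate by 9; raw MADs are 2 and 1
  expect_equal(robust_z_prime(c(8, 10, 12), c(0, 1, 2), mad_scale = 1),
               1 - 3 * (2 + 1) / 9)
  expect_error(robust_z_prime(c(4, 5, 6), c(5, 5)), "separation")
  expect_error(robust_z_prime(c(1), c(0, 0)), "at least 2")
  # brute-force oracle on random short integer lists
  grid <- c(0, 2, 4, 6, 9)
  set.seed(15)
  for (i in 1:200) {
    s <- sample(grid, sample(2:6, 1), replace = TRUE) + 10
    c0 <- sample(grid, sample(2:6, 1), replace = TRUE)
    if (brute_median(s) == brute_median(c0)) next
    expect_equal(robust_z_prime(s, c0, 1), brute_z_prime(s, c0, 1))
  }
  expect_lte(robust_z_prime(c(0, 50, 100), c(200, 210, 220)), 1)
})

test_that("Z' is affine-invariant and decreases with control dispersion", {
  set.seed(16)
  for (i in 1:100) {
    s <- rnorm(8, 80, 5); c0 <- rnorm(8, 10, 3)
    a <- runif(1, 0.1, 5); b <- runif(1, -20, 20)
    expect_equal(robust_z_prime(a * s + b, a * c0 + b),
                 robust_z_prime(s, c0), tolerance = 1e-10)
  }
  base <- c(-2, -1, 0, 1, 2)
  z <- vapply(c(0.5, 1, 2, 4), function(k)
    robust_z_prime(100 + base, 10 + k * base), numeric(1))
  expect_true(all(diff(z) < 0))
})

test_that("assay classification applies the strict Z' > 0.5 rule", {
  expect_equal(classify_assay(0.80), "acceptable")
  expect_equal(classify_assay(0.54), "acceptable")
  expect_equal(classify_assay(0), "unacceptable")
  expect_equal(classify_assay(0.5), "unacceptable")
  expect_error(classify_assay(NaN), "finite")
})

test_that("4PL fitting recovers noiseless parameters and flags degenerate input", {
  d <- simulate_dose_response(top = 50, bottom = 0, ic50 = 0.9, hill = 1)
  f <- fit_4pl(d$dose, d$response, constrain_bottom_zero = TRUE)
  expect_equal(f$ic50, 0.9, tolerance = 1e-6)
  expect_equal(f$top, 50, tolerance = 1e-6)
  expect_equal(f$hill, 1, tolerance = 1e-6)
  expect_equal(f$bottom, 0)
  expect_true(f$ic50_ci[1] <= f$ic50 && f$ic50 <= f$ic50_ci[2])
  # unconstrained fit on a rising curve (negative hill in this form)
  d2 <- simulate_dose_response(top = 16, bottom = 3, ic50 = 1.3, hill = -1)
  f2 <- fit_4pl(d2$dose, d2$response)
  expect_equal(f2$ic50, 1.3, tolerance = 1e-4)
  expect_equal(f2$bottom, 3, tolerance = 1e-4)
  expect_error(fit_4pl(c(1, 2, 4, 8, 16), rep(7, 5)), "degenerate")
  expect_error(fit_4pl(c(1, 2, 4), c(5, 3, 1)), "distinct doses")
  # zero-dose controls are offset below the smallest nonzero dose
  d3 <- rbind(data.frame(dose = 0, response = 50), d)
  f3 <- fit_4pl(d3$dose, d3$response, constrain_bottom_zero = TRUE)
  expect_equal(f3$ic50, 0.9, tolerance = 0.05)
})

test_that("constraining the bottom can only increase the residual sum of squares", {
  for (s in 1:5) {
    d <- simulate_dose_response(top = 50, bottom = 2, ic50 = 1, hill = 1.2,
                                noise_sd = 2.5, seed = s)
    fc <- fit_4pl(d$dose, d$response, constrain_bottom_zero = TRUE)
    fu <- fit_4pl(d$dose, d$response, constrain_bottom_zero = FALSE)
    expect_gte(fc$rss, fu$rss - 1e-8)
  }
})
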