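test_that("pmf matches closed form, symmetry and normalization", {
  # t = 0, n = 1, l1 = l2 = 1: e^-2 I_0(2), and the convolution oracle
  expect_equal(skellam_pmf(0, 1, 1, 1), exp(-2) * besselI(2, 0),
               tolerance = 1e-14)
  expect_equal(skellam_pmf(0, 1, 1, 1), conv_pmf(0, 1, 1, 1),
               tolerance = 1e-12)
  # symmetry about 0 under equal rates
  expect_identical(skellam_pmf(3, 1, 2, 2), skellam_pmf(-3, 1, 2, 2))
  # normalization over a wide window
  expect_equal(sum(skellam_pmf(-200:200, 5, 3, 2)), 1, tolerance = 1e-12)
})

test_that("pmf equals the Poisson convolution over a parameter grid", {
  for (n in c(1, 3)) {
    for (l1 in c(0.5, 2)) {
      for (l2 in c(0.5, 2)) {
        t <- -30:30
        expect_equal(skellam_pmf(t, n, l1, l2), conv_pmf(t, n, l1, l2),
                     tolerance = 1e-12,
                     info = sprintf("n=%d l1=%g l2=%g", n, l1, l2))
        # arm-swap symmetry: g(t | l1, l2) = g(-t | l2, l1)
        expect_equal(skellam_pmf(t, n, l1, l2),
                     skellam_pmf(-t, n, l2, l1), tolerance = 1e-12)
      }
    }
  }
})

test_that("pmf moments match mean n(l1-l2) and variance n(l1+l2)", {
  for (p in list(c(2, 3, 1), c(5, 1.5, 4), c(10, 8, 8))) {
    n <- p[1]; l1 <- p[2]; l2 <- p[3]
    mu <- n * (l1 - l2)
    sig <- sqrt(n * (l1 + l2))
    supp <- floor(mu - 40 * sig):ceiling(mu + 40 * sig)
    g <- skellam_pmf(supp, n, l1, l2)
    expect_equal(sum(supp * g), mu, tolerance = 1e-8)
    expect_equal(sum((supp - mu)^2 * g), sig^2,
                 tolerance = 1e-8 * sig^2 + 1e-10)
  }
})

test_that("cdf agrees with brute-force convolution and closed symmetry", {
  # under l1 = l2 the distribution is symmetric about 0:
  # G(-1) = (1 - g(0)) / 2
  expect_equal(skellam_cdf(-1, 1, 1, 1),
               (1 - skellam_pmf(0, 1, 1, 1)) / 2, tolerance = 1e-12)
  expect_equal(skellam_cdf(0, 1, 1, 1), conv_cdf(0, 1, 1, 1),
               tolerance = 1e-12)
  expect_equal(skellam_cdf(0, 1, 1, 1), 0.654254, tolerance = 1e-6)
  # upper limit saturates
  expect_equal(skellam_cdf(1e6, 10, 30, 30), 1, tolerance = 1e-12)
  expect_equal(skellam_cdf(-1e6, 10, 30, 30), 0, tolerance = 1e-12)
})

test_that("chi-squared and summation cdf routes agree to 1e-10", {
  cases <- list(c(1, 1, 1), c(5, 3, 2), c(42, 15, 12.75), c(73, 30, 30))
  for (p in cases) {
    n <- p[1]; l1 <- p[2]; l2 <- p[3]
    mu <- n * (l1 - l2)
    sig <- sqrt(n * (l1 + l2))
    t <- floor(mu - 6 * sig):ceiling(mu + 6 * sig)
    expect_equal(skellam_cdf(t, n, l1, l2, method = "chisq"),
                 skellam_cdf(t, n, l1, l2, method = "sum"),
                 tolerance = 1e-10,
                 info = sprintf("n=%g l1=%g l2=%g", n, l1, l2))
  }
})

test_that("cdf increments reproduce the pmf across the bulk", {
  n <- 20; l1 <- 6; l2 <- 4
  mu <- n * (l1 - l2)
  sig <- sqrt(n * (l1 + l2))
  t <- floor(mu - 10 * sig):ceiling(mu + 10 * sig)
  expect_equal(skellam_cdf(t, n, l1, l2) - skellam_cdf(t - 1, n, l1, l2),
               skellam_pmf(t, n, l1, l2), tolerance = 1e-10)
})

test_that("large-rate evaluation does not overflow", {
  # n * lambda = 1e4 per arm
  p <- skellam_pmf(c(0, 50, -120), 100, 100, 100)
  expect_true(all(is.finite(p) & p >= 0 & p <= 1))
  expect_gt(p[1], 0)
  expect_equal(sum(skellam_pmf(-4000:4000, 100, 100, 100)), 1,
               tolerance = 1e-10)
})

test_that("contract violations are rejected", {
  expect_error(skellam_pmf(0.5, 1, 1, 1), "integer")
  expect_error(skellam_pmf(0, 1, -1, 1), "positive")
  expect_error(skellam_cdf(0, 0, 1, 1), "positive integer")
})
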