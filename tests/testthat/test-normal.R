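test_that("information levels follow kn/(lambda1+lambda2)", {
  expect_equal(information_levels(1, 30, 15, 15), 1)
  expect_equal(information_levels(3, 10, 2, 3), c(2, 4, 6))
  lv <- information_levels(5, 7, 1.3, 2.9)
  expect_true(all(diff(lv) > 0))
})

test_that("single-stage probabilities match the univariate closed form", {
  d <- gs_design(1, 50, a = 1.6449, r = 1.6449, engine = "normal")
  p <- normal_stage_probs(d, 20, 20)
  expect_equal(p$reject, 1 - pnorm(1.6449), tolerance = 1e-8)
  expect_equal(p$accept + p$reject, 1, tolerance = 1e-8)
  # with drift: mean (l1-l2) sqrt(I1)
  p2 <- normal_stage_probs(d, 20, 18)
  i1 <- information_levels(1, 50, 20, 18)
  expect_equal(p2$reject, 1 - pnorm(1.6449 - 2 * sqrt(i1)), tolerance = 1e-8)
})

test_that("two-stage probabilities agree with bivariate normal simulation", {
  d <- gs_design(2, 40, a = c(0, 1.8), r = c(1.8, 1.8), engine = "normal")
  p <- normal_stage_probs(d, 15, 15)
  # canonical correlation sqrt(1/2): simulate the joint Wald path
  set.seed(42)
  m <- 1e6
  z1 <- rnorm(m)
  z2 <- (z1 + rnorm(m)) / sqrt(2)       # corr sqrt(1/2), unit variance
  r1 <- mean(z1 >= 1.8)
  a1 <- mean(z1 < 0)
  cont <- z1 >= 0 & z1 < 1.8
  r2 <- mean(cont & z2 >= 1.8)
  a2 <- mean(cont & z2 < 1.8) # final stage: accept below shared boundary
  for (pair in list(c(p$reject[1], r1), c(p$accept[1], a1),
                    c(p$reject[2], r2), c(p$accept[2], a2))) {
    se <- sqrt(pair[2] * (1 - pair[2]) / m)
    expect_lt(abs(pair[1] - pair[2]), 3 * se + 1e-8)
  }
  expect_equal(sum(p$accept + p$reject), 1, tolerance = 1e-5)
})

test_that("null stopping probabilities do not depend on the shared rate", {
  d <- gs_design(2, 38, a = c(0.42, 1.67), r = c(2.17, 1.67),
                 engine = "normal")
  rej <- vapply(c(15, 20, 25, 30), function(l) {
    sum(normal_stage_probs(d, l, l)$reject)
  }, numeric(1))
  expect_lt(max(rej) - min(rej), 1e-6)
})

test_that("type-II error is maximized at the upper end of the alternative set", {
  d <- gs_design(2, 38, a = c(0.42, 1.67), r = c(2.17, 1.67),
                 engine = "normal")
  acc <- vapply(seq(15, 30, by = 2.5), function(l) {
    sum(normal_stage_probs(d, l, l - 2.25)$accept)
  }, numeric(1))
  expect_equal(which.max(acc), length(acc))
  t2 <- normal_max_error(d, osah, "typeII")
  expect_equal(t2$value, acc[length(acc)], tolerance = 1e-8)
  expect_equal(t2$argmax, 30)
})

test_that("completeness holds for random valid normal designs", {
  set.seed(5)
  for (i in 1:6) {
    K <- sample(2:4, 1)
    a <- sort(runif(K, -1, 1))
    r <- a + c(runif(K - 1, 0.5, 2), 0)
    a[K] <- r[K] <- max(a[K], r[K - 1] - 0.2)
    if (any(a[-K] >= r[-K])) next
    d <- gs_design(K, sample(10:60, 1), a, r, engine = "normal")
    l1 <- runif(1, 5, 30)
    p <- normal_stage_probs(d, l1, l1 * runif(1, 0.8, 1))
    expect_equal(sum(p$accept + p$reject), 1, tolerance = 1e-5)
    ess <- normal_ess(d, l1, l1)
    expect_gte(ess, 2 * d$n)
    expect_lte(ess, 2 * K * d$n)
  }
})

test_that("exact and normal single-stage rejection probabilities converge", {
  # large groups: integer boundary mapped to the standardized scale
  n <- 250
  for (l in c(15, 22, 30)) {
    rb <- ceiling(1.96 * sqrt(2 * n * l))
    d_ex <- gs_design(1, n, a = rb, r = rb)
    z <- (rb - 0.5) / sqrt(2 * n * l) # continuity-matched standardization
    d_no <- gs_design(1, n, a = z, r = z, engine = "normal")
    p_ex <- exact_stage_probs(d_ex, l, l)$reject
    p_no <- normal_stage_probs(d_no, l, l)$reject
    expect_lt(abs(p_ex - p_no), 0.01)
  }
})
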