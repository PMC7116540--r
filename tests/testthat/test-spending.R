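test_that("spending plans validate their budgets", {
  p <- spending_plan(c(0.1, 0.1), c(0.015, 0.035))
  expect_s3_class(p, "gs_spending_plan")
  expect_error(spending_plan(c(0.1, -0.1), c(0.02, 0.03)), "nonnegative")
  expect_error(spending_plan(0.2, c(0.01, 0.04)), "equal positive length")
  # conformance against the problem is enforced at derivation time
  expect_error(
    derive_boundaries(40, spending_plan(c(0.1, 0.2), c(0.015, 0.035)), osah),
    "conform")
})

test_that("normal single-stage boundary is the alpha quantile", {
  d <- derive_boundaries(71, spending_plan(0.2, 0.05), osah, "normal")
  expect_equal(d$r, qnorm(0.95), tolerance = 1e-6)
  expect_equal(d$a, d$r)
})

test_that("exact spending-derived boundaries respect their stage budgets", {
  plan <- spending_plan(c(0.1, 0.1), c(0.015, 0.035))
  cache <- gspois:::new_skellam_cache()
  d <- derive_boundaries(40, plan, osah, "exact", cache = cache)
  expect_s3_class(d, "gs_design")
  # stage-1 budgets hold with equality-adjacent integers: the chosen
  # boundary meets the cap and the next integer inward violates it
  r1_spend <- function(b) {
    gspois:::max_over_interval(function(l) {
      1 - skellam_cdf(b - 1, 40, l, l)
    }, osah$lambda0)$value
  }
  expect_lte(r1_spend(d$r[1]), 0.015)
  expect_gt(r1_spend(d$r[1] - 1), 0.015)
  a1_spend <- function(b) {
    gspois:::max_over_interval(function(l) {
      skellam_cdf(b - 1, 40, l, l - 2.25)
    }, osah$lambda1)$value
  }
  expect_lte(a1_spend(d$a[1]), 0.1)
  expect_gt(a1_spend(d$a[1] + 1), 0.1)
  # overall type-I control by construction
  expect_lte(exact_max_error(d, osah, "typeI")$value, 0.05 + 1e-10)
})

test_that("boundary derivation is reproducible", {
  plan <- spending_plan(c(0.14, 0.06), c(0.01, 0.04))
  d1 <- derive_boundaries(42, plan, osah, "exact")
  d2 <- derive_boundaries(42, plan, osah, "exact")
  expect_identical(d1[c("K", "n", "a", "r")], d2[c("K", "n", "a", "r")])
})

test_that("shifting rejection spending to stage 1 lowers the first boundary", {
  base <- derive_boundaries(40, spending_plan(c(0.1, 0.1), c(0.015, 0.035)),
                            osah, "exact")
  more <- derive_boundaries(40, spending_plan(c(0.1, 0.1), c(0.03, 0.02)),
                            osah, "exact")
  expect_lte(more$r[1], base$r[1])
})

test_that("group-size search solves a small problem from first principles", {
  # point hypotheses with a huge effect: a single subject per arm suffices
  prob <- design_problem(1, 6, delta = 5, alpha = 0.05, beta = 0.2,
                         lambda_ess = 6)
  d <- find_group_size(spending_plan(0.2, 0.05), prob, "exact", n_cap = 10)
  expect_s3_class(d, "gs_design")
  expect_equal(d$n, 1)
  expect_lte(exact_max_error(d, prob, "typeII")$value, 0.2)
  expect_lte(exact_max_error(d, prob, "typeI")$value, 0.05)
})

test_that("group-size search reports failure with the best attempt", {
  prob <- design_problem(c(15, 30), c(15, 30), delta = 2.25, alpha = 0.05,
                         beta = 0.2, lambda_ess = 15)
  res <- find_group_size(spending_plan(0.2, 0.05), prob, "exact", n_cap = 10)
  expect_s3_class(res, "gs_notfound")
  expect_true(is.finite(res$best_beta) && res$best_beta > 0.2)
  expect_true(res$best_n <= 10)
})

test_that("tiny group sizes leave two-stage plans infeasible or underpowered", {
  plan <- spending_plan(c(0.1, 0.1), c(0.015, 0.035))
  d <- derive_boundaries(1, plan, osah, "exact")
  if (!gspois:::is_infeasible(d)) {
    expect_gt(exact_max_error(d, osah, "typeII")$value, osah$beta)
  } else {
    expect_s3_class(d, "gs_infeasible")
  }
})
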