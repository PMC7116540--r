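test_that("optimality score is the stated weighted combination", {
  d <- gs_design(2, 40, a = c(28, 116), r = c(107, 116))
  s1 <- optimality_score(d, c(1, 0, 0), osah)
  expect_equal(s1, exact_ess(d, 15, 15), tolerance = 1e-10)
  # mixed weights reduce to arithmetic on the module's own ESS output
  s6 <- optimality_score(d, c(1 / 3, 0, 1 / 3), osah)
  expect_equal(s6, (exact_ess(d, 15, 15) + 160) / 3, tolerance = 1e-10)
  # linearity: scaling weights scales the score
  expect_equal(optimality_score(d, 2 * c(1 / 3, 0, 1 / 3), osah), 2 * s6,
               tolerance = 1e-10)
  expect_error(optimality_score(d, c(0, 0, 1), osah), "w1 \\+ w2")
})

test_that("spending grids enumerate conforming plans only", {
  plans2 <- spending_grid(osah, K = 2)
  expect_length(plans2, 81)
  for (p in plans2[c(1, 40, 81)]) {
    expect_equal(sum(p$pi_A), 0.2, tolerance = 1e-12)
    expect_equal(sum(p$pi_R), 0.05, tolerance = 1e-12)
    expect_true(all(p$pi_A >= 0) && all(p$pi_R >= 0))
  }
  # the K = 3 default grid keeps only budget-permissible combinations:
  # 13 acceptance pairs (sum <= beta) x 26 rejection pairs (sum <= alpha)
  expect_warning(plans3 <- spending_grid(osah, K = 3), "dropped")
  expect_length(plans3, 13 * 26)
  expect_true(all(vapply(plans3, function(p) {
    abs(sum(p$pi_A) - 0.2) < 1e-12 && abs(sum(p$pi_R) - 0.05) < 1e-12 &&
      all(p$pi_A >= 0) && all(p$pi_R >= 0)
  }, logical(1))))
  # an over-budget interim grid triggers the drop warning
  expect_warning(
    spending_grid(osah, K = 2, pi_A_interim = list(c(0.1, 0.25)),
                  pi_R_interim = list(0.01)),
    "dropped")
})

test_that("a degenerate single-plan grid returns that plan's design", {
  plan <- spending_plan(c(0.1, 0.1), c(0.015, 0.035))
  res <- grid_search(list(plan), c(1, 0, 0), osah, "exact", n_cap = 60)
  expect_equal(nrow(res), 1)
  expect_equal(res$n, 40)
  expect_equal(res$a[[1]], c(28, 116))
  expect_equal(res$r[[1]], c(107, 116))
  expect_equal(res$score, res$ess_null, tolerance = 1e-10)
})

test_that("grid search ranks by score and keeps the winner first", {
  plans <- list(
    spending_plan(c(0.14, 0.06), c(0.01, 0.04)),   # the w1 winner
    spending_plan(c(0.1, 0.1), c(0.015, 0.035)),
    spending_plan(c(0.02, 0.18), c(0.03, 0.02))
  )
  res <- grid_search(plans, c(1, 0, 0), osah, "exact", n_cap = 60)
  expect_equal(nrow(res), 3)
  expect_true(!is.unsorted(res$score))
  expect_equal(res$n[1], 42)
  expect_equal(res$a[[1]], c(41, 112))
  expect_equal(res$r[[1]], c(118, 112))
  # every returned design controls both error rates under its own engine
  for (i in seq_len(nrow(res))) {
    expect_lte(res$alpha_max[i], osah$alpha + 1e-10)
    expect_lte(1 - res$power[i], osah$beta + 1e-10)
  }
  # nonconforming plans are dropped with a warning
  expect_warning(
    grid_search(list(plans[[1]], spending_plan(c(0.1, 0.2), c(0.01, 0.04))),
                c(1, 0, 0), osah, "exact", n_cap = 60),
    "conform")
})

test_that("normal-engine grid search reproduces a spending-derived design", {
  plan <- spending_plan(c(0.08, 0.12), c(0.015, 0.035))
  res <- grid_search(list(plan), c(1 / 3, 0, 1 / 3), osah, "normal",
                     n_cap = 80)
  expect_equal(res$n[1], 38)
  expect_equal(res$a[[1]][1], 0.42, tolerance = 0.005)
  expect_equal(res$r[[1]][1], 2.17, tolerance = 0.005)
  expect_equal(res$ess_null[1], 100.5, tolerance = 0.05)
})
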