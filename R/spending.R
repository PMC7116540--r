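#' Error spending plan
#'
#' Stage-wise budgets for the type-I (`pi_R`) and type-II (`pi_A`) error
#' rates. A plan conforming to a problem satisfies `sum(pi_R) == alpha` and
#' `sum(pi_A) == beta` with all entries nonnegative.
#'
#' @param pi_A Length-`K` nonnegative acceptance (futility) spending vector.
#' @param pi_R Length-`K` nonnegative rejection (efficacy) spending vector.
#' @return An object of class `gs_spending_plan`.
#' @examples
#' spending_plan(pi_A = c(0.1, 0.1), pi_R = c(0.015, 0.035))
#' @export
spending_plan <- function(pi_A, pi_R) {
  pi_A <- as.numeric(pi_A)
  pi_R <- as.numeric(pi_R)
  if (length(pi_A) != length(pi_R) || length(pi_A) < 1) {
    stop("`pi_A` and `pi_R` must have equal positive length", call. = FALSE)
  }
  if (any(!is.finite(pi_A)) || any(!is.finite(pi_R)) ||
      any(pi_A < 0) || any(pi_R < 0)) {
    stop("spending entries must be nonnegative and finite", call. = FALSE)
  }
  structure(list(pi_A = pi_A, pi_R = pi_R, K = length(pi_A)),
            class = "gs_spending_plan")
}

#' @export
print.gs_spending_plan <- function(x, ...) {
  cat("error spending plan (K =", x$K, ")\n")
  cat("  pi_A:", paste(format(x$pi_A), collapse = ", "), "\n")
  cat("  pi_R:", paste(format(x$pi_R), collapse = ", "), "\n")
  invisible(x)
}

check_plan_conforms <- function(plan, problem, tol = 1e-8) {
  if (!inherits(plan, "gs_spending_plan")) {
    stop("`plan` must be a `spending_plan()`", call. = FALSE)
  }
  if (abs(sum(plan$pi_R) - problem$alpha) > tol ||
      abs(sum(plan$pi_A) - problem$beta) > tol) {
    stop("spending plan does not conform to the problem: need ",
         "sum(pi_R) = alpha and sum(pi_A) = beta", call. = FALSE)
  }
  invisible(TRUE)
}

is_infeasible <- function(x) inherits(x, "gs_infeasible")

infeasible <- function(stage, reason) {
  structure(list(stage = stage, reason = reason), class = "gs_infeasible")
}

#' @export
print.gs_infeasible <- function(x, ...) {
  cat("infeasible design (stage", x$stage, "):", x$reason, "\n")
  invisible(x)
}

# ---- stage-spending evaluators --------------------------------------------

# Exact engine: probability of stopping at stage k on the given side, with
# boundary `bound` at stage k and the supplied interim boundaries before it.
# The interim sub-density through stage k-1 is cached per
# (n, rates, a_prev, r_prev) because integer boundary solves re-evaluate it
# for many candidate bounds.
exact_stage_spend <- function(k, n, a_prev, r_prev, bound, side,
                              lambda1, lambda2, cache) {
  win_pts <- c(a_prev, r_prev, bound)
  m <- floor(min(win_pts))
  M <- ceiling(max(win_pts))
  win <- c(min(m, m - M) - 2, max(M, M - m) + 1)
  tab <- skellam_table(cache, n, lambda1, lambda2, win[1], win[2])
  if (k == 1) {
    return(if (side == "reject") 1 - tab_cdf(tab, bound - 1)
           else tab_cdf(tab, bound - 1))
  }
  hkey <- paste("h", n, signif(lambda1, 15), signif(lambda2, 15),
                paste(a_prev, collapse = ","), paste(r_prev, collapse = ","),
                sep = "|")
  hrec <- if (!is.null(cache)) cache[[hkey]] else NULL
  if (is.null(hrec)) {
    ts <- a_prev[1]:(r_prev[1] - 1)
    hv <- tab_pmf(tab, ts)
    if (k > 2) {
      for (j in 2:(k - 1)) {
        us <- a_prev[j]:(r_prev[j] - 1)
        d0 <- us[1] - ts[length(ts)]
        gv <- tab_pmf(tab, d0:(us[length(us)] - ts[1]))
        hv <- vapply(us, function(u) sum(hv * gv[u - ts - d0 + 1]),
                     numeric(1))
        ts <- us
      }
    }
    hrec <- list(ts = ts, hv = hv)
    if (!is.null(cache)) cache[[hkey]] <- hrec
  }
  if (side == "reject") {
    sum(hrec$hv * (1 - tab_cdf(tab, bound - 1 - hrec$ts)))
  } else {
    sum(hrec$hv * tab_cdf(tab, bound - 1 - hrec$ts))
  }
}

# Normal engine: same quantity from the canonical joint distribution.
normal_stage_spend <- function(k, n, a_prev, r_prev, bound, side,
                               lambda1, lambda2, nodes = GL_NODES) {
  theta <- lambda1 - lambda2
  delta_i <- n / (lambda1 + lambda2)
  sd_inc <- sqrt(delta_i)
  if (k == 1) {
    z <- bound - theta * sqrt(delta_i)
    return(if (side == "reject") stats::pnorm(z, lower.tail = FALSE)
           else stats::pnorm(z))
  }
  rule <- gl_rule(nodes)
  lo <- a_prev[1] * sqrt(delta_i)
  hi <- r_prev[1] * sqrt(delta_i)
  x <- (hi - lo) / 2 * rule$x + (hi + lo) / 2
  w <- (hi - lo) / 2 * rule$w
  f <- stats::dnorm(x, mean = theta * delta_i, sd = sd_inc)
  if (k > 2) {
    for (j in 2:(k - 1)) {
      aj <- a_prev[j] * sqrt(delta_i * j)
      rj <- r_prev[j] * sqrt(delta_i * j)
      y <- (rj - aj) / 2 * rule$x + (rj + aj) / 2
      wy <- (rj - aj) / 2 * rule$w
      f <- vapply(y, function(yy) {
        sum(w * f * stats::dnorm(yy - x - theta * delta_i, sd = sd_inc))
      }, numeric(1))
      x <- y
      w <- wy
    }
  }
  bk <- bound * sqrt(delta_i * k)
  z <- (bk - x - theta * delta_i) / sd_inc
  if (side == "reject") {
    sum(w * f * stats::pnorm(z, lower.tail = FALSE))
  } else {
    sum(w * f * stats::pnorm(z))
  }
}

# ---- integer boundary solves ----------------------------------------------

# Smallest integer b with Ffull(b) <= target, where the spending function is
# nonincreasing in b.  `Fgrid` is a cheap lower bound of `Ffull` (grid-only
# rate maximization) used for bracketing; the bracketing solution is then
# verified against `Ffull` and incremented until it passes, which by
# monotonicity yields the exact solution under `Ffull`.
int_solve_min <- function(Fgrid, Ffull, target, guess, span) {
  lo_cap <- guess - span
  hi_cap <- guess + span
  b <- guess
  if (Fgrid(b) <= target) {
    step <- 1
    while (b - step >= lo_cap && Fgrid(b - step) <= target) {
      b <- b - step
      step <- step * 2
    }
    lo <- max(b - step, lo_cap - 1)    # Fgrid(lo) > target or lo at cap
    hi <- b
    if (lo < lo_cap) {
      # every integer down to the cap passes: spending target is slack
      hi <- lo_cap
      lo <- lo_cap - 1
    }
  } else {
    step <- 1
    while (b + step <= hi_cap && Fgrid(b + step) > target) {
      b <- b + step
      step <- step * 2
    }
    lo <- b
    hi <- min(b + step, hi_cap)
    if (Fgrid(hi) > target) {
      stop("boundary solve failed to bracket within the search span",
           call. = FALSE)
    }
  }
  while (hi - lo > 1) {
    mid <- floor((lo + hi) / 2)
    if (Fgrid(mid) <= target) hi <- mid else lo <- mid
  }
  while (Ffull(hi) > target) hi <- hi + 1
  hi
}

# Largest integer b with Ffull(b) <= target, spending nondecreasing in b.
int_solve_max <- function(Fgrid, Ffull, target, guess, span) {
  lo_cap <- guess - span
  hi_cap <- guess + span
  b <- guess
  if (Fgrid(b) <= target) {
    step <- 1
    while (b + step <= hi_cap && Fgrid(b + step) <= target) {
      b <- b + step
      step <- step * 2
    }
    lo <- b
    hi <- min(b + step, hi_cap + 1)
    if (hi > hi_cap) {
      lo <- hi_cap
      hi <- hi_cap + 1
    }
  } else {
    step <- 1
    while (b - step >= lo_cap && Fgrid(b - step) > target) {
      b <- b - step
      step <- step * 2
    }
    hi <- b
    lo <- max(b - step, lo_cap)
    if (Fgrid(lo) > target) {
      stop("boundary solve failed to bracket within the search span",
           call. = FALSE)
    }
  }
  while (hi - lo > 1) {
    mid <- floor((lo + hi) / 2)
    if (Fgrid(mid) <= target) lo <- mid else hi <- mid
  }
  while (Ffull(lo) > target) lo <- lo - 1
  lo
}

# ---- boundary derivation ---------------------------------------------------

#' Derive stopping boundaries from an error spending plan
#'
#' For a fixed group size `n`, boundaries are found stage by stage: `r_k` is
#' the smallest boundary whose stage-`k` rejection probability, maximized
#' over the null set (exact engine) or evaluated at a fixed null rate
#' (normal engine), does not exceed `pi_R[k]`; `a_k` is the largest boundary
#' whose stage-`k` acceptance probability, maximized over the alternative
#' set (exact) or evaluated at `sup(Lambda1)` (normal), does not exceed
#' `pi_A[k]`. The final stage uses the rejection rule only and sets
#' `a_K = r_K`, which guarantees type-I control at level `alpha` under the
#' engine's own calculus. Exact boundaries are integers; normal boundaries
#' are real.
#'
#' @param n Per-arm per-stage group size.
#' @param plan A [spending_plan()] conforming to the problem.
#' @param problem A [design_problem()].
#' @param engine `"exact"` or `"normal"`.
#' @param cache Optional memoization environment (exact engine).
#' @return A [gs_design()], or an infeasibility marker (class
#'   `gs_infeasible`) when an interim continuation region collapses
#'   (`a_k >= r_k`). Test with `inherits(x, "gs_infeasible")`.
#' @examples
#' derive_boundaries(40, spending_plan(c(0.1, 0.1), c(0.015, 0.035)),
#'                   osah_problem())
#' @export
derive_boundaries <- function(n, plan, problem,
                              engine = c("exact", "normal"), cache = NULL) {
  engine <- match.arg(engine)
  check_plan_conforms(plan, problem)
  check_group_size(n)
  K <- plan$K
  if (engine == "exact") {
    derive_boundaries_exact(n, plan, problem, cache)
  } else {
    derive_boundaries_normal(n, plan, problem)
  }
}

derive_boundaries_exact <- function(n, plan, problem, cache = NULL) {
  if (is.null(cache)) cache <- new_skellam_cache()
  K <- plan$K
  a <- r <- numeric(K)
  l0 <- problem$lambda0
  l1 <- problem$lambda1
  delta <- problem$delta
  sd0 <- sqrt(2 * max(l0))
  sd1 <- sqrt(2 * max(l1) - delta)
  for (k in seq_len(K)) {
    ap <- a[seq_len(k - 1)]
    rp <- r[seq_len(k - 1)]
    spendR <- function(l, b) exact_stage_spend(k, n, ap, rp, b, "reject",
                                               l, l, cache)
    tR <- plan$pi_R[k]
    guessR <- ceiling(stats::qnorm(1 - min(tR, 0.45)) * sd0 * sqrt(k * n))
    r[k] <- int_solve_min(
      Fgrid = function(b) max_over_grid(function(l) spendR(l, b), l0),
      Ffull = function(b) {
        max_over_interval(function(l) spendR(l, b), l0)$value
      },
      target = tR, guess = guessR,
      span = ceiling(60 * sd0 * sqrt(k * n)) + 50
    )
    if (k < K) {
      spendA <- function(l, b) exact_stage_spend(k, n, ap, rp, b, "accept",
                                                 l, l - delta, cache)
      tA <- plan$pi_A[k]
      guessA <- floor(k * n * delta +
                        stats::qnorm(min(tA, 0.45)) * sd1 * sqrt(k * n))
      a[k] <- int_solve_max(
        Fgrid = function(b) max_over_grid(function(l) spendA(l, b), l1),
        Ffull = function(b) {
          max_over_interval(function(l) spendA(l, b), l1)$value
        },
        target = tA, guess = guessA,
        span = ceiling(60 * sd1 * sqrt(k * n)) + 50
      )
      if (a[k] >= r[k]) {
        return(infeasible(k, sprintf(
          "continuation region collapsed at stage %d (a = %g >= r = %g)",
          k, a[k], r[k])))
      }
    }
  }
  a[K] <- r[K]
  gs_design(K, n, a, r, engine = "exact")
}

derive_boundaries_normal <- function(n, plan, problem) {
  K <- plan$K
  a <- r <- numeric(K)
  l_null <- mean(problem$lambda0)       # fixed by convention: null invariant
  l_alt <- problem$lambda1[2]           # sup(Lambda1): least information
  delta <- problem$delta
  for (k in seq_len(K)) {
    ap <- a[seq_len(k - 1)]
    rp <- r[seq_len(k - 1)]
    r[k] <- solve_normal_bound(
      function(b) normal_stage_spend(k, n, ap, rp, b, "reject",
                                     l_null, l_null),
      plan$pi_R[k], decreasing = TRUE
    )
    if (k < K) {
      a[k] <- solve_normal_bound(
        function(b) normal_stage_spend(k, n, ap, rp, b, "accept",
                                       l_alt, l_alt - delta),
        plan$pi_A[k], decreasing = FALSE
      )
      if (a[k] >= r[k]) {
        return(infeasible(k, sprintf(
          "continuation region collapsed at stage %d (a = %.3f >= r = %.3f)",
          k, a[k], r[k])))
      }
    }
  }
  a[K] <- r[K]
  gs_design(K, n, a, r, engine = "normal")
}

# Real-valued boundary solve on the Wald-statistic scale: the spending
# function is continuous and monotone in the boundary, so the solution is a
# plain root.  Z-scale boundaries of practical designs live well inside
# [-30, 30]; targets unreachable inside the bracket clamp to its edge.
solve_normal_bound <- function(F, target, decreasing) {
  g <- if (decreasing) function(b) F(b) - target else function(b) target - F(b)
  lo <- -30
  hi <- 30
  glo <- g(lo)
  ghi <- g(hi)
  if (glo <= 0) return(lo)
  if (ghi > 0) return(hi)
  stats::uniroot(g, c(lo, hi), tol = 1e-10)$root
}

# ---- group-size determination ----------------------------------------------

#' Smallest group size attaining the power target under a spending plan
#'
#' Scans `n = 1, 2, ...` upward; for each `n` the boundaries implied by the
#' plan are derived, and the first `n` whose design attains maximal type-II
#' error at most `beta` (under the design's own engine) is returned. The
#' scan is linear because the attained power of spending-derived exact
#' designs need not be monotone in `n`.
#'
#' @inheritParams derive_boundaries
#' @param n_cap Largest group size considered.
#' @return The selected [gs_design()] with attributes `beta_prime` (attained
#'   maximal type-II error) and `n_evaluated`; if no `n <= n_cap` attains
#'   the power target, an object of class `gs_notfound` recording the best
#'   achieved `beta_prime` and its `n`.
#' @examples
#' \donttest{
#' find_group_size(spending_plan(0.2, 0.05), osah_problem(),
#'                 engine = "exact", n_cap = 100)
#' }
#' @export
find_group_size <- function(plan, problem, engine = c("exact", "normal"),
                            n_cap = 500L, cache = NULL) {
  engine <- match.arg(engine)
  check_plan_conforms(plan, problem)
  if (engine == "exact" && is.null(cache)) cache <- new_skellam_cache()
  best_beta <- Inf
  best_n <- NA_integer_
  for (n in seq_len(n_cap)) {
    d <- derive_boundaries(n, plan, problem, engine, cache = cache)
    if (is_infeasible(d)) next
    bp <- if (engine == "exact") {
      exact_max_error(d, problem, "typeII", cache)$value
    } else {
      normal_max_error(d, problem, "typeII")$value
    }
    if (bp < best_beta) {
      best_beta <- bp
      best_n <- n
    }
    if (bp <= problem$beta) {
      attr(d, "beta_prime") <- bp
      attr(d, "n_evaluated") <- n
      return(d)
    }
  }
  structure(list(best_n = best_n, best_beta = best_beta, n_cap = n_cap),
            class = "gs_notfound")
}

#' @export
print.gs_notfound <- function(x, ...) {
  cat(sprintf(
    "no group size up to %d attains the power target; best beta' = %.4f at n = %d\n",
    x$n_cap, x$best_beta, x$best_n))
  invisible(x)
}
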