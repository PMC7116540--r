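#' Weighted optimality score of a design
#'
#' `w1 * ESS(lambda_ess, lambda_ess) + w2 * ESS(lambda_ess, lambda_ess -
#' delta) + w3 * 2Kn`; lower is better. At least one of the ESS weights
#' must be positive, otherwise many designs share the same minimal maximal
#' sample size and the criterion cannot discriminate.
#'
#' @param design A [gs_design()].
#' @param weights Numeric length-3 vector `(w1, w2, w3)` of nonnegative
#'   weights with `w1 + w2 > 0`.
#' @param problem A [design_problem()].
#' @return The scalar score.
#' @export
optimality_score <- function(design, weights, problem) {
  check_weights(weights)
  l <- problem$lambda_ess
  ess_f <- if (design$engine == "exact") exact_ess else normal_ess
  ess_null <- if (weights[1] > 0) ess_f(design, l, l) else 0
  ess_alt <- if (weights[2] > 0) ess_f(design, l, l - problem$delta) else 0
  weights[1] * ess_null + weights[2] * ess_alt +
    weights[3] * 2 * design$K * design$n
}

check_weights <- function(weights) {
  if (!is.numeric(weights) || length(weights) != 3 ||
      any(!is.finite(weights)) || any(weights < 0)) {
    stop("`weights` must be three nonnegative finite numbers", call. = FALSE)
  }
  if (weights[1] + weights[2] <= 0) {
    stop("`weights` must satisfy w1 + w2 > 0: with both ESS weights zero ",
         "many designs tie on maximal sample size alone", call. = FALSE)
  }
  invisible(TRUE)
}

#' Build a grid of conforming spending plans
#'
#' Takes candidate values for the interim stages of each spending vector
#' and completes the final stage with the remaining budget. Combinations
#' whose final-stage remainder would be negative are dropped with a
#' warning. The defaults are the packaged example grids: for `K = 2`,
#' `pi_A1 in {0.02, 0.04, ..., 0.18}` and `pi_R1 in {0.005, 0.01, ...,
#' 0.045}`; for `K = 3`, `(pi_A1, pi_A2) in {0.03, 0.06, 0.09, 0.12}^2`
#' and `(pi_R1, pi_R2) in {0.01, 0.015, ..., 0.035}^2`.
#'
#' @param problem A [design_problem()] supplying the `alpha`/`beta` budgets.
#' @param K Number of stages (2 or 3 have packaged defaults).
#' @param pi_A_interim,pi_R_interim Lists of length `K - 1` with candidate
#'   spending values per interim stage.
#' @return A list of [spending_plan()] objects.
#' @export
spending_grid <- function(problem, K,
                          pi_A_interim = NULL, pi_R_interim = NULL) {
  if (is.null(pi_A_interim)) {
    pi_A_interim <- switch(as.character(K),
      "2" = list(seq(0.02, 0.18, by = 0.02)),
      "3" = list(c(0.03, 0.06, 0.09, 0.12), c(0.03, 0.06, 0.09, 0.12)),
      stop("no default interim acceptance grid for K = ", K, call. = FALSE))
  }
  if (is.null(pi_R_interim)) {
    pi_R_interim <- switch(as.character(K),
      "2" = list(seq(0.005, 0.045, by = 0.005)),
      "3" = list(seq(0.01, 0.035, by = 0.005), seq(0.01, 0.035, by = 0.005)),
      stop("no default interim rejection grid for K = ", K, call. = FALSE))
  }
  stopifnot(length(pi_A_interim) == K - 1, length(pi_R_interim) == K - 1)
  combos_A <- expand.grid(pi_A_interim, KEEP.OUT.ATTRS = FALSE)
  combos_R <- expand.grid(pi_R_interim, KEEP.OUT.ATTRS = FALSE)
  remA <- problem$beta - rowSums(combos_A)
  remR <- problem$alpha - rowSums(combos_R)
  dropA <- remA < -1e-12
  dropR <- remR < -1e-12
  if (any(dropA) || any(dropR)) {
    warning(sum(dropA) + sum(dropR),
            " interim spending combinations exceed their budget and were dropped",
            call. = FALSE)
  }
  combos_A <- combos_A[!dropA, , drop = FALSE]
  remA <- remA[!dropA]
  combos_R <- combos_R[!dropR, , drop = FALSE]
  remR <- remR[!dropR]
  plans <- list()
  for (i in seq_len(nrow(combos_A))) {
    for (j in seq_len(nrow(combos_R))) {
      plans[[length(plans) + 1]] <- spending_plan(
        pi_A = c(as.numeric(combos_A[i, ]), remA[i]),
        pi_R = c(as.numeric(combos_R[j, ]), remR[j])
      )
    }
  }
  plans
}

#' Near-optimal design search over a grid of spending plans
#'
#' For each plan the required group size and boundaries are determined with
#' [find_group_size()], the design is scored with [optimality_score()], and
#' the feasible designs are returned ranked by score (ascending), with ties
#' broken by smaller maximal sample size, then smaller `n`, then
#' lexicographically smaller `pi_R`. The result is deterministic for given
#' inputs.
#'
#' @param plans A list of [spending_plan()] objects (see [spending_grid()]).
#' @param weights Optimality weights `(w1, w2, w3)`.
#' @param problem A [design_problem()].
#' @param engine `"exact"` or `"normal"`.
#' @param n_cap Largest group size scanned per plan (defaults to twice the
#'   single-stage group size of the same engine).
#' @param evaluate If `TRUE` (default) the returned table carries the full
#'   operating characteristics of each feasible design.
#' @param verbose Log one line per evaluated plan.
#' @return A tibble with one row per feasible plan, ranked; the matched
#'   designs are in the `design` list-column. Zero rows if every plan was
#'   infeasible.
#' @export
grid_search <- function(plans, weights, problem,
                        engine = c("exact", "normal"), n_cap = NULL,
                        evaluate = TRUE, verbose = FALSE) {
  engine <- match.arg(engine)
  check_weights(weights)
  if (length(plans) == 0) stop("`plans` must be nonempty", call. = FALSE)
  if (inherits(plans, "gs_spending_plan")) plans <- list(plans)
  conforms <- vapply(plans, function(p) {
    abs(sum(p$pi_R) - problem$alpha) <= 1e-8 &&
      abs(sum(p$pi_A) - problem$beta) <= 1e-8
  }, logical(1))
  if (any(!conforms)) {
    warning(sum(!conforms), " plans do not conform to (alpha, beta) and ",
            "were dropped", call. = FALSE)
    plans <- plans[conforms]
  }
  if (is.null(n_cap)) {
    fixed <- find_group_size(
      spending_plan(problem$beta, problem$alpha), problem, engine,
      n_cap = 500L)
    if (inherits(fixed, "gs_notfound")) {
      stop("could not size a single-stage design to anchor `n_cap`",
           call. = FALSE)
    }
    n_cap <- 2L * fixed$n
  }
  rows <- purrr::map(plans, function(p) {
    d <- find_group_size(p, problem, engine, n_cap = n_cap)
    if (inherits(d, "gs_notfound") || is_infeasible(d)) {
      if (verbose) {
        message(sprintf("plan piA=(%s) piR=(%s): infeasible up to n = %d",
                        paste(p$pi_A, collapse = ","),
                        paste(p$pi_R, collapse = ","), n_cap))
      }
      return(NULL)
    }
    sc <- optimality_score(d, weights, problem)
    if (verbose) {
      message(sprintf("plan piA=(%s) piR=(%s): n=%d a=(%s) r=(%s) score=%.2f",
                      paste(p$pi_A, collapse = ","),
                      paste(p$pi_R, collapse = ","), d$n,
                      paste(d$a, collapse = ","),
                      paste(d$r, collapse = ","), sc))
    }
    out <- tibble::tibble(
      K = d$K, n = d$n, a = list(d$a), r = list(d$r),
      pi_A = list(p$pi_A), pi_R = list(p$pi_R),
      beta_prime = attr(d, "beta_prime"),
      max_n = 2L * d$K * d$n, score = sc,
      design = list(d)
    )
    out
  })
  res <- dplyr::bind_rows(rows[!vapply(rows, is.null, logical(1))])
  if (nrow(res) == 0) return(res)
  key_R <- vapply(res$pi_R, function(v) {
    paste(sprintf("%.10f", v), collapse = ",")
  }, character(1))
  ord <- order(res$score, res$max_n, res$n, key_R)
  res <- res[ord, ]
  if (evaluate) {
    oc <- purrr::map(res$design, operating_characteristics, problem = problem)
    res$alpha_max <- vapply(oc, `[[`, numeric(1), "alpha_max")
    res$power <- 1 - vapply(oc, `[[`, numeric(1), "beta_max")
    res$ess_null <- vapply(oc, `[[`, numeric(1), "ess_null")
    res$ess_alt <- vapply(oc, `[[`, numeric(1), "ess_alt")
  }
  res
}

# ---- exhaustive optimal search, exact engine, K = 2 ------------------------

#' Exhaustive optimal two-stage exact design search
#'
#' Searches all integer boundary triples in the epsilon-bounded box: for
#' each group size `n` up to `1.5 * n_fixed`, `a_star` is the largest
#' integer whose stage-1 acceptance probability is at most `epsilon` over
#' the null set, `r_star` the smallest integer whose stage-1 rejection
#' probability is at most `epsilon` over the alternative set, and designs
#' with `a1 in [a_star, r_star - 2]`, `r1 in [a1 + 2, r_star]`, and final
#' boundary `a2 = r2 in [a1 + a_star, r1 + r_star]` are considered. For
#' each `(n, a1, r1)` the final boundary is the smallest integer in its box
#' with maximal type-I error at most `alpha`; designs additionally attaining
#' maximal type-II error at most `beta` are feasible, and the feasible
#' design with minimal [optimality_score()] is returned (ties: smaller
#' maximal sample size, then smaller `n`, then smaller `(a1, r1)`).
#'
#' Because the final boundaries coincide, the expected sample size of a
#' two-stage design is `2n * (1 + P(continue past stage 1))`, which does
#' not involve the final boundary; candidates are therefore enumerated in
#' ascending score order and the first feasible one is optimal.
#'
#' @param problem A [design_problem()].
#' @param weights Optimality weights `(w1, w2, w3)`.
#' @param epsilon Stage-1 tail bound defining the search box (default 1e-7).
#' @param n_fixed Single-stage exact group size anchoring the `n` range;
#'   computed if missing.
#' @param n_max Largest `n` searched (default `floor(1.5 * n_fixed)`).
#' @param verbose Log progress.
#' @return The optimal [gs_design()] with attributes `score`,
#'   `alpha_prime`, `beta_prime`, and `n_candidates_tested`; class
#'   `gs_notfound` if no design in the box is feasible.
#' @export
exhaustive_search_k2 <- function(problem, weights, epsilon = 1e-7,
                                 n_fixed = NULL, n_max = NULL,
                                 verbose = FALSE) {
  check_weights(weights)
  if (!is.numeric(epsilon) || epsilon <= 0 || epsilon >= 0.01) {
    stop("`epsilon` must be a small positive tail bound below 0.01",
         call. = FALSE)
  }
  if (is.null(n_fixed)) {
    fx <- find_group_size(spending_plan(problem$beta, problem$alpha),
                          problem, "exact", n_cap = 500L)
    if (inherits(fx, "gs_notfound")) {
      stop("could not size the single-stage anchor design", call. = FALSE)
    }
    n_fixed <- fx$n
  }
  n_max <- n_max %||% floor(1.5 * n_fixed)
  l0 <- problem$lambda0
  l1 <- problem$lambda1
  delta <- problem$delta
  alpha <- problem$alpha
  beta <- problem$beta
  lam0_grid <- rev(seq(l0[1], l0[2], length.out = 21)) # largest (usually
  lam1_grid <- seq(l1[1], l1[2], length.out = 21)      # binding) rate first

  # Wholesale group-size screen: an upper bound on the power of ANY test of
  # size <= alpha based on the full two-stage data (T1~, T2~), from the
  # randomized Neyman-Pearson test of a simple null (l, l) against a simple
  # alternative (l, l - delta).  Group sizes whose bound falls short of
  # 1 - beta admit no feasible boundary triple and are skipped; this prunes
  # the enumeration without affecting the optimum.
  np_power_bound <- function(n, l) {
    ln <- min(max(l, l0[1]), l0[2])   # size evaluated inside the null set
    s0 <- sqrt(2 * max(l, ln) * n)
    sA <- sqrt((2 * l - delta) * n)
    w <- ceiling(8 * max(s0, sA)) + 30
    ts <- (-w):(ceiling(n * delta) + w)
    g0 <- skellam_pmf(ts, n, ln, ln)
    gA <- skellam_pmf(ts, n, l, l - delta)
    lr <- log(gA) - log(g0)
    lr[g0 == 0 & gA == 0] <- -Inf
    lr2 <- outer(lr, lr, "+")
    p0 <- outer(g0, g0)
    pA <- outer(gA, gA)
    ord <- order(lr2, decreasing = TRUE)
    cum0 <- cumsum(p0[ord])
    idx <- which(cum0 >= alpha)[1]
    tail_mass <- 1 - sum(pA)
    if (is.na(idx)) return(1)
    # include the whole crossing term: a valid upper bound on the
    # randomized-test power, plus mass outside the evaluation window
    min(sum(pA[ord[seq_len(idx)]]) + max(tail_mass, 0), 1)
  }
  n_floor <- 1L
  for (n in seq_len(n_max)) {
    b1 <- np_power_bound(n, max(l1))
    if (b1 >= 1 - beta && np_power_bound(n, min(l1)) >= 1 - beta) break
    n_floor <- n + 1L
  }
  if (verbose && n_floor > 1) {
    message(sprintf(
      "group sizes below %d are excluded: even the most powerful size-%.3g test is underpowered",
      n_floor, alpha))
  }

  # Per-n precomputation: box limits, necessary-condition screens, score
  # components, and pmf/cdf arrays on the rate grids.
  cache <- new_skellam_cache()
  pern <- vector("list", n_max)
  prep_n <- function(n) {
    sd0 <- sqrt(2 * max(l0) * n)
    sd1 <- sqrt((2 * max(l1) - delta) * n)
    tabs0 <- lapply(lam0_grid, function(l) {
      skellam_table(cache, n, l, l,
                    floor(-8 * sd0) - 60, ceiling(n * delta + 8 * sd1) + 60)
    })
    tabs1 <- lapply(lam1_grid, function(l) {
      skellam_table(cache, n, l, l - delta,
                    floor(-8 * sd0) - 60, ceiling(n * delta + 8 * sd1) + 60)
    })
    FgridA <- function(b) max(vapply(tabs0, tab_cdf, numeric(1), t = b - 1))
    FfullA <- function(b) {
      max_over_interval(function(l) {
        tab_cdf(skellam_table(cache, n, l, l, b - 2, b + 1), b - 1)
      }, l0)$value
    }
    a_star <- int_solve_max(FgridA, FfullA, epsilon,
                            guess = -ceiling(5.5 * sd0),
                            span = ceiling(20 * sd0) + 50)
    FgridR <- function(b) {
      max(vapply(tabs1, function(tb) 1 - tab_cdf(tb, b - 1), numeric(1)))
    }
    FfullR <- function(b) {
      max_over_interval(function(l) {
        1 - tab_cdf(skellam_table(cache, n, l, l - delta, b - 2, b + 1),
                    b - 1)
      }, l1)$value
    }
    r_star <- int_solve_min(FgridR, FfullR, epsilon,
                            guess = ceiling(n * delta + 5.5 * sd1),
                            span = ceiling(20 * sd1) + 50)
    if (r_star - a_star < 2) return(NULL)
    # necessary conditions for any feasible design at this n:
    #   max over null rates of the stage-1 rejection is at most alpha
    #   max over alternative rates of the stage-1 acceptance is at most beta
    r1_min <- int_solve_min(FgridR0 <- function(b) {
      max(vapply(tabs0, function(tb) 1 - tab_cdf(tb, b - 1), numeric(1)))
    }, FgridR0, alpha, guess = ceiling(1.5 * sd0), span = ceiling(20 * sd0) + 50)
    a1_max <- int_solve_max(FgridA1 <- function(b) {
      max(vapply(tabs1, tab_cdf, numeric(1), t = b - 1))
    }, FgridA1, beta, guess = floor(n * delta - 0.5 * sd1),
    span = ceiling(20 * sd1) + 50)
    a1s <- a_star:min(r_star - 2, a1_max)
    if (length(a1s) == 0 || a1s[1] > a1s[length(a1s)]) return(NULL)
    r1s <- max(a1s[1] + 2, r1_min):r_star
    if (length(r1s) == 0 || r1s[1] > r1s[length(r1s)]) return(NULL)
    # score components at the reporting rate
    tn <- skellam_table(cache, n, problem$lambda_ess, problem$lambda_ess,
                        a_star - 2, r_star + 2)
    ta <- skellam_table(cache, n, problem$lambda_ess,
                        problem$lambda_ess - delta, a_star - 2, r_star + 2)
    base <- 2 * n * (weights[1] + weights[2]) + 4 * n * weights[3]
    u_r1 <- 2 * n * (weights[1] * tab_cdf(tn, r1s - 1) +
                       weights[2] * tab_cdf(ta, r1s - 1))
    v_a1 <- 2 * n * (weights[1] * tab_cdf(tn, a1s - 1) +
                       weights[2] * tab_cdf(ta, a1s - 1))
    list(n = n, a_star = a_star, r_star = r_star,
         a1s = a1s, r1s = r1s, base = base, u_r1 = u_r1, v_a1 = v_a1,
         tabs0 = tabs0, tabs1 = tabs1)
  }

  # score(n, a1, r1) = base + u(r1) - v(a1); u, v are nondecreasing, so for
  # each a1 the candidates inside a score window form a contiguous r1 range.
  emit_batch <- function(pn, lo_score, hi_score) {
    if (is.null(pn)) return(NULL)
    res_n <- integer(0)
    res_a1 <- integer(0)
    res_r1 <- integer(0)
    res_sc <- numeric(0)
    for (ia in seq_along(pn$a1s)) {
      a1 <- pn$a1s[ia]
      lo_u <- lo_score - pn$base + pn$v_a1[ia]
      hi_u <- hi_score - pn$base + pn$v_a1[ia]
      idx <- which(pn$u_r1 > lo_u & pn$u_r1 <= hi_u & pn$r1s >= a1 + 2)
      if (length(idx)) {
        res_n <- c(res_n, rep.int(pn$n, length(idx)))
        res_a1 <- c(res_a1, rep.int(a1, length(idx)))
        res_r1 <- c(res_r1, pn$r1s[idx])
        res_sc <- c(res_sc, pn$base + pn$u_r1[idx] - pn$v_a1[ia])
      }
    }
    if (!length(res_n)) return(NULL)
    list(n = res_n, a1 = res_a1, r1 = res_r1, score = res_sc)
  }

  # Feasibility of one candidate: smallest final boundary in the box with
  # maximal type-I error at most alpha (grid bisection, then Brent-verified
  # increments), then the maximal type-II error check.
  test_candidate <- function(pn, a1, r1) {
    n <- pn$n
    box_lo <- a1 + pn$a_star
    box_hi <- r1 + pn$r_star
    ts <- a1:(r1 - 1)
    alpha_grid <- function(r2) {
      mx <- 0
      for (tb in pn$tabs0) {
        val <- (1 - tab_cdf(tb, r1 - 1)) +
          sum(tab_pmf(tb, ts) * (1 - tab_cdf(tb, r2 - 1 - ts)))
        if (val > mx) mx <- val
        if (mx > alpha) return(mx)
      }
      mx
    }
    if (alpha_grid(box_hi) > alpha) return(NULL)
    lo <- box_lo - 1
    hi <- box_hi
    if (alpha_grid(box_lo) <= alpha) {
      hi <- box_lo
    } else {
      while (hi - lo > 1) {
        mid <- floor((lo + hi) / 2)
        if (alpha_grid(mid) <= alpha) hi <- mid else lo <- mid
      }
    }
    # cheap grid-level power screen before any Brent refinement: the final
    # boundary can only move up during verification, which only lowers power
    beta_grid <- function(r2) {
      max(vapply(pn$tabs1, function(tb) {
        tab_cdf(tb, a1 - 1) +
          sum(tab_pmf(tb, ts) * tab_cdf(tb, r2 - 1 - ts))
      }, numeric(1)))
    }
    if (beta_grid(hi) > beta) return(NULL)
    d <- gs_design(2, n, a = c(a1, hi), r = c(r1, hi), engine = "exact")
    ap <- exact_max_error(d, problem, "typeI", cache)
    while (ap$value > alpha) {
      hi <- hi + 1
      if (hi > box_hi || beta_grid(hi) > beta) return(NULL)
      d <- gs_design(2, n, a = c(a1, hi), r = c(r1, hi), engine = "exact")
      ap <- exact_max_error(d, problem, "typeI", cache)
    }
    bp <- exact_max_error(d, problem, "typeII", cache)
    if (bp$value > beta) return(NULL)
    list(design = d, alpha_prime = ap$value, beta_prime = bp$value)
  }

  # Threshold sweep in ascending score order.
  min_scores <- rep(Inf, n_max)
  for (n in seq_len(n_max)) {
    if (n < n_floor) next
    pern[[n]] <- prep_n(n)
    if (!is.null(pern[[n]])) {
      min_scores[n] <- pern[[n]]$base + min(pern[[n]]$u_r1) -
        max(pern[[n]]$v_a1)
    }
  }
  if (all(!is.finite(min_scores))) {
    return(structure(list(best_n = NA_integer_, best_beta = Inf,
                          n_cap = n_max), class = "gs_notfound"))
  }
  theta <- min(min_scores)
  step <- max(2, 0.02 * theta)
  tested <- 0L
  best <- NULL
  repeat {
    lo_score <- theta - step
    hi_score <- theta
    batches <- purrr::map(pern, emit_batch, lo_score = lo_score,
                          hi_score = hi_score)
    batches <- batches[!vapply(batches, is.null, logical(1))]
    if (length(batches)) {
      cand <- list(
        n = unlist(lapply(batches, `[[`, "n")),
        a1 = unlist(lapply(batches, `[[`, "a1")),
        r1 = unlist(lapply(batches, `[[`, "r1")),
        score = unlist(lapply(batches, `[[`, "score"))
      )
      ord <- order(cand$score, cand$n, cand$a1, cand$r1)
      for (i in ord) {
        if (!is.null(best) && cand$score[i] > best$score) break
        res <- test_candidate(pern[[cand$n[i]]], cand$a1[i], cand$r1[i])
        tested <- tested + 1L
        if (!is.null(res)) {
          cnd <- list(design = res$design, score = cand$score[i],
                      alpha_prime = res$alpha_prime,
                      beta_prime = res$beta_prime)
          if (is.null(best) || better_candidate(cnd, best)) best <- cnd
        }
      }
      if (verbose) {
        message(sprintf("score <= %.2f: %d candidates tested so far%s",
                        hi_score, tested,
                        if (!is.null(best)) sprintf(", best %.3f", best$score)
                        else ""))
      }
    }
    if (!is.null(best) && best$score <= hi_score) break
    if (hi_score > max(vapply(pern, function(p) {
      if (is.null(p)) -Inf else p$base + max(p$u_r1) - min(p$v_a1)
    }, numeric(1)))) {
      break
    }
    theta <- theta + step
  }
  if (is.null(best)) {
    return(structure(list(best_n = NA_integer_, best_beta = Inf,
                          n_cap = n_max), class = "gs_notfound"))
  }
  d <- best$design
  attr(d, "score") <- best$score
  attr(d, "alpha_prime") <- best$alpha_prime
  attr(d, "beta_prime") <- best$beta_prime
  attr(d, "n_candidates_tested") <- tested
  d
}

# tie-breaking between equal-score feasible candidates: smaller maximal
# sample size, then smaller n, then lexicographically smaller (a1, r1)
better_candidate <- function(x, y) {
  if (x$score != y$score) return(x$score < y$score)
  kx <- c(2 * x$design$K * x$design$n, x$design$n, x$design$a[1],
          x$design$r[1])
  ky <- c(2 * y$design$K * y$design$n, y$design$n, y$design$a[1],
          y$design$r[1])
  for (i in seq_along(kx)) {
    if (kx[i] != ky[i]) return(kx[i] < ky[i])
  }
  FALSE
}
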