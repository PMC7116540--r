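# Exact engine: operating characteristics from the Skellam distribution of
# the per-stage difference in event totals.  The cumulative statistic T_Sk
# is not Skellam for k >= 2, but its sub-density restricted to the
# continuation regions obeys a one-step convolution recursion, which is all
# that stage-wise stopping probabilities require.

check_exact <- function(design) {
  if (!inherits(design, "gs_design") || design$engine != "exact") {
    stop("this operation requires an exact-engine `gs_design`",
         call. = FALSE)
  }
  invisible(TRUE)
}

# Working window for cached Skellam tables: covers every pmf/cdf argument
# arising in the recursion (boundary points, continuation supports and all
# pairwise differences between them).
exact_window <- function(a, r) {
  m <- floor(min(c(a, r)))
  M <- ceiling(max(c(a, r)))
  c(min(m, m - M) - 2, max(M, M - m) + 1)
}

# Full set of stage-wise quantities for a design at given rates.  Returns
# accept/reject probabilities per stage plus the interim sub-densities
# (h_k over [a_k, r_k), k = 1..K-1), computed in a single pass.
exact_engine <- function(design, lambda1, lambda2, cache = NULL) {
  check_exact(design)
  check_rates(lambda1, lambda2)
  K <- design$K
  n <- design$n
  a <- floor(design$a)
  r <- floor(design$r)
  win <- exact_window(a, r)
  tab <- skellam_table(cache, n, lambda1, lambda2, win[1], win[2])

  A <- R <- numeric(K)
  R[1] <- 1 - tab_cdf(tab, r[1] - 1)
  A[1] <- tab_cdf(tab, a[1] - 1)
  h <- vector("list", max(K - 1, 0))
  supp <- vector("list", max(K - 1, 0))
  if (K > 1) {
    ts <- a[1]:(r[1] - 1)
    hv <- tab_pmf(tab, ts)
    h[[1]] <- hv
    supp[[1]] <- ts
    for (k in 2:K) {
      R[k] <- sum(hv * (1 - tab_cdf(tab, r[k] - 1 - ts)))
      A[k] <- sum(hv * tab_cdf(tab, a[k] - 1 - ts))
      if (k < K) {
        us <- a[k]:(r[k] - 1)
        # h_k(u) = sum_t h_{k-1}(t) g(u - t): evaluate g once over the
        # union of differences, then accumulate by offset.
        dr <- c(us[1] - ts[length(ts)], us[length(us)] - ts[1])
        gv <- tab_pmf(tab, dr[1]:dr[2])
        hu <- vapply(us, function(u) {
          sum(hv * gv[u - ts - dr[1] + 1])
        }, numeric(1))
        h[[k]] <- hu
        supp[[k]] <- us
        hv <- hu
        ts <- us
      }
    }
  }
  list(accept = A, reject = R, h = h, support = supp)
}

#' Exact stage-wise stopping probabilities
#'
#' Probability of stopping to accept (`A_k`) or reject (`R_k`) the null at
#' each analysis of an exact-engine design, at the given arm rates. The
#' first stage uses the Skellam cdf directly; later stages weight Skellam
#' tails by the interim sub-density over the preceding continuation region.
#' The probabilities always satisfy `sum(accept + reject) == 1` because the
#' final boundaries coincide.
#'
#' @param design An exact-engine [gs_design()].
#' @param lambda1,lambda2 Arm event rates.
#' @param cache Optional environment used to memoize Skellam tables across
#'   repeated evaluations at the same `(n, lambda1, lambda2)`.
#' @return A list with numeric length-`K` components `accept` and `reject`.
#' @examples
#' d <- gs_design(K = 2, n = 5, a = c(-2, 8), r = c(6, 8))
#' exact_stage_probs(d, lambda1 = 2, lambda2 = 1)
#' @export
exact_stage_probs <- function(design, lambda1, lambda2, cache = NULL) {
  out <- exact_engine(design, lambda1, lambda2, cache)
  list(accept = out$accept, reject = out$reject)
}

#' Interim sub-density of the cumulative statistic
#'
#' `h_k(t) = P(T_Sk = t and the trial is still running at analysis k)`,
#' available on the continuation region `[a_k, r_k)`. For `k = 1` this is
#' the Skellam pmf itself; for `k >= 2` it is the convolution of the
#' previous stage's sub-density with the Skellam pmf of one new group.
#' There is no continuation past the final analysis, so `k` must be below
#' `K`.
#'
#' @inheritParams exact_stage_probs
#' @param k Stage index in `1..K-1`.
#' @param t Optional integer vector of evaluation points; defaults to the
#'   whole continuation region `a[k]:(r[k]-1)`.
#' @return Named numeric vector of sub-density values.
#' @export
interim_subdensity <- function(design, lambda1, lambda2, k, t = NULL,
                               cache = NULL) {
  check_exact(design)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k >= design$K ||
      k != round(k)) {
    stop("`k` must be an interim stage index (1 <= k <= K-1)", call. = FALSE)
  }
  out <- exact_engine(design, lambda1, lambda2, cache)
  supp <- out$support[[k]]
  hv <- out$h[[k]]
  if (is.null(t)) {
    t <- supp
  } else {
    if (any(t != round(t))) stop("`t` must be integer", call. = FALSE)
    hv <- ifelse(t %in% supp, hv[match(t, supp)], 0)
    if (k == 1) {
      # Base case is a plain Skellam pmf on all of the integers.
      outside <- !(t %in% supp)
      hv[outside] <- skellam_pmf(t[outside], design$n, lambda1, lambda2)
    }
  }
  stats::setNames(hv, t)
}

#' Maximal error rate of an exact design over a composite hypothesis
#'
#' The type-I error rate `sum_k R_k(lambda, lambda)` is maximized over the
#' null interval, or the type-II error rate `sum_k A_k(lambda, lambda -
#' delta)` over the alternative interval, using a 21-point scan followed by
#' Brent refinement (absolute tolerance 1e-6 in the rate).
#'
#' @param design An exact-engine [gs_design()].
#' @param problem A [design_problem()].
#' @param which `"typeI"` or `"typeII"`.
#' @param cache Optional memoization environment.
#' @return A list with `value` (the maximal error rate) and `argmax` (the
#'   rate at which it is attained).
#' @export
exact_max_error <- function(design, problem, which = c("typeI", "typeII"),
                            cache = NULL) {
  which <- match.arg(which)
  check_exact(design)
  if (is.null(cache)) cache <- new_skellam_cache()
  if (which == "typeI") {
    f <- function(l) sum(exact_stage_probs(design, l, l, cache)$reject)
    max_over_interval(f, problem$lambda0)
  } else {
    f <- function(l) {
      sum(exact_stage_probs(design, l, l - problem$delta, cache)$accept)
    }
    max_over_interval(f, problem$lambda1)
  }
}

#' Expected sample size of an exact design
#'
#' `ESS = 2n * sum_k k * (A_k + R_k)`, the mean total number of subjects
#' over both arms, at the given rates. Bounded between `2n` and `2Kn`.
#'
#' @inheritParams exact_stage_probs
#' @return A scalar expected sample size.
#' @export
exact_ess <- function(design, lambda1, lambda2, cache = NULL) {
  p <- exact_stage_probs(design, lambda1, lambda2, cache)
  2 * design$n * sum(seq_len(design$K) * (p$accept + p$reject))
}

#' Operating characteristics of a design
#'
#' Evaluates the maximal type-I and type-II error rates over the problem's
#' composite hypotheses, the stage-wise stopping probabilities and expected
#' sample sizes at the problem's reporting rate, and the maximal sample
#' size, using the design's own engine.
#'
#' @param design A [gs_design()].
#' @param problem A [design_problem()].
#' @return An object of class `gs_oc` (also a list) with fields
#'   `alpha_max`, `argmax_lambda_null`, `beta_max`, `argmax_lambda_alt`,
#'   `stage_accept`, `stage_reject` (at `lambda1 = lambda2 = lambda_ess`),
#'   `ess_null`, `ess_alt`, `max_n`.
#' @examples
#' d <- gs_design(K = 1, n = 73, a = 110, r = 110)
#' oc <- operating_characteristics(d, osah_problem())
#' oc$alpha_max
#' @export
operating_characteristics <- function(design, problem) {
  cache <- new_skellam_cache()
  if (design$engine == "exact") {
    t1 <- exact_max_error(design, problem, "typeI", cache)
    t2 <- exact_max_error(design, problem, "typeII", cache)
    pn <- exact_stage_probs(design, problem$lambda_ess, problem$lambda_ess,
                            cache)
    ess_null <- exact_ess(design, problem$lambda_ess, problem$lambda_ess,
                          cache)
    ess_alt <- exact_ess(design, problem$lambda_ess,
                         problem$lambda_ess - problem$delta, cache)
  } else {
    t1 <- normal_max_error(design, problem, "typeI")
    t2 <- normal_max_error(design, problem, "typeII")
    pn <- normal_stage_probs(design, problem$lambda_ess, problem$lambda_ess)
    ess_null <- normal_ess(design, problem$lambda_ess, problem$lambda_ess)
    ess_alt <- normal_ess(design, problem$lambda_ess,
                          problem$lambda_ess - problem$delta)
  }
  structure(
    list(
      alpha_max = t1$value, argmax_lambda_null = t1$argmax,
      beta_max = t2$value, argmax_lambda_alt = t2$argmax,
      stage_accept = pn$accept, stage_reject = pn$reject,
      ess_null = ess_null, ess_alt = ess_alt,
      max_n = 2L * design$K * design$n,
      design = design, problem = problem
    ),
    class = "gs_oc"
  )
}

#' @export
print.gs_oc <- function(x, ...) {
  cat(sprintf("alpha' = %.3f (at lambda = %.3f), power = %.3f (beta' at lambda = %.3f)\n",
              x$alpha_max, x$argmax_lambda_null, 1 - x$beta_max,
              x$argmax_lambda_alt))
  cat(sprintf("ESS(null) = %.1f, ESS(alt) = %.1f, max N = %d\n",
              x$ess_null, x$ess_alt, x$max_n))
  invisible(x)
}

#' @rdname operating_characteristics
#' @param x A `gs_oc`.
#' @param ... Unused.
#' @export
glance.gs_oc <- function(x, ...) {
  tibble::tibble(
    K = x$design$K, n = x$design$n,
    a = list(x$design$a), r = list(x$design$r), engine = x$design$engine,
    alpha_max = x$alpha_max, power = 1 - x$beta_max,
    ess_null = x$ess_null, ess_alt = x$ess_alt, max_n = x$max_n
  )
}
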