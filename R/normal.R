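# Normal-approximation engine: the sequence of Wald statistics follows the
# canonical joint distribution (multivariate normal, mean (lambda1 -
# lambda2) * sqrt(I_k), covariance sqrt(I_k1 / I_k2) = sqrt(k1/k2)).  On
# the score scale S_k = T_Wk * sqrt(I_k) the increments are independent
# N(theta * Delta, Delta) with Delta = n / (lambda1 + lambda2), so the
# nested rectangle probabilities are evaluated by the standard
# group-sequential density recursion with Gauss-Legendre quadrature over
# each continuation region.

check_normal <- function(design) {
  if (!inherits(design, "gs_design") || design$engine != "normal") {
    stop("this operation requires a normal-engine `gs_design`",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Information levels of a two-arm Poisson experiment
#'
#' The Fisher information for the rate difference at analysis `k` is
#' `I_k = k * n / (lambda1 + lambda2)`: the inverse variance of the
#' difference of the per-arm rate estimates after `k` groups.
#'
#' @param K Number of analyses.
#' @param n Per-arm per-stage group size.
#' @param lambda1,lambda2 Arm event rates.
#' @return Strictly increasing numeric vector of length `K`.
#' @examples
#' information_levels(3, 10, 2, 3)
#' @export
information_levels <- function(K, n, lambda1, lambda2) {
  stopifnot(is.numeric(K), length(K) == 1, K >= 1, K == round(K))
  check_group_size(n)
  check_rates(lambda1, lambda2)
  (n / (lambda1 + lambda2)) * seq_len(K)
}

# Number of Gauss-Legendre nodes per continuation region.  The integrands
# are products of Gaussians truncated to a few standard deviations, for
# which 96 nodes give absolute accuracy far below the 1e-6 contract.
GL_NODES <- 96L

gl_nodes_cache <- new.env(parent = emptyenv())

gl_rule <- function(m) {
  key <- as.character(m)
  rule <- gl_nodes_cache[[key]]
  if (is.null(rule)) {
    rule <- pracma::gaussLegendre(m, -1, 1)
    gl_nodes_cache[[key]] <- rule
  }
  rule
}

#' Asymptotic stage-wise stopping probabilities
#'
#' Acceptance and rejection probabilities at each analysis of a
#' normal-engine design, computed from the canonical joint normal
#' distribution of the Wald statistics by recursive numerical integration
#' over the continuation regions.
#'
#' @param design A normal-engine [gs_design()] (real-valued boundaries on
#'   the Wald-statistic scale).
#' @param lambda1,lambda2 Arm event rates.
#' @param nodes Number of quadrature nodes per stage.
#' @return A list with numeric length-`K` components `accept` and `reject`.
#' @examples
#' d <- gs_design(K = 1, n = 71, a = 1.6449, r = 1.6449, engine = "normal")
#' normal_stage_probs(d, 30, 27.75)
#' @export
normal_stage_probs <- function(design, lambda1, lambda2, nodes = GL_NODES) {
  check_normal(design)
  check_rates(lambda1, lambda2)
  K <- design$K
  n <- design$n
  theta <- lambda1 - lambda2
  delta_i <- n / (lambda1 + lambda2)       # per-stage information increment
  info <- delta_i * seq_len(K)
  sd_inc <- sqrt(delta_i)

  A <- R <- numeric(K)
  A[1] <- stats::pnorm(design$a[1] - theta * sqrt(info[1]))
  R[1] <- stats::pnorm(design$r[1] - theta * sqrt(info[1]),
                       lower.tail = FALSE)
  if (K == 1) return(list(accept = A, reject = R))

  # score-scale continuation interval and density at stage 1
  lo <- design$a[1] * sqrt(info[1])
  hi <- design$r[1] * sqrt(info[1])
  rule <- gl_rule(nodes)
  x <- (hi - lo) / 2 * rule$x + (hi + lo) / 2
  w <- (hi - lo) / 2 * rule$w
  f <- stats::dnorm(x, mean = theta * info[1], sd = sqrt(info[1]))

  for (k in 2:K) {
    ak <- design$a[k] * sqrt(info[k])
    rk <- design$r[k] * sqrt(info[k])
    A[k] <- sum(w * f * stats::pnorm((ak - x - theta * delta_i) / sd_inc))
    R[k] <- sum(w * f * stats::pnorm((rk - x - theta * delta_i) / sd_inc,
                                     lower.tail = FALSE))
    if (k < K) {
      y <- (rk - ak) / 2 * rule$x + (rk + ak) / 2
      wy <- (rk - ak) / 2 * rule$w
      f <- vapply(y, function(yy) {
        sum(w * f * stats::dnorm(yy - x - theta * delta_i, sd = sd_inc))
      }, numeric(1))
      x <- y
      w <- wy
    }
  }
  list(accept = A, reject = R)
}

#' Maximal error rate of a normal-approximation design
#'
#' Under the null the Wald statistics' joint distribution does not depend
#' on the common rate, so the type-I error rate is evaluated at a fixed
#' (midpoint) rate with no search. The type-II error rate is maximized at
#' the supremum of the alternative interval, where the information is
#' smallest; it is evaluated there directly.
#'
#' @param design A normal-engine [gs_design()].
#' @param problem A [design_problem()].
#' @param which `"typeI"` or `"typeII"`.
#' @return A list with `value` and the evaluation rate `argmax`.
#' @export
normal_max_error <- function(design, problem, which = c("typeI", "typeII")) {
  which <- match.arg(which)
  check_normal(design)
  if (which == "typeI") {
    l <- mean(problem$lambda0)
    list(value = sum(normal_stage_probs(design, l, l)$reject), argmax = l)
  } else {
    l <- problem$lambda1[2]
    list(value = sum(normal_stage_probs(design, l,
                                        l - problem$delta)$accept),
         argmax = l)
  }
}

#' Expected sample size of a normal-approximation design
#'
#' `ESS = 2n * sum_k k * (A_k + R_k)` using the asymptotic stage
#' probabilities.
#'
#' @inheritParams normal_stage_probs
#' @return A scalar expected sample size.
#' @export
normal_ess <- function(design, lambda1, lambda2) {
  p <- normal_stage_probs(design, lambda1, lambda2)
  2 * design$n * sum(seq_len(design$K) * (p$accept + p$reject))
}
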