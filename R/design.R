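#' Specify a two-arm Poisson design problem
#'
#' A design problem fixes the composite hypotheses and error targets: the
#' null set `Lambda0` (an interval of common event rates under
#' `H0: lambda1 = lambda2`), the alternative set `Lambda1` (values of
#' `lambda1` under `lambda1 = lambda2 + delta`), the clinically relevant
#' rate reduction `delta`, the error targets `alpha` and `beta`, and the
#' control-arm rate `lambda_ess` at which expected sample sizes are reported.
#'
#' @param lambda0 Length-2 numeric, the closed null interval (a single value
#'   gives a point hypothesis).
#' @param lambda1 Length-2 numeric, the closed alternative interval for the
#'   arm-1 rate.
#' @param delta Positive rate reduction under the alternative
#'   (`lambda2 = lambda1 - delta`).
#' @param alpha,beta Target maximal type-I and type-II error rates, in (0,1).
#' @param lambda_ess Arm-1 rate at which expected sample sizes are evaluated.
#' @return An object of class `gs_problem`.
#' @examples
#' design_problem(c(15, 30), c(15, 30), delta = 2.25,
#'                alpha = 0.05, beta = 0.2, lambda_ess = 15)
#' @export
design_problem <- function(lambda0, lambda1, delta, alpha, beta,
                           lambda_ess = min(lambda1)) {
  lambda0 <- as_interval(lambda0, "lambda0")
  lambda1 <- as_interval(lambda1, "lambda1")
  stopifnot(is.numeric(delta), length(delta) == 1, is.finite(delta),
            delta > 0)
  if (delta >= lambda1[1]) {
    stop("`delta` must be smaller than min(lambda1) so that the arm-2 rate ",
         "stays positive", call. = FALSE)
  }
  for (nm in c("alpha", "beta")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0 || v >= 1)
      stop("`", nm, "` must be a scalar in (0, 1)", call. = FALSE)
  }
  stopifnot(is.numeric(lambda_ess), length(lambda_ess) == 1,
            is.finite(lambda_ess), lambda_ess > 0)
  structure(
    list(lambda0 = lambda0, lambda1 = lambda1, delta = delta,
         alpha = alpha, beta = beta, lambda_ess = lambda_ess),
    class = "gs_problem"
  )
}

as_interval <- function(x, name) {
  if (!is.numeric(x) || !length(x) %in% c(1, 2) || any(!is.finite(x)) ||
      any(x <= 0)) {
    stop("`", name, "` must be one or two positive finite values",
         call. = FALSE)
  }
  x <- sort(x)
  c(x[1], x[length(x)])
}

#' The worked obstructive sleep apnea-hypopnea (OSAH) design problem
#'
#' The packaged example: mean apnea-hypopnea index in moderate disease lies
#' in \[15, 30\] events per hour on the control arm, a 15% reduction at the
#' lower end of the range (`delta = 2.25`) is targeted, with
#' `alpha = 0.05`, `beta = 0.2`, and expected sample sizes reported at a
#' control rate of 15.
#'
#' @return A `gs_problem`.
#' @export
osah_problem <- function() {
  design_problem(c(15, 30), c(15, 30), delta = 2.25,
                 alpha = 0.05, beta = 0.2, lambda_ess = 15)
}

#' Construct a group sequential design
#'
#' A design is `K` stages of `n` subjects per arm per stage with futility
#' (acceptance) boundaries `a` and efficacy (rejection) boundaries `r`
#' applied to the engine's test statistic: the cumulative difference in
#' event totals for the exact engine (integer boundaries), or the Wald
#' statistic for the normal-approximation engine (real boundaries). At each
#' interim `k < K` the trial stops to reject when the statistic is `>= r[k]`,
#' stops to accept when `< a[k]`, and continues on `[a[k], r[k])`; the final
#' boundaries satisfy `a[K] == r[K]` so a decision is always reached.
#'
#' @param K Number of stages (positive integer).
#' @param n Per-arm per-stage group size (positive integer).
#' @param a,r Length-`K` boundary vectors (`a[k] < r[k]` for `k < K`,
#'   `a[K] == r[K]`; integers when `engine = "exact"`).
#' @param engine `"exact"` or `"normal"`.
#' @return An object of class `gs_design`.
#' @examples
#' gs_design(K = 2, n = 42, a = c(41, 112), r = c(118, 112))
#' @export
gs_design <- function(K, n, a, r, engine = c("exact", "normal")) {
  engine <- match.arg(engine)
  stopifnot(is.numeric(K), length(K) == 1, K >= 1, K == round(K))
  check_group_size(n)
  a <- as.numeric(a)
  r <- as.numeric(r)
  if (length(a) != K || length(r) != K) {
    stop("`a` and `r` must have length K", call. = FALSE)
  }
  if (any(!is.finite(a)) || any(!is.finite(r))) {
    stop("boundaries must be finite", call. = FALSE)
  }
  if (engine == "exact" && (any(a != round(a)) || any(r != round(r)))) {
    stop("exact-engine boundaries must be integers", call. = FALSE)
  }
  if (K > 1 && any(a[-K] >= r[-K])) {
    stop("interim boundaries must satisfy a[k] < r[k]", call. = FALSE)
  }
  if (a[K] != r[K]) {
    stop("final boundaries must satisfy a[K] == r[K]", call. = FALSE)
  }
  structure(
    list(K = as.integer(K), n = as.integer(n), a = a, r = r, engine = engine),
    class = "gs_design"
  )
}

#' @export
print.gs_problem <- function(x, ...) {
  cat("Two-arm Poisson design problem\n")
  cat(sprintf("  H0: lambda1 = lambda2 in [%g, %g]\n",
              x$lambda0[1], x$lambda0[2]))
  cat(sprintf("  H1: lambda1 = lambda2 + %g, lambda1 in [%g, %g]\n",
              x$delta, x$lambda1[1], x$lambda1[2]))
  cat(sprintf("  alpha = %g, beta = %g, lambda_ESS = %g\n",
              x$alpha, x$beta, x$lambda_ess))
  invisible(x)
}

#' @export
print.gs_design <- function(x, ...) {
  fmt <- if (x$engine == "exact") function(v) format(v) else
    function(v) sprintf("%.2f", v)
  cat(sprintf("%s group sequential design: K = %d, n = %d per arm per stage\n",
              x$engine, x$K, x$n))
  cat("  a:", paste(fmt(x$a), collapse = ", "), "\n")
  cat("  r:", paste(fmt(x$r), collapse = ", "), "\n")
  cat(sprintf("  maximal sample size 2Kn = %d\n", 2L * x$K * x$n))
  invisible(x)
}

#' Stage-wise stopping probabilities for either engine
#'
#' Dispatches to [exact_stage_probs()] or [normal_stage_probs()] according
#' to the design's engine.
#'
#' @param design A [gs_design()].
#' @param lambda1,lambda2 Arm event rates at which to evaluate.
#' @param ... Passed to the engine.
#' @return A list with components `accept` and `reject`, each length `K`.
#' @export
stage_probs <- function(design, lambda1, lambda2, ...) {
  if (design$engine == "exact") {
    exact_stage_probs(design, lambda1, lambda2, ...)
  } else {
    normal_stage_probs(design, lambda1, lambda2, ...)
  }
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-stage boundary table of a design
#'
#' @param x A `gs_design`.
#' @param ... Unused.
#' @return A tibble with one row per stage: stage, n cumulated per arm,
#'   futility boundary `a`, efficacy boundary `r`.
#' @export
tidy.gs_design <- function(x, ...) {
  tibble::tibble(
    stage = seq_len(x$K),
    cumulative_n = x$n * seq_len(x$K),
    a = x$a,
    r = x$r,
    engine = x$engine
  )
}

#' One-row summary of a design evaluated against a problem
#'
#' @param x A `gs_design`.
#' @param problem A [design_problem()]; when supplied the maximal error
#'   rates and expected sample sizes are evaluated.
#' @param ... Unused.
#' @return A one-row tibble in the standard design-record schema.
#' @export
glance.gs_design <- function(x, problem = NULL, ...) {
  rec <- tibble::tibble(
    K = x$K, n = x$n,
    a = list(x$a), r = list(x$r),
    engine = x$engine, max_n = 2L * x$K * x$n
  )
  if (!is.null(problem)) {
    oc <- operating_characteristics(x, problem)
    rec$alpha_max <- oc$alpha_max
    rec$power <- 1 - oc$beta_max
    rec$ess_null <- oc$ess_null
    rec$ess_alt <- oc$ess_alt
  }
  rec
}

#' Plot the stopping boundaries of a design
#'
#' Continuation regions are drawn per stage with futility and efficacy
#' boundaries on the engine's statistic scale.
#'
#' @param object A `gs_design`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gs_design <- function(object, ...) {
  dat <- tidy(object)
  long <- tibble::tibble(
    stage = rep(dat$stage, 2),
    boundary = c(dat$a, dat$r),
    type = rep(c("futility (a)", "efficacy (r)"), each = object$K)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = stage, y = boundary,
                                     colour = type)) +
    ggplot2::geom_step(direction = "mid") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_continuous(breaks = dat$stage) +
    ggplot2::labs(
      x = "analysis", colour = NULL,
      y = if (object$engine == "exact") "cumulative event-total difference"
          else "Wald statistic",
      title = sprintf("%s design, K = %d, n = %d per arm per stage",
                      object$engine, object$K, object$n)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
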