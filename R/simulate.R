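# Monte Carlo realization of group sequential two-arm Poisson trials.
# Stage totals Y_jk ~ Po(n * lambda_j) are simulated directly: they are
# sufficient for the statistics of both engines, so per-subject draws would
# change nothing but the run time.

# Engine statistic from cumulative per-arm event totals c1, c2 at stage k:
# exact: the cumulative difference; normal: the Wald statistic, which
# reduces to (c1 - c2) / sqrt(c1 + c2) and is taken as -Inf (accept side)
# when no events have occurred on either arm.
wald_from_totals <- function(c1, c2) {
  tot <- c1 + c2
  out <- rep(-Inf, length(c1))
  pos <- tot > 0
  out[pos] <- (c1[pos] - c2[pos]) / sqrt(tot[pos])
  out
}

#' Simulate a single group sequential trial
#'
#' Draws per-stage event totals, forms the engine's statistic, and applies
#' the stopping rules (reject when the statistic is `>= r[k]`, accept when
#' `< a[k]`, continue otherwise; a decision is forced at stage `K`).
#'
#' @param design A [gs_design()].
#' @param lambda1,lambda2 True arm event rates.
#' @return A list of class `gs_trial`: `stage_sums` (a `stopped_at` x 2
#'   matrix of per-stage totals), `statistic_path`, `stopped_at`,
#'   `decision` (`"reject"` or `"accept"`), `total_sample_size`.
#' @examples
#' set.seed(1)
#' simulate_trial(gs_design(2, 5, c(-2, 8), c(6, 8)), 2, 1)
#' @export
simulate_trial <- function(design, lambda1, lambda2) {
  check_rates(lambda1, lambda2)
  K <- design$K
  n <- design$n
  y1 <- stats::rpois(K, n * lambda1)
  y2 <- stats::rpois(K, n * lambda2)
  c1 <- cumsum(y1)
  c2 <- cumsum(y2)
  stat <- if (design$engine == "exact") c1 - c2 else wald_from_totals(c1, c2)
  stopped_at <- K
  decision <- NA_character_
  for (k in seq_len(K)) {
    if (stat[k] >= design$r[k]) {
      stopped_at <- k
      decision <- "reject"
      break
    }
    if (stat[k] < design$a[k]) {
      stopped_at <- k
      decision <- "accept"
      break
    }
  }
  if (is.na(decision)) {
    # a[K] == r[K] forces a decision; reaching here means continuation at K,
    # impossible by construction
    stop("no decision at the final stage; invalid design", call. = FALSE)
  }
  structure(
    list(
      stage_sums = cbind(y1 = y1[seq_len(stopped_at)],
                         y2 = y2[seq_len(stopped_at)]),
      statistic_path = stat[seq_len(stopped_at)],
      stopped_at = stopped_at,
      decision = decision,
      total_sample_size = 2L * n * stopped_at
    ),
    class = "gs_trial"
  )
}

#' Empirical operating characteristics by simulation
#'
#' Replicates the trial under fixed rates and aggregates the rejection and
#' acceptance frequencies, per-stage stopping distribution, and mean sample
#' size, with binomial standard errors. Simulation is vectorized over
#' replicates but distributionally identical to repeated
#' [simulate_trial()] calls; results are reproducible from `seed`.
#'
#' @param design A [gs_design()].
#' @param lambda1,lambda2 True arm event rates.
#' @param replicates Number of simulated trials.
#' @param seed Integer seed.
#' @return A tibble with one row: `reject_rate`, `accept_rate`, their
#'   shared `se`, `mean_sample_size`, `se_sample_size`, per-stage stopping
#'   probabilities in the list-column `stage_stop`, `replicates`, `seed`.
#' @examples
#' empirical_error_rates(gs_design(2, 5, c(-2, 8), c(6, 8)), 2, 1,
#'                       replicates = 1000, seed = 1)
#' @export
empirical_error_rates <- function(design, lambda1, lambda2,
                                  replicates = 10000L, seed = 1L) {
  check_rates(lambda1, lambda2)
  stopifnot(replicates >= 1)
  K <- design$K
  n <- design$n
  set.seed(seed)
  c1 <- matrix(stats::rpois(replicates * K, n * lambda1), ncol = K)
  c2 <- matrix(stats::rpois(replicates * K, n * lambda2), ncol = K)
  for (k in seq_len(K)[-1]) {
    c1[, k] <- c1[, k] + c1[, k - 1]
    c2[, k] <- c2[, k] + c2[, k - 1]
  }
  reject <- logical(replicates)
  stopped <- rep(K, replicates)
  active <- rep(TRUE, replicates)
  for (k in seq_len(K)) {
    stat_k <- if (design$engine == "exact") {
      c1[active, k] - c2[active, k]
    } else {
      wald_from_totals(c1[active, k], c2[active, k])
    }
    rej <- stat_k >= design$r[k]
    acc <- stat_k < design$a[k]
    idx <- which(active)
    reject[idx[rej]] <- TRUE
    done <- rej | acc
    stopped[idx[done]] <- k
    active[idx[done]] <- FALSE
    if (!any(active)) break
  }
  p_rej <- mean(reject)
  nss <- 2 * n * stopped
  tibble::tibble(
    reject_rate = p_rej,
    accept_rate = 1 - p_rej,
    se = sqrt(p_rej * (1 - p_rej) / replicates),
    mean_sample_size = mean(nss),
    se_sample_size = stats::sd(nss) / sqrt(replicates),
    stage_stop = list(tabulate(stopped, nbins = K) / replicates),
    replicates = replicates,
    seed = seed
  )
}

#' Validate a design's theoretical operating characteristics by simulation
#'
#' Convenience wrapper comparing engine-computed stopping probabilities and
#' expected sample size with their empirical counterparts.
#'
#' @inheritParams empirical_error_rates
#' @return A tibble with theoretical and empirical rejection rates and
#'   expected sample sizes plus the Monte Carlo standard errors.
#' @export
validate_design <- function(design, lambda1, lambda2,
                            replicates = 10000L, seed = 1L) {
  emp <- empirical_error_rates(design, lambda1, lambda2, replicates, seed)
  if (design$engine == "exact") {
    p <- exact_stage_probs(design, lambda1, lambda2)
    ess <- exact_ess(design, lambda1, lambda2)
  } else {
    p <- normal_stage_probs(design, lambda1, lambda2)
    ess <- normal_ess(design, lambda1, lambda2)
  }
  tibble::tibble(
    lambda1 = lambda1, lambda2 = lambda2,
    reject_theory = sum(p$reject),
    reject_empirical = emp$reject_rate,
    reject_se = emp$se,
    ess_theory = ess,
    ess_empirical = emp$mean_sample_size,
    ess_se = emp$se_sample_size,
    replicates = replicates, seed = seed
  )
}
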