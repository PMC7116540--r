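# Independent oracles used across the suite.  These deliberately avoid the
# package's own evaluation paths: brute-force Poisson convolutions and
# exhaustive enumeration over truncated joint supports.

# pmf of Y1 - Y2, Y1 ~ Po(n l1), Y2 ~ Po(n l2), by direct convolution
conv_pmf <- function(t, n, lambda1, lambda2, jmax = 400) {
  mu1 <- n * lambda1
  mu2 <- n * lambda2
  vapply(t, function(tt) {
    j <- 0:jmax
    sum(dpois(tt + j, mu1) * dpois(j, mu2))
  }, numeric(1))
}

conv_cdf <- function(t, n, lambda1, lambda2, jmax = 400, lower = -500) {
  vapply(t, function(tt) {
    sum(conv_pmf(lower:tt, n, lambda1, lambda2, jmax = jmax))
  }, numeric(1))
}

# Stage-wise accept/reject probabilities of a K = 2 exact design by
# exhaustive enumeration of the joint support of the two stage differences,
# truncated at +/- span standard deviations around each stage mean.
enum_k2_probs <- function(design, lambda1, lambda2, span = 12) {
  stopifnot(design$K == 2)
  n <- design$n
  mu <- n * (lambda1 - lambda2)
  sig <- sqrt(n * (lambda1 + lambda2))
  w <- ceiling(span * sig) + 10
  t1 <- (floor(mu) - w):(ceiling(mu) + w)
  g1 <- conv_pmf(t1, n, lambda1, lambda2,
                 jmax = ceiling(n * lambda2 + span * sqrt(n * lambda2)) + 30)
  A <- R <- numeric(2)
  R[1] <- sum(g1[t1 >= design$r[1]])
  A[1] <- sum(g1[t1 < design$a[1]])
  cont <- t1 >= design$a[1] & t1 < design$r[1]
  for (i in which(cont)) {
    tot <- t1[i] + t1    # second-stage increment has the same distribution
    R[2] <- R[2] + g1[i] * sum(g1[tot >= design$r[2]])
    A[2] <- A[2] + g1[i] * sum(g1[tot < design$a[2]])
  }
  list(accept = A, reject = R)
}

# Example problem used throughout: moderate-OSAH trial conditions.
osah <- gspois::osah_problem()
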