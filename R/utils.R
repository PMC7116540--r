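# Maximize a smooth function of the event rate over a closed interval:
# 21-point equispaced scan (endpoints included) to locate the dominant mode,
# then bounded Brent refinement in the bracketing subinterval.  The scan
# guards against Brent converging to a minor mode; there is no simple
# pattern to where the maximal error rate sits on a composite hypothesis
# interval.
max_over_interval <- function(f, interval, tol = 1e-6, grid_n = 21) {
  lo <- interval[1]
  hi <- interval[2]
  if (lo == hi) {
    return(list(value = f(lo), argmax = lo))
  }
  grid <- seq(lo, hi, length.out = grid_n)
  vals <- vapply(grid, f, numeric(1))
  i <- which.max(vals)
  bracket <- c(grid[max(i - 1, 1)], grid[min(i + 1, grid_n)])
  opt <- stats::optimize(f, bracket, maximum = TRUE, tol = tol)
  if (opt$objective >= vals[i]) {
    list(value = opt$objective, argmax = opt$maximum)
  } else {
    list(value = vals[i], argmax = grid[i])
  }
}

# Grid-only version used for cheap bracketing during integer boundary
# solves; always a lower bound on max_over_interval's value.
max_over_grid <- function(f, interval, grid_n = 21) {
  lo <- interval[1]
  hi <- interval[2]
  if (lo == hi) return(f(lo))
  max(vapply(seq(lo, hi, length.out = grid_n), f, numeric(1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
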