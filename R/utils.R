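# Internal numerical helpers shared across modules.

# Run `expr` under a fixed RNG seed without clobbering the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Least-squares slope of y on x with R^2; both vectors finite, length >= 3.
# Returns c(slope, intercept, r2).  R^2 of a zero-variance response is defined
# as 1 (a perfectly flat line is an exact fit).
loglog_fit <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("non-finite values in log-log fit", call. = FALSE)
  }
  mx <- mean(x)
  my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx <= .Machine$double.eps * max(1, mx^2) * length(x)) {
    stop("zero-variance abscissa in log-log fit", call. = FALSE)
  }
  sxy <- sum((x - mx) * (y - my))
  slope <- sxy / sxx
  intercept <- my - slope * mx
  syy <- sum((y - my)^2)
  r2 <- if (syy <= .Machine$double.eps * max(1, my^2) * length(y)) {
    1
  } else {
    max(0, min(1, sxy^2 / (sxx * syy)))
  }
  c(slope = slope, intercept = intercept, r2 = r2)
}

# Trapezoidal integral of y over x (x strictly increasing).
trapz <- function(x, y) {
  n <- length(x)
  stopifnot(n == length(y), n >= 2)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Derivative of y with respect to x on an (uneven) grid: central differences
# in the interior, one-sided at the ends.
grid_derivative <- function(x, y) {
  n <- length(x)
  stopifnot(n == length(y), n >= 3)
  d <- numeric(n)
  d[1] <- (y[2] - y[1]) / (x[2] - x[1])
  d[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  i <- 2:(n - 1)
  d[i] <- (y[i + 1] - y[i - 1]) / (x[i + 1] - x[i - 1])
  d
}

# Local maxima of |y| exceeding `prominence` * max(|y|), at least `min_sep`
# apart in x; stronger peaks win ties.  Returns indices in increasing x.
find_peaks <- function(x, y, prominence = 0.2, min_sep = 1.0) {
  a <- abs(y)
  n <- length(a)
  if (n < 3 || max(a) <= 1e-12) return(integer(0))
  interior <- 2:(n - 1)
  is_max <- a[interior] >= a[interior - 1] & a[interior] >= a[interior + 1] &
    (a[interior] > a[interior - 1] | a[interior] > a[interior + 1])
  cand <- interior[is_max]
  cand <- cand[a[cand] >= prominence * max(a)]
  if (!length(cand)) return(integer(0))
  cand <- cand[order(a[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in cand) {
    if (!length(kept) || all(abs(x[i] - x[kept]) >= min_sep)) kept <- c(kept, i)
  }
  sort(kept)
}
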