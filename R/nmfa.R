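# Node-based multifractal analysis (NMFA).
#
# The pipeline: per-node box masses M_i(r) are normalized into probability
# measures u_i(r) = M_i(r) / N; the partition function U_q(r) = sum_i
# u_i(r)^q is fitted against the observation scale r/d to give the mass
# exponent tau(q); the Legendre transform alpha(q) = dtau/dq, f(alpha) =
# q alpha - tau yields the multifractal spectrum; and D(q) = tau(q)/q is the
# generalized dimension.  tau, alpha, f and q play the roles of free energy,
# energy, entropy and inverse temperature of a thermodynamic system.

#' Distortion-exponent grid
#'
#' A symmetric, strictly increasing grid of distortion exponents `q`
#' containing 0 exactly. Positive `q` amplifies large probability measures
#' (frequent structures); negative `q` amplifies small ones (rare motifs).
#'
#' @param q_min,q_max Grid bounds.
#' @param step Grid step; `q_min`, `q_max` must be integer multiples of it.
#' @return Numeric vector of `q` values.
#' @export
qgrid <- function(q_min = -10, q_max = 10, step = 0.2) {
  stopifnot(q_min < 0, q_max > 0, step > 0)
  lo <- round(q_min / step)
  hi <- round(q_max / step)
  if (abs(lo * step - q_min) > 1e-9 || abs(hi * step - q_max) > 1e-9) {
    stop("q bounds must be integer multiples of the step", call. = FALSE)
  }
  seq(lo, hi) * step
}

#' Probability measures from box masses
#'
#' `u_i(r) = M_i(r) / M`, where `M` is the total mass (the node count).
#'
#' @param mass Matrix of box masses, nodes in rows, radii in columns.
#' @param n_total Total node count `M`.
#' @return Matrix of measures, same shape as `mass`.
#' @export
probability_measures <- function(mass, n_total) {
  stopifnot(n_total >= 2)
  mass / n_total
}

#' Partition function
#'
#' `U_q(r) = sum_i u_i(r)^q`. All measures must be strictly positive at
#' every evaluated radius (guaranteed when the scale grid starts at the
#' largest initial radius `r0` over nodes); otherwise negative `q` diverges.
#'
#' @param u Matrix of probability measures (nodes x radii).
#' @param q Distortion-exponent grid ([qgrid()]).
#' @return Matrix `U` with `length(q)` rows and `ncol(u)` columns.
#' @export
partition_function <- function(u, q) {
  if (any(u <= 0)) {
    bad <- which(u <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("zero probability measure for node %d at scale index %d",
                 bad[1], bad[2]), call. = FALSE)
  }
  lu <- log(u)
  U <- vapply(q, function(qi) colSums(exp(qi * lu)), numeric(ncol(u)))
  t(matrix(U, ncol = length(q), dimnames = list(NULL, paste0("q=", q))))
}

#' Mass exponent curve
#'
#' For each `q`, `tau(q)` is the least-squares slope of `ln U_q(r)` against
#' `ln(r / d)` over the fit radii; the per-`q` `R^2` is reported. `tau(0)` is
#' 0 by construction since `U_0(r) = N` is constant in `r`.
#'
#' @param U Partition-function matrix from [partition_function()].
#' @param radii Radii corresponding to the columns of `U`.
#' @param d Network radius (diameter) normalizing the observation scale.
#' @param fit_idx Indices of the radii used in the fit (default all).
#' @return A list with `tau`, `r2` (both along the q grid) and `fit_idx`.
#' @export
mass_exponent <- function(U, radii, d, fit_idx = seq_along(radii)) {
  if (length(fit_idx) < 3) stop("fewer than 3 usable scales", call. = FALSE)
  x <- log(radii[fit_idx] / d)
  fits <- apply(U[, fit_idx, drop = FALSE], 1, function(uq) {
    loglog_fit(x, log(uq))
  })
  list(tau = unname(fits["slope", ]), r2 = unname(fits["r2", ]),
       fit_idx = fit_idx)
}

#' Legendre multifractal spectrum
#'
#' `alpha(q) = dtau/dq` (central finite differences, one-sided at the grid
#' ends) and `f(alpha) = q alpha(q) - tau(q)`. Summaries: `alpha0` is
#' `alpha` at `q = 0` (the spectrum mode); `alpha_min` and `alpha_max` are
#' the extremes of the spectrum support, i.e. the minimum and maximum of
#' `alpha(q)` over the grid (for a monotone-decreasing `alpha` these sit at
#' `q_max` — frequent structures, left end — and `q_min` — rare motifs,
#' right end; taking grid extremes keeps the summaries well defined when
#' finite-size regression noise makes `alpha` locally non-monotone). The
#' width `w = alpha_max - alpha_min` measures structural heterogeneity.
#'
#' @param tau Mass-exponent values along `q`.
#' @param q Distortion-exponent grid.
#' @return A list with `alpha`, `f_alpha`, `alpha0`, `alpha_min`,
#'   `alpha_max`, `width`.
#' @export
legendre_spectrum <- function(tau, q) {
  if (!all(is.finite(tau))) stop("non-finite mass exponent", call. = FALSE)
  alpha <- grid_derivative(q, tau)
  f_alpha <- q * alpha - tau
  i0 <- which.min(abs(q))
  if (abs(q[i0]) > 1e-9) stop("q grid must contain 0", call. = FALSE)
  list(alpha = alpha, f_alpha = f_alpha,
       alpha0 = alpha[i0],
       alpha_min = min(alpha),
       alpha_max = max(alpha),
       width = max(alpha) - min(alpha))
}

#' Generalized dimension curve
#'
#' `D(q) = tau(q) / q`, with `D(0)` defined by continuity as `alpha(0)`
#' (`tau(0) = 0` makes the ratio 0/0; the limit is `tau'(0)`).
#'
#' @param tau Mass-exponent values along `q`.
#' @param q Distortion-exponent grid.
#' @param alpha Lipschitz-Hölder exponents from [legendre_spectrum()].
#' @return A list with `D`, `D_min`, `D_max`.
#' @export
generalized_dimension <- function(tau, q, alpha) {
  D <- ifelse(abs(q) > 1e-9, tau / q, alpha)
  list(D = D, D_min = min(D), D_max = max(D))
}

#' Node-based multifractal analysis of a network
#'
#' Runs the full pipeline on one network: box-growing mass profiles for all
#' nodes over a shared scale grid, probability measures, partition function,
#' mass exponent, Legendre spectrum and generalized dimension.
#'
#' The scale grid starts at the largest initial radius over nodes (so every
#' measure is positive, as required for `q < 0`) and ends at the network
#' radius `d`; the log-log fits use radii with `r / d <= fit_frac` (default
#' one half) to avoid the saturation plateau near full coverage, extended to
#' the 3 smallest radii when the window is narrower.
#'
#' @param net A network. Disconnected input is reduced to its largest
#'   component when `use_largest_component` is `TRUE` (with a warning),
#'   otherwise it is an error.
#' @param q Distortion-exponent grid ([qgrid()]).
#' @param fit_frac Upper end of the fit range as a fraction of `d`.
#' @param n_scales Number of radii for weighted networks.
#' @param min_scales Minimum number of radii in the fit window; on
#'   small-diameter (small-world) graphs the half-diameter window is widened
#'   to this many of the smallest scales.
#' @param include_center Count the center node in box masses?
#' @param use_largest_component Reduce disconnected input?
#' @return An object of class `nmfa`: a list with the q grid, `tau`,
#'   `tau_r2`, `alpha`, `f_alpha`, `D`, the scale grid and fit indices, the
#'   node count `n`, and summary scalars `alpha0`, `alpha_min`, `alpha_max`,
#'   `width`, `D_min`, `D_max`.
#' @export
nmfa_analyze <- function(net, q = qgrid(), fit_frac = 0.5, n_scales = 20,
                         min_scales = 5, include_center = FALSE,
                         use_largest_component = TRUE) {
  stopifnot(is.numeric(q), length(q) >= 3, !is.unsorted(q, strictly = TRUE))
  if (!igraph::is_connected(net)) {
    if (!use_largest_component) {
      stop("network is disconnected; apply largest_component() first",
           call. = FALSE)
    }
    net <- largest_component(net)
  }
  n <- igraph::vcount(net)
  if (n < 3) stop("degenerate scale grid: network too small", call. = FALSE)
  D_mat <- igraph::distances(net)
  d <- max(D_mat)
  if (d <= 0) stop("degenerate scale grid: zero diameter", call. = FALSE)
  diag(D_mat) <- Inf
  r0 <- apply(D_mat, 1, min)
  r_start <- max(r0)
  radii <- if (is_weighted(net)) {
    exp(seq(log(r_start), log(d), length.out = n_scales))
  } else {
    seq(r_start, d)
  }
  if (length(radii) < 3) {
    stop("degenerate scale grid: fewer than 3 scales", call. = FALSE)
  }
  diag(D_mat) <- 0
  mass <- mass_counts(D_mat, radii) + as.integer(include_center)
  u <- probability_measures(mass, n)
  U <- partition_function(u, q)
  fit_idx <- fit_window(radii, r_start, d, fit_frac, min_scales = min_scales)
  me <- mass_exponent(U, radii, d, fit_idx)
  sp <- legendre_spectrum(me$tau, q)
  gd <- generalized_dimension(me$tau, q, sp$alpha)
  structure(list(q = q, tau = me$tau, tau_r2 = me$r2,
                 alpha = sp$alpha, f_alpha = sp$f_alpha, D = gd$D,
                 radii = radii, fit_idx = fit_idx, d = d, n = n,
                 r_start = r_start, weighted = is_weighted(net),
                 alpha0 = sp$alpha0, alpha_min = sp$alpha_min,
                 alpha_max = sp$alpha_max, width = sp$width,
                 D_min = gd$D_min, D_max = gd$D_max),
            class = "nmfa")
}

#' @export
print.nmfa <- function(x, ...) {
  cat(sprintf("<nmfa> n = %d nodes, d = %g, %d radii (%d in fit), q in [%g, %g]\n",
              x$n, x$d, length(x$radii), length(x$fit_idx), min(x$q), max(x$q)))
  cat(sprintf("  complexity alpha0 = %.4f, heterogeneity w = %.4f\n",
              x$alpha0, x$width))
  cat(sprintf("  D(q): min = %.4f, max = %.4f; asymmetry = %.4f\n",
              x$D_min, x$D_max, asymmetry(x)))
  invisible(x)
}

#' @export
as.data.frame.nmfa <- function(x, ...) {
  data.frame(q = x$q, tau = x$tau, r2 = x$tau_r2, alpha = x$alpha,
             f_alpha = x$f_alpha, D = x$D, C = specific_heat(x)$C)
}
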