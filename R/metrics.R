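# Derived comparative and thermodynamic metrics on NMFA results.

# Extract a (q, D) curve from an nmfa object or a bare list(q, D).
dq_curve <- function(x) {
  if (inherits(x, "nmfa")) list(q = x$q, D = x$D)
  else if (is.list(x) && all(c("q", "D") %in% names(x))) x[c("q", "D")]
  else stop("expected an nmfa result or a list with q and D", call. = FALSE)
}

#' Structure distance between two networks
#'
#' The root-mean-square difference between two generalized-dimension curves
#' over a shared `q` range:
#' `d = sqrt( integral (D1(q) - D2(q))^2 dq / (q_max - q_min) )`,
#' the integral evaluated by the trapezoidal rule on the shared grid.
#' A pseudometric on `D(q)` curves: nonnegative, symmetric, zero on
#' identical curves.
#'
#' @param a,b NMFA results (or lists with elements `q` and `D`) on a common
#'   q grid.
#' @param q_range Optional `c(lo, hi)` restriction, e.g. `c(0.2, 10)` to
#'   compare only frequent-structure dimensions (sub-ranges exclude `q = 0`).
#' @return A nonnegative real.
#' @export
structure_distance <- function(a, b, q_range = NULL) {
  ca <- dq_curve(a); cb <- dq_curve(b)
  if (length(ca$q) != length(cb$q) || max(abs(ca$q - cb$q)) > 1e-9) {
    stop("generalized-dimension curves are on different q grids", call. = FALSE)
  }
  q <- ca$q
  keep <- if (is.null(q_range)) rep(TRUE, length(q)) else {
    q >= q_range[1] - 1e-9 & q <= q_range[2] + 1e-9
  }
  if (sum(keep) < 2) stop("q_range covers fewer than 2 grid points", call. = FALSE)
  qs <- q[keep]
  sq <- (ca$D[keep] - cb$D[keep])^2
  sqrt(trapz(qs, sq) / (max(qs) - min(qs)))
}

#' Pairwise structure-distance matrix
#'
#' @param results A (optionally named) list of NMFA results on a shared q
#'   grid.
#' @param q_range Optional `c(lo, hi)` restriction, as in
#'   [structure_distance()].
#' @return A symmetric matrix with zero diagonal.
#' @export
distance_matrix <- function(results, q_range = NULL) {
  k <- length(results)
  ids <- names(results)
  if (is.null(ids)) ids <- as.character(seq_len(k))
  m <- matrix(0, k, k, dimnames = list(ids, ids))
  if (k >= 2) {
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        m[i, j] <- m[j, i] <- structure_distance(results[[i]], results[[j]],
                                                 q_range = q_range)
      }
    }
  }
  m
}

#' Multifractal-spectrum asymmetry
#'
#' `Asymmetry = ln( (alpha0 - alpha_min) / (alpha_max - alpha0) )`: the
#' log-ratio of the spectrum's left and right half-widths. Positive values
#' mean frequent structures dominate (a hub-dominated "clump", as in
#' preferential-attachment networks); negative values mean rare motifs
#' dominate (a dangling-chain "thorn", as in sparse random graphs); values
#' near 0 mean a symmetric structure. Spectra narrower than `degenerate_tol`
#' are symmetric by convention (the ratio is 0/0) and return 0.
#'
#' @param spec An NMFA result, or a list with `alpha0`, `alpha_min`,
#'   `alpha_max`.
#' @param degenerate_tol Width below which the spectrum counts as
#'   monofractal.
#' @return A real number.
#' @export
asymmetry <- function(spec, degenerate_tol = 1e-3) {
  a0 <- spec$alpha0; lo <- spec$alpha_min; hi <- spec$alpha_max
  stopifnot(is.finite(a0), is.finite(lo), is.finite(hi))
  w <- hi - lo
  if (w < degenerate_tol) return(0)
  tol <- 0.05 * w
  if (a0 < lo - tol || a0 > hi + tol) {
    stop("inconsistent spectrum: alpha0 outside [alpha_min, alpha_max]",
         call. = FALSE)
  }
  left <- max(a0 - lo, w * 1e-9)
  right <- max(hi - a0, w * 1e-9)
  log(left / right)
}

#' Spectrum summary: complexity and heterogeneity
#'
#' `alpha0` (the spectrum mode) measures structural complexity; the spectrum
#' width `w = alpha_max - alpha_min` measures structural heterogeneity.
#'
#' @param spec An NMFA result.
#' @return Named numeric vector `c(complexity, heterogeneity)`.
#' @export
spectrum_summary <- function(spec) {
  c(complexity = spec$alpha0, heterogeneity = spec$width)
}

#' Specific heat curve
#'
#' `C(q) = d alpha / d q`, the second derivative of the mass exponent: the
#' thermodynamic analogue of specific heat, with `q` as inverse temperature.
#' Taken literally, `C <= 0` for a well-behaved (concave-tau) spectrum; peak
#' detection therefore operates on `|C|`, which makes it independent of the
#' sign convention. Peaks of `|C|` mark phase-transition-like changes of the
#' dominant structural mechanism at critical exponents `q_c`.
#'
#' @param spec An NMFA result (or a list with `q` and `alpha`).
#' @param prominence,min_sep Peak-detection parameters, see
#'   [detect_phase_transitions()].
#' @return An object of class `specific_heat`: list with `q`, `C`, and
#'   `peaks` (the [detect_phase_transitions()] table).
#' @export
specific_heat <- function(spec, prominence = 0.2, min_sep = 1.0) {
  stopifnot(length(spec$q) >= 3)
  C <- grid_derivative(spec$q, spec$alpha)
  out <- structure(list(q = spec$q, C = C), class = "specific_heat")
  out$peaks <- detect_phase_transitions(out, prominence = prominence,
                                        min_sep = min_sep)
  out
}

#' @export
print.specific_heat <- function(x, ...) {
  cat(sprintf("<specific_heat> %d q points, max |C| = %.4f, %d peak(s)\n",
              length(x$q), max(abs(x$C)), nrow(x$peaks)))
  if (nrow(x$peaks)) print(x$peaks)
  invisible(x)
}

#' Detect phase transitions in a specific-heat curve
#'
#' Local maxima of `|C(q)|` whose magnitude exceeds `prominence` times the
#' global maximum, at least `min_sep` apart in `q` (stronger peaks win).
#' The sign of each critical exponent classifies the mechanism: `q_c > 0`
#' means large probability measures dominate ("clump"), `q_c < 0` means
#' small measures dominate ("thorn").
#'
#' @param C A [specific_heat()] object or a list with `q` and `C`.
#' @param prominence Fraction of `max |C|` a peak must reach.
#' @param min_sep Minimum separation between reported peaks, in `q` units.
#' @return A data.frame with columns `q_c`, `magnitude`, `mechanism`,
#'   ordered by increasing `q_c`; zero rows when the curve is flat.
#' @export
detect_phase_transitions <- function(C, prominence = 0.2, min_sep = 1.0) {
  idx <- find_peaks(C$q, C$C, prominence = prominence, min_sep = min_sep)
  data.frame(q_c = C$q[idx], magnitude = abs(C$C[idx]),
             mechanism = ifelse(C$q[idx] > 0, "clump", "thorn"),
             stringsAsFactors = FALSE)
}

#' Edge-deletion experiment
#'
#' Ranks all edges once on the original network by edge-betweenness
#' centrality, removes them cumulatively in the requested order in
#' `n_steps` equal batches (up to `frac_remove` of the edges), and after
#' each batch measures the structure distance between the current largest
#' component and the original network. Removing high-importance edges first
#' should drive the network farther, in structure, from its origin than
#' removing unimportant edges first.
#'
#' @param net A connected network.
#' @param order `"descending"` (most important first) or `"ascending"`.
#' @param n_steps Number of deletion batches.
#' @param frac_remove Total fraction of edges to delete.
#' @param q Distortion grid passed to [nmfa_analyze()].
#' @param ... Further arguments to [nmfa_analyze()].
#' @return A data.frame with columns `step`, `edges_removed`, `distance`
#'   (step 0 is the intact network at distance 0).
#' @export
deletion_experiment <- function(net, order = c("descending", "ascending"),
                                n_steps = 5, frac_remove = 0.2,
                                q = qgrid(), ...) {
  order <- match.arg(order)
  if (!igraph::is_connected(net)) stop("network must be connected", call. = FALSE)
  m <- igraph::ecount(net)
  n_remove <- floor(frac_remove * m)
  if (n_remove < n_steps) stop("too few edges to delete", call. = FALSE)
  eb <- igraph::edge_betweenness(net,
                                 weights = if (is_weighted(net)) igraph::E(net)$weight else NA)
  rank <- base::order(eb, decreasing = (order == "descending"))
  base <- nmfa_analyze(net, q = q, ...)
  batch <- floor(seq(0, n_remove, length.out = n_steps + 1))
  out <- data.frame(step = 0:n_steps, edges_removed = batch, distance = 0)
  for (s in seq_len(n_steps)) {
    g <- igraph::delete_edges(net, rank[seq_len(batch[s + 1])])
    res <- suppressWarnings(nmfa_analyze(g, q = q, ...))
    out$distance[s + 1] <- structure_distance(base, res)
  }
  out
}
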