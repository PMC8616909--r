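# Box-growing method: per-node cumulative mass profiles over growing
# shortest-path radii, and the node-based fractal dimension (NFD).
#
# A "growing box" centered on node i with radius r covers all nodes at
# shortest-path distance <= r.  The box mass M_i(r) counts the covered nodes
# EXCLUDING the center: with that convention a k-regular ring lattice obeys
# M(r)/M(r0) = r/r0 exactly, so its NFD is exactly 1 on the fit range.
# Pass include_center = TRUE for the inclusive count.

#' Scale grid for box-growing analysis
#'
#' The ordered radii at which box masses are evaluated, together with the
#' network radius `d` (the diameter) used to normalize the observation scale
#' `r / d`. Unweighted networks use the integer radii `r_start..d`; weighted
#' networks use `n_scales` geometrically spaced radii from `r_start` to `d`.
#'
#' @param net A connected network.
#' @param r_start Smallest radius; defaults to the largest initial radius
#'   `r0` over all nodes, which guarantees every node's box mass is positive
#'   at every grid radius (required for negative distortion exponents).
#' @param n_scales Number of radii for weighted networks.
#' @return An object of class `scale_grid`: a list with elements `radii`,
#'   `d`, and `weighted`.
#' @export
scale_grid <- function(net, r_start = NULL, n_scales = 20) {
  d <- network_radius(net)
  if (d <= 0) stop("degenerate scale grid: single-node network", call. = FALSE)
  wtd <- is_weighted(net)
  if (is.null(r_start)) {
    # max over nodes of the distance to their nearest neighbor
    D <- igraph::distances(net)
    diag(D) <- Inf
    r_start <- max(apply(D, 1, min))
  }
  radii <- if (wtd) {
    exp(seq(log(r_start), log(d), length.out = n_scales))
  } else {
    seq(r_start, d)
  }
  if (length(radii) < 3) {
    stop("degenerate scale grid: fewer than 3 scales", call. = FALSE)
  }
  structure(list(radii = radii, d = d, weighted = wtd), class = "scale_grid")
}

#' @export
print.scale_grid <- function(x, ...) {
  cat(sprintf("<scale_grid> %d %s radii in [%g, %g], network radius d = %g\n",
              length(x$radii), if (x$weighted) "geometric" else "integer",
              min(x$radii), max(x$radii), x$d))
  invisible(x)
}

#' Initial box radius of a node
#'
#' The box around a node is grown until it first covers at least one other
#' node; that radius is `r0` (the distance to the nearest neighbor, 1 for
#' unweighted networks) and the covered count is the initial mass `M(r0)`.
#'
#' @param net A connected network.
#' @param node Node label.
#' @return Named numeric vector `c(r0, m_r0)`.
#' @export
initial_radius <- function(net, node) {
  d <- distances_from(net, node)
  d <- d[is.finite(d) & d > 0]
  if (!length(d)) stop("isolated node: box cannot grow", call. = FALSE)
  r0 <- min(d)
  c(r0 = r0, m_r0 = sum(d <= r0 * (1 + 1e-12)))
}

# Counts per row of `D` (a distance matrix or single row-vector) of entries
# 0 < D <= r for each radius; a small relative tolerance absorbs floating
# accumulation in weighted path sums.
mass_counts <- function(D, radii) {
  if (is.null(dim(D))) D <- matrix(D, nrow = 1)
  radii_tol <- radii * (1 + 1e-12)
  t(apply(D, 1, function(di) {
    di <- di[is.finite(di) & di > 0]
    findInterval(radii_tol, sort(di))
  }))
}

#' Cumulative mass profile of one node
#'
#' `M(r)` = number of non-center nodes within shortest-path distance `r`,
#' evaluated at every grid radius.
#'
#' @param net A connected network.
#' @param node Node label.
#' @param grid A [scale_grid()]; defaults to the node's natural grid (every
#'   distinct distance from the node).
#' @param include_center Count the center node itself in `M(r)`?
#' @return A list of class `mass_profile` with `node`, `r0`, `m_r0`,
#'   `radii`, `mass`, and the profile extent `ecc` (the node's
#'   eccentricity).
#' @export
mass_profile <- function(net, node, grid = NULL, include_center = FALSE) {
  dv <- distances_from(net, node)
  dv <- dv[is.finite(dv)]
  pos <- dv[dv > 0]
  if (!length(pos)) stop("isolated node: box cannot grow", call. = FALSE)
  r0 <- min(pos)
  radii <- if (is.null(grid)) sort(unique(pos)) else grid$radii
  mass <- drop(mass_counts(dv, radii)) + as.integer(include_center)
  structure(list(node = as.character(node), r0 = r0,
                 m_r0 = sum(pos <= r0 * (1 + 1e-12)) + as.integer(include_center),
                 radii = radii, mass = mass, ecc = max(pos)),
            class = "mass_profile")
}

#' @export
print.mass_profile <- function(x, ...) {
  cat(sprintf("<mass_profile> node %s: r0 = %g, M(r0) = %d, %d radii up to %g\n",
              x$node, x$r0, x$m_r0, length(x$radii), max(x$radii)))
  invisible(x)
}

# Fit indices for an NFD/tau regression: radii within [r_lo, fit_frac * r_max]
# (r_max is the diameter for a shared grid, the node eccentricity otherwise).
# Small-world graphs compress all structure into a handful of hops, so the
# window is widened to the `min_scales` smallest usable radii when the
# half-range holds fewer than that.
fit_window <- function(radii, r_lo, r_max, fit_frac, min_scales = 3) {
  usable <- which(radii >= r_lo * (1 - 1e-12))
  if (length(usable) < 3) {
    stop("degenerate scale grid: fewer than 3 usable scales", call. = FALSE)
  }
  idx <- usable[radii[usable] <= fit_frac * r_max * (1 + 1e-12)]
  if (length(idx) < min_scales) {
    idx <- usable[seq_len(min(min_scales, length(usable)))]
  }
  idx
}

#' Node-based fractal dimension (NFD)
#'
#' The NFD of node *i* is the power-law exponent `D` in
#' `M(r) / M(r0) ~ (r / r0)^D`: the spatial dimension of the network's
#' growth seen from that node. It is estimated as the least-squares slope of
#' `ln(M(r)/M(r0))` against `ln(r/r0)` over the fit range
#' `r <= fit_frac * r_max` (by default half the profile extent, which
#' excludes the saturation plateau near full coverage); the goodness of fit
#' `R^2` is reported alongside.
#'
#' @param net A connected network.
#' @param nodes Node labels to analyze; default all nodes.
#' @param grid Optional shared [scale_grid()]. When `NULL` each node uses its
#'   natural grid (all distinct distances from the node) and its own
#'   eccentricity as the profile extent.
#' @param fit_frac Upper end of the fit range as a fraction of the profile
#'   extent.
#' @param include_center Count the center node in `M(r)`?
#' @return A data.frame with columns `node`, `r0`, `m_r0`, `nfd`,
#'   `r_squared`.
#' @export
nfd <- function(net, nodes = NULL, grid = NULL, fit_frac = 0.5,
                include_center = FALSE) {
  labs <- vertex_labels(net)
  if (is.null(nodes)) nodes <- labs
  nodes <- as.character(nodes)
  out <- lapply(nodes, function(nd) {
    prof <- mass_profile(net, nd, grid = grid, include_center = include_center)
    r_max <- if (is.null(grid)) prof$ecc else grid$d
    idx <- fit_window(prof$radii, prof$r0, r_max, fit_frac)
    m <- prof$mass[idx]
    if (any(m <= 0)) stop("zero box mass inside the fit range", call. = FALSE)
    fit <- loglog_fit(log(prof$radii[idx] / prof$r0), log(m / prof$m_r0))
    data.frame(node = prof$node, r0 = prof$r0, m_r0 = prof$m_r0,
               nfd = unname(fit["slope"]), r_squared = unname(fit["r2"]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
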