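# Independent brute-force oracles.  These deliberately share no code with
# the package: distances come from a hand-written Floyd-Warshall, and the
# multifractal quantities from straight loops over the defining sums.

oracle_floyd_warshall <- function(g) {
  n <- igraph::vcount(g)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- if ("weight" %in% igraph::edge_attr_names(g)) {
    igraph::E(g)$weight
  } else {
    rep(1, nrow(el))
  }
  for (e in seq_len(nrow(el))) {
    i <- el[e, 1]; j <- el[e, 2]
    D[i, j] <- min(D[i, j], w[e])
    D[j, i] <- D[i, j]
  }
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  }
  D
}

# Straight-loop node-based multifractal analysis for small unweighted
# connected graphs, mirroring the package's stated conventions (shared scale
# grid from max r0 to the diameter, least-squares mass exponent over radii
# up to half the diameter widened to at least `min_scales` scales, central
# differences, D(0) = alpha(0)).
oracle_nmfa <- function(g, q, fit_frac = 0.5, min_scales = 5) {
  D <- oracle_floyd_warshall(g)
  n <- nrow(D)
  d <- max(D)
  r0 <- vapply(seq_len(n), function(i) min(D[i, -i]), 0)
  radii <- seq(max(r0), d)
  M <- matrix(0, n, length(radii))
  for (i in seq_len(n)) {
    for (ri in seq_along(radii)) {
      M[i, ri] <- sum(D[i, -i] <= radii[ri])
    }
  }
  u <- M / n
  U <- matrix(0, length(q), length(radii))
  for (qi in seq_along(q)) {
    for (ri in seq_along(radii)) {
      U[qi, ri] <- sum(u[, ri]^q[qi])
    }
  }
  idx <- which(radii <= fit_frac * d * (1 + 1e-12))
  if (length(idx) < min_scales) idx <- seq_len(min(min_scales, length(radii)))
  x <- log(radii[idx] / d)
  tau <- numeric(length(q))
  for (qi in seq_along(q)) {
    y <- log(U[qi, idx])
    tau[qi] <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  }
  nq <- length(q)
  alpha <- numeric(nq)
  alpha[1] <- (tau[2] - tau[1]) / (q[2] - q[1])
  alpha[nq] <- (tau[nq] - tau[nq - 1]) / (q[nq] - q[nq - 1])
  for (i in 2:(nq - 1)) {
    alpha[i] <- (tau[i + 1] - tau[i - 1]) / (q[i + 1] - q[i - 1])
  }
  f <- q * alpha - tau
  Dq <- ifelse(abs(q) > 1e-9, tau / q, alpha)
  list(radii = radii, fit_idx = idx, U = U, tau = tau, alpha = alpha,
       f = f, D = Dq)
}

# Random connected graph on n <= 30 nodes: a random recursive tree plus a
# few random extra edges; optionally with random positive weights.
random_connected_graph <- function(n, seed, extra = 3, weighted = FALSE) {
  set.seed(seed)
  parent <- vapply(2:n, function(i) sample.int(i - 1L, 1L), 0L)
  el <- cbind(parent, 2:n)
  for (k in seq_len(extra)) {
    pair <- sample.int(n, 2L)
    el <- rbind(el, pair)
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, t(el))
  g <- igraph::simplify(g)
  if (weighted) {
    igraph::E(g)$weight <- round(stats::runif(igraph::ecount(g), 0.1, 2), 3)
  }
  g
}
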