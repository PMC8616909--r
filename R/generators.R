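# Reference network constructors used for validation and synthetic testing.
# All stochastic generators are deterministic under a fixed `seed` and leave
# the caller's RNG state untouched.

#' Regular ring lattice
#'
#' Places `n` nodes on a ring and connects each node to its `k` nearest
#' neighbors (`k/2` on either side), giving `n * k / 2` edges. This is the
#' initial, perfectly regular state of the Watts-Strogatz model; every node
#' sees an identical linear neighborhood growth, so its node-based fractal
#' dimension is exactly 1.
#'
#' @param n Number of nodes.
#' @param k Neighbors per node; must be even and `< n`.
#' @return A network.
#' @export
ring_lattice <- function(n, k) {
  stopifnot(n >= 3, k >= 2)
  if (k %% 2 != 0) stop("k must be even", call. = FALSE)
  if (k >= n) stop("k must be smaller than n", call. = FALSE)
  i <- rep(seq_len(n), each = k / 2)
  off <- rep(seq_len(k / 2), times = n)
  j <- ((i - 1 + off) %% n) + 1
  igraph::graph_from_edgelist(cbind(i, j), directed = FALSE)
}

#' Erdős–Rényi random graph
#'
#' Each of the `n(n-1)/2` node pairs is included independently with
#' probability `p` (the G(n, p) model).
#'
#' @param n Number of nodes.
#' @param p Edge probability in `[0, 1]`.
#' @param seed Optional integer seed for reproducibility.
#' @return A network.
#' @export
erdos_renyi <- function(n, p, seed = NULL) {
  stopifnot(n >= 1, p >= 0, p <= 1)
  with_seed(seed, {
    pairs <- utils::combn(n, 2)
    keep <- stats::runif(ncol(pairs)) < p
    g <- igraph::make_empty_graph(n, directed = FALSE)
    igraph::add_edges(g, pairs[, keep, drop = FALSE])
  })
}

#' Watts–Strogatz small-world graph
#'
#' Starts from [ring_lattice()]`(n, k)`; each edge `(u, v)` is then, with
#' probability `p`, rewired to `(u, w)` where `w` is drawn uniformly from the
#' nodes that are neither `u` nor already neighbors of `u`. Self-loops and
#' duplicate edges are never created, so node and edge counts are invariant
#' under the rewiring; if no eligible target exists the edge is left in
#' place. Outputs may be disconnected at intermediate `p`; analysis callers
#' should take the largest component.
#'
#' @param n,k Ring-lattice parameters (see [ring_lattice()]).
#' @param p Rewiring probability in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return A network with exactly `n` nodes and `n * k / 2` edges.
#' @export
watts_strogatz <- function(n, k, p, seed = NULL) {
  stopifnot(p >= 0, p <= 1)
  g0 <- ring_lattice(n, k)
  if (p == 0) return(g0)
  el <- igraph::as_edgelist(g0, names = FALSE)
  with_seed(seed, {
    adj <- lapply(igraph::adjacent_vertices(g0, seq_len(n)), as.integer)
    rewire <- stats::runif(nrow(el)) < p
    for (e in which(rewire)) {
      u <- el[e, 1]; v <- el[e, 2]
      candidates <- setdiff(seq_len(n), c(u, adj[[u]]))
      if (!length(candidates)) next
      w <- candidates[sample.int(length(candidates), 1L)]
      adj[[u]] <- c(setdiff(adj[[u]], v), w)
      adj[[v]] <- setdiff(adj[[v]], u)
      adj[[w]] <- c(adj[[w]], u)
      el[e, 2] <- w
    }
    g <- igraph::make_empty_graph(n, directed = FALSE)
    igraph::add_edges(g, t(el))
  })
}

#' Barabási–Albert preferential-attachment graph
#'
#' The seed graph is the complete graph on `m0` nodes; each arriving node
#' attaches to `m` distinct existing nodes, sampled without replacement with
#' probability proportional to current degree. With the default `m0 = m` the
#' edge count is exactly `choose(m0, 2) + (n - m0) * m`.
#'
#' @param n Final number of nodes.
#' @param m Edges added per arriving node.
#' @param m0 Seed-graph size; `m <= m0 < n`.
#' @param seed Optional integer seed.
#' @return A network.
#' @export
barabasi_albert <- function(n, m, m0 = m, seed = NULL) {
  stopifnot(m >= 1, m <= m0, m0 <= n)
  deg <- integer(n)
  seed_edges <- if (m0 >= 2) t(utils::combn(m0, 2)) else matrix(integer(0), 0, 2)
  deg[seq_len(m0)] <- m0 - 1L
  if (n == m0) {
    g <- igraph::make_empty_graph(m0, directed = FALSE)
    return(igraph::add_edges(g, t(seed_edges)))
  }
  new_edges <- matrix(0L, nrow = (n - m0) * m, ncol = 2)
  with_seed(seed, {
    row <- 1L
    for (t in (m0 + 1):n) {
      existing <- seq_len(t - 1L)
      w <- deg[existing]
      if (all(w == 0)) w <- rep(1, length(w))  # degenerate seed (m0 = 1)
      targets <- existing[sample.int(t - 1L, m, replace = FALSE, prob = w)]
      new_edges[row:(row + m - 1L), 1] <- t
      new_edges[row:(row + m - 1L), 2] <- targets
      row <- row + m
      deg[targets] <- deg[targets] + 1L
      deg[t] <- m
    }
  })
  igraph::graph_from_edgelist(rbind(seed_edges, new_edges), directed = FALSE)
}

#' Weighted self-similar fractal tree
#'
#' An outward-growing self-similar weighted tree, a synthetic stand-in for
#' weighted Sierpinski-type fractal networks defined by a copy factor `b`
#' and a scale factor `f`: the root sits at level 0 and every node at level
#' `g - 1` has `b` children. The generation-`g` edge lengths are chosen so
#' that the root's cumulative mass obeys the monofractal closed form
#' `M(r) / M(r0) = (r / r0)^D` with `D = ln(b) / ln(1/f)` *exactly* at every
#' finite generation: the root-to-level-`g` distance is
#' `R_g = (1/f) * (M_g / M_1)^(1/D)` where `M_g = sum_{j<=g} b^j` is the
#' cumulative non-root mass, so `R_g` (and hence the level-`g` edge length
#' `R_g - R_{g-1}`) scales as `(1/f)^g` asymptotically. The root's
#' node-based fractal dimension therefore equals `ln(b) / ln(1/f)` with
#' `R^2 = 1`, which is the property the construction is meant to validate;
#' only that closed form, not a particular Sierpinski embedding, is modeled.
#'
#' The root is vertex 1.
#'
#' @param b Copies per node per generation, `>= 2`.
#' @param f Scaling factor in `(0, 1)`.
#' @param generations Number of levels below the root, `>= 1`.
#' @return A weighted network with `sum_{g=0..generations} b^g` nodes.
#' @export
weighted_fractal <- function(b, f, generations) {
  stopifnot(b >= 2, generations >= 1)
  if (f <= 0 || f >= 1) stop("f must lie strictly between 0 and 1", call. = FALSE)
  sizes <- b^(0:generations)              # nodes per level
  starts <- cumsum(c(1, sizes))           # first index of each level (1-based)
  n <- starts[generations + 2] - 1
  D_dim <- log(b) / log(1 / f)
  mass <- cumsum(b^(1:generations))       # non-root nodes within level <= g
  R <- (1 / f) * (mass / mass[1])^(1 / D_dim)  # root-to-level-g distance
  level_wt <- diff(c(0, R))               # edge length at each generation
  parent <- integer(n - 1)
  wt <- numeric(n - 1)
  for (g in seq_len(generations)) {
    children <- starts[g + 1]:(starts[g + 2] - 1)
    parent[children - 1L] <- starts[g] + (children - starts[g + 1]) %/% b
    wt[children - 1L] <- level_wt[g]
  }
  g <- igraph::graph_from_edgelist(cbind(parent, 2:n), directed = FALSE)
  igraph::E(g)$weight <- wt               # edge order follows child index
  g
}

#' (u, v)-flower hierarchical fractal network
#'
#' Generation 1 is a cycle of `u + v` nodes; each subsequent generation
#' replaces every edge by two parallel paths of `u` and `v` edges. The edge
#' count is `(u + v)^g`; the fractal dimension of the (2, 2)-flower is
#' `ln(u + v) / ln(u) = 2`, making it a standard monofractal fixture.
#'
#' @param u,v Path lengths, `u, v >= 1` and `u + v >= 3`.
#' @param generations Number of generations, `>= 1`.
#' @return A network.
#' @export
uv_flower <- function(u, v, generations) {
  stopifnot(u >= 1, v >= 1, u + v >= 3, generations >= 1)
  w <- u + v
  # generation 1: a cycle of length u + v
  el <- cbind(seq_len(w), c(seq_len(w)[-1], 1L))
  n <- w
  if (generations >= 2) {
    for (g in 2:generations) {
      new_el <- matrix(0L, nrow = nrow(el) * w, ncol = 2)
      row <- 1L
      for (e in seq_len(nrow(el))) {
        a <- el[e, 1]; bb <- el[e, 2]
        for (len in c(u, v)) {
          # path of `len` edges from a to bb through len - 1 fresh nodes
          if (len == 1L) {
            chain <- c(a, bb)
          } else {
            fresh <- n + seq_len(len - 1L)
            n <- n + len - 1L
            chain <- c(a, fresh, bb)
          }
          for (s in seq_len(len)) {
            new_el[row, ] <- c(chain[s], chain[s + 1L])
            row <- row + 1L
          }
        }
      }
      el <- new_el[seq_len(row - 1L), , drop = FALSE]
    }
  }
  igraph::simplify(igraph::graph_from_edgelist(el, directed = FALSE))
}
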