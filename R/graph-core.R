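#' Coerce and validate a network
#'
#' Networks throughout the package are undirected simple [igraph][igraph::graph]
#' objects, optionally carrying a positive `weight` edge attribute interpreted
#' as a length. `as_network()` enforces the invariants every other function
#' relies on: directed input is symmetrized (with a warning), self-loops are
#' dropped (with a warning), parallel edges collapse keeping the minimum
#' weight, and weights must be strictly positive.
#'
#' @param g An igraph object.
#' @return A validated undirected simple igraph object.
#' @export
as_network <- function(g) {
  stopifnot(igraph::is_igraph(g))
  if (igraph::vcount(g) < 1) stop("network must have at least one node", call. = FALSE)
  if (igraph::is_directed(g)) {
    warning("directed input symmetrized to an undirected network", call. = FALSE)
    g <- igraph::as_undirected(g, mode = "collapse",
                               edge.attr.comb = list(weight = "min", "ignore"))
  }
  n_loops <- sum(igraph::which_loop(g))
  if (n_loops > 0) warning(sprintf("dropped %d self-loop(s)", n_loops), call. = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                        edge.attr.comb = list(weight = "min", "ignore"))
  if (is_weighted(g)) {
    w <- igraph::E(g)$weight
    if (any(!is.finite(w)) || any(w <= 0)) {
      stop("edge weights must be finite and strictly positive", call. = FALSE)
    }
  }
  g
}

is_weighted <- function(g) "weight" %in% igraph::edge_attr_names(g)

#' Read a network from a whitespace-delimited edge list
#'
#' Each non-comment line holds one edge: `"u v"` (unweighted) or `"u v w"`
#' (weighted, third token a strictly positive real). Lines starting with `#`
#' and blank lines are ignored. Node labels are kept verbatim as the `name`
#' vertex attribute; integer-like labels are not renumbered.
#'
#' @param path Path to the edge-list file.
#' @param weighted If `TRUE`, parse the third column as edge weight.
#' @return An undirected simple igraph object (see [as_network()]).
#' @export
read_edgelist <- function(path, weighted = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  need <- if (weighted) 3L else 2L
  nt <- lengths(toks)
  bad <- which(nt < need)
  if (length(bad)) {
    stop(sprintf("malformed line %d: expected %d whitespace-separated tokens, got %d",
                 idx[bad[1]], need, nt[bad[1]]), call. = FALSE)
  }
  if (!length(toks)) stop("edge list is empty", call. = FALSE)
  u <- vapply(toks, `[`, "", 1L)
  v <- vapply(toks, `[`, "", 2L)
  g <- igraph::graph_from_edgelist(cbind(u, v), directed = FALSE)
  if (weighted) {
    w <- suppressWarnings(as.numeric(vapply(toks, `[`, "", 3L)))
    if (anyNA(w)) {
      stop(sprintf("malformed line %d: weight is not a number", idx[which(is.na(w))[1]]),
           call. = FALSE)
    }
    if (any(w <= 0)) {
      stop(sprintf("validation error at line %d: weight must be strictly positive",
                   idx[which(w <= 0)[1]]), call. = FALSE)
    }
    igraph::E(g)$weight <- w
  }
  as_network(g)
}

#' Write a network to an edge-list file
#'
#' Inverse of [read_edgelist()]: one `"u v"` or `"u v w"` line per edge.
#'
#' @param net A network (igraph object).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(net, path) {
  el <- igraph::as_edgelist(net, names = TRUE)
  lines <- if (is_weighted(net)) {
    paste(el[, 1], el[, 2], format(igraph::E(net)$weight, digits = 17, trim = TRUE))
  } else {
    paste(el[, 1], el[, 2])
  }
  writeLines(lines, path)
  invisible(path)
}

#' Largest connected component
#'
#' Returns the induced subgraph on the largest connected component; ties are
#' broken by the smallest node label (smallest vertex index for unnamed
#' graphs). Warns when nodes are dropped.
#'
#' @param net A network.
#' @return The induced subgraph, a network.
#' @export
largest_component <- function(net) {
  comp <- igraph::components(net)
  if (comp$no == 1L) return(net)
  biggest <- which(comp$csize == max(comp$csize))
  if (length(biggest) > 1L) {
    # ties: pick the component holding the lexicographically smallest label
    labs <- vertex_labels(net)
    firsts <- vapply(biggest, function(k) min(labs[comp$membership == k]), "")
    biggest <- biggest[order(firsts)][1L]
  }
  keep <- which(comp$membership == biggest)
  warning(sprintf("kept largest component: %d of %d nodes", length(keep),
                  igraph::vcount(net)), call. = FALSE)
  igraph::induced_subgraph(net, keep)
}

vertex_labels <- function(net) {
  if ("name" %in% igraph::vertex_attr_names(net)) {
    igraph::V(net)$name
  } else {
    as.character(seq_len(igraph::vcount(net)))
  }
}

#' Shortest-path distances from one node
#'
#' Hop counts for unweighted networks, sums of edge weights for weighted ones.
#' Unreachable nodes get `Inf`.
#'
#' @param net A network.
#' @param source Node label (or vertex index for unnamed graphs).
#' @return Named numeric vector of distances, `0` at the source.
#' @export
distances_from <- function(net, source) {
  v <- resolve_vertex(net, source)
  d <- igraph::distances(net, v = v)[1, ]
  names(d) <- vertex_labels(net)
  d
}

resolve_vertex <- function(net, node) {
  labs <- vertex_labels(net)
  i <- match(as.character(node), labs)
  if (is.na(i)) stop("unknown node: ", node, call. = FALSE)
  i
}

#' Network radius (diameter)
#'
#' The maximum over node pairs of the shortest-path distance — the largest
#' radius any growing box needs, used to normalize the observation scale
#' `r / d`.
#'
#' @param net A connected network.
#' @return A positive real.
#' @export
network_radius <- function(net) {
  if (!igraph::is_connected(net)) {
    stop("network is disconnected; apply largest_component() first", call. = FALSE)
  }
  igraph::diameter(net, weights = if (is_weighted(net)) igraph::E(net)$weight else NA)
}

#' Average degree
#'
#' `2 * E / N`, the mean number of neighbors per node.
#'
#' @param net A network.
#' @return A nonnegative real.
#' @export
average_degree <- function(net) {
  2 * igraph::ecount(net) / igraph::vcount(net)
}
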