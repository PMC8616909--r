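# Shared small fixtures, built in code.

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

path_graph <- function(n, labels = letters[seq_len(n)]) {
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(seq_len(n - 1), 2:n))
  igraph::V(g)$name <- labels
  g
}

complete_graph <- function(n) {
  g <- igraph::make_empty_graph(n, directed = FALSE)
  igraph::add_edges(g, utils::combn(n, 2))
}

write_edge_lines <- function(lines) {
  f <- tempfile(fileext = ".edges")
  writeLines(lines, f)
  f
}

# BA and ER components merged by one edge between their highest-degree
# nodes, the two-mechanism fixture.
merged_ba_er <- function(n = 200, m = 3, seed = 1) {
  ba <- barabasi_albert(n, m, seed = seed)
  er <- erdos_renyi(n, 2 * (m * n) / (n * (n - 1)), seed = seed)
  er <- suppressWarnings(largest_component(er))
  merged <- igraph::disjoint_union(ba, er)
  merged <- igraph::add_edges(merged, c(which.max(igraph::degree(ba)),
                                        igraph::vcount(ba) + which.max(igraph::degree(er))))
  list(ba = ba, er = er, merged = merged)
}
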