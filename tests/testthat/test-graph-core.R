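test_that("read_edgelist parses plain, commented and weighted files", {
  f <- write_edge_lines(c("# comment", "a b", "", "b c"))
  g <- read_edgelist(f)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)
  expect_setequal(igraph::V(g)$name, c("a", "b", "c"))

  fw <- write_edge_lines("a b 0.5")
  gw <- read_edgelist(fw, weighted = TRUE)
  expect_equal(igraph::E(gw)$weight, 0.5)

  # self-loop dropped with a warning
  fl <- write_edge_lines(c("a a"))
  expect_warning(gl <- read_edgelist(fl), "self-loop")
  expect_equal(igraph::vcount(gl), 1)
  expect_equal(igraph::ecount(gl), 0)
})

test_that("read_edgelist rejects malformed input, naming the line", {
  f <- write_edge_lines(c("a b", "c"))
  expect_error(read_edgelist(f), "line 2")
  fw <- write_edge_lines(c("a b 1.0", "b c -2"))
  expect_error(read_edgelist(fw, weighted = TRUE), "line 2.*positive")
  f3 <- write_edge_lines(c("# only", "a b"))
  expect_error(read_edgelist(f3, weighted = TRUE), "line 2")
  expect_error(read_edgelist(tempfile()), "not found")
})

test_that("edge lists round-trip through write_edgelist", {
  for (wtd in c(FALSE, TRUE)) {
    g <- random_connected_graph(12, seed = 7, weighted = wtd)
    igraph::V(g)$name <- paste0("n", seq_len(igraph::vcount(g)))
    f <- tempfile()
    write_edgelist(g, f)
    g2 <- read_edgelist(f, weighted = wtd)
    key <- function(el) paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
    k1 <- key(igraph::as_edgelist(g))
    k2 <- key(igraph::as_edgelist(g2))
    expect_identical(sort(k1), sort(k2))
    if (wtd) {
      expect_equal(igraph::E(g)$weight[order(k1)],
                   igraph::E(g2)$weight[order(k2)], tolerance = 1e-12)
    }
  }
})

test_that("largest_component keeps the biggest piece and warns", {
  p5 <- path_graph(5)
  expect_equal(igraph::vcount(largest_component(p5)), 5)

  two <- igraph::disjoint_union(complete_graph(4), complete_graph(2))
  expect_warning(lc <- largest_component(two), "largest component")
  expect_equal(igraph::vcount(lc), 4)

  edgeless <- igraph::make_empty_graph(3, directed = FALSE)
  expect_warning(lc2 <- largest_component(edgeless), "largest component")
  expect_equal(igraph::vcount(lc2), 1)
})

test_that("distances_from matches hand examples and handles errors", {
  p5 <- path_graph(5)
  d <- distances_from(p5, "c")
  expect_equal(d[c("a", "b", "c", "d", "e")],
               c(a = 2, b = 1, c = 0, d = 1, e = 2))
  k5 <- complete_graph(5)
  expect_equal(unname(distances_from(k5, 1)), c(0, 1, 1, 1, 1))
  # weighted triangle: the two-hop route beats the heavy direct edge
  f <- write_edge_lines(c("a b 1", "b c 1", "a c 3"))
  gt <- read_edgelist(f, weighted = TRUE)
  expect_equal(distances_from(gt, "a")[["c"]], 2)
  expect_error(distances_from(p5, "zz"), "unknown node")
})

test_that("distances agree with a Floyd-Warshall oracle on random graphs", {
  for (s in 1:6) {
    wtd <- s %% 2 == 0
    g <- random_connected_graph(sample(10:30, 1), seed = 100 + s, weighted = wtd)
    Dref <- oracle_floyd_warshall(g)
    Dpkg <- t(vapply(seq_len(igraph::vcount(g)),
                     function(i) unname(distances_from(g, i)),
                     numeric(igraph::vcount(g))))
    if (wtd) {
      expect_equal(Dpkg, Dref, tolerance = 1e-9, ignore_attr = TRUE)
    } else {
      expect_identical(unname(Dpkg), unname(Dref))
    }
  }
})

test_that("network_radius is the diameter and demands connectivity", {
  expect_equal(network_radius(ring_lattice(1000, 4)), 250)
  expect_equal(network_radius(path_graph(5)), 4)
  expect_equal(network_radius(complete_graph(5)), 1)
  # equals the max over per-source distance vectors
  g <- random_connected_graph(20, seed = 42)
  allmax <- max(vapply(seq_len(20), function(i) max(distances_from(g, i)), 0))
  expect_equal(network_radius(g), allmax)
  two <- igraph::disjoint_union(complete_graph(3), complete_graph(3))
  expect_error(network_radius(two), "largest_component")
})

test_that("average_degree reproduces printed social-network values", {
  # Facebook-like Forum t3: 899 nodes, 7046 edges
  g1 <- with_seed_local(1, igraph::sample_gnm(899, 7046))
  expect_equal(round(average_degree(g1), 2), 15.68)
  # Ask Ubuntu t3: 152,597 nodes, 453,211 edges
  g2 <- with_seed_local(1, igraph::sample_gnm(152597, 453211))
  expect_equal(round(average_degree(g2), 2), 5.94)
  expect_equal(average_degree(ring_lattice(50, 4)), 4)
})

test_that("as_network symmetrizes, deduplicates and validates weights", {
  dg <- igraph::make_graph(c(1, 2, 2, 1, 2, 3), directed = TRUE)
  expect_warning(ug <- as_network(dg), "symmetrized")
  expect_equal(igraph::ecount(ug), 2)
  # parallel edges collapse to the minimum weight
  mg <- igraph::make_graph(c(1, 2, 1, 2), directed = FALSE)
  igraph::E(mg)$weight <- c(3, 1)
  expect_equal(igraph::E(as_network(mg))$weight, 1)
  bg <- igraph::make_graph(c(1, 2), directed = FALSE)
  igraph::E(bg)$weight <- -1
  expect_error(as_network(bg), "positive")
})
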