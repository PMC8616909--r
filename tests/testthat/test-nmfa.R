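test_that("qgrid contains exact zero and validates bounds", {
  q <- qgrid()
  expect_equal(length(q), 101)
  expect_true(0 %in% q)
  expect_equal(q[1], -10)
  expect_true(all(diff(q) > 0))
  expect_error(qgrid(-10, 10, 0.3), "integer multiples")
})

test_that("probability measures normalize by total mass", {
  k5 <- complete_graph(5)
  # K5: M_i(1) = 4 for every node, u_i = 4/5
  m <- t(vapply(1:5, function(i) mass_profile(k5, i)$mass, numeric(1)))
  expect_equal(unname(probability_measures(matrix(m, 5, 1), 5)),
               matrix(0.8, 5, 1))
  # at r = d every measure is (N-1)/N under the center-excluded convention
  g <- random_connected_graph(15, seed = 2)
  d <- network_radius(g)
  u_at_d <- vapply(1:15, function(i) {
    p <- mass_profile(g, i)
    p$mass[match(d, p$radii)] / 15
  }, 0)
  expect_true(all(is.na(u_at_d) | u_at_d == 14 / 15))
  # single-scale graphs cannot support the analysis
  expect_error(nmfa_analyze(k5), "degenerate")
})

test_that("partition function follows the defining sums", {
  # K5 at r = 1: every u_i = 4/5
  u <- matrix(4 / 5, nrow = 5, ncol = 1)
  q <- c(-1, 0, 1, 2)
  U <- partition_function(u, q)
  expect_equal(unname(U[q == 0, 1]), 5)          # x^0 sums to N
  expect_equal(unname(U[q == 1, 1]), 4.0)        # 5 * 0.8
  expect_equal(unname(U[q == 2, 1]), 3.2)        # 5 * 0.64
  expect_equal(unname(U[q == -1, 1]), 5 / 0.8)
  expect_error(partition_function(matrix(c(0.5, 0), 2, 1), q), "zero probability")
})

test_that("ring-lattice mass exponent is exactly linear: tau(q) = q", {
  res <- nmfa_analyze(ring_lattice(200, 4))
  expect_equal(res$tau, res$q, tolerance = 1e-9)
  expect_equal(res$tau_r2, rep(1, length(res$q)), tolerance = 1e-9)
  expect_equal(res$tau[res$q == 0], 0)
  expect_equal(res$alpha, rep(1, length(res$q)), tolerance = 1e-9)
  expect_equal(res$f_alpha, rep(0, length(res$q)), tolerance = 1e-8)
  expect_equal(res$D, rep(1, length(res$q)), tolerance = 1e-9)
  expect_lt(res$width, 1e-9)
})

test_that("Legendre transform identity holds on arbitrary curves", {
  q <- qgrid(-5, 5, 0.5)
  tau <- 2 * q - 0.1 * q^2  # a concave toy free energy
  sp <- legendre_spectrum(tau, q)
  expect_equal(sp$f_alpha + tau - q * sp$alpha, rep(0, length(q)),
               tolerance = 1e-12)
  # monofractal tau = q * D collapses to a point
  spm <- legendre_spectrum(1.7 * q, q)
  expect_equal(spm$alpha, rep(1.7, length(q)))
  expect_equal(spm$f_alpha, rep(0, length(q)))
  expect_equal(spm$width, 0)
  expect_error(legendre_spectrum(c(tau[-1], NaN), q), "non-finite")
})

test_that("generalized dimension uses the continuity rule at q = 0", {
  q <- qgrid(-5, 5, 0.5)
  tau <- 2 * q - 0.1 * q^2
  sp <- legendre_spectrum(tau, q)
  gd <- generalized_dimension(tau, q, sp$alpha)
  expect_equal(gd$D[q == 0], sp$alpha[q == 0])
  expect_equal(gd$D[abs(q) > 1e-9], (tau / q)[abs(q) > 1e-9])
  expect_equal(gd$D_min, min(gd$D))
  expect_equal(gd$D_max, max(gd$D))
})

test_that("partition series is monotone in r with the sign of q", {
  g <- random_connected_graph(25, seed = 31)
  res <- nmfa_analyze(g, q = qgrid(-4, 4, 0.5))
  D_mat <- igraph::distances(g)
  diag(D_mat) <- Inf
  r0 <- apply(D_mat, 1, min)
  radii <- res$radii
  mass <- t(vapply(seq_len(igraph::vcount(g)), function(i) {
    vapply(radii, function(r) sum(D_mat[i, ] <= r), 0)
  }, numeric(length(radii))))
  U <- partition_function(mass / igraph::vcount(g), res$q)
  for (qi in seq_along(res$q)) {
    if (res$q[qi] > 0) expect_true(all(diff(U[qi, ]) >= 0))
    if (res$q[qi] < 0) expect_true(all(diff(U[qi, ]) <= 0))
  }
})

test_that("pipeline matches the straight-loop oracle on random graphs", {
  q <- qgrid(-6, 6, 0.5)
  for (s in 1:5) {
    g <- random_connected_graph(sample(12:30, 1), seed = 300 + s)
    res <- nmfa_analyze(g, q = q)
    ref <- oracle_nmfa(g, q)
    expect_equal(res$radii, ref$radii)
    expect_equal(res$fit_idx, ref$fit_idx)
    expect_equal(res$tau, ref$tau, tolerance = 1e-9)
    expect_equal(res$alpha, ref$alpha, tolerance = 1e-9)
    expect_equal(res$f_alpha, ref$f, tolerance = 1e-9)
    expect_equal(res$D, ref$D, tolerance = 1e-9)
  }
})

test_that("spectrum width grows from ordered to random rewiring", {
  widths <- vapply(c(0.001, 1), function(p) {
    mean(vapply(1:5, function(s) {
      suppressWarnings(nmfa_analyze(watts_strogatz(200, 4, p, seed = s)))$width
    }, 0))
  }, 0)
  expect_gt(widths[2], widths[1])
})

test_that("nmfa_analyze is deterministic and rejects degenerate input", {
  g <- barabasi_albert(80, 2, seed = 4)
  r1 <- nmfa_analyze(g)
  r2 <- nmfa_analyze(g)
  expect_identical(r1, r2)
  expect_error(nmfa_analyze(path_graph(2)), "degenerate")
  # disconnected input is reduced with a warning
  two <- igraph::disjoint_union(ring_lattice(30, 4), complete_graph(3))
  expect_warning(res <- nmfa_analyze(two), "largest component")
  expect_equal(res$n, 30)
  expect_error(nmfa_analyze(two, use_largest_component = FALSE), "disconnected")
})
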