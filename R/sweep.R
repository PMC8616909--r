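# Watts-Strogatz rewiring sweep: ensemble NMFA trajectories as the lattice
# randomizes, tracing the small-world transition.

ci99 <- function(x) 2.576 * stats::sd(x) / sqrt(length(x))

#' Watts–Strogatz rewiring sweep
#'
#' For each rewiring probability `p`, generates `replicates` WS networks,
#' runs NMFA on the largest component of each, and aggregates ensemble
#' means with 99% normal-approximation confidence half-widths
#' (`2.576 * sd / sqrt(replicates)`) for: complexity `alpha0`,
#' heterogeneity `w`, `D_min`, `D_max`, the number of detected
#' specific-heat peaks, and the structure distance from the initial
#' (`p = 0`) ring lattice.
#'
#' The default scale (`n = 500`, 20 replicates) is a desk-scale reduction;
#' raise `n` and `replicates` for production sweeps.
#'
#' @param n,k Ring-lattice parameters.
#' @param p_values Rewiring probabilities to sweep.
#' @param replicates Networks per `p`.
#' @param seed Base seed; replicate seeds are derived deterministically.
#' @param q Distortion grid.
#' @param ... Passed to [nmfa_analyze()].
#' @return A data.frame, one row per `p`, with `<metric>_mean` and
#'   `<metric>_ci` columns.
#' @export
sweep_ws <- function(n = 500, k = 4, p_values = c(0, 0.001, 0.01, 0.1, 1),
                     replicates = 20, seed = 1, q = qgrid(), ...) {
  base <- nmfa_analyze(ring_lattice(n, k), q = q, ...)
  rows <- lapply(seq_along(p_values), function(ip) {
    p <- p_values[ip]
    stats_m <- vapply(seq_len(replicates), function(rep) {
      g <- watts_strogatz(n, k, p, seed = seed + (ip - 1L) * replicates + rep - 1L)
      res <- suppressWarnings(nmfa_analyze(g, q = q, ...))
      sh <- specific_heat(res)
      c(alpha0 = res$alpha0, width = res$width,
        d_min = res$D_min, d_max = res$D_max,
        n_peaks = nrow(sh$peaks),
        dist = structure_distance(base, res))
    }, numeric(6))
    means <- rowMeans(stats_m)
    cis <- apply(stats_m, 1, ci99)
    out <- as.data.frame(as.list(c(p = p,
                                   stats::setNames(means, paste0(names(means), "_mean")),
                                   stats::setNames(cis, paste0(names(cis), "_ci")))))
    out
  })
  do.call(rbind, rows)
}
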