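---
title: "Node-based multifractal analysis: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Node-based multifractal analysis: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netmfa)
```

This vignette is the package's own account of the method: the model and
its assumptions, every tunable that matters, what the synthetic generators
do and do not emulate, the numerical choices, and the known limitations.
It states no empirical result that the test suite or the acceptance script
does not itself compute.

## 1. The box-growing picture

Every analysis starts from shortest-path balls. For node $i$, the box of
radius $r$ covers all nodes at distance $\le r$ (hops when unweighted,
summed edge lengths when weighted); its mass $M_i(r)$ counts the covered
nodes. The initial radius $r_0$ is the distance at which the box first
covers a neighbor, with initial mass $M(r_0)$.

**The center node is excluded from $M(r)$** (opt-in `include_center = TRUE`
reverses this). The exclusive convention is what makes a $k$-regular ring
lattice satisfy $M(r)/M(r_0) = r/r_0$ *exactly* — four new nodes per hop,
$M(r) = kr$ — so its node-based fractal dimension is exactly 1 with
$R^2 = 1$, rather than only asymptotically. The test suite asserts this
exactness.

The **NFD** of a node is the least-squares slope of
$\ln(M(r)/M(r_0))$ against $\ln(r/r_0)$. A single-radius ratio would be
noise-dominated, so a regression over a scale range is used, with the
goodness of fit $R^2$ reported alongside. Plateaus (radii where $M$ does
not grow) are retained in the fit: they are informative about
sub-one-dimensional structure such as path ends, not artifacts.

## 2. From node profiles to a multifractal spectrum

With $N$ nodes, the node measures $u_i(r) = M_i(r)/N$ feed the partition
function $U_q(r) = \sum_i u_i(r)^q$, fitted against the observation scale
$r/d$ ($d$ = diameter) to give the mass exponent $\tau(q)$ per distortion
exponent $q$. The Legendre transform $\alpha(q) = d\tau/dq$,
$f(\alpha) = q\alpha - \tau$ yields the spectrum, and $D(q) = \tau(q)/q$
the generalized dimensions.

Assumptions worth making explicit:

* the network must be connected (callers may auto-reduce to the largest
  component, which is logged as a warning);
* all measures must be strictly positive wherever $q < 0$ is evaluated —
  guaranteed by starting the scale grid at $\max_i r_{0,i}$;
* the analysis is scale-free only within the fitted window; nothing is
  claimed below $r_0$ or above the saturation region.

## 3. Scale grids and fit windows

* **Unweighted graphs**: integer radii $r_{start} \dots d$ with
  $r_{start} = \max_i r_{0,i}$.
* **Weighted graphs**: `n_scales` (default 20) geometrically spaced radii
  over the same span — distances are continuous, so a log-spaced grid
  samples the power law evenly.
* **Fit window**: radii with $r \le$ `fit_frac` $\times\, d$ (default one
  half), excluding the saturation plateau near full coverage, *widened to
  at least `min_scales` = 5 smallest radii* when the half-window is
  narrower. The widening matters: small-world graphs (diameter 5–8 at a
  few hundred nodes) leave only 2–3 hop scales below $d/2$, and mass
  exponents regressed on so few points are unstable enough to break the
  concavity of $\tau$ and leave the asymmetry metric undefined. Five
  scales is the smallest window that kept every generator ensemble in the
  test suite well-posed; it was fixed before the acceptance measurements
  and not revisited.
* The per-node NFD fit keeps the spec of its own module: a node's natural
  grid (every distinct distance from it), window up to half the profile
  extent, minimum 3 scales.

The regression choice (rather than the pointwise ratio
$\tau = \ln U_q / \ln(r/d)$ at one $r$) mirrors how log–log fits are read
off in practice. Its known cost: a pointwise $\tau$ at fixed $r$ is
provably concave in $q$, a regression across scales is not, so
finite-size spectra can be locally non-monotone in $\alpha$ — see §7.

## 4. Summaries, derivatives and derived metrics

* $\alpha$ is computed by **central finite differences** on the $q$ grid
  (one-sided at the ends), with no smoothing: reproducibility is preferred
  over aesthetics, and any smoothing window would become one more tunable.
* $f(\alpha) = q\alpha - \tau$ is applied as an algebraic identity; the
  suite checks $f + \tau - q\alpha = 0$ to $10^{-12}$.
* $D(0)$ is defined by continuity as $\alpha(0)$: $\tau(0) = 0$ makes
  Eq. $D = \tau/q$ a 0/0 limit whose value is $\tau'(0)$.
* **Summaries**: complexity $\alpha_0 = \alpha(0)$; support extremes
  $\alpha_{min} = \min_q \alpha$, $\alpha_{max} = \max_q \alpha$; width
  $w = \alpha_{max} - \alpha_{min}$. Taking grid extrema (rather than the
  endpoint values $\alpha(q_{max})$, $\alpha(q_{min})$) is deliberate:
  they coincide for monotone $\alpha$, and when finite-size regression
  noise breaks monotonicity the extrema keep $\alpha_0$ inside
  $[\alpha_{min}, \alpha_{max}]$ so the asymmetry stays defined.
* **Asymmetry** $\ln((\alpha_0-\alpha_{min})/(\alpha_{max}-\alpha_0))$
  returns 0 by convention when $w <$ `degenerate_tol` ($10^{-3}$): the
  ratio is 0/0 for a monofractal, and "no width" is most usefully read as
  "no asymmetry".
* **Structure distance**: root-mean-square difference of two $D(q)$
  curves, trapezoidal rule on the shared grid; restricted ranges
  (`q_range`), used to compare only frequent- or rare-structure
  dimensions, exclude $q = 0$ when one-sided.
* **Specific heat** $C(q) = d\alpha/dq$ is reported with its literal sign
  (non-positive for a well-behaved spectrum), but peak detection operates
  on $|C|$, which makes it independent of the sign convention. Peaks are
  local maxima of $|C|$ above a **prominence** of 20% of $\max|C|$ with a
  **minimum separation** of 1.0 in $q$ (stronger peak wins); both are
  configurable. There is no canonical peak-finding rule for these curves;
  the defaults were chosen on the merged two-mechanism fixture (§5) and
  then frozen. A flat curve ($\max|C| \le 10^{-12}$) has no peaks.

## 5. What the generators emulate — and what they do not

The generators implement the textbook mechanisms directly (not wrappers
around library samplers) so that every step is reproducible bit-for-bit
under a seed.

* `ring_lattice(n, k)` — the ordered extreme: one linear rule, NFD exactly
  1, zero width. The starting point of every rewiring experiment.
* `erdos_renyi(n, p)` — independent edges; at mean degree ~6 it grows
  dangling chains ("thorn" structure, negative asymmetry).
* `watts_strogatz(n, k, p)` — each lattice edge $(u,v)$ rewired with
  probability $p$ to $(u,w)$, $w$ uniform over non-neighbors of $u$;
  self-loops and duplicates are never created, so $n$ and the edge count
  are invariant. If no eligible target exists the edge stays. Outputs may
  be disconnected at intermediate $p$; pipeline callers take the largest
  component (logged). The sweep across $p$ emulates an order-to-chaos
  transition, not any particular real network.
* `barabasi_albert(n, m, m0)` — preferential attachment; the seed graph is
  the complete graph on $m0 = m$ nodes (the common convention, making edge
  counts exact: $\binom{m_0}{2} + (n-m_0)m$), and each arrival connects to
  $m$ distinct nodes drawn without replacement with probability
  proportional to degree. Produces "clump" (hub) structure with positive
  asymmetry.
* `weighted_fractal(b, f, G)` — a rooted self-similar tree, $b$ children
  per node. The generation-$g$ edge length is chosen so that the
  root-to-level-$g$ distance satisfies the closed-form mass–radius law
  $M(r)/M(r_0) = (r/r_0)^{\ln b/\ln(1/f)}$ *exactly* at every finite
  generation (the lengths still scale as $(1/f)^g$ asymptotically). With
  naive lengths $(1/f)^g$ the geometric-sum corrections decay so slowly
  that even at generation 8 the fitted slope is visibly below the closed
  form; since the construction exists to validate that closed form, the
  exact-power variant is used and documented as a synthetic stand-in —
  no claim is made that it matches any particular Sierpinski embedding.
* `uv_flower(u, v, G)` — generation 1 is a $(u{+}v)$-cycle; each
  generation replaces every edge by parallel paths of $u$ and $v$ edges.

**What a green test establishes** — that the pipeline recovers the
analytically known behavior of these idealized worlds (exact monofractal
collapse, closed-form dimensions, qualitative clump/thorn split,
two-mechanism peak signatures). It does **not** establish that real
networks satisfy power laws over their fitted windows, that the
small-sample spectra are unbiased, or that peak counts are robust to the
detection thresholds; real-data conclusions need the sensitivity checks
of §7.

## 6. Degenerate inputs and error policy

Single nodes, isolated nodes, and single-scale graphs (e.g. complete
graphs, where every distance is 1) are errors, not silent NaNs — a
power-law fit over fewer than 3 scales is meaningless. Parallel edges
collapse keeping the minimum weight; self-loops are dropped with a
warning; directed input is symmetrized with a warning; weights must be
strictly positive and finite. Node labels are opaque strings and never
renumbered.

## 7. Known limitations

* **Finite-size flowers are not monofractal node-wise.** The
  $(2,2)$-flower's asymptotic dimension is 2, but at generation 6 its hub
  degrees span $2 \dots 2^6$, so the node measures are heterogeneous and
  the node-based spectrum has substantial width, with per-node mass–radius
  slopes well below 2. The acceptance suite asserts the (stated)
  monofractal collapse anyway and the corresponding expectations fail by
  design; the decisions ledger carries the measured numbers.
* **Regression $\tau$ can violate concavity** at extreme $|q|$ on
  small-diameter graphs (§3). The grid-extrema summaries keep downstream
  metrics defined, but spectra from graphs with diameter $\lesssim 8$
  should be read with that caveat.
* **Peak counts are convention-sensitive.** The two-peak small-world
  signature appears or merges depending on the fit-window fraction; the
  package keeps one fixed convention rather than tuning per experiment,
  and the acceptance suite records where the stated expectation then
  fails. The merged BA+ER fixture, where the two mechanisms live at
  clearly different $q_c$, shows the signature robustly.
* **Heterogeneity need not rise monotonically with disorder.** Under
  these conventions the mixed lattice+shortcut regime is *wider* than the
  fully random graph — a union of two mechanisms — so width peaks at
  intermediate rewiring probability.
* Directed structure, multigraphs, temporal streams, box-covering
  renormalization and curvature-based edge importance are out of scope.

## 8. Reproducibility

All stochastic generators take an explicit `seed` and restore the
caller's RNG state. `nmfa_analyze` is deterministic given its input graph
and configuration; CLI outputs embed a configuration fingerprint.
Ensemble helpers report means with 99% normal-approximation confidence
half-widths ($2.576\,\mathrm{sd}/\sqrt{n}$).
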