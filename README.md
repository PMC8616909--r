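# netmfa — node-based multifractal analysis of complex networks

Real networks — brain connectomes, social graphs, protein interaction maps —
are rarely produced by a single generating rule. A lattice-like core, a few
preferential-attachment hubs and some random shortcuts can coexist in one
graph, and whole-network summaries (degree distributions, a single fractal
dimension) average them away. `netmfa` characterizes a network *from its
nodes outward*: it grows a shortest-path ball around every node, tracks how
much of the network each ball swallows, and turns the family of growth
curves into a multifractal description of the whole graph. The package is
aimed at network scientists and systems biologists who want a
scale-dependent fingerprint of a graph — to compare networks, to watch one
evolve, or to detect that two different growth mechanisms are coexisting.

## The model

For a node *i*, let `M_i(r)` be the number of other nodes within
shortest-path distance `r` (hop count, or summed edge lengths for weighted
graphs), and `r0` the distance at which the growing box first covers a
neighbor. The **node-based fractal dimension** (NFD) is the power-law
exponent of the box growth,

    M(r) / M(r0) ~ (r / r0)^D ,

estimated per node by least squares on the log-log profile. For networks
mixing several rules, the node measures `u_i(r) = M_i(r) / N` are combined
into a partition function and mass exponent over the observation scale
`r / d` (`d` = diameter):

    U_q(r) = Σ_i u_i(r)^q ~ (r / d)^τ(q) ,

with the distortion exponent `q` amplifying frequent (`q > 0`) or rare
(`q < 0`) structures. The Legendre transform `α(q) = dτ/dq`,
`f(α) = qα − τ` gives the multifractal spectrum, and `D(q) = τ(q)/q` the
generalized dimensions. Derived summaries:

* **complexity** `α0 = α(0)` and **heterogeneity** `w = α_max − α_min`;
* **asymmetry** `ln((α0 − α_min)/(α_max − α0))` — positive for
  hub-dominated "clump" structure (preferential attachment), negative for
  dangling "thorn" structure (sparse random graphs);
* **structure distance** between two networks,
  `sqrt( ∫ (D1(q) − D2(q))² dq / (q_max − q_min) )`;
* **specific heat** `C(q) = dα/dq`, whose |C| peaks mark
  phase-transition-like changes of the dominant mechanism at critical
  exponents `q_c` (`q_c > 0` clump, `q_c < 0` thorn).

Reference generators (ring lattice, Erdős–Rényi, Watts–Strogatz,
Barabási–Albert, weighted self-similar fractal trees with closed-form root
dimension `ln b / ln(1/f)`, and (u,v)-flowers) are included for validation
and synthetic experiments.

## Worked example

A regular ring lattice (1000 nodes, each linked to its 4 nearest
neighbors) is a perfect monofractal; rewiring 3% of its edges
(Watts–Strogatz small-world regime) makes it complex and heterogeneous:

```r
library(netmfa)

lattice <- ring_lattice(1000, 4)
nmfa_analyze(lattice)
#> <nmfa> n = 1000 nodes, d = 250, 250 radii (125 in fit), q in [-10, 10]
#>   complexity alpha0 = 1.0000, heterogeneity w = 0.0000
#>   D(q): min = 1.0000, max = 1.0000; asymmetry = 0.0000

sw  <- largest_component(watts_strogatz(1000, 4, p = 0.03, seed = 1))
res <- nmfa_analyze(sw)
res
#> <nmfa> n = 1000 nodes, d = 36, 36 radii (18 in fit), q in [-10, 10]
#>   complexity alpha0 = 1.8607, heterogeneity w = 0.5703
#>   D(q): min = 1.5183, max = 1.9402; asymmetry = 1.5542

specific_heat(res)$peaks
#>    q_c magnitude mechanism
#> 1 -1.6 0.1096529     thorn

structure_distance(nmfa_analyze(lattice), res)
#> [1] 0.8040081
```

Reading: the lattice has dimension exactly 1 at every scale and zero
spectrum width (one generating rule). Thirty rewired edges raise the
complexity `α0` from 1 to 1.86, open a spectrum width of 0.57 (two rules
now coexist), and move the network a structure distance of 0.80 from its
ordered origin; the specific-heat peak at `q_c = −1.6` flags a transition
driven by rare, chain-like motifs.

A command-line pipeline wraps the same operations
(`inst/cli/netmfa generate | nfd | analyze | compare | deletion |
sweep-ws`), reading whitespace-delimited edge lists (`u v` or `u v w`,
`#` comments) and writing CSV/JSON.

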