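---
title: "Topological swarm dynamics: model, order parameters, and network analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological swarm dynamics: model, order parameters, and network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toposwarm)
```

## The model

`toposwarm` simulates a group of N agents whose only interaction is a
piecewise attraction/repulsion force exchanged with each agent's K nearest
neighbors. Neighborhood is *topological*: an agent always perceives exactly
K others, by distance rank, no matter how far away they are. There is no
velocity state and no alignment rule; the dynamics are first order in
position.

The pair force at distance $x$ is

$$
f(x) =
\begin{cases}
k_1\!\left(\tfrac1x - \tfrac1{d_e}\right) & d_l < x < d_e \quad\text{(repulsion)}\\[2pt]
k_2 \sin\!\left(\tfrac{(x-d_e)\pi}{d_h-d_e}\right) & d_e < x \le \tfrac{d_e+d_h}{2} \quad\text{(attraction)}\\[2pt]
k_3 & x > \tfrac{d_e+d_h}{2} \quad\text{(saturated attraction)}\\[2pt]
0 & \text{otherwise.}
\end{cases}
$$

$d_e$ is the equilibrium ("expected") spacing at which the force vanishes;
repulsion diverges as $x \to 0$, which is itself the collision-avoidance
mechanism (exact coincidence is treated as a degenerate-geometry error — it
is a measure-zero event under continuous dynamics). Attraction rises
sinusoidally above $d_e$ and stays pinned at $k_3$ beyond the saturation
threshold $(d_e+d_h)/2$: distant neighbors pull exactly as hard as
mid-range ones, which is what lets an isolated agent rejoin the group from
any distance. With the default $k_3 = k_2$ the force is continuous at the
threshold; the package permits $k_3 \neq k_2$ but warns, because the force
is then discontinuous there.

The resultant force on agent $i$ sums $a\,A(x_{ij}) - b\,R(x_{ij})$ over
its K neighbors $j$, resolved along the unit vector from $i$ toward $j$
($A$, $R$ are the attractive and repulsive magnitudes above), and positions
update synchronously:
$S_i(t{+}1) = S_i(t) + c\,F_i(t)$.
Because perception is asymmetric (being someone's nearest neighbor is not
reciprocal), net momentum is not conserved — this asymmetry is exactly what
drives collective translation and rotation. At $K = N-1$ the graph is
symmetric, momentum is conserved, and the group freezes in place.

### Parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `d_l` | 0 | length | lower bound of the repulsive range |
| `d_e` | 5.2 | length | equilibrium spacing |
| `d_h` | 12 | length | upper bound entering the sine period |
| `k1`, `k2`, `k3` | 1, 0.3, 0.3 | force | branch coefficients |
| `a`, `b` | 0.08, 0.2 | — | attraction/repulsion weights |
| `c` | 1 | length/force | displacement per unit force |
| `dims` | 3 | — | spatial dimensionality (2 supported for tests/plots) |
| `t_max` | 20000 | steps | maximum run length |
| `stability_tol` | 1e-6 | — | stationarity tolerance, relative to `d_e` |
| `stability_window` | 50 | steps | consecutive quiet steps required |

Stationarity is defined on the *relative configuration*: the largest
per-step change over all pairwise distances must stay below
`stability_tol * d_e` for `stability_window` consecutive steps. A rigidly
translating or rotating group is therefore stationary — stable collective
motions keep moving while their internal geometry is fixed. The tolerance
is deliberately tight so that slowly-contracting spirals are not truncated
prematurely; one consequence is that even a rapidly aggregating group
needs a few thousand steps to satisfy it formally.

## Order parameters and the motion taxonomy

Two bounded, dimensionless order parameters summarise a trajectory over an
analysis window (by default the last 25% of steps, skipping the long
initial transient):

* **Straightness (S)** — chord over arc of the *centroid* path: 1 for
  straight translation, about $2/\pi$ for a semicircular sweep, 0 for a
  closed orbit. Computed on the full-resolution centroid path, which the
  trajectory object always stores even when agent snapshots are thinned —
  an arc length measured on a strided path would be biased low for
  spirals.
* **Helicity (H)** — time-averaged normalized group angular momentum about
  the instantaneous centroid,
  $|\sum_i \mathbf r_i \times \mathbf v_i| \,/\, \sum_i |\mathbf r_i||\mathbf v_i|$:
  1 for rigid rotation, 0 for any motion whose per-step displacements are
  identical across agents (the summed cross product then vanishes because
  the $\mathbf r_i$ are centred).

Both are invariant under translation, rotation and uniform rescaling of
the trajectory.

The emergent motions fall into eight types plus fission. The classifier is
a cascade; all its cut points live in `motion_thresholds()` because the
taxonomy constrains only the *ordering* of S and H across types, not the
boundaries:

1. **Sustained splits.** If the interaction digraph's weak-component count
   exceeds one continuously for `fission_window` steps (500 by default =
   50 snapshots at the default stride of 10) *and* the final graph is
   still disconnected, the run has fragmented. It is classified
   **fission** when the fragments keep moving as coherent subgroups, and
   **type 8** (unformed motion) when the whole configuration has frozen
   into static scattered remnants. The distinction is mechanical, not
   cosmetic: a fragment of size $\le K{+}1$ has a complete, hence
   symmetric, internal graph, generates no net drive, and stalls —
   low-K runs end as motionless debris, which is disorder, not two
   subgroups on the move. A transient early split that re-merges is
   not fission.
2. **Type 7** (rapid aggregation): the group is stationary, its centroid
   has stopped, and there is no orbital angular momentum
   (`H < h_orbit`). This is the characteristic outcome of large K
   (always at $K = N-1$, where symmetry freezes the group).
3. **Type 8** also covers runs that never become stationary and whose
   mean nearest-neighbor spacing does not settle (relative fluctuation
   above `settle_tol` over the window).
4. Everything else maps to **types 1–6** by straightness bands
   (`s_type1` … `s_type4`, descending) with the low-S orbit split into
   types 5/6 by `h_type6`. This respects the taxonomy's orderings
   (S decreasing, H broadly increasing from type 1 to 6); the exact cut
   values between adjacent types are free choices surfaced as
   configuration.

A seemingly natural alternative gate for type 7 — requiring stationarity
*within* a fixed early fraction of `t_max` — interacts badly with the
tight stationarity tolerance: formal stationarity of an aggregating
group arrives only after ~25% of `t_max` even though the collapse is
effectively finished within a few hundred steps. The classifier
therefore identifies type 7 by the frozen end state itself (stationary,
centroid at rest, no rotation), which is also how the taxonomy pins it
($S = H = 0$).

## Fission detection and its critical point

Fission is detected on graph connectivity, not spatial clustering: the
subgroups are the weakly connected components of the final interaction
graph, and the critical step is the first step of the sustained
multi-component episode. Because every agent's K nearest neighbors lie
inside its own weak component, each subgroup necessarily has at least
K+1 members; this structural bound (and the aggregate bounds K ≤ N/2 and
subgroup count ≤ N/K) is asserted in the test suite on every detected
fission. The component count is recorded at every step during simulation,
so detection does not depend on the snapshot stride.

## Network metrics

The directed interaction graph has an edge from perceived neighbor to
perceiver, so every in-degree equals K by construction, and the density
is exactly $K/(N-1)$ at every step. The out-degree of an agent counts how
many others watch it — its influence. In stationary groups out-degrees
concentrate near K with a single conspicuous agent near 2K (the "leader"
effect), which the suite checks as a max/median ratio in [1.5, 2.5].

* **Network entropy** — the reference analysis names the quantity but not
  its formula. We use the Shannon entropy (natural log) of the out-degree
  distribution: the in-degree distribution is degenerate by construction,
  and this choice reproduces the one pinned value (0 for the degree-regular
  graph at $K = N-1$). The base (nats vs bits) is otherwise unconstrained.
* **Average geodesic distance** — mean directed shortest-path length over
  reachable ordered pairs; unreachable pairs (across fission subgroups)
  are excluded and reported as a reachable-pair fraction. In compact
  stationary groups it tracks $g \approx 2 - K/(N-1)$: a fraction
  $K/(N-1)$ of ordered pairs is one hop away, nearly all the rest two.
  Under the uniform-random initial conditions this holds tightly for
  $K \gtrsim 8$ at N = 21; connected end states at smaller K are
  elongated rather than compact and sit somewhat above the prediction,
  and at K = 5 every seeded run fissions, leaving that regime empty.
* **Average clustering** — Watts–Strogatz local coefficients on the
  undirected projection (no directed variant is specified in the
  reference analysis), vertices of degree < 2 contributing 0.

All four metrics are validated against brute-force oracles (adjacency
powers for shortest paths, explicit triangle counting for clustering) on
random configurations.

## Initial-condition generators

Three seeded families emulate the study's setups: a uniformly drawn cloud,
a cloud plus one isolated individual beyond the saturation threshold, and
2–3 pre-aggregated subgroups with centroids more than `d_h` apart. All are
pure functions of their arguments (seed included), use R's default
Mersenne–Twister stream without touching the caller's RNG state, and
reject near-coincident points.

The cloud's default target spacing — a mean nearest-neighbor distance of
8.6 length units, the midpoint between $d_e$ and the saturation
threshold — places the group in the loosely distributed regime where
attraction dominates initially. The reference study describes its initial
positions only as well distributed and never publishes coordinates; we
read this as uniform random. Two alternative readings were examined and
discarded. A near-regular, evenly spaced arrangement suppresses the
reported phenomenology almost entirely (order into straight translation
already at K = 3, essentially no fission). A minimum-separation
(hard-core) cloud with floor $d_e$ keeps the low-K disorder regime but
pushes the emergence of majority collective motion to K = 7 and still
fissions below K = 5. Uniform random reproduces the reported taxonomy,
the fission region with its predominantly two-subgroup structure, and
the leader effect, at the cost of harsher low-K outcomes: intrinsic
density fluctuations of uniform sampling seed local clumps that detach
during the initial collapse. Under these conditions the measured
emergence threshold lands at K = 6 (the study reports 5, within its own
stated band of 5–7; K = 5 is collective in exactly half of the seeds),
the smallest fissioning K is 4 rather than 5, a minority of splits
produce three subgroups, and mid-size groups (N ≳ 20) can lack a
collective majority for every K ≤ 7. These deviations are reported as
measured rather than calibrated away.

## Experiment layer

`run_experiment()` produces a complete artifact set (trajectory CSV,
metric time series, behavior JSON, final-graph edge list, summary JSON
embedding the full parameter set and seed); identical inputs yield
byte-identical summaries. `sweep_nk()` runs an (N, K, seed) grid with
per-cell error capture; `fission_summary()` reduces a sweep to the
fission region and its K/N statistics; `emergence_threshold()` scans K
upward and reports the smallest K whose runs are, by majority vote over
seeds, coherent collective motion (types 1–7). Majority voting stands in
for the study's single unpublished initial configuration. A thin command
line front end over these functions ships in `inst/cli/toposwarm.R`.

## Problem sizes used in the checks

The packaged checks run the model at the study's scales: single runs use
the full `t_max = 20000`; the emergence scan uses N ∈ {15, 16}, K
ascending, 10 seeds; the fission sweep uses N ∈ {20, …, 30},
K ∈ {4, …, 8}, 5 seeds. The K/N fission statistics, which the study
derives from its full N ≤ 50 grid, are checked on a thinned grid
(N sampled in steps of 4, K up to 12, 2 seeds) — the package's choice of
a representative subsample of that region; the `sweep_nk()` surface runs
the full grid unchanged if desired.

## Known limitations

* The reference coordinates and RNG are unpublished, so figure-level
  shapes are not reproducible point-for-point; only the (S, H, fission)
  signatures and network laws are.
* Straightness/helicity are named but never defined in the reference
  analysis; the chord-over-arc and normalized-angular-momentum choices
  here are one defensible pair, selected for boundedness, invariance, and
  for reproducing the stated orderings on archetype motions.
* Helicity is computed on stored snapshots; with very coarse strides and
  fast rotations it would alias. At the default stride (10) rotation
  periods observed in practice span hundreds of steps, far from the
  aliasing regime.
* No metric-radius interaction mode, perception noise, heterogeneous K,
  or velocity/alignment state: these are outside the model family.
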