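---
title: "Minimum control nodes for exact network controllability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimum control nodes for exact network controllability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netctrl)
```

## The problem

A directed weighted network of `N` dynamical (state) nodes with `P`
candidate external inputs (control nodes) evolves as a linear
time-invariant system

$$\dot x = A x + B u,$$

where `A[i, j]` is the coupling weight of the link from state node `j`
to state node `i` and `B[i, j]` is the weight of the link from candidate
control `j` to state `i`.  Each state node listens to at most one
control, but one control may feed several states.  The question this
package answers is combinatorial: **what is the smallest subset of the
candidate controls that leaves the network fully controllable**, i.e.
able to be steered between arbitrary states in finite time?

Selecting controls is encoded as a binary diagonal matrix
$D = \mathrm{diag}(d_1,\dots,d_P)$; the index matrix $M$ extracts the
nonzero columns of $D$, so the reduced input matrix is $B^* = BDM$
([apply_scheme()]).  Full controllability is tested with the
Popov-Belevitch-Hautus (PBH) rank condition: the pair $(A, B^*)$ is
controllable iff

$$\mathrm{rank}\,[\lambda I_N - A \mid B^*] = N$$

for every distinct eigenvalue $\lambda$ of $A$.  Unlike structural
controllability (which assumes free generic weights), the PBH test is
*exact*: it respects the given weights, self-loops, bidirectional links
and undirected structure.

## Penalised fitness

The selection problem is

$$\min_D \textstyle\sum_j d_j \quad \text{s.t. the PBH condition holds},$$

relaxed into an unconstrained objective by a quadratic rank-deficiency
penalty.  Writing $def_i(D) = N - \mathrm{rank}[\lambda_i I - A \mid B^*]$
over the `l` distinct eigenvalues,

$$f(D) = \sum_j d_j + \sum_{i=1}^{l} \sigma_i \, def_i(D)^2,
  \qquad \sigma_i = 10P\,c^{\,i-1}.$$

With $\sigma_1 = 10P$ any single unit deficiency costs more than
selecting every control, so $f(D) \le P$ iff $D$ is feasible; the
default multiplier is $c = 1$ (all coefficients equal, which makes their
assignment order irrelevant); $c > 1$ gives the strictly increasing
variant ([penalty_schedule()]).

## The optimiser

[paqga()] is a quantum-inspired genetic algorithm.  Each of `m = 15`
chromosomes carries two amplitude chains $(\alpha_k, \beta_k)$ of length
`P` with $\alpha_k^2 + \beta_k^2 = 1$, so a generation proposes `2m = 30`
binary individuals.  Per generation:

1. **Observation** — gene `k` collapses to 1 with probability
   $\beta_k^2$ ([observe_chain()]).
2. **Adaptive crossover** — individual `i` takes each gene from the
   incumbent `D_best` with probability
   $p_c(i) = (m/Q)\,p_{c0}\,e^{-(f_{max}-f_i)/(f_{max}-f_{min})}$,
   where `Q` (clamped to at least 1) counts current individuals fitter
   than the incumbent; worse individuals are pulled harder towards the
   incumbent ([crossover_probability()], [crossover_bits()]).
3. **Evaluation and incumbent update** — only a *strictly* fitter scheme
   replaces `D_best`.  Since the search starts at the all-selected
   scheme with $f = P$, every later incumbent satisfies $f < P$ and is
   therefore feasible: the incumbent's penalty is identically zero
   throughout the run, which [run_convergence()] asserts.
4. **Q-gate rotation** — each chain rotates towards the fitter of
   (candidate bit, incumbent bit) with magnitude
   $(f_c/f_{best}) \cdot 0.03\pi$ (or $0.01\pi$ when the candidate is
   fitter), signs from the adaptive lookup rules
   ([rotation_angle()], [qgate_rotate()]).
5. **Catastrophe** — after `patience` generations without improvement
   the incumbent's bits are frozen into one chromosome and all other
   amplitudes reset to $1/\sqrt2$ ([catastrophe()]).

### Interpretation choices

Several points of the operator definitions are genuinely open design
choices, which this implementation resolves as follows (each choice
was settled by checking internal consistency and measured convergence
on generated ensembles):

* **Observation semantics.** $\beta^2$ is the probability of observing
  bit 1, matching the amplitude semantics of the qubit superposition
  and the direction of the rotation sign table.  (The alternative
  $\alpha^2$ reading makes every tabulated rotation push probability
  mass *away* from the fitter bit; measured on 100-node ensembles it
  converges strictly worse.)
* **Rotation magnitude.** The tabulated factor $f_c/f_{best}$ can exceed
  50 when $f_c$ carries a penalty term, which would rotate an amplitude
  far past the pole; the magnitude is capped at $\pi/2$.
* **Amplitude floor.** After every rotation each amplitude magnitude is
  kept at or above 0.1 (so every gene retains at least a 1% chance of
  flipping).  This is the standard quantum-evolutionary guard against
  premature convergence; without it a gene saturated at a pole can never
  be reconsidered and the late pruning phase stalls — even a complete
  weighted digraph, whose true minimum is one controller on every
  instance, then terminates at two on some seeds.
* **Catastrophe patience.** The trigger ("several successive
  generations") defaults to 10.  Measured on ER ensembles
  (3 instances x 3 seeds), patience 5 / 10 / 20 give mean minima
  10.7 / 9.0 / 8.9: short patience keeps resetting the asymmetric
  amplitude saturation that makes pruning proposals productive.
* **Chromosome length** is `P` (genes index candidate controls); all
  benchmark ensembles here use `N = P`.
* **Q = 0 clamp.** When no individual beats the incumbent the crossover
  scaling `m/Q` is undefined; `Q` is clamped to 1.
* **Parallelism.** Fitness evaluations are pure functions of the bit
  pattern; `workers > 1` forks them with a fixed reduction order, so
  the result is bit-identical for any width.

### What the optimiser achieves at the default budget

At the default settings (population 30, 100 generations) the search
matches the exhaustive oracle on essentially every small instance
(`N = P = 10`: 20/20 in the shipped tests) and finds the single
controller of complete networks on every seed tried.  On sparse 100-node
ensembles the best-fitness trace is typically *still descending* at
generation 100 (about one control shed per five generations), so the
reported `n_cm` there sits above the structural maximum-matching
benchmark — a budget artefact, not a floor.  Users who want tighter
minima on such instances should raise `maxgen`; the per-generation cost
is small because the PBH evaluation is cached (below).

## Numerical design

**Rank tests.**  All ranks are SVD-based with the standard threshold
$\sigma_k > tol \cdot \max(\mathrm{dim}) \cdot \sigma_{max}$ at machine
epsilon scale (`tol_rank`), and eigenvalues are merged when closer than
`tol_group = 1e-8` in modulus ([distinct_eigenvalues()]).

**The defective-zero candidate.**  Sparse digraphs contain nilpotent
chain structure, whose zero eigenvalue is defective; floating-point
eigensolvers scatter it to $O(\varepsilon^{1/k})$, far beyond any
reasonable clustering tolerance.  Testing only the scattered values
over-reports controllability (the scattered pseudo-eigenvectors mix the
true null directions, so one input appears to cover several of them).
Whenever `A` is numerically rank deficient and no candidate is already
near zero, an explicit $\lambda = 0$ candidate is appended; it carries
the exact left null space and restores the missed deficiencies.  The
candidate count can therefore reach `N + 1` on nilpotent inputs.  The
equivalence "zero penalty iff Kalman-rank controllable" is tested on
sparse random instances (where defective chains are common) against an
independent QR-based Kalman oracle.  Exactly repeated *nonzero*
eigenvalues of unweighted graphs can still scatter undetected; the
package targets weighted networks, where such coincidences have measure
zero.

**Cached evaluation.**  [pbh_evaluator()] precomputes, per candidate
eigenvalue, the geometric multiplicity `g` and the projection
$C_\lambda = W_\lambda^H B$ of the candidate inputs onto the left null
space of $\lambda I - A$.  A scheme's deficiency at $\lambda$ is then
`g - rank` of the selected columns of $C_\lambda$ — for the typical
`g = 1` a constant-time coverage test — so the optimiser's inner loop
costs microseconds instead of an $O((N+P)^3)$ SVD per eigenvalue.
Simple well-separated eigenvalues take their left eigenvector from one
`eigen(t(A))` call guarded by a residual check; clusters and failed
checks fall back to a full SVD.  Fitness values are memoised by bit
pattern.  The cached path is tested for exact agreement with the direct
PBH computation.

## Baselines

* [mm_driver_count()] — structural controllability: drivers are the
  unmatched nodes of a maximum matching on the bipartite out/in-copy
  graph (self-loops are legitimate matching edges), floored at one
  driver.  The matching itself is igraph's; an independent
  augmenting-path matcher serves as test oracle.
* [mmt_driver_count()] — maximum geometric multiplicity
  $\max_\lambda (N - \mathrm{rank}(\lambda I - A))$, sharing the rank
  and clustering tolerances above.
* [brute_force_min_controls()] — exhaustive enumeration by increasing
  cardinality, the ground truth for `P <= 15`.

On directed networks with i.i.d. continuous weights and one input per
state these three agree with each other and with the optimiser on
essentially all small instances; exact agreement can fail on
measure-zero weight coincidences and on structures where the fixed
control attachment constrains the selection.

## Generated ensembles

All generators draw arc weights i.i.d. uniform(0, 1), reject self-loops
and duplicate arcs, and are bit-reproducible from their seed.

* **Degree convention.**  The arc count is $L = N\langle k\rangle$ under
  the default `degree_convention = "out"` ($\langle k\rangle$ = mean
  out-degree = mean in-degree) or $L = N\langle k\rangle/2$ under
  `"total"`.  Benchmark tables in this literature rarely state the convention;
  the default was calibrated once against the reference value for the
  100-node ER benchmark condition (the `"out"` reading lands within a
  few controls of it, the `"total"` reading is off by a factor of four)
  and is exposed as a switch.
* **ER** ([gen_er()]): `L` distinct arcs uniform over ordered pairs.
* **Scale-free** ([gen_sf()]): static-model sampling — both endpoints
  drawn with probability $\propto i^{-\xi}$ over node ranks,
  $\xi = 1/(\gamma - 1)$, duplicates rejected.  The fitted tail exponent
  tracks $\gamma$ at scale (tested at `N = 3000`).
* **Small-world** ([gen_sw()]): Newman-Watts construction — a ring
  lattice of `sw_base` nearest neighbours plus uniformly random shortcut
  arcs up to `L`.  Each lattice edge is oriented by a fair coin by
  default: a purely clockwise ring admits a perfect matching and makes
  every instance controllable from a single node, which would make the
  ensemble trivial as a controllability benchmark; the clockwise variant
  remains available (`ring_orientation = "clockwise"`).
* **Regular / complete** ([gen_regular()], [gen_complete()]): superposed
  random cycles (in-degree = out-degree = k/2), and the full off-diagonal
  arc set.
* **Control attachment** ([attach_controls()]): every state node gets
  exactly one incoming control link with uniform(0, 1) weight.  When
  `P = N` the default assignment is a uniformly random *bijection*, so
  `B` is invertible and the fully wired network is always controllable —
  the precondition of the optimiser's initial feasibility argument.
  Independent uniform assignment (`"uniform"`) is available but lets two
  states share a control; two otherwise indistinguishable states (e.g.
  both of in-degree zero) sharing one control make even the all-selected
  scheme infeasible, and the optimiser then aborts with a diagnostic by
  design.

**What the generators do not emulate.**  Real networks have degree
correlations, communities, reciprocity and heavy-tailed weights that
these null models lack, and real interaction strengths are rarely
uniform(0, 1).  Passing ensemble tests therefore validates the
machinery and its scaling behaviour, not any claim about a particular
empirical network; real networks should be loaded from edge-list or
Pajek files ([read_network()]) and analysed directly.

## Topology statistics

[degree_heterogeneity()] is the RMS spread of the (total) degree
sequence; [clustering_coefficient()] is the mean local clustering of
the undirected simple projection (nodes of degree < 2 contribute zero,
self-loops and weights ignored — the definition is undirected, so the
directed state graph is projected).  [run_topology_sweep()] relates the
minimum control density to $\langle k\rangle$, $\gamma$, H and C via
rank-correlation signs rather than point values, since all such ensemble
results are stochastic: denser and more clustered networks need fewer
controls, more heterogeneous ones need more.

## Problem sizes in the shipped tests

The test suite exercises the full pipeline at `N = P = 100` (three
ensembles), benchmark means at `N = P` of 100 and 200 over 10 seeded
replicates, and oracle comparisons at `N = P = 10` over 20 seeds; the
topology sweeps in the unit tests run at `N = 30` with the structural
method so that the whole suite completes in a few minutes.  Larger
sweeps (e.g. the 500-node grids) use the same entry points with larger
`N` and more replicates.

## Known limitations

* The optimiser is stochastic and anytime: at the default 100
  generation budget it typically terminates above the structural
  benchmark on sparse 100+-node instances (see above).
* Exactly repeated nonzero eigenvalues (unweighted, highly symmetric
  inputs) may evade the defective-zero guard.
* The catastrophe/crossover loop assumes `N = P`-scale chromosomes;
  very large `P` with tiny populations has not been tuned.
* Time-varying topologies and control-energy constraints are out of
  scope.
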