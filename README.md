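# netctrl

Minimum control-node selection for the **exact controllability** of
directed weighted networks.

## The problem

A network of `N` dynamical (state) nodes with `P` candidate external
inputs (control nodes) follows linear time-invariant dynamics

    ẋ = A x + B u

with `A[i, j]` the weight of the link from state `j` to state `i` and
`B[i, j]` the weight of the link from control `u_j` to state `x_i` (each
state listens to at most one control).  Selecting a subset of controls is
a binary diagonal matrix `D`; the reduced input matrix is `B* = B D M`.
The network is *fully controllable* under the selection iff the
Popov–Belevitch–Hautus (PBH) condition

    rank[λI − A | B*] = N    for every distinct eigenvalue λ of A

holds.  Unlike structural controllability, the PBH test is exact: it
respects actual weights, self-loops, bidirectional pairs and undirected
structure.  `netctrl` finds a minimum selection by minimising the
penalised fitness

    f(D) = Σ d_j + Σ_i σ_i · (N − rank[λ_i I − A | B*])²,   σ_i = 10P·c^(i−1)

with a quantum-inspired genetic algorithm: qubit chromosomes (two
amplitude chains per chromosome, observed into binary schemes), adaptive
crossover towards the incumbent, adaptive Q-gate rotation, and a
population catastrophe after stagnation.  Because the search starts from
the all-selected scheme and only strictly fitter schemes replace the
incumbent, the incumbent stays feasible (zero penalty) at every
generation.

The package is aimed at network scientists studying controllability of
weighted directed networks — food webs, circuits, citation and social
graphs, regulatory networks — and ships the standard baselines
(maximum-matching structural drivers, maximum eigenvalue multiplicity,
exhaustive oracle), generators for ER / static-model scale-free /
Newman–Watts small-world / regular / complete ensembles with candidate
control attachment, topology statistics (degree heterogeneity H,
clustering C), and scripted benchmark and sweep experiments.

## Worked example

```r
library(netctrl)

net <- gen_er(100, 100, 4, seed = 1)   # ER digraph, N = P = 100, <k> = 4
net
#> control_network: 100 state nodes, 100 candidate control nodes
#>   state links:   400 (incl. 0 self-loops)
#>   control links: 100

run <- paqga(net, paqga_params(seed = 1))
run
#> paqga_run: n_cm = 3 (density 0.0300), converged at generation 64/100

mm_driver_count(net)      # structural (maximum matching) benchmark
#> driver_result: n_d = 2 (density 0.0200)
mmt_driver_count(net$A)   # maximum eigenvalue multiplicity
#> driver_result: n_d = 2 (density 0.0200)
```

Three of the hundred candidate controls suffice for this instance
(`run$scheme$d` holds the selection); the per-generation history
(`run$history`: best and mean fitness, incumbent penalty — identically
zero — and selected count) shows the descent from the all-selected
scheme.  The structural benchmark for the same instance is two drivers:
the optimiser is stochastic and anytime, and at the default budget of
100 generations it can terminate slightly above the benchmark on sparse
instances (raise `maxgen` for tighter minima).  On small problems it
matches the exhaustive oracle: see `brute_force_min_controls()`.

Networks travel as tagged weighted edge lists (TSV) or Pajek `.net`
files via `read_network()` / `write_network()`.  A command-line front
end over the same functions is installed at
`system.file("cli", "paqga.R", package = "netctrl")` with `generate`,
`optimize`, `baseline` and `stats` subcommands.

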