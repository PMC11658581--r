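---
title: "Lesion connectomics: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lesion connectomics: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`lesionconn` quantifies what a focal brain lesion does to a weighted,
directed, bilateral connectome: which structural properties change and by how
much relative to chance, which intact regions are most exposed to the lesion,
and how signal dynamics in remote regions are predicted to change. This
vignette documents the models, the tunable parameters, the numerical choices
and the points where the design was genuinely open.

## The data model

A connectome is a simple directed graph over named regions. Region identity
is the abbreviation string; bilateral homologs are paired by base
abbreviation with explicit `_L` / `_R` suffixes, because lesions in
experimental stroke are hemisphere-specific. Every connection carries an
ordinal weight category (light / moderate / strong), a numeric weight mapped
from it (default `light = 1, moderate = 2, strong = 3`; collation studies
rarely publish a numeric scale, so the mapping is explicit configuration and
every downstream computation uses the numeric value), and an observation
count — the number of independent tract-tracing reports supporting the
connection, which later serves as a reliability filter. Self-loops are
rejected by default since all the graph metrics assume simple digraphs.

## The synthetic generator

Whole-brain tract-tracing collations are typically not redistributable, so
the generator produces connectomes with the statistical structure the
analysis relies on: a bilateral region set, a fixed edge count, a reciprocity
target (edges whose reverse exists), hub-skewed degree propensities,
hemispheric mirroring and a controllable fraction of cross-hemisphere edges.
Defaults emulate the scale of a rat whole-brain collation: 540 regions and
13183 directed links. Edges are placed in units (a reciprocal pair or a
one-way edge, optionally together with its mirrored copy), reciprocal pairs
first until the target count is reached, so the realized edge count is exact
and the realized reciprocity is off by at most a couple of edges.

Values the source material does not pin down were fixed once at
field-plausible levels and not revisited: reciprocity target 0.45,
weight-category probabilities (0.5, 0.3, 0.2), observation distribution
(0.6, 0.25, 0.15 with a geometric tail above 3), mirror probability 0.7,
cross-hemisphere fraction 0.1, hub exponent 0.8. What the generator does
*not* emulate: the real connectome's modular partition, its exact degree
sequence, distance-dependent wiring costs, and any weight–topology coupling.
Passing tests on synthetic data therefore demonstrate correctness of the
computations and directional robustness of the dynamic effects, not
quantitative reproduction of any empirical connectome's numbers.

## Differential connectomics

`apply_lesion()` removes the lesioned regions and every incident edge;
`differential_report()` compares control and lesioned connectomes on region,
link and reciprocal-edge counts, average clustering, transitivity, average
path length and small-worldness, reporting relative changes in percent
(reductions and increases relative to the control value). Metrics undefined
on a degenerate lesioned graph are reported as `NA` rather than raised as
errors, so batch comparisons over many lesion models do not abort.

Path lengths are unweighted hop counts; unreachable ordered pairs are
excluded from the mean but counted and reported, making disconnection
visible instead of silently absorbed into an infinity convention. Clustering
and transitivity are computed on the underlying undirected simple graph, the
standard triplet-based reading; directed clustering variants are out of
scope.

## Local importance and the MCRD filter

`local_parameters()` computes 14 per-region parameters (degrees, Katz
status, local clustering, leverage, locality, local efficiency, betweenness,
eigenvector centrality, flow coefficient, a Monte-Carlo Shapley rating of
the neighbourhood-coverage game, and harmonic closeness in both directions).
Each parameter declares its orientation (`higher_better`) as registry
metadata rather than a hidden assumption; `average_rank()` ranks every
parameter (1 = most important, ties averaged) and averages ranks per region,
so a low average rank means high network importance. The registry is
extensible; the full battery of several dozen parameters used in some
connectome platforms is deliberately not reproduced — orientation and
definition of many exotic parameters are not published, and the ranking
machinery is independent of the registry size.

The MCRD (multidimensional circular relationship diagram) filter reduces the
lesion's partner table with three thresholds: `reli` (minimum observation
count, default 2 — connections reported at least twice are deemed reliable),
`muli` (minimum number of distinct lesioned regions a partner touches,
default 4), and `neti` (the partner must rank within the best `neti`
importance quantile, default 0.2, i.e. the top 20% of regions by average
rank; boundary ties are kept). Direction is classified relative to the
lesioned region, reciprocal when both directions exist; a reciprocal pair
counts once for `muli`. Only direct edges count — hierarchical
region-to-subregion relations are upstream preprocessing, not part of the
data model.

## Null models and calibration

Two ensembles: Erdős–Rényi G(n,m) (matched edge count, the appropriate
density-matched null) and degree-preserving directed rewiring (the stricter
null; 10 swap attempts per edge by default, a common mixing heuristic).
Small-worldness uses `S = (T/⟨T_rand⟩)/(L/⟨L_rand⟩)` against a configurable
ensemble, rewiring by default.

`permutation_test()` compares the observed lesion-induced change with
size-matched random lesions, either of the control network itself
(`null_mode = "lesion"`) or of freshly drawn null networks
(`null_mode = "graph"`); the sources describing this kind of analysis do not
fix which is meant, so both are provided and neither is presented as
canonical. The two-sided p-value uses the add-one estimator
`(1 + #{|Δ*| ≥ |Δ_obs|})/(1 + n_perm)`, the standard finite-sample
correction. A caveat the test suite makes explicit: p-values are uniform
under the null only for effectively continuous metrics. Integer count
metrics (e.g. reciprocal edges) tie heavily, and ties make the estimator
conservative — correct but not uniform.

## Similarity indices

The connectivity matching index of regions i and j is the normalized overlap
of their connections over all third regions k:

$$\mathrm{CMI}_{ij} = \frac{\sum_{k \ne i,j} A_{ik}A_{jk} + A_{ki}A_{kj}}
{\sum_{k \ne i,j} \max(A_{ik},A_{jk}) + \max(A_{ki},A_{kj})}$$

On the default binary adjacency this reduces to the shared/union set overlap
of in- and out-neighbourhoods (1 = identical connectivity), which is also
the independent oracle the tests check against; a weighted variant keeps the
numeric weights inside the products and maxima. Both nodes isolated gives a
zero denominator, returned as 0 with a `defined = FALSE` flag.

GTOM (generalized topological overlap) counts shared m-step neighbours on
the symmetrized graph, normalized by
`min(|N_i|,|N_j|) + 1 − a_ij`. One property worth knowing: entries are *not*
strictly monotone in m under this normalization (numerator and denominator
both grow; occasional dips of order 0.02 occur), though overlap saturates
toward 1 on a connected component as m reaches the diameter.

The ranked pair table joins, per (region, lesioned region) pair, the
directed graph distances, the Euclidean distance, CMI and a model
coactivation value, with per-column tie-averaged ranks (1 = best); resorting
it by any column reproduces the usual similarity screening workflow. Mean
distances are reported over finite entries only.

## Node dynamics

All three node models couple through the transposed weighted adjacency
matrix (presynaptic drive), row-normalized by in-strength so the coupling
term is a weighted mean of inputs — unnormalized coupling diverges at
connectome scale where in-degrees span two orders of magnitude. The
normalization is configurable (`none`, `instrength`, `spectral`).

**FitzHugh–Nagumo.** One unit per region:
`τ_x dx/dt = γx − x³/3 − y + k·D·φf(x) + σν_x`,
`τ_y dy/dt = ε(βy + s·x + α) + σν_y`, with logistic `f`, Gaussian noise and
Euler–Maruyama integration. Defaults: `α = 0, β = −0.064, γ = 1, φ = 1,
ε = 2, k = 1, σ = 0.25, τ = 1`, initial states uniform on [−2, 2], 500
recorded steps of 1 ms. Two deliberate choices:

* *Recovery sign `s`.* With `s = −1` the recovery variable feeds back
  positively (det J < 0 at every equilibrium), making each node bistable
  with rest states near x = ±7 — it can never behave as the relaxation
  oscillator this model family is used as, and σ = 0.25 noise cannot cross
  the wells. The default is therefore the classic negative-feedback `s = +1`
  (x drives y up, y pulls x down), which oscillates; `s = −1` remains
  available.
* *Substeps.* A plain 1 ms Euler step is unstable for the cubic once
  |x| exceeds ≈ 4.5 (|1 − x²|·h > 2), which the recovery scaling makes
  routine (y ≈ x/|β| ≈ 15x). Each recorded step is therefore integrated in
  50 Euler–Maruyama substeps (h = 0.02 ms, noise scaled by √h).

`ε` and `φ` are exposed as multipliers of the recovery right-hand side and
of `f` respectively — they are declared scaling factors whose placement in
the printed equations is not explicit, so their position here is a
documented interpretation.

**Wilson–Cowan.** Per-region excitatory/inhibitory rate pair with logistic
activation; network coupling (not part of the textbook two-population
equations) enters the excitatory input as `k_net·(D x)` with the same `D` as
the FHN model, so the three models are comparable. Defaults
(`w_xx = 16, w_yx = 12, w_xy = 15, w_yy = 3`, negative external drives
standing in for activation thresholds) put an isolated pair in an
oscillatory regime; activity stays in (0, 1).

**Mimura–Murray.** Activator-inhibitor kinetics
`f(P,Q) = ((a + bP − P²)/c − Q)P`, `g(P,Q) = (P − (1 + dQ))Q` — the
textbook form of the model; printed reproductions of these equations are
frequently typographically corrupted, so the kinetics follow the canonical
source while the parameter values (`a = 13, b = 16, c = 9, d = 0.4,
D_P = 0.1, D_Q = 0.01`) are taken as printed. Diffusion runs on the graph
Laplacian `L[u]_i = Σ_j Ŵ_ij(u_j − u_i)` with `Ŵ` the symmetrized,
in-strength-normalized weights (a directed in-Laplacian is a configuration
away). The uniform kinetic equilibrium (P ≈ 3.537, Q ≈ 6.343 at the default
parameters, `mm_equilibrium()`) is an exact steady state of the network
system and the basis of one analytic test. At the default parameters the
equilibrium is an unstable spiral, so every node oscillates; initial states
are uniform (P = 6, Q = 12), symmetry-broken by the stimulus. "Stimulation"
of a named region defaults to a +10% multiplicative perturbation of its
initial activator value, configurable to a sustained additive drive. The
default solver is adaptive Dormand–Prince (rtol = atol = 1e-8); an Euler
path with 100 substeps per unit step exists for strict step-by-step
comparability.

**Spikes, coactivation, synchrony.** A region "spikes" when its trace
exceeds its own temporal mean by z standard deviations (z = 1). Relative
coactivation normalizes joint activity by the union of active samples,
`Co_ij = Σ_t c_i c_j / Σ_t max(c_i, c_j)` — two regions with identical spike
trains score 1 regardless of firing density — with a per-time variant
dividing by the sample count. The sum in the union normalization runs over
time, matching the numerator. The Kuramoto order parameter uses phases from
the FFT-based analytic signal of each mean-subtracted trace;
`R(t) = |mean_j e^{iθ_j}|`, time-averaged for a scalar summary; whether to
evaluate it over all regions or a subset of interest (e.g. the hippocampal
CA1/DG pair) is an explicit argument, since either convention is defensible.

## LIF populations

`build_population_network()` places `neurons_per_region` leaky
integrate-and-fire neurons per region (80% excitatory), connects neuron
pairs within a region with probability `p_connect_intra`, and projects
excitatory neurons between regions with probability proportional to the
connectome edge weight; inhibitory neurons stay local, reflecting that
long-range projections are predominantly excitatory. Membrane dynamics
follow `dV/dt = (I − V/R − (V − V_rest)/R_leak)/C` with threshold, reset and
a 2 ms absolute refractory period; synapses are delta increments delivered
after a 1 ms delay (the simplest standard choice; synapse kinetics are not
part of the model's definition); the stimulated region's excitatory neurons
receive Poisson drive (default 10 kHz). The electrical constants are pure
configuration at textbook values (τ_m = 10 ms). `isi_stats()` computes per
neuron the coefficient of variation of interspike intervals (≥ 3 spikes to
qualify) and per region `CE_isi`, the mean CV — 0 for clockwork firing,
→ 1 for Poisson firing, which is exactly the pair of analytic cases the
tests pin down.

## The packaged lesion experiments

`mm_hub_lesion_experiment()` and `lif_hub_lesion_experiment()` implement the
paired in-silico design used by the acceptance checks: generate a synthetic
connectome from a seed, remove its top-degree hubs, stimulate the strongest
*surviving* region identically in both runs, and compare coherence
(coactivation, Kuramoto) or spiking regularity (`CE_isi` over remote regions
active in both runs). The expected directions — hub lesions reduce dynamic
coherence and increase interspike variability — hold as a majority over
seeds, not deterministically per seed; the tests therefore use sign tests
across 12 seeds. The LIF effect has a mechanistic reading: removing hubs
withdraws recurrent drive, moving remote neurons from a mean-driven
(regular) to a fluctuation-driven (irregular) regime.

## Problem sizes and runtimes

The test suite and the acceptance script run entirely on synthetic data:
oracle comparisons use 200 random digraphs per metric at 8–50 nodes
(exhaustive knotty-centrality enumeration at 8 nodes), calibration uses 500
permutation-test replicates at n_perm = 199 on a 30-node graph, and the
dynamics experiments use 60-region (Mimura–Murray) and 24-region × 20-neuron
(LIF) networks over 10–12 seeds — sizes chosen so a full run completes in
minutes while keeping every statistical check adequately powered. The
differential-connectomics path is additionally exercised at the full
540-region / 13183-link scale.

## Known limitations

* Synthetic connectomes do not reproduce empirical modularity, spatial
  embedding or weight–topology coupling; quantitative metric values on them
  are not comparable to any real connectome's.
* Greedy knotty-centrality above the exhaustive cutoff is a heuristic; it
  can undershoot the optimal subset (tests bound it by the exhaustive
  optimum on small graphs).
* The Shapley rating is a Monte-Carlo estimate; its standard error scales
  as n_perm^(-1/2) (the coverage game has a closed form used as a test
  oracle, but the Monte-Carlo path generalizes to other games).
* Eigenvector centrality on disconnected graphs assigns (near-)zero scores
  to minor components rather than flagging them.
* Dynamic-model time is in model units; no attempt is made to fit
  physiological frequencies.
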