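---
title: "Testing trait-dependent diversification with traitsse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing trait-dependent diversification with traitsse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitsse)
```

## The problem

Clades such as the damselfishes show strongly uneven distributions of
discrete ecological characters — dietary ecotype (benthic, intermediate,
pelagic) and body-size class (small, medium, large) — across their
time-calibrated phylogeny. Two very different processes can produce such
unevenness: asymmetric *transition* rates between states, or differences in
*diversification* (speciation minus extinction) among lineages carrying the
states. Telling these apart requires jointly modelling character change and
lineage birth/death. `traitsse` implements the full analysis chain for this
question: trait discretization, Markov models of character change with
ancestral reconstruction and stochastic mapping, phylogenetic-signal
statistics, tree-shape diagnostics, and a multistate hidden-state
speciation–extinction (SSE) model set compared by Akaike weights.

Everything operates on `ape` `"phylo"` trees, and a simulation module
generates trees and traits with the exact statistical structure the methods
assume, so every stage is testable without any external data.

## Trait coding

Continuous body sizes are binned by **gap coding**: with `k` classes the
`k − 1` boundaries are placed in the `k − 1` widest gaps between consecutive
distinct sorted values, each boundary reported as the midpoint of its gap.
Ties in gap width are resolved toward the smaller values; both conventions
are deterministic and documented because the choice of representative point
inside a gap is arbitrary (only class membership matters downstream).

```{r}
sizes <- c(4.5, 6.1, 8.8, 10.5, 12.0, 14.1, 14.4, 22.0, 45.0)
gap_code(sizes, k = 3)
```

For the SSE models a three-state character is re-expressed as two binary
characters: the extremes become `01` (small / benthic) and `10`
(large / pelagic), the intermediate `11`, and `00` is reserved for the
never-observed combination. A single event flips one binary character, so
direct `01 ↔ 10` jumps are excluded by construction — the "constrained"
transition structure in which evolution between extremes passes through the
intermediate state. The unobserved `00` code is excluded from the state
space entirely rather than carried as a dead state; this keeps every model
smaller and changes nothing observable.

```{r}
encode_binary_pair(c(sp1 = "S", sp2 = "M", sp3 = "L"))
```

## Markov models of discrete characters

`build_rate_matrix()` builds equal-rates (ER), symmetric (SYM) and
all-rates-different (ARD) structures, each optionally constrained
(extreme↔extreme cells structurally zero; 4 free rates for constrained ARD
on three states). The likelihood is Felsenstein pruning with per-branch
`exp(Qt)` computed by scaling-and-squaring — deliberately not by
eigendecomposition, because masked generators can be defective. Missing tip
states are fully ambiguous (all-ones partials). Three root treatments are
available: `"fitzjohn"` (states weighted by their share of the root
likelihood; the default, and the same convention the SSE module uses),
`"uniform"` and `"stationary"`.

Rates are fitted by box-constrained quasi-Newton search in log-rate space
(bounds `1e-9`–`1e3` per my) from multiple starts; `marginal_asr()` gives
per-node marginal state probabilities via the up/down re-rooting pass; and
`sample_stochastic_maps()` draws complete character histories: node states
by backward pruning + forward sampling, within-branch paths by
**uniformization**, which samples the number of (possibly virtual) jumps
from its exact conditional distribution and so remains correct when the
endpoints differ and rates are small — the regime where naive rejection
sampling stalls. Transition counts are reported per map (integers), as
means, and as per-cell modal counts, since a published single-integer count
may summarize any of these.

## Phylogenetic signal and trait association

* **Blomberg's K** compares the observed ratio of ordinary to
  phylogenetically corrected mean squared error with its Brownian-motion
  expectation on the same tree; K = 1 matches Brownian motion. Significance
  comes from tip-label randomizations of the phylogenetically corrected
  error variance (the standard permutation target), with a `+1/(N+1)`
  continuity correction.
* **Pagel's λ (continuous)** maximizes a Gaussian likelihood whose
  covariance has its off-diagonal entries scaled by λ ∈ [0, 1], profiling
  the root mean and rate analytically; the test against λ = 0 is a 1-df
  likelihood-ratio test. The χ²(1) reference ignores the boundary at 0;
  a halved (conservative) version is available by flag.
* **Pagel's λ (discrete)** rescales internal branches by λ while preserving
  tip depths, refits the Mk model at each λ, and compares against the
  λ = 0 star-tree collapse. The Mk structure inside the fit defaults to ER
  (the simplest structure; ARD is available) — the published analyses do
  not state which structure they used inside the discrete-λ fit.
* **Phylogenetic ANOVA** computes the classical one-way F on tip data and
  calibrates it against F values from Brownian-motion simulations on the
  tree, with the Brownian rate set to its phylogenetic ML estimate from the
  observed response (an REML variant is a one-line change; ML is the
  default for consistency with the λ machinery).

Published p-values of this kind depend on the original data matrix and are
not reproduction targets; what the test suite checks instead are the
statistics' *calibration properties*: K centres on 1 under Brownian motion,
λ recovers its generating value, and the ANOVA holds its nominal type-I
error under the null.

## Tree-shape diagnostics

`ltt_curve()` returns the lineage-through-time step function (time negative
before present). `gamma_statistic()` standardizes the internode intervals:
with `g_j` the duration spent with `j` lineages and
`T_k = Σ_{j≤k} j·g_j`,

γ = [ mean(T_2..T_{n−1}) − T_n/2 ] / [ T_n √(1/(12(n−2))) ],

asymptotically standard normal under constant-rate pure birth.
`mccr_test()` corrects the one-tailed slowdown test for incomplete
sampling: each null replicate grows a constant-rate tree to the full
richness `N` and prunes it uniformly to the observed `n`, reproducing the
spurious negative shift incomplete sampling induces. The null is pure birth
by default (the test's classical form); a birth–death null with chosen
extinction fraction is exposed as an option. With `N = n` the procedure
reduces exactly to the plain test at the same seed.

## The SSE model set

Each composite state (observed code × hidden class) carries a turnover
`τ = λ + μ` and extinction fraction `ε = μ/λ` — the reparameterization that
behaves better than raw (λ, μ) when the two are correlated. Along each
branch, backward in time, the engine integrates the standard coupled system
for the extinction probability `E_i(t)` and data likelihood `D_i(t)`:

dE_i/dt = μ_i − (λ_i + μ_i + Σ_j q_ij) E_i + λ_i E_i² + Σ_j q_ij E_j

dD_i/dt = −(λ_i + μ_i + Σ_j q_ij) D_i + 2 λ_i E_i D_i + Σ_j q_ij D_j

with tips initialized at `D_i = ρ` for matching observed states and
`E_i = 1 − ρ` (per-observed-state sampling fractions), `D` multiplied by
`λ_i` across nodes, and the root combined with FitzJohn weights and
conditioned on the survival of both root lineages. Integration is an
adaptive Cash–Karp Runge–Kutta (absolute tolerance 1e-10, relative 1e-8,
in compiled code) with per-node rescaling of `D`, exact because the `D`
system is linear in `D`.

`build_model_set()` returns the eight models compared for each trait:

| model | diversification | hidden classes |
|---|---|---|
| "Dull" | one shared (τ, ε) | 1 |
| MuSSE | per observed state | 1 |
| MuHiSSE | per observed × hidden state | 2 |
| MuHiSSE Relaxed | as MuHiSSE, directional hidden rates | 2 |
| Large/Pelagic Absorbing | as MuHiSSE, no moves out of `10` | 2 |
| Small/Benthic Absorbing | as MuHiSSE, no moves out of `01` | 2 |
| CID2 | per hidden class only | 2 |
| CID3 | per hidden class only | 3 |

All share the constrained observed-transition structure (4 free observed
rates, shared across hidden classes), hidden-class moves change only the
hidden class (one shared rate; the "Relaxed" variant frees the second
direction — the minimal one-parameter relaxation), and no event changes
both characters at once. The CID (character-independent) models are the
proper null for state-dependent diversification: they absorb rate
heterogeneity into hidden classes unrelated to the focal trait. The
absorbing models keep their hidden class and zero only the observed
out-transition, so "being stuck" in a state remains compatible with
background rate variation. Exact free-parameter counts under this scheme
(Dull 6 … Relaxed 18) are one concrete choice from the family of
parameterizations consistent with the published model descriptions; the
patterns that matter for interpretation — the null is smallest, Relaxed =
MuHiSSE + 1, CID3 = CID2 + 2 — hold by construction, and the sharing maps
are fully user-configurable through `sse_spec()`.

Fitting (`fit_sse()`) maximizes over log-τ, log-ε and log-q with
box constraints (τ ∈ [1e-4, 10]/my, ε ∈ [1e-6, 3], q ∈ [1e-6, 1]/my) from
`n_starts` log-uniform random initializations plus one deterministic
heuristic start; the published analyses used 100 starts on a cluster, and
that remains available, but recovery experiments here plateau far earlier,
so the default is 25 and the tests use 1–3. `rank_models()` computes
ΔAIC and Akaike weights (AICc available), `marginal_reconstruction_sse()`
per-node composite-state marginals, and `model_average_rates()`
weight-averages net diversification, turnover and transition outflow over
models and states — a convex combination, so averaged rates always lie
within the contributing models' range. Sampling fractions default to the
published per-ecotype values (benthic 0.72, pelagic 0.68, intermediate
0.76), reused for the size classes since no size-specific fractions are
published; both are overridable.

## The simulators, and what passing tests do and do not show

`simulate_sse_tree()` is a forward Gillespie simulation from a crown of two
lineages: state-dependent speciation/extinction plus anagenetic change,
extinct lineages pruned, tips subsampled by their state's ρ, and the true
per-branch histories retained so transition counting can be validated
against the truth rather than against another inference. Tip-target runs
stop halfway into the waiting time after the target is reached (so terminal
branches are positive); trees outside a ±20% window of the expected sampled
tip count, or fully extinct, are rejected and retried within a bounded
budget — which mildly biases tail scenarios with extreme extinction, a
caveat documented here once. `simulate_mk_traits()` evolves characters by
exact waiting-time simulation; `simulate_continuous_traits()` draws from
the λ-scaled Brownian covariance.

The generators emulate exactly the processes the estimators assume
(homogeneous rates, ultrametric extant-only trees, uniform-by-state
sampling). Real damselfish data violate several of these — rate shifts
unrelated to the focal trait, non-uniform sampling, measurement error in
the trait matrix — so green tests certify the *machinery* (likelihoods
match oracles, estimators are calibrated under their own model), not the
biological conclusions on any empirical tree.

## Numerical choices and problem sizes

Matrix exponentials by scaling-and-squaring (Taylor core, norm-halving);
pruning partials renormalized per node; SSE `D` vectors renormalized per
node with accumulated log factors; optimizer convergence `factr = 1e8`;
ultrametricity tolerance 1e-6 relative, boundary inclusive; p-values always
carry the `(r+1)/(N+1)` correction. Degenerate inputs: a single observed
state warns and fits at the rate lower bound; zero-length branches are
valid (identity transition); a constant continuous trait is an error for K.

The shipped test-and-validation runs use these problem sizes, chosen to
exercise each property at the scale where it is informative while keeping
a complete run on one CPU comfortably under half an hour: oracle
equivalences on 2–6-tip trees (enumeration is exact there); K calibration
with 100 Brownian replicates on 128 tips; λ recovery with 20 replicates at
256 tips; ANOVA calibration with 400 null replicates of 500 simulations
each; MuSSE turnover-ordering recovery with 6 replicates at 300 tips; and
CID-versus-state-dependent model selection with 6 replicates per scenario
at 200 tips. The recovery experiments show their properties as majorities
at these replicate counts; pushing the replicate counts up (the package
functions take the counts as arguments) sharpens them toward the
frequencies reported for larger designs.

## Known limitations

Cladogenetic state change (ClaSSE/GeoSSE-style), time-varying rates,
Bayesian SSE, likelihood-surface support regions, and κ/δ branch
transforms are out of scope. The γ machinery assumes fully bifurcating
ultrametric trees. Discrete-λ and SSE fits assume ultrametry; fossil tips
are not supported. Model-set free-parameter counts are one defensible
parameterization, not a reproduction of an unpublished supplement.
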