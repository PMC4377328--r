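---
title: "Methods and design notes for degnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for degnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degnet)
```

`degnet` analyses the deregulation of a seed gene family — the
aminoacyl-tRNA synthetases (ARSs) and their AIMP scaffold partners — across
cancer transcriptomes and the protein–protein interaction (PPI) network.
This vignette records the model, its assumptions, the tunable parameters,
and the design decisions taken where the method left genuine latitude.

## Expressed-gene filtering

Microarray-style log2 intensity distributions are bimodal: a low mode of
probes without real signal and a high mode of expressed genes.
`fit_expression_mixture()` fits a two-component Gaussian mixture to the
pooled intensities of one dataset by expectation-maximization (5 random
restarts, log-likelihood tolerance 1e-8) and defines the expression
threshold as the intensity where the two *weighted* component densities are
equal, searched numerically strictly between the component means. With
unequal component variances this equation can have two roots in that
interval; the root closest to the midpoint of the means is taken, a
tie-break the method itself does not dictate. A fit whose means are closer
than 0.1 pooled standard deviations is rejected as "not separable" — this
is what happens on unimodal heavy-tailed data, where EM converges to a
scale mixture with coincident means. A gene is *expressed* when its maximum
intensity across samples is strictly greater than the threshold ("higher
than" is read as a strict inequality).

Inputs are assumed to be pre-normalized log2 intensities;
`quantile_normalize()` (via limma, ties averaged) is available and is
idempotent. Raw-array (CEL-level) processing is out of scope.

## The dual differential statistic and its empirical null

For each expressed gene, two statistics are computed between cancer and
normal samples: the pooled-variance Student *t* and the log2-median-ratio
(`lmr`, a difference of medians since values are already log2). The null
distribution of each statistic is estimated by permuting the sample labels
(`n_perm`, default 1000; at least 100, and fewer than the number of
distinct label assignments — tiny cohorts are refused with advice to use
exact enumeration) and pooling the permuted statistics *across genes* into
one null per dataset and statistic. Pooling across genes is a deliberate
choice — a per-gene null at 200 permutations would have a granularity of
only 1/200 — and it assumes the expressed genes share an exchangeable null
scale; gene-specific variance outliers are partially absorbed by the *t*
statistic's internal studentization.

The pooled draws are smoothed with a Gaussian kernel (Silverman's
rule-of-thumb bandwidth), whose cumulative distribution is evaluated in
closed form as the average of normal CDFs, so no grid interpolation is
involved. Two-tailed P values double the smaller tail,
P = min(1, 2·min(F, 1−F)), which remains valid for asymmetric nulls. All P
values are clamped to [1e-15, 1] so downstream inverse-normal conversions
never see 0; an infinite statistic (zero pooled variance with nonzero mean
difference) therefore maps to the floor, not to an error.

## Stouffer combination and the dependence caveat

`stouffer_combine()` converts each two-tailed P to a signed one-sided Z,
z = sign·Φ⁻¹(1 − p/2), averages by √k, and converts back; discordant
directions cancel. The same operation combines the two per-gene statistics
within a dataset and the per-dataset combined Ps into one representative P
per cancer type (signs from each dataset's mean-shift direction). The
representative log2-fold-change is the unweighted mean of per-dataset mean
differences.

One property deserves emphasis: the *t* and `lmr` statistics are computed
on the same samples and are strongly positively dependent (their null z
correlation is about 0.85 in the synthetic world). The plain Stouffer
denominator √2 assumes independence, so the combined P of the default
pipeline is **anticonservative** — on null data the empirical type-I error
at α = 0.05 is roughly 0.12–0.18, not 0.05. This is a property of the
method as published, and the default `identify_degs()` reproduces it
faithfully. For calibrated inference the package offers
`identify_degs(..., dependence_adjust = TRUE)`, which estimates the null
correlation ρ of the two statistics from paired label permutations and uses
the dependence-corrected denominator √(2 + 2ρ) (Strube's adjustment); the
test suite verifies that this restores the type-I error to within three
binomial standard errors of α. The adjustment is off by default because the
downstream score and module stages are defined relative to the original
calling behaviour.

## Network model and scores

The network model contains the seed genes present in the interactome plus
their first-neighbour cancer-associated genes (CAGs), with interactome
edges induced on that node set. Per cancer type, each node's representative
P becomes Z = Φ⁻¹(1 − p); negative Z (P > 0.5) is retained rather than
clamped, so consistently non-deregulated interactors pull a neighbour's
score down.

- *Deregulation score* of a node: per cancer type, the sum of Z over the
  node's direct interactors in the model (its own Z excluded — the score
  describes the neighbourhood, not the node); then the mean over types.
- *Co-association score* of an edge: the number of cancer types where both
  endpoints are DEGs divided by the number of types in scope.

Where a gene has no expression data in some cancer type, two denominator
conventions exist: `"measured"` (default) drops such types from the edge
denominator and averages node scores over types with any interactor data;
`"total"` uses the full type count, treating missing evidence as absence of
deregulation. The default reflects the view that an unmeasured type is not
evidence either way; it is a configuration choice, not a claim about the
original analysis, which had data for all 10 types.

## Random walk with restart and the module null

`rwr()` iterates p ← c·W·p + (1−c)·p₀ on the column-stochastic matrix W
built from co-association weights floored at `weight_floor` (default 0.01,
so zero-scored edges remain traversable), with uniform p₀ over all nodes.
The "transition rate of probability 0.75" is read as the continuation
probability c = 0.75 (restart 0.25); this reading is configurable via
`continue_prob`. Iteration stops when the L1 change drops below 1e-6
(configurable); the update conserves total probability at every step, the
residual contracts geometrically, and the fixed point equals the direct
linear solve (1−c)(I−cW)⁻¹p₀, which the test suite checks to 1e-8 on random
graphs.

Significance of a node's steady-state probability is assessed against
`n_rand` (default 1000) degree-preserving double-edge-swap randomizations
(10·|E| attempted swaps each; edge weights are randomly permuted onto the
rewired edges). Because walk mass correlates strongly with degree, nodes
are compared within degree-quintile strata by default (`stratify = FALSE`
pools globally); the choice of a stratified pooled null is a design
decision, not a documented property of the original procedure. Empirical
right-sided Ps use a plus-one pseudocount and are never zero. Key modules
are the connected components of {P < 0.05} that contain at least one seed
gene, sorted by size.

## Conserved motifs

Each species' PPI network is collapsed to ortholog groups; self-loops
created by many-to-one mapping and duplicate group edges are removed, and
unmapped proteins are dropped with a warning. Connected induced subgraphs
of size k are enumerated exactly (ESU algorithm). Three decisions shape the
conservation step:

- **k = 3 by default** (2–4 supported): exhibited conserved motifs in this
  problem domain are triads.
- **Motif identity is by group-id set plus edge pattern**, not by unlabeled
  isomorphism class: conservation means the *same ortholog groups*
  interacting the same way in several species. The isomorphism class
  ("path"/"triangle", degree sequence for k = 4) is reported as metadata.
- **Conservation is target-anchored**: a motif must be present in the
  target species (human) and at least `min_species − 1` others.

Conserved group motifs are expanded to every protein instantiation
(Cartesian product over group members in the target species) and kept only
if each motif edge exists in the real interactome and at least one member
is a seed gene. On small instances the whole pipeline is verified against a
brute-force oracle that enumerates protein k-subsets directly.

## The synthetic world

The generators state a fixed world rather than knobs tuned per test:

- **Cohorts**: gene baselines from a low (mean 4) or high (mean 10)
  component with unit-sd Gaussian noise on the log2 scale — matching the
  two-component structure the expressed filter assumes, with the expressed
  fraction 0.7; planted DEGs receive a ±2 log2-unit shift in cancer
  samples at 10+10 samples per class. These are conventional microarray
  abstractions (log2-normal noise, 2-fold-change effects).
- **Interactomes**: Erdős–Rényi background (mean degree 6 at 200 nodes)
  with a planted dense module (size 8, a clique by default) containing the
  seed genes; the catalog labels module plus a random 30% of the
  background as CAGs.
- **Species**: ortholog groups with 2 proteins each; planted triads
  instantiated as triangles in every species; independent background group
  edges at rate `edge_noise`.

What the generators do **not** emulate: probe-level effects, batch
structure, heavy-tailed intensity noise, and the scale-free degree
distribution of real interactomes. A green test therefore establishes
correctness of the algorithms on their stated model, not robustness to
real-data pathologies.

All generators are bit-reproducible from their seed, and `write_truth()`
manifests carry the full parameter set needed to regenerate the data.

## Numerical choices

- P clamp 1e-15 everywhere a P feeds an inverse-normal transform.
- EM: 5 restarts (first split at the median, others at random quantiles),
  component sd floor 1e-6, separability bound 0.1 pooled sd.
- KDE bandwidth: Silverman's rule (`bw.nrd0`).
- RWR: tol 1e-6, max 10⁴ iterations, weight floor 0.01.
- Empirical Ps (permutation and randomization): plus-one pseudocount.
- Derived RNG streams stay below 2³¹; generators never disturb the
  caller's RNG state.

## Limitations

- The default combined P is anticonservative by construction (see the
  dependence caveat); treat the DEG list as a ranking unless
  `dependence_adjust = TRUE` is used.
- The permutation null is pooled across genes; strongly heteroscedastic
  genes are only partially normalized by the statistics themselves.
- Multiple-testing correction across genes is intentionally absent (calls
  use the raw combined P), matching the original procedure.
- Second-tier neighbours are identified but not scored; motif directionality
  is unavailable in undirected PPI data.
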