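---
title: "Diagnosing phylogenetic incongruence: models, tests and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing phylogenetic incongruence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Phylogenies estimated from morphology, from different genes, or from
different site classes of the same gene frequently disagree. Much of that
disagreement is not noise but the footprint of identifiable evolutionary
processes: bounded character-state spaces that force homoplasy as a clade
radiates, multiple substitutions that erase signal at fast-evolving sites,
compositional drift that overprints a misleading signal on those same sites,
and adaptive convergence that makes independently derived lineages look like
sisters. `phyloconflict` implements a connected set of diagnostics for
pulling those mechanisms apart, together with simulators that generate data
with exactly the structure each diagnostic assumes, so every stage can be
validated end to end without external data.

This vignette records the models, the tunable parameters, and the design
choices made where the methods literature leaves the details open. The
numbered scripts under `analysis/` run the full workflow on a simulated
study system; nothing here states an empirical result that those scripts and
the test suite do not themselves compute.

## Character-state exhaustion

Discrete morphological characters have small state pools. As lineages
accumulate changes, new states appear quickly at first and then stop
appearing: further steps necessarily revisit old states and create
homoplasy. `state_step_curve()` quantifies this by optimizing every
character (unordered) on a reference tree with accelerated transformation
(ACCTRAN), ordering branches from oldest to youngest, and accumulating per
branch the number of parsimony steps and the number of first-appearing
states. Orders come from node ages when branch lengths carry time, otherwise
from a breadth-first depth rank with deterministic tie-breaking (clade size,
then first tip label). States present in the assigned ACCTRAN root
reconstruction count as already seen.

Three analyses interrogate the curve:

* `fit_breakpoint()` fits a continuous two-segment least-squares regression
  of cumulative states on cumulative steps. The breakpoint grid is the set
  of observed step counts, refined by Brent search between the grid
  neighbors of the optimum. The early, linear segment (expected under any
  model of state acquisition) is discarded before the tests below.
* `state_addition_test()` labels each post-breakpoint step by whether it
  added a new state and runs a two-sided Mann-Whitney test on the step
  indices of the two groups (exact for small tie-free samples, normal
  approximation otherwise, the `stats::wilcox.test()` conventions). When a
  branch contributes several steps, its state-adding steps are placed first
  within the branch; this within-branch order is not identified by the data
  and is documented rather than estimated.
* `fit_exhaustion_models()` compares a one-parameter finite-pool
  (rarefaction) model, `S(t) = S_max (1 - (1 - 1/S_max)^t)`, against a
  two-parameter power law `S(t) = b t^c`, fitted by multi-start nonlinear
  least squares. The exact algebraic forms are stated here because the
  upstream methods literature presents them only graphically; the forms
  chosen reproduce the parameter counts implied by published estimates (one
  free parameter plus error for the finite model, two plus error for the
  power law). Models are ranked by `AIC = n log(RSS/n) + 2k` with the
  Gaussian error variance counted in `k`; using one convention for both
  models makes the AIC difference well defined even though the absolute
  values differ from R's `AIC()` by a constant.

## Molecular saturation and compositional bias

`distance_profile()` computes, for every sequence pair in a partition with
at least 50 shared unambiguous sites, the uncorrected distance split into
transition-type and transversion-type mismatches, and the maximum-likelihood
distance under a fixed GTR-family model (Brent search on the branch length,
tolerance 1e-8, model parameters held at alignment-wide estimates). The
saturation statistic is the ordinary least-squares slope (with intercept; a
zero-intercept variant is available by flag) of each uncorrected distance on
the corrected distance: a slope near zero means observed differences no
longer track evolutionary change. Both mismatch classes are regressed
against the same model-corrected distance.

`base_homogeneity_test()` is the classical taxa-by-base chi-square against
pooled frequencies, with absent bases dropped and degrees of freedom
adjusted. `weighting_scheme()` turns slopes into analysis weights: slopes at
or below 0.005 (observed change essentially independent of evolutionary
change) exclude the partition; slopes below 0.2 down-weight it to 0.25;
everything else keeps weight 1. The near-zero exclusion default is
deliberate: partitions with slopes of a few percent still carry usable
signal and are retained at reduced weight, and all three thresholds are
user-overridable.

## Parsimony, homoplasy and the retention index

`count_steps()` uses Fitch state-set counting for unordered characters and
Sankoff dynamic programming with linear cost for ordered ones; polymorphic
cells cost nothing to reach any member state (interval hull for ordered
characters), and missing/inapplicable cells contribute nothing.
`step_bounds()` gives the across-tree minimum `m` (for unordered characters
an exact minimal hitting set over the observed state pool, feasible because
morphological pools are small) and the star-tree maximum `g`; the
consistency index is `m/s` and the retention index `(g-s)/(g-m)`, undefined
when `g = m`. Ensemble indices are computed over all variable characters by
default (the common software convention), with an informative-only variant
by flag, and the RI = 1 census for the G test counts only characters with
defined RI.

ACCTRAN is implemented as a Sankoff downpass plus a preorder assignment
that, among cost-minimal child states, prefers the state farthest from the
parent (forcing the change onto the current, more rootward branch), with
remaining ties going to the lower state — a deterministic rule documented
because the classical description does not fix the tie order.

`mp_search()` is a random-addition-sequence heuristic with full
tree-bisection-reconnection swapping to a local optimum per replicate,
deterministic given its seed. On six-taxon problems it provably reaches the
exhaustive optimum over all 105 unrooted topologies (a standing test); on
larger matrices replicate counts play the usual role of escaping local
optima.

## The likelihood engine

A single pruning core (Felsenstein's algorithm with per-pattern rescaling)
drives three state spaces: nucleotides under the GTR family (JC, HKY, SYM,
GTR, each optionally with invariant sites and 4-category discrete gamma
rates using mean-of-class discretization), amino acids under empirical
replacement matrices (mtMAM bundled via the model library of `phangorn`;
any `list(Q, pi)` is accepted), and codons under Goldman-Yang models (below).
With invariant sites, branch lengths remain expected substitutions per site
overall, so variable-class rates are scaled by `1/(1-p_inv)` — the
convention of the standard ML tools, verified in the tests against an
independent implementation and against explicit summation over ancestral
states on four-taxon trees.

`fit_tree()` optimizes, on a fixed topology, shared branch lengths jointly
with per-partition substitution parameters and per-partition rate
multipliers (site-weighted mean constrained to 1; a flag forces strictly
identical branch lengths instead, mirroring the protocol where one set of
parameters is imposed across partitions). Optimization is bounded
quasi-Newton on log/logit-transformed parameters, iterated until the total
log-likelihood changes by less than the tolerance between passes (default
1e-6). Per-site log-likelihoods are retained and are exactly additive over
partitions and sites.

Model selection (`select_substitution_model()`) ranks candidates by
`AICc = -2 lnL + 2K + 2K(K+1)/(n-K-1)` with `K` counting substitution
parameters (five relative exchangeabilities for GTR/SYM, frequencies where
free, invariant proportion, gamma shape) plus branch lengths, and `n` the
site count; candidates with `n <= K + 1` are skipped. Partition-scheme
comparison adds BIC and a decision-theoretic risk, `risk_i = sum_j w_j
d(i,j)` with `d` the Euclidean distance between the schemes' optimized
branch-length vectors (aligned by tip-set splits) and `w_j` the BIC weights.

## Localizing support: PLS and topology tests

`partitioned_support()` decomposes the total log-likelihood difference
between the best topology and each alternative into per-partition sums of
per-site differences (positive = the partition supports the best tree); the
decomposition is exact by construction. `topology_tests()` implements both
resampling tests on the same RELL bootstrap framework: the weighted
Shimodaira-Hasegawa test (pairwise differences standardized by their
bootstrap standard deviation, maximum over rivals, centered null), and the
approximately unbiased test (multiscale bootstrap over ten scale factors
0.5-1.4 by default, 10,000 replicates per scale, weighted probit regression
`z(r) = d sqrt(r) + c/sqrt(r)`, `p = 1 - Phi(d - c)`). Scale set and
replicate counts follow standard multiscale-bootstrap practice; they are
arguments, not constants. Two numerical details matter: bootstrap ties for
the best topology are broken uniformly at random (so duplicated topologies
receive exchangeable p-values), and a topology that never (or always) wins
at any scale gets p = 0 (or 1) directly, because the probit fit is
unidentified on flat clipped win probabilities. A random anchor topology can
be appended (`random_topology()`) to keep the range of log-likelihood
differences comparable across analyses. The collapsed-node alternative is
evaluated by pinning the focal branch at zero length during re-optimization
rather than re-searching. For reports, alternative resolutions count as
conflicting at >= 50% bootstrap or >= 0.97 posterior probability
(`CONFLICT_BOOTSTRAP`, `CONFLICT_POSTERIOR`).

## Codon models and molecular convergence

`fit_codon_model()` fits Goldman-Yang mixtures on the sense-codon space of
the vertebrate mitochondrial (60 codons) or universal (61) genetic code,
with F3x4 frequencies by default (F61 by flag). The nearly-neutral null has
two site classes (purifying `0 < omega0 < 1` with proportion `p0`, and
neutral `omega = 1`); clade model C adds a divergent class whose omega
differs between a designated foreground clade (stem plus descendants) and
the background. Each class rate matrix is scaled to one expected
substitution per codon, a self-consistent convention shared by the
simulator, so branch lengths mean the same thing in generation and fitting.
Optimization multi-starts over a grid of omega starting values (default
0.001, 0.01, 0.1, 1, 10) and keeps a per-start log; branch lengths are
fixed by default (estimate them upstream or supply them) with joint
optimization by flag. `selection_shift_test()` compares the two models by
`2 (lnL_alt - lnL_null)` against chi-square with 3 degrees of freedom (the
divergent proportion and its two omegas) and flags codons whose posterior
probability of the divergent class reaches the threshold (default 0.95).
Site flagging uses posteriors at the maximum-likelihood estimates — naive
empirical Bayes, not full Bayes integration over parameter uncertainty; at
the alignment sizes this package targets, the difference is the familiar
slight anticonservatism of plug-in posteriors, and the flag threshold should
be read accordingly.

`site_support_profile()` optimizes branch lengths of two topologies (with
and without a focal clade) under an empirical amino-acid model and returns
the exact per-site log-likelihood differences. `convergence_association()`
classifies sites against the 2.5/97.5 percentile envelope of pooled null
profiles — codon alignments simulated under the fitted null model, translated
and profiled identically — and applies Williams-uncorrected G tests of
independence: flagged-by-extremes (3x2, df 2) and flagged-by-region (df =
regions - 1). The percentile cutoffs are documented defaults; the extremes
layout is independence, with the goodness-of-fit variant available through
`g_test()` directly.

## The synthetic study system

The generators produce data with the statistical structure each stage
assumes, under one RNG stream per component (seeds derived by stable
hashing of the master seed and the component name, so adding a generator
never shifts existing streams):

* `sim_tree()`: pure-birth topology conditioned on the tip count, rescaled
  to a target depth; node ages follow from the ultrametric branch lengths.
* `sim_morphology()`: bounded state pools (69% binary, the remainder spread
  over 3-6 states, matching the make-up of typical morphological matrices),
  a fifth of multistate characters ordered (reflecting +/-1 chains),
  lognormal rate variation across characters, then missing cells (default
  28.6%) and polymorphic cells (default 2%) injected at the stated
  fractions. These defaults are the study conditions for every downstream
  calibration.
* `sim_nucleotide()`: per-partition GTR-family models with rate multipliers
  and optional compositional drift on a designated clade — the saturated,
  biased fast class that the saturation profile is designed to catch.
* `sim_codon()`: site classes with per-class omega and an optional
  foreground clade with a different omega in the divergent class; the
  generator acts on sense codons, so stop codons cannot arise, and the
  per-site class assignment is emitted as truth for recovery tests.

What the simulators do not emulate — alignment error, indels, heterotachy,
lineage sorting, among-gene tree discordance — bounds what a passing test
shows about real data: the diagnostics are validated against the specific
mechanisms they target, not against every process that can produce conflict.

## Problem sizes, tolerances and known limitations

The test suite and the acceptance script run everything at desk scale: trees
of 6-40 taxa, partitions of a few hundred sites, codon genes of 150-400
codons, calibration batches of tens of replicates with pass bounds set at
the 99.5th binomial percentile of the nominal rate, and parameter-recovery
bands widened from their large-sample counterparts by the square root of the
size ratio. These sizes are choices, not measurements: the methods scale to
study-sized data linearly in sites and close to linearly in taxa, with the
codon mixture (60-codon matrix exponentials per branch class) the most
expensive stage.

Known limitations: the likelihood engine performs no tree search (topologies
come from the parsimony search, from NNI alternatives, or from the user);
the Mkv ascertainment correction for morphology is out of scope, so
morphological likelihoods are not offered at all rather than offered wrong;
empirical-Bayes flags are plug-in posteriors as noted above; and the TBR
search, while exact on small problems, is a local-optimum heuristic whose
replicate count is the user's lever on larger matrices.
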