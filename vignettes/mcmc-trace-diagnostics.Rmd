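---
title: "Methods: MCMC trace diagnostics and tree-posterior analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MCMC trace diagnostics and tree-posterior analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylotrace)
```

phylotrace post-processes MCMC traces from Bayesian phylogenetics runs. This
vignette is the package's own account of the statistical machinery: what each
method assumes, which knobs matter, how degenerate inputs are handled, and
what the synthetic test data does and does not demonstrate.

## Trace model and parsing

A trace is an ordered record of samples; after some unknown prefix (the
burn-in) the chain is assumed to sample from its stationary distribution, and
all statistics here are computed on the post-burn-in suffix. Files are
tab-separated with a header; lines whose first non-blank character is `#`
are treated as comments, and `[`-prefixed lines are accepted before the
header (the MrBayes ID line). Fields are split on tabs *only*: Newick
strings may contain spaces, so runs of spaces cannot be separators. Different
MCMC programs decorate their output differently and no published grammar
covers them all; our comment-skipping rule is a deliberately permissive
superset and is flagged as such in `?parse_trace`. A column is numeric when
every value parses as a decimal (scientific notation, `NA`/`NaN` allowed —
`NA`s are dropped within each downstream statistic), tree-valued when every
value is parseable Newick ending in `;`, and otherwise ignored. Sample
indexing is 0-based with half-open intervals `[start, end)` everywhere,
including burn-in counts.

## Effective sample size and what it buys you

`ess()` estimates `ESS = n / (1 + 2 Σ_{k=1}^{K} ρ̂_k)` where `ρ̂_k` is the
lag-`k` sample autocorrelation. The truncation `K` is the *initial positive
sequence*: summation stops just before the first non-positive `ρ̂_k`, capped
at lag `n/2`. This rule is simpler than Geyer's monotone-pair rule but tracks
the Tracer-style estimator closely on the well-behaved, positively
autocorrelated chains this tool targets (the test suite cross-checks against
`coda::effectiveSize` within 25% on AR(1) chains); it is a documented choice,
isolated in one function, and swappable. Two conventions: a zero-variance
series returns `ESS = n` (a degenerate posterior is sampled perfectly), and
the estimate is clamped to `(0, n]` — the initial-positive-sequence rule
cannot produce superefficient values, which we consider a feature for a
diagnostic tool.

`ess_uncertainty()` converts an ESS into something decision-relevant: the
full width of the 95% confidence interval of the posterior-mean estimate,
expressed as a percentage of the posterior standard deviation,
`100 · 2 · 1.96 / √ESS`. The 0.975 normal quantile is hard-coded as 1.96
rather than looked up, so the two reference conversions are bit-reproducible:
ESS 6000 → 5.06 ≈ 5%, ESS 200 → 27.7 ≈ 28%. The second number is the reason
the widespread "ESS > 200" convergence heuristic should be read as a bare
minimum: it tolerates a mean estimate whose confidence interval spans more
than a quarter of the posterior spread.

## Convergence diagnostics

**Geweke.** `geweke_z()` compares the first 10% of the chain against the last
50% (the classical window choices) with
`z = (x̄_A − x̄_B) / √(ŝ²_A/n_A + ŝ²_B/n_B)`. The within-window variances are
adjusted for autocorrelation as `ŝ² = s² · n/ESS`, i.e. the spectral density
at frequency zero is estimated through the ESS rather than a windowed
periodogram — simpler, and it reuses one audited estimator. Under
stationarity `z` is asymptotically standard normal; the suite verifies the
empirical size stays in [0.03, 0.08] at the 1.96 cutoff over 1000 chains of
10,000 iid draws. If both windows are constant the statistic is defined as 0.

**Gelman-Rubin.** `gelman_rubin()` computes
`PSRF = √(((n−1)/n) W + B/n) / √W` from two or more equal-length chains.
Identical chains land exactly on the floor `√((n−1)/n)`; zero within-chain
variance with distinct means returns `Inf`; all-constant chains return 1.
Applied to a single trace the series is half-split into two pseudo-chains —
a pragmatic, documented convention for using a multi-chain diagnostic on one
chain; it detects drift (the halves then differ in mean) but not
between-run multimodality, which requires genuinely parallel chains.

**Burn-in estimation.** Two estimators share a candidate grid
`{0, 0.01, 0.02, …, 0.5}·n` (step and cap configurable).
`estimate_burnin_ess()` returns the candidate maximizing the post-burn-in
ESS, ties toward smaller burn-in; discarding a non-stationary prefix removes
the trend that inflates autocorrelation, so the ESS of the remainder jumps
when the prefix is gone. It is deterministic given the series.
`estimate_burnin_geweke()` returns the smallest candidate whose remaining
chain passes `|z| < 1.96`, or the grid maximum flagged non-converged if none
does. One interaction worth knowing: when the Geweke window straddles a sharp
level shift, the window's ESS collapses, its adjusted variance balloons, and
the test can pass slightly *before* the shift is fully discarded. The
combined suggestion used by `diagnose_series()` — the maximum of both
estimators — is therefore the quantity to act on, and on a chain whose first
20% is displaced by 10 sd it lands at 20% of `n`.

**Verdict.** `diagnose_series()` declares convergence when, at the suggested
burn-in, `|z| < 1.96`, half-split `PSRF < 1.1` and `ESS ≥ ess_min`
(default 200). All components are reported so callers can impose stricter
rules; given the 28% uncertainty attached to ESS 200, raising `ess_min` is
often warranted. These are non-convergence heuristics: they can flag a bad
chain but can never prove convergence, and a chain stuck in one mode of a
multimodal posterior will pass all three.

## Tree posteriors

Topology identity is **unrooted**: `topology_key()` serializes the sorted set
of non-trivial leaf bipartitions, each written as the side not containing the
lexicographically smallest leaf, plus the leaf set itself. Keys are invariant
to branch lengths, node rotations and root placement (a degree-2 root is
suppressed). We chose unrooted identity because it matches the unweighted
Robinson-Foulds metric used in tree-space analysis; rooted traces whose trees
differ only in root position collapse to one topology, which a clade-based
(rooted) convention would keep apart.

`topology_frequencies()` sorts unique topologies by posterior probability,
ties broken by first occurrence for determinism, exemplar Newick = first
occurrence with branch lengths stripped. `majority_consensus()` retains a
split iff its weighted frequency strictly exceeds 0.5 (an exact 0.5 is
dropped): strict majority guarantees pairwise compatibility, so the consensus
assembles by nesting clades with no greedy tie-breaking, unresolved regions
becoming polytomies. Supports are the weighted frequencies of the *selected*
trees only, in `(0.5, 1]`, written as internal node labels. Branch lengths
are never summarized onto the consensus (out of scope).

## Tree space

`rf_distance()` is the size of the symmetric difference of the two canonical
split sets — 0 exactly for equal keys, at most `2(L−3)` and even for binary
trees; polytomies are allowed (the evenness then lapses). `rf_matrix()`
restricts the quadratic distance computation to topologies with posterior
probability ≥ 0.2% (default) — below that a topology's point in tree space
carries negligible posterior mass — and warns, without refusing, when more
than 45 topologies qualify, since the analysis then becomes slow and the
plot crowded. `mds_2d()` is classical (Torgerson) scaling via
`stats::cmdscale`: double-center `−½ J D² J`, take the top two non-negative
eigenpairs, clamp negative eigenvalues to zero. Metric MDS was chosen over
non-metric variants as the reproducible, optimization-free baseline. The
eigenvector sign indeterminacy is fixed by making each axis's first nonzero
coordinate positive, so outputs are deterministic; comparisons with other MDS
implementations must still allow rotation/reflection. Degenerate cases: a
single topology or an all-zero matrix maps to the origin; RF distances are
generally not planar-Euclidean, so the 2-D embedding is a lossy summary —
exact only when the input distances happen to be (tested on planar
configurations to 1e-6).

## Parallel chains

`mann_whitney()` uses midranks, reports `U = min(U₁, U₂)`, and switches
between an exact route — full enumeration of the `choose(n₁+n₂, n₁)`
labelings of the pooled midranks, valid under ties — and the tie-corrected
normal approximation with continuity correction at `n₁·n₂ ≥ 20`. The folded
distribution of `min(U, n₁n₂−U)` already pools both tails, so its tail
probability is the two-sided p-value.

`split_chisq()` compares per-split presence counts between the chains:
expected counts from the pooled proportion, statistic `Σ (O−E)²/E` over
splits × chains, `df = categories − 1`, splits with a minimum expected count
below 5 merged into an "other" category first. Splits co-occur within a tree,
so the statistic is an approximation, not an exact multinomial test; for
binary trees on a fixed leaf set it coincides with the standard homogeneity
chi-square on the split-count table, and simulation under the null (two
chains drawn from the same 4-topology distribution, 400 trees each) keeps the
empirical size within [0.02, 0.09] at the 5% level. Mann-Whitney results are
reported per parameter without multiple-testing correction, mirroring how
such per-parameter panels are usually read; callers can apply their own
correction to the returned p-values.

`combine_chains()` appends post-burn-in samples column-wise and renumbers the
generation column from 0, since iteration numbers of independent runs do not
concatenate meaningfully.

## Synthetic data: what it shows and what it cannot

`gen_ar1()` produces stationary Gaussian AR(1) chains (closed-form lag-1
autocorrelation `ρ`, ESS fraction `(1−ρ)/(1+ρ)`) with an optional displaced
prefix of known length — enough structure to give every diagnostic a known
truth. `gen_tree_trace()` draws topologies iid from a specified distribution,
which pins down true posterior frequencies for the tree-side machinery. Both
are pure functions of their arguments including the seed, and never touch the
caller's RNG stream.

What these emulate: autocorrelation, non-stationary prefixes, known topology
frequencies, bimodality (as a mixture of two topology clusters). What they do
not: real phylogenetic MCMC proposals (topology sequences in real traces are
autocorrelated, not iid), heavy-tailed or drifting continuous posteriors,
correlation between tree and continuous parameters. Passing tests therefore
validate the *estimators and bookkeeping*, not the claim that every real
chain failing/passing these diagnostics is bad/good — no diagnostic can
certify convergence.

Problem sizes in the test suite were chosen to make Monte-Carlo bands tight
relative to the tolerances being checked while keeping the default run fast:
10,000-sample chains for ESS/Geweke calibration (1000 replicates for test
sizes), 400-tree chains over 4 topologies (400 replicates) for the split
test, 8-leaf trees for the Robinson-Foulds oracle comparisons (all 225
five-leaf pairs exhaustively, plus 200 random 8-leaf pairs).

## Known limitations

* ESS truncation differs from windowed-spectral and monotone-sequence
  estimators; on pathological (e.g. oscillating-autocorrelation) chains the
  estimates can disagree materially.
* Single-chain PSRF (half-split) cannot see multimodality; use two runs and
  `run_compare()`.
* The split chi-square ignores within-tree split dependence; treat borderline
  p-values with caution.
* HPD intervals, clade-credibility (MCC) trees, weighted RF and BHV geodesic
  distances, and more than two parallel chains are out of scope.
* The `ess_min = 200` default is a community heuristic without theoretical
  grounding; the reported `rel_uncertainty_pct` is the principled quantity.
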