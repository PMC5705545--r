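---
title: "Consensus-query screening: models, choices and caveats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus-query screening: models, choices and caveats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consensr)
```

This vignette is the package's own account of the science it implements:
the scoring model, the design decisions that were genuinely open, the
numerical conventions, and what the synthetic benchmarks do and do not
demonstrate.

## The screening model

Ligand-based virtual screening ranks a database of candidate molecules by
chemical similarity to what is already known to bind a target. The premise
of consensus queries is that when several actives are known, pooling them
beats electing any single one. All methods here are parameter-free in the
machine-learning sense: no training set, no fitting, and activity labels
are never consulted until a performance metric is computed.

Candidates and queries are 2D binary fingerprints. Similarity is Tanimoto
throughout, in its set form `|A∩B| / |A∪B|` for binary fingerprints and in
its real-valued form `Σxy / Σ(x² + y² − xy)` for frequency-valued consensus
fingerprints. The five consensus policies differ only in how the query set
Q enters the score: kept as a set and fused at score time by the maximum
rule (opportunist), fused into one binary fingerprint by intersection
(pessimist) or union (optimist), or fused into one real-valued fingerprint
holding per-bit frequencies (realist), optionally with queries weighted by
potency (knowledgeable).

At N = 1 every policy collapses to the plain single-query similarity
search; the test suite checks this algebraically, together with the
sandwich `pess ⊆ every query ⊆ opti` and the dominance of the opportunist
score over each of its members.

## Fingerprints

* **MACCS (166 keys)** and **ECFP4 (2048 bits)** are adapters over Open
  Babel via `ChemmineOB`. Open Babel's ECFP4 is produced in a 4096-bit
  vector and folded modulo 2048, the conventional length for this
  fingerprint; folding only merges keys, so set semantics are preserved.
  Exact bit positions are backend-specific: they are pinned as regression
  fixtures against the backing toolkit, not asserted against any other
  implementation.
* **UMOP2D** (unfolded MOLPRINT2D) is computed natively from the molecular
  graph. Each heavy atom contributes the canonical key
  `"T0|d1:c1xt1+c2xt2+...|d2:..."`: its SYBYL type plus the multiset of
  SYBYL types at graph distance 1 and 2 (shortest path over heavy atoms;
  hydrogens are never typed). The fingerprint is the *set* of distinct keys
  — per-molecule multiplicity is dropped so the set form of the Tanimoto
  coefficient applies directly, and the key count never exceeds the
  heavy-atom count. Any injective canonical string would give identical
  similarities; this one was chosen to be readable and safe to store in the
  comma-separated fingerprint cache (hence `+`, not `,`, between pairs
  within a shell).

SYBYL typing is an explicit rules table over element, aromatic-ring
membership and incident bond orders, rather than an opaque toolkit call, so
UMOP2D keys are reproducible and auditable across backends. Aromatic-ring
membership is the 2-core of the subgraph of aromatic bonds, which accepts
benzene/pyridine rings while rejecting the acyclic delocalised bonds some
toolkits write for carboxylates. Known simplifications: formal charges are
not modelled (no `N.4`/`C.cat`), and nitro nitrogen types as `N.2` where
some toolkits write `N.pl3`. The test suite cross-checks the rules table
against Open Babel's own MOL2 type column and *logs* (does not fail on)
discrepancies, which is the appropriate contract for a typing scheme with
several extant dialects.

## Potency weighting

The knowledgeable policy weighs query i by
`w_i = log10(IC50_worst) − log10(IC50_i) + 1`, where `IC50_worst` is the
largest (least potent) IC50 among the queries. This is linear over the
whole potency range and anchors the least active query at weight exactly 1.
Two conventions had to be fixed:

* **Log base.** Base 10, the pIC50 convention. Any other base rescales
  `w − 1` linearly and preserves all orderings; base 10 makes "one order of
  magnitude more potent = one extra weight unit" exact.
* **Normalisation of the fused fingerprint.** The weighted fusion is the
  weighted mean `value(k) = Σ w_i [k ∈ q_i] / Σ w_i`. This keeps fused
  values in [0, 1] (a precondition for interpreting them as bit
  probabilities in the real-valued Tanimoto) and reduces exactly to the
  realist policy when all weights are equal — both properties are tested.
  Unnormalised scaling would inflate the self-similarity term of the
  Tanimoto denominator and break the N = 1 collapse.

IC50s are used as given, in whatever single unit the dataset employs; only
ratios enter the weights, so no unit conversion is attempted.

## Numerical conventions

* **Empty fingerprints.** `Tani(∅, ∅) = 0`, not 1: a featureless query
  should match nothing. The same convention covers the all-zero case of the
  real-valued form (denominator 0).
* **Sparse evaluation.** The real-valued Tanimoto is evaluated over the
  union of keys present in either operand; absent keys contribute zero to
  every sum, which recovers the dense fixed-length formulation and is the
  only way to apply it to the unfolded key space, where no global vector
  length exists.
* **Tie handling.** Rankings sort by descending score with ties kept in
  stable input order — deterministic and seed-free, so repeated experiments
  are reproducible bit for bit. AUC is computed from the rank statistic
  with ties counting one half, so tied blocks are unbiased regardless of
  their stored order.
* **Power metric threshold.** The top-x% prefix is `ceil(x% · n)` entries,
  never fewer than one. The prefix is non-empty, so TPR and FPR cannot both
  be zero.
* **Median / MAD.** Raw MAD (`median |v − median|`, no Gaussian consistency
  constant), even-length medians as the mean of the central pair — the
  convention used for all median ± MAD summaries and median curves.
* **KS comparison.** The standard asymptotic two-sample test (via
  `stats::ks.test`); exact small-sample p-values are out of scope. The
  statistic is cross-checked against a brute-force ECDF sup-difference in
  the tests.

## Experiment protocols

Per repetition of a retrospective experiment, N actives are drawn uniformly
without replacement, *removed from the database to screen* (so benchmarks
do not get easier as N grows), fused under the policy, and the remaining
molecules ranked; AUC and PM are computed per repetition and aggregated as
median ± MAD. Draws are seeded per repetition from the experiment seed, so
a seed fixes the entire result. Consensus sizes are restricted to 2–20
(beyond ~20 known actives one would train a QSAR model instead), and a
warning is issued when N exceeds half the actives.

For the single-query baseline, "each active is used in turn" is the
documented default whenever the actives fit within the repetition budget
(enumeration, cycling through the actives in order and therefore seed-free);
otherwise one active is drawn uniformly per repetition. Both modes are
selectable.

The CPU-bounded protocol gives the faster policy the full candidate set and
the slower policy a uniformly random `floor(|C|/speedup)` subset (never
exceeding the budget), with both policies sharing each repetition's query
draw; the two median accumulated-actives curves are returned on a common
rank axis and dominance is left to the caller's judgement. The delta-rank
protocol records, for every active, the median rank under each of two
policies across repetitions — counting only repetitions in which that
active was not itself drawn into the query (a query molecule has no rank) —
and reports `Δ = median rank A − median rank B` ordered from least to most
potent.

## The synthetic generator

`generate_target()` emulates a decoy-free screening target: `n_modes`
chemotype templates over a folded key space, actives that copy a uniformly
chosen template bit-by-bit with probability `mode_fidelity` (falling back
to the Bernoulli(`density`) background otherwise), inactives drawn from the
background at matched density, and log-uniform IC50s spanning
`potency_range_logs` orders of magnitude. Defaults — 50 actives among 2,000
molecules, 3 modes, density 0.025 on a 2048-bit space, fidelity 0.8, 3
potency decades — are chosen to resemble a mid-sized ECFP4 screening deck
(drug-like molecules set roughly 40–60 of 2048 bits; real targets' potency
spreads cover several decades). For MACCS-like 166-bit experiments a
density of 0.3 is the realistic analogue.

Two generator design points deserve a note:

* **Copy semantics.** `mode_fidelity = 1` makes every active an exact copy
  of its template; `mode_fidelity = 0` makes actives exactly exchangeable
  with inactives, which is what the signal-free null uses. Fidelity
  interpolates between the two as a per-bit convex mixture, and the
  expected bit count is `density · L` at every fidelity.
* **Exact-size templates.** Templates are random subsets of exactly
  `round(density · L)` keys rather than Bernoulli draws. With Bernoulli
  templates, template-count luck hands actives a systematic set-bit-count
  offset relative to the inactives, and a saturated consensus fingerprint
  (e.g. a 20-query optimist union on a 166-bit space, which fills the
  space) then ranks purely by bit count — leaking a spurious signal that
  matched-density real benchmarks do not carry. Fixing the template size
  removes that confound and leaves only the intended chemotype structure.

Multi-mode actives are the structural feature that makes the policy
comparison meaningful: the max-of-scores rule handles multimodality
naturally (each query retrieves its own chemotype), while a single fused
fingerprint blurs modes — on a short, dense key space the optimist union
saturates and loses selectivity, which is exactly the degeneration the
benchmark suite reproduces.

What the generator does **not** emulate: real chemical similarity structure
(bit correlations from substructure nesting), activity cliffs, assay noise
in labels, analogue series, or any relationship between potency and
fingerprint content. Passing the synthetic benchmarks therefore shows that
the machinery ranks, fuses and scores correctly and that the qualitative
policy behaviour has the right mechanism — not that any particular AUC will
be attained on a real target.

## Problem sizes used by the test suite

The retrospective benchmarks in the tests use 2,000-molecule targets with
50 actives and 100 query draws per configuration (200 for the signal-free
null), sizes at which the median statistics are stable while the whole
suite stays interactive. Oracle-equivalence checks run 500 random ranked
lists (n ≤ 200) against a brute-force all-pairs AUC and 1,000 random set
pairs against the binary/real-valued Tanimoto reduction; the policy algebra
is property-checked over 200 random query sets.

## Known limitations

* ECFP4 bits come from Open Babel's implementation; other toolkits'
  ECFP4 variants hash differently, so cross-toolkit bit identity must not
  be assumed (similarity *values* are comparable, bit positions are not).
* The SYBYL rules table intentionally ignores formal charge.
* The pessimist policy is implemented and tested but is a poor screening
  choice for diverse query sets (the intersection empties out); it is not
  part of the recommended menu.
* KS p-values are asymptotic; with very few repetitions they are
  approximate.
* No wall-clock speed claims are made anywhere: the CPU-bounded protocol
  models a scoring budget abstractly via database subsampling.
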