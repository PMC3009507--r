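---
title: "Measuring functional coherence and its relationship to network proximity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring functional coherence and its relationship to network proximity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funcoh)
```

## The problem

Sets of interacting biomolecules — protein complexes, domains in a
domain–domain interaction network, candidate modules mined from a graph —
are interesting precisely when their members do related things. Judging
"related" requires two ingredients: a measure of the functional coherence
of a *set* of molecules annotated against a DAG-shaped ontology, and a
measure of topological proximity in an interaction network robust to the
noise and incompleteness typical of high-throughput data. This vignette
explains the models implemented in `funcoh`, the assumptions behind them,
the parameters that matter, and what the synthetic benchmarks do and do
not demonstrate.

## Ontology model and information content

An ontology is a finite set of terms partially ordered by is-a / part-of
edges, with a single most-general root. The two relation kinds are
collapsed into one edge kind: none of the implemented measures
distinguishes them. Ancestor sets are **reflexive** — `ancestors(ont, c)`
contains `c` itself — because every formula that consumes ancestor sets
(intersection DAGs, shared-term weights) needs the term's own information
to count; the strict relation is recovered from `term_comparable()` plus
an identity check.

Annotations enter as molecule → term-set maps and are reduced to their
most specific members, the non-redundant representation in which no stored
term is an ancestor of another. The true-path rule is materialized as a
closure index: a molecule annotated with `c` supports every ancestor of
`c`. Information content is `I(c) = -log2(|G_c|/|G_r|)` in bits (base 2
matches the natural reading of the worked example below), so `I(root) = 0`
and I never decreases when moving to a more specific term. For a term
*set*, `I` counts the molecules supporting *all* members of the set.

Two boundary conventions are worth stating. Terms annotated in a corpus
but absent from the ontology are dropped with a warning — real annotation
releases routinely contain obsolete identifiers. A term set supported by
no molecule has infinite information content; this cannot arise in the
similarity measures (minimum-common-ancestor sets are always supported by
the molecules that generated them) but can be triggered by hand, so it is
surfaced as an `Inf` sentinel rather than an error. The shortest-path
length between comparable terms is exposed (`term_path_length()`) but no
implemented measure consumes it.

## From terms to molecules to modules

`delta_i(ci, cj)` is the information content of the pair's minimum common
ancestor — on a DAG there can be several minimal common ancestors, and we
take the most informative, the standard Resnik convention (ties cannot
occur on tree-shaped examples, so worked-example values are unaffected).
Because `delta_i` ignores how specific the compared terms themselves are,
`delta_jc` normalizes by the self-similarities through the Jiang–Conrath
distance: `1/(I(ci) + I(cj) - 2 delta_i + 1)`, bounded in (0, 1] with
maximum exactly at distance zero. The reciprocal-distance form was chosen
for structural consistency with the set-level `rho_jc` below, and
satisfies the bounded-with-maximum-1 properties required of it.

For molecules carrying term *sets*, `rho_i(Si, Sj)` is the information
content of Λ(S_i, S_j): collect the minimum common ancestors of every
cross pair, then apply the generalized union (reduce to most specific
members). `rho_jc` normalizes it the same way:
`1/(rho_i(Si,Si) + rho_i(Sj,Sj) - 2 rho_i(Si,Sj) + 1)`. The classical
aggregates `rho_a` (mean), `rho_m` (max) and `rho_h` (best-match average)
are included as baselines; `rho_h` is symmetrized by averaging both
directions, since downstream correlation analysis assumes symmetric pair
scores.

Module-level measures score ℛ = {S_1, …, S_n}:

* `sigma_a` — mean pairwise score, any pair measure plugged in
  (default `rho_a`/`delta_i`).
* `sigma_i` — `I(Λ(ℛ))` where Λ(ℛ) generalizes the
  minimum-common-ancestor set to n-tuples. Enumerating one term per
  member is exponential in n, so the implementation folds pairwise:
  Λ(…Λ(Λ(S_1,S_2),S_3)…,S_n). The fold is equivalent on trees, and a
  brute-force tuple oracle in the test suite confirms agreement on every
  random DAG fixture tried (n ≤ 4).
* `sigma_g` — IC of the intersection of the members' ancestor DAGs over
  IC of their union. When the union carries zero information (all members
  annotated only at the root) the module is vacuously homogeneous and the
  score is 1 by convention.
* `sigma_w` — each term in any member's ancestor DAG is weighted by the
  count n_t of members containing it; the score is
  `Σ_{n_t≥2} n_t I(t) / Σ_t n_t I(t)`. The root contributes nothing
  because its IC is 0, so no special-casing is needed; the all-root
  degenerate case returns 1 by the same convention as `sigma_g`.

On the built-in six-molecule example, the bridged complex
{S1, S2, S3, S4} scores `sigma_a = 3/8`, `sigma_i = 0`, `sigma_g = 0`,
`sigma_w ≈ 0.86`, and the specialized sub-complex {S1, S2, S3} scores
2/3, 1, 1/2, 3/4 — the contrast that motivates the weighted measure.

```{r example}
fx <- build_figure1()
sigma_w(fx$corpus, c("S1", "S2", "S3", "S4"))
```

Coherence scoring defaults to a single sub-ontology (biological process
in practice, where shared processes span network neighborhoods); for pair
scores across two sub-ontologies, `combine_subontology()` implements the
funsim-style combination — half the sum of squared normalized scores. The
normalizing maxima are exposed as arguments and default, in analysis
code, to the corpus-wide observed maxima, since a theoretical maximum is
not well defined for unbounded IC-based scores.

## Post-processing: size adjustment and detectability

Raw coherence drifts with module size, so `size_adjust()` subtracts the
mean score of `n_random` same-size modules drawn uniformly (without
replacement, from annotated molecules only). Subtracting — rather than
dividing by — the background preserves score units and centres the null
at zero at every size; at least 30 draws are required, and the whole
procedure is deterministic given a seed.

To compare measures, `detectability()` summarizes test-vs-control score
collections by the binormal separation `D = (m_T − m_C)/√(v_T + v_C)`
(sample variances). Φ(D) equals the area under the binormal ROC curve —
verified in the tests against numerical integration of the ROC — and
D > Φ⁻¹(0.95) ≈ 1.645 marks separation significant at p < 0.05 under a
standard-normal reference. Zero pooled variance is reported as 0 for
equal means and a signed infinity otherwise.

## Random-walk proximity

Transition probabilities are edge-weight proportional (row-normalized
adjacency W); the walk from source i follows
`p ← (1−c)·Wᵀ·p + c·e_i` to its fixed point, and entry (i, j) is the
stationary mass at j. Because the measure is asymmetric, each pair is
reported as the average of its two orientations. Defaults: restart
`c = 0.3` (where correlation with functional similarity peaks on
interaction networks — smaller c explores farther, c = 1 never leaves
the source), convergence when the L1 change drops below 1e-10, cap 1000
iterations (both configurable; hitting the cap is an error carrying the
residual). Isolated nodes are made absorbing so every row remains a
probability vector; pairs in different components are excluded from
correlation, mirroring the `Inf` sentinel of the shortest-path matrix.
The iterative solution is verified against the closed form
`p = c(I − (1−c)Wᵀ)⁻¹e_i` to 1e-8 on random graphs.

The correlation analysis z-normalizes similarity scores (population
standard deviation, the natural choice when the full pair population is
in hand; the sample variant is a parameter), sorts pairs by symmetrized
proximity with ties broken by node identifiers for reproducibility, and
splits them into equal-count bins (sizes differ by at most one).
`restart_sweep()` emits the correlation-vs-c table over c ∈ {0.1, …,
0.9}.

## What the synthetic generators emulate

Everything is testable offline because the fixtures module reconstructs
the worked example exactly (its construction asserts all six information
contents) and generates randomized inputs:

* `simulate_ontology()` grows a rooted DAG by giving each new term 1 to
  `max_parents` parents among earlier terms — acyclic and single-rooted
  by construction.
* `simulate_corpus()` annotates molecules with leaf-biased term draws
  (leaves three times as likely), mimicking most-specific-annotation
  practice.
* `simulate_test_control_modules()` emulates a known-complex benchmark:
  control modules are uniform draws; test modules draw members from
  planted functional families (molecules below a mid-depth term). Modules
  above ~4 members are split into sub-blocks with *separate* planted
  terms, reflecting the biology of large complexes assembling from
  functionally specific sub-complexes. This is what makes the qualitative
  measure ordering observable: whole-set agreement (`sigma_g`, `sigma_i`)
  dilutes as sub-blocks accumulate, while pair-counted sharing
  (`sigma_w`, `sigma_a`) persists. The acceptance suite runs sizes 4–11
  with 40 test and 40 control modules per size and coherence bias 0.9 —
  module sizes mirror curated complex benchmarks; the bias is high but
  sub-unity because even curated complexes carry incompletely annotated
  members.
* `simulate_modular_network()` builds a planted-partition graph whose
  blocks *are* functional families (default p_in = 0.8, p_out = 0.05,
  six blocks of eight), so topological modularity and functional
  coherence coincide by design. The few inter-block edges are exactly
  the condition under which diffusion-based proximity outperforms
  shortest paths: a single shortcut collapses graph distance but barely
  perturbs walk mass.

All generators are pure functions of their seed.

**What passing these benchmarks does not show.** The synthetic corpora
have uniform annotation depth and density; real GOA-style corpora have
heavy-tailed term frequencies, evidence-code biases, and annotation
propagated from sequence similarity. The planted networks have sharp
block structure and no degree heterogeneity, unlike scale-free-ish
interaction data. The benchmarks therefore validate the *measures and
machinery* (arithmetic, invariances, qualitative orderings), not
quantitative claims about any particular organism's interactome.

## Numerical choices and degenerate inputs

* Information content in bits throughout; `-0` is normalized to `0`.
* Non-redundancy reduction is idempotent and order-independent; input
  sets to pair measures are defensively reduced.
* Equal-count binning requires at least as many pairs as bins; constant
  score vectors are rejected by `znormalize()` rather than silently
  producing NaN.
* Problem sizes in the shipped test and acceptance runs (ontologies of
  ~120 terms, corpora of ~400 molecules, networks of ~48 nodes, 640
  scored modules) were chosen as the smallest at which the stochastic
  contrasts are comfortably visible; all complete in about two minutes.
* Module lists, edge lists and score tables round-trip through plain TSV
  with lexicographic ordering so outputs diff cleanly.

## Known limitations

* `sigma_i`'s pairwise fold is proven equivalent to tuple enumeration
  only empirically on DAGs (exhaustively on trees); pathological DAGs
  could in principle differ, which is why the tuple oracle remains in
  the test suite.
* Relation-type semantics (e.g. *regulates*), evidence-based annotation
  filtering (available but off by default — typical corpus use does not
  filter), and obsolete-term remapping are out of scope.
* Directed networks and alternative diffusion measures (effective
  resistance, commute distance) are not implemented.
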