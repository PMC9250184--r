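---
title: "Consensus Bayesian networks for binary methylation states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus Bayesian networks for binary methylation states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

`methbn` addresses a common situation in epigenetics: a modest number of
individuals (tens), each measured over a set of differentially methylated
regions (DMRs) as non-negative read counts, plus one binary experimental
condition (say control vs. stress). The goal is not prediction but
structure discovery — which DMRs are functionally related to each other
and which stand in close relationship to the condition.

The tool for this is a discrete Bayesian network: a DAG over the
variables $X_1,\dots,X_p$ (the DMRs plus the condition) whose joint law
factorizes as

$$\Pr(X_1,\dots,X_p) = \prod_{i=1}^{p} \Pr(X_i \mid \mathrm{Pa}_i),$$

with $\mathrm{Pa}_i$ the parents of $X_i$ in the DAG. The *Markov
blanket* of a node — its parents, children, and spouses (co-parents of
its children) — renders it conditionally independent of everything else,
which is why the blanket of the condition node is the natural candidate
set of condition-associated biomarkers.

## Why each pipeline stage exists

**Binarization at zero.** Methylation counts in this design are strongly
zero-inflated: zero is the single most frequent value. Two states (zero /
non-zero) is then the discretization closest to balanced state counts,
which is where discrete scores have the most power. The rule is
magnitude-free: count 0 becomes state 0, any positive count becomes
state 1. No alternative discretizers are offered on purpose.

**Chi-square arc screening.** Even after binarization the states are
imbalanced, and over-represented states of unrelated variables can
"predict" each other, creating artefactual arcs. Before any search, every
unordered pair of variables gets a Pearson chi-square test on its 2x2
joint-state table; pairs with $p \ge 0.25$ (inclusive) show no evidence
of contingency and both directed arcs between them are *blocked* —
excluded a priori from every search. Notes on the defaults:

* Yates continuity correction is on by default, matching R's own 2x2
  default; `yates = FALSE` is available and the choice is recorded in the
  provenance output, since either variant is defensible.
* A variable constant across samples yields a zero-margin table; its
  p-value is *defined* as 1 (blocked), erring toward exclusion, with a
  warning.
* No multiple-testing adjustment: the 0.25 cut removes candidate
  dependence, it never declares dependence, so per-pair screening is the
  intended semantics.
* The condition variable is screened exactly like any DMR.

**BDe scoring.** Network quality is the Bayesian Dirichlet equivalent
(BDe) log marginal likelihood with the equivalent sample size `ess`
spread uniformly: each pseudo-count is $\alpha = \mathrm{ess}/(q r)$ for
$q$ parent configurations and $r = 2$ child states. BDe is
score-equivalent (Markov-equivalent DAGs score identically), so learned
arc *directions* within an equivalence class are not evidence. Defaults:
`ess = 1` (a standard weak-prior choice; the appropriate value for a
given dataset is genuinely unknowable a priori, so it is a visible
parameter), uniform structure prior, all arithmetic in the log domain
via `lgamma`. There is no hard parent cap by default, though with ~46
samples roughly three parents per node is the practical recovery limit.

**Tabu search, 100 random restarts.** The search space is multimodal:
similar-scoring networks can differ strongly in structure. Each search
starts from a random DAG (random topological order; each order-respecting
non-blocked arc included with probability `2/(v-1)`, about one arc per
node) and applies best-improvement moves (add / delete / reverse one
arc), never crossing the blocklist or creating a cycle. The applied
move's inverse is tabu for `tabu_length = 10` iterations (aspiration:
a tabu move that beats the best score is allowed), and up to
`max_noimprove = 10` consecutive non-improving moves are accepted before
stopping. Ties between equal-delta moves break to the lexicographically
smallest (from, to, move type), so a search is a deterministic function
of its starting DAG. These tabu specifics follow common practice for
this family of learners; they are all configurable.

**Score-weighted model averaging.** The 100 top networks are combined by
softmax weighting over their BDe log-scores,
$w_i \propto \exp(s_i - s_{\max})$ — i.e. posterior-proportional model
averaging under the uniform structure prior; an arc's probability is the
total weight of networks containing it. "Softmax over BDe log-scores" is
stamped into the provenance metadata because other readings of
"score-weighted" exist. Duplicate networks keep their weight mass
deliberately: reaching the same optimum from many starts *is* evidence.

**High/low classification.** Arc probabilities are bimodal in practice,
so a two-component 1-D Gaussian mixture is fitted by EM (quantile
initialization at the 25th/75th percentiles, at most 500 iterations,
log-likelihood tolerance $10^{-8}$, variance floor $10^{-6}$; fully
deterministic). The components share a common variance: a repetition
yields only a few dozen probabilities, and the free-variance mixture
likelihood is unbounded — a component can collapse onto near-coincident
values (e.g. several arcs at exactly 1.0) and then mislabel genuine
high-cluster arcs as uncertain. The pooled-variance model is the
standard bounded-likelihood choice at this sample size. The larger-mean component is "high"; an arc's
uncertainty is one minus its maximum posterior responsibility. Arcs
labelled high with probability $\ge 0.5$ and uncertainty $\le 0.01$
(both inclusive) are selected. Degenerate inputs (fewer than four
distinct probabilities, or EM collapse) fall back to a hard threshold at
0.5 with uncertainty 0, flagged in the output. The Gaussian-mixture
reading of the two-category classification is a documented design
choice of this package, not a verbatim port of any particular
implementation.

**Consensus over 50 repetitions.** Even the selected arcs vary between
batches, so the batch-average-select cycle is repeated (default 50
times, independent derived seeds) and only arcs selected in *every*
repetition survive, weighted by the mean of their per-repetition
probabilities. The intersection is over *directed* arcs — matching the
arc-table output dialect — even though score equivalence can flip
directions between searches; a skeleton-level reading is available to
callers by collapsing (from, to) pairs. The consensus is an arc summary,
not a single DAG, so it is not forced acyclic, and the Markov blanket of
the condition is read off its directed structure as-is.

## Seeds and determinism

One master seed determines everything. Per-repetition and per-search
seeds are derived by a counter-based mixing function
(`derive_seed(master, index)`), so results do not depend on execution
order, identical master seeds give byte-identical output files, and all
derived seeds stay below $2^{31}$. All seeded functions restore the
caller's RNG state.

## What the synthetic generator does and does not emulate

`generate_ground_truth()` + `sample_counts()` stand in for real count
tables. They emulate the features that matter to this pipeline: a known
DAG over binary features plus a condition node participating like any
other node; zero-inflated counts (state 0 maps to count 0 exactly, state
1 to a positive count `1 + Poisson(4)` truncated at 39, matching the
observed 0–39 range); strong state imbalance; and a 22/24-style
condition split (the condition's root probability defaults to
study-scale proportions, so the realized split matches in expectation,
not exactly). CPTs are drawn away from 0/1 by a configurable floor
(default 0.05). The Poisson choice is cosmetic by construction — the
pipeline binarizes at zero, so any positive-support law gives identical
downstream inference; tests verify that binarization recovers the
latent states exactly.

Not emulated: sequencing reads, enrichment chemistry, alignment, DMR
calling, genomic autocorrelation between DMRs, or batch effects. A green
test suite therefore establishes the *statistical machinery* —
scoring, search, averaging, consensus, blanket extraction — not the
upstream bioinformatics.

## Validation strategy

Every numerical component is dual-routed against an independent oracle
in the test suite: family scores against a loop-based no-cache
evaluation and the Beta-Binomial closed form $\ln(1/8)$; search optima
against exhaustive enumeration of all 25 three-node and 543 four-node
DAGs; score equivalence against Markov-equivalence classes derived from
a moralization-based d-separation oracle; Markov blankets against a
brute-force d-separation definition; mixture posteriors against a
grid-search fit. The end-to-end recovery test uses a 10-node ground
truth with strong OR-gate CPTs (a node is active with probability 0.9
if any parent is active, 0.1 otherwise), $n = 500$ samples and a scaled
protocol (20 searches x 5 repetitions) — chosen once as a realistic
strong-signal regime; directionality is deliberately not scored, since
BDe cannot distinguish equivalent orientations.

## Known limitations

* With tens of samples the consensus is conservative: fewer arcs, not
  wrong arcs, is the expected failure mode, and isolated variables are
  normal.
* Arc directions inside an equivalence class are an artefact of search
  order and tie-breaking; interpret the skeleton plus the blanket.
* When the learned equivalence class does not compel an arc's direction,
  score-weighted averaging splits that arc's mass across its two
  orientations; a badly split arc (near 0.5/0.5) can then fail the
  per-repetition selection gate in *both* directions and drop out of the
  consensus entirely, even though its skeleton edge is well supported.
  The scaled recovery test exhibits exactly this on a minority of seeds.
  `build_consensus(directed = FALSE)` mitigates flips *across*
  repetitions but cannot recover arcs lost at the selection stage.
* The `ess` value materially affects arc counts; published arc counts
  are reproducible only under the (unstated) original setting.
* The consensus graph may contain cycles when repetitions disagree on
  orientation; blanket extraction treats it as a directed graph without
  repair.
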