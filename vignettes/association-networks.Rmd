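---
title: "Inferring gene-gene association networks from GO-guided literature co-occurrence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring gene-gene association networks from GO-guided literature co-occurrence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litgonet)
```

## The model

Genes that contribute to the same biological function are rarely all
mentioned together in a single paper, but they *are* discussed in terms of
the same Gene Ontology (GO) concepts. `litgonet` exploits this: instead of
linking two genes only when they co-occur in an abstract, it links them
when the literature associates them with similar sets of GO terms.

The unit of evidence is one abstract, reduced to the set of gene symbols
and GO terms it mentions. From a corpus of such mention records we tally

* $n_{i\cdot}$ — abstracts mentioning gene $i$,
* $n_{\cdot j}$ — abstracts mentioning GO term $j$,
* $n_{ij}$ — abstracts mentioning both,
* $n_{\cdot\cdot}$ — abstracts mentioning at least one gene or GO term.

Under the null hypothesis that mentions of $i$ and $j$ fall independently
across abstracts, the co-occurrence count $X$ is hypergeometric with
population $n_{\cdot\cdot}$, $n_{\cdot j}$ successes and $n_{i\cdot}$
draws. The association p-value is the **mid-p** upper tail

$$p_{ij} = P(X > n_{ij}) + \tfrac12\,P(X = n_{ij}),$$

which counts only half the probability of the observed outcome. For a
discrete test this is the natural continuity correction: the plain tail
$P(X \ge n_{ij})$ is conservative, and the mid-p variant restores the
property that upper and lower tails sum exactly to one (a property the
test suite asserts on an exhaustive grid of margins, against an exact
big-integer rational enumeration of the PMF). The statistic is evaluated
through the survival function and the log-space PMF of `stats::phyper` /
`stats::dhyper`, so it remains accurate when $n_{\cdot\cdot}$ is in the
millions. A pair with $n_{ij} = 0$ has *no stored p-value*: "never
co-mentioned" is treated as absence of evidence, not as $p = 1$.

Each gene then carries a weight profile over GO terms,

$$w_{ij} = -\log \max(p_{ij}, 10^{-6}),$$

with absent pairs contributing zero, and the similarity of two genes is
the cosine of the angle between their profiles over the union of their
supports:

$$\gamma_{i,i'} = \frac{\sum_j w_{ij} w_{i'j}}
{\sqrt{\sum_j w_{ij}^2}\sqrt{\sum_j w_{i'j}^2}} \in [0, 1].$$

A network is obtained by drawing an edge whenever $\gamma_{i,i'} \ge c$
for a user-chosen cutoff $c$ (the boundary is included). Communities are
found by asynchronous label propagation, and each community is annotated
by the mean of its genes' $p_{ij}$ per GO term, with missing p-values
counted as 1 so that poorly studied pairs can never *create* enrichment.

## Tunable parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| truncation floor | $10^{-6}$ | $p_{ij}$ is clamped below at this value before taking logs. Without it a handful of astronomically small p-values would dominate every profile; with it the strongest associations saturate at $-\log 10^{-6} \approx 13.8$. |
| log base | $e$ | Only fixed for reproducible weight exports. $\gamma$ depends on ratios of weights only, so it is provably (and test-assertedly) independent of the base. |
| cutoff $c$ | preset `"high"` | Numeric in $[0,1]$, or a preset: `"median"`, `"moderate"`, `"high"` resolve to the 50th, 95th and 99th percentile of the *user's own* similarity distribution. Percentile calibration makes the confidence level explicit: at the 99th percentile only the top 1% of gene pairs are connected. The concrete cutoff value is database-dependent and is always recomputed, never hard-coded. |
| percentile rule | type 7 | Linear interpolation between order statistics, R's default; configurable because any empirical-quantile definition is defensible. |
| label-propagation `max_iter` | 100 sweeps | Non-convergence is a warning, not an error: oscillation is possible on bipartite-like graphs, and the partition at the iteration cap is still usable. |
| Bonferroni family size $m$ | #GO terms (gene queries), #genes (GO queries) | The most conservative defensible family: everything the matrix indexes. Overridable, since the appropriate family for a focused query can be smaller. |
| layout spacing $k$ | $1/\sqrt{n}$ | The Fruchterman-Reingold "optimal distance". Larger $k$ spreads the drawing out; the contract that mean pairwise distance grows with $k$ is checked statistically over seeds. |

## Dictionary filtering and matching

Surface-name dictionaries map term identifiers (HGNC symbols, `GO:NNNNNNN`
accessions) to the names under which they may appear in text. Before
scanning, names shorter than 3 characters and names equal to common
English words are removed — a GO term like *learning* (`GO:0007612`)
shares its only name with an everyday word and would otherwise match
constantly. The term identifier survives filtering even when all its
names are removed (it then matches nothing), keeping identifier spaces
stable across filter settings; such terms are reported via `message()`.

The matcher is deliberately simple and fully specified: text and names
are lower-cased and split on non-alphanumeric characters, and a name
matches iff its token sequence occurs consecutively. This is a
deterministic, testable rule, not an attempt at biomedical named-entity
recognition; disambiguation and negation handling are out of scope. The
pipeline equally accepts pre-extracted mention records (TSV), skipping
text scanning entirely.

## The co-occurrence baseline

For method comparison the package also computes the similarity that
ignores GO terms: the cosine of two genes' 0/1 abstract-incidence
vectors, $n_{ii'} / \sqrt{n_{i\cdot} n_{i'\cdot}}$. `edge_richness()`
compares the two measures at matched percentile cutoffs, each drawn from
its own corpus-wide pair distribution; when a gene signature is supplied,
edges are counted within that signature's subnetwork while the cutoffs
stay corpus-wide — the comparison that reveals whether GO guidance links
signature genes that rarely co-occur directly.

## What the synthetic generator emulates

`simulate_corpus()` plants functional modules in a corpus of mention
records. Each abstract is topical with probability `p_signal_gene`
(default 0.8, reflecting that most indexed abstracts are about
something); a topical abstract concerns one module (uniform), mentions a
single focal gene of that module, mentions each *other* module gene only
with probability `p_direct_cooccurrence` (default 0.05), and mentions
each of the module's GO terms with probability `p_signal_go` (default
0.6). Independently, every gene and GO term appears as background noise
with probability `p_background` (default 0.01).

The one-focal-gene design is deliberate: module genes share GO context
but almost never co-occur directly, which is precisely the regime where
GO-guided inference outperforms direct co-occurrence — and therefore the
regime in which the pipeline's recovery claims are meaningfully testable.

What the generator does **not** emulate: natural-language text (records
are mention sets), synonym ambiguity, citation and temporal structure,
the heavy-tailed popularity of real genes, and correlations between GO
terms induced by the ontology graph. Passing recovery tests on this
generator therefore demonstrates that the statistical pipeline works
when its assumptions hold, not that literature mining on real abstracts
is accurate.

## Numerical choices and degenerate inputs

* p-values that underflow double precision are clamped at $10^{-300}$
  when the matrix is built, keeping the invariant $0 < p \le 1$; the
  similarity floor of $10^{-6}$ makes the clamp value immaterial.
* A gene whose profile is all-zero has *undefined* similarity. It is
  stored as $\gamma = 0$ with an `undefined` flag rather than `NaN`, so
  thresholding never emits edges for unstudied genes and they surface as
  isolated nodes.
* Ties in label propagation are broken uniformly at random from a seeded
  generator, and the node order is reshuffled every sweep; the caller's
  RNG state is saved and restored around every seeded computation.
* Ties in rankings (top-GO selection, query tables) break
  lexicographically by identifier, making all orderings deterministic.
* `select_top_go()` ranks only GO terms with at least one stored pair
  among the queried genes (all-missing terms tie at average 1 and carry
  no signal); asking for more terms than exist returns all with a
  warning.
* Raw p-values are stored unfloored; flooring happens in
  `weight_profile()`. This keeps the stored matrix faithful to the test
  and lets the floor be changed without re-tallying.

## Design decisions that were genuinely open

* **Matching rule.** Token-based, case-insensitive matching was chosen
  over substring or case-sensitive variants as the simplest rule that is
  deterministic, testable, and robust to punctuation; it is a documented
  stand-in, not a claim about how any production mining system matches.
* **Stop-word source.** A plain-text list of a few hundred common
  English words ships as a fixture and any list can be substituted; this
  replaces a lexical-database dependency while preserving the filter
  semantics.
* **Baseline similarity.** The co-occurrence comparison needs a
  similarity on the same $[0,1]$ scale; the incidence-vector cosine is
  the natural analogue of $\gamma$ and reduces to familiar quantities
  ($1$ for identical incidence, $0$ for never co-mentioned).
* **Probit clamp.** The transform clamps $p$ into
  $[10^{-6}, 1 - 10^{-6}]$; the lower end matches the similarity floor
  and the upper end is its symmetric completion so that missing
  p-values (treated as 1) map to a finite value, $+4.753$.
* **Community labels** are dense integers `0..K-1` in reading order of
  first appearance, so partitions are comparable across runs.

## Problem sizes used in validation

The bundled checks run at desk scale, chosen to finish in seconds to a
few minutes while still exercising every code path: the mid-p statistic
is compared to an exact rational oracle on *all* valid margins with
$n_{\cdot\cdot} \le 60$ (about 1.2 million cases); planted-module
recovery uses 20 replicate corpora of 2,000 abstracts, 40 genes and 80
GO terms with 4 planted modules of 5 genes and 8 GO terms each; the
richness comparison evaluates percentiles $0.90, 0.92, \ldots, 1.00$ on
the same corpora.

## Known limitations

* At the default recovery scale, the 40 within-module gene pairs make up
  about 5% of all 780 pairs, so a 99th-percentile cutoff (top ~8 edges)
  necessarily fragments the planted modules; full recovery (ARI = 1 in
  every tested seed) appears once the cutoff admits the module block,
  e.g. at the 94.8th percentile or the `"moderate"` preset. Percentile
  presets should always be read against the size and enrichment of the
  gene set at hand.
* Mention-record quality bounds everything downstream; the scanner is a
  contract, not an NER system.
* Only Bonferroni adjustment is offered; FDR-style procedures and
  GO-graph-aware semantic similarity are out of scope.
* Label propagation is unweighted in its frequency counts; edge weights
  influence only which edges exist, not their vote.
```{r session}
sessionInfo()
```
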