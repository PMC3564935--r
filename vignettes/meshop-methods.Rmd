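---
title: "Term over-representation profiles: model, parameters, and validation"
author: "meshopr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Term over-representation profiles: model, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meshopr)
```

## The problem

Biomedical literature databases annotate each article with descriptors from
a controlled vocabulary (MeSH being the canonical example).  For any entity
with a bibliography — a gene, a disease, a chemical, a research topic — the
annotations of its articles summarize what the literature says about it.
`meshopr` condenses such a bibliography into a *term over-representation
profile*: a vector of (term, p-value) pairs in which each p-value measures
how surprisingly often that term is attached to the entity's articles
relative to a reference background.

## The statistical model

Curators assign the *most specific* applicable descriptors, so an article
tagged "Alzheimer Disease" is not also tagged "Brain Diseases".  Before any
counting we therefore close every article's annotation upward: an article
annotated with a term counts as annotated with all of that term's ancestors,
where ancestry is defined by dot-delimited tree numbers (a term occupying
position `A.B` is an ancestor of one occupying `A.B.C`).  One descriptor may
occupy several tree positions; its ancestors are collected from every
branch.  Supplementary concepts (mostly chemicals) have no tree position and
take part in counting but not in hierarchy operations.  Coordinated
annotations carry no linkage in the source records, so no co-annotation
structure is modelled: terms are counted marginally, once per article.

For a foreground of $n$ articles inside a background of $N$ articles, a
term attached (after closure) to $a$ foreground articles and to $k$
background articles in total defines the 2x2 table

|              | term present | term absent |
|--------------|--------------|-------------|
| foreground   | $a$          | $n - a$     |
| bg only      | $k - a$      | $N - n - (k - a)$ |

and the profile entry is the one-sided Fisher's exact p-value
$P(X \ge a)$ for $X$ hypergeometric with population $N$, $k$ successes and
$n$ draws — the probability that a uniformly random article set of the same
size would contain the term at least as prevalently.  Only
over-representation is tested; a two-sided option is deliberately absent.
The null hypothesis is independent random assignment of terms to articles.
Every term occurring in the foreground is reported (`min_count = 1`);
significance thresholds are a downstream choice, and a Bonferroni
correction across the members of an entity family is available via
`bonferroni()` (e.g. `n` = number of diseases profiled).

The background is either *universal* — every corpus article carrying at
least one resolvable term — or *class-specific* — the union of the
bibliographies of a class of entities (for instance all articles addressing
at least one gene of the studied organism), again restricted to
term-bearing articles.  A class background absorbs enrichment that is
generic to the class: a term common to all gene literature is strongly
enriched against the universal background but unremarkable against the
gene-class background.  Articles carrying no resolvable term are excluded
from every background, and foreground articles that are absent from the
corpus or term-free are dropped with a recorded count before the
foreground-within-background invariant is enforced.

## Profile post-processing

**Specificity filtering** (`filter_most_specific`) keeps, among the terms
with $p \le \alpha$, only those that are not ancestors of another retained
term.  The survivors form an antichain of the hierarchy — the most specific
significant terms.  The threshold is applied *before* the antichain
reduction, so an insignificant descendant cannot knock out a significant
ancestor.  The operation is idempotent.

**Query-term exclusion** (`exclude_term_family`) removes a term and its
ancestors, used when the bibliography was itself selected by that term and
its enrichment is tautological.

**Temporal slicing** (`temporal_slice`) represents the state of a field in
year $y$ by the $n$ most recent articles published in or before $y$
(default $n = 50$).  The source data gives no within-year ordering, so ties
break by descending article ID — documented and deterministic.  Articles
without a year are excluded from slicing only.

**Comparison.**  Profiles are stacked into an entities-by-terms matrix of
weights $-\log_{10}\max(p, c)$ with cap $c = 10^{-30}$.  The cap, the same
one used for word-cloud weights, keeps a single extremely studied term from
dominating every distance.  Two column policies are offered because the
choice is genuinely open: `"shared"` (default) compares entities on the
terms present in all profiles; `"union"` keeps every term and scores absent
entries 0, i.e. as if $p = 1$.  Entity dissimilarity is the Euclidean
distance between rows, and `cluster_complete()` performs agglomerative
complete-linkage clustering on those distances (via `stats::hclust`, whose
merge-height monotonicity complete linkage guarantees).
`cooccurrence_submatrix()` restricts the matrix to a named term panel, for
entity-vs-term-family views such as scoring each vitamin against the panel
of vitamin terms; it applies no p-value threshold.

**Word clouds** (`to_cloud`, `write_tagcloud`) export the top 150 terms by
profile order with weight $-\log_{10}\max(p, 10^{-30})$, so weights lie in
$[0, 30]$; zero-weight entries are dropped and multi-word names are joined
non-breakingly so layout engines keep each term whole.  Weights are printed
with 4 significant digits — a documented choice, since the upstream
rendering service's precision is unspecified.  Only the layout input is
produced; geometry and rendering are out of scope.

## Numerical choices

The hypergeometric tail is computed by `stats::phyper`, which works in
log space internally; p-values remain accurate and positive down to the
doubles' range (the package's tests verify agreement with a direct
log-binomial-coefficient summation to below $10^{-280}$).  Profile order is
ascending p-value with ties broken by term ID, making every output
byte-reproducible.  Hierarchy queries treat only positions present in the
vocabulary as terms; unoccupied prefix positions (as arise in vocabulary
subsets) are skipped silently, and whether category roots count as terms is
thereby decided by the vocabulary's own content.

## The synthetic generator

`synthetic_spec()` + `generate_corpus()` draw corpora under the null of
independent term assignment, with optional planted signal.  Only leaf terms
are assigned directly — ancestors arrive solely through closure — mirroring
the curation rule of most-specific assignment and making the closure
machinery itself testable.  Background articles receive each leaf
independently at a base rate (default 0.05 over a depth-3, branching-3 tree
of 39 terms); entity articles elevate their planted leaves to a stated
foreground probability.  Years are uniform over the configured range.  A
single seed governs all draws, with per-entity substreams derived
deterministically from (seed, entity ID).

Two canonical scenarios define the validation conditions:

* `recovery_spec()`: 500 background articles, one entity with 30 articles,
  one planted leaf at probability 0.5 against base 0.05.  The planted term
  should attain the smallest p-value in the profile.
* `two_group_spec()`: two groups of five entities (25 articles each), each
  group carrying a disjoint *three-leaf* signature at probability 0.5.
  A multi-term signature is used because the realized strength of any
  single planted term varies binomially across entities; with one term per
  group that variance is comparable to the between-group separation and
  complete linkage — sensitive to its most extreme pair — then splits
  groups erratically.  Entities of a real class share several topical
  terms, which the signature emulates; with it, cutting the dendrogram at
  k = 2 recovers the groups essentially always.

What the generator does **not** emulate: citation-count tails, correlated
co-assignment of terms, curation drift over time, or entity bibliographies
that overlap.  Passing the planted-recovery and calibration checks
therefore demonstrates the statistical machinery is correct under the
stated null, not that real literature satisfies that null — real MeSH
assignments are strongly correlated, and real profiles should be read with
the Bonferroni or specificity-filtering tools engaged.

## Validation performed by the test suite

All of the following are computed by `tests/testthat/` and
`scripts/acceptance.R`; problem sizes are chosen for desk-scale runs:

* exact-test agreement with brute-force tail enumeration on every 2x2
  table with total at most 25 and on random tables with totals up to
  10,000;
* the six-article worked example ($a=2, b=0, c=1, d=3$, $p = 3/15$)
  end-to-end through the command-line interface;
* closure idempotence/monotonicity and filter antichain/idempotence on
  1,000 random profiles against brute-force ancestor scans;
* calibration: across 1,000 simulated null entities, per-term p-values are
  not anti-conservative (one-sided Kolmogorov–Smirnov against uniform —
  the discrete test is conservative, so the empirical CDF sits below the
  diagonal);
* planted-term recovery across 100 seeds of `recovery_spec()` and
  two-group recovery across 100 seeds of `two_group_spec()`;
* the word-cloud contract (at most 150 entries, weights at most 30,
  lossless round-trip at the documented precision);
* the class-background effect on a constructed fixture in which a term is
  class-enriched but not member-enriched.

## Limitations

Annotation closure is cached per article at load time; memory grows with
corpus size times average closure depth, which is fine for desk-scale
corpora but not for a full literature baseline.  Parent–child-conditioned
enrichment tests and false-discovery-rate procedures beyond Bonferroni are
not provided.  The vocabulary readers cover the descriptor ASCII dialect
and a simple TSV; XML descriptor files, qualifier records and entry-term
synonyms are out of scope.
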