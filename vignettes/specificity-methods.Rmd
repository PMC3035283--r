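---
title: "Measuring GO term specificity: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring GO term specificity: models, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gospec)
```

## The problem

The Gene Ontology organizes protein function as a directed acyclic graph
(DAG): terms become narrower as one moves away from the namespace root.
Path length is an unreliable proxy for that narrowing — edges carry no
weights and the depth of equally specific terms varies wildly — so `gospec`
quantifies specificity through *node counts* and *annotation frequency*
instead. Four measures are computed per term $t$:

* **Ancestor count** $A_t$: the number of unique terms reachable from $t$
  by repeatedly following child→parent edges, root included. Computed by a
  visited-marking depth-first search; marking matters, because in a DAG a
  naive DFS counts a multiply-reachable ancestor once per path.
* **Normalized offspring** $\mathrm{Offsp_N}(t) = \ln\frac{M+1}{k_t+1}$,
  where $k_t$ is $t$'s offspring count and $M$ the maximum offspring count
  (the root's). The $+1$ in numerator and denominator pin the endpoints:
  exactly $0$ at the root ($k = M$) and $\ln(M+1)$ at leaves, so the measure
  increases with specificity like the ancestor count does. The variant
  $\ln(M/(k+1))$ was rejected: it makes the minimum slightly negative
  instead of 0. Units are nats.
* **GO proportion** $P_t = 1 - k_t/(k_t + A_t)$: the share of $t$'s
  reachable terms that are *not* beneath it; 0 at the root of a nontrivial
  ontology, 1 at leaves, and undefined for an isolated single node (0/0).
* **Information content** $\mathrm{IC}(t) = -\log_2 p(t)$ in bits, where
  $p(t)$ is the fraction of annotation units (genes or proteins — the id
  column is treated opaquely) assigned to $t$ *or any of its offspring*.
  Rare terms are assumed more specific. IC is the only data-dependent
  measure.

## Conventions that needed a decision

**$p(t)$ counts offspring, not ancestors, and deduplicates units.** The
closure that defines $p(t)$ is $\{t\} \cup \mathrm{offspring}(t)$ — only
that reading makes the toy worked example come out to $p = 4/11$, and only
it gives the root $p = 1$, hence $\mathrm{IC} = 0$, the baseline for the
least specific function. A unit annotated to both a term and one of its
offspring is counted **once** (default `count_mode = "unique"`): this keeps
$p \le 1$ and makes $p$ monotone non-increasing from parent to child, which
in turn makes IC monotone non-decreasing. The literal "add the two counts"
procedure is available as `count_mode = "sum"` for compatibility; it can
exceed 1 when annotations overlap, and its IC is then reported as the raw
$-\log_2 p$ (possibly negative) rather than silently clamped.

**The probability denominator** is the number of distinct units that
survive namespace filtering — not the pre-filter total. This convention is
what forces $p(\mathrm{root}) = 1$ exactly, whatever the data set.

**Which edges define "parent" is explicit.** Only `is_a` by default;
`part_of` can be added (`edge_types = c("is_a", "part_of")`). Published
ancestor counts built on pre-packaged GO distributions blend relation types
and include a bookkeeping pseudo-root `"all"` above the three namespace
roots; `gospec` excludes that pseudo-node and treats the namespace root
(e.g. `GO:0003674`) as the apex, so counts can sit one below what
`GO.db`-style `ANCESTOR` maps report. Cross-validating against such output
should account for both choices.

**Undefined is a value, not zero.** A term absent from the data set has
$p = 0$ and no IC; an isolated node has no GO proportion. Both are
represented as `NA` in records and serialized as the string `NA`, never as
0 or infinity. Values are kept at full precision internally; tables round
only at presentation (6 significant digits in the TSV; 2 decimals for
Offsp_N/GO proportion and 1 for IC when comparing against published
tables).

**Obsolete terms** are parsed and retained (so files referencing them fail
loudly in diagnostics rather than mysteriously) but carry no edges and are
excluded from every metric, every traversal and every annotation count.
`alt_id` accessions resolve silently to their primary term. `NOT`-qualified
annotation rows are dropped: a NOT annotation is evidence of absence and
would corrupt $p(t)$.

**$M$ is configurable.** By default $M$ is derived from the loaded ontology
as the root's offspring count; `metric_config(max_offspring = 8267)`
overrides it with a published constant so that printed values (e.g. a leaf's
$\ln 8268 \approx 9.02$) can be reproduced on any fixture. A supplied $M$
smaller than some term's offspring count is a hard error, not a clamp.

## Algorithms

Per-term queries use the marking DFS directly. The whole-ontology table is
one memoized sweep: the constructor materializes a topological order (Kahn's
algorithm doubles as the acyclicity proof — any unreachable remainder is a
cycle and is reported by member name), ancestors are unioned top-down,
offspring and per-term annotation-unit sets bottom-up. The test suite checks
this sweep against two independent references: the per-term DFS, and a
brute-force transitive closure computed by repeated boolean matrix squaring
on seeded DAGs of up to 60 nodes.

## What the synthetic generator does and does not establish

`generate_synthetic()` builds layered random DAGs: the root alone on layer
0, each non-root term drawing 1..`max_parents` parents from strictly earlier
layers with weight decaying by layer distance. Layering buys single-
rootedness and acyclicity by construction and mimics the broad-to-narrow
fan-out of real ontologies. Annotation units then sample terms with weight
$(\mathrm{depth}+1)^{\mathrm{depth\_bias}}$, imitating curators' preference
for specific terms. Defaults — 60 terms, up to 3 parents, 200 units, depth
bias 1, seed 7 — are the frozen benchmark the correlation property runs on:
small enough for exhaustive per-term oracles, large enough that all six
pairwise Spearman correlations among the four metrics are positive, the
qualitative pattern seen on real GO data.

The generator does **not** calibrate to real GO degree distributions, term
counts (~10⁴ molecular-function terms), annotation sparsity or evidence-code
composition. A green suite therefore establishes correctness of the
formulas, traversals, parsers and their contracts — not that any particular
published, release-dependent value (per-term IC on a 2010 annotation
snapshot, the 8267 root offspring count as a recomputed quantity) is
reproduced. Those depend on retired data releases and enter only as printed
inputs.

## Degenerate inputs and edge behavior

* Single-node ontology: the root is its own leaf, $M$ derives to 0 and
  $\mathrm{Offsp_N}$ is degenerately 0 ($k = M$); the GO proportion is
  `NA` (0/0).
* Multiple parentless terms: root ambiguity, a validation error listing
  candidates — except in `build_dag()`, where the root is declared and any
  other parentless node means an undeclared attachment edge.
* Multi-namespace OBO files require an explicit `namespace_filter`;
  in-file edges crossing out of the chosen namespace are dropped, while
  references to terms never defined at all remain dangling-edge errors.
* Annotation tables: unknown/obsolete/unresolvable terms are dropped with a
  reported count; zero surviving rows is an error, never an empty set.
* Correlations use pairwise-complete observations with per-pair n reported,
  because IC-undefined terms are expected and listwise deletion would bias
  the structural-metric correlations; any pair with fewer than 3 complete
  rows is an error, and an all-`NA` metric is skipped with a warning.

## Known limitations

* OWL, `regulates`/`has_part` relations and cross-namespace edges are out
  of scope; so are Resnik/Lin-style pairwise similarity measures built on
  IC.
* Evidence codes are parsed but not used for weighting or filtering; taxon
  filtering is available for gene2go input only.
* IC inherits the biases of the annotation corpus: heavily studied proteins
  drag $p$ upward for their terms, and a term missing from the corpus has
  no IC at all. The structural measures are corpus-independent but
  ontology-release-dependent.
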