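# gospec — function specificity metrics for Gene Ontology terms

Gene Ontology (GO) terms range from very broad (*binding*) to very narrow
(*collagen V binding*), and many analyses — automated protein annotation,
semantic similarity, enrichment interpretation — need a **number** that says
how specific a term is. `gospec` computes four complementary specificity
measures for every term of any OBO-format ontology:

| metric | definition | needs |
|---|---|---|
| `n_ancestors` | number of unique terms above `t`, up to and including the root | ontology only |
| `offsp_n` | Offsp_N = ln((M+1)/(k+1)), where k = offspring count of `t` and M = the root's offspring count | ontology only |
| `go_prop` | P_t = 1 − offspring/(offspring + ancestors), the proportion of `t`'s reachable terms that are *not* below it | ontology only |
| `ic` | IC(t) = −log₂ p(t), where p(t) is the fraction of annotation units assigned to `t` or any of its offspring | ontology + annotation table |

All counts are over **unique nodes** (a DAG node reached along several paths
is counted once). `offsp_n` is 0 at the root (k = M) and maximal, ln(M+1),
at leaves; `go_prop` runs from 0 (root) to 1 (leaf); the root's IC is 0 bits
by construction since every annotated unit falls inside its closure. IC is
undefined (`NA`) for terms absent from the data set.

Inputs are OBO 1.2 flat files, NCBI `gene2go`-dialect TSVs (both the full
8-column dialect and a minimal `GeneID`/`GOTerm` one) and GAF 2.x, all gzip-
friendly. A seeded generator of GO-like layered random DAGs with depth-biased
annotations backs the test suite, so nothing is downloaded.

## Worked example

```r
library(gospec)

# five-term neighborhood of "collagen binding"
obo <- system.file("extdata", "collagen_binding.obo", package = "gospec")
dag <- parse_obo(obo)
ancestor_set(dag, "GO:0005518")
#> [1] "GO:0003674" "GO:0005488" "GO:0005515"
offspring_set(dag, "GO:0005518")
#> [1] "GO:0070052"

# the built-in toy ontology: 7 terms, 11 annotated units
fx <- figure1_fixture()
tab <- compute_all(fx$dag, fx$ann, metric_config(max_offspring = 8267))
tab[, c("term_id", "n_ancestors", "n_offspring", "offsp_n", "go_prop", "p", "ic")]
#>     term_id n_ancestors n_offspring offsp_n go_prop      p    ic
#> 1 GO:Term_1           0           6    7.07   0.000 1.0000 0.000
#> 2 GO:Term_2           1           2    7.92   0.333 0.5455 0.874
#> 3 GO:Term_3           1           2    7.92   0.333 0.3636 1.459
#> 4 GO:Term_6           2           0    9.02   1.000 0.1818 2.459
#> 5 GO:Term_7           2           0    9.02   1.000 0.2727 1.874
#> 6 GO:Term_4           2           0    9.02   1.000 0.1818 2.459
#> 7 GO:Term_5           2           0    9.02   1.000 0.0909 3.459
```

`GO:Term_3` carries one directly annotated unit and its offspring carry three
more, so p = 4/11 and IC = −log₂(4/11) ≈ 1.459 bits (1.5 at one decimal).
With the `max_offspring = 8267` override (the molecular-function root's
offspring count in the 2010 GO release), a leaf's `offsp_n` is
ln(8268) ≈ 9.02 nats, and the root's IC is exactly 0: every unit is inside
its closure. Leaves have `go_prop = 1`; the root has 0.

## Command line

```sh
gospec fixtures --out demo/                      # write the built-in toy files
gospec compute --annotations demo/annotations.tsv --out demo/metrics.tsv demo/ontology.obo
gospec correlate --out demo/corr.tsv --plot demo/pairs.png demo/metrics.tsv
```

`compute` emits one TSV row per non-obsolete term with a `#` metadata header
(M, edge types, dropped-annotation counts); exit status is 1 on ontology
validation failures (cycles, root ambiguity, dangling edges) and 2 on
file/schema problems. `correlate` reports Pearson and Spearman matrices over
the four metrics, pairwise-complete with per-pair n. Which relations count as
"parent" is explicit: `--edge-types is_a` (default) or `is_a,part_of`.

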