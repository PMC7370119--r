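# rnamodcensus

A curated, machine-readable census of known RNA modifications
(epitranscriptomic marks) organized as a **rooted modification forest**,
with a nomenclature parser, validators, stage statistics, annotation
queries, and deterministic graph exporters.

## The problem and the model

Well over a hundred chemically modified ribonucleosides have been
described across eukarya, bacteria and archaea — m6A, pseudouridine (Ψ),
queuosine (Q), the wyosine family, dozens of thiolated and side-chain
uridines — but the field lacks a standard way to organize them. This
package implements a staged classification: every placed mark descends
from one of the four natural ribonucleosides (A, C, G, U) through a chain
of single chemical-modification steps, so the marks form four rooted
trees. A mark's **stage** is its edge distance from the root, i.e. the
total number of modifications added to the initial base:

```
stage(root base) = 0
stage(child)     = stage(parent) + 1
```

The shipped census holds 158 records: **134 placed** marks forming the
four trees, **3 unplaced** marks (ac6A, cm5s2U, cnm5U) whose biosynthesis
is too poorly characterized for a stage assignment, and **21 nascent**
5′/3′-end marks (cap structures and end states) that cannot be rooted to
a single internal ribonucleoside. Two curated **cross-talk** edges record
the enzymatic deamination routes C→U and m3C→m3U between the cytidine and
uridine trees; they are annotations, never tree edges.

Each record also carries annotations harvested from the literature:
kingdoms, RNA classes, tRNA positions (text labels such as `34`, `47b`,
`20A`, with kingdom qualifiers like `22[bacteria]`), mRNA regions and
motifs (`DRACH`, `AGAUC`, `UCCUC`, ...), writer/reader/eraser enzymes,
and reversibility.

The second pillar is a **short-name parser**: `mcm5s2U` tokenizes into
the core `U` plus prefix operations `mcm@5` and `s@2`, giving the root
base and a multiset of chemical operations. The token vocabulary is data
(`inst/extdata/token_table.json`), not code. Family symbols with
idiosyncratic multi-step chemistry (Q, G+, imG, yW, o2yW, ...) are
*atomic cores*: their root is known but their operation count is
undefined. The parser cross-validates the curation: every placed name
must parse to its curated root, and for non-atomic cores the operation
count is a lower bound on the curated stage (compound side-chain tokens
such as `mcm5` count as one operation).

## Worked example

```r
library(rnamodcensus)
cen <- rnamod_census()
cen
#> RNA modification census v1.0
#>   records: 158 (134 placed, 3 unplaced, 21 nascent)

f <- build_forest(cen)
summary(f)
#>        A  C  G  U
#> 1     11  9  7 13
#> 2     16  6  8 24
#> 3      5  3  5 12
#> 4      0  0  2  6
#> 5      0  0  1  0
#> 6      0  0  1  0
#> 7      0  0  2  0
#> 8      0  0  2  0
#> 9      0  0  1  0
#> total 32 18 29 55
#> grand total: 134
```

The grid is the per-base × per-stage count matrix: uridine contributes
the largest branch (55 marks, 24 of the 54 second-stage marks alone),
first-stage counts range from 7 (G) to 13 (U), and only the guanosine
tree reaches stage 9 — the peroxywybutosine (o2yW) endpoint of the
wyosine pathway:

```r
parse_short_name("mcm5s2U")
#> name: mcm5s2U
#> root: U
#> operations (2 total):
#>   carboxymethyl-side-chain @5 x1
#>   thiolation @2 x1

compute_stage(f, "o2yW")
#> [1] 9

descendants(f, "m1G")        # the 12 marks built on m1G37
#>  [1] "OHyW"  "OHyWx" "OHyWy" "imG"  "imG-14" "imG2" "mimG" "o2yW"
#>  [9] "yW"    "yW-58" "yW-72" "yW-86"

query_census(cen, trna_position = "58")$short_name
#> [1] "m1A"  "m1Am"
```

Exports are byte-stable: `to_dot()` (stage-colored Graphviz digraph),
`to_newick()` (single-quoted labels, so `'m2,2G'` survives a conforming
reader), and `to_json_graph()` (node-link JSON). A command-line wrapper
ships at `inst/cli/rnamodcensus`:

```sh
rnamodcensus stats inst/extdata/census.tsv
rnamodcensus parse m2,2G
rnamodcensus tree inst/extdata/census.tsv --base G --format newick
rnamodcensus query inst/extdata/census.tsv --kingdom archaea --position 15
```

## Package layout

- `inst/extdata/census.tsv` — the curated census (the single source of truth)
- `inst/extdata/token_table.json` — the nomenclature token registry
- `R/` — census model, nomenclature, forest, queries, exporters, CLI
- `vignettes/staged-census.Rmd` — the methods vignette (curation rules,
  parser grammar, design choices, limitations)
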