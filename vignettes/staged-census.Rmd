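---
title: "A staged census of RNA modifications: model, curation and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A staged census of RNA modifications: model, curation and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnamodcensus)
```

## The classification model

Post-transcriptional RNA modifications are classified here by lineage:
every placed mark derives from one of the four natural ribonucleosides
(adenosine, cytidine, guanosine, uridine) through a chain of single
chemical-modification steps, each step catalyzed by one or more enzymes
and yielding a modified ribonucleoside that has itself been observed in
some RNA. The marks therefore form four rooted trees — a *modification
forest* — and a mark's **stage** is its edge distance from the root,
equivalently the total number of modifications added to the initial
base. The roots are virtual stage-0 nodes; a first-stage mark is one
chemical operation away from the unmodified base (m6A, s2U, Ψ, ...), a
second-stage mark modifies a first-stage product (m6Am from Am,
mcm5U from cm5U), and so on.

The model makes three structural commitments:

1. **Single parent.** Each placed mark has exactly one primary parent.
   Where the chemistry admits two derivations (m6Am can arise from Am or
   from m6A) the census records one primary parent — the derivation the
   literature singles out, here Am, because the cap-adjacent first
   nucleotide is always derived from Am — and keeps the alternative in
   `alt_parents`. Stage assignments are unaffected by these choices.
2. **Stage recurrence.** Every tree edge adds exactly one stage:
   `stage(child) = stage(parent) + 1`. This is enforced at build time and
   re-verified exhaustively by the test suite against an independent
   breadth-first search.
3. **Cross-talk is not ancestry.** Enzymatic conversion of cytidine
   derivatives into uridine derivatives (C→U, m3C→m3U) connects two
   trees. These routes are stored as *cross-talk edges* on the forest and
   rendered dashed in exports, but they never participate in stage
   computation, descendant sets, or counts — otherwise the uridine branch
   would silently absorb cytidine-derived chemistry.

## What the census contains

The packaged census (`inst/extdata/census.tsv`) holds 158 records:

- **134 placed** marks spanning the four trees, with branch totals
  A = 32, C = 18, G = 29, U = 55. Uridine's dominance is concentrated at
  stage 2 (24 of 54 second-stage marks), reflecting the combinatorial
  elaboration of s2U- and side-chain-modified wobble uridines.
- **3 unplaced** marks — ac6A, cm5s2U, cnm5U — whose biosynthesis is too
  poorly characterized to assign a stage.
- **21 nascent** records for 5′/3′-end marks of nascent transcripts (cap
  structures, end phosphorylation states, tail additions). These cannot
  be rooted to a single internal ribonucleoside, so they carry neither
  root base nor parent. Their authoritative name list is not part of the
  text the census was curated from; the shipped entries are placeholder
  names of standard end marks, each flagged `provenance=placeholder` in
  its notes, and only their count (21) is asserted by the tests.

Annotations (kingdoms, RNA classes, tRNA positions, mRNA regions,
motifs, enzymes, reversibility) are curated from the per-base survey
sections of the source literature. tRNA positions are **text labels**,
never integers, to support `47b`, `20A`, `20B`; kingdom-restricted
occurrences are qualified in place (`22[bacteria]`) and match both the
bare and the qualified query. Motifs are stored as labels (`DRACH`,
`AGAUC`, `UCCUC`, `GA-rich`) and matched as text — the census records
where a motif is reported, it does not scan sequences. Reversibility
defaults to `unknown` and is set to `yes` only for m1A, m6A, Am and m6Am
and to `no` for queuosine, the cases the literature states explicitly.

### Curation choices the data alone does not fix

- **Wyosine pathway order.** The guanosine tree must reach stage 9 at
  peroxywybutosine (o2yW) and m1G must have exactly 12 descendants, but
  the published material does not spell out the full node order between
  4-demethylwyosine (imG-14) and o2yW. The census curates the spine as
  m1G → imG-14 → imG → yW-86 → yW-72 → yW-58 → yW → OHyW → o2yW, with
  isowyosine (imG2 → mimG) branching at imG-14 and the undermodified
  hydroxywybutosine forms (OHyWx → OHyWy) branching at yW-58. Any
  alternative respecting the three guarding counts (height 9, 12
  descendants, branch total 29) would be an equally valid reading; the
  choice is recorded here once and is not revisited.
- **m1Gm hangs under Gm** (alternative parent m1G). Keeping m1Gm out of
  the m1G subtree is what makes "m1G is the precursor of 12
  modifications" come out exactly: the 12 are the wyosine family.
- **m2,7G hangs under m7G** (alternative parent m2G), following the
  cap-related methylation series m7G → m2,7G → m2,2,7G.
- **Errata.** Where a textual gloss conflicts with the tree legends, the
  legends win: m3U is 3-methyluridine (one gloss misprints it as a
  cytidine), and cm5s2U is 5-carboxymethyl-2-thiouridine (one tRNA-map
  legend glosses it as carbamoylmethyl); both discrepancies are kept in
  the records' notes.

## The nomenclature grammar

`parse_short_name()` decomposes a short name deterministically:

- exactly one **core** token terminates the name: a plain base letter, a
  special core carrying implied chemistry (I = deaminated A,
  Ψ = isomerized U, D = reduced U, C+ = agmatinated C), or an **atomic**
  family symbol (queuosine family Q, G+, galQ, manQ, gluQ, oQ, preQ0/1;
  wyosine family imG-14 through o2yW) whose internal multi-step chemistry
  is deliberately not decomposed — `op_count` is `NA` for these and they
  are excluded from the stage-bound property;
- **prefix** tokens are matched left-to-right by longest match and must
  be followed by a comma-separated locant list: `m2,2` is methylation at
  N2 twice, `m2,2,7G` parses to three methylations. Requiring the locant
  is what disambiguates `mimG` (an atomic core) from `m` + `imG`;
- the **suffixes** `m` and `r(p)` after the core denote ribose
  2′-O-methylation and 2′-O-ribosylation (`Ψm`, `Gr(p)`);
- compound side-chain tokens (`mcm5`, `cmnm5`, `ncm5`, ...) are single
  registered operations. Consequently `op_count` is a *lower bound* on
  the curated stage, never an upper bound, and the consistency check
  `check_consistency()` asserts `1 ≤ op_count ≤ stage` for every placed
  non-atomic record, plus parsed-root/curated-root agreement for all 134.

The vocabulary lives in `inst/extdata/token_table.json`; adding a newly
described mark is a data edit, not a grammar change. Matching is
case-sensitive with no fuzzy correction: `M6A` is not a name. ASCII
aliases (`psi-m` for `Ψm`) are registered in the same file and applied by
`normalize_name()`, which also NFC-normalizes and trims its input; every
lookup accepts either spelling. One registered token goes beyond the
base vocabulary: `cnm` (cyanomethyl, for the unplaced cnm5U), typed as
`complex`. Similarly `ms` (methylthio) and `msms` are single operations
of the thiolation kind, and `mchm5` is registered as one token because
the available text does not resolve whether its methyl ester should
count as a separate step.

## Numerical and formatting choices

- **Determinism.** Children lists, query results, report keys and all
  exporter output are sorted with a locale-independent (radix) order, so
  identical inputs give identical bytes on any machine.
- **TSV dialect.** UTF-8, fixed 19-column header, `";"` as the list
  separator for *all* multi-valued cells (short names contain commas),
  empty cell = absent. Two optional leading comment lines
  (`# version:`, `# source_note:`) carry the census metadata so that
  write → load is an identity on the whole object, not just the records.
  Unknown columns are a hard error — no silent dropping.
- **JSON dialect.** One object `{version, source_note, records}` with
  record keys equal to the TSV columns and deterministic key order; the
  loader enforces the shape (unknown keys error) in code.
- **Position ordering.** `positions_report()` orders labels numerically
  with letter suffixes after their number (..., 20, 20A, 20B, 21, ...),
  and non-numeric labels, if any ever appear, after all numeric ones.
- **Newick quoting.** Labels containing grammar characters are
  single-quoted with internal quotes doubled (`'m2,2G'`), the one
  portable way to keep comma-bearing names parseable. Trees are emitted
  rooted, internal nodes labeled, without branch lengths.
- **Degenerate inputs.** An empty census is valid; its forest has the
  four roots, height 0 everywhere, and exporters emit well-formed
  documents (a DOT digraph with 4 nodes, `"A;"` as a Newick tree).

## What the tests do and do not show

The suite validates three layers: (i) the curated file reproduces every
printed summary statistic (the partition 134/3/21, branch totals,
second-stage counts, first-stage range 7–13, height 9 only at o2yW, the
12 m1G descendants); (ii) structural invariants hold for *any* valid
census, exercised on randomized synthetic forests — count conservation,
stage recurrence, breadth-first-search equivalence, serialization
round-trips; (iii) independent oracles agree — a hand-built table of
roots and methyl counts derived from the full chemical names checks the
parser, ape's Newick reader checks the exporter, and a naive full-scan
checks the query engine on 200 randomized filters.

What passing does **not** show: that the curation is chemically complete
(figures in the source material show more tRNA positions than the text
states, and only text-stated facts are asserted), that the placeholder
nascent names are the real ones, or that motif labels generalize to
transcriptome coordinates — the census stores reported annotations, it
performs no sequence analysis.

## Known limitations

- The census is a snapshot; marks described after the source material
  are absent by construction, though both the census file and the token
  table are designed to be extended by data edits.
- Stage assignments inherit any ambiguity of the underlying pathway
  literature; `alt_parents` preserves the alternatives but only the
  primary parent shapes the tree.
- Chemical structure (SMILES/InChI) and stoichiometry are out of scope;
  `stoichiometry_note` is free text.
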