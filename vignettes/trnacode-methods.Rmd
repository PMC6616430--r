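---
title: "Methods: primordial tRNA models, code sectoring, and aaRS networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: primordial tRNA models, code sectoring, and aaRS networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trnacode)
```

## Scope

`trnacode` implements three connected analyses of early translation
evolution: (i) a repeat-based origin model for tRNA, (ii) an
anticodon-centric 32-cell representation of the genetic code with a
stepwise sectoring simulation, and (iii) homology-network analysis of
aminoacyl-tRNA synthetase (aaRS) score matrices. A synthetic-data
module provides mutated tRNAomes and planted-tree score matrices so
that every statistical procedure can be exercised offline.

## The tRNA origin model

The model posits that tRNA condensed from ordered repeats rather than
random sequence. The building blocks (all constants are available from
`primordial_spec()`):

* 5' acceptor strand `GCGGCGG` — a truncated GCG repeat;
* 3' acceptor strand `CCGCCGC` — its reverse complement, a truncated
  CGC repeat;
* D-loop element `UAGCCUAGCCUAGCCUA` — a truncated UAGCC repeat;
* stem-loop-stem `CCGGGUUAAAAACCCGG` — an inverted repeat with 5-bp
  stems and a 7-nt loop, shared by the anticodon arm and the T arm.

Three 31-nt minihelices (acceptor strand + 17-mer + acceptor strand)
ligate into a 93-nt precursor. Each ligation seam spells the 14-nt
junction `CCGCCGCGCGGCGG` (3' strand followed by 5' strand). Internal
processing deletes exactly 9 nt inside a junction: retaining the 3'
end leaves `GGCGG` (the last five nucleotides of the D-loop region),
retaining the 5' end leaves `CCGCC` (the type I V loop). Processing
both junctions yields the 75-nt type I core; processing only junction
1 leaves the intact 14-mer as the expanded V region of the 84-nt type
II core. `build_trna_pri()` constructs either model with per-segment
provenance labels and cross-checks the segment construction against
the string-level deletion pipeline on every call.

Numerical conventions: coordinates are 1-based inclusive on the model
sequence itself (no canonical tRNA position numbering); the alphabet
is RNA internally, with `T` normalized to `U` (and a warning) on
input. Several distinct 9-nt windows inside the junction could in
principle leave the same 5-mer; the implementation canonically deletes
the maximal prefix (3'-retention) or maximal suffix (5'-retention),
and the test suite enumerates all six windows to confirm that every
window leaving the specified remnant produces the identical string.
The loop of the stem-loop-stem is the one weakly determined region of
the model; it is a constructor parameter (`primordial_spec(loop17 =)`)
with the literal repeat-derived sequence as the default. That default
implies an anticodon-loop sequence whose central triplet is `AAA`,
which the model stores literally: the tension between a repeat-derived
`AAA` anticodon and glycine `NCC` anticodons is a feature of the
hypothesis itself and is deliberately not resolved in code.

## Scoring sequences against the model

`segment_sequence()` maps a query tRNA onto the segmented model: an
equal-length query maps positionally; otherwise a global affine-gap
alignment (match +1, mismatch −1, gap open −4, gap extend −1 — all
exposed as parameters; no published values exist for this comparison,
so conventional unit-cost scoring was chosen) transfers segment labels.
Query length must lie within `core − 10` to `core + max_slack`. The
upper slack defaults to 8 for type I models so that a type II core
(84 nt = 75 + 9) is rejected as a probable type mismatch, and to 30
for type II models to admit long expanded V loops; both bounds are
parameters.

`identity_to_pri()` reports per-segment identity fractions and their
length-weighted mean. Model positions deleted in the query count as
non-identical; query insertions are excluded from the denominator.

`loop_homology_test()` operationalizes the anticodon-arm/T-arm
homology claim as a permutation test: the statistic is positional
identity between two equal-length segments, and the null shuffles the
positions of the second sequence, preserving composition exactly.
Position shuffling (rather than i.i.d. resampling) is the tighter null
for a claim about *positional* identity. p-values use the add-one rule
`(1 + #{null ≥ observed}) / (n_perm + 1)`, which is valid (super-uniform
under the null) at any permutation count; the suite verifies
super-uniformity empirically over 500 simulated nulls. This test is a
stand-in defined by this package, not a reproduction of the original
statistical analyses, which were published without formulas.

## The 32-cell codon–anticodon table

Anticodons are written 5'→3' as (wobble, position 2, position 3);
position 2 pairs the codon 2nd base and position 3 the codon 1st base.
At the base of code evolution the wobble position achieves only
purine/pyrimidine resolution: wobble G reads codon-3rd U/C (half A),
wobble C/U read codon-3rd G and A/G (half B), and wobble A is
represented but flagged unused, matching archaeal usage. The 64 codons
therefore collapse to 32 cells — 4 columns (position 2) × 4 rows
(position 3) × 2 halves — each covering exactly two codons. Rows and
columns are numbered 1 = A, 2 = G, 3 = U, 4 = C, reconstructed from the
published placements (Phe in row 1, Val/Ala/Asp/Gly in row 4, His at
2A, Lys at 3B).

Internally the representation is per-codon (64 entries); the 32-cell
table is a view (`cells_of()`). This makes the two genuinely mixed
cells — Ile/Met at anticodon `AU(A/G)` and STOP/Trp at `UG(A/G)` —
representable without loss.

The anticodon preference scale C>(U~G)>A maps bases to ordinals
(C = 2, U = G = 1, A = 0) at positions 2 and 3, compared
lexicographically; `rank_cells()` reports explicit tie groups because
U and G are genuinely indistinguishable under the scale.

## The sectoring simulation

The four stages of the working model are **data**, not code: the
packaged `sectoring_events.tsv` lists one record per displacement
event (stage, column, rows, half, optional explicit codons, incoming,
displaced), and alternative orderings can be simulated from an edited
copy. The shipped file encodes:

1. `columns` — from the all-Gly state, columns 1–3 go to Val, Ala,
   Asp; Gly retains column 4.
2. `split8` — columns 1, 2 and 4 cede their purine rows (third
   position A/G) to Leu, Pro and Arg; column 3 splits on the wobble
   half instead (half A Asp, half B Glu). Column 3 is the one column
   modeled at half-cell granularity, mirroring its distinct
   sectoring mechanism.
3. `post_latch_16` — once ribosomal latch closure allows single-base
   reading of position 3: Ile (column 1, row 3), Thr (2, row 3), Ser
   (2, row 1), Asn (3, 3A), His (3, 2A), Lys (3, 3B), Gln (3, 2B).
   Exact enumeration of this state gives 15 distinct amino acids; the
   historical "~16-letter" label is treated as a label only and the
   package reports the exact count.
4. `completion` — Met (codon `AUG` only, making cell 1-3B mixed), Phe
   (1, 1A), Tyr (3, 1A), stops (3, 1B and codon `UGA`), Ser and Arg
   gains in column 4 (3A and 3B, both from Gly), Cys (4, 1A), Trp
   (codon `UGG`).

Two event-file choices deserve note. The published prose places Met at
"row 4B", but the standard code and the model's own row convention put
the `AUG` cell in row 3B; the event file uses 3B. Whether Arg's
occupancy of cell 4-3B is a gain from Gly or a retained holding is
under-specified; it is encoded as a gain from Gly. Both choices are
recorded in the event file's audit trail and the final state is
asserted equal, codon for codon, to the standard genetic code.

`displacement_audit()` formalizes the claim that incumbents always
retain their more favored cells. For every (column, displaced amino
acid) pair it collects the cells ceded to later *amino acids* across
the whole trajectory and compares their maximum position-3 ordinal
with the minimum ordinal of the cells the incumbent still holds in
that column at the end. Cessions to STOP are exempt — stops are read
by proteins and sit outside anticodon preference rules — and
incumbents that ceded an entire column are skipped as vacuous. The
shipped trajectory produces zero violations; this is an assertion
about the event data, recomputed on every run, not a hard-coded
outcome.

## aaRS homology networks

Score matrices are directed (row = query, column = target), with `ND`
(not detected) and `NR` (diagonal, not reported) tokens preserved
through I/O. `ND` is treated as **absence of an edge**, never as a
zero score: a failed fold-recognition search is absence of evidence.
Symmetrization defaults to the maximum of the two directions — the
better direction is what the source tables report as the connection
strength — with the mean available for sensitivity analysis (maximum ≥
mean edge-wise, an asserted invariant).

`max_spanning_tree()` formalizes the hand-drawn strongest-connection
lineages as a maximum-weight spanning tree: Kruskal's algorithm over
edges sorted by decreasing weight with lexicographic tie-breaking on
the node pair, so equal-weight alternatives resolve identically across
runs. The tests compare its result against exhaustive enumeration of
all spanning trees on small complete graphs and against an
independently coded Prim's algorithm on both packaged fixtures.
Rooting (GlyRS-IIA for class II, ValRS-IA for class I, by convention)
only orients parent pointers for presentation; it is not an inference.
The published analysis also discounts two bacterial innovations
(LysRS-IIB, GlyRS-IID) when reading the archaeal radiation; that
judgment is available as an exclusion list (`load_matrix(exclude =)`,
CLI `--exclude`), not hard-coded.

`column_coherence()` tests whether enzymes sharing a genetic-code
column are more homologous than chance: the statistic is the mean
symmetrized score over same-column pairs with edges, and the null
permutes the column labels across the mapped enzymes (add-one
p-value, explicit seed). The packaged column maps follow the published
clade descriptions.

## The synthetic-data generator

`synth_trnaome()` emulates the radiation of a tRNAome from the
primordial type I tRNA. Each record is mutated per site (uniform
substitution over the three alternatives) and its anticodon — loop
positions 3–5 of the anticodon arm — is overwritten with an anticodon
drawn from a code state, excluding wobble A as in archaea. Records of
the same amino acid share a parent mutated at the full substitution
rate and diverge from it at half that rate, giving the two-level
relatedness (within-isoacceptor vs between) that nearest-neighbor
tests need. Indels are restricted to the D-loop and V-loop segments,
where real tRNA length variation concentrates, keeping the acceptor
and anticodon scaffolds alignable. Defaults (substitution rate 0.1,
no indels) represent moderate divergence: ancient archaeal tRNAs
retain clear primordial signal, and a 10% per-site divergence keeps
that regime while separating isoacceptor families.

`planted_tree_matrix()` emulates the structure of the printed score
tables: a uniform random labelled tree (Prüfer-decoded from the seed),
scores `base_score × decay^distance` with independent Gaussian noise
per direction, rounded to integers and floored at 1, `NR` diagonal.
Defaults (13 nodes, base 800, decay 0.6, noise sd 4) give score ranges
comparable to the class II table. With noiseless scores the planted
tree is provably the unique maximum spanning tree (direct edges always
outscore detours), so recovery experiments measure noise tolerance:
the suite checks ≥95% exact recovery over 100 seeds at noise equal to
a quarter of the smallest gap between adjacent distance classes.

What a green suite does **not** establish: the generator draws from
the stated model world (uniform substitutions, geometric score decay).
It says nothing about real archaeal tRNAomes, tRNA modifications,
structure-aware alignment, or fold-recognition score distributions;
conclusions about those require real data, which this package
deliberately does not download.

## Reproducibility conventions

Every stochastic entry point takes an explicit integer seed and
restores the caller's RNG state afterwards; identical inputs give
byte-identical outputs. CLI runs emit a JSON manifest (command,
parameters, input digests, package version, timestamp). Nearest
neighbors, best hits and spanning-tree ties all break
lexicographically so that no result depends on input order.

## Known limitations

* The precursor/deletion model is a string-level reconstruction: no
  3D geometry, U-turn modeling, base modification, or canonical tRNA
  numbering.
* Exact reproduction of every arrow of the hand-drawn lineage figures
  is not a defined computation; only quoted edge scores and
  graph-theoretic objects (spanning trees, best-hit digraphs) are
  tested.
* Published e-values for individual alignments come from external
  servers and are consumed as annotations at most, never recomputed.
* The permutation tests defined here replace, and do not reproduce,
  the original statistical analyses.
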