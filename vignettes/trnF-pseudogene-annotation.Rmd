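---
title: "Annotating tandem trnF pseudogene arrays in plastid trnL-F spacers"
author: "trnfscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating tandem trnF pseudogene arrays in plastid trnL-F spacers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trnfscan)
```

## The biological problem

The chloroplast genome of land plants is strongly conserved in gene content
and order, which is why the non-coding trnL–trnF intergenic spacer (IGS) is
such a popular phylogenetic marker. In several angiosperm lineages, however,
the phenylalanine tRNA gene (trnF, anticodon GAA) that bounds this spacer has
been duplicated repeatedly: a tandem array of one to seven decayed
*pseudogene copies* sits immediately 5' of the functional gene. Each copy is
a mosaic of fragments of the original tRNA cloverleaf — mostly the anticodon
domain (the best-conserved element), often parts of the D- and T-domains,
and essentially never the acceptor stems. Copies are typically 32–73 bp
long, begin with a short ATT(G)\_n bordering motif, and insert downstream of
the spacer's σ70-type promoter elements (−35 `TTGACA`, −10 `GAGGAT`).
Unrecognized, these arrays corrupt alignments of the spacer and therefore
phylogenies built from it; recognized, their presence/absence is itself a
rare genomic character that can delimit clades, and in Solanoideae it marks
a single-origin clade of 29 genera.

`trnfscan` turns the originally manual annotation protocol into a tested,
deterministic pipeline: a structural reference model of the trnF gene, a
scanner that locates the functional gene and segments the upstream array,
parsimony machinery that maps copy presence onto a rooted tree, and a
planted-truth simulator that makes every stage testable without any
downloads.

## The reference model

The search template is a trnF gene sequence tiled into five contiguous
domains, `ACC5 | DDOM | ANTICODON | TDOM | ACC3`, by a deterministic rule:
the anticodon window is centred on the GAA triplet (17 nt "arm" mode by
default — 5 nt stem, 7 nt loop, 5 nt stem — or a 7 nt "loop" mode, since
descriptions of the "anticodon domain" are ambiguous between the two); the
acceptor stems are the first and last 7 nt; D- and T-domains fill the gaps.
The boundaries are a conventional cloverleaf approximation — no published
coordinates exist for them — and all of them are configurable.

The packaged default (`load_reference()`) is a **synthetic** 73-nt
tRNA-Phe(GAA) template with this canonical layout, shipped as
`inst/extdata/trnF_gene_synthetic.fasta` plus a JSON sidecar of curated
domain intervals. Shipping a synthetic template rather than a database
extract keeps the package fully self-contained; a real reference (e.g. the
tobacco plastome trnF gene) can be substituted from any GenBank flat file
via `load_reference(record, span, strand)`. The synthetic template is
additionally *motif-clean by construction*: no incidental exact `ATT`+G
border motif, no promoter hexamer within one mismatch, and no second
anticodon-arm-like window occur anywhere in the gene or in any
border+domain concatenation the simulator can emit. This matters because it
makes simulated ground truth unambiguous — every border and anchor the
scanner can find in an undecayed simulated copy is a planted one — and it
is asserted by tests, not assumed.

## The scanner

`scan_sequence()` orchestrates six operations, each exported and testable
in isolation:

1. **Functional gene** (`find_functional_gene`): the full reference gene is
   fitted semi-globally (free end-gaps on the spacer) against both strands;
   a hit needs overall identity ≥ 0.90 *and* at least 5/7 exact matches in
   each acceptor-stem domain. The stem check is what separates the one
   functional gene from its stemless upstream duplicates.
2. **Anchors** (`find_anchors`): approximate occurrences of the 17-nt
   anticodon arm with edit distance ≤ 3, found by an in-package semi-global
   dynamic program. Candidates are selected greedily (fewest edits first,
   ties to the leftmost start) into a non-overlapping set. The DP and the
   selection rule are verified against an exhaustive sliding-window
   `adist` oracle, and the anchor set is provably monotone in the edit
   budget because start recovery enumerates only lengths within the
   *achieved* distance.
3. **Segmentation** (`segment_copies`): each anchor's copy starts at the
   bordering motif — an `ATT` core with ≤ 1 substitution followed by ≥ 1 G
   — found within a 40-nt lookback window. Candidates are ranked by core
   mismatches first, then proximity to the anchor: an exact `ATT(G)n`
   border beats a nearer degenerate 4-mer such as `GTTG`, which real D-arm
   sequence frequently contains. Without a border, a fixed 15-nt flank is
   used. Copy *i* ends where copy *i*+1 begins; the last copy ends at the
   functional-gene start. Lookback (40 nt) and flank (15 nt) are invented
   defaults — the original protocol determined cut points by eye — and
   configurable.
4. **Domain annotation** (`annotate_copy`): each reference domain is fitted
   into the copy; hits need identity ≥ 0.70 and are trimmed to non-overlap
   with precedence ANTICODON > DDOM > TDOM > ACC5 > ACC3, mirroring the
   observed conservation gradient. With 7-nt stems a 0.70 threshold means
   5/7 matches, so spurious stem "residues" do appear occasionally — which
   is also how the acceptor stems behave in real arrays.
5. **Simple repeats** (`detect_internal_repeats`): maximal perfect tandem
   runs (≥ 2 units) of AT, AAT, ATT and AATCC, checked against a regex
   oracle.
6. **Promoters** (`detect_promoters`): all pairings of `TTGACA` and
   `GAGGAT` (≤ 1 mismatch each) separated by 12–25 nt. The element
   sequences are fixed by observation; the spacing window is a σ70
   convention, not a published value. Promoter search runs on the region
   5' of the first copy; promoter-like pairs *inside* the array are
   reported as warnings because arrays are expected to insert strictly
   after the promoter.

Copy lengths outside [32, 73] bp raise a warning, never a rejection: the
range is an empirical observation, not a rule. Coordinates are 0-based
half-open internally and 1-based inclusive in GFF3; a reverse-strand scan
reports results on the scanned strand and `write_gff3()` maps them back to
the plus strand of the input record with strand `-`. Downstream (3') copies
are not searched by default — their existence is undocumented — but
`scan_downstream = TRUE` reports downstream anchors as warnings.

## Phylogenetic mapping

Copy numbers are binarized (> 0 → present) and bound to a rooted tree
(`character_map`; tips without states are pruned with a warning — a missing
state is *unknown*, not absent). `fitch_min_changes()` computes the exact
minimum number of binary state changes using Hartigan's generalization of
the Fitch algorithm, so multifurcating input is handled exactly; the count
is verified against exhaustive enumeration of all internal labelings and
against an independent parsimony implementation. One caveat worth spelling
out: resolving a polytomy can legitimately *decrease* the minimum count (a
star over tips 1,1,0,0 costs 2; its ((1,1),(0,0)) resolution costs 1), so
the count is a statement about the tree as given.

"Single origin" is formalized as a Fitch minimum of exactly 1.
`dollo_reconstruction()` places the single gain at the MRCA of the positive
tips and counts losses as maximal all-negative subtrees below it.
`delimit_clade()` combines both and censuses the genera of the gain clade,
where a genus is the first whitespace/underscore token of the taxon label,
passed through an explicit corrections table. The packaged survey fixture
ships the published copy-number table verbatim — including an apparent
one-letter genus misprint — and the corrections table (one entry) is
applied only where requested, keeping the printed artifact and its
biological reading separable. With the correction the clade census is 29
genera; without it, 30.

## The simulator and what it does (not) show

`generate_spacer()` builds each sequence 5'→3' as: random background —
optional promoter pair — a variable gap (optionally containing a planted
AT/AAT tandem tract) — 0–7 tandem copies — the intact functional gene — a
short tail. Each copy is a sampled domain subset in canonical order behind
an `ATT` + G-run border (run length uniform 1–4), then decayed by i.i.d.
per-site substitutions and geometric(mean 2) indels. Defaults and their
reasons:

* **Domain menu** {D+A, A+T, D+A+T}: every copy keeps the anticodon domain
  (the observed anchor of real copies) and none keeps acceptor stems
  (observed to be absent). With the shipped reference these compositions
  give copy lengths of 40–66 bp, inside the observed 32–73 bp envelope.
* **Copies abut** each other and the functional gene (linker 0 nt),
  matching the tandem-array schematic and the gene's "close 5' proximity";
  an inter-copy linker is available by configuration.
* **Rates**: substitution 0.02/site and indel 0.005/site as a mildly
  decayed default; divergence of real copies is unquantified, so these are
  tool parameters, not biological claims.
* **Background**: GC 0.32 (AT-rich plastid IGS composition), lengths 80–160
  nt (5' background), 20–60 nt (promoter–array gap), 10–30 nt (tail).
  Background chunks are rejection-sampled to contain no anticodon-arm
  match within the scanner's edit budget, so planted copies are the only
  anchors and the truth table is complete. Promoter-like hexamer pairs are
  *not* screened out of the background — they occur in real spacers too —
  so truth-checking asserts containment of the planted promoter rather
  than set equality.
* **Copy numbers** for positive taxa are uniform on 1–7 by default; the
  empirical distribution of the packaged survey is available as
  `copy_number_dist = "table1"`.
* **Trees** are seeded pure-birth; under the `single_origin` scenario the
  positive taxa are constrained to one clade, under `scattered` they are
  placed at random tips.

Everything is deterministic given the seed, byte for byte.

Because of the abutting layout and the motif-clean reference, recovery of
planted arrays at mutation rate 0 is exact by construction — the test suite
asserts copy counts *and* interval-exact boundaries for all copy numbers
0–7 across seeds. What the simulator does **not** emulate: rate
heterogeneity or any realistic substitution model, inter-copy homogenization
(gene conversion), nested or partial tandem duplication mechanisms,
alignment artifacts of real GenBank amplicons, or sequencing error. Passing
the closed loop therefore demonstrates the scanner's logic is correct under
its own model assumptions, not that real accessions will be called with the
same accuracy; on real data the manual-inspection warnings (length range,
promoter placement, missing borders) are the intended safety net.

## Problem sizes and numerical choices

The simulation studies run at sizes chosen to keep the full suite quick on
a laptop: exact-recovery checks use 80 spacers (copy numbers 0–7 × 10
seeds); the decay study uses 50-taxon datasets over 20 seeds (1 000
sequences) in the test suite and 10 datasets in the acceptance script; the
decay-monotonicity check uses 40 spacers per rate at rates 0, 0.02, 0.05
and 0.10. Aggregate copy-number recovery at 2% substitution is ~97–98%,
comfortably above the 95% property threshold; failures are single-copy
undercounts where decay has pushed an anticodon arm beyond the edit budget.

Alignment scoring is match +1 / mismatch −1 / gap open 2 / gap extend 1
over the ACGTN alphabet; all non-ACGT IUPAC codes are mapped to N, and N
matches nothing (including N), i.e. ambiguity is always counted as
mismatch. Identity is defined as exact matches divided by the *reference*
(pattern) length, so gapped fits are penalized. Anchor ties break to the
leftmost start; equal-mismatch border candidates break to the nearest;
degenerate tilings (a gene too short for its anticodon position) and
overlapping segmentations are hard errors, asserted on every scan.

## Known limitations

* The scanner assumes one functional gene per spacer; paralogous spacers
  or chimeric amplicons are out of scope.
* Borders more degenerate than one substitution in the core fall back to
  the fixed flank, which can shift a copy's 5' boundary by a few nt.
* The Dollo reconstruction conditions on a single gain; if a character
  truly arose twice, `n_gains > 1` flags it but the gain-node placement is
  then only the MRCA heuristic.
* GenBank parsing is deliberately minimal (simple and `complement()`
  locations); joined or fuzzy locations are skipped.
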