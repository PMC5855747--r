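---
title: "Comparative plastome analysis with plastomekit: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative plastome analysis with plastomekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastomekit)
```

## The analysis this package implements

Land-plant chloroplast genomes are circular molecules of 115–165 kb with a
highly conserved quadripartite layout: a large and a small single-copy
region (LSC, SSC) separated by two identical inverted repeats (IRa, IRb).
Comparative plastome studies characterise a newly assembled genome by a
standard battery of analyses: the sizes and GC content of the four regions
and of the coding/non-coding classes; the gene inventory with its
IR-duplicated subset; the position of the four single-copy/IR junctions
(J~LA~, J~SA~, J~SB~, J~LB~) relative to their flanking genes, whose
movement records IR expansion and contraction; the microsatellite (SSR)
and long-repeat landscapes; intron presence across related taxa, including
verification of intron losses by PCR with exon-anchored primers; per-gene
alignment variability for marker selection; and whole-genome dot-plots to
rule out large rearrangements.

`plastomekit` implements this battery as composable functions over a
simple annotated-genome container (`plastome_record`: one linearized
circular sequence, 1-based inclusive coordinates, plus exon-level gene
annotations). A synthetic-genome generator with a recorded truth table
stands in for sequenced accessions, so every stage of the pipeline is
testable end-to-end without downloads. The `analysis/` directory of the
source repository strings the stages together as a numbered workflow.

## Coordinate conventions

All internal coordinates are 1-based inclusive, the native convention of
R and of the Bioconductor sequence stack used for I/O; BED output is
converted to 0-based half-open at the writer, and GenBank/GFF3 emission is
1-based as those formats require. Junction coordinates are stored as
cumulative offsets — the position of the last base of each region walking
LSC → IRa → SSC → IRb — which makes them identical integers under either
convention (the canonical genome of this package has junctions at 86,315,
112,892, 131,383 and 157,960). The genome is linearized at LSC base 1;
features and IRs crossing the origin are handled by interval unwrapping
(an interval whose end exceeds the genome length continues past the
origin).

## IR detection and the quadripartite partition

`detect_ir()` anchors the sequence against its own reverse complement with
unique 21-mers. A palindromic pairing satisfies $p + q = \text{const}$ for
every paired base pair $(p, q)$, so anchors are grouped by this
anti-diagonal; the best candidates are then scanned base-by-base with a
two-pointer window that returns the longest pair of disjoint intervals
whose sequences are reverse complements within a mismatch budget
(`max_mismatch_frac`, default 0 — plastome IRs are typically identical;
ties break toward the smaller IRa start). For circular records the search
runs a second time on a half-rotated copy so an IR spanning the
linearization origin is still found. A quadratic brute-force matcher with
the same contract serves as the test oracle. `partition_from_ir()` labels
the longer inter-IR arc LSC and the shorter SSC; arcs of equal length are
refused rather than guessed.

Junction reports follow a fixed distance convention, since figure-level
sources rarely state one: for a gene ending short of a junction the
distance is the number of bases strictly between the gene end and the
junction (a gene ending exactly on the junction has distance 0); for a
gene spanning a junction the distance is the extent of the gene into the
region holding the minority of its bases. A gene running from a
single-copy region into an IR implies a mirrored fragment in the other IR;
the report names the expected partner (`psi_<gene>`) and checks whether an
annotation exists at the mirrored interval — pseudogene presence is never
inferred from sequence.

## SSR and long-repeat scanning

`find_ssrs()` reports maximal perfect tandem runs of primitive 1–6 bp
motifs at the conventional copy-number cutoffs (mono ≥ 8, di ≥ 4, tri-
through hexanucleotide ≥ 3 copies). Runs are detected at their leftmost
phase from base-level self-comparison at each period; trailing partial
copies are truncated so `end − start + 1 = copies × motif length`, and a
run reportable at two motif lengths (a homopolymer inside a longer
dinucleotide tract) is reported once, preferring the longer span.
Compound SSRs are not merged. Both IR copies are scanned; mirrored
duplicates are collapsed to one locus by default (`collapse_ir`), since
the two copies are the same sequence.

`find_long_repeats()` covers the four orientation classes — forward,
reverse, complement, palindromic — as gapless pairings with Hamming
identity ≥ 0.90 and length ≥ 30 bp. The scanner seeds with exact 7-mers
(the longest seed guaranteed to occur in a 30 bp hit carrying the 3
mismatches the identity floor allows), clusters seeds per alignment line,
applies a match-density prefilter, and enumerates candidate windows that
are maximal for their mismatch count with match-trimmed ends. Overlapping
candidates are resolved by identity dominance: when one candidate's
intervals nest inside another's, the higher-identity (tie: longer)
representative survives. This makes a verbatim 35 bp duplication come out
as exactly one hit of length 35 and identity 1.0 rather than a sloppier
extended window. Nested hits, low-complexity hits (≥ 90% one nucleotide in
either interval) and the genome-scale IR pair itself are excluded; hits
fully inside both IRs are de-duplicated to one representative. The
brute-force oracle enumerates every mismatch-flanked window on every line
and applies the same redundancy rules.

## Intron tools and in-silico PCR

Gene models carry alternating exon/intron lengths along the strand;
`intron_table()` derives intron counts, totals and the longest intron.
The trans-spliced *rps12* is flagged and its trans junction excluded from
cis intron counting. In the default synthetic inventory *rps16* carries no
intron — the configuration of the studied family, where the intron loss is
the phenomenon of interest — and intron-bearing *rps16* models are
supplied explicitly for outgroup-like taxa.

`in_silico_pcr()` finds forward-primer sites on the plus strand and
reverse-primer sites as reverse complements downstream (Biostrings
pattern matching stands behind the site search), requires the three
3′-terminal bases of each primer to match exactly whenever mismatches are
tolerated (default `max_mismatch = 0`), and emits every pairing up to a
10 kb product cap. Product length is the outer-coordinate distance,
matching gel sizing, and circular templates allow origin-spanning
products. `intron_presence()` compares annotation-derived intron counts
across taxa against a reference, distinguishing intron loss (fewer
introns) from whole-gene loss (gene absent).

## Variability statistics

For a gapped per-gene alignment, a column is conserved when all non-missing
tokens agree, and parsimony-informative when at least two states each occur
in at least two taxa; gaps and `N` are missing data throughout (they
contribute the full state set to Fitch, are not states for site
classification, and are excluded pairwise from sequence identity, which is
the mean over row pairs of identity at mutually non-missing positions —
definitions that are stated here because published tables typically do not
state them). The informative percentage is rounded half away from zero to
two decimals, the precision of the printed tables this work mirrors.

`fitch_length()` is a vectorised Fitch downward pass over bit-encoded
states on any binary `ape::phylo`. Per column $i$, with $s_i$ observed
steps, $m_i$ = (observed states − 1) the minimum conceivable and
$g_i$ = (non-missing tokens − largest state frequency) the steps on a star
tree, the indices are $CI = \sum m / \sum s$ and
$RI = (\sum g - \sum s)/(\sum g - \sum m)$, summed over variable columns
(invariant columns contribute zero to all three sums; uninformative
variable columns are included, matching common practice). $m_i \le s_i \le
g_i$ holds per column and is asserted as a property test against an
exhaustive-labelling oracle. When no tree is supplied, a neighbour-joining
topology from the p-distance matrix is built internally; full
likelihood/Bayesian inference is out of scope. `rank_genes()` orders genes
by informative percentage, keeping genes longer than 200 bp by default;
because published rankings include a 96 bp gene, the workflow also emits
the unfiltered variant.

## Dot-plot comparison

`dotplot()` reports all shared unique 21-mers in both orientations;
`detect_rearrangements()` chains anchors per diagonal (anti-diagonal for
inverted anchors) with a 2k diagonal jitter tolerance and a 1 kb
positional gap (unique-k-mer filtering leaves holes where k-mers repeat),
merges contiguous chains, and calls inverted segments of at least 5 kb as
inversions. The IRs of two collinear plastomes always cross-match in
inverted orientation; segments lying inside both genomes' IRs are excluded
from the verdict via the `exclude` argument. A planted 30 kb inversion
with 0.5% substitution noise is recovered with exact span in the bundled
workflow.

## The synthetic study system

`plastome_spec()` defaults describe the studied Celastraceae-type genome:
LSC 86,315 bp, SSC 18,491 bp, IRs 26,577 bp (total 157,960 bp), region GC
targets 35.1/31.8/42.7%, and a 112-gene inventory with 17 IR-duplicated
genes (37 tRNA, 84 protein and 8 rRNA copies) in which intron-bearing
genes carry their published exon/intron lengths (longest intron 2,495 bp
in *trnK-UUU*) and other genes carry nominal lengths typical of their
families. IRb is written as the exact reverse complement of IRa. Planted
SSRs, repeat pairs (mismatches evenly spaced in the central half so that
sub-windows carry the same error density as the whole), and primer
constructs are placed at recorded coordinates with guard bases that stop
tandem runs and repeat pairings from extending by chance, including at the
region boundaries where the IR anti-diagonal continues into the
single-copy regions.

Background screening is local rather than rejection-based: an AT-rich
158 kb random background contains accidental mononucleotide SSRs with
expectation above one, so whole-genome rejection would not converge.
Instead the generator rescans after assembly and re-samples only the
windows containing accidental SSRs or qualifying repeats (for an
accidental repeat pair, whichever copy is not inside a planted feature;
for accidents straddling a planted feature's edge, the unprotected
overhang), up to a retry cap of 1000 patches, after which residual
accidents are recorded in the truth table rather than silently ignored.
Repeat and primer constructs are themselves screened at generation so the
protected spans carry no unpatchable accidents.

`evolve_taxa()` evolves tip genomes along a user tree under an
equal-rates (Jukes–Cantor) model — per-site substitution probability
$\tfrac34(1 - e^{-\tfrac43 b r})$ on a branch of length $b$ at rate
multiplier $r$, so expected substitutions per site equal $b\,r$ — with no
indels and no rate heterogeneity across sites; a single-parameter model
suffices for the structural and counting analyses validated here and is a
stated limitation for anything rate-model-sensitive. Loss events
(intron or whole gene) are applied on the named tips as physical
deletions with coordinate shifting; per-gene alignments come from the
known homology in the ancestral frame, with lost introns gapped and
lost-gene taxa dropped, so no realignment step is needed.

What the generator does **not** emulate: indel evolution (alignments are
gap-free except planted losses), rate variation among sites and lineages,
biased base composition beyond a per-region GC target, tRNA secondary
structure, and real gene sequence content (genes are GC-matched random
background). Passing tests therefore demonstrate correctness of the
measurement machinery on genomes with known truth, not robustness to every
property of real accessions.

## Problem sizes and numerical choices

The test suite validates each scanner against its brute-force oracle on
dozens of 0.3–2.5 kb sequences and recovers planted IRs across genomes of
5–6 kb over many seeds; full-size (158 kb) genomes are exercised in the
bundled workflow and the reproduction script. These sizes were chosen so
the whole suite runs in about a minute while still covering every code
path; the oracles are quadratic or worse by design and gain nothing from
larger instances. Percentages are rounded half away from zero (1 decimal
for composition, 2 for informative percentages), matching the printed
precision of the tables the report layer reproduces; base R's
round-half-even would disagree on exact halves. All randomness flows from
explicit integer seeds; the same seed yields byte-identical genomes.

## Known limitations

* IR detection assumes one dominant IR pair; plastomes that have lost one
  IR copy return a no-IR result rather than a partition.
* Long-repeat identity is Hamming over gapless pairings; indel-containing
  repeats are not found (REPuter's edit-distance variants are not
  reproduced), a deliberate trade for determinism and an exact oracle.
* The per-gene variability panel consumes alignments; it does not build
  them. With no supplied tree the internal NJ topology is a convenience,
  not an inference.
* `in_silico_pcr()` has no thermodynamic model; primer sites are sequence
  matches only.
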