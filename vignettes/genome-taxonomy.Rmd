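---
title: "Genome-based taxonomic delineation with taxongauge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-based taxonomic delineation with taxongauge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxongauge)
```

## The problem

Public sequence databases carry bacterial assemblies under the names they
were deposited with, and for closely related genera — here *Cupriavidus*
and *Ralstonia*, two β-proteobacterial genera with a long history of
reshuffling — those names frequently disagree with what the genomes say.
`taxongauge` implements the standard whole-genome yardsticks (ANI, POCP,
tetranucleotide signatures, marker-gene phylogenetics) and a consensus
engine that turns them into explicit, flagged reclassification proposals.
This vignette documents the models, the parameters that matter, the
numerical conventions, and what the test suite does and does not
demonstrate.

## Fragment-based ANI

A query genome is cut per contig into consecutive, non-overlapping
windows of 1,020 bp (a remainder shorter than one window is discarded;
windows with more than half ambiguous bases are dropped; fragments never
span contig joins). Each fragment is aligned against both strands of the
partner genome by exact 15-mer seeding followed by Smith–Waterman
extension in a band (half-width 32) around the seeded diagonals, under
BLASTN-like scores: match +1, mismatch −2, gap open −4, gap extend −2. A
hit qualifies if its identity — matches over alignment columns, gap
columns counting as mismatches — is at least 30 % across at least 70 % of
the fragment. One-way ANI is the unweighted mean identity of qualifying
hits; the two-way value weights the two directions by hit count, which is
equivalent to averaging over the pooled hits. All parameters live in
`aniConfig()` and the seeded aligner is held to an exhaustive
Smith–Waterman oracle in the tests (identical score, identity to 1e−6,
and strand on every checked fragment).

Two conventions deserve explicit statement because the underlying
protocol leaves them open. First, hits are filtered, not trimmed: a hit
passing the 30 %/70 % gates contributes its full identity. Second, a pair
in which either direction yields zero qualifying hits is reported as
"no signal" (`NA` in the matrix) and the clustering stage refuses to
proceed rather than imputing — a missing comparison is a fact about the
data, not a zero.

Species groups come from average-linkage (UPGMA) clustering of
*d* = 1 − ANI/100, cut so that clusters are the maximal subtrees merging
*strictly below* 1 − *t*/100. The strict inequality makes the boundary
case deterministic: strains joined at exactly the threshold identity stay
separate. The threshold *t* is context-dependent (`thresholdConfig()`):
95 % by default, 90 % for the genus *Cupriavidus* and for clusters
containing the *R. pickettii* type strain, both groups being too diverse
for the standard cut-off. Raising the threshold can only split clusters,
never merge them; the tests assert this refinement property directly.

## POCP and the genus boundary

For proteomes 1 and 2, POCP = 100·(C₁+C₂)/(T₁+T₂), with Cᵢ the number of
proteins having a best hit in the partner proteome that passes E < 1e−5,
identity ≥ 40 %, and coverage of at least half the query. Alignment is
local BLOSUM62 with gap open 11 / extend 1 (via Biostrings); the E-value
uses the Karlin–Altschul form E = K·m·n·e^(−λS) with the ungapped BLOSUM62
constants K = 0.041, λ = 0.267. The approximation is deliberate — no
external BLAST is invoked — and benign at these cut-offs, because the
identity and coverage filters dominate: in the null test, shuffled decoys
exceed E = 1e−5 in ≥ 95/100 trials. Coverage is interpreted per direction
(the query is always the proteome whose C is being counted), one best hit
per query suffices, and no reciprocal-best requirement is imposed: POCP
counts conserved proteins, not ortholog pairs. Group means
(`meanPocpVsGroup()`) exclude self-comparisons. A strain whose mean POCP
reaches 60 % for exactly one genus is assigned to it; at or above 60 % for
several the call is "ambiguous", below it everywhere "neither".

## Tetranucleotide signatures

`tetraProfile()` counts all 256 4-mers in sliding windows (step 1) on the
forward strand only — matching the default of the classic composition
tools — skipping any window containing a non-ACGT character; a flag
enables strand-summed counts but is off by default. Frequencies (not
z-scores) enter a centred, unscaled PCA, and the first three component
scores are clustered by average linkage. The reference cluster letters carried by
the strain panel were assigned by eye from a 3-D plot and are not reproducible from
sequence; `clusterEmbedding()` is the deterministic surrogate (cut height
chosen by the caller, labels A, B, … by decreasing size, ties by
first-seen order), while the packaged evidence table keeps those
letters as reference data.

## Marker-gene phylogenetics

Marker alignments arrive pre-aligned; alignment itself is upstream of the
package, and the simulator emits already-aligned (gapless) data. Columns
containing any gap or missing-data symbol (`-`, `.`, `N`, `X`) in any row
are deleted (complete deletion), the operation being idempotent. Genes
concatenate in a fixed order with per-gene lengths recorded; the
four-marker MLSA fixture (1,278 + 2,571 + 822 + 1,662 = 6,333 bp)
exercises the bookkeeping. Distances are p or JC69
(−¾·ln(1 − 4p/3), defined only for p < 0.75 — a pair at or beyond that
bound is a named error, not a silent `NaN`); trees come from canonical NJ
(negative branches clamped to zero, with a message) or UPGMA; supports
from column bootstrap, deterministic under a seed. Maximum-likelihood
estimation is intentionally out of scope: genus- and species-level clade
membership is robust to the distance surrogate here, and disagreements
between methods surface as conflict flags rather than being hidden.
`percentIdentity()` compares only columns where both rows carry an
unambiguous base, which is the convention behind reported 16S similarity
percentages.

## The consensus decision engine

The engine formalises reasoning that taxonomists usually apply
narratively. Its precedence is fixed: POCP names the genus; ANI names the
species; phylotype overrides inside the *R. solanacearum* species
complex; conflicts are flagged, never dropped.

The species step needs one non-obvious construction. A cluster "contains
the type strain of species X" is decisive when a type strain was
sequenced, but many species in a real panel have none. The engine
therefore *anchors* every named species to exactly one ANI cluster: the
type strain's cluster when available, otherwise the cluster holding the
plurality of the strains currently bearing that name (ties resolved to
the first-listed strain's cluster). A strain keeps its species when its
own cluster anchors it; it adopts its cluster's anchored species when its
tetranucleotide cluster matches that species' modal one (the TNA gate
prevents adoptions that the genome signature contradicts); a strain whose
cluster anchors nothing of its genus — including one separated from the
cluster anchoring its current name — becomes "genus sp.". Strains in
singleton ANI clusters may instead borrow a species carried by a strict
majority of their TNA cluster, which is how isolated genomes whose
signature sits squarely inside a species cloud get resolved. Phylotypes,
where recorded, map I/III → *R. pseudosolanacearum*, II →
*R. solanacearum*, IV → *R. syzygii*. Decisions depend only on the panel
evidence, not on row order, and the per-method flags report
agree/conflict/unavailable against the final proposal, with ANI taking
precedence when methods disagree.

The packaged evidence table records the curated 150-strain reference panel
(46 *Cupriavidus*, 104 *Ralstonia*). One transcription choice matters:
strains of the species complex whose phylotype-based renaming had already
been proposed in earlier literature are recorded under that accepted name
rather than their lagging database label, because the analysis proposes
only *new* changes; the fixture header documents the affected strains. On
this table the engine changes 41 strains, and the acceptance script
recomputes that number end to end.

## Motif scanning and COG comparisons

`scanMotif()` reports every window, on both strands, violating the IUPAC
consensus in at most `max_mismatches` positions. A genome `N` matches
only the `N` class — an ambiguous base is not free evidence for a
specific one. Coordinates are 0-based half-open on the forward strand
(the single coordinate convention used throughout the package), all
overlapping hits are reported, and the scanner is held to a per-window
brute-force oracle in the tests. The built-in patterns are the DnaA box
`TTWTNCACA` (≤ 1 mismatch, as classically required) and the RepA
(`CGCWGAWWYVGGTWCGS`) and TrfA (`VHGCCCCYCAWGTGTCA`) iterons; the iteron
allowance of ≤ 2 mismatches is a package default, exposed in
`motifPattern()`, since the sources state no tolerance for them. Whole
replicons are scanned; restricting to a window around a replication
origin is left to the caller.

Per-replicon COG comparisons test one 2×2 table per category (in-category
vs not, replicon A vs B) with two-sided Fisher's exact test
(minimum-likelihood rule; a zero-margin table is p = 1 by convention) and
adjust by Benjamini–Hochberg within the replicon pair — the FDR family is
the pair, matching how such figures are starred per comparison. Counts
are protein-category assignments, so a multi-category protein contributes
once per category.

## The synthetic-data generator

The simulator provides the study conditions at desk scale: i.i.d. ancestor
genomes with controlled GC; Jukes–Cantor substitution (uniform choice
among the three alternatives) so that a copy evolved at rate r has
expected ungapped identity 1 − r, making planted ANI analytic; optional
geometric indels, off by default for calibration fixtures; clade panels
whose within/between identities are planted through JC additivity;
proteome pairs with a planted shared-ortholog fraction (the planted POCP);
marker alignments evolved site-wise along a known tree; and motif
plantings with exact coordinates. Every generator returns its ground
truth alongside the data and is bit-reproducible given a seed; no test
reads truth out of the data itself.

What the simulator does not emulate bounds what the tests show:
rearrangement, horizontal transfer, repeat content, composition bias
beyond GC, and assembly artefacts are all absent. Passing the planted
recovery suites demonstrates that the implementations compute their
definitions correctly and recover clean planted structure — not that the
biological thresholds (90/95 % ANI, 60 % POCP) are themselves optimal for
any particular genus pair.

## Problem sizes and numerical conventions

The test suite runs everything at deliberately modest sizes: ANI
calibration on a 110-kb pair (107 fragments, recovering 95.0 ± 0.5 % at
substitution rate 0.05, and 100·(1 − r) across r = 0.01–0.15), oracle
equivalence on ≤ 12-kb genomes, the end-to-end two-genus panel on eight
30-kb genomes with 20-protein proteomes, and motif oracles on ≤ 10-kb
sequences. These sizes were chosen so the full suite completes in about
two minutes on one core while still leaving every statistical tolerance
comfortably wide of its simulation noise.

Conventions, stated once: sequence comparisons are case-insensitive and
soft-masking is ignored; ambiguity codes count toward length but not GC;
all coordinates are 0-based half-open with strand as `+`/`−`; cluster and
component labelling is deterministic (size-descending, first-seen
tie-break); every stochastic routine takes an explicit seed and restores
the caller's RNG state.

## Limitations

ANI here is alignment-based and intended for genome pairs above roughly
70 % identity; unrelated genomes correctly return "no signal" rather than
a number. The E-value model is an approximation (documented above), the
ML trees of the original analyses are replaced by distance surrogates,
and the agreement flags approximate judgments that were partly
qualitative in the source material — rows where a human weighed evidence
loosely may flag differently. The decision engine's anchoring rule is a
formalisation choice; it reproduces the reference panel's outcome exactly, but
other defensible rules exist and the engine's inputs are plain data
frames precisely so alternatives can be tried.
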