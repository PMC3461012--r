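---
title: "Detecting structural variants from large-insert DNA-PET libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting structural variants from large-insert DNA-PET libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petsv)
```

## The method

DNA paired-end-tag (PET) sequencing reads only the two short terminal tags
of size-selected genomic DNA fragments (here 25 bp tags of 1 kb, 10 kb or
20 kb inserts). After both tags of a fragment are mapped to the reference,
the *mapping pattern* of the pair is a readout of genome structure: a pair
that maps to one chromosome, on the expected strand(s), in correct
5'-to-3' order, and with an outer-coordinate span inside the library's
size-selection range is **concordant** (cPET); any violation makes it
**discordant** (dPET) and a candidate breakage/fusion signal. Span bounds
are inclusive, and the span is measured between the outermost mapped
coordinates of the two tags — the fragment length in reference space. The
orientation convention is configurable; the default is the SOLiD mate-pair
convention (both tags on one strand, order reversed on `-`), with an
`"fr"` option for forward/reverse paired-end chemistry.

Because chimeric ligation during circularisation produces spurious dPETs,
single discordant pairs are never trusted. dPETs spanning the same fusion
point must co-**cluster**: two dPETs join when they share the chromosome
pair and strand pair and the coordinate hull of their 5' tags, and
likewise of their 3' tags, fits within one maximum insert length (two
fragments spanning one fusion point can differ by at most one fragment
length on each side). Clustering is the transitive closure (single
linkage) of this relation, so it is order-independent; clusters below a
count cutoff (default 3) are discarded as noise. The genomic regions
covered by the member tags are the 5' and 3' **anchors**, and the
predicted breakpoints are the anchor edges nearest the fusion: reading a
fragment 5' to 3', the 5' anchor runs *into* the fusion (so its inner
edge is the reading-direction end) while the 3' anchor runs *out of* it
(its inner edge is the reading-direction start). A single-member cluster
therefore predicts the PET's inner tag edges.

### SV signatures

Single clusters identify one-junction events by pattern: a **deletion**
when orientation and order are concordant but the anchor hull exceeds the
span bound (the hull, not the breakpoint distance, carries the
discordance — a 3 kb deletion seen by a 1 kb library has breakpoints only
3 kb apart while every member span exceeds the bound); a **tandem
duplication** when the order is 3'-to-5'; an **unpaired inversion** when
the strands disagree; an **isolated translocation** when the chromosomes
differ. A consequence of the deletion rule is that deletions smaller than
the concordant span bound are invisible to that library — which is
exactly why short-insert libraries find sub-5 kb deletions that
large-insert libraries miss.

Two-junction events are identified by two closely positioned clusters
(pairing window = one maximum insert, since each flanking fusion point is
localised within a fragment length):

* **inversion** — two opposite-orientation clusters whose anchors
  coincide side-for-side at both breakpoints;
* **balanced translocation** — a reciprocal inter-chromosomal pair whose
  anchors coincide cross-side on both chromosomes;
* **insertion** — two clusters sharing exactly one locus cross-side (the
  target point), with the far anchors delimiting the inserted segment on
  the source chromosome.

Insertions split into eight sub-types: intra-chromosomal direct/inverted
× forward/backward (1–4), the deletion-plus variants (5–6) in which the
source copy is lost, and inter-chromosomal direct/inverted (7–8).
Forward/backward has no meaning across chromosomes — there is no shared
axis — so the inter-chromosomal signatures collapse into two sub-types.
Pairing is greedy by descending combined cluster count, with ties broken
by summed anchor distance, which makes the result deterministic and
invariant to input order; unpaired clusters fall back to single-cluster
calls.

When a physical-coverage track is available, insertion candidates must
also be copy-number consistent: the target flanks must be intact, and the
source segment must be either *gained* (copy-and-paste raises it above
baseline) or flanked by *lost* margins (deletion-plus-insertion). This
gate matters: the three clusters of a deletion-plus-insertion admit a
false alternative pairing (the deletion junction combined with one
insertion junction mimics a backward insertion of the intervening
segment) that is geometrically valid and only copy number can reject.
Note that an *exact* cut-and-paste leaves no interior coverage gap at all
— tags of the moved copy still map to the source coordinates — so
sub-types 5–6 are defined by coverage loss in the margins around the
re-inserted segment. Without a coverage track, such events are reported
as sub-types 1/3 with a `subtype_without_coverage` caveat.

### Superclusters: isolated versus complex

Densely rearranged regions (amplicons, chromothripsis-like loci) produce
interleaved clusters whose individual calls should not be interpreted as
simple events. Each anchor is extended by one maximum insert on both
sides; clusters whose extended windows overlap anywhere on the same
chromosome (either anchor may mediate the join; touching counts) form
**superclusters** — connected components of the window-overlap graph. SVs
whose clusters all sit in superclusters of count ≤ 3 are *isolated*;
everything else is *complex*.

### Comparing insert sizes

To match calls between libraries, each isolated call of the larger-insert
library extends its anchors one-sidedly *toward* the breakpoints by its
own maximum insert; a same-type call from the other library whose
breakpoints fall into all windows is *common* (nearest by summed distance
on ties). Because the comparison is asymmetric in confidence, the other
library may contribute low-count (size 2) clusters for matching, while
unmatched large-insert calls must meet a raised count cutoff (6 instead
of 3) before being called library-specific; unmatched calls below it are
set aside as low confidence. Breakpoint **resolution** is the distance in
bp between a predicted and a true breakpoint (validated or simulated);
the contingency of resolution > 1.5 kb against breakpoint class is
tested with an exact probability computed by full enumeration of all
tables with the observed margins (cross-checked against
`stats::fisher.test` in the tests).

### Copy number and amplicon reconstruction

Physical (clone) coverage — concordant fragments overlapping a bin —
estimates copy number after dividing by the genome-wide median depth and
scaling by the baseline ploidy (median, not mean, so focal amplicons do
not inflate the baseline). The reference genome is segmented into
**contigs** at every predicted breakpoint and at the boundaries of
zero-coverage runs (a run must span a full bin, guarding against binning
artifacts). Consecutive contigs are connected by a *reference edge* when
at least one concordant fragment straddles their junction; clusters
connect contigs with *dPET edges* weighted by cluster size, the fused
contig end (head/tail) recorded from the anchor strands.

Amplicon graphs grow by fusion-point-guided concatenation: seed at the
heaviest unused dPET edge (its two contigs enter unconditionally), then
repeatedly add neighbours over both edge kinds as long as they are
amplified, until a fixpoint; mark traversed dPET edges used; repeat on
the remaining edges; keep only graphs with more than two contigs.
"Amplified" means nearest-integer copy number strictly greater than 2
(tunable for non-diploid genomes): the integer call is essential because
the continuous estimate scatters around the true copy number, and a strict
`> 2` on raw values would flip on baseline noise. Equal-weight seed ties
go to the lowest contig coordinates. Reference-edge traversal requires
only that the edge exists (its cPET support was already established when
the edge was built).

## The simulator

The simulator is coordinate-level: it never generates nucleotide
sequences because the analysis chain begins at mapped tags. A genome plan
holds chromosome lengths, masked intervals, and — after planting —
the donor genome as an ordered list of reference segments per donor
chromosome, with every fusion point recorded analytically at base-pair
precision together with the call type and sub-type it should produce.
Fragments are drawn uniformly along the donor with truncated-normal
lengths — presets (1000, 100), (10000, 1000), (20000, 2000) bp,
reflecting tight unimodal gel size selections whose spread scales with
the insert — and each fragment's terminal tags are mapped back through
the segment map. Each fragment is reported in its donor-forward
orientation; the mirror-strand reading of the same fragment carries no
additional information and is collapsed, as pairing pipelines effectively
do. A tag crossing a segment junction or overlapping a masked interval is
unmappable and drops its PET — the same total loss real pipelines impose
on ambiguous repeat mappings. Chimeric ligation joins the 5' tag of one
fragment to the 3' tag of an independent one at a configurable rate
(default 1%), and PCR duplicates re-emit records at a configurable rate
(default 2%). All draws are governed by one explicit seed.

What the simulator does *not* emulate: sequencing errors and mapping
mismatches, non-uniform fragmentation and GC bias, subclonal mixtures and
ploidy heterogeneity, and partially mappable repeats (masking is all or
nothing). Passing benchmarks therefore demonstrates the correctness of
the detection logic under clean mapping, not robustness to alignment
artifacts.

### The standard study

The built-in study (`sim_study_plan()`) uses a 50 Mb genome — five 9 Mb
chromosomes plus a 5 Mb contrast chromosome — sized so a full two-library
benchmark runs in minutes on one core while every event class still
appears several times. Thirty panel events cover the six base SV types
and all eight insertion sub-types. Event geometry follows from the
detection limits: deletions of 30–500 kb (above the 10 kb library's
20 kb span bound), inserted segments of 80 kb (so the two far anchors of
an insertion, each up to 20 kb long, cannot sit within one pairing window
of each other and masquerade as an inversion or translocation),
insertion distances of 150 kb and up, and events spaced hundreds of kb
apart so superclustering leaves them isolated. Deletion-plus-insertions
carry 25 kb co-deleted margins — wider than the 20 kb pairing window, so
the source-deletion cluster cannot pair with the insertion clusters.
Unpaired inversions are planted as terminal fold-backs, the one geometry
that yields exactly one inversion-type fusion. The contrast chromosome
carries three small deletions (2.5/3/4 kb — above the 1 kb library's
3 kb span bound once a fragment length is added, below the 10 kb
library's) and one 50 kb deletion whose breakpoints are flanked by
1.5 kb masked tracts that 1 kb fragments cannot reach across.

Coverages follow the study design the package benchmarks emulate: 60×
physical for the 10 kb library and 8× for the 1 kb library (the same
tag count yields roughly tenfold more physical coverage at tenfold the
insert). At 8×, the number of fragments spanning a given junction is
Poisson with mean ≈ 7.6, so an individual small deletion falls below the
3-cluster cutoff in a few percent of libraries; the small-deletion
contrast is accordingly scored on the set, not on each event.

The amplicon study (`sim_amplicon_plan()`) plants a dominant two-segment
derivative chromosome in 20 copies and a satellite derivative in 2
copies across three chromosomes, so the dominant fusion's cluster is
about ten times heavier than the satellites and the first-grown amplicon
graph must seed there and collect the amplified segments of all three
chromosomes.

## Numerical and design choices

* Coordinates are 0-based half-open everywhere; the readers accept
  1-based input via a flag.
* The span definition (outer-coordinate distance) is an explicit choice;
  inner-coordinate spans differ by two tag lengths and can be emulated by
  adjusting the span bounds.
* Span bounds, co-clustering windows and supercluster overlap are all
  inclusive (touching counts): window edges are already slack, and
  closed intervals keep the partition properties exact.
* The minimum concordant span defaults to 0 — size selection implies a
  practical minimum, but only the maximum is part of the concordance
  definition.
* The co-clustering distance, the pairing window, the supercluster
  extension and the comparison extension all default to the library's
  maximum concordant span; each is independently overridable.
* Deduplication keys on the exact coordinate tuple of both tags, never
  on read content.
* Down-sampling retains each PET independently with probability
  `required/total` (binomial count, not an exact subset), reproducibly
  under a fixed seed.
* The raised count cutoff for library-specific calls (6) is applied
  uniformly to the reference library, not per SV type.
* A cluster whose pattern matches concordance cannot arise from genuine
  dPETs and raises an error rather than a silent drop.
* Exact association probabilities sum hypergeometric masses over all
  margin-fixed tables no more probable than the observed one (the
  classical two-sided convention), with a 1e-7 relative slack on the
  comparison to absorb floating-point ties.

## Known limitations

* Breakpoints are localised to anchor edges; there is no split-read or
  assembly refinement, so resolution is bounded by tag spacing near the
  fusion (median ≈ 100–150 bp at 60× physical coverage in the standard
  study).
* Inter-chromosomal insertions of segments shorter than the pairing
  window are indistinguishable from reciprocal translocations by pattern
  alone, and inverted insertions closer to their source than the window
  can mimic inversions; the copy-number gate resolves most but not all
  such cases.
* An exact cut-and-paste (no co-deleted margin) cannot be separated from
  a copy-and-paste plus coincidental pairing by coverage; with a track
  supplied, such candidates are rejected rather than guessed.
* The amplicon grower reconstructs graph membership, not the donor path
  through the amplicon: no Eulerian traversal is attempted.
* Complex regions are flagged via supercluster count, not interpreted;
  calls inside them keep their pattern-based type labels.
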