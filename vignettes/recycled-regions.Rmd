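---
title: "Recycled regions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recycled regions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrgenesis)
```

## The evolutionary trap

After the whole genome duplication (WGD) at the base of the teleost fish
lineage, roughly 75% of duplicated genes lost one copy.  The decaying copy
normally drifts beyond recognition, but occasionally it is "recycled": the
ancestrally coding sequence acquires a de novo regulatory function and is
retained under selection for that new function.  Such a **recycled region
(RR)** is special because its history is legible: it still aligns to the
intact coding ortholog in other lineages (human, shark), yet its own
reading frame is demonstrably broken.  The ancestral coding function acts
as an evolutionary trap that lets us identify the orthologs of a
lineage-specific enhancer — the prerequisite for showing that the enhancer
arose de novo rather than diverging from an older one.

An RR candidate must therefore satisfy three criteria: (1) it lies in the
duplicate locus that *lost* the gene, with conserved synteny tying it to
that locus; (2) it is alignable to part of the coding ortholog while
showing no evidence of coding function (in-frame stop codons or
frameshifts); and (3) for the biology pursued here — embryonic enhancers —
it is flanked by at least one gene with a developmental Gene Ontology
annotation, the putative regulatory target.

## The discovery funnel

`run_funnel()` turns those criteria into an ordered filter cascade over
exon-to-genome local alignment hits:

1. **Exon loading** — reference exons shorter than 20 bp are excluded
   (below that length local alignment seeds are meaningless).
2. **Mapping** — each exon is aligned to the target genome on both strands
   by the internal seeded aligner: exact affine-gap local dynamic
   programming (match 5, mismatch −4, gap open 12, extension 3) on windows
   anchored by 12-mer seed matches.  The default score threshold is 0.5 ×
   the exon's maximum attainable score, because absolute local-alignment
   scores only make sense relative to a scoring scheme.  A 12-column BLAST
   tabular file can replace this stage (`load_blast_hits()`), with the
   score threshold supplied by the user since bit scores live on a
   different scale.
3. **Fusion** — hits of one exon within 1 kb of each other are merged into
   one putative regulatory unit (single linkage, boundary inclusive;
   strand is ignored and recorded as `"mixed"` when members disagree).
4. **Ortholog presence** — exons of genes without an annotated target
   ortholog are removed: without an ortholog the duplicate-locus logic
   below has no anchor.
5. **Ortholog proximity** — hits within 2 Mb of the source gene's ortholog
   locus (same contig; gap between intervals) are removed: those are the
   *retained* coding copy and its surroundings, not the gene-lost locus.
   Hits on other contigs count as infinitely distant and are kept.
6. **Exon/EST overlap** — any hit overlapping an annotated exon or EST by
   at least 1 bp is removed; under half-open coordinates, intervals that
   merely touch do not overlap.
7. **Synteny** — developmental genes within 300 kb of the source exon on
   the reference are mapped to their target orthologs; a hit is retained
   iff at least one such ortholog lies within 100 kb with at most five
   annotated genes in between.  Afterwards, if more than one hit of the
   same source gene falls within a 300 kb span, all hits of that gene are
   discarded — a guard against unannotated paralogs.  The distance metric
   (minimum gap between intervals, 0 when overlapping) and the
   strictly-between definition of "intervening" are implementation
   choices; the thresholds themselves are the published ones.
8. **Developmental flank** — the nearest annotated gene on each side of
   the hit (within the synteny window) must include one whose GO
   annotation intersects the developmental closure: the four roots
   GO:0045165, GO:0032502, GO:0030528, GO:0003700 plus all `is_a`/
   `part_of` descendants.
9. **Frame disruption** — the hit region is translated in all six frames
   and each translation locally aligned (BLOSUM62, gap open 10, extension
   0.5) to the source exon's peptide.  The region is *intact* — and
   discarded, since it may simply be an unannotated exon — iff some single
   frame is stop free and covers at least 95% of the region.  "The entire
   region" is operationalised as a coverage fraction (default 0.95) so the
   boundary is explicit and testable.

The funnel report records input/output counts and dropped hits per stage;
from fusion onward the counts are monotone and each stage consumes exactly
the survivors of the previous one.

### Coordinate scale

All thresholds are held at their literal published scale (1 kb / 100 kb /
300 kb / 2 Mb).  The scenario generator likewise lays out its contigs at
that scale by default.  `genome_scale_divisor` divides both the generated
distances and (through `funnel_config()`) every distance threshold, so the
same comparison logic can be exercised on smaller coordinates; the package
defaults keep divisor 1 and desk-scale contigs of tens to hundreds of kb.

## The synthetic scenario generator

No accessions accompany the original screen, so validation rests on
`generate_scenario()`: fully specified toy genomes in which the truth is
known by construction.  Per scenario gene it emits

* a reference contig: developmental flanking gene (left), single-exon
  coding gene (60 codons by default), non-developmental flanking gene
  (right), spaced by 5 kb intergenic runs;
* a retained-duplicate contig (the coding paralog, evolved under
  protein-level constraint, 20 accepted synonymous substitutions);
* a gene-lost contig carrying the RR relic: the exon degraded at 8%
  substitutions per site with two in-frame stop codons planted at uniform
  codon positions excluding the first and last three codons (so fused-hit
  boundaries are not confounded).  Substitutions that would create an
  extra in-frame stop are redirected to a non-stop base, keeping the stop
  count exactly at its configured value — that is what makes the truth
  records exact.  The default indel rate is 0 for the same reason: frame
  disruption in the bundles comes from stops alone, and indel handling is
  exercised directly in the unit tests.

Each requested decoy class adds one scenario violating exactly its filter:
a source gene missing from the orthology map; a relic placed 50 kb from
the retained ortholog on the same contig; an EST annotated on top of the
relic; a relic 150 kb from its developmental neighbours; a relic whose
nearest flanking genes are non-developmental (the developmental pair
pushed one gene further out); and a relic degraded without stops, which
survives everything until the frame assessment calls it intact.

The bundle also carries per-gene outgroup sequences (human = the exon;
mouse, chicken, frog, shark under protein-level constraint with 6/10/14/18
accepted substitutions; the medaka coding paralog; and three teleost RR
orthologs derived from the relic with a few additional substitutions that
spare the planted stop codons and motif).  Because all of these evolve by
substitution only, they are equal length and form a trivially exact
alignment — deliberate, so that alignment-column bookkeeping in the TFBS
module is tested against exact expectations rather than against an
aligner's output.  One synthetic PFM consensus (drawn from A/C/G only, so
it can never spell a stop codon) is substituted into the teleost RR
sequences at a position clear of the planted stops: the planted
teleost-specific binding site.

Everything is drawn from a single RNG stream seeded by `config$seed`, in a
fixed documented order (PFM set, then scenarios), which makes bundles
byte-reproducible — `write_scenario_bundle()` emits FASTA/GFF3/TSV/OBO/
Newick/PFM/JSON files whose bytes depend only on the configuration.

**What the generator does not emulate:** chromosome-scale genomes, repeat
content and masking artefacts, transposable elements, real intron/exon
structure (flank genes have two exons, source genes one), EST noise,
annotation errors, alignment uncertainty in deep-time comparisons, or
rate variation across sites and lineages.  Mutation rates and divergence
counts are free parameters chosen to produce alignable relics (~15–20%
diverged), not calibrated estimates of 450 My of evolution.  A green test
suite therefore demonstrates that the *logic* of every filter and
statistic is correct, not that the pipeline's sensitivity on real genomes
matches the original screen.

## Evolutionary diagnostics

`identity_profile()` contrasts nucleotide identity with amino-acid
similarity relative to the reference exon.  Similarity means a positive
BLOSUM62 score for the aligned codon pair, translated in the reference
frame.  Two denominators are supported — the alignable reference length
(default) and the shorter of the two sequences — because both conventions
are in circulation; results state which was used.  A coding sequence
shows AA similarity ≥ NT identity (synonymous changes are invisible in
protein space); an RR shows the reverse, the signature of selection acting
at the nucleotide rather than the protein level.

`compute_kaks()` implements Nei–Gojobori (1986) counting: synonymous site
fractions per codon position (changes to stop codons count as
nonsynonymous), site counts averaged over both sequences, substitution
counts averaged with equal weight over all mutational pathways of
multi-hit codons (pathways through stop codons are excluded unless all
are blocked), and the Jukes–Cantor correction applied to both proportions.
Degenerate cases carry explicit sentinels: `undefined_no_sites` (identical
sequences), `infinite_ks_zero` (nonsynonymous change without synonymous
change), `saturated` (a proportion ≥ 3/4, where the correction is
undefined — unavoidable for very short pairs).  A maximum-likelihood
codon-model estimate is deliberately out of scope; NG86 is transparent,
fast, and checkable against an exhaustive pathway-enumeration oracle,
which the test suite does on all 61 × 61 sense-codon pairs to 1e-9.
Numerical agreement with ML-based estimates on real data is not claimed.

Indels and stop codons are stripped before Ka/Ks
(`strip_indels_and_stops()`): reference codons touching a gap or
interrupted by an insertion are dropped whole, as are codons that are
stops in either sequence, and the removal counts are reported — for an RR
the removed stop count *is* the frame-disruption evidence.

## TFBS analysis

PWMs carry a background-distributed pseudocount of 0.8 (a common
convention; the counts themselves decide little at this information
content) and are scored as log2 odds against a uniform background.  The
relative score of a window is `(raw − min) / (max − min)` over the
matrix's attainable range, and the default threshold is 0.8 — the usual
"80% relative profile score".  Scanning covers both strands; IUPAC
ambiguity codes score as the best compatible base, so a hit on an
ambiguous sequence means *some* disambiguation reaches the threshold.

The ancestral sequence is reconstructed by Fitch parsimony — the
post-order intersection/union pass *and* the pre-order final-state pass.
The second pass matters: preliminary Fitch sets at nodes above the teleost
clade always contain the teleost state, so with optimistic ambiguity
scoring no site could ever be called absent from the ancestor.  The
final-state pass lets the outgroup resolve internal nodes (shark agreeing
with the tetrapods pulls the bony-vertebrate ancestor to their state),
which restores the intended semantics of "absent from the predicted
ancestral reconstruction".  The pipeline reconstructs at the labelled
`bony` node — the last common ancestor of bony vertebrates, immediately
preceding the teleost WGD.  Reconstruction is deterministic; ties surface
as IUPAC codes rather than arbitrary choices.  This parsimony approach
replaces a probabilistic reconstruction: it is exactly checkable against
brute-force minimisation over all labelings (done for every rooted
topology with up to six leaves in the tests), at the cost of ignoring
branch lengths.

A binding site is **teleost specific** when a hit with the same matrix
overlaps the same alignment columns in *every* teleost sequence (a
configurable "any" mode relaxes this) and no non-teleost sequence nor the
ancestor has such a hit.  Hits are compared in alignment-column
coordinates so species with different indel histories remain comparable.

`s200()` summarises binding-site density as sites per 200 bp, and
`regulatory_potential()` is the overlap coefficient (sum of bin-wise
minimum proportions, in percent) between two S200 histograms, with 1.0
site/200 bp bins from zero by default.  Bin-based overlap was chosen over
kernel density for exact testability; the coefficient is symmetric and
bounded in [0, 100].

## Numerical choices and degenerate inputs

* Alignment traceback (global and local) is deterministic via the DP
  implementation's fixed preference order, so repeated runs are
  byte-identical.
* Empty inputs degrade explicitly: an empty hit set flows through the
  funnel as zero counts; an empty annotation is a warning plus empty
  result; malformed tabular rows report their line number; an exon
  interval outside its contig names the offending record.
* Uninformative (flat) PFMs have an empty score range and are rejected at
  load time with a warning.
* Stripping that leaves fewer than three codons is an error rather than a
  silent near-empty Ka/Ks.

## Problem sizes

The shipped tests and the acceptance script run, per invocation: 20
scenario bundles (3 planted RRs + 6 decoys each, ~1 Mb of genome per
bundle) through the full funnel; 200 paired evolution replicates for the
selection-signature checks; all 3,721 sense-codon pairs against the Ka/Ks
oracle; 50 random sequence/PWM scans against per-position rescoring; all
1,065 rooted topologies on 4–6 leaves against exhaustive parsimony
minimisation; and two complete pipeline runs compared byte for byte.
These sizes exercise every code path while keeping a full run in the
minutes range on one CPU.

## Limitations

The funnel's absolute sensitivity and specificity on real genomes depend
on alignment tools, annotation quality and assembly contiguity that the
synthetic bundles idealise.  NG86 underestimates rate ratios under strong
transition/transversion bias; the parsimony ancestor ignores branch
lengths; PWM hit counts depend on the matrix collection supplied.  The
transfer of candidates between two target genomes (stickleback to medaka
in the original screen) is not implemented.
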