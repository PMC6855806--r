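---
title: "Drop-in knock-in design: model, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drop-in knock-in design: model, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropinDesign)
```

This vignette documents the scientific model behind `dropinDesign`, the
conventions and tunable parameters, the decisions taken where the design
space was genuinely open, and the limits of what the synthetic fixtures can
demonstrate.

## The procedure being modeled

The package implements the design side of a "drop-in" knock-in workflow:
a swappable integration cassette (SIC) is inserted by CRISPR-Cas9
homology-directed repair into a **coding intron** of a target gene, using
short (100-nt) homology arms rather than the traditional 0.5-1 kb arms.
Three donor classes are supported, differing in how the donor molecule is
produced:

* **ssDNA drop-in donors** are made by a single PCR in which gene-specific
  100-nt homology arms ride along as 5' overhangs on universal primers
  (26-nt forward / 24-nt reverse priming segments shared by all genes), so
  no cloning step is needed. One primer is 5'-phosphorylated; lambda
  exonuclease, a 5'-to-3' nuclease preferring phosphorylated 5' ends, then
  degrades that strand, leaving the other as the single-stranded donor.
* **Synthesized dsDNA drop-in donors** embed
  `gRNA1 target - LHA - cassette - RHA - gRNA1 target` in a cloning
  plasmid. gRNA1 is a guide with no target in the host genome, so
  co-injected Cas9 linearizes the plasmid in vivo, releasing the donor.
* **Subcloned plasmid donors** handle cassettes too large for economical
  synthesis: a `gRNA1 - LHA - RE1 - stuffer - RE2 - RHA - gRNA1` fragment
  is synthesized once per gene, and the large cassette is moved in by a
  single directional restriction subcloning step.

The edited allele, the gene-trap or protein-trap transcript it produces,
and the in/out genotyping PCR are simulated so every design can be checked
before anything is ordered.

## Coordinate conventions

Feature intervals (exons, CDS, introns, arms, primer sites) are 1-based
closed, following the IRanges/Bioconductor convention used by every
container the package touches. Cut sites and insertion points are
**interbase**: `cut_site = k` means the cut falls between reference
positions `k` and `k + 1`. Interbase cut coordinates make the arm
arithmetic exact and convention-free: the left arm is positions
`[k - lha_len + 1, k]`, the right arm `[k + 1, k + rha_len]`, and the two
representations agree on every number the cut-site rule produces (a
+-strand guide whose 23-mer footprint starts at 0-based offset `w` in a
window cuts at interbase `w + 17`).

## The cut-site and arm rule

SpCas9 cuts bluntly 3 nt 5' of the NGG PAM, i.e. between protospacer
positions 17 and 18. The left homology arm is therefore the `lha_len` nt
ending exactly 3 nt before the PAM of a +-strand guide. The published
description of the right arm ("97 nt downstream of that region") conflicts
with the repeatedly stated "two 100 nt homology arms" and with the printed
donor totals (1442 = 1242 + 2 x 100); we implement **symmetric arms
abutting the blunt cut (100/100 default)** as the only reading consistent
with all stated lengths, and expose `lha_len`/`rha_len` so the literal
100/97 reading is a configuration, not a code change. Asymmetric-arm
strategies get no special logic for the same reason: they are untested in
the source workflow.

For minus-strand genes both arms are extracted on the forward strand and
then reverse-complemented and swapped, so the LHA is always
transcriptionally upstream. An `N` anywhere in an arm disqualifies the site
outright (an unknown base in a homology arm risks mispairing during HDR and
cannot be ordered faithfully); the next-ranked guide is tried instead.

## Guide ranking

Ranking uses only facts the workflow itself establishes:

* **variant cleanliness** — a guide whose protospacer+PAM footprint
  (optionally padded) overlaps a strain variant is demoted, not dropped:
  variant positions are often known imprecisely, and a demoted guide may
  still be the only option. The default pad is 0 nt.
* **splice-distance exclusion** — cuts closer than `min_splice_distance`
  (default 50 nt) to either splice junction are excluded so the homology
  arms and the repaired junction stay clear of splice signals. The source
  workflow does not state its buffer; 50 nt keeps a 100-nt arm from
  reaching more than halfway into the splice-site region and is
  configurable.
* **arm feasibility** — arms must fit inside the contig, contain no `N`
  and none of the design's forbidden motifs (chosen restriction sites, the
  gRNA1 unit).
* **centrality** — among equals, cuts near the intron midpoint win;
  remaining ties break by genomic coordinate then strand (`+` first), so
  output is deterministic.

On-target efficiency scores (Doench-style) are deliberately out of scope:
no scoring scheme is part of the modeled workflow, and adding one would
change designs silently. Off-target reporting is exact-match only and
informational.

Multi-isoform genes default to introns that are coding, with identical
boundaries and phase, in **every** coding transcript
(`any_isoform = FALSE` relaxes this). The conservative default guarantees
the insertion truncates or tags all isoforms; the source material is silent
on this point, so the default is ours and documented rather than asserted
as upstream practice.

## Cassette templates and reading frames

The bundled library contains five templates whose element layout and
lengths match the published constructs: the 1242-nt
`attP-3XP3-EGFP-attP` landing-site template (1442-nt donor with arms), the
protein-trap `attP-SA-sfGFP-SD-attP` (1392 nt with arms), the minimal gene
trap `attP-SA-3XSTOP-minipolyA-U6gRNA1-attP` (715 nt with arms), the GAL4
gene trap `attP-SA-T2A-miniGAL4-minipolyA-U6gRNA1-attP` (1968 nt with
arms; miniGAL4 is 1200 nt), and a full
`attP-FRT-SA-T2A-GAL4-polyA-3XP3-EGFP-FRT-attP` cassette for subcloning
designs. All are **synthetic stand-ins**: deterministic sequences with real
splice elements (polypyrimidine/AG acceptor, GT donor), stop-free
codon-sampled coding payloads, a three-frame stop block
(`TAGCTAGCTAGC`), polyA signals, and a fixed synthetic gRNA1 spacer —
sufficient for every structural, frame and length check, but not the real
vector sequences. Production use means constructing `cassette_template()`
objects from real records; everything downstream is unchanged.

**Phase matching.** An intron of phase `p` leaves `p` nt of an interrupted
codon upstream, so the artificial exon needs `(3 - p) %% 3` pad bases after
the splice acceptor before its payload codons start. Protein traps
additionally get a compensating pad before the splice donor so the
artificial exon length stays a multiple of 3 and the downstream native
frame is preserved. Phase variants are generated from the phase-0 template
(`cassette_phase_variant()`), adding at most 3 nt; the published totals
refer to the phase-0 forms. Whether real template collections carry all
three phases per cassette is metadata, not something this package assumes.

## Synthesis constructs, restriction model and linearization

The gRNA1 units flanking synthesized donors are oriented **PAM-inward**, so
the Cas9-released fragment keeps only a 3-nt + PAM (6-nt) remnant at each
end — the minimal scar compatible with cutting. The orientation is a
recorded convention of the construct builder and configurable in the sense
that any unit sequence can be supplied; the absence of the gRNA1
protospacer+PAM from the target genome is verified on both strands at build
time and is a hard error otherwise.

Restriction cloning is modeled as exact recognition-site string matching
with enzyme-specific cut offsets and overhangs from a small bundled
catalog of palindromic enzymes; ligation requires complementary overhangs,
which for two distinct enzymes forces the subcloning orientation.
`choose_re_pair()` returns the first catalog pair whose sites are absent
from arms, cassette and backbone, making enzyme choice deterministic. The
bundled 2710-nt circular backbone is a synthetic stand-in scrubbed of all
catalog sites and of the gRNA1 unit, so enzyme choice and linearization
are controlled entirely by the insert; any circular vector record can be
used instead. Donor regions produced by subcloning and by direct synthesis
of the same payload are byte-identical (both retain the RE1/RE2 junction
sites), which the tests assert literally.

Printed construct totals are reported as **cassette plus arms**; the
length including the two gRNA1 units is reported separately
(`lengths$full_insert`), since published totals do not state whether the
units are counted.

## Edited-allele and transcript model

HDR is modeled as the intended product only:
`reference[..cut] + cassette + reference[cut+1..]`, with the cassette
reverse-complemented for minus-strand genes. Imperfect repair (NHEJ indels)
is not modeled; the workflow verifies precise insertion by junction PCR, so
the design-relevant objects are the intended allele and its validation
assay. Two invariants are enforced on every design: excising the insert
restores the reference byte-for-byte, and no intact protospacer+PAM of the
guide survives on either strand (the cut always falls inside the
protospacer, so a seamless insertion necessarily splits it).

Trap transcripts are modeled structurally: upstream exons splice to the
cassette's artificial exon at its SA; gene traps end at the cassette polyA
(downstream native exons dropped), protein traps splice out at the SD and
retain the native stop. The ORF report translates upstream CDS continued
into the cassette frame and states where translation stops and whether the
payload is in frame for the intron phase. Expression levels are biological
measurements and are not predicted.

## Validation PCR

Primer constraints beyond the workflow's stated orientation and 200-800 nt
product window are this package's own: length 18-25 nt, GC 35-65%,
nearest-neighbor Tm 57-63 °C, no mononucleotide run over 4. Tm uses the
unified nearest-neighbor parameter set (SantaLucia 1998) with terminal
initiation terms and the entropic salt correction
`dS' = dS + 0.368 (N-1) ln[Na+]`, at 250 nM primer and 50 mM monovalent
salt by default — ordinary genotyping-PCR conditions. Pairs are chosen to
put the amplicon nearest 500 nt; uniqueness of each primer in the edited
allele is required, and every emitted pair is re-verified by virtual PCR.
Virtual PCR is exact-match only: mismatch-tolerant binding prediction is
out of scope, which means primers that would mis-prime with mismatches are
not flagged — acceptable at single-locus scale, where uniqueness within
the locus window is the operative constraint.

## The synthetic fixture generator

`generate_locus()` builds a single-contig genome carrying one multi-exon
protein-coding gene: a valid ORF (ATG...stop, stop-free internal codons,
CDS length a multiple of 3), GT..AG introns, UTRs in the terminal exons,
plantable NGG guides at recorded positions with their expected cut sites,
injectable SNVs/indels, and an optional decoy gRNA1 site. One PRNG stream
per call, seeded from the spec, makes every output byte-reproducible; the
caller's RNG state is untouched. Defaults (4 exons of 150-300 nt, introns
of 300-600 nt, GC 0.45, 1.5-kb flanks) give a compact locus in the size
range of a typical insect or cell-line target gene.

What the generator emulates — and what it does not — bounds what passing
tests show. It produces uniform-composition random sequence: no repeats,
no paralogs, no GC extremes, no soft-masked regions, no alternative
isoforms, and single-locus scale rather than genome scale. Tests on these
fixtures therefore demonstrate **algorithmic correctness** (coordinates,
frames, assembly arithmetic, determinism), not in-vivo knock-in efficiency
or genome-wide guide specificity. In particular the exact-match gRNA1 and
off-target checks are trivially clean on random fixtures; on a real genome
they do real work.

## Problem sizes and numerical choices

The test and acceptance workloads use desk-scale sizes chosen to exercise
every code path while staying instant to run: 2-kb guide-scan windows
against the brute-force oracle (50 windows in the acceptance suite),
batches of 6-9 end-to-end designs across strands and donor classes, and
single-locus genomes of ~5-9 kb. Degenerate inputs are handled by typed
errors (classed conditions) rather than sentinel values: windows outside
the contig, arms over a contig edge or containing N, a gRNA1 hit in the
genome, fewer or more than two linearization sites, unsatisfiable primer
constraints, and infeasible fixture specs all fail loudly with the reason
attached. Where a step can exclude candidates (guides, enzymes, primers),
the exclusion reasons are recorded and surfaced in the run summary, so a
failed gene is diagnosable from the JSON alone.

## Known limitations

* Exact-match models throughout: off-target census, gRNA1 absence check,
  virtual PCR. No mismatch-tolerant search.
* No on-target efficiency scoring; ranking is structural.
* No NHEJ/imperfect-repair outcomes; only the intended HDR product.
* No synthesis-vendor constraint screening beyond a GC note on the
  ordering sheet.
* The bundled cassettes and backbone are synthetic stand-ins; results that
  depend on real cassette sequence (e.g. internal restriction sites of the
  true vectors) require loading real records.
* Non-canonical splice sites produce a warning, not an error; the
  transcript model assumes canonical SA/SD behavior.
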