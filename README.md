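# dropinDesign

Design toolkit for "drop-in" CRISPR-Cas9 knock-ins into coding introns of
protein-coding genes. Given a reference genome (FASTA), a gene annotation
(GFF3) and optionally a strain-variant VCF, the package designs the three
donor classes used for scarless cassette integration by homology-directed
repair (HDR), simulates every intermediate molecule, and designs the
genotyping PCR that verifies the insertion. It is aimed at fly and cell-line
genome engineers building gene-trap, protein-trap, and landing-site alleles
at scale, and at tool builders who need a fully testable in-silico model of
the design workflow.

## The design model

**Target selection.** Insertions go into *coding introns* — introns flanked
by two CDS-containing exons — so that a splice-acceptor cassette is spliced
into the mature transcript. Each intron carries a phase
`p = (cumulative upstream CDS length) mod 3`, which fixes the reading frame
the artificial exon must adopt. By default only introns shared (same
boundaries and phase) by all coding isoforms are used.

**Guides and the cut rule.** SpCas9 guides are all 23-mers matching
`N20-NGG` on either strand. Cas9 cuts bluntly 3 nt 5' of the PAM, between
protospacer positions 17 and 18; in interbase coordinates,

```
+ strand:  cut = protospacer_start0 + 17
- strand:  cut = protospacer_start0 + 3
```

Guides overlapped by strain variants (protospacer + PAM footprint) are
demoted; guides cutting within 50 nt of a splice junction are excluded;
remaining guides are ranked by variant cleanliness, homology-arm
feasibility, and centrality in the intron, with deterministic tie-breaks.

**Homology arms.** The left homology arm (LHA) is the 100 nt immediately 5'
of the blunt cut — i.e. the region ending 3 nt before the PAM for a
+-strand guide — and the right arm (RHA) the 100 nt immediately 3' of it,
both normalized to the gene's coding strand. `LHA + RHA` equals the
contiguous reference window around the cut, the precondition for seamless
HDR. Arm lengths are configurable (e.g. 100/97).

**Donor classes.**

1. *ssDNA drop-in (PCR-based):* long primers `LHA + 26-nt universal forward
   priming segment` and `revcomp(RHA) + 24-nt universal reverse priming
   segment` amplify a cassette template (e.g. the 1242-nt
   `attP-3XP3-EGFP-attP` template → a 1442-nt donor with two 100-nt arms).
   The reverse primer is 5'-phosphorylated; lambda exonuclease degrades the
   phosphorylated strand, leaving the other strand as the ssDNA donor.
2. *Synthesized dsDNA drop-in:* insert `gRNA1-LHA-cassette-RHA-gRNA1` in a
   cloning plasmid, where gRNA1 is a guide with no target in the host
   genome (verified at build time). The gRNA1 units point PAM-inward, so
   in-vivo Cas9 linearization releases the donor with a minimal 6-nt
   (3 nt + PAM) remnant at each end. Example payloads: the 715-nt (with
   arms) `attP-SA-3XSTOP-minipolyA-U6gRNA1-attP` minimal gene trap and the
   1968-nt `attP-SA-T2A-miniGAL4-minipolyA-U6gRNA1-attP` GAL4 gene trap.
3. *Subcloned plasmid donors:* for large cassettes, a
   `gRNA1-LHA-RE1-stuffer-RE2-RHA-gRNA1` fragment is synthesized and the
   cassette is subcloned directionally via the two distinct restriction
   sites (simulated digestion/ligation), yielding a donor region
   byte-identical to direct synthesis.

**Simulation and validation.** The HDR product is
`reference[..cut] + cassette + reference[cut+1..]`; the package asserts
that excising the insert restores the reference exactly and that no intact
protospacer+PAM of the chosen guide survives. For splice-acceptor cassettes
it predicts the trap transcript and ORF (gene traps terminate at the
cassette polyA; protein traps splice back out at the SD and retain the
native stop codon) and reports frame compatibility with the intron phase.
Finally it designs in/out genotyping PCR: genomic flanking primers paired
with outward-facing cassette-internal primers, every amplicon in the
200-800 nt window and re-verified by exact-match virtual PCR; in/out pairs
give no product on the unedited allele.

The bundled cassette sequences are deterministic, length-faithful
**synthetic stand-ins** (element layout and totals match the published
constructs); load real template records for production designs.

## Worked example

```r
library(dropinDesign)

# deterministic synthetic test locus: FASTA + GFF3 + truth report
fx <- generate_locus(synthetic_locus_spec(seed = 42), dir = "demo")

cfg <- design_config(
  genome = fx$paths$fasta, gff3 = fx$paths$gff3,
  genes = "geneA",
  cassette = "attP-SA-T2A-miniGAL4-minipolyA-U6gRNA1-attP",
  design_type = "synthesis", out_dir = "demo_out", seed = 42)
res <- run_design(cfg)

d <- res$designs$geneA
d$guide[, c("protospacer", "pam", "strand", "cut_site")]
print(d$arms); print(d$construct); print(d$edited)
print(d$trap_report); print(d$validation)
```

which prints:

```
           protospacer pam strand cut_site
1 CATGCTTTGCACTAGACTGA AGG      +     1913
homology_arms: 100/100 nt around cut 1913 (chrSyn, + strand)
synthesis_construct (cassette): insert 2014 nt (payload+arms 1968 nt), plasmid 4724 nt
edited_allele: chrSyn, 1768 nt insert at 1914..3681 (cut 1913, + strand)
  surviving guide target sites: 0
trap_transcript_report (gene_trap): intron phase 0, cassette phase 0, payload in frame
  transcript 1496 nt; translation stops inside the cassette (exon nt 1261)
validation_primer_set:
  5prime_junction: genomic_fwd + insert_rev_5p -> 500 nt (1559..2058)
  3prime_junction: insert_fwd_3p + genomic_rev -> 500 nt (3346..3845)
```

Reading the output: the chosen guide cuts at interbase 1913 inside a
phase-0 coding intron; the 1968-nt payload-plus-arms insert (2014 nt with
the two gRNA1 units) sits in a 4724-nt plasmid; after simulated HDR the
edited allele carries the 1768-nt cassette with no surviving guide site;
the T2A-miniGAL4 payload is in frame for the intron phase and translation
stops at the cassette's stop codon; and both junction-spanning genotyping
amplicons are 500 nt, inside the 200-800 nt window. `demo_out/` contains
the guide report, ordering sheet, GenBank records, primer TSV and
`summary.json`.

A thin command-line wrapper is included at `inst/cli/dropin-design.R`
(`design` and `fixtures` subcommands).

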