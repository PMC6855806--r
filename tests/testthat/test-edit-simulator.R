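# HDR simulation, trap-transcript prediction and allele classification.

design_into_intron <- function(loc, cassette, intron_idx = 1L) {
  ci <- find_coding_introns(loc$gene)
  intron <- ci[intron_idx, , drop = FALSE]
  guides <- filter_by_variants(
    scan_guides(loc$genome, loc$truth$contig, intron$start, intron$end), NULL)
  ranked <- rank_guides(guides, intron, genome = loc$genome)
  guide <- ranked[1, , drop = FALSE]
  arms <- design_arms(loc$genome, loc$truth$contig, guide$cut_site,
                      gene_strand = loc$gene$strand)
  list(intron = intron, guide = guide, arms = arms,
       edited = simulate_hdr(loc$genome, arms, cassette, guide = guide))
}

test_that("HDR conserves length and excising the insert restores the reference", {
  for (strand in c("+", "-")) {
    loc <- make_locus(seed = 51, gene_strand = strand)
    tpl <- cassette_library()[["attP-3XP3-EGFP-attP"]]
    d <- design_into_intron(loc, tpl)
    ed <- d$edited
    expect_equal(nchar(ed$sequence), nchar(loc$seq) + tpl$core_len)
    restored <- paste0(
      substr(ed$sequence, 1, ed$insert_interval["start"] - 1L),
      substring(ed$sequence, ed$insert_interval["end"] + 1L))
    expect_identical(restored, loc$seq)
    # the core is inserted in gene orientation
    ins <- substring(ed$sequence, ed$insert_interval["start"],
                     ed$insert_interval["end"])
    expect_identical(ins, if (strand == "+") tpl$core_seq else
      oracle_revcomp(tpl$core_seq))
  }
})

test_that("no intact guide target survives HDR (exhaustive 23-mer scan)", {
  for (seed in c(53, 54)) {
    loc <- make_locus(seed = seed, gene_strand = if (seed %% 2) "+" else "-")
    d <- design_into_intron(loc, cassette_library()[[1]])
    unit <- paste0(d$guide$protospacer, d$guide$pam)
    expect_gte(oracle_count_unit(loc$seq, unit), 1L)   # present in reference
    expect_equal(oracle_count_unit(d$edited$sequence, unit), 0L)
    expect_equal(d$edited$recut_sites, 0L)
  }
})

test_that("stale arms (wrong genome or strand) are rejected", {
  loc <- make_locus(seed = 55)
  other <- make_locus(seed = 56)
  arms <- design_arms(loc$genome, "chrSyn", 1500L)
  expect_error(simulate_hdr(other$genome, arms, "ACGTACGT"),
               "do not match the reference flanks")
  arms_minus <- design_arms(loc$genome, "chrSyn", 1500L, gene_strand = "-")
  arms_minus$orientation <- "+"   # simulate a strand-normalization mix-up
  expect_error(simulate_hdr(loc$genome, arms_minus, "ACGTACGT"),
               "do not match the reference flanks")
})

test_that("gene-trap transcripts end at the cassette polyA with the payload in frame", {
  loc <- make_locus(seed = 61, n_exons = 4)
  ci <- find_coding_introns(loc$gene)
  base <- cassette_library()[["attP-SA-T2A-miniGAL4-minipolyA-U6gRNA1-attP"]]
  idx <- 1L
  tpl <- cassette_phase_variant(base, ci$phase[idx])
  d <- design_into_intron(loc, tpl, idx)
  rep <- predict_trap_transcript(d$edited, loc$gene, loc$genome, tpl)
  expect_identical(rep$trap_type, "gene_trap")
  expect_true(rep$payload_in_frame)
  expect_equal(rep$cassette_phase, rep$intron_phase)
  # downstream native exons are absent from the transcript
  tx <- loc$gene$transcripts[[1]]
  last_exon <- substring(loc$seq, IRanges::start(tx$exons)[4],
                         IRanges::end(tx$exons)[4])
  expect_false(grepl(last_exon, rep$transcript_seq, fixed = TRUE))
  # translation oracle: upstream protein is intact, then T2A-miniGAL4, then stop
  prot <- oracle_translate(rep$orf_nt)
  up_prot <- oracle_translate(substr(rep$orf_nt, 1, rep$upstream_cds_nt))
  expect_false(grepl("*", up_prot, fixed = TRUE))
  expect_identical(substr(prot, 1, nchar(up_prot)), up_prot)
  stop_at <- regexpr("*", prot, fixed = TRUE)
  expect_gt(stop_at, nchar(up_prot))
  # the stop is the planted one after miniGAL4, inside the cassette
  expect_false(is.na(rep$stop_in_cassette_nt))
  expect_identical(substr(rep$protein, nchar(rep$protein), nchar(rep$protein)), "*")
})

test_that("a phase-mismatched cassette is reported out of frame", {
  loc <- make_locus(seed = 61, n_exons = 4)
  ci <- find_coding_introns(loc$gene)
  base <- cassette_library()[["attP-SA-T2A-miniGAL4-minipolyA-U6gRNA1-attP"]]
  wrong_phase <- (ci$phase[1] + 1L) %% 3L
  tpl <- cassette_phase_variant(base, wrong_phase)
  d <- design_into_intron(loc, tpl, 1L)
  rep <- predict_trap_transcript(d$edited, loc$gene, loc$genome, tpl)
  expect_false(rep$payload_in_frame)
  expect_false(rep$cassette_phase == rep$intron_phase)
})

test_that("protein traps splice back out and retain the native stop codon", {
  for (strand in c("+", "-")) {
    loc <- make_locus(seed = 63, n_exons = 4, gene_strand = strand)
    ci <- find_coding_introns(loc$gene)
    base <- cassette_library()[["attP-SA-sfGFP-SD-attP"]]
    idx <- 2L
    tpl <- cassette_phase_variant(base, ci$phase[idx])
    d <- design_into_intron(loc, tpl, idx)
    rep <- predict_trap_transcript(d$edited, loc$gene, loc$genome, tpl)
    expect_identical(rep$trap_type, "protein_trap")
    expect_true(rep$payload_in_frame)
    expect_true(rep$retains_native_stop)
    expect_equal(rep$artificial_exon_nt %% 3L, 0L)
    # translation oracle: full-length fusion, single stop at the native end
    prot <- oracle_translate(rep$orf_nt)
    expect_equal(length(gregexpr("*", prot, fixed = TRUE)[[1]]), 1L)
    expect_identical(substring(prot, nchar(prot)), "*")
    # the fusion protein is native protein plus the exon-encoded tag
    tx <- loc$gene$transcripts[[1]]
    parts <- substring(loc$seq, IRanges::start(tx$cds), IRanges::end(tx$cds))
    native_cds <- if (strand == "+") paste(parts, collapse = "") else
      paste(rev(oracle_revcomp(parts)), collapse = "")
    native_prot <- oracle_translate(native_cds)
    expect_equal(nchar(prot), nchar(native_prot) + rep$artificial_exon_nt / 3L)
  }
})

test_that("cassettes without the required splice features are rejected", {
  loc <- make_locus(seed = 65)
  tpl <- cassette_library()[["attP-3XP3-EGFP-attP"]]
  d <- design_into_intron(loc, tpl)
  expect_error(predict_trap_transcript(d$edited, loc$gene, loc$genome, tpl),
               "no SA feature")
  expect_error(cassette_phase_variant(tpl, 1L), "no splice acceptor")
})

test_that("allele classification follows cassette class and insertion context", {
  lib <- cassette_library()
  r <- classify_allele(lib[["attP-3XP3-EGFP-attP"]], "intron")
  expect_identical(r$allele_class, "neutral_landing_site")
  expect_false(r$disruptive)
  r <- classify_allele(lib[["attP-3XP3-EGFP-attP"]], "exon")
  expect_true(r$disruptive)
  r <- classify_allele(lib[["attP-SA-T2A-miniGAL4-minipolyA-U6gRNA1-attP"]], "intron")
  expect_identical(r$allele_class, "gene_trap")
  expect_true(r$disruptive)
  r <- classify_allele(lib[["attP-SA-3XSTOP-minipolyA-U6gRNA1-attP"]], "intron")
  expect_identical(r$allele_class, "gene_trap")
  r <- classify_allele(lib[["attP-SA-sfGFP-SD-attP"]], "intron")
  expect_identical(r$allele_class, "protein_trap")
  expect_false(r$disruptive)
})
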