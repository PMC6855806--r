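# HDR outcome simulation: the edited allele, its gene-trap / protein-trap
# transcript, and the molecular classification of the insertion.

#' Simulate the HDR-edited allele
#'
#' Inserts the cassette core at the blunt cut, seamlessly: the edited
#' contig is reference[1..cut] + oriented core + reference[cut+1..]. The
#' core is reverse-complemented when the gene is on the minus strand so the
#' cassette runs with the gene. Asserts the seamlessness invariants and
#' reports whether any intact protospacer+PAM of the guide used survives
#' (HDR across the cut destroys the target site, so a clean design leaves
#' none).
#'
#' @param genome genome from [load_genome()].
#' @param arms `homology_arms` (defines contig, cut site and orientation).
#' @param cassette a `cassette_template` or DNA string (core, in gene
#'   orientation).
#' @param guide optional one-row `guide_set`; when given, the edited allele
#'   is scanned for surviving protospacer+PAM sites of that guide.
#' @return `edited_allele`: `contig`, `sequence`, `insert_interval`
#'   (1-based closed), `cut_site`, `core_genomic` (core as inserted, forward
#'   strand), `cassette_name`, `gene_strand`, `recut_sites` (count).
#' @export
simulate_hdr <- function(genome, arms, cassette, guide = NULL) {
  stopifnot(inherits(arms, "homology_arms"))
  seq <- contig_seq(genome, arms$contig)
  cut <- arms$cut_site
  up_len <- if (arms$orientation == "+") arms$lha_len else arms$rha_len
  dn_len <- if (arms$orientation == "+") arms$rha_len else arms$lha_len
  ref_left <- substring(seq, cut - up_len + 1L, cut)
  ref_right <- substring(seq, cut + 1L, cut + dn_len)
  exp_lha <- if (arms$orientation == "+") ref_left else revcomp(ref_right)
  exp_rha <- if (arms$orientation == "+") ref_right else revcomp(ref_left)
  if (!identical(arms$lha, exp_lha) || !identical(arms$rha, exp_rha)) {
    dropin_error(
      "homology arms do not match the reference flanks at the cut site (stale genome or wrong strand normalization?)",
      "dropin_hdr_error")
  }
  core <- if (inherits(cassette, "cassette_template")) cassette$core_seq else cassette
  cassette_name <- if (inherits(cassette, "cassette_template")) cassette$name else NA_character_
  core_genomic <- if (arms$orientation == "+") core else revcomp(core)
  edited <- paste0(substr(seq, 1L, cut), core_genomic, substring(seq, cut + 1L))
  insert_interval <- c(start = cut + 1L, end = cut + nchar(core_genomic))
  # seamlessness: excising the insert must restore the reference exactly
  restored <- paste0(substr(edited, 1L, insert_interval["start"] - 1L),
                     substring(edited, insert_interval["end"] + 1L))
  stopifnot(identical(restored, seq))
  recut <- NA_integer_
  if (!is.null(guide)) {
    unit <- paste0(guide$protospacer, guide$pam)
    recut <- length(find_exact(unit, edited)) +
      length(find_exact(revcomp(unit), edited))
  }
  structure(list(
    contig = arms$contig,
    sequence = edited,
    insert_interval = insert_interval,
    cut_site = cut,
    core_genomic = core_genomic,
    cassette_name = cassette_name,
    gene_strand = arms$orientation,
    recut_sites = recut
  ), class = "edited_allele")
}

#' @export
print.edited_allele <- function(x, ...) {
  cat(sprintf("edited_allele: %s, %d nt insert at %d..%d (cut %d, %s strand)\n",
              x$contig, x$insert_interval["end"] - x$insert_interval["start"] + 1L,
              x$insert_interval["start"], x$insert_interval["end"],
              x$cut_site, x$gene_strand))
  if (!is.na(x$recut_sites))
    cat(sprintf("  surviving guide target sites: %d\n", x$recut_sites))
  invisible(x)
}

# concatenated sequence of ranges on the gene strand, transcription order
# (ranges may be supplied in any order; they are sorted internally)
spliced_seq <- function(seq, ranges, strand) {
  if (length(ranges) == 0L) return("")
  ranges <- ranges[order(IRanges::start(ranges))]
  parts <- substring(seq, IRanges::start(ranges), IRanges::end(ranges))
  if (strand == "-") parts <- rev(revcomp(parts))
  paste(parts, collapse = "")
}

# translate nucleotides (truncating a trailing partial codon)
translate_nt <- function(nt) {
  n <- nchar(nt) - nchar(nt) %% 3L
  if (n < 3L) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(substr(nt, 1L, n)),
                                     if.fuzzy.codon = "X"))
}

#' Predict the transcript and ORF of a trap insertion
#'
#' Models the mature mRNA after intronic insertion of a splice-acceptor
#' cassette: upstream exons splice to the cassette's artificial exon at its
#' SA. Gene traps (SA...polyA) terminate the transcript at the cassette
#' polyA, dropping all downstream native exons; protein traps (SA...SD)
#' splice back out at the SD, retaining the downstream exons and the native
#' stop codon. The ORF continues the upstream CDS into the cassette reading
#' frame; the report states whether the payload is in frame for the intron
#' phase and where translation stops.
#'
#' @param edited `edited_allele` from [simulate_hdr()] (intronic insertion).
#' @param gene `gene_model` of the host gene.
#' @param genome reference genome (exon sequences are unchanged by an
#'   intronic insertion).
#' @param template the inserted `cassette_template`; must have an SA plus a
#'   polyA (gene trap) or SD (protein trap) feature.
#' @param transcript transcript id (default: first coding transcript
#'   containing the insertion intron).
#' @return `trap_transcript_report`: `transcript_seq`, `orf_nt`, `protein`,
#'   `payload_in_frame`, `intron_phase`, `cassette_phase`,
#'   `stop_in_cassette_nt` (1-based nt offset of the first stop codon's
#'   first base within the artificial exon, NA if none),
#'   `retains_native_stop`, `trap_type`.
#' @export
predict_trap_transcript <- function(edited, gene, genome, template,
                                    transcript = NULL) {
  stopifnot(inherits(edited, "edited_allele"), inherits(gene, "gene_model"),
            inherits(template, "cassette_template"))
  sa <- feature_interval(template, "SA")
  if (is.null(sa)) {
    dropin_error(sprintf("cassette '%s' has no SA feature", template$name),
                 "dropin_template_error")
  }
  polya <- feature_interval(template, "minipolyA") %||%
    feature_interval(template, "polyA")
  sd <- feature_interval(template, "SD")
  trap_type <- if (!is.null(sd)) "protein_trap" else "gene_trap"
  if (trap_type == "gene_trap" && is.null(polya)) {
    dropin_error(sprintf("cassette '%s' has neither polyA nor SD feature",
                         template$name), "dropin_template_error")
  }
  introns <- find_coding_introns(gene)
  cut <- edited$cut_site
  hit <- which(introns$start - 1L <= cut & cut <= introns$end)
  if (length(hit) != 1L) {
    dropin_error("insertion cut site is not inside a coding intron of the gene",
                 "dropin_hdr_error")
  }
  intron <- introns[hit, , drop = FALSE]
  txs <- Filter(function(t) length(t$cds) > 0, gene$transcripts)
  tx <- if (is.null(transcript)) txs[[1]] else gene$transcripts[[transcript]]
  strand <- gene$strand
  seq <- contig_seq(genome, gene$contig)
  ord <- if (strand == "+") order(IRanges::start(tx$exons)) else
    order(-IRanges::start(tx$exons))
  ex_tx <- tx$exons[ord]
  # upstream = exons wholly 5' (transcription sense) of the intron
  up_idx <- if (strand == "+") which(IRanges::end(ex_tx) <= intron$start - 1L) else
    which(IRanges::start(ex_tx) >= intron$end + 1L)
  dn_idx <- setdiff(seq_along(ex_tx), up_idx)
  up_exons <- ex_tx[up_idx]
  dn_exons <- ex_tx[dn_idx]
  core <- template$core_seq
  art_exon <- if (trap_type == "gene_trap") {
    substring(core, sa$end + 1L, polya$end)
  } else {
    substring(core, sa$end + 1L, sd$start - 1L)
  }
  up_seq <- spliced_seq(seq, up_exons, strand)
  transcript_seq <- if (trap_type == "gene_trap") {
    paste0(up_seq, art_exon)
  } else {
    paste0(up_seq, art_exon, spliced_seq(seq, dn_exons, strand))
  }
  # ORF: upstream CDS continued into the artificial exon
  cds_tx <- tx$cds[if (strand == "+") order(IRanges::start(tx$cds)) else
    order(-IRanges::start(tx$cds))]
  up_cds_idx <- if (strand == "+") which(IRanges::end(cds_tx) <= intron$start - 1L) else
    which(IRanges::start(cds_tx) >= intron$end + 1L)
  up_cds <- spliced_seq(seq, cds_tx[up_cds_idx], strand)
  orf_nt <- if (trap_type == "gene_trap") {
    paste0(up_cds, art_exon)
  } else {
    paste0(up_cds, art_exon,
           spliced_seq(seq, cds_tx[setdiff(seq_along(cds_tx), up_cds_idx)], strand))
  }
  protein_full <- translate_nt(orf_nt)
  stop_at <- regexpr("*", protein_full, fixed = TRUE)
  protein <- if (stop_at > 0L) substr(protein_full, 1L, stop_at) else protein_full
  stop_nt0 <- if (stop_at > 0L) (as.integer(stop_at) - 1L) * 3L + 1L else NA_integer_
  stop_in_cassette <- if (!is.na(stop_nt0) && stop_nt0 > nchar(up_cds) &&
                          stop_nt0 <= nchar(up_cds) + nchar(art_exon)) {
    stop_nt0 - nchar(up_cds)
  } else NA_integer_
  retains_native_stop <- trap_type == "protein_trap" && !is.na(stop_nt0) &&
    stop_nt0 > nchar(up_cds) + nchar(art_exon)
  cassette_phase <- template$phase_variant
  payload_in_frame <- !is.na(cassette_phase) && cassette_phase == intron$phase
  structure(list(
    transcript_seq = transcript_seq,
    orf_nt = orf_nt,
    protein = protein,
    payload_in_frame = payload_in_frame,
    intron_phase = intron$phase,
    cassette_phase = cassette_phase,
    stop_in_cassette_nt = stop_in_cassette,
    retains_native_stop = retains_native_stop,
    trap_type = trap_type,
    upstream_cds_nt = nchar(up_cds),
    artificial_exon_nt = nchar(art_exon)
  ), class = "trap_transcript_report")
}

#' @export
print.trap_transcript_report <- function(x, ...) {
  cat(sprintf("trap_transcript_report (%s): intron phase %d, cassette phase %s, payload %s\n",
              x$trap_type, x$intron_phase,
              ifelse(is.na(x$cassette_phase), "NA", x$cassette_phase),
              if (x$payload_in_frame) "in frame" else "OUT OF FRAME"))
  cat(sprintf("  transcript %d nt; translation stops %s\n",
              nchar(x$transcript_seq),
              if (x$retains_native_stop) "at the native stop codon"
              else if (!is.na(x$stop_in_cassette_nt))
                sprintf("inside the cassette (exon nt %d)", x$stop_in_cassette_nt)
              else "nowhere before transcript end"))
  invisible(x)
}

#' Classify the molecular consequence of a cassette insertion
#'
#' Intronic insertions: attP-marker-attP cassettes without splice elements
#' are neutral landing sites; SA...polyA cassettes are gene traps;
#' SA...SD cassettes are protein traps (internal tag, translation
#' continues). Exonic insertion of any cassette disrupts the gene.
#'
#' @param cassette a `cassette_template`.
#' @param insertion_context "intron" or "exon".
#' @return list `allele_class` (gene_trap / protein_trap /
#'   neutral_landing_site) and `disruptive` (TRUE unless a neutral landing
#'   site placed in an intron).
#' @export
classify_allele <- function(cassette, insertion_context = c("intron", "exon")) {
  stopifnot(inherits(cassette, "cassette_template"))
  insertion_context <- match.arg(insertion_context)
  cls <- cassette$mutagenic_class
  if (!cls %in% c("gene_trap", "protein_trap", "neutral_landing_site")) {
    dropin_error(sprintf("unknown cassette class '%s'", cls),
                 "dropin_template_error")
  }
  disruptive <- insertion_context == "exon" || cls == "gene_trap"
  list(allele_class = cls, disruptive = disruptive,
       insertion_context = insertion_context)
}
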