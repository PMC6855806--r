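# Deterministic synthetic-locus generator: a single-contig genome carrying
# one multi-exon protein-coding gene with coding introns, plantable NGG
# guide sites, injectable variants and an optional decoy gRNA1 site, plus a
# machine-readable truth report for oracle tests.

#' Specification of a synthetic test locus
#'
#' @param seed integer; the single PRNG seed for the whole locus (same
#'   seed + spec give byte-identical FASTA/GFF3/VCF outputs).
#' @param n_exons number of exons (>= 2).
#' @param exon_len,intron_len length ranges (nt) sampled per exon/intron.
#' @param gc GC fraction of generated sequence.
#' @param gene_strand "+" or "-".
#' @param utr5_len,utr3_len UTR lengths within the terminal exons; the
#'   3'UTR absorbs the remainder so the CDS length is a multiple of 3. A
#'   5'UTR longer than the first exon(s) pushes the CDS start into a later
#'   exon, creating UTR introns.
#' @param flank nt of intergenic sequence on each side of the gene.
#' @param contig_id,gene_id feature identifiers.
#' @param planted_guides data frame with `intron` (index, transcription
#'   order), `strand` (genomic), `offset` (1-based from the genomic intron
#'   start), or "auto" (default: one +-strand guide at each intron center),
#'   or NULL for none.
#' @param planted_variants data frame with `where` ("intron", "flank5",
#'   "flank3"), `index` (intron index; ignored for flanks), `offset`,
#'   `kind` ("SNV", "insertion", "deletion"), or NULL.
#' @param decoy_grna1 plant the gRNA1 unit in the 5' flank (makes
#'   [build_synthesis_construct()] refuse the genome).
#' @param coding annotate a CDS (default TRUE).
#' @return `synthetic_locus_spec` list.
#' @export
synthetic_locus_spec <- function(seed = 1L, n_exons = 4L,
                                 exon_len = c(150L, 300L),
                                 intron_len = c(300L, 600L),
                                 gc = 0.45, gene_strand = "+",
                                 utr5_len = 60L, utr3_len = 80L,
                                 flank = 1500L,
                                 contig_id = "chrSyn", gene_id = "geneA",
                                 planted_guides = "auto",
                                 planted_variants = NULL,
                                 decoy_grna1 = FALSE, coding = TRUE) {
  if (n_exons < 2L) dropin_error("need at least 2 exons", "dropin_fixture_error")
  structure(as.list(environment()), class = "synthetic_locus_spec")
}

#' Generate a synthetic locus with truth report
#'
#' Builds the contig, annotation, variants and truth report in memory and
#' optionally writes FASTA / GFF3 / VCF / JSON to `dir`. All planted
#' features (guides with expected cut sites, variants, decoys) are listed
#' in the truth report so oracle tests can compare pipeline output against
#' ground truth. Regenerating with the same spec yields identical output.
#'
#' @param spec a `synthetic_locus_spec`.
#' @param dir optional output directory (created if needed).
#' @return list: `genome` ([Biostrings::DNAStringSet]), `annotation`
#'   (GFF3-style [GenomicRanges::GRanges]), `variants` (data frame in VCF
#'   column layout), `truth` (list), `paths` (when `dir` given).
#' @export
generate_locus <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_locus_spec"))
  res <- with_seed(spec$seed, build_locus(spec))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(
      fasta = file.path(dir, paste0(spec$contig_id, ".fa")),
      gff3 = file.path(dir, paste0(spec$contig_id, ".gff3")),
      vcf = file.path(dir, paste0(spec$contig_id, ".vcf")),
      truth = file.path(dir, "truth.json"))
    Biostrings::writeXStringSet(res$genome, paths$fasta)
    rtracklayer::export(res$annotation, paths$gff3, format = "gff3")
    write_minimal_vcf(res$variants, spec$contig_id,
                      nchar(as.character(res$genome[[1]])), paths$vcf)
    jsonlite::write_json(res$truth, paths$truth, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    res$paths <- paths
  }
  res
}

build_locus <- function(spec) {
  n <- spec$n_exons
  exon_lens <- sample(seq(spec$exon_len[1], spec$exon_len[2]), n, replace = TRUE)
  intron_lens <- sample(seq(spec$intron_len[1], spec$intron_len[2]), n - 1L,
                        replace = TRUE)
  tx_len <- sum(exon_lens)
  utr5 <- spec$utr5_len
  utr3 <- spec$utr3_len
  cds_len <- tx_len - utr5 - utr3
  if (spec$coding) {
    if (cds_len < 30L) {
      dropin_error("infeasible spec: transcript too short for UTRs plus a CDS",
                   "dropin_fixture_error")
    }
    utr3 <- utr3 + cds_len %% 3L
    cds_len <- cds_len - cds_len %% 3L
    cds <- paste0("ATG", random_codons(cds_len - 6L), "TAA")
    mrna <- paste0(random_dna(utr5, spec$gc), cds, random_dna(utr3, spec$gc))
    cds_tx <- c(utr5 + 1L, utr5 + cds_len)
  } else {
    mrna <- random_dna(tx_len, spec$gc)
    cds_tx <- NULL
  }
  exon_end_tx <- cumsum(exon_lens)
  exon_start_tx <- exon_end_tx - exon_lens + 1L
  exon_seqs <- substring(mrna, exon_start_tx, exon_end_tx)
  intron_seqs <- vapply(intron_lens, function(L) {
    paste0("GT", random_dna(L - 4L, spec$gc), "AG")
  }, character(1))
  pre <- character(2L * n - 1L)
  pre[seq(1L, by = 2L, length.out = n)] <- exon_seqs
  if (n > 1L) pre[seq(2L, by = 2L, length.out = n - 1L)] <- intron_seqs
  pre_mrna <- paste(pre, collapse = "")
  gene_len <- nchar(pre_mrna)
  # pre-mRNA block coordinates (1-based within the pre-mRNA)
  blk_len <- integer(2L * n - 1L)
  blk_len[seq(1L, by = 2L, length.out = n)] <- exon_lens
  if (n > 1L) blk_len[seq(2L, by = 2L, length.out = n - 1L)] <- intron_lens
  blk_end <- cumsum(blk_len)
  blk_start <- blk_end - blk_len + 1L
  gene_seq <- if (spec$gene_strand == "+") pre_mrna else revcomp(pre_mrna)
  contig <- paste0(random_dna(spec$flank, spec$gc), gene_seq,
                   random_dna(spec$flank, spec$gc))
  gs <- spec$flank + 1L
  ge <- spec$flank + gene_len
  pre2gen <- function(a, b) {
    if (spec$gene_strand == "+") c(gs - 1L + a, gs - 1L + b)
    else c(ge + 1L - b, ge + 1L - a)
  }
  exon_g <- t(vapply(seq_len(n), function(k)
    pre2gen(blk_start[2L * k - 1L], blk_end[2L * k - 1L]), numeric(2)))
  intron_g <- if (n > 1L) t(vapply(seq_len(n - 1L), function(k)
    pre2gen(blk_start[2L * k], blk_end[2L * k]), numeric(2))) else
      matrix(numeric(0), ncol = 2)
  # CDS segments per exon (transcript interval mapped through exons)
  cds_g <- NULL
  intron_phase <- rep(NA_integer_, max(0L, n - 1L))
  intron_coding <- rep(FALSE, max(0L, n - 1L))
  if (spec$coding) {
    segs <- list()
    for (k in seq_len(n)) {
      a <- max(exon_start_tx[k], cds_tx[1])
      b <- min(exon_end_tx[k], cds_tx[2])
      if (a <= b) {
        # tx position -> pre-mRNA position within this exon block
        off <- blk_start[2L * k - 1L] - exon_start_tx[k]
        segs[[length(segs) + 1L]] <- pre2gen(a + off, b + off)
      }
    }
    cds_g <- do.call(rbind, segs)
    for (k in seq_len(n - 1L)) {
      e <- exon_end_tx[k]
      intron_coding[k] <- e >= cds_tx[1] && e < cds_tx[2]
      up_cds <- max(0L, min(e, cds_tx[2]) - cds_tx[1] + 1L)
      intron_phase[k] <- up_cds %% 3L
    }
  }
  # plant guides
  pg <- spec$planted_guides
  if (identical(pg, "auto") && n > 1L) {
    pg <- data.frame(intron = seq_len(n - 1L), strand = "+",
                     offset = pmax(3L, intron_lens %/% 2L - 11L))
  } else if (identical(pg, "auto")) pg <- NULL
  truth_guides <- NULL
  if (!is.null(pg) && nrow(pg) > 0L) {
    rows <- list()
    for (i in seq_len(nrow(pg))) {
      k <- pg$intron[i]
      ist <- intron_g[k, 1]; ien <- intron_g[k, 2]
      p <- ist + pg$offset[i] - 1L
      if (p < ist + 2L || p + 22L > ien - 2L) {
        dropin_error(sprintf(
          "infeasible spec: planted guide %d does not fit inside intron %d", i, k),
          "dropin_fixture_error")
      }
      proto <- random_dna(20L, 0.5)
      unit <- paste0(proto, "AGG")
      written <- if (pg$strand[i] == "+") unit else revcomp(unit)
      substr(contig, p, p + 22L) <- written
      rows[[i]] <- data.frame(
        intron = k, strand = pg$strand[i], protospacer = proto, pam = "AGG",
        p_start = if (pg$strand[i] == "+") p else p + 3L,
        p_end = if (pg$strand[i] == "+") p + 19L else p + 22L,
        cut_site = if (pg$strand[i] == "+") p + 16L else p + 5L,
        stringsAsFactors = FALSE)
    }
    truth_guides <- do.call(rbind, rows)
  }
  # decoy gRNA1 target in the 5' flank
  if (isTRUE(spec$decoy_grna1)) {
    u <- grna1_unit()$unit
    substr(contig, 200L, 200L + nchar(u) - 1L) <- u
  }
  # planted variants
  pv <- spec$planted_variants
  variants <- data.frame(CHROM = character(0), POS = integer(0),
                         ID = character(0), REF = character(0),
                         ALT = character(0), stringsAsFactors = FALSE)
  if (!is.null(pv) && nrow(pv) > 0L) {
    rot <- c(A = "C", C = "G", G = "T", T = "A")
    rows <- list()
    for (i in seq_len(nrow(pv))) {
      base <- switch(pv$where[i],
        intron = intron_g[pv$index[i], 1],
        flank5 = 1L,
        flank3 = ge + 1L,
        dropin_error("unknown variant placement", "dropin_fixture_error"))
      pos <- as.integer(base + pv$offset[i] - 1L)
      ref1 <- substr(contig, pos, pos)
      rec <- switch(pv$kind[i],
        SNV = list(ref = ref1, alt = rot[[ref1]]),
        insertion = list(ref = ref1, alt = paste0(ref1, "TCA")),
        deletion = list(ref = substr(contig, pos, pos + 3L), alt = ref1),
        dropin_error("unknown variant kind", "dropin_fixture_error"))
      rows[[i]] <- data.frame(CHROM = spec$contig_id, POS = pos,
                              ID = sprintf("pv%d", i), REF = rec$ref,
                              ALT = rec$alt, stringsAsFactors = FALSE)
    }
    variants <- do.call(rbind, rows)
  }
  genome <- Biostrings::DNAStringSet(setNames(contig, spec$contig_id))
  annotation <- locus_granges(spec, gs, ge, exon_g, cds_g)
  truth <- list(
    seed = spec$seed,
    contig = spec$contig_id,
    contig_len = nchar(contig),
    gene_id = spec$gene_id,
    strand = spec$gene_strand,
    gene = c(start = gs, end = ge),
    exons = data.frame(tx_order = seq_len(n), start = exon_g[, 1],
                       end = exon_g[, 2]),
    introns = if (n > 1L) data.frame(
      tx_order = seq_len(n - 1L), start = intron_g[, 1], end = intron_g[, 2],
      phase = intron_phase, coding = intron_coding) else NULL,
    cds = if (!is.null(cds_g)) data.frame(start = cds_g[, 1], end = cds_g[, 2])
      else NULL,
    planted_guides = truth_guides,
    variants = if (nrow(variants)) variants else NULL,
    decoy_grna1 = isTRUE(spec$decoy_grna1)
  )
  list(genome = genome, annotation = annotation, variants = variants,
       truth = truth)
}

# gene/mRNA/exon/CDS GRanges in GFF3 layout
locus_granges <- function(spec, gs, ge, exon_g, cds_g) {
  gid <- spec$gene_id
  tid <- paste0(gid, ".t1")
  n_ex <- nrow(exon_g)
  n_cds <- if (is.null(cds_g)) 0L else nrow(cds_g)
  starts <- c(gs, gs, exon_g[, 1], if (n_cds) cds_g[, 1])
  ends <- c(ge, ge, exon_g[, 2], if (n_cds) cds_g[, 2])
  type <- c("gene", "mRNA", rep("exon", n_ex), rep("CDS", n_cds))
  ids <- c(gid, tid, sprintf("%s.exon%d", tid, seq_len(n_ex)),
           if (n_cds) sprintf("%s.cds%d", tid, seq_len(n_cds)))
  parents <- c(NA, gid, rep(tid, n_ex), rep(tid, n_cds))
  gr <- GenomicRanges::GRanges(
    seqnames = spec$contig_id,
    ranges = IRanges::IRanges(start = starts, end = ends),
    strand = spec$gene_strand)
  gr$source <- "dropinDesign"
  gr$type <- type
  gr$ID <- ids
  # GFF3 phase for CDS rows: bases to skip to reach a codon boundary
  phase <- rep(NA_integer_, length(gr))
  if (n_cds) {
    w <- cds_g[, 2] - cds_g[, 1] + 1L
    tx_ord <- if (spec$gene_strand == "+") seq_len(n_cds) else rev(seq_len(n_cds))
    cum_before <- cumsum(c(0L, w[tx_ord]))[seq_len(n_cds)]
    ph <- (3L - cum_before %% 3L) %% 3L
    phase[2L + n_ex + tx_ord] <- ph
  }
  gr$phase <- phase
  gr$Parent <- S4Vectors::unname(IRanges::CharacterList(
    lapply(parents, function(p) if (is.na(p)) character(0) else p)))
  GenomeInfoDb::seqlengths(gr) <- setNames(
    spec$flank * 2L + (ge - gs + 1L) + 0L, spec$contig_id)
  gr
}

# minimal VCFv4.2 writer for the generator's variant table
write_minimal_vcf <- function(variants, contig_id, contig_len, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", contig_id, contig_len),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(variants)) {
    writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.",
                       variants$CHROM, variants$POS, variants$ID,
                       variants$REF, variants$ALT), con)
  }
  invisible(path)
}
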