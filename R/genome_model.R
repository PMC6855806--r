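# Genome / annotation ingestion and gene models.
#
# Conventions: feature intervals (exons, CDS, introns, arms) are 1-based
# closed, the IRanges convention. Cut sites and insertion points are
# *interbase*: cut_site = k means the cut falls between reference positions
# k and k+1, i.e. k bases lie 5' of the cut on the forward strand. This
# makes the homology-arm arithmetic exact: the left arm is positions
# [k - lha_len + 1, k] and the right arm [k + 1, k + rha_len].

#' Load a reference genome from FASTA
#'
#' Sequences are uppercased; soft-masked (lowercase) stretches are preserved
#' as per-contig ranges in `metadata(x)$softmask`. IUPAC ambiguity codes
#' other than N are converted to N with a warning; any other character is a
#' hard error naming the contig and offset. Duplicate contig ids are
#' rejected.
#'
#' @param path FASTA file (may be multi-record).
#' @return a [Biostrings::DNAStringSet] keyed by contig id.
#' @export
load_genome <- function(path) {
  if (!file.exists(path)) {
    dropin_error(sprintf("genome FASTA not found: %s", path), "dropin_io_error")
  }
  raw <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    dropin_error(sprintf("duplicate contig id in FASTA: '%s'", dup),
                 "dropin_fasta_error")
  }
  seqs <- character(length(raw))
  softmask <- vector("list", length(raw))
  names(softmask) <- ids
  for (i in seq_along(raw)) {
    s <- as.character(raw[[i]])
    low <- gregexpr("[a-z]", s)[[1]]
    softmask[[i]] <- if (low[1] == -1L) {
      IRanges::IRanges()
    } else {
      IRanges::reduce(IRanges::IRanges(as.integer(low), width = 1L))
    }
    s <- toupper(s)
    bad <- regexpr("[^ACGTNRYSWKMBDHV]", s)
    if (bad != -1L) {
      dropin_error(
        sprintf("non-DNA character '%s' in contig '%s' at position %d",
                substr(s, bad, bad), ids[i], as.integer(bad)),
        "dropin_fasta_error")
    }
    if (grepl("[RYSWKMBDHV]", s)) {
      warning(sprintf(
        "contig '%s': IUPAC ambiguity codes other than N converted to N",
        ids[i]))
      s <- gsub("[RYSWKMBDHV]", "N", s)
    }
    seqs[i] <- s
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  S4Vectors::metadata(out)$softmask <- softmask
  out
}

# fetch one contig as a plain character string
contig_seq <- function(genome, contig) {
  if (!contig %in% names(genome)) {
    dropin_error(sprintf("contig '%s' not in genome", contig),
                 "dropin_coord_error")
  }
  as.character(genome[[contig]])
}

#' Build gene models from a GFF3 annotation
#'
#' Expects gene/mRNA/exon/CDS features linked by `Parent` attributes (the
#' layout produced by [generate_locus()] and by standard genome
#' annotations).
#'
#' @param annotation path to a GFF3 file, or a [GenomicRanges::GRanges] as
#'   returned by `rtracklayer::import`.
#' @param gene_ids optional character vector restricting the result.
#' @return named list of `gene_model` objects, each a list with
#'   `gene_id`, `contig`, `strand` and `transcripts` (per transcript:
#'   `tx_id`, `exons`, `cds` as genomic [IRanges::IRanges], ascending).
#' @export
gene_models <- function(annotation, gene_ids = NULL) {
  gr <- if (is.character(annotation)) {
    rtracklayer::import(annotation, format = "gff3")
  } else annotation
  stopifnot(is(gr, "GRanges"))
  type <- as.character(gr$type)
  genes <- gr[type == "gene"]
  if (!is.null(gene_ids)) genes <- genes[genes$ID %in% gene_ids]
  mrnas <- gr[type == "mRNA"]
  exons <- gr[type == "exon"]
  cdss  <- gr[type == "CDS"]
  parent1 <- function(x) vapply(x$Parent, function(p) p[1], character(1))
  out <- list()
  for (i in seq_along(genes)) {
    gid <- genes$ID[i]
    txs <- mrnas[parent1(mrnas) == gid]
    tlist <- list()
    for (j in seq_along(txs)) {
      tid <- txs$ID[j]
      ex <- exons[parent1(exons) == tid]
      cd <- cdss[parent1(cdss) == tid]
      ex_ir <- IRanges::IRanges(GenomicRanges::start(ex),
                                GenomicRanges::end(ex))
      ex_ir <- ex_ir[order(IRanges::start(ex_ir))]
      cd_ir <- IRanges::IRanges(GenomicRanges::start(cd),
                                GenomicRanges::end(cd))
      cd_ir <- cd_ir[order(IRanges::start(cd_ir))]
      if (length(ex_ir) > 1 &&
          any(IRanges::start(ex_ir)[-1] <= IRanges::end(ex_ir)[-length(ex_ir)])) {
        dropin_error(sprintf("transcript '%s': overlapping exons", tid),
                     "dropin_annotation_error")
      }
      if (length(cd_ir) &&
          !all(IRanges::overlapsAny(cd_ir, ex_ir, type = "within"))) {
        dropin_error(sprintf("transcript '%s': CDS not contained in exons", tid),
                     "dropin_annotation_error")
      }
      tlist[[tid]] <- list(tx_id = tid, exons = ex_ir, cds = cd_ir)
    }
    gm <- structure(list(
      gene_id = gid,
      contig = as.character(GenomicRanges::seqnames(genes))[i],
      strand = as.character(GenomicRanges::strand(genes))[i],
      transcripts = tlist
    ), class = "gene_model")
    out[[gid]] <- gm
  }
  out
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model '%s' (%s strand, contig %s), %d transcript(s)\n",
              x$gene_id, x$strand, x$contig, length(x$transcripts)))
  invisible(x)
}

# introns of one transcript in transcription order, with phase and coding
# status at both junctions
transcript_coding_introns <- function(tx, strand) {
  ex <- tx$exons
  if (length(ex) < 2L || length(tx$cds) == 0L) return(NULL)
  ord <- if (strand == "+") seq_along(ex) else rev(seq_along(ex))
  ex_tx <- ex[ord]
  cds <- tx$cds
  n <- length(ex_tx) - 1L
  res <- data.frame(start = integer(n), end = integer(n), phase = integer(n),
                    coding = logical(n), upstream_exon = character(n),
                    downstream_exon = character(n))
  cum_cds <- 0L
  for (k in seq_len(n)) {
    up <- ex_tx[k]; dn <- ex_tx[k + 1L]
    in_up <- cds[IRanges::overlapsAny(cds, up)]
    cum_cds <- cum_cds + sum(IRanges::width(in_up))
    if (strand == "+") {
      istart <- IRanges::end(up) + 1L
      iend <- IRanges::start(dn) - 1L
      up_coding <- any(IRanges::end(in_up) == IRanges::end(up))
      in_dn <- cds[IRanges::overlapsAny(cds, dn)]
      dn_coding <- any(IRanges::start(in_dn) == IRanges::start(dn))
    } else {
      istart <- IRanges::end(dn) + 1L
      iend <- IRanges::start(up) - 1L
      up_coding <- any(IRanges::start(in_up) == IRanges::start(up))
      in_dn <- cds[IRanges::overlapsAny(cds, dn)]
      dn_coding <- any(IRanges::end(in_dn) == IRanges::end(dn))
    }
    res$start[k] <- istart
    res$end[k] <- iend
    res$phase[k] <- cum_cds %% 3L
    res$coding[k] <- up_coding && dn_coding && length(in_up) > 0 && length(in_dn) > 0
    res$upstream_exon[k] <- sprintf("%s:exon%d", tx$tx_id, k)
    res$downstream_exon[k] <- sprintf("%s:exon%d", tx$tx_id, k + 1L)
  }
  res
}

#' Find coding introns of a gene, with phase
#'
#' A coding intron is flanked by two exons that each carry CDS right up to
#' the intron boundary. Phase is the cumulative CDS length upstream of the
#' intron (in transcription order) modulo 3. An intron is flagged
#' `shared_by_all_coding_transcripts` when every coding transcript of the
#' gene contains it as a coding intron with identical boundaries and phase.
#'
#' @param gene a `gene_model` (see [gene_models()]).
#' @return data frame (class `coding_introns`) sorted by genomic start with
#'   columns `start`, `end` (1-based closed intron body), `width`, `phase`,
#'   `upstream_exon`, `downstream_exon`, `shared_by_all_coding_transcripts`.
#'   A gene with no annotated CDS yields an empty frame with a warning.
#' @export
find_coding_introns <- function(gene) {
  stopifnot(inherits(gene, "gene_model"))
  coding_txs <- Filter(function(t) length(t$cds) > 0, gene$transcripts)
  if (length(coding_txs) == 0L) {
    warning(sprintf("gene '%s' has no annotated CDS; no coding introns",
                    gene$gene_id))
    return(empty_coding_introns(gene))
  }
  per_tx <- lapply(coding_txs, transcript_coding_introns, strand = gene$strand)
  per_tx <- Filter(Negate(is.null), per_tx)
  all_coding <- do.call(rbind, lapply(per_tx, function(d) d[d$coding, , drop = FALSE]))
  if (is.null(all_coding) || nrow(all_coding) == 0L) {
    return(empty_coding_introns(gene))
  }
  key <- paste(all_coding$start, all_coding$end, all_coding$phase)
  uniq <- all_coding[!duplicated(key), , drop = FALSE]
  # conflicting phases for the same boundaries across isoforms: keep one row
  # per boundary pair, unshared
  bkey <- paste(uniq$start, uniq$end)
  uniq <- uniq[!duplicated(bkey), , drop = FALSE]
  shared <- vapply(seq_len(nrow(uniq)), function(i) {
    all(vapply(per_tx, function(d) {
      any(d$coding & d$start == uniq$start[i] & d$end == uniq$end[i] &
            d$phase == uniq$phase[i])
    }, logical(1)))
  }, logical(1))
  out <- data.frame(
    gene_id = gene$gene_id,
    contig = gene$contig,
    start = uniq$start,
    end = uniq$end,
    width = uniq$end - uniq$start + 1L,
    phase = uniq$phase,
    upstream_exon = uniq$upstream_exon,
    downstream_exon = uniq$downstream_exon,
    shared_by_all_coding_transcripts = shared,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("coding_introns", "data.frame")
  out
}

empty_coding_introns <- function(gene) {
  out <- data.frame(gene_id = character(0), contig = character(0),
                    start = integer(0), end = integer(0), width = integer(0),
                    phase = integer(0), upstream_exon = character(0),
                    downstream_exon = character(0),
                    shared_by_all_coding_transcripts = logical(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("coding_introns", "data.frame")
  out
}

#' Check splice dinucleotides of introns
#'
#' Verifies that each intron body starts with the canonical donor GT and
#' ends with the acceptor AG on the gene strand. Non-canonical sites give a
#' warning, not an error.
#'
#' @param genome [Biostrings::DNAStringSet] from [load_genome()].
#' @param introns a `coding_introns` frame.
#' @param strand gene strand, "+" or "-".
#' @return the frame with `donor_site`, `acceptor_site`, `canonical` added.
#' @export
check_splice_sites <- function(genome, introns, strand = "+") {
  if (nrow(introns) == 0L) {
    introns$donor_site <- character(0)
    introns$acceptor_site <- character(0)
    introns$canonical <- logical(0)
    return(introns)
  }
  seq <- contig_seq(genome, introns$contig[1])
  body <- substring(seq, introns$start, introns$end)
  if (strand == "-") body <- revcomp(body)
  introns$donor_site <- substr(body, 1L, 2L)
  introns$acceptor_site <- substring(body, nchar(body) - 1L, nchar(body))
  introns$canonical <- introns$donor_site == "GT" & introns$acceptor_site == "AG"
  if (any(!introns$canonical)) {
    warning(sprintf("%d intron(s) with non-canonical splice dinucleotides",
                    sum(!introns$canonical)))
  }
  introns
}

#' Load strain variants from a VCF, verified against the genome
#'
#' Positions are converted from the VCF's 1-based convention; `pos` is the
#' 1-based start of the REF allele and `pos0` the interbase coordinate
#' (`pos - 1`). Variants whose REF allele disagrees with the reference
#' genome are dropped with a warning. Multi-allelic records are expanded.
#'
#' @param path VCF file (v4.x, plain or bgzipped).
#' @param genome genome from [load_genome()] used for REF verification.
#' @param contig restrict to this contig (default: all).
#' @param start,end optional 1-based closed interval filter on `pos`.
#' @return data frame (class `strain_variants`) with columns `contig`,
#'   `pos`, `pos0`, `end`, `ref`, `alt`, `kind`
#'   (SNV/insertion/deletion/MNV).
#' @export
load_variants <- function(path, genome, contig = NULL, start = NULL, end = NULL) {
  if (!file.exists(path)) {
    dropin_error(sprintf("VCF not found: %s", path), "dropin_io_error")
  }
  vcf <- tryCatch(
    VariantAnnotation::expand(VariantAnnotation::readVcf(path)),
    error = function(e) dropin_error(
      sprintf("failed to parse VCF '%s': %s", path, conditionMessage(e)),
      "dropin_vcf_error")
  )
  rr <- SummarizedExperiment::rowRanges(vcf)
  df <- data.frame(
    contig = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(rr$REF),
    alt = as.character(rr$ALT),
    stringsAsFactors = FALSE
  )
  if (!is.null(contig)) df <- df[df$contig == contig, , drop = FALSE]
  if (!is.null(start)) df <- df[df$pos >= start, , drop = FALSE]
  if (!is.null(end)) df <- df[df$pos <= end, , drop = FALSE]
  if (nrow(df)) {
    ok <- logical(nrow(df))
    for (i in seq_len(nrow(df))) {
      if (!df$contig[i] %in% names(genome)) { ok[i] <- FALSE; next }
      seq <- contig_seq(genome, df$contig[i])
      obs <- substring(seq, df$pos[i], df$pos[i] + nchar(df$ref[i]) - 1L)
      ok[i] <- identical(obs, df$ref[i])
    }
    if (any(!ok)) {
      warning(sprintf(
        "%d variant(s) dropped: REF allele disagrees with the reference genome (%s)",
        sum(!ok),
        paste(sprintf("%s:%d", df$contig[!ok], df$pos[!ok]), collapse = ", ")))
      df <- df[ok, , drop = FALSE]
    }
  }
  nr <- nchar(df$ref); na <- nchar(df$alt)
  df$kind <- ifelse(nr == 1 & na == 1, "SNV",
             ifelse(nr < na, "insertion",
             ifelse(nr > na, "deletion", "MNV")))
  df$pos0 <- df$pos - 1L
  df$end <- df$pos + nr - 1L
  df <- df[, c("contig", "pos", "pos0", "end", "ref", "alt", "kind")]
  rownames(df) <- NULL
  class(df) <- c("strain_variants", "data.frame")
  df
}
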