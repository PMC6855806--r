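# Independent oracles: deliberately separate implementations (no calls into
# the package's sequence machinery) used to cross-check the pipeline.

# reverse complement by character table, no Biostrings
oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", toupper(s)), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# brute-force SpCas9 NGG scan: test every 23-mer on both strands of the
# 1-based closed window [start, end]; cut rule applied by hand
oracle_scan_guides <- function(seq, start, end) {
  rows <- list()
  n_pos <- end - start + 1L - 22L
  if (n_pos < 1L) return(NULL)
  starts <- start:(end - 22L)
  mers <- substring(seq, starts, starts + 22L)
  hasN <- grepl("N", mers, fixed = TRUE)
  # + strand: positions 22 and 23 of the 23-mer must be G
  plus <- !hasN & substr(mers, 22L, 22L) == "G" & substr(mers, 23L, 23L) == "G"
  if (any(plus)) {
    i <- starts[plus]
    rows$p <- data.frame(
      protospacer = substr(mers[plus], 1L, 20L),
      pam = substr(mers[plus], 21L, 23L),
      strand = "+", p_start = i, p_end = i + 19L,
      cut_site = i + 16L, stringsAsFactors = FALSE)
  }
  # - strand: revcomp of the 23-mer is protospacer+PAM
  rc <- oracle_revcomp(mers)
  minus <- !hasN & substr(rc, 22L, 22L) == "G" & substr(rc, 23L, 23L) == "G"
  if (any(minus)) {
    i <- starts[minus]
    rows$m <- data.frame(
      protospacer = substr(rc[minus], 1L, 20L),
      pam = substr(rc[minus], 21L, 23L),
      strand = "-", p_start = i + 3L, p_end = i + 22L,
      cut_site = i + 5L, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  out <- out[order(out$cut_site, out$strand, out$p_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# count exact occurrences of a unit on both strands by exhaustive k-mer scan
oracle_count_unit <- function(seq, unit) {
  k <- nchar(unit)
  n <- nchar(seq)
  if (n < k) return(0L)
  mers <- substring(seq, 1:(n - k + 1L), k:n)
  sum(mers == unit) + sum(mers == oracle_revcomp(unit))
}

# hand-coded standard genetic code translation (independent of Biostrings)
ORACLE_CODONS <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

oracle_translate <- function(nt) {
  n <- nchar(nt) - nchar(nt) %% 3L
  if (n < 3L) return("")
  codons <- substring(nt, seq(1L, n, 3L), seq(3L, n, 3L))
  paste(ORACLE_CODONS[codons], collapse = "")
}

# second, independently coded nearest-neighbor Tm (same published unified
# parameter set, different data layout and iteration)
oracle_tm <- function(primer, conc_nM = 250, na_mM = 50) {
  p <- strsplit(toupper(primer), "")[[1]]
  n <- length(p)
  dH <- matrix(NA_real_, 4, 4, dimnames = list(c("A","C","G","T"),
                                               c("A","C","G","T")))
  dS <- dH
  set2 <- function(x, y, h, s) {
    dH[x, y] <<- h; dS[x, y] <<- s
    rx <- chartr("ACGT", "TGCA", y); ry <- chartr("ACGT", "TGCA", x)
    dH[rx, ry] <<- h; dS[rx, ry] <<- s
  }
  set2("A", "A", -7.9, -22.2); set2("A", "T", -7.2, -20.4)
  set2("T", "A", -7.2, -21.3); set2("C", "A", -8.5, -22.7)
  set2("G", "T", -8.4, -22.4); set2("C", "T", -7.8, -21.0)
  set2("G", "A", -8.2, -22.2); set2("C", "G", -10.6, -27.2)
  set2("G", "C", -9.8, -24.4); set2("G", "G", -8.0, -19.9)
  h <- 0; s <- 0
  for (i in seq_len(n - 1L)) {
    h <- h + dH[p[i], p[i + 1L]]
    s <- s + dS[p[i], p[i + 1L]]
  }
  for (term in p[c(1L, n)]) {
    if (term %in% c("G", "C")) { h <- h + 0.1; s <- s - 2.8 }
    else { h <- h + 2.3; s <- s + 4.1 }
  }
  s <- s + 0.368 * (n - 1L) * log(na_mM / 1000)
  h * 1000 / (s + 1.987 * log(conc_nM * 1e-9 / 4)) - 273.15
}

# convenience: generate a locus and return it with handy accessors
make_locus <- function(seed = 1L, ...) {
  res <- generate_locus(synthetic_locus_spec(seed = seed, ...))
  res$seq <- as.character(res$genome[[1]])
  res$gene <- gene_models(res$annotation)[[1]]
  res
}

# a tiny single-contig genome from a raw string
string_genome <- function(seq, id = "ctg") {
  Biostrings::DNAStringSet(stats::setNames(seq, id))
}
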