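# In/out genotyping PCR design: genomic flanking primers combined with
# outward-facing cassette-internal primers, amplicons in 200-800 nt.

# SantaLucia (1998) unified nearest-neighbor parameters.
# dH kcal/mol, dS cal/(mol K), keyed by top-strand dinucleotide.
NN_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
           CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
           TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2,
           CC = -8.0)
NN_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
           CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
           TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
           CC = -19.9)

#' Nearest-neighbor melting temperature
#'
#' Unified nearest-neighbor model (SantaLucia 1998) with terminal
#' initiation terms and the entropic salt correction
#' dS' = dS + 0.368 (N-1) ln\[Na+\]. Tm is reported for the
#' non-self-complementary duplex case at primer concentration `conc_nM`.
#' By strand symmetry of the parameter table, Tm(p) == Tm(revcomp(p)).
#'
#' @param primer DNA string, 10-40 nt, no N.
#' @param conc_nM primer concentration in nM (default 250).
#' @param na_mM monovalent cation concentration in mM (default 50).
#' @return melting temperature in degrees Celsius.
#' @export
compute_tm <- function(primer, conc_nM = 250, na_mM = 50) {
  primer <- toupper(primer)
  n <- nchar(primer)
  if (n < 10L || n > 40L) {
    dropin_error(sprintf("primer length %d outside 10-40 nt", n),
                 "dropin_primer_error")
  }
  if (grepl("[^ACGT]", primer)) {
    dropin_error("primer contains a non-ACGT character", "dropin_primer_error")
  }
  pairs <- substring(primer, 1:(n - 1L), 2:n)
  dh <- sum(NN_DH[pairs])
  ds <- sum(NN_DS[pairs])
  ends <- c(substr(primer, 1L, 1L), substr(primer, n, n))
  for (e in ends) {
    if (e %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds + (-2.8) }
    else { dh <- dh + 2.3; ds <- ds + 4.1 }
  }
  ds <- ds + 0.368 * (n - 1L) * log(na_mM / 1000)
  ct <- conc_nM * 1e-9
  dh * 1000 / (ds + 1.987 * log(ct / 4)) - 273.15
}

# enumerate acceptable primer substrings of `seq` (template orientation)
# within a 1-based window; returns start, len, seq, tm, gc
candidate_primers <- function(seq, win_start, win_end, params) {
  out <- list()
  for (len in params$len_range[1]:params$len_range[2]) {
    starts <- seq.int(max(1L, win_start), win_end - len + 1L)
    starts <- starts[starts + len - 1L <= nchar(seq)]
    if (!length(starts)) next
    cand <- substring(seq, starts, starts + len - 1L)
    keep <- !grepl("N", cand, fixed = TRUE)
    starts <- starts[keep]; cand <- cand[keep]
    if (!length(starts)) next
    gc <- vapply(cand, gc_fraction, numeric(1))
    run_ok <- vapply(cand, max_homopolymer_run, numeric(1)) <= params$max_run
    sel <- gc >= params$gc_range[1] & gc <= params$gc_range[2] & run_ok
    starts <- starts[sel]; cand <- cand[sel]; gc <- gc[sel]
    if (!length(starts)) next
    tm <- vapply(cand, compute_tm, numeric(1))
    sel <- tm >= params$tm_range[1] & tm <= params$tm_range[2]
    if (!any(sel)) next
    out[[length(out) + 1L]] <- data.frame(
      start = starts[sel], len = len, seq = unname(cand[sel]),
      tm = unname(tm[sel]), gc = unname(gc[sel]), stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), len = integer(0),
                      seq = character(0), tm = numeric(0), gc = numeric(0)))
  }
  do.call(rbind, out)
}

#' Default validation-PCR design parameters
#'
#' @param search_window nt of genomic flank searched on each side of a
#'   junction (default 700).
#' @param insert_window nt of cassette sequence searched at each cassette
#'   end (default 400).
#' @param len_range primer length bounds (default 18-25).
#' @param gc_range GC-fraction bounds (default 0.35-0.65).
#' @param tm_range nearest-neighbor Tm window in deg C (default 57-63).
#' @param max_run longest allowed mononucleotide run (default 4).
#' @param amplicon_range allowed product size (default 200-800 nt).
#' @param amplicon_target preferred product size (default 500 nt).
#' @return parameter list for [design_validation_primers()].
#' @export
validation_params <- function(search_window = 700L, insert_window = 400L,
                              len_range = c(18L, 25L),
                              gc_range = c(0.35, 0.65),
                              tm_range = c(57, 63), max_run = 4L,
                              amplicon_range = c(200L, 800L),
                              amplicon_target = 500L) {
  list(search_window = search_window, insert_window = insert_window,
       len_range = len_range, gc_range = gc_range, tm_range = tm_range,
       max_run = max_run, amplicon_range = amplicon_range,
       amplicon_target = amplicon_target)
}

# count exact binding sites of a primer (either strand) in a sequence
binding_sites <- function(primer, seq) {
  length(find_exact(primer, seq)) + length(find_exact(revcomp(primer), seq))
}

#' Design in/out genotyping primers for an edited allele
#'
#' Two junction-spanning pairs are designed on the edited allele: a genomic
#' forward primer upstream of the insert paired with a cassette-internal
#' reverse primer near the insert 5' end, and a cassette-internal forward
#' primer near the insert 3' end paired with a genomic reverse primer
#' downstream. Primers must pass length/GC/Tm/homopolymer filters and bind
#' exactly once in the edited allele; each pair's amplicon must fall in the
#' allowed window, preferring the size closest to the target. The insert
#' primers have no binding site in the unedited reference, so in/out pairs
#' are knock-in specific. Design is deterministic.
#'
#' @param edited `edited_allele` from [simulate_hdr()].
#' @param params see [validation_params()].
#' @return `validation_primer_set`: `primers` (data frame: name, seq, tm,
#'   gc, strand, start on edited allele) and `amplicons` (data frame: pair,
#'   fwd/rev names, start, end, length).
#' @export
design_validation_primers <- function(edited, params = validation_params()) {
  stopifnot(inherits(edited, "edited_allele"))
  seq <- edited$sequence
  ins <- edited$insert_interval
  pick_pair <- function(fwd_cand, rev_cand, label) {
    # fwd_cand: forward-strand primers (start = 5' position);
    # rev_cand rows carry `start`,`len` of the binding site on the forward
    # strand; the primer itself is the revcomp. Uniqueness in the edited
    # allele is verified lazily on the selected pair (dropping a primer and
    # reselecting on failure), which keeps the search deterministic.
    uniq_cache <- new.env(parent = emptyenv())
    is_unique <- function(p) {
      hit <- uniq_cache[[p]]
      if (is.null(hit)) {
        hit <- binding_sites(p, seq) == 1L
        uniq_cache[[p]] <- hit
      }
      hit
    }
    repeat {
      if (nrow(fwd_cand) == 0L || nrow(rev_cand) == 0L) {
        dropin_error(sprintf(
          "no candidate primers for the %s junction (fwd %d, rev %d survivors)",
          label, nrow(fwd_cand), nrow(rev_cand)),
          "dropin_primer_error",
          counts = c(fwd = nrow(fwd_cand), rev = nrow(rev_cand)))
      }
      best <- NULL
      for (i in seq_len(nrow(fwd_cand))) {
        alen <- (rev_cand$start + rev_cand$len - 1L) - fwd_cand$start[i] + 1L
        ok <- which(alen >= params$amplicon_range[1] &
                      alen <= params$amplicon_range[2])
        if (!length(ok)) next
        j <- ok[which.min(abs(alen[ok] - params$amplicon_target))]
        cand <- list(fwd = fwd_cand[i, ], rev = rev_cand[j, ], length = alen[j])
        if (is.null(best) ||
            abs(cand$length - params$amplicon_target) <
              abs(best$length - params$amplicon_target)) {
          best <- cand
        }
      }
      if (is.null(best)) {
        dropin_error(sprintf(
          "no %s-junction primer pair yields an amplicon in [%d,%d]",
          label, params$amplicon_range[1], params$amplicon_range[2]),
          "dropin_primer_error")
      }
      if (!is_unique(best$fwd$seq)) {
        fwd_cand <- fwd_cand[fwd_cand$seq != best$fwd$seq, , drop = FALSE]
        next
      }
      if (!is_unique(best$rev$seq)) {
        rev_cand <- rev_cand[rev_cand$seq != best$rev$seq, , drop = FALSE]
        next
      }
      return(best)
    }
  }
  W <- params$search_window; IW <- params$insert_window
  # 5' junction: genomic fwd upstream of insert + insert-internal reverse
  g5 <- candidate_primers(seq, max(1L, ins["start"] - W), ins["start"] - 1L,
                          params)
  i5 <- candidate_primers(seq, ins["start"],
                          min(ins["end"], ins["start"] + IW - 1L), params)
  p5 <- pick_pair(g5, i5, "5prime")
  # 3' junction: insert-internal forward + genomic reverse downstream
  i3 <- candidate_primers(seq, max(ins["start"], ins["end"] - IW + 1L),
                          ins["end"], params)
  g3 <- candidate_primers(seq, ins["end"] + 1L,
                          min(nchar(seq), ins["end"] + W), params)
  p3 <- pick_pair(i3, g3, "3prime")
  mk <- function(row, name, strand) {
    pseq <- if (strand == "+") row$seq else revcomp(row$seq)
    data.frame(name = name, seq = pseq, tm = row$tm, gc = row$gc,
               strand = strand, start = row$start, len = row$len,
               stringsAsFactors = FALSE)
  }
  primers <- rbind(
    mk(p5$fwd, "genomic_fwd", "+"),
    mk(p5$rev, "insert_rev_5p", "-"),
    mk(p3$fwd, "insert_fwd_3p", "+"),
    mk(p3$rev, "genomic_rev", "-"))
  amplicons <- data.frame(
    pair = c("5prime_junction", "3prime_junction"),
    fwd = c("genomic_fwd", "insert_fwd_3p"),
    rev = c("insert_rev_5p", "genomic_rev"),
    start = c(p5$fwd$start, p3$fwd$start),
    end = c(p5$rev$start + p5$rev$len - 1L, p3$rev$start + p3$rev$len - 1L),
    length = c(p5$length, p3$length),
    stringsAsFactors = FALSE)
  structure(list(primers = primers, amplicons = amplicons),
            class = "validation_primer_set")
}

#' @export
print.validation_primer_set <- function(x, ...) {
  cat("validation_primer_set:\n")
  for (i in seq_len(nrow(x$amplicons))) {
    a <- x$amplicons[i, ]
    cat(sprintf("  %s: %s + %s -> %d nt (%d..%d)\n",
                a$pair, a$fwd, a$rev, a$length, a$start, a$end))
  }
  invisible(x)
}

#' Virtual PCR by exact primer matching
#'
#' Finds all products of a primer pair on a template: forward-primer exact
#' matches on the top strand paired with reverse-primer matches (as
#' revcomp on the top strand) downstream of them, convergent orientation.
#'
#' @param template DNA string.
#' @param fwd,rev primer sequences (5'->3').
#' @param max_len ignore products longer than this (default 20 kb).
#' @return data frame `start`, `end`, `length` per product.
#' @export
virtual_pcr <- function(template, fwd, rev, max_len = 20000L) {
  f <- find_exact(fwd, template)
  r_site <- revcomp(rev)
  r <- find_exact(r_site, template)
  out <- list()
  for (fs in f) {
    re <- r[r + nchar(r_site) - 1L >= fs + nchar(fwd) - 1L]
    for (rs in re) {
      len <- rs + nchar(r_site) - 1L - fs + 1L
      if (len <= max_len) {
        out[[length(out) + 1L]] <- data.frame(
          start = fs, end = rs + nchar(r_site) - 1L, length = len)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0), length = integer(0)))
  }
  do.call(rbind, out)
}

#' Write a validation-primer TSV
#' @param vset `validation_primer_set`.
#' @param path output TSV.
#' @return the path, invisibly.
#' @export
write_primer_report <- function(vset, path) {
  pr <- vset$primers
  pair <- c(genomic_fwd = "5prime_junction", insert_rev_5p = "5prime_junction",
            insert_fwd_3p = "3prime_junction", genomic_rev = "3prime_junction")
  pr$pair <- pair[pr$name]
  pr$product_len <- vset$amplicons$length[match(pr$pair, vset$amplicons$pair)]
  write.table(pr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
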