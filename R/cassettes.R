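# Cassette template library.
#
# The templates bundled here are *synthetic stand-ins*: deterministic
# sequences with the same element layout, element lengths and total lengths
# as the published drop-in cassettes, built so that every design-time check
# (priming segments, splice elements, reading frames, polyA signals,
# printed length arithmetic) behaves as with the real sequences. They are
# not the real vector sequences and must not be ordered for synthesis.
# Loading a real template library simply means constructing
# cassette_template() objects from the vendor/repository records.

.cassette_env <- new.env(parent = emptyenv())

# deterministic sequence elements shared by the stand-in templates
cassette_elements <- function() {
  if (!is.null(.cassette_env$elements)) return(.cassette_env$elements)
  el <- with_seed(603011, {
    polyY <- "TCTTTCTTTCCTTTCTCTCCTTTTCCTTAG"      # 3' splice site, ends AG
    list(
      attp_l   = random_dna(50),
      attp_r   = random_dna(50),
      frt      = random_dna(34),
      sa       = paste0(random_dna(51), polyY),    # 81 nt, acceptor AG at 3'
      sd       = paste0("GTAAGT", random_dna(24)), # 30 nt, donor GT at 5'
      stop3x   = "TAGCTAGCTAGC",                   # stop in all three frames
      minipolya = paste0(random_dna(8), "AATAAA", random_dna(21)),   # 35 nt
      polya    = paste0(random_dna(20), "AATAAA", random_dna(109)),  # 135 nt
      u6grna1_prom = random_dna(261),
      grna1_protospacer = random_dna(20),
      grna1_pam = "TGG",
      grna1_term = "TTTTTT",
      t2a      = random_codons(60),
      minigal4 = random_codons(1200),
      gal4     = random_codons(2646),
      p3egfp   = random_dna(1142),
      linker1  = random_codons(132),
      sfgfp    = random_codons(714),
      linker2  = random_codons(135),
      stopc    = "TAA",
      spacer2  = "GC",
      stuffer_spacer = random_dna(24)
    )
  })
  el$u6grna1 <- paste0(el$u6grna1_prom, el$grna1_protospacer, el$grna1_term)
  .cassette_env$elements <- el
  el
}

#' The gRNA1 linearization unit
#'
#' A 20-nt protospacer plus NGG PAM with no target in the genomes the
#' package designs against (verified at construct-build time). It flanks
#' synthesized dsDNA drop-in donors so Cas9 releases the donor from the
#' plasmid in vivo, and is also carried by the U6-gRNA1 marker element.
#' The bundled sequence is a synthetic stand-in.
#'
#' @return list with `protospacer`, `pam` and `unit` (protospacer+PAM).
#' @export
grna1_unit <- function() {
  el <- cassette_elements()
  list(protospacer = el$grna1_protospacer, pam = el$grna1_pam,
       unit = paste0(el$grna1_protospacer, el$grna1_pam))
}

# assemble named parts into a core sequence plus a feature table
assemble_core <- function(parts) {
  lens <- nchar(parts)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  core <- paste(parts, collapse = "")
  feats <- data.frame(label = names(parts), start = as.integer(starts),
                      end = as.integer(ends), stringsAsFactors = FALSE)
  list(core = core, features = feats)
}

#' Construct a cassette template
#'
#' @param name cassette name.
#' @param core_seq the attP...attP core sequence (PCR template / synthesis
#'   payload, homology arms not included).
#' @param features data frame `label`, `start`, `end` (1-based within
#'   core).
#' @param mutagenic_class one of `gene_trap`, `protein_trap`,
#'   `neutral_landing_site`.
#' @param phase_variant 0/1/2 for splice-acceptor cassettes, NA otherwise.
#' @param standin TRUE when the sequence is a synthetic stand-in rather
#'   than the real cassette.
#' @return a `cassette_template` object. The universal priming segments are
#'   derived from the core: `fwd_priming` is its first 26 nt; `rev_priming`
#'   is the 24-nt reverse PCR primer, i.e. the reverse complement of its
#'   last 24 nt.
#' @export
cassette_template <- function(name, core_seq, features,
                              mutagenic_class = c("gene_trap", "protein_trap",
                                                  "neutral_landing_site"),
                              phase_variant = NA_integer_,
                              standin = FALSE) {
  mutagenic_class <- match.arg(mutagenic_class)
  n <- nchar(core_seq)
  if (n < 50L) dropin_error("cassette core too short", "dropin_template_error")
  if (any(features$start < 1L | features$end > n | features$end < features$start)) {
    dropin_error("cassette feature interval outside core", "dropin_template_error")
  }
  structure(list(
    name = name,
    core_seq = core_seq,
    core_len = n,
    fwd_priming = substr(core_seq, 1L, 26L),
    rev_priming = revcomp(substring(core_seq, n - 23L, n)),
    features = features,
    mutagenic_class = mutagenic_class,
    phase_variant = phase_variant,
    standin = standin
  ), class = "cassette_template")
}

#' @export
print.cassette_template <- function(x, ...) {
  cat(sprintf("cassette_template '%s': %d nt core, class %s%s\n",
              x$name, x$core_len, x$mutagenic_class,
              if (isTRUE(x$standin)) " (synthetic stand-in)" else ""))
  cat("  features:", paste(unique(x$features$label), collapse = ", "), "\n")
  invisible(x)
}

# interval of a named feature (first occurrence unless last = TRUE)
feature_interval <- function(template, label, last = FALSE) {
  f <- template$features[template$features$label == label, , drop = FALSE]
  if (nrow(f) == 0L) return(NULL)
  if (last) f[nrow(f), ] else f[1, ]
}

#' Bundled cassette template library (synthetic stand-ins)
#'
#' Builds the five drop-in cassette templates with element layouts and
#' total core lengths matching the published constructs:
#' \itemize{
#'   \item `attP-3XP3-EGFP-attP` - 1242 nt neutral landing-site PCR
#'     template (1442 nt donor with two 100-nt arms);
#'   \item `attP-SA-sfGFP-SD-attP` - protein-trap artificial exon, 1192 nt
#'     core (1392 nt donor with arms);
#'   \item `attP-SA-3XSTOP-minipolyA-U6gRNA1-attP` - minimal mutagenic gene
#'     trap, 515 nt core (715 nt with arms);
#'   \item `attP-SA-T2A-miniGAL4-minipolyA-U6gRNA1-attP` - gene trap with
#'     GAL4 driver, 1768 nt core (1968 nt with arms);
#'   \item `attP-FRT-SA-T2A-GAL4-polyA-3XP3-EGFP-FRT-attP` - full
#'     swappable integration cassette used for plasmid subcloning designs.
#' }
#' All sequences are deterministic synthetic stand-ins (see
#' [cassette_template()]); regenerating the library always yields identical
#' sequences.
#'
#' @return named list of `cassette_template` objects.
#' @export
cassette_library <- function() {
  if (!is.null(.cassette_env$library)) return(.cassette_env$library)
  el <- cassette_elements()
  lib <- list()

  a <- assemble_core(c(attP = el$attp_l, `3XP3-EGFP` = el$p3egfp,
                       attP = el$attp_r))
  lib[["attP-3XP3-EGFP-attP"]] <- cassette_template(
    "attP-3XP3-EGFP-attP", a$core, a$features,
    mutagenic_class = "neutral_landing_site", standin = TRUE)

  a <- assemble_core(c(attP = el$attp_l, SA = el$sa, Linker = el$linker1,
                       sfGFP = el$sfgfp, Linker = el$linker2, SD = el$sd,
                       attP = el$attp_r))
  lib[["attP-SA-sfGFP-SD-attP"]] <- cassette_template(
    "attP-SA-sfGFP-SD-attP", a$core, a$features,
    mutagenic_class = "protein_trap", phase_variant = 0L, standin = TRUE)

  a <- assemble_core(c(attP = el$attp_l, SA = el$sa, `3XSTOP` = el$stop3x,
                       minipolyA = el$minipolya, `U6-gRNA1` = el$u6grna1,
                       attP = el$attp_r))
  lib[["attP-SA-3XSTOP-minipolyA-U6gRNA1-attP"]] <- cassette_template(
    "attP-SA-3XSTOP-minipolyA-U6gRNA1-attP", a$core, a$features,
    mutagenic_class = "gene_trap", phase_variant = 0L, standin = TRUE)

  a <- assemble_core(c(attP = el$attp_l, SA = el$sa, T2A = el$t2a,
                       miniGAL4 = el$minigal4, stop = el$stopc,
                       minipolyA = el$minipolya, spacer = el$spacer2,
                       `U6-gRNA1` = el$u6grna1, attP = el$attp_r))
  lib[["attP-SA-T2A-miniGAL4-minipolyA-U6gRNA1-attP"]] <- cassette_template(
    "attP-SA-T2A-miniGAL4-minipolyA-U6gRNA1-attP", a$core, a$features,
    mutagenic_class = "gene_trap", phase_variant = 0L, standin = TRUE)

  a <- assemble_core(c(attP = el$attp_l, FRT = el$frt, SA = el$sa,
                       T2A = el$t2a, GAL4 = el$gal4, stop = el$stopc,
                       polyA = el$polya, `3XP3-EGFP` = el$p3egfp,
                       FRT = el$frt, attP = el$attp_r))
  lib[["attP-FRT-SA-T2A-GAL4-polyA-3XP3-EGFP-FRT-attP"]] <- cassette_template(
    "attP-FRT-SA-T2A-GAL4-polyA-3XP3-EGFP-FRT-attP", a$core, a$features,
    mutagenic_class = "gene_trap", phase_variant = 0L, standin = TRUE)

  .cassette_env$library <- lib
  lib
}

#' Phase variant of a splice-acceptor cassette
#'
#' The reading frame downstream of the splice acceptor must match the
#' intron phase p (= cumulative upstream CDS mod 3). The phase-p variant
#' inserts `(3 - p) %% 3` codon-completing nucleotides immediately after
#' the SA element so the payload starts on a codon boundary; for protein
#' traps a compensating pad before the SD keeps the artificial-exon length
#' a multiple of 3, preserving the downstream native frame.
#'
#' @param template a splice-acceptor `cassette_template` (phase-0 form).
#' @param phase target intron phase, 0/1/2.
#' @return a `cassette_template` for that phase (total length +0 or +3 nt).
#' @export
cassette_phase_variant <- function(template, phase) {
  stopifnot(inherits(template, "cassette_template"), phase %in% 0:2)
  sa <- feature_interval(template, "SA")
  if (is.null(sa)) {
    dropin_error(sprintf("cassette '%s' has no splice acceptor; phase is not applicable",
                         template$name), "dropin_template_error")
  }
  if (phase == 0L) {
    t <- template
    t$phase_variant <- 0L
    return(t)
  }
  pad <- (3L - phase) %% 3L
  pad_seq <- substr("GC", 1L, pad)
  insert_at <- function(core, feats, pos0, seq, label) {
    # insert `seq` after interbase position pos0, shifting features
    n <- nchar(seq)
    core2 <- paste0(substr(core, 1L, pos0), seq,
                    substring(core, pos0 + 1L))
    feats$start <- ifelse(feats$start > pos0, feats$start + n, feats$start)
    feats$end <- ifelse(feats$end > pos0, feats$end + n, feats$end)
    feats <- rbind(feats, data.frame(label = label, start = pos0 + 1L,
                                     end = pos0 + n, stringsAsFactors = FALSE))
    feats <- feats[order(feats$start), , drop = FALSE]
    list(core = core2, features = feats)
  }
  st <- insert_at(template$core_seq, template$features, sa$end, pad_seq,
                  "phase_pad")
  if (template$mutagenic_class == "protein_trap") {
    sd <- feature_interval(
      cassette_template(template$name, st$core, st$features,
                        template$mutagenic_class, standin = template$standin),
      "SD")
    comp <- (3L - pad) %% 3L
    comp_seq <- substr("CG", 1L, comp)
    st <- insert_at(st$core, st$features, sd$start - 1L, comp_seq,
                    "phase_pad")
  }
  out <- cassette_template(template$name, st$core, st$features,
                           mutagenic_class = template$mutagenic_class,
                           phase_variant = as.integer(phase),
                           standin = template$standin)
  out
}

#' Restriction enzyme catalog for subcloning designs
#'
#' A small table of palindromic enzymes with cut offsets: `cut_top` and
#' `cut_bottom` are interbase offsets of the top- and bottom-strand cuts
#' within the recognition site. All bundled sites are palindromic, so
#' overhangs from the same enzyme are mutually complementary.
#'
#' @return data frame `name`, `site`, `cut_top`, `cut_bottom`.
#' @export
re_catalog <- function() {
  data.frame(
    name = c("EcoRI", "BamHI", "HindIII", "XhoI", "NheI", "SpeI",
             "KpnI", "SacI", "NotI"),
    site = c("GAATTC", "GGATCC", "AAGCTT", "CTCGAG", "GCTAGC", "ACTAGT",
             "GGTACC", "GAGCTC", "GCGGCCGC"),
    cut_top = c(1L, 1L, 1L, 1L, 1L, 1L, 5L, 5L, 2L),
    cut_bottom = c(5L, 5L, 5L, 5L, 5L, 5L, 1L, 1L, 6L),
    stringsAsFactors = FALSE
  )
}

#' Cloning-vector backbone (synthetic stand-in)
#'
#' A deterministic 2710-nt circular backbone standing in for a pUC57-class
#' cloning vector. It is scrubbed of every [re_catalog()] recognition site
#' and of the gRNA1 unit on both strands, so enzyme choice and
#' linearization are controlled entirely by the insert.
#'
#' @return single DNA string (circular by convention).
#' @export
puc57_backbone <- function() {
  if (!is.null(.cassette_env$backbone)) return(.cassette_env$backbone)
  seq <- with_seed(702013, random_dna(2710, gc = 0.5))
  motifs <- c(re_catalog()$site, grna1_unit()$unit)
  motifs <- unique(c(motifs, revcomp(motifs)))
  rot <- c(A = "C", C = "G", G = "T", T = "A")
  repeat {
    hit <- FALSE
    for (m in motifs) {
      p <- find_exact(m, seq)
      while (length(p)) {
        i <- p[1] + nchar(m) %/% 2L
        substr(seq, i, i) <- rot[[substr(seq, i, i)]]
        hit <- TRUE
        p <- find_exact(m, seq)
      }
    }
    if (!hit) break
  }
  .cassette_env$backbone <- seq
  seq
}
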