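# Homology-arm extraction around the blunt Cas9 cut.
#
# The left arm is the lha_len nt immediately 5' of the cut and the right
# arm the rha_len nt immediately 3' of it, on the gene's coding strand.
# For a +-strand guide the left arm therefore ends exactly 3 nt before the
# PAM. Arms abut the cut with no gap, so lha + rha reproduces the
# contiguous reference window around the cut (seamless HDR precondition).

#' Extract and vet homology arms around a cut site
#'
#' Arms are taken on the reference forward strand around `cut_site`, then
#' both reverse-complemented and swapped when `gene_strand` is "-", so the
#' LHA is always transcriptionally upstream of the insert.
#'
#' @param genome genome from [load_genome()].
#' @param contig contig id.
#' @param cut_site interbase cut coordinate (e.g. `guide$cut_site`).
#' @param gene_strand strand of the target gene, "+" or "-".
#' @param lha_len,rha_len arm lengths in nt (default 100/100; the literal
#'   100/97 asymmetric reading is available by setting `rha_len = 97`).
#' @param forbidden_re_sites restriction recognition sequences that must
#'   not occur in either arm (searched on both strands).
#' @param grna1_site the gRNA1 protospacer+PAM unit (for synthesized
#'   donors), flagged if present in an arm.
#' @param variants optional `strain_variants`; any overlap with an arm sets
#'   `contains_variant`.
#' @return a `homology_arms` object: `lha`, `rha` (character, coding-strand
#'   orientation), `lha_len`, `rha_len`, `cut_site`, `contig`,
#'   `orientation`, and a `flags` list
#'   (`contains_variant`, `contains_forbidden_RE_site`,
#'   `contains_gRNA1_site`). An N anywhere in an arm is an error.
#' @export
design_arms <- function(genome, contig, cut_site, gene_strand = "+",
                        lha_len = 100L, rha_len = 100L,
                        forbidden_re_sites = character(0),
                        grna1_site = NULL, variants = NULL) {
  if (lha_len < 20L || rha_len < 20L) {
    dropin_error("homology arms must be at least 20 nt", "dropin_arm_error")
  }
  seq <- contig_seq(genome, contig)
  # genomic extents: the transcriptionally-left arm length depends on strand
  up_len <- if (gene_strand == "+") lha_len else rha_len
  dn_len <- if (gene_strand == "+") rha_len else lha_len
  if (cut_site - up_len < 0L || cut_site + dn_len > nchar(seq)) {
    dropin_error(sprintf(
      "cut site %d too close to the edge of contig '%s' for %d/%d arms",
      cut_site, contig, lha_len, rha_len), "dropin_arm_error")
  }
  fwd_left <- substring(seq, cut_site - up_len + 1L, cut_site)
  fwd_right <- substring(seq, cut_site + 1L, cut_site + dn_len)
  if (gene_strand == "+") {
    lha <- fwd_left; rha <- fwd_right
  } else {
    lha <- revcomp(fwd_right); rha <- revcomp(fwd_left)
  }
  both <- paste0(lha, rha)
  if (grepl("N", both, fixed = TRUE)) {
    dropin_error(sprintf("homology arm around cut %d contains N", cut_site),
                 "dropin_arm_error")
  }
  flags <- list(
    contains_N = FALSE,
    contains_variant = FALSE,
    contains_forbidden_RE_site = FALSE,
    contains_gRNA1_site = FALSE
  )
  which_arm <- function(motif) {
    hits <- c(if (motif_on_either_strand(motif, lha)) "LHA",
              if (motif_on_either_strand(motif, rha)) "RHA")
    hits
  }
  re_hits <- character(0)
  for (m in forbidden_re_sites) {
    h <- which_arm(m)
    if (length(h)) re_hits <- c(re_hits, sprintf("%s in %s", m, h))
  }
  if (length(re_hits)) flags$contains_forbidden_RE_site <- TRUE
  if (!is.null(grna1_site) && length(which_arm(grna1_site))) {
    flags$contains_gRNA1_site <- TRUE
  }
  if (!is.null(variants) && nrow(variants) > 0L) {
    arm_ir <- IRanges::IRanges(cut_site - up_len + 1L, cut_site + dn_len)
    v_ir <- IRanges::IRanges(variants$pos, variants$end)
    flags$contains_variant <- any(IRanges::overlapsAny(v_ir, arm_ir))
  }
  structure(list(
    lha = lha, rha = rha,
    lha_len = as.integer(lha_len), rha_len = as.integer(rha_len),
    cut_site = as.integer(cut_site), contig = contig,
    orientation = gene_strand,
    flags = flags,
    forbidden_hits = re_hits
  ), class = "homology_arms")
}

#' @export
print.homology_arms <- function(x, ...) {
  cat(sprintf("homology_arms: %d/%d nt around cut %d (%s, %s strand)\n",
              x$lha_len, x$rha_len, x$cut_site, x$contig, x$orientation))
  flag_on <- names(Filter(isTRUE, x$flags))
  if (length(flag_on)) cat("  flags:", paste(flag_on, collapse = ", "), "\n")
  invisible(x)
}
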