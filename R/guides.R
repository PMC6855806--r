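# SpCas9 (NGG) guide enumeration, variant-aware filtering and ranking.
#
# Cut-site model: SpCas9 cuts bluntly between the 17th and 18th protospacer
# nucleotide, i.e. 3 nt 5' of the PAM. With interbase coordinates this is
#   + strand: cut_site = protospacer_start0 + 17
#   - strand: cut_site = protospacer_start0 + 3
# where protospacer_start0 is the 0-based genomic start of the protospacer
# footprint (p_start - 1 in the 1-based columns below).

empty_guide_set <- function() {
  out <- data.frame(contig = character(0), protospacer = character(0),
                    pam = character(0), strand = character(0),
                    p_start = integer(0), p_end = integer(0),
                    cut_site = integer(0), variant_clean = logical(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("guide_set", "data.frame")
  out
}

#' Enumerate SpCas9 guides in a genomic window
#'
#' Every 23-mer matching N20-NGG on either strand within the window yields
#' one guide. Protospacers containing N are excluded. `p_start`/`p_end` are
#' the 1-based genomic footprint of the 20-nt protospacer; `cut_site` is
#' interbase (bases 5' of the blunt cut).
#'
#' @param genome genome from [load_genome()].
#' @param contig contig id.
#' @param start,end 1-based closed window; width must be >= 23.
#' @return `guide_set` data frame sorted by `cut_site`.
#' @export
scan_guides <- function(genome, contig, start, end) {
  seq <- contig_seq(genome, contig)
  if (start < 1L || end > nchar(seq)) {
    dropin_error(sprintf("window [%d,%d] outside contig '%s' (len %d)",
                         start, end, contig, nchar(seq)), "dropin_coord_error")
  }
  if (end - start + 1L < 23L) {
    dropin_error("guide scan window must be at least 23 nt", "dropin_coord_error")
  }
  win <- substring(seq, start, end)
  plus <- scan_strand(win)
  minus <- scan_strand(revcomp(win))
  L <- nchar(win)
  rows <- list()
  if (nrow(plus)) {
    rows$plus <- data.frame(
      contig = contig,
      protospacer = plus$protospacer, pam = plus$pam, strand = "+",
      p_start = start + plus$offset,            # offset is 0-based in window
      p_end = start + plus$offset + 19L,
      cut_site = (start - 1L) + plus$offset + 17L,
      stringsAsFactors = FALSE)
  }
  if (nrow(minus)) {
    # 23-mer at 0-based offset o in the revcomp window maps to forward
    # window offset L - o - 23; protospacer occupies the last 20 nt of the
    # forward-strand footprint
    fo <- L - minus$offset - 23L
    rows$minus <- data.frame(
      contig = contig,
      protospacer = minus$protospacer, pam = minus$pam, strand = "-",
      p_start = start + fo + 3L,
      p_end = start + fo + 22L,
      cut_site = (start - 1L) + fo + 6L,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_guide_set()
  for (col in c("p_start", "p_end", "cut_site")) out[[col]] <- as.integer(out[[col]])
  out$variant_clean <- rep(NA, nrow(out))
  out <- out[order(out$cut_site, out$strand, out$p_start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("guide_set", "data.frame")
  out
}

# N20-NGG matches on one strand of a window; returns 0-based offsets
scan_strand <- function(win) {
  L <- nchar(win)
  if (L < 23L) {
    return(data.frame(offset = integer(0), protospacer = character(0),
                      pam = character(0)))
  }
  starts <- seq_len(L - 22L)                 # 1-based 23-mer starts
  g1 <- substring(win, starts + 21L, starts + 21L) == "G"
  g2 <- substring(win, starts + 22L, starts + 22L) == "G"
  hit <- which(g1 & g2)
  if (!length(hit)) {
    return(data.frame(offset = integer(0), protospacer = character(0),
                      pam = character(0)))
  }
  proto <- substring(win, hit, hit + 19L)
  pam <- substring(win, hit + 20L, hit + 22L)
  keep <- !grepl("N", proto, fixed = TRUE) & !grepl("N", pam, fixed = TRUE)
  data.frame(offset = hit[keep] - 1L, protospacer = proto[keep],
             pam = pam[keep], stringsAsFactors = FALSE)
}

# guide footprint including PAM, 1-based closed
guide_footprint <- function(guides) {
  fs <- ifelse(guides$strand == "+", guides$p_start, guides$p_start - 3L)
  fe <- ifelse(guides$strand == "+", guides$p_end + 3L, guides$p_end)
  data.frame(start = fs, end = fe)
}

#' Flag guides overlapped by strain variants
#'
#' A guide is `variant_clean` iff no variant overlaps its
#' protospacer-plus-PAM footprint extended by `pad` nt on each side.
#' Non-clean guides are retained (they are demoted by [rank_guides()]).
#'
#' @param guides `guide_set` from [scan_guides()].
#' @param variants `strain_variants` from [load_variants()] (same contig).
#' @param pad extra nt of context on each side of the footprint (default 0).
#' @return the guide set with `variant_clean` filled in.
#' @export
filter_by_variants <- function(guides, variants, pad = 0L) {
  if (nrow(guides) == 0L) return(guides)
  if (is.null(variants) || nrow(variants) == 0L) {
    guides$variant_clean <- TRUE
    return(guides)
  }
  fp <- guide_footprint(guides)
  g_ir <- IRanges::IRanges(fp$start - pad, fp$end + pad)
  v_ir <- IRanges::IRanges(variants$pos, variants$end)
  guides$variant_clean <- !IRanges::overlapsAny(g_ir, v_ir)
  guides
}

#' Rank guides within a coding intron
#'
#' Guides cutting closer than `min_splice_distance` nt to either splice
#' junction are excluded. The rest are ordered by variant cleanliness
#' (clean first), homology-arm feasibility (arms extractable without N and
#' free of forbidden motifs), then centrality (|cut - intron midpoint|),
#' with deterministic ties broken by genomic coordinate then strand ("+"
#' before "-").
#'
#' @param guides `guide_set` with `variant_clean` set (see
#'   [filter_by_variants()]); guides cutting outside the intron are
#'   excluded with reason.
#' @param intron one row of a `coding_introns` frame.
#' @param genome optional genome for arm-feasibility checks.
#' @param min_splice_distance minimum distance from cut to either splice
#'   junction, nt (default 50).
#' @param lha_len,rha_len arm lengths used for the feasibility check.
#' @param forbidden_sites DNA motifs that must not occur in either arm
#'   (searched on both strands), e.g. chosen restriction sites or the gRNA1
#'   protospacer.
#' @return ranked `guide_set` with `splice_distance` and `arm_feasible`
#'   columns. If nothing survives, an error of class
#'   `dropin_no_viable_guide` is raised whose `exclusions` field lists each
#'   guide with its exclusion reason.
#' @export
rank_guides <- function(guides, intron, genome = NULL,
                        min_splice_distance = 50L,
                        lha_len = 100L, rha_len = 100L,
                        forbidden_sites = character(0)) {
  stopifnot(nrow(intron) == 1L)
  g <- guides
  left0 <- intron$start - 1L     # interbase coordinates of the two junctions
  right0 <- intron$end
  reasons <- character(nrow(g))
  inside <- g$cut_site > left0 & g$cut_site < right0
  reasons[!inside] <- "cut_outside_intron"
  dist <- pmin(g$cut_site - left0, right0 - g$cut_site)
  too_close <- inside & dist < min_splice_distance
  reasons[too_close] <- sprintf("splice_distance_%dnt_lt_%d",
                                dist[too_close], min_splice_distance)
  g$splice_distance <- dist
  g$arm_feasible <- TRUE
  if (!is.null(genome)) {
    for (i in seq_len(nrow(g))) {
      g$arm_feasible[i] <- arm_feasible(genome, g$contig[i], g$cut_site[i],
                                        lha_len, rha_len, forbidden_sites)
    }
  }
  keep <- which(reasons == "")
  if (length(keep) == 0L) {
    excl <- data.frame(protospacer = g$protospacer, strand = g$strand,
                       cut_site = g$cut_site, reason = reasons,
                       stringsAsFactors = FALSE)
    dropin_error(sprintf("no viable guide in intron %d-%d (%d excluded)",
                         intron$start, intron$end, nrow(excl)),
                 "dropin_no_viable_guide", exclusions = excl)
  }
  g <- g[keep, , drop = FALSE]
  mid <- (left0 + right0) / 2
  clean <- !is.na(g$variant_clean) & g$variant_clean
  ord <- order(!clean, !g$arm_feasible, abs(g$cut_site - mid),
               g$p_start, g$strand != "+")
  g <- g[ord, , drop = FALSE]
  rownames(g) <- NULL
  class(g) <- c("guide_set", "data.frame")
  g
}

# can 100/100-style arms be taken around this cut without N or forbidden
# motifs?
arm_feasible <- function(genome, contig, cut_site, lha_len, rha_len,
                         forbidden_sites = character(0)) {
  seq <- contig_seq(genome, contig)
  if (cut_site - lha_len < 0L || cut_site + rha_len > nchar(seq)) return(FALSE)
  window <- substring(seq, cut_site - lha_len + 1L, cut_site + rha_len)
  if (grepl("N", window, fixed = TRUE)) return(FALSE)
  for (m in forbidden_sites) {
    if (motif_on_either_strand(m, window)) return(FALSE)
  }
  TRUE
}

#' Report exact protospacer+PAM matches of a guide elsewhere in the genome
#'
#' Exact-match off-target census (both strands, all contigs). Reported for
#' information; ranking does not block on it.
#'
#' @param genome genome from [load_genome()].
#' @param protospacer 20-nt guide sequence.
#' @param pam 3-nt PAM as matched at the on-target site.
#' @return data frame with `contig`, `start` (1-based), `strand` per match.
#' @export
off_target_census <- function(genome, protospacer, pam) {
  unit <- paste0(protospacer, pam)
  hits <- list()
  for (ctg in names(genome)) {
    seq <- contig_seq(genome, ctg)
    p <- find_exact(unit, seq)
    m <- find_exact(revcomp(unit), seq)
    if (length(p)) hits[[paste0(ctg, "+")]] <-
      data.frame(contig = ctg, start = p, strand = "+", stringsAsFactors = FALSE)
    if (length(m)) hits[[paste0(ctg, "-")]] <-
      data.frame(contig = ctg, start = m, strand = "-", stringsAsFactors = FALSE)
  }
  if (!length(hits)) {
    return(data.frame(contig = character(0), start = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' Write a guide report TSV
#'
#' One row per guide: gene, intron index, protospacer, PAM, strand,
#' cut site (displayed 1-based: the last reference base 5' of the cut),
#' and flags.
#'
#' @param guides ranked `guide_set`.
#' @param path output TSV path.
#' @param gene_id,intron_index identifiers for the report.
#' @return the path, invisibly.
#' @export
write_guide_report <- function(guides, path, gene_id = NA, intron_index = NA) {
  df <- data.frame(
    gene_id = gene_id,
    intron_index = intron_index,
    protospacer = guides$protospacer,
    pam = guides$pam,
    strand = guides$strand,
    cut_site_1based = guides$cut_site,
    variant_clean = guides$variant_clean,
    arm_feasible = if ("arm_feasible" %in% names(guides)) guides$arm_feasible else NA,
    splice_distance = if ("splice_distance" %in% names(guides)) guides$splice_distance else NA,
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
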