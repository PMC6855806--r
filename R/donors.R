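# Donor assembly: long-primer ssDNA drop-in designs, synthesized dsDNA
# drop-in constructs flanked by gRNA1 target units, and plasmid donors by
# simulated directional restriction subcloning.

#' Assemble a PCR/ssDNA drop-in design
#'
#' The forward long primer is LHA + the cassette's 26-nt universal forward
#' priming segment; the reverse long primer is revcomp(RHA) + the 24-nt
#' universal reverse priming segment and is 5'-phosphorylated by default.
#' The predicted PCR duplex (top strand) is LHA + core + RHA; lambda
#' exonuclease then degrades the phosphorylated strand, so the surviving
#' ssDNA donor is the strand primed by the non-phosphorylated primer.
#'
#' @param arms `homology_arms` from [design_arms()].
#' @param template a `cassette_template`.
#' @param phosphorylated which primer carries the 5' phosphate ("reverse",
#'   the default, leaves the top strand as the donor).
#' @return `ssdna_design` with elements `primers` (`forward`, `reverse`,
#'   `reverse_5prime_phosphorylated`, ...), `donor` (`duplex_top`,
#'   `ssdna_seq`, `surviving_strand`, `total_len`), `arms`, `template_name`.
#' @export
build_ssdna_design <- function(arms, template,
                               phosphorylated = c("reverse", "forward")) {
  stopifnot(inherits(arms, "homology_arms"),
            inherits(template, "cassette_template"))
  phosphorylated <- match.arg(phosphorylated)
  fwd <- paste0(arms$lha, template$fwd_priming)
  rev_ <- paste0(revcomp(arms$rha), template$rev_priming)
  for (seg in c(template$fwd_priming, template$rev_priming)) {
    if (motif_on_either_strand(seg, paste0(arms$lha, arms$rha))) {
      warning(sprintf(
        "universal priming segment occurs inside a homology arm (mispriming risk) for cut %d",
        arms$cut_site))
    }
  }
  duplex_top <- paste0(arms$lha, template$core_seq, arms$rha)
  phos_strand <- if (phosphorylated == "reverse") "bottom" else "top"
  ssdna <- simulate_lambda_exo(duplex_top, phosphorylated_strand = phos_strand)
  structure(list(
    primers = structure(list(
      forward = fwd,
      reverse = rev_,
      forward_len = nchar(fwd),
      reverse_len = nchar(rev_),
      reverse_5prime_phosphorylated = phosphorylated == "reverse",
      forward_5prime_phosphorylated = phosphorylated == "forward"
    ), class = "long_primer_pair"),
    donor = structure(list(
      duplex_top = duplex_top,
      ssdna_seq = ssdna,
      surviving_strand = if (phos_strand == "bottom") "top" else "bottom",
      total_len = nchar(duplex_top)
    ), class = "ssdna_donor"),
    arms = arms,
    template_name = template$name
  ), class = "ssdna_design")
}

#' @export
print.ssdna_design <- function(x, ...) {
  cat(sprintf(
    "ssdna_design '%s': donor %d nt (arms %d/%d + core %d), primers %d/%d nt\n",
    x$template_name, x$donor$total_len, x$arms$lha_len, x$arms$rha_len,
    x$donor$total_len - x$arms$lha_len - x$arms$rha_len,
    x$primers$forward_len, x$primers$reverse_len))
  invisible(x)
}

#' Lambda-exonuclease strand selection
#'
#' Lambda exonuclease is a 5'-to-3' nuclease preferring 5'-phosphorylated
#' DNA: the phosphorylated strand of the PCR duplex is degraded and the
#' other strand survives as the ssDNA donor.
#'
#' @param duplex_top top strand of the PCR duplex, 5'->3'.
#' @param phosphorylated_strand "top" or "bottom".
#' @return the surviving strand, 5'->3'.
#' @export
simulate_lambda_exo <- function(duplex_top,
                                phosphorylated_strand = c("bottom", "top")) {
  phosphorylated_strand <- match.arg(phosphorylated_strand)
  if (phosphorylated_strand == "bottom") duplex_top else revcomp(duplex_top)
}

#' Choose a restriction enzyme pair for a subcloning design
#'
#' Returns the first pair, in stable catalog order, whose recognition sites
#' are absent (both strands) from every supplied context sequence: the two
#' homology arms, the cassette to be subcloned, and the vector backbone.
#'
#' @param contexts named character vector/list of DNA sequences that must
#'   not contain the chosen sites.
#' @param catalog enzyme table, see [re_catalog()].
#' @return two-row slice of the catalog (RE1, RE2).
#' @export
choose_re_pair <- function(contexts, catalog = re_catalog()) {
  if (nrow(catalog) < 2L) {
    dropin_error("need at least two candidate enzymes", "dropin_re_error")
  }
  contexts <- unlist(contexts)
  conflicts <- vapply(seq_len(nrow(catalog)), function(i) {
    hit <- vapply(contexts, function(s)
      motif_on_either_strand(catalog$site[i], s), logical(1))
    if (any(hit)) paste(names(contexts)[hit], collapse = ",") else ""
  }, character(1))
  ok <- which(conflicts == "")
  if (length(ok) < 2L) {
    msg <- paste(sprintf("%s (%s): conflicts in %s",
                         catalog$name, catalog$site,
                         ifelse(conflicts == "", "none", conflicts)),
                 collapse = "; ")
    dropin_error(paste0("no viable restriction enzyme pair; ", msg),
                 "dropin_re_error", conflicts = conflicts)
  }
  catalog[ok[1:2], , drop = FALSE]
}

#' Assemble a synthesized dsDNA drop-in construct
#'
#' The synthesis insert is gRNA1 unit + LHA + payload + RHA + gRNA1 unit,
#' placed in a circular cloning vector. The gRNA1 units are oriented
#' PAM-inward (PAM facing the arms) so that Cas9 linearization leaves only
#' a minimal 3-nt + PAM remnant (6 nt) at each donor end. The gRNA1
#' protospacer+PAM must have no exact match in the target genome on either
#' strand (hard error otherwise).
#'
#' Payload modes: `"cassette"` embeds a cassette core directly (the
#' published dsDNA drop-in donors); `"stuffer"` embeds
#' RE1 site + spacer + RE2 site, the synthesis intermediate that a large
#' swappable cassette is later subcloned into (see
#' [simulate_subcloning()]).
#'
#' @param arms `homology_arms`.
#' @param genome genome the design targets (for the gRNA1 absence check).
#' @param payload a `cassette_template`, a DNA string (mode "cassette"), or
#'   NULL (mode "stuffer").
#' @param payload_mode "cassette" or "stuffer".
#' @param sic_core in stuffer mode, the cassette that will be subcloned
#'   (used to pick enzymes whose sites it lacks); optional.
#' @param re_pair optional explicit 2-row enzyme table; validated.
#' @param grna1 gRNA1 unit, see [grna1_unit()].
#' @param backbone circular vector sequence (default [puc57_backbone()]).
#' @param catalog enzyme catalog for [choose_re_pair()].
#' @return `synthesis_construct`: `insert_seq`, `payload_seq`, `lha`,
#'   `rha`, `re1`/`re2` (stuffer mode), `plasmid` (`seq`, `circular`),
#'   `donor_region` interval, and a `lengths` list with
#'   `cassette_plus_arms` (payload+arms, the printed construct size) and
#'   `full_insert` (including both gRNA1 units).
#' @export
build_synthesis_construct <- function(arms, genome, payload = NULL,
                                      payload_mode = c("cassette", "stuffer"),
                                      sic_core = NULL, re_pair = NULL,
                                      grna1 = grna1_unit(),
                                      backbone = puc57_backbone(),
                                      catalog = re_catalog()) {
  stopifnot(inherits(arms, "homology_arms"))
  payload_mode <- match.arg(payload_mode)
  hits <- off_target_census(genome, grna1$protospacer, grna1$pam)
  if (nrow(hits) > 0L) {
    dropin_error(sprintf(
      "gRNA1 protospacer+PAM matches the target genome at %s:%d (%s); pick another gRNA1",
      hits$contig[1], hits$start[1], hits$strand[1]),
      "dropin_grna1_error", hits = hits)
  }
  re1 <- re2 <- NULL
  if (payload_mode == "stuffer") {
    if (is.null(re_pair)) {
      ctx <- list(LHA = arms$lha, RHA = arms$rha, backbone = backbone)
      if (!is.null(sic_core)) ctx$SIC <- sic_core
      re_pair <- choose_re_pair(ctx, catalog)
    } else {
      stopifnot(nrow(re_pair) == 2L)
      ctx <- c(LHA = arms$lha, RHA = arms$rha, backbone = backbone)
      if (!is.null(sic_core)) ctx <- c(ctx, SIC = sic_core)
      for (i in 1:2) {
        bad <- vapply(ctx, function(s)
          motif_on_either_strand(re_pair$site[i], s), logical(1))
        if (any(bad)) {
          alt <- tryCatch(choose_re_pair(as.list(ctx), catalog),
                          error = function(e) NULL)
          sug <- if (is.null(alt)) "none available" else
            paste(alt$name, collapse = " + ")
          dropin_error(sprintf(
            "%s site %s found in %s; suggested alternative pair: %s",
            re_pair$name[i], re_pair$site[i],
            paste(names(ctx)[bad], collapse = ","), sug),
            "dropin_re_error")
        }
      }
    }
    re1 <- re_pair[1, ]; re2 <- re_pair[2, ]
    payload_seq <- paste0(re1$site, cassette_elements()$stuffer_spacer, re2$site)
  } else {
    if (inherits(payload, "cassette_template")) {
      payload_seq <- payload$core_seq
    } else if (is.character(payload) && length(payload) == 1L) {
      payload_seq <- payload
    } else {
      dropin_error("payload must be a cassette_template or DNA string",
                   "dropin_template_error")
    }
  }
  unit_left <- grna1$unit                  # protospacer+PAM, PAM abuts LHA
  unit_right <- revcomp(grna1$unit)        # PAM abuts RHA on the other side
  insert <- paste0(unit_left, arms$lha, payload_seq, arms$rha, unit_right)
  plasmid_seq <- paste0(backbone, insert)
  donor_start <- nchar(backbone) + 1L
  structure(list(
    insert_seq = insert,
    payload_seq = payload_seq,
    payload_mode = payload_mode,
    lha = arms$lha, rha = arms$rha,
    arms = arms,
    re1 = re1, re2 = re2,
    grna1 = grna1,
    backbone_len = nchar(backbone),
    plasmid = list(seq = plasmid_seq, circular = TRUE),
    donor_region = c(start = donor_start,
                     end = donor_start + nchar(insert) - 1L),
    lengths = list(
      cassette_plus_arms = nchar(arms$lha) + nchar(payload_seq) + nchar(arms$rha),
      full_insert = nchar(insert)
    ),
    provenance = "direct_synthesis"
  ), class = "synthesis_construct")
}

#' @export
print.synthesis_construct <- function(x, ...) {
  cat(sprintf(
    "synthesis_construct (%s): insert %d nt (payload+arms %d nt), plasmid %d nt\n",
    x$payload_mode, x$lengths$full_insert, x$lengths$cassette_plus_arms,
    nchar(x$plasmid$seq)))
  if (!is.null(x$re1)) cat(sprintf("  stuffer enzymes: %s / %s\n",
                                   x$re1$name, x$re2$name))
  invisible(x)
}

# ---- restriction digestion / ligation -------------------------------------

#' In-silico restriction digest
#'
#' Recognition sites are matched as exact strings (the bundled catalog is
#' palindromic, so a forward-strand search covers both strands). Fragments
#' are delimited by the top-strand cut positions; each fragment end records
#' the generating enzyme and its single-stranded overhang, and ligation
#' requires complementary overhangs (same enzyme for palindromic sites).
#'
#' @param seq DNA string.
#' @param enzymes rows of [re_catalog()].
#' @param circular is `seq` a circle?
#' @return list of fragments: `seq` (top strand between top cuts),
#'   `left_end`/`right_end` (list `enzyme`, `overhang`, `type`; NULL for a
#'   natural blunt end of a linear substrate).
#' @export
digest_sequence <- function(seq, enzymes, circular = FALSE) {
  n <- nchar(seq)
  cuts <- list()
  for (i in seq_len(nrow(enzymes))) {
    e <- enzymes[i, ]
    if (circular) {
      # catch recognition sites spanning the origin
      ext <- paste0(seq, substr(seq, 1L, nchar(e$site) - 1L))
      pos <- find_exact(e$site, ext)
      pos <- pos[pos <= n]
    } else {
      pos <- find_exact(e$site, seq)
    }
    for (p in pos) {
      s0 <- p - 1L
      lo0 <- s0 + min(e$cut_top, e$cut_bottom)
      hi0 <- s0 + max(e$cut_top, e$cut_bottom)
      # overhang read from the (possibly origin-spanning) site itself
      over <- if (hi0 <= n) substring(seq, lo0 + 1L, hi0) else
        paste0(substring(seq, lo0 + 1L, n), substr(seq, 1L, hi0 - n))
      t0 <- s0 + e$cut_top
      if (circular) t0 <- t0 %% n
      cuts[[length(cuts) + 1L]] <- list(
        enzyme = e$name, top0 = t0,
        overhang = over,
        type = if (e$cut_top < e$cut_bottom) "5p"
               else if (e$cut_top > e$cut_bottom) "3p" else "blunt")
    }
  }
  if (!length(cuts)) {
    return(list(list(seq = seq, left_end = NULL, right_end = NULL)))
  }
  ord <- order(vapply(cuts, `[[`, numeric(1), "top0"))
  cuts <- cuts[ord]
  n <- nchar(seq)
  frags <- list()
  end_of <- function(cut) list(enzyme = cut$enzyme, overhang = cut$overhang,
                               type = cut$type)
  if (circular) {
    k <- length(cuts)
    for (j in seq_len(k)) {
      a <- cuts[[j]]
      b <- cuts[[if (j == k) 1L else j + 1L]]
      frag_seq <- if (j == k) {
        paste0(substring(seq, a$top0 + 1L, n), substr(seq, 1L, b$top0))
      } else {
        substring(seq, a$top0 + 1L, b$top0)
      }
      frags[[j]] <- list(seq = frag_seq, left_end = end_of(a),
                         right_end = end_of(b))
    }
  } else {
    bounds0 <- c(0L, vapply(cuts, `[[`, numeric(1), "top0"), n)
    ends <- c(list(NULL), lapply(cuts, end_of), list(NULL))
    for (j in seq_len(length(bounds0) - 1L)) {
      frags[[j]] <- list(
        seq = substring(seq, bounds0[j] + 1L, bounds0[j + 1L]),
        left_end = ends[[j]],
        right_end = ends[[j + 1L]])
    }
  }
  frags
}

# can two fragment ends ligate? (complementary overhangs; with palindromic
# sites this reduces to same enzyme + same overhang type)
ends_compatible <- function(right_end, left_end) {
  if (is.null(right_end) || is.null(left_end)) return(FALSE)
  identical(right_end$enzyme, left_end$enzyme) &&
    identical(right_end$type, left_end$type) &&
    identical(right_end$overhang, left_end$overhang)
}

#' Reverse a restriction fragment (flip orientation)
#' @param frag fragment from [digest_sequence()].
#' @return the fragment on the opposite strand, ends swapped.
#' @export
flip_fragment <- function(frag) {
  flip_end <- function(e) {
    if (is.null(e)) return(NULL)
    # palindromic overhangs are their own reverse complement in duplex
    # terms; the enzyme identity carries compatibility
    e
  }
  list(seq = revcomp(frag$seq), left_end = flip_end(frag$right_end),
       right_end = flip_end(frag$left_end))
}

#' Ligate restriction fragments
#'
#' Joins fragments in the given order, requiring compatible (complementary)
#' overhangs at every junction; with `circularize = TRUE` the last
#' fragment's right end must also match the first fragment's left end.
#'
#' @param frags list of fragments from [digest_sequence()].
#' @param circularize close the product into a circle?
#' @return list `seq`, `circular`.
#' @export
ligate_fragments <- function(frags, circularize = TRUE) {
  k <- length(frags)
  stopifnot(k >= 1L)
  n_junctions <- if (circularize) k else k - 1L
  for (j in seq_len(n_junctions)) {
    a <- frags[[j]]
    b <- frags[[if (j == k) 1L else j + 1L]]
    if (!ends_compatible(a$right_end, b$left_end)) {
      dropin_error(sprintf(
        "incompatible ends at junction %d (%s right vs %s left)", j,
        a$right_end$enzyme %||% "blunt", b$left_end$enzyme %||% "blunt"),
        "dropin_ligation_error")
    }
  }
  list(seq = paste0(vapply(frags, `[[`, character(1), "seq"), collapse = ""),
       circular = circularize)
}

#' Directional subcloning of a cassette into a stuffer plasmid
#'
#' Digests the stuffer synthesis plasmid with RE1+RE2, discards the
#' stuffer, digests the RE1-cassette-RE2 synthesis fragment, and ligates
#' the cassette in the orientation forced by the two distinct sites. The
#' resulting donor region is gRNA1 + LHA + RE1 site + cassette + RE2 site +
#' RHA + gRNA1, byte-identical to direct synthesis of the same payload.
#'
#' @param construct stuffer-mode `synthesis_construct`.
#' @param sic_core the cassette (SIC) core to subclone; it must not contain
#'   an internal RE1 or RE2 site.
#' @return `drop_in_plasmid`: `seq` (circular), `donor_region` (sequence
#'   and interval), `provenance = "subcloned"`, plus the enzymes, arms and
#'   gRNA1 carried over.
#' @export
simulate_subcloning <- function(construct, sic_core) {
  stopifnot(inherits(construct, "synthesis_construct"))
  if (construct$payload_mode != "stuffer") {
    dropin_error("subcloning requires a stuffer-mode synthesis construct",
                 "dropin_cloning_error")
  }
  if (inherits(sic_core, "cassette_template")) sic_core <- sic_core$core_seq
  re1 <- construct$re1; re2 <- construct$re2
  for (e in list(re1, re2)) {
    if (motif_on_either_strand(e$site, sic_core)) {
      dropin_error(sprintf("cassette contains an internal %s site (%s)",
                           e$name, e$site), "dropin_cloning_error")
    }
  }
  enz <- rbind(re1, re2)
  plasmid_frags <- digest_sequence(construct$plasmid$seq, enz, circular = TRUE)
  if (length(plasmid_frags) != 2L) {
    dropin_error(sprintf("expected 2 fragments from stuffer plasmid, got %d",
                         length(plasmid_frags)), "dropin_cloning_error")
  }
  is_backbone <- vapply(plasmid_frags, function(f)
    grepl(construct$lha, f$seq, fixed = TRUE), logical(1))
  if (sum(is_backbone) != 1L) {
    dropin_error("could not identify the backbone fragment",
                 "dropin_cloning_error")
  }
  backbone_frag <- plasmid_frags[[which(is_backbone)]]
  synth_input <- paste0(re1$site, sic_core, re2$site)
  in_frags <- digest_sequence(synth_input, enz, circular = FALSE)
  if (length(in_frags) != 3L) {
    dropin_error("cassette synthesis fragment digested into an unexpected number of pieces",
                 "dropin_cloning_error")
  }
  sic_frag <- in_frags[[2L]]
  res <- ligate_fragments(list(backbone_frag, sic_frag), circularize = TRUE)
  donor_seq <- paste0(construct$grna1$unit, construct$lha,
                      re1$site, sic_core, re2$site,
                      construct$rha, revcomp(construct$grna1$unit))
  doubled <- paste0(res$seq, res$seq)
  pos <- find_exact(donor_seq, doubled)
  if (!length(pos)) {
    dropin_error("subcloned plasmid lacks the expected donor region",
                 "dropin_cloning_error")
  }
  structure(list(
    seq = res$seq,
    circular = TRUE,
    donor_region_seq = donor_seq,
    donor_region = c(start = ((pos[1] - 1L) %% nchar(res$seq)) + 1L,
                     end = ((pos[1] - 1L + nchar(donor_seq) - 1L) %% nchar(res$seq)) + 1L),
    sic_name = NULL,
    re1 = re1, re2 = re2,
    lha = construct$lha, rha = construct$rha,
    grna1 = construct$grna1,
    provenance = "subcloned"
  ), class = "drop_in_plasmid")
}

#' Simulate in-vivo Cas9 linearization of a donor plasmid
#'
#' Cuts the circular plasmid at every gRNA1 protospacer+PAM occurrence
#' (both strands) using the blunt-cut rule (3 nt 5' of the PAM) and
#' returns the fragments, identifying the donor fragment (the one carrying
#' LHA, payload and RHA). With PAM-inward gRNA1 units the donor carries a
#' 6-nt remnant (3 nt + PAM) at each end.
#'
#' @param x a `synthesis_construct` or `drop_in_plasmid`.
#' @param grna1 gRNA1 unit (defaults to the one recorded in `x`).
#' @return list with `fragments` (character), `donor` (donor fragment
#'   sequence), `backbone`, `remnant_lengths` (left/right remnant on the
#'   donor), `cut_sites` (interbase on the plasmid string).
#' @export
simulate_linearization <- function(x, grna1 = NULL) {
  if (inherits(x, "synthesis_construct")) {
    seq <- x$plasmid$seq; lha <- x$lha; rha <- x$rha
    if (is.null(grna1)) grna1 <- x$grna1
  } else if (inherits(x, "drop_in_plasmid")) {
    seq <- x$seq; lha <- x$lha; rha <- x$rha
    if (is.null(grna1)) grna1 <- x$grna1
  } else {
    dropin_error("x must be a synthesis_construct or drop_in_plasmid",
                 "dropin_cloning_error")
  }
  n <- nchar(seq)
  unit <- grna1$unit
  doubled <- paste0(seq, seq)
  plus <- find_exact(unit, doubled)
  plus <- unique((plus[plus <= n] - 1L) %% n)            # footprint start0
  minus <- find_exact(revcomp(unit), doubled)
  minus <- unique((minus[minus <= n] - 1L) %% n)
  cuts0 <- sort(unique(c((plus + 17L) %% n, (minus + 6L) %% n)))
  if (length(cuts0) != 2L) {
    dropin_error(sprintf("expected exactly 2 gRNA1 cut sites, found %d",
                         length(cuts0)), "dropin_grna1_error")
  }
  c1 <- cuts0[1]; c2 <- cuts0[2]
  fragA <- substring(seq, c1 + 1L, c2)
  fragB <- paste0(substring(seq, c2 + 1L, n), substr(seq, 1L, c1))
  frags <- c(fragA, fragB)
  is_donor <- vapply(frags, function(f)
    grepl(lha, f, fixed = TRUE) && grepl(rha, f, fixed = TRUE), logical(1))
  if (sum(is_donor) != 1L) {
    dropin_error("could not uniquely identify the donor fragment",
                 "dropin_cloning_error")
  }
  donor <- frags[which(is_donor)]
  lha_at <- regexpr(lha, donor, fixed = TRUE)
  rha_at <- regexpr(rha, donor, fixed = TRUE)
  list(
    fragments = unname(frags),
    donor = unname(donor),
    backbone = unname(frags[which(!is_donor)]),
    remnant_lengths = c(left = as.integer(lha_at - 1L),
                        right = as.integer(nchar(donor) - (rha_at + nchar(rha) - 1L))),
    cut_sites = cuts0
  )
}
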