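# Donor assembly: ssDNA long-primer designs, lambda-exo strand selection,
# synthesized dsDNA constructs, enzyme choice, subcloning, linearization.

arms_at <- function(loc, cut = 1500L, strand = "+") {
  design_arms(loc$genome, loc$truth$contig, cut, gene_strand = strand)
}

test_that("ssDNA designs reproduce the published length arithmetic", {
  loc <- make_locus(seed = 2)
  arms <- arms_at(loc)
  lib <- cassette_library()
  egfp <- build_ssdna_design(arms, lib[["attP-3XP3-EGFP-attP"]])
  expect_equal(egfp$donor$total_len, 1442L)        # 1242 template + 2 x 100
  sfgfp <- build_ssdna_design(arms, lib[["attP-SA-sfGFP-SD-attP"]])
  expect_equal(sfgfp$donor$total_len, 1392L)
  # long-primer composition: arm + 26/24 universal priming segments
  expect_equal(egfp$primers$forward_len, 126L)
  expect_equal(egfp$primers$reverse_len, 124L)
  expect_true(egfp$primers$reverse_5prime_phosphorylated)
  expect_false(egfp$primers$forward_5prime_phosphorylated)
  tpl <- lib[["attP-3XP3-EGFP-attP"]]
  expect_identical(egfp$primers$forward, paste0(arms$lha, tpl$fwd_priming))
  expect_identical(egfp$primers$reverse,
                   paste0(oracle_revcomp(arms$rha), tpl$rev_priming))
  # predicted duplex and surviving strand
  expect_identical(egfp$donor$duplex_top,
                   paste0(arms$lha, tpl$core_seq, arms$rha))
  expect_identical(egfp$donor$ssdna_seq, egfp$donor$duplex_top)
  expect_identical(egfp$donor$surviving_strand, "top")
})

test_that("phosphorylating the forward primer flips the surviving strand", {
  loc <- make_locus(seed = 2)
  d <- build_ssdna_design(arms_at(loc), cassette_library()[[1]],
                          phosphorylated = "forward")
  expect_identical(d$donor$ssdna_seq, oracle_revcomp(d$donor$duplex_top))
  expect_identical(d$donor$surviving_strand, "bottom")
})

test_that("lambda exonuclease leaves the non-phosphorylated strand", {
  expect_identical(simulate_lambda_exo("ACGT", "bottom"), "ACGT")
  expect_identical(simulate_lambda_exo("ACGT", "top"), "ACGT")  # palindrome
  with_seed <- function(s, n) { set.seed(s)
    paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "") }
  r <- with_seed(5, 500)
  expect_identical(simulate_lambda_exo(r, "bottom"), r)
  expect_identical(simulate_lambda_exo(r, "top"), oracle_revcomp(r))
})

test_that("synthesized dsDNA constructs reproduce the published totals", {
  loc <- make_locus(seed = 2)
  arms <- arms_at(loc)
  lib <- cassette_library()
  stopc <- build_synthesis_construct(arms, loc$genome,
    payload = lib[["attP-SA-3XSTOP-minipolyA-U6gRNA1-attP"]])
  expect_equal(stopc$lengths$cassette_plus_arms, 715L)
  mg4 <- build_synthesis_construct(arms, loc$genome,
    payload = lib[["attP-SA-T2A-miniGAL4-minipolyA-U6gRNA1-attP"]])
  expect_equal(mg4$lengths$cassette_plus_arms, 1968L)
  # full insert adds the two 23-nt gRNA1 units
  expect_equal(mg4$lengths$full_insert, 1968L + 46L)
  # PAM-inward orientation: unit then arms then reverse-complemented unit
  u <- grna1_unit()$unit
  expect_identical(substr(mg4$insert_seq, 1, 23), u)
  expect_identical(substring(mg4$insert_seq, nchar(mg4$insert_seq) - 22),
                   oracle_revcomp(u))
})

test_that("a gRNA1 match in the genome is a hard error", {
  loc <- make_locus(seed = 6, decoy_grna1 = TRUE)
  arms <- arms_at(loc)
  expect_error(
    build_synthesis_construct(arms, loc$genome, payload = cassette_library()[[1]]),
    "matches the target genome")
  expect_true(loc$truth$decoy_grna1)
})

test_that("enzyme choice skips conflicting enzymes deterministically", {
  cat <- re_catalog()
  ctx <- list(LHA = paste0("TTTT", cat$site[1], "TTTT"),   # EcoRI conflict
              RHA = "ACGTACGTACGT", backbone = "CCCCCCCC")
  pair <- choose_re_pair(ctx, cat)
  expect_identical(pair$name, cat$name[2:3])
  # chosen sites pass an independent substring-absence oracle (both strands)
  for (s in pair$site) {
    for (x in unlist(ctx)) {
      expect_false(grepl(s, x, fixed = TRUE) ||
                     grepl(oracle_revcomp(s), x, fixed = TRUE))
    }
  }
  # all conflicting -> structured failure
  allctx <- list(ALL = paste(c(cat$site, "T"), collapse = "TT"))
  expect_error(choose_re_pair(allctx, cat), "no viable restriction enzyme pair")
  # randomized property
  for (seed in 1:5) {
    set.seed(seed)
    ctx <- list(LHA = paste(sample(c("A","C","G","T"), 150, TRUE), collapse = ""),
                RHA = paste(sample(c("A","C","G","T"), 150, TRUE), collapse = ""))
    pair <- choose_re_pair(ctx, cat)
    for (s in pair$site) for (x in unlist(ctx)) {
      expect_false(grepl(s, x, fixed = TRUE) ||
                     grepl(oracle_revcomp(s), x, fixed = TRUE))
    }
  }
})

test_that("an explicit enzyme whose site sits in an arm is rejected with alternatives", {
  # build a genome whose left arm region contains an EcoRI site
  base <- make_locus(seed = 8)
  seq <- base$seq
  cut <- 1500L
  substr(seq, cut - 50L, cut - 45L) <- "GAATTC"
  g <- string_genome(seq, base$truth$contig)
  arms <- design_arms(g, base$truth$contig, cut)
  cat <- re_catalog()
  err <- tryCatch(
    build_synthesis_construct(arms, g, payload_mode = "stuffer",
                              re_pair = cat[cat$name %in% c("EcoRI", "BamHI"), ]),
    error = function(e) e)
  expect_match(conditionMessage(err), "EcoRI site GAATTC found in LHA")
  expect_match(conditionMessage(err), "suggested alternative")
  # automatic choice simply avoids EcoRI
  auto <- build_synthesis_construct(arms, g, payload_mode = "stuffer")
  expect_false("EcoRI" %in% c(auto$re1$name, auto$re2$name))
})

test_that("directional subcloning equals the string-assembly oracle and direct synthesis", {
  loc <- make_locus(seed = 12)
  arms <- arms_at(loc)
  sic <- cassette_library()[["attP-FRT-SA-T2A-GAL4-polyA-3XP3-EGFP-FRT-attP"]]
  stuffer <- build_synthesis_construct(arms, loc$genome,
                                       payload_mode = "stuffer",
                                       sic_core = sic$core_seq)
  plasmid <- simulate_subcloning(stuffer, sic$core_seq)
  want <- paste0(grna1_unit()$unit, arms$lha, stuffer$re1$site, sic$core_seq,
                 stuffer$re2$site, arms$rha, oracle_revcomp(grna1_unit()$unit))
  expect_identical(plasmid$donor_region_seq, want)
  expect_true(grepl(want, paste0(plasmid$seq, plasmid$seq), fixed = TRUE))
  # byte-identity with direct synthesis of the same payload
  direct <- build_synthesis_construct(arms, loc$genome,
    payload = paste0(stuffer$re1$site, sic$core_seq, stuffer$re2$site))
  expect_identical(direct$insert_seq, want)
})

test_that("subcloning is directional and digest/ligate round trips are exact", {
  loc <- make_locus(seed = 12)
  arms <- arms_at(loc)
  sic <- cassette_library()[["attP-SA-sfGFP-SD-attP"]]
  stuffer <- build_synthesis_construct(arms, loc$genome,
                                       payload_mode = "stuffer",
                                       sic_core = sic$core_seq)
  enz <- rbind(stuffer$re1, stuffer$re2)
  # re-digesting the subcloned plasmid recovers the cassette fragment exactly
  plasmid <- simulate_subcloning(stuffer, sic$core_seq)
  synth_input <- paste0(stuffer$re1$site, sic$core_seq, stuffer$re2$site)
  sic_frag <- digest_sequence(synth_input, enz, circular = FALSE)[[2]]
  redig <- digest_sequence(plasmid$seq, enz, circular = TRUE)
  expect_equal(length(redig), 2L)
  seqs <- vapply(redig, `[[`, character(1), "seq")
  expect_true(sic_frag$seq %in% seqs)
  # digest -> ligate -> digest is idempotent on the fragment multiset
  relig <- ligate_fragments(redig, circularize = TRUE)
  redig2 <- digest_sequence(relig$seq, enz, circular = TRUE)
  expect_setequal(vapply(redig2, `[[`, character(1), "seq"), seqs)
  # flipping the cassette fragment breaks end compatibility (orientation rule)
  backbone <- redig[[which(seqs != sic_frag$seq)]]
  expect_error(ligate_fragments(list(backbone, flip_fragment(sic_frag))),
               "incompatible ends")
  # an internal RE site in the cassette is rejected
  bad_sic <- paste0(substr(sic$core_seq, 1, 300), stuffer$re1$site,
                    substring(sic$core_seq, 301))
  expect_error(simulate_subcloning(stuffer, bad_sic), "internal")
})

test_that("Cas9 linearization releases the donor with 3-nt+PAM remnants", {
  loc <- make_locus(seed = 14)
  arms <- arms_at(loc)
  tpl <- cassette_library()[["attP-SA-3XSTOP-minipolyA-U6gRNA1-attP"]]
  con <- build_synthesis_construct(arms, loc$genome, payload = tpl)
  lin <- simulate_linearization(con)
  expect_equal(length(lin$fragments), 2L)
  expect_equal(unname(lin$remnant_lengths), c(6L, 6L))
  # cut-position oracle: donor = insert minus the PAM-distal 17 nt of each unit
  insert <- con$insert_seq
  want <- substring(insert, 18L, nchar(insert) - 17L)
  expect_identical(lin$donor, want)
  expect_true(grepl(tpl$core_seq, lin$donor, fixed = TRUE))
  # total sequence is conserved across the two fragments
  expect_equal(sum(nchar(lin$fragments)), nchar(con$plasmid$seq))
  # a plasmid without gRNA1 sites is an error
  fake <- con
  fake$grna1 <- list(protospacer = strrep("A", 20), pam = "AGG",
                     unit = paste0(strrep("A", 20), "AGG"))
  expect_error(simulate_linearization(fake), "expected exactly 2")
})

test_that("ordering sheets list the orderable molecules", {
  loc <- make_locus(seed = 2)
  arms <- arms_at(loc)
  d <- build_ssdna_design(arms, cassette_library()[[1]])
  sheet <- ordering_sheet(d, "geneA")
  expect_equal(nrow(sheet), 2L)
  expect_equal(sheet$length, c(126L, 124L))
  expect_identical(sheet$phosphorylated_5prime, c(FALSE, TRUE))
  con <- build_synthesis_construct(arms, loc$genome,
    payload = cassette_library()[["attP-SA-3XSTOP-minipolyA-U6gRNA1-attP"]])
  sheet2 <- ordering_sheet(con, "geneA")
  expect_equal(sheet2$length, 715L + 46L)
  expect_match(sheet2$note, "GC")
})
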