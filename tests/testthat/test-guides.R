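# SpCas9 guide enumeration, the blunt-cut rule, variant filtering, ranking.

test_that("a PAM-free window yields no guides", {
  g <- string_genome(paste0(strrep("A", 80), strrep("T", 20)))
  expect_equal(nrow(scan_guides(g, "ctg", 1, 50)), 0L)
  expect_error(scan_guides(g, "ctg", 1, 200), "outside contig")
  expect_error(scan_guides(g, "ctg", 1, 20), "at least 23")
})

test_that("the blunt cut falls 3 nt 5' of the PAM (hand-checked)", {
  # plant A*20 + AGG at 1-based position 101 inside a PAM-free background
  seq <- paste0(strrep("T", 100), strrep("A", 20), "AGG", strrep("T", 100))
  g <- string_genome(seq)
  hits <- scan_guides(g, "ctg", 101, 123)
  expect_equal(nrow(hits), 1L)
  expect_identical(hits$strand, "+")
  expect_identical(hits$protospacer, strrep("A", 20))
  expect_identical(hits$pam, "AGG")
  # window_start0 = 100; cut_site = window_start0 + 17
  expect_equal(hits$cut_site, 100L + 17L)
  expect_equal(hits$p_start, 101L)
  expect_equal(hits$p_end, 120L)
})

test_that("guide scan equals a brute-force 23-mer oracle on random fixtures", {
  for (seed in c(7, 8, 9)) {
    loc <- make_locus(seed = seed, flank = 400L)
    end <- min(2000L, nchar(loc$seq))
    got <- scan_guides(loc$genome, loc$truth$contig, 1, end)
    want <- oracle_scan_guides(loc$seq, 1L, end)
    expect_gt(nrow(got), 10L)
    expect_equal(nrow(got), nrow(want))
    for (col in c("protospacer", "pam", "strand", "p_start", "p_end", "cut_site")) {
      expect_identical(unname(got[[col]]), unname(want[[col]]))
    }
  }
})

test_that("every planted guide is recovered with its recorded cut site", {
  pg <- data.frame(intron = c(1L, 1L, 2L), strand = c("+", "-", "+"),
                   offset = c(40L, 120L, 80L))
  loc <- make_locus(seed = 17, n_exons = 3, planted_guides = pg)
  truth <- loc$truth$planted_guides
  all_guides <- scan_guides(loc$genome, loc$truth$contig, 1, nchar(loc$seq))
  for (i in seq_len(nrow(truth))) {
    m <- all_guides[all_guides$cut_site == truth$cut_site[i] &
                      all_guides$strand == truth$strand[i], ]
    expect_equal(nrow(m), 1L)
    expect_identical(m$protospacer, truth$protospacer[i])
    expect_equal(m$p_start, truth$p_start[i])
  }
})

test_that("scanning the reverse complement mirrors the guide set", {
  loc <- make_locus(seed = 23, flank = 300L)
  n <- 1500L
  fwd <- scan_guides(loc$genome, loc$truth$contig, 1, n)
  rc_genome <- string_genome(oracle_revcomp(substr(loc$seq, 1, n)), "rc")
  rev <- scan_guides(rc_genome, "rc", 1, n)
  expect_equal(nrow(fwd), nrow(rev))
  # mirror map: strand flips, footprint reflects, cut reflects
  mirrored <- data.frame(
    protospacer = rev$protospacer, pam = rev$pam,
    strand = ifelse(rev$strand == "+", "-", "+"),
    p_start = n - rev$p_end + 1L, p_end = n - rev$p_start + 1L,
    cut_site = n - rev$cut_site)
  key <- function(d) sort(with(d, paste(protospacer, pam, strand,
                                        p_start, p_end, cut_site)))
  expect_identical(key(fwd), key(mirrored))
})

test_that("returned guides match the genome slice on their strand", {
  loc <- make_locus(seed = 29)
  guides <- scan_guides(loc$genome, loc$truth$contig, 1, 2000)
  for (i in seq_len(nrow(guides))) {
    gi <- guides[i, ]
    fwd23 <- substring(loc$seq,
                       if (gi$strand == "+") gi$p_start else gi$p_start - 3L,
                       if (gi$strand == "+") gi$p_end + 3L else gi$p_end)
    unit <- if (gi$strand == "+") fwd23 else oracle_revcomp(fwd23)
    expect_identical(substr(unit, 1, 20), gi$protospacer)
    expect_identical(substring(unit, 21), gi$pam)
  }
})

test_that("variant overlap flags follow the footprint rule", {
  seq <- paste0(strrep("T", 100), strrep("A", 20), "AGG", strrep("T", 100))
  g <- string_genome(seq)
  guide <- scan_guides(g, "ctg", 101, 123)
  snv <- function(pos) {
    v <- data.frame(contig = "ctg", pos = pos, pos0 = pos - 1L, end = pos,
                    ref = "A", alt = "C")
    class(v) <- c("strain_variants", "data.frame")
    v
  }
  expect_false(filter_by_variants(guide, snv(122L))$variant_clean)  # in PAM
  expect_true(filter_by_variants(guide, snv(133L))$variant_clean)   # 10 nt out
  expect_false(filter_by_variants(guide, snv(133L), pad = 15L)$variant_clean)
  expect_true(filter_by_variants(guide, NULL)$variant_clean)
})

test_that("variant flags agree with an independent interval-overlap oracle", {
  loc <- make_locus(seed = 37)
  guides <- scan_guides(loc$genome, loc$truth$contig, 1, 3000)
  guides <- guides[seq_len(min(100L, nrow(guides))), ]
  set.seed(99)
  vpos <- sort(sample(3000L, 20L))
  v <- data.frame(contig = loc$truth$contig, pos = vpos, pos0 = vpos - 1L,
                  end = vpos + sample(0:3, 20, replace = TRUE),
                  ref = "N", alt = "N")
  class(v) <- c("strain_variants", "data.frame")
  got <- filter_by_variants(guides, v)$variant_clean
  for (i in seq_len(nrow(guides))) {
    fs <- if (guides$strand[i] == "+") guides$p_start[i] else guides$p_start[i] - 3L
    fe <- if (guides$strand[i] == "+") guides$p_end[i] + 3L else guides$p_end[i]
    clean <- !any(v$pos <= fe & v$end >= fs)   # closed-interval overlap
    expect_identical(unname(got[i]), clean)
  }
})

test_that("ranking excludes splice-adjacent cuts and sorts by the stated keys", {
  loc <- make_locus(seed = 41, n_exons = 3)
  ci <- find_coding_introns(loc$gene)
  intron <- ci[1, , drop = FALSE]
  guides <- scan_guides(loc$genome, loc$truth$contig, intron$start, intron$end)
  guides <- filter_by_variants(guides, NULL)
  ranked <- rank_guides(guides, intron, genome = loc$genome)
  expect_true(all(ranked$splice_distance >= 50))
  left0 <- intron$start - 1L; right0 <- intron$end
  expect_true(all(ranked$cut_site - left0 >= 50 & right0 - ranked$cut_site >= 50))
  # explicit sort-key oracle on the surviving set
  mid <- (left0 + right0) / 2
  o <- order(!ranked$variant_clean, !ranked$arm_feasible,
             abs(ranked$cut_site - mid), ranked$p_start, ranked$strand != "+")
  expect_identical(o, seq_len(nrow(ranked)))
  # a guide cutting 10 nt from the acceptor is excluded at the default buffer
  near <- guides[which.min(abs(guides$cut_site - (right0 - 10L)))[1], , drop = FALSE]
  if (min(near$cut_site - left0, right0 - near$cut_site) < 50) {
    expect_false(near$protospacer %in% ranked$protospacer &
                   near$cut_site %in% ranked$cut_site)
  }
  # demoted, not dropped: non-clean guides sort after clean ones
  guides2 <- guides
  guides2$variant_clean <- rep(c(TRUE, FALSE), length.out = nrow(guides2))
  ranked2 <- rank_guides(guides2, intron, genome = loc$genome)
  cl <- ranked2$variant_clean
  expect_true(all(diff(as.integer(!cl)) >= 0))
})

test_that("an empty ranking is a structured no-viable-guide failure", {
  seq <- paste0(strrep("T", 60), strrep("A", 20), "AGG", strrep("T", 60))
  g <- string_genome(seq)
  guides <- filter_by_variants(scan_guides(g, "ctg", 61, 83), NULL)
  intron <- data.frame(start = 56L, end = 130L)  # cut 17 nt from the donor side
  err <- tryCatch(rank_guides(guides, intron, min_splice_distance = 50L),
                  dropin_no_viable_guide = function(e) e)
  expect_s3_class(err, "dropin_no_viable_guide")
  expect_s3_class(err$exclusions, "data.frame")
  expect_equal(nrow(err$exclusions), 1L)
  expect_match(err$exclusions$reason, "splice_distance")
})
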