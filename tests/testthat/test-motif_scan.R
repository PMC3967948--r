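test_that("built-in TBE motifs match their defining examples", {
  m <- tbe_motifs()
  # (T/A)GGTG(T/A/G): one sense hit at the start
  h <- scan_sequence("TGGTGT", m$TBE_DNA)
  expect_equal(nrow(h), 1L)
  expect_equal(h$start, 0L)
  expect_equal(h$strand, "+")
  # probe carrying two RNA TBEs UGGUGU
  h2 <- scan_sequence("UGGUGUUGGUGU", m$RNA_TBE)
  expect_equal(nrow(h2), 2L)
  expect_equal(h2$start, c(0L, 6L))
  # the GGUGU -> CCUGU mutation destroys the RNA TBE
  expect_equal(nrow(scan_sequence("UCCUGU", m$RNA_TBE)), 0L)
  # GGTG core found on the reverse strand as CACC
  h3 <- scan_sequence("ACACCA", m$TBE_CORE)
  expect_equal(nrow(h3), 1L)
  expect_equal(h3$strand, "-")
  expect_equal(h3$matched_text, "CACC")
  expect_equal(h3$start, 1L)
  # empty sequence gives an empty hit table
  expect_equal(nrow(scan_sequence("", m$TBE_CORE)), 0L)
})

test_that("RNA motifs are sense-only and N extends the relaxed core", {
  m <- tbe_motifs()
  # reverse complement of UGGUGU present, but RNA scanning is sense-only
  expect_equal(nrow(scan_sequence("ACACCA", m$RNA_TBE)), 0L)
  expect_equal(motif_length(m$RELAXED), 5L)
  expect_equal(nrow(scan_sequence("GGTGA", m$RELAXED)[
    scan_sequence("GGTGA", m$RELAXED)$strand == "+", , drop = FALSE]), 1L)
  expect_error(motif_pattern("short", "GGT"), ">= 4")
})

test_that("scanning agrees with a brute-force sliding-window oracle", {
  m <- tbe_motifs()
  set.seed(21)
  for (i in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
               collapse = "")
    for (mot in m[c("TBE_DNA", "TBE_CORE", "RELAXED")]) {
      hits <- scan_sequence(s, mot)
      fwd <- oracle_scan_starts(s, mot$positions)
      rc_positions <- rev(lapply(mot$positions, function(set)
        chartr("ACGT", "TGCA", set)))
      rev_ <- oracle_scan_starts(s, rc_positions)
      expect_equal(sort(hits$start[hits$strand == "+"]), sort(fwd))
      expect_equal(sort(hits$start[hits$strand == "-"]), sort(rev_))
    }
  }
})

test_that("both-strand hit counts are strand symmetric", {
  m <- tbe_motifs()
  set.seed(22)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
               collapse = "")
    rc <- oracle_revcomp(s)
    for (mot in m[c("TBE_DNA", "TBE_CONSENSUS", "TBE_CORE", "RELAXED")])
      expect_equal(nrow(scan_sequence(s, mot)),
                   nrow(scan_sequence(rc, mot)))
  }
})

test_that("expected counts follow the closed form", {
  uniform <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  core_sense <- motif_pattern("core_sense", "GGTG",
                              strand_policy = "sense-only")
  expect_equal(expected_count(core_sense, 103, uniform), 100 * (1 / 4)^4)
  expect_equal(expected_count(core_sense, 3, uniform), 0)
  tbe_sense <- motif_pattern("tbe_sense", "WGGTGD",
                             strand_policy = "sense-only")
  expect_equal(expected_count(tbe_sense, 1005, uniform), 1000 * 6 / 4^6)
  # both-strand core doubles (GGTG and CACC are disjoint word sets)
  core_both <- motif_pattern("core_both", "GGTG")
  expect_equal(expected_count(core_both, 103, uniform),
               2 * 100 * (1 / 4)^4)
  expect_error(expected_count(core_both, 100, c(A = 0.5, C = 0.5, G = 0.5,
                                                T = 0.5)), "sum to 1")
})

test_that("binomial enrichment test is exact", {
  r <- enrichment_test(10, 1, 1000)
  # independent exact sum of the upper binomial tail
  want <- sum(vapply(10:1000, function(k)
    stats::dbinom(k, 1000, 1 / 1000), numeric(1)))
  expect_equal(r$p, want, tolerance = 1e-9)
  expect_equal(r$p, 1.11e-7, tolerance = 0.01)
  expect_equal(enrichment_test(0, 1, 100)$p, 1)
  # observing about the expected count is never significant
  expect_gt(enrichment_test(round(5), 5, 1000)$p, 0.4)
  expect_error(enrichment_test(11, 1, 10), "exceeds")
})

test_that("flank extraction respects strand and clips at constitutive exons", {
  set.seed(23)
  seq_chr <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                   collapse = "")
  genome <- Biostrings::DNAStringSet(c(chrT = seq_chr))
  make_ann <- function(strand) splice_annotation(
    events = data.frame(event_id = "ev1", gene_id = "g1", chrom = "chrT",
                        strand = strand, alt_first = 2L, alt_last = 2L),
    exons = data.frame(event_id = "ev1", exon_index = 1:3,
                       start = c(20L, 50L, 90L), end = c(30L, 60L, 100L),
                       is_alt = c(FALSE, TRUE, FALSE)))
  plus <- extract_flanks(make_ann("+"), "ev1", genome)
  # upstream is the lower-coordinate intron [30,50), clipped at exon 1
  expect_equal(plus$upstream, substr(seq_chr, 31, 50))
  expect_equal(plus$exon, substr(seq_chr, 51, 60))
  expect_equal(plus$downstream, substr(seq_chr, 61, 90))
  minus <- extract_flanks(make_ann("-"), "ev1", genome)
  # upstream flank is the reverse complement of the higher-coordinate intron
  expect_equal(minus$upstream, oracle_revcomp(substr(seq_chr, 61, 90)))
  expect_equal(minus$exon, oracle_revcomp(substr(seq_chr, 51, 60)))
  expect_equal(minus$downstream, oracle_revcomp(substr(seq_chr, 31, 50)))
  # zero flank yields empty flanks, exon only
  none <- extract_flanks(make_ann("+"), "ev1", genome, flank_bp = 0L)
  expect_equal(none$upstream, "")
  expect_equal(none$downstream, "")
  expect_equal(none$exon, substr(seq_chr, 51, 60))
})

test_that("presence summary reports planted 9-of-11 intronic TBEs", {
  d <- simulation_design(n_genes = 11, seed = 31)
  ann <- generate_annotation(d)
  psi <- matrix(0.5, 2, 2, dimnames = list(c("control", "mutant"),
                                           c("anterior", "posterior")))
  with_tbe <- ann$events$event_id[1:9]
  planted <- lapply(with_tbe, function(ev)
    planted_event(ev, psi, data.frame(motif_name = "TBE_DNA",
                                      flank = "upstream", copies = 1L)))
  # an A/T background can produce neither GGTG nor its CACC complement,
  # isolating the planted truth
  gen <- generate_genome(ann, background_freqs = c(A = 0.5, C = 0,
                                                   G = 0, T = 0.5),
                         planted = planted, seed = 32)
  ps <- presence_summary(ann, gen, tbe_motifs()$TBE_DNA)
  expect_equal(ps$summary, "9/11")
  expect_equal(ps$k, 9L)
  expect_setequal(ps$per_event$event_id[ps$per_event$present], with_tbe)
  # motif-free background alone gives 0/n
  gen0 <- generate_genome(ann, background_freqs = c(A = 0.5, C = 0,
                                                    G = 0, T = 0.5),
                          seed = 33)
  expect_equal(presence_summary(ann, gen0, tbe_motifs()$TBE_DNA)$summary,
               "0/11")
})
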