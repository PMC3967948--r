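test_that("generated annotation is a valid cassette layout with internal alt exons", {
  d <- simulation_design(n_genes = 100, seed = 7)
  ann <- generate_annotation(d, exons_per_gene = c(5L, 9L))
  expect_s3_class(ann, "splice_annotation")
  expect_equal(nrow(ann$events), 100L)
  # exhaustive check: alternative exons are never first or last
  for (i in seq_len(nrow(ann$events))) {
    ev <- ann$events[i, ]
    n_ex <- sum(ann$exons$event_id == ev$event_id)
    expect_gte(ev$alt_first, 2L)
    expect_lte(ev$alt_last, n_ex - 1L)
  }
  # minimal 3-exon design puts the alt exon in the middle
  ann3 <- generate_annotation(simulation_design(n_genes = 1, seed = 1),
                              exons_per_gene = c(3L, 3L))
  expect_equal(ann3$events$alt_first, 2L)
  expect_equal(ann3$events$alt_last, 2L)
  expect_error(generate_annotation(simulation_design(1), c(2L, 2L)),
               "at least 3 exons")
})

test_that("generators are seed-deterministic, byte for byte", {
  d <- simulation_design(n_genes = 20, seed = 7)
  expect_identical(generate_annotation(d), generate_annotation(d))
  ann <- generate_annotation(d)
  g1 <- generate_genome(ann, seed = 11)
  g2 <- generate_genome(ann, seed = 11)
  expect_identical(as.character(g1$seq), as.character(g2$seq))
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_genome_fasta(g1, f1); write_genome_fasta(g2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_identical(simulate_counts(ann, d), simulate_counts(ann, d))
})

test_that("simulated counts respect conservation invariants", {
  d <- simulation_design(n_genes = 50, seed = 3)
  ann <- generate_annotation(d)
  sim <- simulate_counts(ann, d)
  expect_true(all(sim$counts$exon_count <= sim$counts$gene_count))
  for (g in split(sim$counts, sim$counts$sample_id))
    expect_equal(unique(g$library_size), sum(g$gene_count))
  # 2 genotypes x 2 compartments x 2 replicates
  expect_equal(length(unique(sim$counts$sample_id)), 8L)
})

test_that("zero depth gives an all-zero table without error", {
  d <- simulation_design(n_genes = 5, mean_gene_depth = 0, seed = 2)
  ann <- generate_annotation(d)
  sim <- simulate_counts(ann, d)
  expect_true(all(sim$counts$gene_count == 0))
  expect_true(all(sim$counts$exon_count == 0))
})

test_that("invalid planted PSI and unknown events are rejected", {
  d <- simulation_design(n_genes = 2, seed = 1)
  ann <- generate_annotation(d)
  expect_error(planted_event("ev001",
    matrix(c(1.2, 0.5, 0.5, 0.5), 2, 2,
           dimnames = list(c("control", "mutant"),
                           c("anterior", "posterior")))),
    "\\[0, 1\\]")
  pe <- planted_event("nope",
    matrix(0.5, 2, 2, dimnames = list(c("control", "mutant"),
                                      c("anterior", "posterior"))))
  expect_error(simulate_counts(ann, d, list(pe)), "not in annotation")
})

test_that("planted motifs are recovered verbatim at recorded positions", {
  d <- simulation_design(n_genes = 6, seed = 5)
  ann <- generate_annotation(d)
  psi <- matrix(0.5, 2, 2, dimnames = list(c("control", "mutant"),
                                           c("anterior", "posterior")))
  planted <- list(
    planted_event("ev001", psi, data.frame(
      motif_name = "TBE_CONSENSUS", flank = "upstream", copies = 2L)),
    planted_event("ev002", psi, data.frame(
      motif_name = "TBE_DNA", flank = "downstream", copies = 3L)))
  gen <- generate_genome(ann, planted = planted, seed = 9)
  expect_equal(nrow(gen$plants), 5L)
  motifs <- tbe_motifs()
  for (i in seq_len(nrow(gen$plants))) {
    pl <- gen$plants[i, ]
    chrom_seq <- as.character(gen$seq[[pl$chrom]])
    k <- nchar(pl$word)
    expect_identical(substr(chrom_seq, pl$start + 1L, pl$start + k), pl$word)
    hits <- scan_sequence(chrom_seq, motifs[[pl$motif_name]], pl$chrom)
    expect_true(pl$start %in% hits$start)
  }
  # scanner finds >= planted copies in the extracted upstream flank
  fl <- extract_flanks(ann, "ev001", gen)
  expect_gte(nrow(scan_sequence(fl$upstream, motifs$TBE_CONSENSUS)), 2L)
})

test_that("planting fails when the flank cannot hold the copies", {
  d <- simulation_design(n_genes = 1, seed = 4)
  ann <- generate_annotation(d, intron_len = c(8L, 10L))
  psi <- matrix(0.5, 2, 2, dimnames = list(c("control", "mutant"),
                                           c("anterior", "posterior")))
  pe <- planted_event("ev001", psi, data.frame(
    motif_name = "TBE_CONSENSUS", flank = "upstream", copies = 5L))
  expect_error(generate_genome(ann, planted = list(pe), seed = 1),
               "planting error")
})

test_that("background motif frequency matches the binomial expectation", {
  core <- motif_pattern("core_sense", "GGTG", strand_policy = "sense-only")
  d <- simulation_design(n_genes = 1, seed = 8)
  ann <- generate_annotation(d, exons_per_gene = c(3L, 3L),
                             intron_len = c(49000L, 49000L))
  gen <- generate_genome(ann, seed = 8)
  seq_chr <- as.character(gen$seq[[1]])
  L <- nchar(seq_chr)
  expect_gte(L, 1e5 * 0.98)
  obs <- nrow(scan_sequence(seq_chr, core))
  expected <- (L - 3) * (1 / 4)^4
  sd4 <- 4 * sqrt(expected * (1 - (1 / 4)^4))
  expect_lt(abs(obs - expected), sd4)
})

test_that("detection-matrix simulation has recorded, recoverable truth", {
  # perfect detection: filter recovers exactly the true interactors
  dm <- simulate_detection_matrix(40, n_experiments = 7, n_controls = 2,
                                  p_true = 1, p_background = 0,
                                  p_control = 0, seed = 1)
  expect_setequal(filter_interactors(dm),
                  dm$truth$protein[dm$truth$is_true])
  # nothing detected: empty interactor set
  dm0 <- simulate_detection_matrix(40, p_true = 0, p_background = 0,
                                   p_control = 0, seed = 1)
  expect_length(filter_interactors(dm0), 0L)
  expect_error(simulate_detection_matrix(10, n_experiments = 1),
               ">= 2")
  expect_error(simulate_detection_matrix(10, p_true = 1.4),
               "\\[0, 1\\]")
})

test_that("filter precision on a noisy matrix equals a brute-force recount", {
  dm <- simulate_detection_matrix(100, n_experiments = 7, n_controls = 1,
                                  p_true = 0.8, p_background = 0.1,
                                  p_control = 0.9, seed = 3)
  kept <- filter_interactors(dm, min_datasets = 2)
  # independent recount straight off the boolean matrix
  det <- dm$detected
  ctl <- dm$experiments$is_control
  manual <- rownames(det)[rowSums(det[, !ctl]) >= 2 &
                            rowSums(det[, ctl, drop = FALSE]) == 0]
  expect_setequal(kept, manual)
  truth <- dm$truth$protein[dm$truth$is_true]
  precision <- mean(kept %in% truth)
  expect_equal(precision, sum(manual %in% truth) / length(manual))
})
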