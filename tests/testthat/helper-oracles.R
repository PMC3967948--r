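# Independent oracles used across tests. Deliberately naive: these
# re-derive expected values by enumeration or brute force, not by
# calling the implementation under test.

# Two-sided Fisher p by full enumeration of the conditional distribution,
# with point probabilities from choose() ratios.
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, support) * choose(r2, c1 - support) /
    choose(r1 + r2, c1)
  p_obs <- probs[support == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Brute-force degenerate motif scan: slide a window and compare each
# position against the per-position allowed sets, on one strand.
oracle_scan_starts <- function(seq_chr, positions) {
  k <- length(positions)
  n <- nchar(seq_chr)
  if (n < k) return(integer())
  chars <- strsplit(seq_chr, "")[[1]]
  starts0 <- integer()
  for (s in seq_len(n - k + 1)) {
    if (all(mapply(function(ch, set) ch %in% set,
                   chars[s:(s + k - 1)], positions)))
      starts0 <- c(starts0, s - 1L)
  }
  starts0
}

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

# O(n*m) interval-overlap recount for read assignment.
oracle_count_reads <- function(reads, exons) {
  overlaps <- function(rs, re, es, ee) rs < ee && es < re
  gene <- 0L; alt <- 0L
  for (i in seq_len(nrow(reads))) {
    hit_any <- FALSE; hit_alt <- FALSE
    for (j in seq_len(nrow(exons))) {
      if (reads$chrom[i] == exons$chrom[j] &&
          overlaps(reads$start[i], reads$end[i],
                   exons$start[j], exons$end[j])) {
        hit_any <- TRUE
        if (exons$is_alt[j]) hit_alt <- TRUE
      }
    }
    gene <- gene + hit_any; alt <- alt + hit_alt
  }
  c(exon_count = alt, gene_count = gene)
}

# Small hand-buildable count table in the package schema.
make_counts <- function(event_id, exon_ctl, gene_ctl, exon_mut, gene_mut,
                        compartment = "anterior") {
  n <- length(exon_ctl)
  rbind(
    data.frame(event_id = event_id, sample_id = paste0("c", seq_len(n)),
               condition = "control", compartment = compartment,
               replicate = seq_len(n), exon_count = exon_ctl,
               gene_count = gene_ctl, library_size = sum(gene_ctl)),
    data.frame(event_id = event_id, sample_id = paste0("m", seq_len(n)),
               condition = "mutant", compartment = compartment,
               replicate = seq_len(n), exon_count = exon_mut,
               gene_count = gene_mut, library_size = sum(gene_mut)))
}

# Recovery study shared by unit and acceptance tests: plants 30 strong
# switches among 200 genes at mean depth 200 and calls both compartments.
run_recovery_study <- function(seed) {
  d <- simulation_design(n_genes = 200, mean_gene_depth = 200, seed = seed)
  ann <- generate_annotation(d)
  planted <- plant_splicing_events(ann, 30, seed = seed + 1L)
  sim <- simulate_counts(ann, d, planted)
  calls <- call_events(sim$counts, ann)
  list(annotation = ann, planted = planted, sim = sim, calls = calls,
       planted_ids = vapply(planted, `[[`, character(1), "event_id"))
}
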