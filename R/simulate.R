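#' Simulation design for the two-genotype, two-compartment experiment
#'
#' Describes the sampling layout the count simulator emulates: a control
#' vs. mutant genotype contrast measured in two tissue compartments
#' (anterior and posterior limb mesenchyme) with a small number of
#' biological replicates per group, as in cDNA libraries prepared two per
#' genotype/tissue type.
#'
#' @param n_genes number of genes (one cassette event each) to simulate.
#' @param replicates_per_group biological replicates per
#'   condition-by-compartment group (default 2).
#' @param mean_gene_depth expected reads per gene per sample. Default 200
#'   places a typical event at the read depth where all four filters have
#'   good power while keeping desk-scale runtimes.
#' @param dispersion negative-binomial overdispersion (variance =
#'   mu + dispersion * mu^2); must be > 0. Default 0.05, typical for
#'   biological replicates of inbred tissue.
#' @param conditions ordered genotype labels, control first.
#' @param compartments ordered compartment labels.
#' @param seed integer seed driving every generator that takes the design.
#'
#' @return An object of class `simulation_design`.
#' @export
simulation_design <- function(n_genes,
                              replicates_per_group = 2L,
                              mean_gene_depth = 200,
                              dispersion = 0.05,
                              conditions = c("control", "mutant"),
                              compartments = c("anterior", "posterior"),
                              seed = 1L) {
  if (n_genes < 1L) stop("n_genes must be >= 1")
  if (replicates_per_group < 1L) stop("replicates_per_group must be >= 1")
  if (mean_gene_depth < 0) stop("mean_gene_depth must be >= 0")
  if (dispersion <= 0) stop("dispersion must be > 0")
  if (length(conditions) != 2L) stop("exactly two conditions are required")
  structure(list(n_genes = as.integer(n_genes),
                 replicates_per_group = as.integer(replicates_per_group),
                 mean_gene_depth = mean_gene_depth,
                 dispersion = dispersion,
                 conditions = conditions,
                 compartments = compartments,
                 seed = as.integer(seed)),
            class = "simulation_design")
}

#' Planted splicing event: the simulated ground truth
#'
#' Fixes the inclusion level (PSI) of one event per condition and
#' compartment, and optionally plans motif copies to be written into the
#' event's flanks by [generate_genome()]. Opposite-direction planting
#' (e.g. +0.4 PSI difference anterior, -0.4 posterior) emulates
#' compartment-specific reversal of splicing regulation.
#'
#' @param event_id identifier of an annotated event.
#' @param psi numeric matrix of inclusion levels in \[0,1\] with rownames =
#'   conditions and colnames = compartments.
#' @param motif_plan optional data.frame with columns `motif_name`,
#'   `flank` (one of `"upstream"`, `"downstream"`, `"exon"`) and `copies`.
#'
#' @return An object of class `planted_event`.
#' @export
planted_event <- function(event_id, psi, motif_plan = NULL) {
  if (!is.matrix(psi) || is.null(rownames(psi)) || is.null(colnames(psi)))
    stop("psi must be a matrix with condition rownames and compartment colnames")
  if (any(psi < 0 | psi > 1)) stop("psi values must lie in [0, 1]")
  if (!is.null(motif_plan)) {
    stopifnot(all(c("motif_name", "flank", "copies") %in% names(motif_plan)))
    if (!all(motif_plan$flank %in% c("upstream", "downstream", "exon")))
      stop("flank must be 'upstream', 'downstream' or 'exon'")
    if (any(motif_plan$copies < 0)) stop("motif copies must be >= 0")
  }
  structure(list(event_id = event_id, psi = psi, motif_plan = motif_plan),
            class = "planted_event")
}

# Uniform integer draw on [lo, hi]; safe when lo == hi (unlike sample()).
sample_range <- function(lo, hi, n = 1L) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate cassette-exon annotation with known structure
#'
#' Lays out `n_genes` genes, one cassette event per gene, each on its own
#' chromosome (`chrS1`, `chrS2`, ...). Exon and intron lengths are drawn
#' uniformly from the given ranges; the alternative block is a single
#' internal exon or, with probability `two_exon_prob`, two adjacent
#' internal exons (included or skipped together).
#'
#' @param design a [simulation_design]; its `seed` makes the output
#'   byte-reproducible.
#' @param exons_per_gene integer range `c(min, max)` of exons per gene;
#'   minimum 3 (two constitutive flanks plus one alternative).
#' @param exon_len,intron_len length ranges in bp.
#' @param two_exon_prob probability that the alternative block spans two
#'   adjacent exons.
#' @param gene_offset bp of intergenic sequence before each gene start.
#'
#' @return A [splice_annotation].
#' @export
#' @examples
#' d <- simulation_design(n_genes = 5, seed = 7)
#' ann <- generate_annotation(d)
#' ann
generate_annotation <- function(design,
                                exons_per_gene = c(5L, 9L),
                                exon_len = c(80L, 300L),
                                intron_len = c(200L, 1500L),
                                two_exon_prob = 0.2,
                                gene_offset = 100L) {
  if (min(exons_per_gene) < 3L)
    stop("invalid design: at least 3 exons per gene are required")
  with_seed(design$seed, {
    ev_rows <- vector("list", design$n_genes)
    ex_rows <- vector("list", design$n_genes)
    for (g in seq_len(design$n_genes)) {
      n_ex <- sample_range(exons_per_gene[1], exons_per_gene[2])
      e_len <- sample_range(exon_len[1], exon_len[2], n_ex)
      i_len <- sample_range(intron_len[1], intron_len[2], n_ex - 1L)
      starts <- integer(n_ex); ends <- integer(n_ex)
      pos <- gene_offset
      for (i in seq_len(n_ex)) {
        starts[i] <- pos
        ends[i] <- pos + e_len[i]
        pos <- ends[i] + if (i < n_ex) i_len[i] else 0L
      }
      two <- n_ex >= 4L && runif(1) < two_exon_prob
      alt_first <- sample_range(2L, n_ex - 1L - as.integer(two))
      alt_last <- alt_first + as.integer(two)
      strand <- sample(c("+", "-"), 1L)
      gid <- sprintf("gene%03d", g)
      eid <- sprintf("ev%03d", g)
      ev_rows[[g]] <- data.frame(event_id = eid, gene_id = gid,
                                 chrom = paste0("chrS", g), strand = strand,
                                 alt_first = alt_first, alt_last = alt_last)
      ex_rows[[g]] <- data.frame(event_id = eid, exon_index = seq_len(n_ex),
                                 start = starts, end = ends,
                                 is_alt = seq_len(n_ex) %in%
                                   seq.int(alt_first, alt_last))
    }
    splice_annotation(do.call(rbind, ev_rows), do.call(rbind, ex_rows))
  })
}

#' Generate genome sequence with planted motifs
#'
#' Samples i.i.d. background sequence for every chromosome in the
#' annotation and overwrites planted motif copies inside the intronic
#' flanks (or the alternative exon) of the planned events. Motifs are
#' planted in transcript orientation: on "-" strand genes the reverse
#' complement is written so that strand-aware extraction recovers the
#' motif verbatim. `upstream` means 5' of the alternative exon in
#' transcript orientation.
#'
#' @param annotation a [splice_annotation].
#' @param background_freqs named base probabilities (A, C, G, T), summing
#'   to 1 within 1e-9.
#' @param planted list of [planted_event] objects with non-NULL
#'   `motif_plan`s.
#' @param seed integer seed.
#' @param chrom_pad bp of sequence appended beyond the last exon.
#' @param motifs named list of [motif_pattern]s to draw planted words
#'   from; defaults to [tbe_motifs()].
#'
#' @return A list with `seq` (a [Biostrings::DNAStringSet] keyed by
#'   chromosome) and `plants` (data.frame of `event_id`, `motif_name`,
#'   `flank`, `chrom`, `start` 0-based genomic, `strand`, `word` as
#'   written on the forward strand, and `word_tx` in transcript
#'   orientation).
#' @export
generate_genome <- function(annotation,
                            background_freqs = c(A = 0.25, C = 0.25,
                                                 G = 0.25, T = 0.25),
                            planted = list(),
                            seed = 1L,
                            chrom_pad = 200L,
                            motifs = tbe_motifs()) {
  if (abs(sum(background_freqs) - 1) > 1e-9)
    stop("background_freqs must sum to 1")
  bases <- c("A", "C", "G", "T")
  if (!all(bases %in% names(background_freqs)))
    stop("background_freqs must be named with A, C, G, T")
  with_seed(seed, {
    chroms <- unique(annotation$events$chrom)
    seqs <- lapply(chroms, function(ch) {
      evs <- annotation$events$event_id[annotation$events$chrom == ch]
      len <- max(annotation$exons$end[annotation$exons$event_id %in% evs]) +
        chrom_pad
      paste(sample(bases, len, replace = TRUE,
                   prob = background_freqs[bases]), collapse = "")
    })
    names(seqs) <- chroms
    plant_rows <- list()
    for (pe in planted) {
      if (is.null(pe$motif_plan)) next
      meta <- event_meta(annotation, pe$event_id)
      iv <- alt_flank_intervals(annotation, pe$event_id, flank_bp = 1000L)
      minus <- meta$strand == "-"
      for (j in seq_len(nrow(pe$motif_plan))) {
        plan <- pe$motif_plan[j, ]
        if (plan$copies == 0L) next
        mot <- motifs[[plan$motif_name]]
        if (is.null(mot)) stop("unknown motif: ", plan$motif_name)
        # genomic interval corresponding to the requested transcript flank
        slot <- switch(plan$flank,
                       exon = iv$alt,
                       upstream = if (minus) iv$right else iv$left,
                       downstream = if (minus) iv$left else iv$right)
        k <- motif_length(mot)
        L <- slot[2] - slot[1]
        if (L < plan$copies * k)
          stop("planting error: flank of event ", pe$event_id,
               " (", L, " bp) too short for ", plan$copies,
               " copies of ", plan$motif_name)
        # one copy per equal chunk, jittered, so copies never overlap
        chunk <- as.integer(L %/% plan$copies)
        offs <- vapply(seq_len(plan$copies) - 1L, function(i)
          i * chunk + sample.int(chunk - k + 1L, 1L) - 1L, numeric(1))
        for (off in offs) {
          word_tx <- sample(motif_words(mot), 1L)
          word_fw <- if (minus) revcomp(word_tx) else word_tx
          s <- slot[1] + off            # 0-based genomic start
          substr(seqs[[meta$chrom]], s + 1L, s + k) <- word_fw
          plant_rows[[length(plant_rows) + 1L]] <-
            data.frame(event_id = pe$event_id, motif_name = plan$motif_name,
                       flank = plan$flank, chrom = meta$chrom, start = s,
                       strand = meta$strand, word = word_fw,
                       word_tx = word_tx)
        }
      }
    }
    plants <- if (length(plant_rows)) do.call(rbind, plant_rows) else
      data.frame(event_id = character(), motif_name = character(),
                 flank = character(), chrom = character(), start = integer(),
                 strand = character(), word = character(),
                 word_tx = character())
    list(seq = Biostrings::DNAStringSet(unlist(seqs)), plants = plants)
  })
}

#' Write a simulated genome to FASTA
#'
#' @param genome result of [generate_genome()] or a `DNAStringSet`.
#' @param path output FASTA path; records are wrapped at 60 columns.
#' @return The path, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  seqs <- if (is.list(genome) && !is.null(genome$seq)) genome$seq else genome
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' Simulate exon-level counts with planted inclusion differences
#'
#' For every event and sample the gene count is drawn from a negative
#' binomial with mean `mean_gene_depth` and the alternative-exon count
#' from a binomial whose success probability is the exon's share of the
#' gene's exonic length multiplied by the event's inclusion level (PSI).
#' Unplanted events receive one PSI drawn uniformly from \[0.3, 0.7\] and
#' shared by every group, so they are null for the downstream caller.
#' Library size is the per-sample sum of gene counts.
#'
#' @param annotation a [splice_annotation].
#' @param design a [simulation_design]; `design$seed` fixes the draw.
#' @param planted list of [planted_event]s overriding PSI per group.
#'
#' @return A list with `counts` (data.frame: `event_id`, `sample_id`,
#'   `condition`, `compartment`, `replicate`, `exon_count`, `gene_count`,
#'   `library_size`) and `truth` (data.frame per event and compartment:
#'   planted PSI per condition, `delta_psi` = mutant - control, and the
#'   implied `direction` label).
#' @export
simulate_counts <- function(annotation, design, planted = list()) {
  for (pe in planted) {
    if (!pe$event_id %in% annotation$events$event_id)
      stop("planted event not in annotation: ", pe$event_id)
    if (!identical(sort(rownames(pe$psi)), sort(design$conditions)) ||
        !identical(sort(colnames(pe$psi)), sort(design$compartments)))
      stop("psi matrix of ", pe$event_id,
           " must be indexed by the design's conditions and compartments")
  }
  ids <- annotation$events$event_id
  alt_len <- vapply(ids, function(e) alt_exon_length(annotation, e), numeric(1))
  gene_len <- vapply(ids, function(e) gene_exonic_length(annotation, e),
                     numeric(1))
  share <- alt_len / gene_len
  planted_ids <- vapply(planted, `[[`, character(1), "event_id")

  with_seed(design$seed + 1L, {
    base_psi <- setNames(runif(length(ids), 0.3, 0.7), ids)
    psi_of <- function(ev, cond, comp) {
      k <- match(ev, planted_ids)
      if (!is.na(k)) planted[[k]]$psi[cond, comp] else base_psi[[ev]]
    }
    rows <- list()
    for (comp in design$compartments) {
      for (cond in design$conditions) {
        for (rep in seq_len(design$replicates_per_group)) {
          gc <- rnbinom(length(ids), mu = design$mean_gene_depth,
                        size = 1 / design$dispersion)
          psi <- vapply(ids, psi_of, numeric(1), cond = cond, comp = comp)
          ec <- rbinom(length(ids), gc, share * psi)
          rows[[length(rows) + 1L]] <- data.frame(
            event_id = ids,
            sample_id = paste(cond, comp, rep, sep = "_"),
            condition = cond, compartment = comp, replicate = rep,
            exon_count = ec, gene_count = gc,
            library_size = sum(gc))
        }
      }
    }
    counts <- do.call(rbind, rows)
    rownames(counts) <- NULL
    truth <- do.call(rbind, lapply(design$compartments, function(comp) {
      pc <- vapply(ids, psi_of, numeric(1), cond = design$conditions[1],
                   comp = comp)
      pm <- vapply(ids, psi_of, numeric(1), cond = design$conditions[2],
                   comp = comp)
      data.frame(event_id = ids, compartment = comp,
                 psi_control = pc, psi_mutant = pm, delta_psi = pm - pc,
                 direction = classify_direction(pc, pm, min_delta = 0))
    }))
    rownames(truth) <- NULL
    list(counts = counts, truth = truth)
  })
}

#' Plant splicing effects for a parameter-recovery study
#'
#' Selects `n_events` events and assigns each a strong inclusion switch:
#' a high inclusion level drawn from `psi_high_range` in one group and a
#' drop of `delta_range` PSI in the other, with the affected group
#' (control or mutant) drawn independently per compartment, so some
#' events reverse direction between compartments. Defaults emulate
#' clear, RT-PCR-visible isoform switches. Only events whose alternative
#' exon block carries at least `min_share` of the gene's exonic length
#' are eligible: a regulated exon holding a few percent of the gene's
#' read mass is undetectable by any count-based test at desk-scale depth
#' and is not a meaningful recovery target.
#'
#' @param annotation a [splice_annotation].
#' @param n_events number of events to plant.
#' @param delta_range PSI drop range (absolute delta-PSI >= 0.3 is kept).
#' @param psi_high_range inclusion level of the unaffected state.
#' @param min_share minimum alternative-exon share of gene exonic length.
#' @param conditions,compartments group labels (control first).
#' @param seed integer seed.
#' @return List of [planted_event]s.
#' @export
plant_splicing_events <- function(annotation, n_events,
                                  delta_range = c(0.4, 0.6),
                                  psi_high_range = c(0.75, 0.9),
                                  min_share = 0.12,
                                  conditions = c("control", "mutant"),
                                  compartments = c("anterior", "posterior"),
                                  seed = 1L) {
  if (min(delta_range) < 0.3)
    stop("planted effects must have |delta PSI| >= 0.3")
  ids <- annotation$events$event_id
  share <- vapply(ids, function(e)
    alt_exon_length(annotation, e) / gene_exonic_length(annotation, e),
    numeric(1))
  eligible <- ids[share >= min_share]
  if (length(eligible) < n_events)
    stop("only ", length(eligible), " events meet min_share = ", min_share)
  with_seed(seed, {
    chosen <- sample(eligible, n_events)
    lapply(chosen, function(ev) {
      hi <- runif(1, psi_high_range[1], psi_high_range[2])
      dl <- runif(1, delta_range[1], delta_range[2])
      col_for <- function() {
        # which condition keeps the high inclusion level
        if (runif(1) < 0.5) c(hi, hi - dl) else c(hi - dl, hi)
      }
      psi <- cbind(col_for(), col_for())
      dimnames(psi) <- list(conditions, compartments)
      planted_event(ev, psi)
    })
  })
}

#' Simulate an IP-MS detection matrix with known interactors
#'
#' Proteins are split into true interactors and contaminants. True
#' interactors are detected in each non-control IP experiment with
#' probability `p_true` and never in negative controls; contaminants are
#' detected with probability `p_background` in IPs and `p_control` in
#' negative controls.
#'
#' @param n_proteins number of proteins.
#' @param n_experiments number of non-control IP-MS experiments (>= 2).
#' @param n_controls number of negative-control IPs.
#' @param p_true,p_background,p_control detection probabilities in \[0,1\].
#' @param prop_true fraction of proteins that are true interactors.
#' @param species species label per non-control experiment; recycled. The
#'   default mirrors a screen of three mouse-embryo and four human-cell
#'   IPs. Controls take the species of the matching position.
#' @param seed integer seed.
#'
#' @return A [detection_matrix] whose `truth` element records the true
#'   interactor labels.
#' @export
simulate_detection_matrix <- function(n_proteins,
                                      n_experiments = 7L,
                                      n_controls = 1L,
                                      p_true = 0.8,
                                      p_background = 0.05,
                                      p_control = 0.9,
                                      prop_true = 0.3,
                                      species = c("mouse", "mouse", "mouse",
                                                  "human", "human", "human",
                                                  "human"),
                                      seed = 1L) {
  if (n_experiments < 2L) stop("n_experiments must be >= 2")
  probs <- c(p_true, p_background, p_control, prop_true)
  if (any(probs < 0 | probs > 1))
    stop("invalid parameter: probabilities must lie in [0, 1]")
  with_seed(seed, {
    prot <- sprintf("prot%03d", seq_len(n_proteins))
    is_true <- runif(n_proteins) < prop_true
    sp <- rep_len(species, n_experiments)
    exps <- data.frame(
      label = c(paste0("IP", seq_len(n_experiments)),
                if (n_controls > 0) paste0("CTL", seq_len(n_controls))),
      species = c(sp, rep_len(sp, n_controls)),
      is_control = c(rep(FALSE, n_experiments), rep(TRUE, n_controls)))
    p_det <- matrix(NA_real_, n_proteins, nrow(exps))
    for (j in seq_len(nrow(exps))) {
      p_det[, j] <- if (exps$is_control[j])
        ifelse(is_true, 0, p_control)
      else
        ifelse(is_true, p_true, p_background)
    }
    det <- matrix(runif(length(p_det)) < p_det, n_proteins,
                  dimnames = list(prot, exps$label))
    dm <- detection_matrix(det, exps)
    dm$truth <- data.frame(protein = prot, is_true = is_true)
    dm
  })
}

#' Write an exon count table to TSV
#'
#' @param counts the `counts` data.frame of [simulate_counts()] (or any
#'   data.frame in the same schema).
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_counts_tsv <- function(counts, path) {
  write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an exon count table from TSV
#'
#' @param path file written by [write_counts_tsv()].
#' @return data.frame in the count-table schema.
#' @export
read_counts_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
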