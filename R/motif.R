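#' Degenerate motif pattern
#'
#' A fixed-length motif with per-position alternative base sets, e.g. the
#' T-box binding element (T/A)GGTG(T/A/G). RNA motifs are stored with U
#' normalized to T and are scanned on the sense strand only (RNA has one
#' strand); DNA motifs may be scanned on both strands.
#'
#' @param name motif name.
#' @param positions list of character vectors, one per position, each a
#'   subset of A/C/G/T (U accepted and normalized); or a single IUPAC
#'   string such as `"WGGTGD"`.
#' @param alphabet `"DNA"` or `"RNA"`.
#' @param strand_policy `"both"` or `"sense-only"`.
#' @return An object of class `motif_pattern`.
#' @export
#' @examples
#' motif_pattern("TBE_DNA", list(c("T","A"), "G", "G", "T", "G",
#'                               c("T","A","G")))
motif_pattern <- function(name, positions,
                          alphabet = c("DNA", "RNA"),
                          strand_policy = c("both", "sense-only")) {
  alphabet <- match.arg(alphabet)
  strand_policy <- match.arg(strand_policy)
  if (is.character(positions) && length(positions) == 1L)
    positions <- iupac_to_sets(positions)
  positions <- lapply(positions, function(s) {
    s <- toupper(chartr("U", "T", s))
    if (!all(s %in% c("A", "C", "G", "T")))
      stop("positions must be subsets of A/C/G/T (or U)")
    sort(unique(s))
  })
  if (length(positions) < 4L) stop("pattern length must be >= 4")
  if (alphabet == "RNA" && strand_policy == "both")
    stop("RNA motifs are sense-only")
  structure(list(name = name, positions = positions, alphabet = alphabet,
                 strand_policy = strand_policy),
            class = "motif_pattern")
}

IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

iupac_to_sets <- function(code) {
  chars <- strsplit(toupper(chartr("U", "T", code)), "")[[1]]
  lapply(chars, function(ch) {
    s <- IUPAC_SETS[[ch]]
    if (is.null(s)) stop("unknown IUPAC code: ", ch)
    s
  })
}

sets_to_iupac <- function(positions) {
  keys <- vapply(IUPAC_SETS, function(s) paste(sort(s), collapse = ""),
                 character(1))
  paste(vapply(positions, function(s) {
    names(keys)[match(paste(sort(s), collapse = ""), keys)]
  }, character(1)), collapse = "")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat("motif_pattern", x$name, ":", sets_to_iupac(x$positions),
      paste0("(", x$alphabet, ", ", x$strand_policy, ")\n"))
  invisible(x)
}

#' Motif length in bases
#' @param motif a [motif_pattern].
#' @return Integer length.
#' @export
motif_length <- function(motif) length(motif$positions)

#' All concrete words matching a degenerate motif
#' @param motif a [motif_pattern].
#' @return Character vector of DNA-alphabet words.
#' @export
motif_words <- function(motif) {
  grid <- expand.grid(motif$positions, stringsAsFactors = FALSE)
  apply(grid, 1L, paste, collapse = "")
}

revcomp <- function(x) {
  vapply(x, function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))),
    character(1), USE.NAMES = FALSE)
}

#' Built-in T-box binding element motifs
#'
#' The TBE family as defined in the T-box literature:
#' * `TBE_DNA` — (T/A)GGTG(T/A/G), the conservative putative TBE, both
#'   strands.
#' * `TBE_CONSENSUS` — (A/T)GGTGTG, the consensus TBE, both strands.
#' * `TBE_CORE` — GGTG (complement CACC), both strands.
#' * `RNA_TBE` — UGGUGU, the RNA counterpart, sense strand only.
#' * `RELAXED` — (G/T)(G/C)TGN, the less stringent ChIP-derived core,
#'   both strands; N matches any base and extends the length to 5.
#'
#' @return Named list of [motif_pattern]s.
#' @export
tbe_motifs <- function() {
  list(
    TBE_DNA = motif_pattern("TBE_DNA", "WGGTGD", "DNA", "both"),
    TBE_CONSENSUS = motif_pattern("TBE_CONSENSUS", "WGGTGTG", "DNA", "both"),
    TBE_CORE = motif_pattern("TBE_CORE", "GGTG", "DNA", "both"),
    RNA_TBE = motif_pattern("RNA_TBE", "TGGTGT", "RNA", "sense-only"),
    RELAXED = motif_pattern("RELAXED", "KSTGN", "DNA", "both"))
}

#' Scan a sequence for all (overlapping) motif matches
#'
#' Finds every match of the motif on the allowed strand(s). Overlapping
#' matches are all reported (no greedy consumption), since motif
#' multiplicity matters. Reverse-strand hits are reported in forward
#' coordinates with strand `"-"`; `matched_text` is always the forward
#' subject substring.
#'
#' @param sequence character string, `DNAString`, or `RNAString` (U is
#'   normalized to T on read).
#' @param motif a [motif_pattern].
#' @param sequence_id identifier recorded per hit.
#' @return data.frame with `sequence_id`, `start` (0-based), `strand`,
#'   `matched_text`, `motif_name`; zero rows when there is no match or
#'   the sequence is empty.
#' @export
#' @examples
#' m <- tbe_motifs()
#' scan_sequence("TGGTGT", m$TBE_DNA)
#' scan_sequence("UGGUGUUGGUGU", m$RNA_TBE)   # two overlap-free RNA TBEs
scan_sequence <- function(sequence, motif, sequence_id = "seq1") {
  seq_chr <- toupper(chartr("U", "T", as.character(sequence)))
  empty <- data.frame(sequence_id = character(), start = integer(),
                      strand = character(), matched_text = character(),
                      motif_name = character())
  k <- motif_length(motif)
  if (nchar(seq_chr) < k) return(empty)
  subj <- Biostrings::DNAString(seq_chr)
  pat <- Biostrings::DNAString(sets_to_iupac(motif$positions))
  fwd <- Biostrings::matchPattern(pat, subj, fixed = FALSE)
  rows <- list()
  if (length(fwd))
    rows[[1L]] <- data.frame(
      sequence_id = sequence_id,
      start = Biostrings::start(fwd) - 1L, strand = "+",
      matched_text = as.character(fwd), motif_name = motif$name)
  if (motif$strand_policy == "both") {
    rev <- Biostrings::matchPattern(Biostrings::reverseComplement(pat),
                                    subj, fixed = FALSE)
    if (length(rev))
      rows[[length(rows) + 1L]] <- data.frame(
        sequence_id = sequence_id,
        start = Biostrings::start(rev) - 1L, strand = "-",
        matched_text = as.character(rev), motif_name = motif$name)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Scan a set of sequences
#'
#' @param sequences named character vector or `DNAStringSet`.
#' @param motif a [motif_pattern].
#' @return Row-bound [scan_sequence()] results.
#' @export
scan_sequences <- function(sequences, motif) {
  seqs <- as.character(sequences)
  if (is.null(names(seqs)))
    names(seqs) <- paste0("seq", seq_along(seqs))
  out <- do.call(rbind, lapply(names(seqs), function(id)
    scan_sequence(seqs[[id]], motif, sequence_id = id)))
  rownames(out) <- NULL
  out
}

#' Expected number of motif matches by chance
#'
#' Closed-form expectation under an i.i.d. background:
#' `(L - k + 1)` positions times the per-position match probability (the
#' sum over all concrete words in the degenerate set of the product of
#' base frequencies), doubled when the motif is scanned on both strands
#' and its word set is not closed under reverse complement.
#'
#' @param motif a [motif_pattern].
#' @param sequence_length L in bases.
#' @param background_freqs named base probabilities summing to 1.
#' @return Expected match count (0 when L < motif length).
#' @export
#' @examples
#' core <- motif_pattern("core", "GGTG", strand_policy = "sense-only")
#' expected_count(core, 103, c(A = .25, C = .25, G = .25, T = .25))  # 0.390625
expected_count <- function(motif, sequence_length,
                           background_freqs = c(A = 0.25, C = 0.25,
                                                G = 0.25, T = 0.25)) {
  if (abs(sum(background_freqs) - 1) > 1e-9)
    stop("background_freqs must sum to 1")
  k <- motif_length(motif)
  if (sequence_length < k) return(0)
  words <- motif_words(motif)
  word_prob <- function(w) {
    prod(background_freqs[strsplit(w, "")[[1]]])
  }
  pw <- sum(vapply(words, word_prob, numeric(1)))
  n_pos <- sequence_length - k + 1
  if (motif$strand_policy == "both" &&
      !setequal(words, revcomp(words)))
    pw <- pw + sum(vapply(revcomp(words), word_prob, numeric(1)))
  n_pos * pw
}

#' Binomial over-representation test for motif counts
#'
#' Upper-tail binomial probability of observing at least `observed`
#' matches over `n_positions` scannable positions when the per-position
#' match probability is `expected / n_positions`.
#'
#' @param observed observed match count.
#' @param expected expected count under the background model.
#' @param n_positions number of scannable positions (>= 1).
#' @param motif_name optional label carried into the result.
#' @return data.frame with `motif_name`, `observed`, `expected`,
#'   `n_positions`, `p`.
#' @export
enrichment_test <- function(observed, expected, n_positions,
                            motif_name = NA_character_) {
  if (n_positions < 1) stop("n_positions must be >= 1")
  if (observed > n_positions) stop("observed exceeds n_positions")
  if (observed < 0 || expected < 0) stop("counts must be non-negative")
  p <- if (observed == 0) 1 else
    pbinom(observed - 1, n_positions, min(1, expected / n_positions),
           lower.tail = FALSE)
  data.frame(motif_name = motif_name, observed = observed,
             expected = expected, n_positions = n_positions, p = p)
}

#' Extract the alternative exon and its intronic flanks
#'
#' Returns up to `flank_bp` of intronic sequence on each side of the
#' alternative exon block, clipped at the neighbouring constitutive
#' exons, plus the exon block itself. All three sequences are reported in
#' transcript orientation: for "-" strand genes the higher-coordinate
#' intron is the upstream flank and every sequence is
#' reverse-complemented.
#'
#' @param annotation a [splice_annotation].
#' @param event_id event to extract.
#' @param genome `DNAStringSet` (or [generate_genome()] result) covering
#'   the event's chromosome.
#' @param flank_bp flank length in bp (default 1000); 0 yields empty
#'   flanks.
#' @return Named list of character strings `upstream`, `exon`,
#'   `downstream`.
#' @export
extract_flanks <- function(annotation, event_id, genome, flank_bp = 1000L) {
  seqs <- if (is.list(genome) && !is.null(genome$seq)) genome$seq else genome
  meta <- event_meta(annotation, event_id)
  if (!meta$chrom %in% names(seqs))
    stop("genome does not cover chromosome ", meta$chrom)
  chrom_seq <- seqs[[meta$chrom]]
  iv <- alt_flank_intervals(annotation, event_id, flank_bp = flank_bp)
  if (iv$alt[2] > length(chrom_seq))
    stop("event ", event_id, " extends beyond sequence end (",
         iv$alt[2], " > ", length(chrom_seq), ")")
  get <- function(b) {
    s <- max(0L, b[1]); e <- min(length(chrom_seq), b[2])
    if (e <= s) return("")
    as.character(Biostrings::subseq(chrom_seq, s + 1L, e))
  }
  left <- get(iv$left); mid <- get(iv$alt); right <- get(iv$right)
  if (meta$strand == "+") {
    list(upstream = left, exon = mid, downstream = right)
  } else {
    rc <- function(x) if (nzchar(x)) revcomp(x) else x
    list(upstream = rc(right), exon = rc(mid), downstream = rc(left))
  }
}

#' Fraction of events with a motif hit in a flanking intron
#'
#' Scans both intronic flanks (not the exon) of every event and reports
#' which events carry at least one hit, with the aggregate "k/n" count.
#'
#' @param annotation a [splice_annotation].
#' @param genome sequence set covering the events.
#' @param motif a [motif_pattern].
#' @param event_ids subset of events (default: all).
#' @param flank_bp intronic flank length (default 1000).
#' @return List with `per_event` (data.frame: `event_id`, `hits_upstream`,
#'   `hits_downstream`, `present`), `k`, `n`, `summary` ("k/n") and
#'   `fraction`.
#' @export
presence_summary <- function(annotation, genome, motif,
                             event_ids = NULL, flank_bp = 1000L) {
  if (is.null(event_ids)) event_ids <- annotation$events$event_id
  if (length(event_ids) == 0L) stop("at least one event is required")
  per <- do.call(rbind, lapply(event_ids, function(ev) {
    fl <- extract_flanks(annotation, ev, genome, flank_bp = flank_bp)
    up <- nrow(scan_sequence(fl$upstream, motif, ev))
    dn <- nrow(scan_sequence(fl$downstream, motif, ev))
    data.frame(event_id = ev, hits_upstream = up, hits_downstream = dn,
               present = (up + dn) > 0L)
  }))
  k <- sum(per$present); n <- nrow(per)
  list(per_event = per, k = k, n = n,
       summary = paste0(k, "/", n), fraction = k / n)
}

#' Write motif hits to BED6
#'
#' @param hits data.frame from [scan_sequence()]/[scan_sequences()].
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_hits_bed <- function(hits, path) {
  k <- nchar(hits$matched_text)
  bed <- data.frame(chrom = hits$sequence_id, start = hits$start,
                    end = hits$start + k, name = hits$motif_name,
                    score = 1L, strand = hits$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
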