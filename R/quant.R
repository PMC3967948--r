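#' Reads per kilobase per million mapped reads
#'
#' `rpkm = count / ((length_bp/1000) * (library_size/1e6))`. Vectorized;
#' linear in `count`, inversely proportional to feature length and
#' library size.
#'
#' @param count non-negative read count.
#' @param length_bp feature length in bp (>= 1).
#' @param library_size total mapped reads (>= 1).
#' @return Non-negative numeric RPKM value(s); 0 when `count` is 0.
#' @export
#' @examples
#' rpkm(10, 500, 1e6)   # 20
#' rpkm(15, 92, 2e6)    # a 92 bp exon at 15 reads in a 2M-read library
rpkm <- function(count, length_bp, library_size) {
  if (any(length_bp < 1)) stop("invalid parameter: length_bp must be >= 1")
  if (any(library_size < 1)) stop("invalid parameter: library_size must be >= 1")
  if (any(count < 0)) stop("invalid parameter: count must be >= 0")
  count / ((length_bp / 1000) * (library_size / 1e6))
}

#' Default usage-ratio pseudocount in RPKM units
#'
#' Half a read, expressed on the RPKM scale of a 1 kb feature:
#' `0.5 / (library_size / 1e6)`.
#'
#' @param library_size total mapped reads.
#' @return Pseudocount in RPKM units.
#' @export
default_pseudocount <- function(library_size) {
  0.5 / (library_size / 1e6)
}

#' Exon usage ratio
#'
#' `(exon_rpkm + eps) / (gene_rpkm + eps)`: the event's inclusion measure
#' (PSI-like). With alternative-exon reads a subset of gene reads and a
#' shared library, the ratio is at most ~1; 0/0 yields exactly 1
#' (uninformative).
#'
#' @param exon_rpkm RPKM of the alternative exon block.
#' @param gene_rpkm RPKM of the whole gene (all exons).
#' @param pseudocount continuity correction eps > 0.
#' @return Ratio in `[0, Inf)`; invariant to library-size rescaling when
#'   counts scale proportionally.
#' @export
usage_ratio <- function(exon_rpkm, gene_rpkm, pseudocount = 0.01) {
  if (any(pseudocount <= 0)) stop("invalid parameter: pseudocount must be > 0")
  if (any(exon_rpkm < 0) || any(gene_rpkm < 0))
    stop("invalid parameter: RPKM values must be >= 0")
  (exon_rpkm + pseudocount) / (gene_rpkm + pseudocount)
}

#' Count reads over an event annotation
#'
#' Assigns each read interval (0-based half-open) to an event: a read
#' counts toward `gene_count` if it overlaps any exon of the event's gene
#' by at least 1 bp (once, however many exons it touches) and toward
#' `exon_count` if it overlaps any alternative exon. Junction logic is
#' out of scope: reads are plain intervals.
#'
#' @param reads data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open). Reads on chromosomes absent from the annotation are
#'   skipped with a warning but still counted in `library_size`.
#' @param annotation a [splice_annotation].
#' @param sample_id label recorded in the output.
#' @return data.frame with `event_id`, `sample_id`, `exon_count`,
#'   `gene_count`, `library_size`.
#' @export
count_reads <- function(reads, annotation, sample_id = "sample1") {
  stopifnot(all(c("chrom", "start", "end") %in% names(reads)))
  if (any(reads$end <= reads$start))
    stop("malformed read interval: end <= start")
  known <- unique(annotation$events$chrom)
  unknown <- setdiff(unique(reads$chrom), known)
  if (length(unknown))
    warning("skipping reads on unknown chromosomes: ",
            paste(unknown, collapse = ", "))
  lib <- nrow(reads)
  use <- reads[reads$chrom %in% known, , drop = FALSE]
  rg <- GenomicRanges::GRanges(use$chrom,
                               IRanges::IRanges(use$start + 1L, use$end))
  ex <- merge(annotation$exons,
              annotation$events[, c("event_id", "chrom")], by = "event_id")
  eg <- GenomicRanges::GRanges(ex$chrom,
                               IRanges::IRanges(ex$start + 1L, ex$end))
  hits <- GenomicRanges::findOverlaps(rg, eg, minoverlap = 1L)
  hit_ev <- ex$event_id[S4Vectors::subjectHits(hits)]
  hit_alt <- ex$is_alt[S4Vectors::subjectHits(hits)]
  hit_read <- S4Vectors::queryHits(hits)
  ids <- annotation$events$event_id
  gene_count <- vapply(ids, function(e)
    length(unique(hit_read[hit_ev == e])), integer(1))
  exon_count <- vapply(ids, function(e)
    length(unique(hit_read[hit_ev == e & hit_alt])), integer(1))
  data.frame(event_id = ids, sample_id = sample_id,
             exon_count = exon_count, gene_count = gene_count,
             library_size = lib, row.names = NULL)
}

#' Read read intervals from a BED file
#'
#' Thin wrapper over `rtracklayer::import` returning the package's
#' 0-based half-open read schema.
#'
#' @param path BED file path.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open)
#'   and, when present, `name` and `strand`.
#' @export
read_reads_bed <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading BED requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    strand = as.character(GenomicRanges::strand(gr)))
  nm <- gr$name
  if (!is.null(nm)) out$name <- nm
  out
}

#' Add RPKM and usage-ratio columns to a count table
#'
#' @param counts count table in the [simulate_counts()] schema.
#' @param annotation a [splice_annotation] supplying exon and gene
#'   exonic lengths.
#' @param pseudocount eps for [usage_ratio()]; defaults to
#'   [default_pseudocount()] of each row's library size.
#' @return The input with `rpkm_exon`, `rpkm_gene` and `usage_ratio`
#'   columns appended.
#' @export
quantify_usage <- function(counts, annotation, pseudocount = NULL) {
  alt_len <- vapply(counts$event_id, function(e)
    alt_exon_length(annotation, e), numeric(1))
  gene_len <- vapply(counts$event_id, function(e)
    gene_exonic_length(annotation, e), numeric(1))
  lib <- pmax(counts$library_size, 1)
  eps <- if (is.null(pseudocount)) default_pseudocount(lib) else pseudocount
  counts$rpkm_exon <- rpkm(counts$exon_count, alt_len, lib)
  counts$rpkm_gene <- rpkm(counts$gene_count, gene_len, lib)
  counts$usage_ratio <- usage_ratio(counts$rpkm_exon, counts$rpkm_gene, eps)
  counts
}
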