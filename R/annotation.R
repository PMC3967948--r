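#' Cassette-exon splice event annotation
#'
#' Container for a set of cassette-exon events. Each event belongs to one
#' gene and consists of an ordered set of exons, of which one or two
#' adjacent *internal* exons are alternative (included or skipped as a
#' unit) while the remaining exons are constitutive. All coordinates are
#' 0-based, half-open (BED convention), on the forward genomic strand;
#' the `strand` column records the gene's transcriptional orientation.
#'
#' @param events data.frame with one row per event and columns
#'   `event_id`, `gene_id`, `chrom`, `strand` (`"+"` or `"-"`),
#'   `alt_first`, `alt_last` (1-based exon indices of the alternative
#'   block, strictly internal).
#' @param exons data.frame with one row per exon and columns `event_id`,
#'   `exon_index` (1-based, in genomic coordinate order), `start`, `end`
#'   (0-based half-open), `is_alt` (logical).
#'
#' @return An object of class `splice_annotation`: a list with elements
#'   `events` and `exons`.
#' @export
#' @examples
#' ann <- splice_annotation(
#'   events = data.frame(event_id = "ev1", gene_id = "g1", chrom = "chrS1",
#'                       strand = "+", alt_first = 2L, alt_last = 2L),
#'   exons  = data.frame(event_id = "ev1", exon_index = 1:3,
#'                       start = c(0L, 200L, 500L), end = c(100L, 300L, 650L),
#'                       is_alt = c(FALSE, TRUE, FALSE)))
#' alt_exon_length(ann, "ev1")
splice_annotation <- function(events, exons) {
  stopifnot(is.data.frame(events), is.data.frame(exons))
  need_ev <- c("event_id", "gene_id", "chrom", "strand", "alt_first", "alt_last")
  need_ex <- c("event_id", "exon_index", "start", "end", "is_alt")
  if (!all(need_ev %in% names(events)))
    stop("events is missing columns: ",
         paste(setdiff(need_ev, names(events)), collapse = ", "))
  if (!all(need_ex %in% names(exons)))
    stop("exons is missing columns: ",
         paste(setdiff(need_ex, names(exons)), collapse = ", "))
  if (anyDuplicated(events$event_id))
    stop("event_id values must be unique")
  if (!all(events$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (any(exons$end <= exons$start))
    stop("malformed exon interval: end <= start")

  for (ev in events$event_id) {
    ex <- exons[exons$event_id == ev, ]
    ex <- ex[order(ex$exon_index), ]
    n <- nrow(ex)
    if (n < 3L) stop("event ", ev, " has fewer than 3 exons")
    if (is.unsorted(ex$start, strictly = TRUE) ||
        any(ex$start[-1] < ex$end[-n]))
      stop("event ", ev, ": exons must be sorted and pairwise disjoint")
    meta <- events[events$event_id == ev, ]
    idx <- seq.int(meta$alt_first, meta$alt_last)
    if (meta$alt_first < 2L || meta$alt_last > n - 1L)
      stop("event ", ev, ": alternative exons must be strictly internal")
    if (!identical(sort(which(ex$is_alt)), as.integer(idx)))
      stop("event ", ev, ": is_alt flags disagree with alt indices")
  }
  structure(list(events = events, exons = exons), class = "splice_annotation")
}

#' @export
print.splice_annotation <- function(x, ...) {
  cat("splice_annotation:", nrow(x$events), "cassette events,",
      nrow(x$exons), "exons\n")
  invisible(x)
}

exons_of <- function(annotation, event_id) {
  ex <- annotation$exons[annotation$exons$event_id == event_id, ]
  if (nrow(ex) == 0L) stop("unknown event_id: ", event_id)
  ex[order(ex$exon_index), ]
}

event_meta <- function(annotation, event_id) {
  m <- annotation$events[annotation$events$event_id == event_id, ]
  if (nrow(m) == 0L) stop("unknown event_id: ", event_id)
  m
}

#' Summed length of the alternative exon block of an event
#'
#' @param annotation a [splice_annotation].
#' @param event_id event identifier.
#' @return Integer number of base pairs covered by the alternative
#'   exon(s); for two-exon blocks this is the summed exon length.
#' @export
alt_exon_length <- function(annotation, event_id) {
  ex <- exons_of(annotation, event_id)
  sum(ex$end[ex$is_alt] - ex$start[ex$is_alt])
}

#' Summed exonic length of an event's gene
#'
#' @inheritParams alt_exon_length
#' @return Integer total exonic base pairs (all exons of the event).
#' @export
gene_exonic_length <- function(annotation, event_id) {
  ex <- exons_of(annotation, event_id)
  sum(ex$end - ex$start)
}

# Intronic intervals immediately flanking the alternative block, clipped at
# the neighbouring constitutive exons. Genomic (not transcript) orientation.
alt_flank_intervals <- function(annotation, event_id, flank_bp = 1000L) {
  ex <- exons_of(annotation, event_id)
  meta <- event_meta(annotation, event_id)
  alt_s <- ex$start[meta$alt_first]
  alt_e <- ex$end[meta$alt_last]
  prev_end <- ex$end[meta$alt_first - 1L]
  next_start <- ex$start[meta$alt_last + 1L]
  left <- c(max(prev_end, alt_s - flank_bp), alt_s)
  right <- c(alt_e, min(next_start, alt_e + flank_bp))
  list(left = left, alt = c(alt_s, alt_e), right = right)
}

#' Write events to BED6
#'
#' One line per alternative exon; `name` is the event identifier, score
#' is 0 and the strand column carries the gene strand.
#'
#' @param annotation a [splice_annotation].
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_events_bed <- function(annotation, path) {
  rows <- do.call(rbind, lapply(annotation$events$event_id, function(ev) {
    ex <- exons_of(annotation, ev)
    meta <- event_meta(annotation, ev)
    alt <- ex[ex$is_alt, ]
    data.frame(chrom = meta$chrom, start = alt$start, end = alt$end,
               name = ev, score = 0L, strand = meta$strand)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
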