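#' Splicing-reporter (minigene) construct
#'
#' Ordered exon/intron segment model of a three-exon, two-intron
#' splicing reporter of the pRHCglo type, in which the second (internal)
#' exon is the regulated cassette. Roles must strictly alternate,
#' starting and ending with an exon.
#'
#' @param name construct name.
#' @param lengths integer segment lengths in bp (all >= 1), in order.
#' @param roles character vector over `"exon"`/`"intron"`; defaults to
#'   the alternating pattern implied by `lengths`.
#' @param ids segment identifiers; default `E1, I1, E2, I2, E3, ...`.
#' @param sequences optional character vector of segment sequences (NA
#'   allowed); non-NA entries must match `lengths`.
#' @return An object of class `reporter_construct` with a `segments`
#'   data.frame.
#' @export
#' @examples
#' rg <- reporter_construct("control", c(50, 700, 32, 824, 108))
#' enumerate_isoforms(rg)
reporter_construct <- function(name, lengths, roles = NULL, ids = NULL,
                               sequences = NULL) {
  n <- length(lengths)
  if (n < 1L) stop("a construct needs at least one segment")
  if (is.null(roles))
    roles <- rep_len(c("exon", "intron"), n)
  if (!all(roles %in% c("exon", "intron")))
    stop("roles must be 'exon' or 'intron'")
  if (roles[1] != "exon" || roles[n] != "exon" ||
      (n > 1L && any(roles[-1] == roles[-n])))
    stop("structural error: roles must alternate, starting and ending with an exon")
  if (any(lengths < 1)) stop("all segment lengths must be >= 1")
  if (is.null(ids)) {
    ne <- cumsum(roles == "exon"); ni <- cumsum(roles == "intron")
    ids <- ifelse(roles == "exon", paste0("E", ne), paste0("I", ni))
  }
  if (anyDuplicated(ids)) stop("segment ids must be unique")
  if (is.null(sequences)) sequences <- rep(NA_character_, n)
  ok <- is.na(sequences) | nchar(sequences) == lengths
  if (!all(ok)) stop("sequence length must equal segment length")
  structure(list(name = name,
                 segments = data.frame(id = ids, role = roles,
                                       length = as.integer(lengths),
                                       sequence = sequences)),
            class = "reporter_construct")
}

#' @export
print.reporter_construct <- function(x, ...) {
  cat("reporter_construct", x$name, ":",
      paste(sprintf("%s(%s,%d)", x$segments$id,
                    substr(x$segments$role, 1, 1), x$segments$length),
            collapse = "-"), "\n")
  invisible(x)
}

#' Replace (or delete) a segment of a reporter construct
#'
#' Models insert swaps such as replacing a reporter's 32 bp second exon
#' with a 31 bp T-box binding element, or with a 92 bp test exon.
#' `new_length = 0` deletes an internal exon and merges its flanking
#' introns; any edit that breaks exon/intron alternation is a structural
#' error.
#'
#' @param construct a [reporter_construct].
#' @param segment_id segment to replace.
#' @param new_length new length in bp (>= 1), or 0 to delete an internal
#'   exon.
#' @param new_sequence optional sequence of length `new_length`.
#' @return The edited [reporter_construct].
#' @export
replace_segment <- function(construct, segment_id, new_length,
                            new_sequence = NULL) {
  seg <- construct$segments
  i <- match(segment_id, seg$id)
  if (is.na(i)) stop("unknown segment: ", segment_id)
  if (new_length == 0) {
    if (seg$role[i] != "exon" || i == 1L || i == nrow(seg))
      stop("structural error: only an internal exon can be deleted")
    merged <- data.frame(id = paste0(seg$id[i - 1L], seg$id[i + 1L]),
                         role = "intron",
                         length = seg$length[i - 1L] + seg$length[i + 1L],
                         sequence = NA_character_)
    seg <- rbind(seg[seq_len(i - 2L), ], merged,
                 seg[seq.int(i + 2L, nrow(seg)), ])
  } else {
    if (!is.null(new_sequence) && nchar(new_sequence) != new_length)
      stop("sequence length must equal new_length")
    seg$length[i] <- as.integer(new_length)
    seg$sequence[i] <- if (is.null(new_sequence)) NA_character_ else
      new_sequence
  }
  reporter_construct(construct$name, seg$length, seg$role, seg$id,
                     seg$sequence)
}

#' Enumerate splice outcomes of a reporter construct
#'
#' Models the products observable by RT-PCR: the unspliced pre-mRNA;
#' each partially spliced form with exactly one intron removed (when the
#' construct has more than one intron); the fully spliced form with all
#' introns removed; and, for each internal exon, the cassette-skipped
#' form in which that exon and both flanking introns are removed.
#' Introns are only removable as whole units and exon order is
#' preserved; cryptic splice sites are not modelled.
#'
#' @param construct a [reporter_construct].
#' @return data.frame with `isoform`, `retained_ids` (comma-separated),
#'   `removed_introns`, `skipped_exons`, `product_length`.
#' @export
enumerate_isoforms <- function(construct) {
  seg <- construct$segments
  introns <- seg$id[seg$role == "intron"]
  inner_exons <- seg$id[seg$role == "exon"]
  inner_exons <- inner_exons[-c(1L, length(inner_exons))]
  outcome <- function(label, removed) {
    keep <- !(seg$id %in% removed)
    data.frame(isoform = label,
               retained_ids = paste(seg$id[keep], collapse = ","),
               removed_introns = paste(intersect(removed, introns),
                                       collapse = ","),
               skipped_exons = paste(setdiff(removed, introns),
                                     collapse = ","),
               product_length = sum(seg$length[keep]))
  }
  rows <- list(outcome("unspliced", character()))
  if (length(introns) > 1L)
    for (ii in introns)
      rows[[length(rows) + 1L]] <- outcome(paste0("partial_", ii), ii)
  if (length(introns) >= 1L)
    rows[[length(rows) + 1L]] <- outcome("full_inclusion", introns)
  for (ex in inner_exons) {
    i <- match(ex, seg$id)
    rows[[length(rows) + 1L]] <-
      outcome(paste0("skip_", ex), c(introns, ex))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Predicted RT-PCR product size for a splice outcome
#'
#' Subtracts the unamplified terminal overhangs implied by primer
#' placement: a 5' primer offset into the first exon and a 3' offset
#' into the last exon. Offsets must not exceed the terminal exon
#' lengths.
#'
#' @param construct the [reporter_construct] the outcome came from.
#' @param outcome a row of [enumerate_isoforms()] output, or a numeric
#'   product length.
#' @param primer_offsets numeric `c(offset5, offset3)` in bp.
#' @return Product size in bp.
#' @export
product_size <- function(construct, outcome, primer_offsets = c(0, 0)) {
  len <- if (is.data.frame(outcome)) outcome$product_length else
    as.numeric(outcome)
  seg <- construct$segments
  ex <- seg[seg$role == "exon", ]
  if (primer_offsets[1] < 0 || primer_offsets[2] < 0)
    stop("offsets must be >= 0")
  if (primer_offsets[1] > ex$length[1] ||
      primer_offsets[2] > ex$length[nrow(ex)])
    stop("offsets exceed terminal exon lengths")
  len - sum(primer_offsets)
}

#' Read/write reporter constructs as JSON
#'
#' @param construct a [reporter_construct].
#' @param path JSON file path.
#' @return `write_construct_json` returns the path invisibly;
#'   `read_construct_json` returns a [reporter_construct].
#' @export
write_construct_json <- function(construct, path) {
  jsonlite::write_json(list(name = construct$name,
                            segments = construct$segments),
                       path, auto_unbox = TRUE, na = "null", digits = NA)
  invisible(path)
}

#' @rdname write_construct_json
#' @export
read_construct_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sq <- x$segments$sequence
  if (is.null(sq)) sq <- rep(NA_character_, nrow(x$segments))
  reporter_construct(x$name, x$segments$length, x$segments$role,
                     x$segments$id, sq)
}
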