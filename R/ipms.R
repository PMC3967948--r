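#' IP-MS detection matrix
#'
#' Boolean protein-by-experiment detection calls from an
#' immunoprecipitation / mass-spectrometry screen, with per-experiment
#' species and negative-control metadata. Peptide-count evidence is
#' reduced to presence/absence, since the screen's inclusion rule is
#' presence-based.
#'
#' @param detected logical matrix, proteins in rows (unique rownames),
#'   experiments in columns (colnames matching `experiments$label`).
#' @param experiments data.frame with columns `label`, `species`
#'   (`"mouse"` or `"human"`), `is_control` (logical). At least one
#'   non-control experiment is required.
#' @return An object of class `detection_matrix`.
#' @export
detection_matrix <- function(detected, experiments) {
  stopifnot(is.matrix(detected), is.logical(detected))
  if (is.null(rownames(detected)) || anyDuplicated(rownames(detected)))
    stop("detected must have unique protein rownames")
  stopifnot(all(c("label", "species", "is_control") %in% names(experiments)))
  if (!identical(colnames(detected), experiments$label))
    stop("colnames(detected) must equal experiments$label")
  if (!any(!experiments$is_control))
    stop("at least one non-control experiment is required")
  structure(list(detected = detected, experiments = experiments),
            class = "detection_matrix")
}

#' @export
print.detection_matrix <- function(x, ...) {
  cat("detection_matrix:", nrow(x$detected), "proteins x",
      ncol(x$detected), "experiments (",
      sum(x$experiments$is_control), "negative controls )\n")
  invisible(x)
}

#' Filter the interactor set from an IP-MS screen
#'
#' A protein is retained iff it is detected in at least `min_datasets`
#' independent non-control IP-MS experiments and in zero negative-control
#' IPs. By default "independent datasets" pools experiments across
#' species; `per_species = TRUE` instead requires the detection threshold
#' to be met within a single species.
#'
#' @param matrix a [detection_matrix].
#' @param min_datasets minimum number of detecting IP experiments
#'   (default 2).
#' @param per_species require `min_datasets` within one species.
#' @return Sorted character vector of retained protein identifiers.
#' @export
filter_interactors <- function(matrix, min_datasets = 2L,
                               per_species = FALSE) {
  stopifnot(inherits(matrix, "detection_matrix"))
  if (min_datasets < 1L) stop("min_datasets must be >= 1")
  det <- matrix$detected
  if (nrow(det) == 0L) return(character())
  ctl <- matrix$experiments$is_control
  in_control <- if (any(ctl)) rowSums(det[, ctl, drop = FALSE]) > 0L
    else rep(FALSE, nrow(det))
  if (per_species) {
    keep_n <- rep(FALSE, nrow(det))
    for (sp in unique(matrix$experiments$species[!ctl])) {
      cols <- !ctl & matrix$experiments$species == sp
      keep_n <- keep_n | rowSums(det[, cols, drop = FALSE]) >= min_datasets
    }
  } else {
    keep_n <- rowSums(det[, !ctl, drop = FALSE]) >= min_datasets
  }
  sort(rownames(det)[keep_n & !in_control])
}

#' Cross-species overlap of an interactor set
#'
#' Flags, for each retained interactor, detection in at least one
#' non-control experiment of each species and counts the proteins
#' detected in both. Cross-species identity is by shared (case-
#' insensitive) protein identifier; supply pre-mapped orthologs if
#' identifiers differ between species.
#'
#' @param interactors character vector (e.g. from [filter_interactors()]).
#' @param matrix a [detection_matrix] containing both species among its
#'   non-control experiments.
#' @return List with `total`, `both_species`, and `per_protein`
#'   (data.frame: `protein`, `in_mouse`, `in_human`, `both`).
#' @export
cross_species_overlap <- function(interactors, matrix) {
  stopifnot(inherits(matrix, "detection_matrix"))
  sp <- matrix$experiments$species[!matrix$experiments$is_control]
  if (length(unique(sp)) < 2L)
    stop("matrix must contain non-control experiments of both species")
  det <- matrix$detected
  rn <- tolower(rownames(det))
  idx <- match(tolower(interactors), rn)
  if (anyNA(idx)) stop("unknown interactor: ",
                       paste(interactors[is.na(idx)], collapse = ", "))
  ncc <- !matrix$experiments$is_control
  in_sp <- function(s) {
    cols <- ncc & matrix$experiments$species == s
    rowSums(det[idx, cols, drop = FALSE]) > 0L
  }
  m <- in_sp("mouse"); h <- in_sp("human")
  per <- data.frame(protein = interactors, in_mouse = m, in_human = h,
                    both = m & h, row.names = NULL)
  list(total = length(interactors), both_species = sum(per$both),
       per_protein = per)
}

#' Category fold enrichment over a proteome background
#'
#' Fold enrichment of a category among an interactor set relative to the
#' whole proteome, `(k/n) / (K/N)`, with an upper-tail hypergeometric
#' p-value for drawing at least `k` category members in a sample of `n`
#' from a proteome of `N` containing `K` members.
#'
#' @param k_in_set category members in the interactor set.
#' @param n_set interactor set size.
#' @param K_background category members in the proteome.
#' @param N_background proteome size.
#' @return List with `fold` and `p`.
#' @export
#' @examples
#' fold_enrichment(33, 75, 2200, 20000)   # fold = 4
fold_enrichment <- function(k_in_set, n_set, K_background, N_background) {
  if (n_set < 1 || N_background < 1) stop("set sizes must be >= 1")
  if (K_background < 1) stop("background category count must be >= 1")
  if (k_in_set > n_set || K_background > N_background ||
      k_in_set > K_background)
    stop("counts violate k <= n, K <= N, k <= K")
  fold <- (k_in_set / n_set) / (K_background / N_background)
  p <- phyper(k_in_set - 1, K_background, N_background - K_background,
              n_set, lower.tail = FALSE)
  list(fold = fold, p = p)
}
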