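#' Filter thresholds for calling significant splicing events
#'
#' The four conjunctive criteria used to declare an event significantly
#' alternatively spliced in one comparison: two-sided Fisher exact test
#' p <= `p_max`, Bayesian error rate <= `ber_max`, usage-ratio fold
#' change >= `fc_min`, and total reads supporting the event >=
#' `min_support`.
#'
#' @param p_max maximum Fisher p (default 0.05).
#' @param ber_max maximum Bayesian error rate (default 0.1).
#' @param fc_min minimum fold change (default 1.5).
#' @param min_support minimum summed alternative-exon reads over all
#'   samples of the comparison (default 15).
#' @return An object of class `as_thresholds`.
#' @export
as_thresholds <- function(p_max = 0.05, ber_max = 0.1,
                          fc_min = 1.5, min_support = 15) {
  if (p_max <= 0 || p_max > 1) stop("p_max must be in (0, 1]")
  if (ber_max <= 0 || ber_max > 1) stop("ber_max must be in (0, 1]")
  if (fc_min < 1) stop("fc_min must be >= 1")
  if (min_support < 0) stop("min_support must be >= 0")
  structure(list(p_max = p_max, ber_max = ber_max,
                 fc_min = fc_min, min_support = min_support),
            class = "as_thresholds")
}

#' Build the 2x2 contingency table for one event and comparison
#'
#' Rows are conditions (replicates pooled by summation; at two replicates
#' per group there is no scope for within-group variance modelling),
#' columns are alternative-exon reads and gene-remainder reads
#' (`gene_count - exon_count`).
#'
#' @param counts count table in the [simulate_counts()] schema.
#' @param event_id event to tabulate.
#' @param comparison compartment defining the comparison.
#' @param conditions the two condition labels, control first.
#' @return 2x2 integer matrix with condition rownames and columns
#'   `alt_exon`, `gene_rest`. An all-zero table carries attribute
#'   `uninformative = TRUE`.
#' @export
#' @examples
#' counts <- data.frame(
#'   event_id = "ev1", sample_id = paste0("s", 1:4),
#'   condition = rep(c("control", "mutant"), each = 2),
#'   compartment = "anterior", replicate = c(1, 2, 1, 2),
#'   exon_count = c(10, 12, 2, 3), gene_count = c(40, 44, 41, 39),
#'   library_size = 1000)
#' build_contingency(counts, "ev1", "anterior")   # [[22, 62], [5, 75]]
build_contingency <- function(counts, event_id, comparison,
                              conditions = c("control", "mutant")) {
  sub <- counts[counts$event_id == event_id &
                  counts$compartment == comparison, , drop = FALSE]
  tab <- matrix(0L, 2L, 2L,
                dimnames = list(conditions, c("alt_exon", "gene_rest")))
  for (i in seq_along(conditions)) {
    g <- sub[sub$condition == conditions[i], , drop = FALSE]
    if (nrow(g) == 0L)
      stop("no samples for condition '", conditions[i], "' in comparison '",
           comparison, "' (event ", event_id, ")")
    if (any(g$gene_count < g$exon_count))
      stop("data integrity error: gene_count < exon_count for event ",
           event_id)
    tab[i, 1L] <- sum(g$exon_count)
    tab[i, 2L] <- sum(g$gene_count) - sum(g$exon_count)
  }
  if (all(tab == 0L)) attr(tab, "uninformative") <- TRUE
  tab
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Point-probability rule: the p-value is the sum of hypergeometric
#' probabilities, over all tables with the observed margins, whose point
#' probability does not exceed the observed table's (ties included at
#' relative tolerance 1e-7). A table with a zero row or column margin is
#' degenerate and returns p = 1 with attribute `degenerate = TRUE`.
#'
#' @param table 2x2 matrix of non-negative integers.
#' @return p-value in (0, 1].
#' @export
#' @examples
#' fisher_exact_two_sided(matrix(c(5, 5, 5, 5), 2))    # 1
#' fisher_exact_two_sided(matrix(c(10, 0, 0, 10), 2))  # 2/choose(20,10)
fisher_exact_two_sided <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2L))
  if (any(table < 0) || any(table != round(table)))
    stop("table entries must be non-negative integers")
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    p <- 1
    attr(p, "degenerate") <- TRUE
    return(p)
  }
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(support, r1, r2, c1)
  p_obs <- probs[support == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Fold change between two usage ratios
#'
#' `max(psi_ctl/psi_mut, psi_mut/psi_ctl)`; symmetric in its arguments
#' and always >= 1.
#'
#' @param psi_ctl,psi_mut strictly positive usage ratios (pseudocounted
#'   upstream).
#' @return Numeric fold change >= 1.
#' @export
fold_change <- function(psi_ctl, psi_mut) {
  if (any(psi_ctl <= 0) || any(psi_mut <= 0))
    stop("invalid parameter: usage ratios must be > 0")
  pmax(psi_ctl / psi_mut, psi_mut / psi_ctl)
}

#' Q-value style Bayesian error rate per event
#'
#' Posterior error bound computed from the vector of Fisher p-values of
#' one comparison. The null proportion is estimated as
#' `pi0 = min(1, mean(p > 0.5) / 0.5)` and the error rate of event i is
#' the minimum of `pi0 * t * M / rank(t)` over thresholds `t >= p_i`
#' (Storey-style step-up with a fixed lambda of 0.5). The estimator is
#' monotone non-decreasing in p and capped at 1. A 5% FDR validation cut
#' and the 0.1 error-rate filter are this same machinery at different
#' thresholds.
#'
#' @param p_values vector of p-values in (0, 1], one per event.
#' @return Vector of error rates in \[0, 1\], in input order.
#' @export
bayesian_error_rate <- function(p_values) {
  if (length(p_values) == 0L) stop("empty p-value vector")
  if (any(p_values <= 0 | p_values > 1)) stop("p-values must lie in (0, 1]")
  M <- length(p_values)
  pi0 <- min(1, mean(p_values > 0.5) / 0.5)
  ord <- order(p_values)
  q <- pi0 * p_values[ord] * M / seq_len(M)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(M)
  out[ord] <- q
  out
}

#' Classify the direction of a splicing change
#'
#' Interprets a control-vs-mutant PSI difference as the factor's action:
#' lower inclusion in the mutant means the factor promotes inclusion
#' (its loss causes exclusion), higher inclusion in the mutant means the
#' factor promotes skipping. Changes within `min_delta` are `"none"`.
#'
#' @param psi_ctl,psi_mut usage ratios in the control and mutant groups.
#' @param min_delta minimum PSI difference to call a direction
#'   (default 0.05).
#' @return Character vector over `"factor-promotes-inclusion"`,
#'   `"factor-promotes-skipping"`, `"none"`.
#' @export
classify_direction <- function(psi_ctl, psi_mut, min_delta = 0.05) {
  ifelse(psi_mut < psi_ctl - min_delta, "factor-promotes-inclusion",
         ifelse(psi_mut > psi_ctl + min_delta, "factor-promotes-skipping",
                "none"))
}

#' Call significant alternative splicing events
#'
#' Applies the four-filter cascade to every event in every compartment
#' present in the count table. Per comparison: replicates are pooled into
#' a 2x2 table for the Fisher test; usage ratios are computed from pooled
#' RPKM values (or pooled count proportions when no annotation is given);
#' the Bayesian error rate is estimated across all events of the same
#' comparison; support is the summed alternative-exon read count over all
#' samples of the comparison. An event is significant iff all four
#' filters pass.
#'
#' @param counts count table in the [simulate_counts()] schema.
#' @param annotation optional [splice_annotation]; when supplied, usage
#'   ratios are RPKM-based (alternative-exon RPKM over gene RPKM).
#' @param thresholds an [as_thresholds].
#' @param conditions condition labels, control first.
#' @param min_delta direction-call threshold, see [classify_direction()].
#' @param raw_rpkm_fc if TRUE, the fold-change filter uses raw
#'   alternative-exon RPKM rather than the usage ratio, so gene-level
#'   expression changes are not factored out (annotation required).
#' @return data.frame of calls: `event_id`, `comparison`, `p`, `ber`,
#'   `fc`, `support`, `psi_ctl`, `psi_mut`, `direction`, the four
#'   per-filter booleans, and `significant`.
#' @export
call_events <- function(counts, annotation = NULL,
                        thresholds = as_thresholds(),
                        conditions = c("control", "mutant"),
                        min_delta = 0.05,
                        raw_rpkm_fc = FALSE) {
  stopifnot(inherits(thresholds, "as_thresholds"))
  if (raw_rpkm_fc && is.null(annotation))
    stop("raw_rpkm_fc requires an annotation")
  comps <- unique(counts$compartment)
  if (length(comps) == 0L) stop("counts cover no comparison")
  out <- list()
  for (comp in comps) {
    sub <- counts[counts$compartment == comp, , drop = FALSE]
    ids <- unique(sub$event_id)
    p <- numeric(length(ids)); fc <- numeric(length(ids))
    support <- numeric(length(ids))
    psi_ctl <- numeric(length(ids)); psi_mut <- numeric(length(ids))
    for (i in seq_along(ids)) {
      tab <- build_contingency(sub, ids[i], comp, conditions)
      p[i] <- as.numeric(fisher_exact_two_sided(tab))
      support[i] <- sum(tab[, "alt_exon"])
      grp <- function(cond) sub[sub$event_id == ids[i] &
                                  sub$condition == cond, , drop = FALSE]
      psi_grp <- function(cond) {
        g <- grp(cond)
        lib <- max(sum(g$library_size), 1)
        eps <- default_pseudocount(lib)
        if (is.null(annotation)) {
          usage_ratio(sum(g$exon_count), sum(g$gene_count), 0.5)
        } else {
          e_rpkm <- rpkm(sum(g$exon_count),
                         alt_exon_length(annotation, ids[i]), lib)
          g_rpkm <- rpkm(sum(g$gene_count),
                         gene_exonic_length(annotation, ids[i]), lib)
          usage_ratio(e_rpkm, g_rpkm, eps)
        }
      }
      psi_ctl[i] <- psi_grp(conditions[1])
      psi_mut[i] <- psi_grp(conditions[2])
      if (raw_rpkm_fc) {
        len <- alt_exon_length(annotation, ids[i])
        rp <- vapply(conditions, function(cond) {
          g <- grp(cond)
          lib <- max(sum(g$library_size), 1)
          rpkm(sum(g$exon_count), len, lib) + default_pseudocount(lib)
        }, numeric(1))
        fc[i] <- fold_change(rp[1], rp[2])
      } else {
        fc[i] <- fold_change(psi_ctl[i], psi_mut[i])
      }
    }
    ber <- bayesian_error_rate(p)
    pass_p <- p <= thresholds$p_max
    pass_ber <- ber <= thresholds$ber_max
    pass_fc <- fc >= thresholds$fc_min
    pass_support <- support >= thresholds$min_support
    out[[comp]] <- data.frame(
      event_id = ids, comparison = comp, p = p, ber = ber, fc = fc,
      support = support, psi_ctl = psi_ctl, psi_mut = psi_mut,
      direction = classify_direction(psi_ctl, psi_mut, min_delta),
      pass_p = pass_p, pass_ber = pass_ber, pass_fc = pass_fc,
      pass_support = pass_support,
      significant = pass_p & pass_ber & pass_fc & pass_support)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write splicing calls to TSV
#'
#' @param calls data.frame from [call_events()].
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
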