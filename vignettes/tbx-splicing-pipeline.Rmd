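---
title: "Calling T-box factor dependent alternative splicing from exon-level counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling T-box factor dependent alternative splicing from exon-level counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tbxsplice)
```

## The problem

T-box transcription factors such as TBX3 — whose haploinsufficiency causes
ulnar-mammary syndrome — were long studied purely as transcriptional
repressors. Proteomic screens, however, place TBX3 in complexes with
hnRNPs, DDX helicases and other splicing factors, and loss of Tbx3 in the
embryonic limb changes which cassette exons are included in specific
transcripts — in opposite directions in the anterior and posterior limb
compartments for the same gene. `tbxsplice` packages the informatics
needed to study this phenotype: a cassette-exon caller driven by a filter
cascade on exon-level RNA-Seq counts, degenerate T-box binding element
(TBE) scanning of alternative exons and their intronic flanks, the
interactome-filter arithmetic for IP-MS screens, and a segment model of
three-exon splicing-reporter (minigene) constructs. A seeded
synthetic-data generator makes every stage testable offline against known
ground truth.

## The splicing caller

The unit of analysis is a *cassette event*: one or two adjacent internal
exons of a gene that are included or skipped as a block. For each event
and each comparison (one tissue compartment, control vs. mutant
genotype), the caller works from per-sample counts of reads on the
alternative exon block (`exon_count`) and on all exons of the gene
(`gene_count`).

Inclusion is measured by the **usage ratio**
$\hat\psi = \frac{\mathrm{RPKM}_{\text{exon}} + \varepsilon}{\mathrm{RPKM}_{\text{gene}} + \varepsilon}$,
with RPKM = count / (length in kb × library size in millions) and a
half-read pseudocount $\varepsilon$. Using the ratio rather than raw exon
RPKM means a change in the gene's overall expression does not masquerade
as a splicing change (a raw-RPKM mode is available via
`call_events(raw_rpkm_fc = TRUE)`).

Four conjunctive filters declare an event significant in a comparison
(`as_thresholds()` defaults):

1. **Fisher's exact test p ≤ 0.05.** Replicates are pooled by summation
   into a 2×2 table of {control, mutant} × {alternative-exon reads,
   gene-remainder reads}. With two replicates per group there is too
   little replication to model within-group variance, so an exact
   conditional test on pooled counts is the appropriate design; this is a
   documented limitation, not an oversight — a dispersion-based
   exon-usage model (DEXSeq-style) is a non-goal. The two-sided p-value
   follows the point-probability rule: the sum of hypergeometric
   probabilities of all tables with the observed margins whose point
   probability is at most the observed one (ties included at relative
   tolerance $10^{-7}$). The test suite checks this exhaustively against
   full enumeration for every table with margins ≤ 30.
2. **Bayesian error rate ≤ 0.1.** A per-event posterior error bound
   computed across all events of one comparison: the null proportion is
   estimated as $\hat\pi_0 = \min(1, \overline{[p > 0.5]}/0.5)$ and the
   error rate of event $i$ is $\min_{t \ge p_i} \hat\pi_0\, t\, M /
   \mathrm{rank}(t)$ — a Storey-style q-value with $\lambda = 0.5$. This
   estimator is the package's own choice of a q-value-style bound; it is
   monotone in p and capped at 1. The same machinery at a 5% threshold
   gives the FDR cut used to separate validated from unvalidated events.
3. **Fold change ≥ 1.5**, computed as
   $\max(\hat\psi_{ctl}/\hat\psi_{mut},\, \hat\psi_{mut}/\hat\psi_{ctl})$
   on pooled per-group usage ratios.
4. **Read support ≥ 15**: the summed alternative-exon reads over all
   (four, by default) samples of the comparison. The threshold is a
   per-event number, so support is defined per comparison, not per
   sample.

Direction is interpreted as the factor's action:
$\hat\psi_{mut} < \hat\psi_{ctl} - \delta$ means the factor promotes
inclusion (its loss causes exclusion), the reverse means it promotes
skipping; $\delta$ defaults to 0.05 so near-ties are called `"none"`.
Because each compartment is called and error-rate-corrected separately,
an event regulated in opposite directions in the two compartments — the
hallmark observed for *Dlg3* exons 8/9 and *Nfkb1* exon 11 — yields two
calls with opposite direction labels.

```{r caller-demo, eval = FALSE}
d <- simulation_design(n_genes = 200, mean_gene_depth = 200, seed = 42)
ann <- generate_annotation(d)
planted <- plant_splicing_events(ann, 30, seed = 43)
sim <- simulate_counts(ann, d, planted)
calls <- call_events(sim$counts, ann)
subset(calls, significant)
```

## What the synthetic data emulate — and what they do not

The generator reproduces the *design* of the limb RNA-Seq experiment: two
genotypes × two compartments × two replicates, one cassette event per
gene, each gene on its own chromosome (`chrS1`, `chrS2`, ...).

* **Gene counts** are negative binomial with mean `mean_gene_depth`
  (default 200 reads/gene/sample — the depth of a moderately expressed
  gene in a few tens of millions of reads, and enough for the filters to
  have power at desk scale; the original libraries' depths are not
  stated anywhere we could use) and dispersion 0.05, typical for
  biological replicates of inbred tissue.
* **Exon counts** are binomial given the gene count, with success
  probability (alternative-exon share of gene exonic length) × PSI, so
  inclusion modulates only the alternative exon and `exon_count <=
  gene_count` holds by construction. Unplanted events get one PSI drawn
  from U(0.3, 0.7) shared by all groups — exactly null for the caller —
  which makes null calibration checkable: conditional on the margins the
  2×2 table is hypergeometric, so the Fisher p is exact (and slightly
  conservative through discreteness).
* **Planted events** (`plant_splicing_events()`) model the kind of event
  the study validated: clear isoform switches, with ΔPSI drawn from
  U(0.4, 0.6) off a high-inclusion state in U(0.75, 0.9), and the
  affected genotype drawn independently per compartment so roughly half
  the planted events reverse direction between compartments. Only events
  whose alternative block carries at least 12% of the gene's exonic
  length are eligible for planting: at 200 reads/gene, an exon with a
  few percent of the read mass yields ~20 supporting reads total, and no
  count-based test can reliably see any ΔPSI there — such events are a
  statement about coverage, not about the caller. Annotation geometry
  (5–9 exons of 80–300 bp, introns 200–1500 bp, a 20% chance of a
  two-exon alternative block with perfectly correlated inclusion)
  mirrors compact mammalian genes and the two-exon *Dlg3* block.

The generator simulates counts, not reads, because every statistic
downstream operates on counts/RPKM; `count_reads()` exists for interval
data and is checked against a brute-force overlap oracle. Not modelled:
junction reads, sequencing error, paired ends, isoform-level structure
beyond the cassette, and genuinely correlated biological replicates. A
passing recovery test therefore shows the *filter cascade* recovers
planted truth under its own sampling assumptions; it cannot show
robustness to misannotation or junction-mapping artefacts in real data.

## Motif scanning

`tbe_motifs()` registers the TBE family exactly as used in the T-box
literature: the conservative putative TBE (T/A)GGTG(T/A/G), the consensus
(A/T)GGTGTG, the GGTG core (complement CACC), the RNA TBE UGGUGU, and the
relaxed ChIP-derived core (G/T)(G/C)TGN (N extends its length to 5).
Scanning reports *all* matches including overlapping ones — multiplicity
matters, e.g. for a probe carrying two adjacent RNA TBEs. DNA motifs are
scanned on both strands with reverse-strand hits mapped back to forward
coordinates; RNA motifs are sense-only. Matching is delegated to
`Biostrings::matchPattern` on IUPAC-encoded patterns and cross-checked in
the tests against a naive sliding-window oracle.

`expected_count()` gives the closed-form chance expectation
$(L-k+1)\sum_{w} \prod_j f_{w_j}$ (summed over both strands when they
are scanned and the word set is not reverse-complement closed), and
`enrichment_test()` an exact upper-tail binomial p — a fixed-pattern
over-representation test, deliberately not a de-novo discovery algorithm
(MEME remains an external tool). `presence_summary()` answers the
"present in the flanking introns of k/n validated events" question:
flanks are clipped at the neighbouring constitutive exons because the
question concerns *intronic* TBEs, extracted in transcript orientation
(upstream = 5' of the alternative exon; reverse-complemented for minus
strand genes) with a 1 kb default.

## IP-MS filtering

`filter_interactors()` is the screen's inclusion rule: detected in at
least two independent non-control IP-MS datasets and in zero negative
controls. "Independent datasets" pools experiments across species by
default, matching a rule stated over a combined set of mouse-embryo and
human-cell IPs; `per_species = TRUE` is exposed because the alternative
reading (two detections within one species) is also defensible.
`cross_species_overlap()` counts interactors detected in both species
(identity by case-insensitive shared identifier; pre-map orthologs if
needed), and `fold_enrichment()` gives category fold enrichment over a
proteome background with an exact hypergeometric upper tail — the same
conditional distribution as the caller's Fisher core, which the tests
exploit as a cross-module consistency check.

## The minigene model

`reporter_construct()` models a splicing reporter as alternating
exon/intron segments (exon first and last). `enumerate_isoforms()`
returns the outcomes observable by RT-PCR: unspliced, each single-intron
partial, fully spliced, and cassette skipping of each internal exon with
both flanking introns. Only whole-intron removal is modelled — no
cryptic splice sites — so every product length is a simple sum of
retained segment lengths and obeys skip ≤ full inclusion ≤ partial ≤
unspliced. Published band sizes for related constructs are not mutually
reconcilable under one shared backbone, so the model is validated by
these conservation invariants on randomized constructs rather than by
bit-exact product sizes; `product_size()` subtracts primer offsets into
the terminal exons for comparing against gel bands.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open (BED convention) everywhere
  internally; 1-based inputs are converted at the boundary
  (`read_reads_bed()`).
* A read overlaps an exon if they share ≥ 1 bp; a read touching two
  exons of one gene counts once toward `gene_count`.
* The usage-ratio pseudocount defaults to half a read in RPKM units,
  `0.5/(library_size/1e6)`; a 0/0 event has ratio exactly 1 and is
  uninformative rather than an error, as is an all-zero contingency
  table (flagged, p = 1).
* Fisher tables with a zero margin return p = 1 with a `degenerate`
  flag.
* A single p-value of 1 has Bayesian error rate 1 (the cap); ties in p
  share the smallest downstream q through the step-up minimum.
* `fold_change()` requires strictly positive ratios — pseudocounting is
  the caller's job, and raw zeros are a usage error.
* Motif planting writes copies into equal-width chunks of the target
  flank so planted copies never overlap; planting fails loudly if the
  flank cannot hold them.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` run entirely from the seeded
generator: exhaustive Fisher validation over all 2×2 tables with margins
≤ 30 (~160k tables); null calibration on 2,000 null events × 5 seeds;
recovery of 30 planted switches among 200 genes at depth 200; 500
Monte-Carlo sequences of 1 kb per motif for the chance model; 1,000
randomized reporter constructs. These sizes give stable Monte-Carlo
estimates in a couple of minutes on a laptop.

## Known limitations

Pooling replicates discards biological variance; with more replicates a
GLM with estimated dispersion would be preferable, and the exact test
will be anticonservative for strongly overdispersed real data. The
error-rate estimator is a generic q-value bound, not a fitted mixture
posterior. PSI is an RPKM ratio, not a junction-based estimate, and is
only approximately the inclusion fraction when exon lengths are
misannotated. Motif scanning is pattern counting: no PWM scoring, no
conservation, no SINE annotation.
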