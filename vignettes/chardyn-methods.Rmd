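---
title: "Methods: classifying chromatin-accessible region dynamics across the Th17-to-Th1 conversion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ChAR dynamics across the Th17-to-Th1 conversion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis

Pathogenic Th17 cells — the pro-inflammatory subgroup that drives
autoimmune pathology such as experimental autoimmune encephalomyelitis —
differ from conventional regulatory Th17 not only in transcription but in
chromatin accessibility, and during disease they convert further into
pro-inflammatory Th1 in two steps (regulatory Th17 → pathogenic Th17 →
Th1). `chardyn` implements a desk-scale, fully testable version of the
accessibility analysis of that conversion:

1. **Peak universe.** ATAC-seq peak calls are merged (overlapping or
   book-ended intervals fuse) and regions whose nearest gene is not *truly
   expressed* — TPM > 5 in both replicates of either Th17 state — are
   dropped.
2. **Differential ChARs.** Peak counts are length-normalised to TPM
   (each sample rescaled to 10^6) and regions are called patho-ChARs when
   the pseudocounted fold change between pathogenic and regulatory Th17
   exceeds 2, reg-ChARs below 1/2, common otherwise. No variance model or
   FDR is applied: the upstream analysis uses a bare fold-change rule, and
   we reproduce that deliberately (see *Limitations*).
3. **TSS annotation.** Each region's center is linked to the nearest TSS;
   |distance| ≤ 1 kb is *TSS-proximal* (promoter-like), the rest
   *TSS-distal* (enhancer/suppressor-like).
4. **Conservation.** Length-weighted mean phastCons-style scores are taken
   over each region with absent bases scoring 0 (the `mean0` convention:
   unalignable sequence is effectively unconserved); regions above 0.5 are
   *conserved*.
5. **Expression integration.** Differential ChARs whose linked gene moves
   ≥ 2-fold in the same direction are *concordant*; opposite, *contrary*;
   neither, *irrelevant*.
6. **Temporal dynamics.** For every gene related to a concordant ChAR, all
   of its regions are profiled over the two conversion steps
   (fold changes pathogenic/regulatory and Th1/pathogenic at threshold
   1.5). Regions moving with their gene's expected direction in at least
   one step and never against it are *opening* (patho-related) or
   *closing* (reg-related), with modes up-constant / up-up / constant-up
   and their mirrors; any 1.5-fold step against the expected direction is
   *contrary*, and two constant steps *irrelevant*.
7. **Motif-based TF inference.** Region sequences are scanned with PWMs by
   log2-odds score; motifs with more than 20 hits across opening plus
   closing regions are patho-TFs when the pseudocounted opening:closing
   ratio exceeds 1.5 (reg-TFs below 1/1.5), and patho-TFs are ranked by the
   proportion of their opening-region hits carried by first-step modes.

```{r, eval = FALSE}
library(chardyn)
bundle <- simulate_chardyn(chardyn_config(seed = 1))
run <- run_pipeline(bundle)
run
generics::tidy(run)
plot_step_counts(run$step_counts)
```

## Thresholds and their defaults

| Parameter | Default | Meaning |
|---|---|---|
| `fc_differential` | 2 | ChAR call and expression-concordance threshold (strict `>`) |
| `fc_step` | 1.5 | per-step fold change for dynamics modes (`up` at ≥ 1.5) |
| `tpm_expressed` | 5 TPM | truly-expressed gene filter, strict `>`, both replicates |
| `conservation_cutoff` | 0.5 | conserved-ChAR cutoff, strict `>` |
| `proximal_window` | 1000 bp | TSS-proximal half-window |
| `motif_min_total` | 20 hits | floor for a TF call, strict `>` |
| `motif_ratio` | 1.5 | opening:closing ratio for patho-/reg-TF |
| `pseudocount` | 1 TPM | added to every fold-change numerator and denominator |
| `min_score_frac` | 0.6 | PWM hit threshold as a fraction of the maximal log-odds score |

Choices the underlying method leaves open, decided here once and
documented:

* **Pseudocount.** Zero-denominator handling for fold changes is
  unspecified upstream; we add 1 TPM to both sides of every ratio. It is
  configurable, and at typical signal (tens to hundreds of TPM) it hardly
  moves calls.
* **Fold change on replicate means.** Fold changes compare replicate-mean
  TPM, not per-replicate tests — the method is a fold-change rule, not a
  statistical test.
* **Six accessibility bins.** The six accessibility-difference groups are
  binned on log2 fold change at ±log2(1.5) and ±1, symmetric around zero,
  because 1.5× and 2× are the two thresholds the method uses everywhere
  else; boundaries go to the lower-magnitude bin.
* **Distance from peak center.** TSS distance is measured from the peak
  center (the HOMER-style convention); strand flips only the sign, so
  proximal calls are strand-independent.
* **Strict boundaries.** "Cutoff at 0.5", "more than 20", "fold change
  > 2" are all implemented as strict inequalities.
* **Contrary rule.** "Never show any contrary changes" means any ≥ 1.5-fold
  step against the expected direction makes the region contrary, whatever
  the other step does.
* **Genes related to both classes.** A gene linked to both concordant
  patho- and reg-ChARs joins the side with more concordant ChARs, ties to
  patho.
* **Motif occurrences, not regions.** Every hit is counted (overlapping
  hits of one motif included); `count_by_dynamics()` counts occurrences,
  and a two-step (up-up) region's hits count in both steps.
* **Scan threshold.** No scanning threshold is reported upstream; the
  default is 60% of each PWM's maximal attainable log2-odds score,
  overridable in absolute bits.
* **Similarity subset.** Cross-state Spearman similarity is exposed for any
  region subset; the shipped summary uses concordant patho-ChARs, the
  subset the conversion claim is about.
* **Enrichment inputs.** Gene-set enrichment takes user-supplied GMT sets
  tested against a gene universe; ChAR subsets are mapped to genes through
  the nearest-TSS links. Raw hypergeometric p-values are reported by
  default (Benjamini–Hochberg available as an option).

## What the synthetic generator emulates

`simulate_chardyn()` builds the full study design with planted truth:
three states × two replicates for both ATAC and RNA; 2,000 genes laid out
in private territories on four chromosomes (so peaks of different genes
cannot overlap and nearest-TSS truth is unambiguous); five peaks per gene,
30% proximal; 15% pathogenic-program and 15% regulatory-program genes.

The temporal design mirrors the proximal-first, distal-second conversion
pattern: an effected proximal peak of a patho-program gene opens at step 1
and holds (up-constant), an effected distal peak opens at step 2
(constant-up) or, for 20% of them, in both steps (up-up); regulatory
programs are mirror-imaged with the down modes. Only a fraction
(`effect_frac`, default 0.19) of a program gene's peaks carry the effect:
the collection step preferentially selects genes with more effected peaks,
and 0.19 places the opening+closing share of collected ChARs at roughly a
third, the calibration the analysis expects. Counts are negative binomial
(variance μ + μ²·disp, default dispersion 0.05, baseline mean 100,
log-normal spread across peaks); 70% of program genes get concordant RNA
expression.

Per-region effect sizes are jittered (±0.5 on the log scale around
`open_effect` = 4). This matters beyond realism: with one shared
multiplier, pathogenic and regulatory samples would have *identical ranks*
over uniformly-opened regions, and rank-based similarity could not see the
planted structure at all. Heterogeneous effects give Th1 and pathogenic
Th17 a shared effect-size pattern that regulatory Th17 lacks, which is
exactly the structure the similarity analysis measures. The degenerate
settings `nb_dispersion = 0, effect_jitter = 0` give exact-recovery limits
used by the tests.

Conservation is planted as stepwise tracks with interval means in
[0.7, 1] for conserved regions and [0, 0.3] otherwise; motif consensus
strings (never PWM samples) are inserted at rate 0.5 into regions whose
planted mode matches the motif's role — `TF_early` into up-constant,
`TF_late` into constant-up, `TF_open`/`TF_close` into any opening/closing
mode — and at rate 0.02 elsewhere. The synthetic PWMs are sharp
(0.985 consensus probability, width 10) so the 60% scan threshold admits
essentially only consensus occurrences and planted instances are
recoverable exactly.

**What it does not emulate:** read-level artefacts (GC and fragment-length
bias, duplicates), overlapping regulatory domains of neighbouring genes,
correlated replicate noise, realistic motif degeneracy, or linkage between
conservation and function. Passing planted-truth tests therefore shows the
*rules* are implemented correctly at study scale, not that the biological
conclusions would replicate on real sequencing data.

## Numerical choices

* Coordinates are 0-based half-open throughout; readers reject rather than
  repair malformed input, naming the offending line.
* TPM columns sum to 10^6 to a relative 10^-6; all-zero samples are an
  error rather than a silent NaN.
* Spearman uses average ranks; a constant sample over the chosen subset is
  an error (undefined correlation).
* Mann–Whitney U switches from exact enumeration (valid under ties) to a
  tie-corrected normal approximation above a combined n of 20, with p = 1
  when every value is identical.
* The hypergeometric tail comes from `stats::phyper` (stable tail
  summation); k = 0 gives p = 1.
* PWM scanning scores N bases as 0 bits; minus-strand windows are scored on
  the reverse complement and reported at the window's leftmost forward
  offset. Ties in TF ranking break lexicographically by motif id.
* Test and example problem sizes: module tests run a 300-gene cohort
  (~1,500 peaks); study-scale checks (recovery, calibration, qualitative
  patterns) run the default 2,000-gene, ~10,000-peak cohort, which
  completes in about a minute.

## Limitations

* Differential accessibility is a bare fold-change rule by design; regions
  near the threshold are sensitive to noise and no error control is
  attached. Anyone needing inference should run a count model (e.g. a
  negative-binomial GLM) alongside.
* Nearest-TSS assignment links each region to exactly one gene; regions in
  dense loci may be mis-assigned, and the synthetic territories deliberately
  avoid that regime rather than model it.
* Conservation input is a bedGraph track, not bigWig; convert upstream.
* The proportion and ordering checks on synthetic data validate the
  pipeline's mechanics under the planted design, not effect sizes in any
  real dataset.
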