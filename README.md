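# chardyn

Chromatin-accessible region (ChAR) dynamics across the two-step
regulatory Th17 → pathogenic Th17 → pro-inflammatory Th1 conversion.

Pathogenic Th17 cells drive autoimmune disease and eventually convert to
pro-inflammatory Th1. `chardyn` is an R toolkit for the ATAC-seq side of
that story: given peak calls, a region-by-sample count matrix, RNA-seq
TPM, a TSS annotation, a conservation track, region sequences and motifs,
it classifies every accessible region and reconstructs *when* (which
conversion step) and *where* (TSS-proximal vs TSS-distal) chromatin opens
or closes. A synthetic-data generator with planted ground truth makes the
whole pipeline testable without any sequencing data.

## The method

With replicate-mean accessibility `a_s(r)` of region `r` in state
`s ∈ {regTh17, pathoTh17, Th1}` (peak-level TPM, pseudocount 1):

* **Differential ChARs** — `FC(r) = (a_patho + 1) / (a_reg + 1)`;
  `FC > 2` ⇒ patho-ChAR, `FC < 1/2` ⇒ reg-ChAR, else common. The peak
  universe is first restricted to regions whose nearest gene has
  TPM > 5 in both replicates of either Th17 state.
* **Location** — regions link to the nearest TSS by center distance;
  |d| ≤ 1 kb is proximal.
* **Conservation** — length-weighted mean base score (absent bases = 0);
  mean > 0.5 ⇒ conserved.
* **Concordance** — a differential ChAR whose linked gene also moves
  ≥ 2-fold in the same direction is concordant.
* **Dynamics** — over the two steps `FC1 = patho/reg`, `FC2 = Th1/patho`
  at threshold 1.5: regions of concordant-ChAR-related genes are
  *opening*/*closing* (≥ 1 concordant step, no contrary step) with modes
  `up-constant`, `up-up`, `constant-up` (and mirrored `down` modes),
  *contrary*, or *irrelevant*.
* **patho-TFs / reg-TFs** — PWM log-odds hits are counted in opening vs
  closing regions; motifs with > 20 total hits and
  `(n_open + 1)/(n_close + 1) > 1.5` are patho-TFs (< 1/1.5 reg-TFs),
  ranked by the share of their opening hits in first-step modes.

Supporting statistics: two-sided Mann–Whitney U, Spearman correlation,
and upper-tail hypergeometric gene-set enrichment (GMT input).

## Worked example

```r
library(chardyn)

bundle <- simulate_chardyn(chardyn_config(seed = 1))  # 2,000 genes, 10,000 peaks
run <- run_pipeline(bundle)
run
```

```
<chardyn_run>
  universe: 10000 regions, 2000 expressed genes
  ChARs: common=9687, patho-ChAR=175, reg-ChAR=138
  dynamics: closing=155, contrary=69, irrelevant=398, opening=118
  TF calls: neither=2, patho-TF=3, reg-TF=1
```

About 3% of regions are called differential (the planted program genes'
step-1 peaks), and among the 740 ChARs collected around
concordant-ChAR-related genes roughly a third open or close across the
conversion — opening for pathogenic-program genes, closing for
regulatory-program genes.

```r
run$summary$step_counts
```

```
  direction step location n_genes
1   opening  1st proximal      46
2   opening  1st   distal      32
3   opening  2nd proximal       2
4   opening  2nd   distal      44
```

The planted pattern is the headline result: opening regions change
proximally at the first step (46 genes vs 2) and distally at the second
(44 vs 32) — chromatin opens promoter-first, enhancer-second.

```r
run$patho_rank[, c("motif_id", "ratio", "step1_proportion")]
```

```
  motif_id     ratio step1_proportion
1 TF_early  4.285714        0.9333333
2  TF_open 11.600000        0.5342466
3  TF_late  6.000000        0.3076923
```

The motif planted in first-step regions ranks top, the second-step motif
last; their opening-region hits are 93% vs 22% TSS-proximal. `tidy(run)`
returns the whole summary as a long tibble; `glance(run)` a one-row
overview; `plot_step_counts()`, `plot_tss_distance()`, `plot_fc_bins()`
and `plot_tf_ranking()` draw the corresponding panels.

See `vignettes/chardyn-methods.Rmd` for the model, every threshold, and
what the synthetic generator does and does not emulate.

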