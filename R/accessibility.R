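#' Merge peak sets into a non-redundant peak universe
#'
#' Takes any number of peak tables and merges overlapping or book-ended
#' (adjacent) intervals into single regions, the standard consensus-peak
#' construction. Region ids are assigned as `chrom:start-end`.
#'
#' @param peak_sets A list of interval tibbles (`chrom`, `start`, `end`,
#'   0-based half-open), or a single tibble.
#' @return Tibble `chrom`, `start`, `end`, `name` sorted by (chrom, start),
#'   with pairwise non-overlapping intervals.
#' @export
merge_peak_sets <- function(peak_sets) {
  if (is.data.frame(peak_sets)) peak_sets <- list(peak_sets)
  all <- bind_rows(lapply(peak_sets, function(p) {
    as_tibble(p)[, c("chrom", "start", "end")]
  }))
  if (nrow(all) == 0L) {
    return(tibble(chrom = character(), start = double(), end = double(),
                  name = character()))
  }
  if (any(all$start < 0 | all$start >= all$end)) {
    abort("interval error: need 0 <= start < end")
  }
  merged <- all |>
    group_by(.data$chrom) |>
    group_modify(function(d, key) {
      ir <- IRanges::reduce(IRanges::IRanges(d$start + 1, d$end))
      tibble(start = IRanges::start(ir) - 1, end = as.numeric(IRanges::end(ir)))
    }) |>
    ungroup() |>
    arrange(.data$chrom, .data$start)
  merged$name <- region_id(merged)
  merged
}

#' Truly expressed genes under the two-replicate TPM rule
#'
#' A gene is kept when its TPM exceeds the threshold in every replicate of
#' regulatory Th17 or in every replicate of pathogenic Th17 (strict
#' inequality).
#'
#' @param rna_tpm Gene-by-sample TPM matrix tibble (first column
#'   `feature_id`).
#' @param design Sample design covering the matrix columns.
#' @param threshold TPM threshold (default 5).
#' @return Character vector of expressed gene ids.
#' @export
expressed_genes <- function(rna_tpm, design, threshold = 5) {
  design <- validate_design(design)
  vals <- matrix_values(rna_tpm)
  passes <- lapply(c("regTh17", "pathoTh17"), function(st) {
    cols <- design$sample_id[design$state == st]
    if (length(cols) < 2L) {
      abort(sprintf(
        "configuration error: state %s has %d replicate(s); the both-repeats rule needs >= 2",
        st, length(cols)))
    }
    if (!all(cols %in% colnames(vals))) {
      abort(sprintf("configuration error: design sample(s) missing from matrix: %s",
                    paste(setdiff(cols, colnames(vals)), collapse = ", ")))
    }
    apply(vals[, cols, drop = FALSE] > threshold, 1L, all)
  })
  rna_tpm$feature_id[passes[[1]] | passes[[2]]]
}

#' Filter a peak universe to regions linked to expressed genes
#'
#' @param universe Peak universe tibble (with `name`).
#' @param links Region-to-gene links from [annotate_nearest_tss()].
#' @param expressed Character vector of expressed gene ids.
#' @return The universe restricted to regions whose nearest gene is
#'   expressed; region ids preserved.
#' @export
filter_universe <- function(universe, links, expressed) {
  miss <- setdiff(universe$name, links$region_id)
  if (length(miss) > 0L) {
    abort(sprintf("link error: %d region(s) lack a nearest-gene link (e.g. %s)",
                  length(miss), miss[1]))
  }
  keep <- links$region_id[links$gene_id %in% expressed]
  universe |> filter(.data$name %in% keep)
}

#' Length-normalised TPM for peak-level counts
#'
#' Per sample, each count is divided by its region width and the resulting
#' rates are rescaled to sum to one million.
#'
#' @param counts Region-by-sample count matrix tibble.
#' @param universe Peak universe supplying region widths (rows must match
#'   `counts$feature_id`).
#' @return TPM matrix tibble; every column sums to 1e6.
#' @export
peak_tpm <- function(counts, universe) {
  widths <- setNames(universe$end - universe$start, universe$name)
  miss <- setdiff(counts$feature_id, names(widths))
  if (length(miss) > 0L) {
    abort(sprintf("universe error: no width for region %s", miss[1]))
  }
  tpm_normalise(counts, widths[counts$feature_id])
}

tpm_normalise <- function(counts, widths) {
  vals <- matrix_values(counts)
  if (any(widths <= 0)) abort("universe error: non-positive region width")
  rate <- vals / widths
  cs <- colSums(rate)
  if (any(cs == 0)) {
    abort(sprintf("normalisation error: sample %s has all-zero counts",
                  colnames(vals)[cs == 0][1]))
  }
  tpm <- sweep(rate, 2L, cs, "/") * 1e6
  bind_cols(tibble(feature_id = counts$feature_id),
            as_tibble(as.data.frame(tpm)))
}

#' Replicate-mean signal per state
#'
#' @param tpm Feature-by-sample matrix tibble.
#' @param design Sample design mapping columns to states.
#' @return Tibble `feature_id` plus one column per state holding the
#'   arithmetic mean over that state's replicates.
#' @export
state_means <- function(tpm, design) {
  design <- validate_design(design)
  vals <- matrix_values(tpm)
  sts <- unique(design$state)
  means <- vapply(sts, function(st) {
    cols <- design$sample_id[design$state == st]
    rowMeans(vals[, cols, drop = FALSE])
  }, numeric(nrow(vals)))
  if (nrow(vals) == 1L) means <- matrix(means, nrow = 1, dimnames = list(NULL, sts))
  bind_cols(tibble(feature_id = tpm$feature_id),
            as_tibble(as.data.frame(means)))
}

#' Call differential ChARs by fold change between the two Th17 states
#'
#' The fold change is `(mean pathoTh17 + pseudocount) / (mean regTh17 +
#' pseudocount)`. Regions with fold change strictly above the threshold are
#' patho-ChARs, strictly below its reciprocal reg-ChARs, all others common.
#'
#' @param means State-mean tibble from [state_means()] with `regTh17` and
#'   `pathoTh17` columns.
#' @param fc_threshold Fold-change threshold (default 2).
#' @param pseudocount Added to numerator and denominator (default 1 TPM).
#' @return Tibble `region_id`, `fc`, `label` with `label` in
#'   patho-ChAR / reg-ChAR / common.
#' @export
call_chars <- function(means, fc_threshold = 2, pseudocount = 1) {
  stopifnot(all(c("regTh17", "pathoTh17") %in% names(means)))
  if (any(means$regTh17 < 0 | means$pathoTh17 < 0)) {
    abort("value error: negative state means")
  }
  fc <- (means$pathoTh17 + pseudocount) / (means$regTh17 + pseudocount)
  tibble(region_id = means$feature_id, fc = fc,
         label = case_when(fc > fc_threshold ~ "patho-ChAR",
                           fc < 1 / fc_threshold ~ "reg-ChAR",
                           TRUE ~ "common"))
}

#' Bin regions into six accessibility-difference groups
#'
#' Bins are on the log2 fold change between pathogenic and regulatory Th17,
#' symmetric around zero at the 1.5-fold and 2-fold thresholds:
#' `(-Inf,-1], (-1,-log2 1.5], (-log2 1.5, 0], (0, log2 1.5], (log2 1.5, 1],
#' (1, Inf)`, i.e. >2-fold down, 1.5-2-fold down, <1.5-fold down, <1.5-fold
#' up, 1.5-2-fold up, >2-fold up. Boundaries go to the lower-magnitude bin.
#'
#' @param chars Output of [call_chars()] (uses the `fc` column).
#' @return `chars` with an integer `bin` column in 1..6.
#' @export
bin_by_fc <- function(chars) {
  breaks <- c(-Inf, -1, -log2(1.5), 0, log2(1.5), 1, Inf)
  chars |>
    mutate(bin = as.integer(cut(log2(.data$fc), breaks = breaks,
                                labels = FALSE, right = TRUE)))
}
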