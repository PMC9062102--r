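#' Annotate regions to their nearest transcription start site
#'
#' The peak center (`floor((start + end) / 2)`) is linked to the gene whose
#' TSS minimises the absolute distance on the same chromosome. The signed
#' distance is center minus TSS, with the sign flipped on minus-strand genes
#' so that positive always means downstream of the TSS. Equidistant genes
#' resolve to the lexicographically smallest gene id.
#'
#' @param universe Peak universe tibble (`chrom`, `start`, `end`, `name`).
#' @param genes Gene annotation tibble (`gene_id`, `chrom`, `tss`, `strand`).
#' @param proximal_window Half-width in bp of the TSS-proximal window
#'   (default 1000, i.e. +/-1 kb).
#' @param on_missing_chrom `"error"` (default) aborts when a region sits on a
#'   chromosome without genes; `"drop"` drops such regions with a warning.
#' @return Tibble `region_id`, `gene_id`, `signed_distance`, `proximal`.
#' @export
annotate_nearest_tss <- function(universe, genes, proximal_window = 1000,
                                 on_missing_chrom = c("error", "drop")) {
  on_missing_chrom <- match.arg(on_missing_chrom)
  orphan <- setdiff(unique(universe$chrom), unique(genes$chrom))
  if (length(orphan) > 0L) {
    if (on_missing_chrom == "error") {
      abort(sprintf("unlinked error: no gene on chromosome %s", orphan[1]))
    }
    warn(sprintf("dropping %d region(s) on gene-less chromosome(s): %s",
                 sum(universe$chrom %in% orphan),
                 paste(orphan, collapse = ", ")))
    universe <- universe |> filter(!.data$chrom %in% orphan)
  }
  out <- universe |>
    mutate(center = floor((.data$start + .data$end) / 2)) |>
    group_by(.data$chrom) |>
    group_modify(function(d, key) {
      g <- genes |>
        filter(.data$chrom == key$chrom) |>
        arrange(.data$tss, .data$gene_id) |>
        # for co-located TSSs only the smallest gene id can win a tie
        distinct(.data$tss, .keep_all = TRUE)
      j <- findInterval(d$center, g$tss)
      lo <- pmax(j, 1L)
      hi <- pmin(j + 1L, nrow(g))
      d_lo <- abs(d$center - g$tss[lo])
      d_hi <- abs(d$center - g$tss[hi])
      pick_lo <- (j >= 1L) &
        (d_lo < d_hi | (d_lo == d_hi & g$gene_id[lo] <= g$gene_id[hi]) |
           j >= nrow(g))
      idx <- ifelse(pick_lo, lo, hi)
      tibble(region_id = d$name,
             gene_id = g$gene_id[idx],
             signed_distance = (d$center - g$tss[idx]) *
               ifelse(g$strand[idx] == "-", -1, 1))
    }) |>
    ungroup() |>
    select(-"chrom") |>
    mutate(proximal = abs(.data$signed_distance) <= proximal_window)
  # restore universe order
  out[match(intersect(universe$name, out$region_id), out$region_id), ]
}

#' TSS-distance histogram and proximal percentage for a region subset
#'
#' @param links Links from [annotate_nearest_tss()].
#' @param subset Region ids to profile; default all linked regions.
#' @param binwidth Histogram bin width in bp (default 500).
#' @param span Histogram half-range in bp (default 50000).
#' @return A list: `histogram` (tibble `bin_start`, `bin_end`, `count`) and
#'   `proximal_pct` (percentage, exact division).
#' @export
proximal_profile <- function(links, subset = NULL, binwidth = 500,
                             span = 50000) {
  d <- if (is.null(subset)) links else links |>
    filter(.data$region_id %in% subset)
  if (nrow(d) == 0L) {
    abort("undefined-percentage error: empty region subset")
  }
  breaks <- seq(-span, span, by = binwidth)
  x <- pmin(pmax(d$signed_distance, -span), span - 1)
  cnt <- table(cut(x, breaks = breaks, right = FALSE))
  list(histogram = tibble(bin_start = breaks[-length(breaks)],
                          bin_end = breaks[-1],
                          count = as.integer(cnt)),
       proximal_pct = 100 * sum(d$proximal) / nrow(d))
}

#' Length-weighted mean conservation over regions
#'
#' Computes, for each region, the mean of the base-level conservation track
#' over all bases of the region, with bases absent from the track scoring 0
#' (the `mean0` convention of bigWigAverageOverBed, appropriate because
#' phastCons gaps denote unalignable, effectively unconserved sequence).
#'
#' @param regions Interval tibble (`chrom`, `start`, `end`, `name`).
#' @param track Sorted, non-overlapping conservation track
#'   (`chrom`, `start`, `end`, `score`).
#' @return Numeric vector of mean scores, one per region, named by region id.
#' @export
interval_mean_conservation <- function(regions, track) {
  out <- numeric(nrow(regions))
  names(out) <- regions$name
  for (ch in unique(regions$chrom)) {
    ri <- which(regions$chrom == ch)
    tr <- track |> filter(.data$chrom == ch)
    if (nrow(tr) == 0L) next
    rr <- IRanges::IRanges(regions$start[ri] + 1, regions$end[ri])
    tt <- IRanges::IRanges(tr$start + 1, tr$end)
    hits <- IRanges::findOverlaps(rr, tt)
    if (length(hits) == 0L) next
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    ov <- IRanges::width(IRanges::pintersect(rr[qi], tt[si]))
    contrib <- tapply(ov * tr$score[si], qi, sum)
    out[ri[as.integer(names(contrib))]] <-
      contrib / IRanges::width(rr)[as.integer(names(contrib))]
  }
  out
}

#' Flag conserved regions by mean conservation score
#'
#' A region is conserved when its length-weighted mean score strictly
#' exceeds the cutoff.
#'
#' @param regions Interval tibble with `name`.
#' @param track Conservation track.
#' @param cutoff Conservation cutoff (default 0.5, strict `>`).
#' @return Tibble `region_id`, `mean_score`, `conserved`.
#' @export
conserved_filter <- function(regions, track, cutoff = 0.5) {
  sc <- interval_mean_conservation(regions, track)
  tibble(region_id = regions$name, mean_score = unname(sc),
         conserved = unname(sc) > cutoff)
}

#' Expression-correlation category of differential ChARs
#'
#' A differential ChAR is positively correlated when its linked gene's
#' expression fold change exceeds the threshold in the same direction as the
#' chromatin change, negatively correlated when it exceeds the threshold in
#' the opposite direction, and irrelevant otherwise.
#'
#' @param chars Output of [call_chars()]; only differential rows (patho-ChAR
#'   or reg-ChAR) are accepted.
#' @param gene_fc Named numeric vector of pathoTh17-vs-regTh17 gene
#'   expression fold changes, one per region id in `chars` (pseudocount
#'   already applied).
#' @param fc_threshold Fold-change threshold (default 2, strict).
#' @return Tibble `region_id`, `category` in positive / negative /
#'   irrelevant.
#' @export
correlation_category <- function(chars, gene_fc, fc_threshold = 2) {
  if (any(chars$label == "common")) {
    abort("domain error: correlation categories are defined only for differential ChARs")
  }
  fc <- gene_fc[chars$region_id]
  if (any(is.na(fc))) {
    abort(sprintf("missing gene expression fold change for region %s",
                  chars$region_id[is.na(fc)][1]))
  }
  up <- fc > fc_threshold
  down <- fc < 1 / fc_threshold
  tibble(region_id = chars$region_id,
         category = case_when(
           chars$label == "patho-ChAR" & up ~ "positive",
           chars$label == "patho-ChAR" & down ~ "negative",
           chars$label == "reg-ChAR" & down ~ "positive",
           chars$label == "reg-ChAR" & up ~ "negative",
           TRUE ~ "irrelevant"))
}
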