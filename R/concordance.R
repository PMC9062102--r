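#' Classify differential ChARs as expression-concordant or unconcordant
#'
#' A differential ChAR is concordant when its linked gene's expression fold
#' change (pathogenic vs regulatory Th17, with pseudocount) exceeds the
#' threshold in the same direction as the chromatin change; for reg-ChARs
#' concordance therefore means higher expression in regulatory Th17.
#' Unconcordant ChARs split into `contrary` (opposite direction beyond the
#' threshold) and `irrelevant` (within the threshold band).
#'
#' @param chars Output of [call_chars()]; rows with label `common` are
#'   ignored.
#' @param links Region-to-gene links from [annotate_nearest_tss()].
#' @param gene_means Gene-level state means from [state_means()] with
#'   `regTh17` and `pathoTh17` columns.
#' @param fc_threshold Expression fold-change threshold (default 2, strict).
#' @param pseudocount Added to both means (default 1).
#' @return Tibble `region_id`, `gene_id`, `char_label`, `gene_fc`, `label`
#'   (concordant / unconcordant), `sublabel` (`NA` / irrelevant / contrary).
#' @export
classify_concordance <- function(chars, links, gene_means, fc_threshold = 2,
                                 pseudocount = 1) {
  diff <- chars |> filter(.data$label != "common")
  d <- diff |>
    left_join(links |> select("region_id", "gene_id"), by = "region_id")
  if (any(is.na(d$gene_id))) {
    abort(sprintf("link error: differential ChAR without a gene link: %s",
                  paste(utils::head(d$region_id[is.na(d$gene_id)], 5),
                        collapse = ", ")))
  }
  gm <- gene_means |>
    mutate(gene_fc = (.data$pathoTh17 + pseudocount) /
             (.data$regTh17 + pseudocount)) |>
    select(gene_id = "feature_id", "gene_fc")
  d <- d |> left_join(gm, by = "gene_id")
  if (any(is.na(d$gene_fc))) {
    abort(sprintf("missing gene expression for region(s): %s",
                  paste(utils::head(d$region_id[is.na(d$gene_fc)], 5),
                        collapse = ", ")))
  }
  d |>
    mutate(
      same = (.data$label == "patho-ChAR" & .data$gene_fc > fc_threshold) |
        (.data$label == "reg-ChAR" & .data$gene_fc < 1 / fc_threshold),
      opposite = (.data$label == "patho-ChAR" & .data$gene_fc < 1 / fc_threshold) |
        (.data$label == "reg-ChAR" & .data$gene_fc > fc_threshold),
      char_label = .data$label,
      label = if_else(.data$same, "concordant", "unconcordant"),
      sublabel = case_when(.data$same ~ NA_character_,
                           .data$opposite ~ "contrary",
                           TRUE ~ "irrelevant")) |>
    select("region_id", "gene_id", "char_label", "gene_fc", "label",
           "sublabel")
}

#' Pairwise Spearman similarity between samples over a region subset
#'
#' @param tpm Region-by-sample TPM matrix tibble.
#' @param subset Region ids to restrict to (>= 3 required).
#' @param design Optional design used only to order columns state-by-state.
#' @return Symmetric matrix of Spearman rho between all sample pairs
#'   (diagonal 1), ties handled by average ranks.
#' @export
state_similarity <- function(tpm, subset, design = NULL) {
  d <- tpm |> filter(.data$feature_id %in% subset)
  if (nrow(d) < 3L) {
    abort("similarity error: need at least 3 regions in the subset")
  }
  vals <- matrix_values(d)
  if (!is.null(design)) {
    design <- validate_design(design)
    vals <- vals[, design$sample_id, drop = FALSE]
  }
  if (any(apply(vals, 2L, function(x) length(unique(x)) == 1L))) {
    abort("undefined-correlation error: a sample is constant over the subset")
  }
  stats::cor(vals, method = "spearman")
}

#' Mean similarity of Th1 samples to each Th17 state
#'
#' Convenience summary of [state_similarity()]: the average Spearman rho of
#' every Th1 sample against the samples of each Th17 state.
#'
#' @inheritParams state_similarity
#' @param design Sample design (required here).
#' @return Tibble `state`, `mean_rho`.
#' @export
th1_similarity <- function(tpm, subset, design) {
  design <- validate_design(design)
  s <- state_similarity(tpm, subset)
  th1 <- design$sample_id[design$state == "Th1"]
  purrr::map_dfr(c("regTh17", "pathoTh17"), function(st) {
    cols <- design$sample_id[design$state == st]
    tibble(state = st, mean_rho = mean(s[th1, cols]))
  })
}
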