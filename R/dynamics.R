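#' Collect all ChARs of concordant-ChAR-related genes
#'
#' Genes linked to at least one concordant patho-ChAR form the patho-related
#' gene set (expected direction: opening); genes linked to a concordant
#' reg-ChAR form the reg-related set (closing). A gene qualifying for both
#' is assigned to the set with more concordant ChARs, ties to patho. For
#' every related gene, ALL universe regions linked to it are collected, not
#' just the differential ones.
#'
#' @param concordance Output of [classify_concordance()].
#' @param links Region-to-gene links covering the universe.
#' @return Tibble `gene_id`, `expected_direction` (opening / closing),
#'   `region_id` — one row per collected ChAR.
#' @export
collect_related_chars <- function(concordance, links) {
  conc <- concordance |> filter(.data$label == "concordant")
  per_gene <- conc |>
    dplyr::count(.data$gene_id, .data$char_label) |>
    tidyr::pivot_wider(names_from = "char_label", values_from = "n",
                       values_fill = 0L)
  for (col in c("patho-ChAR", "reg-ChAR")) {
    if (!col %in% names(per_gene)) per_gene[[col]] <- 0L
  }
  gene_dir <- per_gene |>
    mutate(expected_direction = if_else(
      .data$`patho-ChAR` >= .data$`reg-ChAR`, "opening", "closing")) |>
    select("gene_id", "expected_direction")
  links |>
    inner_join(gene_dir, by = "gene_id") |>
    select("gene_id", "expected_direction", "region_id")
}

#' Classify temporal accessibility dynamics over the two conversion steps
#'
#' Step fold changes are `fc1 = pathoTh17 / regTh17` and
#' `fc2 = Th1 / pathoTh17` on pseudocounted state means. A step is `up` when
#' its fold change is at least the step threshold, `down` when at most its
#' reciprocal, `constant` otherwise. A region whose expected direction is
#' opening is classed `contrary` if any step goes down, `opening` if at
#' least one step goes up and none down, and `irrelevant` when both steps
#' are constant; closing mirrors this. Opening regions receive a mode
#' (up-constant / up-up / constant-up) from their step pattern, closing
#' regions the mirrored down modes.
#'
#' @param collected Output of [collect_related_chars()].
#' @param means Region state means from [state_means()] with `regTh17`,
#'   `pathoTh17` and `Th1` columns.
#' @param step_threshold Step fold-change threshold (default 1.5).
#' @param pseudocount Added to all means (default 1).
#' @return Tibble `region_id`, `gene_id`, `expected_direction`, `fc1`,
#'   `fc2`, `step1`, `step2`, `klass`, `mode`.
#' @export
classify_dynamics <- function(collected, means, step_threshold = 1.5,
                              pseudocount = 1) {
  stopifnot(all(c("regTh17", "pathoTh17", "Th1") %in% names(means)))
  d <- collected |>
    inner_join(means, by = c(region_id = "feature_id")) |>
    mutate(
      fc1 = (.data$pathoTh17 + pseudocount) / (.data$regTh17 + pseudocount),
      fc2 = (.data$Th1 + pseudocount) / (.data$pathoTh17 + pseudocount),
      step1 = step_call(.data$fc1, step_threshold),
      step2 = step_call(.data$fc2, step_threshold))
  d |>
    mutate(
      n_up = (.data$step1 == "up") + (.data$step2 == "up"),
      n_down = (.data$step1 == "down") + (.data$step2 == "down"),
      klass = case_when(
        .data$expected_direction == "opening" & .data$n_down > 0 ~ "contrary",
        .data$expected_direction == "opening" & .data$n_up > 0 ~ "opening",
        .data$expected_direction == "closing" & .data$n_up > 0 ~ "contrary",
        .data$expected_direction == "closing" & .data$n_down > 0 ~ "closing",
        TRUE ~ "irrelevant"),
      mode = case_when(
        .data$klass == "opening" & .data$step1 == "up" & .data$step2 == "up" ~ "up-up",
        .data$klass == "opening" & .data$step1 == "up" ~ "up-constant",
        .data$klass == "opening" ~ "constant-up",
        .data$klass == "closing" & .data$step1 == "down" & .data$step2 == "down" ~ "down-down",
        .data$klass == "closing" & .data$step1 == "down" ~ "down-constant",
        .data$klass == "closing" ~ "constant-down",
        TRUE ~ "none")) |>
    select("region_id", "gene_id", "expected_direction", "fc1", "fc2",
           "step1", "step2", "klass", "mode")
}

step_call <- function(fc, threshold) {
  case_when(fc >= threshold ~ "up",
            fc <= 1 / threshold ~ "down",
            TRUE ~ "constant")
}

#' TSS-proximal percentage of regions carrying a given dynamics mode
#'
#' @param labels Output of [classify_dynamics()].
#' @param links Region-to-gene links (for the proximal flag).
#' @param mode One of the six modes.
#' @return Proximal percentage (exact division).
#' @export
mode_tss_profile <- function(labels, links, mode) {
  ids <- labels$region_id[labels$mode == mode]
  if (length(ids) == 0L) {
    abort(sprintf("undefined-percentage error: no region carries mode '%s'", mode))
  }
  proximal_profile(links, subset = ids)$proximal_pct
}

#' Count genes whose opening/closing ChARs change at each step and location
#'
#' A gene counts in a (step, location) cell when at least one of its
#' opening (resp. closing) ChARs at that location changes at that step:
#' step 1 covers the up-constant and up-up (down-constant, down-down)
#' modes, step 2 the constant-up and up-up (constant-down, down-down)
#' modes. A region with a two-step mode therefore counts its gene in both
#' steps.
#'
#' @param labels Output of [classify_dynamics()].
#' @param links Region-to-gene links (for the proximal flag).
#' @return Tibble `direction` (opening / closing), `step` (1st / 2nd),
#'   `location` (proximal / distal), `n_genes` — 8 rows.
#' @export
count_gene_step_changes <- function(labels, links) {
  d <- labels |>
    filter(.data$klass %in% c("opening", "closing")) |>
    left_join(links |> select("region_id", "proximal"), by = "region_id") |>
    mutate(location = if_else(.data$proximal, "proximal", "distal"),
           step1_hit = .data$mode %in% c("up-constant", "up-up",
                                         "down-constant", "down-down"),
           step2_hit = .data$mode %in% c("constant-up", "up-up",
                                         "constant-down", "down-down"))
  cells <- tidyr::expand_grid(direction = c("opening", "closing"),
                              step = c("1st", "2nd"),
                              location = c("proximal", "distal"))
  counts <- bind_rows(
    d |> filter(.data$step1_hit) |>
      distinct(.data$klass, .data$location, .data$gene_id) |>
      dplyr::count(direction = .data$klass, .data$location) |>
      mutate(step = "1st"),
    d |> filter(.data$step2_hit) |>
      distinct(.data$klass, .data$location, .data$gene_id) |>
      dplyr::count(direction = .data$klass, .data$location) |>
      mutate(step = "2nd"))
  cells |>
    left_join(counts, by = c("direction", "step", "location")) |>
    mutate(n_genes = dplyr::coalesce(.data$n, 0L)) |>
    select("direction", "step", "location", "n_genes")
}
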