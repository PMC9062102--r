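#' Load pipeline inputs from a directory of plain-text files
#'
#' Reads the file layout written by [write_chardyn_bundle()]: `peaks.bed`,
#' `atac_counts.tsv`, `rna_tpm.tsv`, `genes.tsv`, `conservation.bedGraph`,
#' `regions.fasta`, `motifs.meme`, `design_atac.tsv`, `design_rna.tsv`.
#'
#' @param dir Directory containing the inputs.
#' @return A named list compatible with [run_pipeline()].
#' @export
load_chardyn_inputs <- function(dir) {
  fp <- function(x) file.path(dir, x)
  list(peaks = read_bed(fp("peaks.bed")),
       atac_counts = read_matrix(fp("atac_counts.tsv")),
       rna_tpm = read_matrix(fp("rna_tpm.tsv")),
       genes = readr::read_tsv(fp("genes.tsv"), show_col_types = FALSE,
                               progress = FALSE),
       track = read_bedgraph(fp("conservation.bedGraph")),
       sequences = read_fasta(fp("regions.fasta")),
       pwms = read_meme(fp("motifs.meme")),
       design_atac = read_design(fp("design_atac.tsv")),
       design_rna = read_design(fp("design_rna.tsv")))
}

#' Run the full ChAR dynamics analysis
#'
#' Orchestrates the whole pipeline: peak-universe construction,
#' expression filtering, peak TPM normalisation, differential ChAR calling,
#' TSS annotation, conservation filtering, expression-correlation
#' categories, concordance classification, cross-state similarity, temporal
#' dynamics over the two conversion steps, and motif-based TF
#' classification.
#'
#' @param inputs A list as returned by [simulate_chardyn()] or
#'   [load_chardyn_inputs()]: `peaks`, `atac_counts`, `rna_tpm`, `genes`,
#'   `track`, `sequences`, `pwms`, `design_atac`, `design_rna`.
#' @param fc_differential Fold-change threshold for differential ChARs
#'   (default 2).
#' @param fc_step Step fold-change threshold for dynamics (default 1.5).
#' @param tpm_expressed TPM threshold for truly expressed genes (default 5).
#' @param conservation_cutoff Conserved-ChAR cutoff (default 0.5).
#' @param proximal_window TSS-proximal half-window in bp (default 1000).
#' @param motif_min_total Minimum motif hits for a TF call (default 20).
#' @param motif_ratio Opening:closing ratio threshold (default 1.5).
#' @param pseudocount Pseudocount for every fold change (default 1 TPM).
#' @param min_score_frac PWM scan threshold as fraction of max score
#'   (default 0.6).
#' @param verbose Log per-stage row counts to stderr (default FALSE).
#' @return A `chardyn_run` object; see Details. Inspect with `print()`,
#'   [generics::tidy()] and [generics::glance()].
#' @details The returned object carries `universe`, `links`, `expressed`,
#'   `atac_tpm`, `atac_means`, `chars` (with fold-change bins),
#'   `conservation`, `categories`, `concordance`, `similarity`,
#'   `collected`, `dynamics`, `step_counts`, `mode_profiles`, `hits`,
#'   `tf_classes`, `patho_rank`, and a `summary` list of report tables.
#' @export
run_pipeline <- function(inputs,
                         fc_differential = 2,
                         fc_step = 1.5,
                         tpm_expressed = 5,
                         conservation_cutoff = 0.5,
                         proximal_window = 1000,
                         motif_min_total = 20,
                         motif_ratio = 1.5,
                         pseudocount = 1,
                         min_score_frac = 0.6,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))

  universe <- merge_peak_sets(list(inputs$peaks))
  say("universe: %d regions", nrow(universe))
  links <- annotate_nearest_tss(universe, inputs$genes, proximal_window)
  expressed <- expressed_genes(inputs$rna_tpm, inputs$design_rna,
                               tpm_expressed)
  say("expressed genes: %d / %d", length(expressed), nrow(inputs$rna_tpm))
  universe <- filter_universe(universe, links, expressed)
  links <- links |> filter(.data$region_id %in% universe$name)
  say("filtered universe: %d regions", nrow(universe))

  counts <- inputs$atac_counts |>
    filter(.data$feature_id %in% universe$name)
  atac_tpm <- peak_tpm(counts, universe)
  atac_means <- state_means(atac_tpm, inputs$design_atac)
  chars <- call_chars(atac_means, fc_differential, pseudocount) |>
    bin_by_fc()
  say("ChARs: %d patho / %d reg / %d common",
      sum(chars$label == "patho-ChAR"), sum(chars$label == "reg-ChAR"),
      sum(chars$label == "common"))

  conservation <- conserved_filter(universe, inputs$track,
                                   conservation_cutoff)
  rna_means <- state_means(inputs$rna_tpm, inputs$design_rna)
  gene_fc_vec <- setNames((rna_means$pathoTh17 + pseudocount) /
                            (rna_means$regTh17 + pseudocount),
                          rna_means$feature_id)
  diff_chars <- chars |> filter(.data$label != "common")
  conserved_ids <- conservation$region_id[conservation$conserved]
  cons_diff <- diff_chars |> filter(.data$region_id %in% conserved_ids)
  categories <- if (nrow(cons_diff) > 0) {
    region_fc <- setNames(
      gene_fc_vec[links$gene_id[match(cons_diff$region_id, links$region_id)]],
      cons_diff$region_id)
    correlation_category(cons_diff, region_fc, fc_differential) |>
      left_join(links |> select("region_id", "proximal"), by = "region_id") |>
      left_join(chars |> select("region_id", char_label = "label"),
                by = "region_id")
  } else NULL

  concordance <- classify_concordance(chars, links, rna_means,
                                      fc_differential, pseudocount)
  conc_patho <- concordance |>
    filter(.data$label == "concordant", .data$char_label == "patho-ChAR")
  similarity <- if (nrow(conc_patho) >= 3) {
    th1_similarity(atac_tpm, conc_patho$region_id, inputs$design_atac)
  } else NULL

  collected <- collect_related_chars(concordance, links)
  dynamics <- classify_dynamics(collected, atac_means, fc_step, pseudocount)
  step_counts <- count_gene_step_changes(dynamics, links)
  modes <- c("up-constant", "up-up", "constant-up",
             "down-constant", "down-down", "constant-down")
  mode_profiles <- purrr::map_dfr(modes, function(m) {
    n <- sum(dynamics$mode == m)
    tibble(mode = m, n = n,
           proximal_pct = if (n > 0) mode_tss_profile(dynamics, links, m)
           else NA_real_)
  })
  say("dynamics: %d opening / %d closing / %d contrary / %d irrelevant",
      sum(dynamics$klass == "opening"), sum(dynamics$klass == "closing"),
      sum(dynamics$klass == "contrary"), sum(dynamics$klass == "irrelevant"))

  seqs <- inputs$sequences[intersect(names(inputs$sequences), universe$name)]
  hits <- scan_pwm(seqs, inputs$pwms, min_score_frac)
  tf_counts <- count_by_dynamics(
    hits, dynamics, motif_ids = vapply(inputs$pwms, `[[`, character(1),
                                       "motif_id"))
  tf_classes <- classify_tfs(tf_counts, motif_min_total, motif_ratio)
  patho_rank <- rank_patho_tfs(tf_classes)
  say("TFs: %d patho / %d reg of %d motifs",
      sum(tf_classes$call == "patho-TF"), sum(tf_classes$call == "reg-TF"),
      nrow(tf_classes))

  summary <- build_summary(chars, links, conservation, categories,
                           concordance, dynamics, step_counts,
                           mode_profiles, tf_classes)
  structure(
    list(universe = universe, links = links, expressed = expressed,
         atac_tpm = atac_tpm, atac_means = atac_means, chars = chars,
         conservation = conservation, categories = categories,
         concordance = concordance, similarity = similarity,
         collected = collected, dynamics = dynamics,
         step_counts = step_counts, mode_profiles = mode_profiles,
         hits = hits, tf_classes = tf_classes, patho_rank = patho_rank,
         summary = summary,
         params = list(fc_differential = fc_differential, fc_step = fc_step,
                       tpm_expressed = tpm_expressed,
                       conservation_cutoff = conservation_cutoff,
                       proximal_window = proximal_window,
                       motif_min_total = motif_min_total,
                       motif_ratio = motif_ratio,
                       pseudocount = pseudocount,
                       min_score_frac = min_score_frac)),
    class = "chardyn_run")
}

build_summary <- function(chars, links, conservation, categories,
                          concordance, dynamics, step_counts,
                          mode_profiles, tf_classes) {
  by_class <- chars |>
    left_join(links |> select("region_id", "proximal"), by = "region_id") |>
    group_by(label = .data$label) |>
    summarise(n = dplyr::n(), distal = sum(!.data$proximal),
              proximal = sum(.data$proximal), .groups = "drop")
  location <- report_location_table(
    by_class |> select(subset = "label", "proximal", "distal"))
  conserved_loc <- chars |>
    filter(.data$label != "common",
           .data$region_id %in%
             conservation$region_id[conservation$conserved]) |>
    left_join(links |> select("region_id", "proximal"), by = "region_id") |>
    group_by(subset = paste0("conserved ", .data$label)) |>
    summarise(distal = sum(!.data$proximal), proximal = sum(.data$proximal),
              .groups = "drop")
  conserved_loc <- if (nrow(conserved_loc) > 0) {
    report_location_table(conserved_loc)
  } else NULL
  category_table <- if (!is.null(categories)) {
    report_category_table(categories)
  } else NULL
  concordance_table <- concordance |>
    dplyr::count(.data$char_label, .data$label) |>
    tidyr::pivot_wider(names_from = "label", values_from = "n",
                       values_fill = 0L)
  list(class_counts = by_class |> select("label", "n"),
       location = location,
       conserved_location = conserved_loc,
       categories = category_table,
       concordance = concordance_table,
       dynamics_klass = dynamics |> dplyr::count(.data$klass),
       mode_profiles = mode_profiles,
       step_counts = step_counts,
       tf_calls = tf_classes |> dplyr::count(.data$call))
}

#' Proximal/distal percentage table
#'
#' Turns raw proximal and distal counts into percentages rounded to two
#' decimals, retaining the raw counts.
#'
#' @param subset_counts Tibble with columns `subset`, `proximal`, `distal`
#'   (non-negative counts; each row's total must be positive).
#' @return The table with `total`, `proximal_pct`, `distal_pct` added.
#' @export
report_location_table <- function(subset_counts) {
  stopifnot(all(c("proximal", "distal") %in% names(subset_counts)))
  if (any(subset_counts$proximal < 0 | subset_counts$distal < 0)) {
    abort("report error: negative counts")
  }
  total <- subset_counts$proximal + subset_counts$distal
  if (any(total == 0)) abort("report error: zero total in a subset row")
  subset_counts |>
    mutate(total = total,
           proximal_pct = round(100 * .data$proximal / total, 2),
           distal_pct = round(100 * .data$distal / total, 2))
}

#' Correlation-category percentage table
#'
#' Tabulates positive / negative / irrelevant counts within each
#' (ChAR class x proximal/distal) cell and reports exact-division
#' percentages rounded to two decimals.
#'
#' @param categories Category tibble with `category`, `proximal`,
#'   `char_label` columns (as built by [run_pipeline()]), or a
#'   pre-aggregated tibble with `cell`, `category`, `n`.
#' @return Tibble `cell`, `category`, `n`, `cell_total`, `pct`.
#' @export
report_category_table <- function(categories) {
  counts <- if (all(c("cell", "category", "n") %in% names(categories))) {
    categories
  } else {
    categories |>
      mutate(cell = paste(.data$char_label,
                          if_else(.data$proximal, "proximal", "distal"))) |>
      dplyr::count(.data$cell, .data$category)
  }
  counts |>
    group_by(.data$cell) |>
    mutate(cell_total = sum(.data$n)) |>
    ungroup() |>
    mutate(pct = round(100 * .data$n / .data$cell_total, 2)) |>
    arrange(.data$cell, .data$category)
}

#' @export
print.chardyn_run <- function(x, ...) {
  cat("<chardyn_run>\n")
  cat(sprintf("  universe: %d regions, %d expressed genes\n",
              nrow(x$universe), length(x$expressed)))
  cc <- x$summary$class_counts
  cat(sprintf("  ChARs: %s\n",
              paste(sprintf("%s=%d", cc$label, cc$n), collapse = ", ")))
  dk <- x$summary$dynamics_klass
  cat(sprintf("  dynamics: %s\n",
              paste(sprintf("%s=%d", dk$klass, dk$n), collapse = ", ")))
  tf <- x$summary$tf_calls
  cat(sprintf("  TF calls: %s\n",
              paste(sprintf("%s=%d", tf$call, tf$n), collapse = ", ")))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy summary of a pipeline run
#'
#' @param x A `chardyn_run`.
#' @param ... Unused.
#' @return Long tibble `section`, `item`, `metric`, `value` covering class
#'   counts, location percentages, concordance, dynamics classes, mode
#'   profiles, step gene counts and TF calls.
#' @exportS3Method generics::tidy
tidy.chardyn_run <- function(x, ...) {
  s <- x$summary
  num_row <- function(section, item, metric, value) {
    tibble(section = section, item = item, metric = metric,
           value = as.numeric(value))
  }
  bind_rows(
    purrr::pmap_dfr(s$class_counts, function(label, n)
      num_row("chars", label, "n", n)),
    purrr::pmap_dfr(s$location, function(subset, proximal, distal, total,
                                         proximal_pct, distal_pct)
      num_row("location", subset, "proximal_pct", proximal_pct)),
    if (!is.null(s$conserved_location))
      purrr::pmap_dfr(s$conserved_location,
                      function(subset, proximal, distal, total,
                               proximal_pct, distal_pct)
        num_row("conserved_location", subset, "proximal_pct", proximal_pct)),
    purrr::pmap_dfr(s$dynamics_klass, function(klass, n)
      num_row("dynamics", klass, "n", n)),
    purrr::pmap_dfr(s$mode_profiles, function(mode, n, proximal_pct)
      num_row("mode_proximal_pct", mode, "proximal_pct", proximal_pct)),
    purrr::pmap_dfr(s$step_counts, function(direction, step, location,
                                            n_genes)
      num_row("step_gene_counts", paste(direction, step, location),
              "n_genes", n_genes)),
    purrr::pmap_dfr(s$tf_calls, function(call, n)
      num_row("tf_calls", call, "n", n)))
}

#' One-row summary of a pipeline run
#'
#' @param x A `chardyn_run`.
#' @param ... Unused.
#' @return One-row tibble with the headline counts.
#' @exportS3Method generics::glance
glance.chardyn_run <- function(x, ...) {
  cc <- setNames(x$summary$class_counts$n, x$summary$class_counts$label)
  conc <- x$concordance
  tibble(
    n_universe = nrow(x$universe),
    n_expressed = length(x$expressed),
    n_patho_chars = unname(cc["patho-ChAR"] %||% 0L),
    n_reg_chars = unname(cc["reg-ChAR"] %||% 0L),
    n_common = unname(cc["common"] %||% 0L),
    n_concordant_patho = sum(conc$label == "concordant" &
                               conc$char_label == "patho-ChAR"),
    n_concordant_reg = sum(conc$label == "concordant" &
                             conc$char_label == "reg-ChAR"),
    n_opening = sum(x$dynamics$klass == "opening"),
    n_closing = sum(x$dynamics$klass == "closing"),
    n_patho_tfs = sum(x$tf_classes$call == "patho-TF"),
    n_reg_tfs = sum(x$tf_classes$call == "reg-TF"))
}
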