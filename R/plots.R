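#' TSS-distance histogram for ChAR subsets
#'
#' Histogram of signed peak-center-to-TSS distances, faceted or coloured by
#' ChAR class, with the +/-1 kb proximal window marked.
#'
#' @param links Links from [annotate_nearest_tss()].
#' @param chars Optional [call_chars()] output to colour by class.
#' @param span Half-range of the x axis in bp (default 50 kb).
#' @param binwidth Histogram bin width in bp (default 500).
#' @return A ggplot object.
#' @export
plot_tss_distance <- function(links, chars = NULL, span = 50000,
                              binwidth = 500) {
  d <- links
  if (!is.null(chars)) {
    d <- d |> left_join(chars |> select("region_id", "label"),
                        by = "region_id")
  } else {
    d$label <- "all"
  }
  d <- d |> filter(abs(.data$signed_distance) <= span)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$signed_distance,
                                  fill = .data$label)) +
    ggplot2::geom_histogram(binwidth = binwidth, position = "identity",
                            alpha = 0.6) +
    ggplot2::geom_vline(xintercept = c(-1000, 1000), linetype = "dashed") +
    ggplot2::labs(x = "signed distance to nearest TSS (bp)", y = "regions",
                  fill = "class") +
    ggplot2::theme_minimal()
}

#' Accessibility fold-change bin counts
#'
#' @param chars Output of [bin_by_fc()].
#' @return A ggplot object: counts per six log2 fold-change bins.
#' @export
plot_fc_bins <- function(chars) {
  lab <- c(">2x down", "1.5-2x down", "<1.5x down",
           "<1.5x up", "1.5-2x up", ">2x up")
  d <- chars |> dplyr::count(.data$bin) |>
    mutate(bin_label = factor(lab[.data$bin], levels = lab))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin_label, y = .data$n)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "accessibility difference (pathogenic vs regulatory Th17)",
                  y = "regions") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Step-by-location gene counts for opening/closing ChARs
#'
#' @param step_counts Output of [count_gene_step_changes()].
#' @return A ggplot object mirroring the per-step gene counting.
#' @export
plot_step_counts <- function(step_counts) {
  ggplot2::ggplot(step_counts,
                  ggplot2::aes(x = .data$step, y = .data$n_genes,
                               fill = .data$location)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~direction) +
    ggplot2::labs(x = "conversion step", y = "genes") +
    ggplot2::theme_minimal()
}

#' Patho-TF ranking by first-step motif proportion
#'
#' @param tf_classes Output of [classify_tfs()].
#' @return A ggplot object of patho-TFs ordered by `step1_proportion`.
#' @export
plot_tf_ranking <- function(tf_classes) {
  d <- rank_patho_tfs(tf_classes) |>
    mutate(motif_id = factor(.data$motif_id, levels = rev(.data$motif_id)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$step1_proportion,
                                  y = .data$motif_id)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::labs(x = "proportion of opening-ChAR motifs in step 1",
                  y = NULL) +
    ggplot2::xlim(0, 1) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Overview plot of a pipeline run
#'
#' @param object A `chardyn_run`.
#' @param ... Unused.
#' @return A ggplot object: ChAR class counts.
#' @exportS3Method ggplot2::autoplot
autoplot.chardyn_run <- function(object, ...) {
  d <- object$summary$class_counts
  ggplot2::ggplot(d, ggplot2::aes(x = .data$label, y = .data$n,
                                  fill = .data$label)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "regions") +
    ggplot2::theme_minimal()
}
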