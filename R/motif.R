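BASE_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 5L)

# log2-odds lookup with rows A,C,G,T,N,separator; N contributes 0 bits and
# the separator -Inf so windows can never straddle two regions
logodds_matrix <- function(pwm) {
  lo <- log2(sweep(t(pwm$probs), 1L, pwm$background, "/"))
  rbind(lo, 0, -Inf)
}

revcomp_pwm <- function(pwm) {
  probs <- pwm$probs[rev(seq_len(nrow(pwm$probs))), c("T", "G", "C", "A"),
                     drop = FALSE]
  colnames(probs) <- c("A", "C", "G", "T")
  list(motif_id = pwm$motif_id, probs = probs,
       background = unname(pwm$background[c(4, 3, 2, 1)]) |>
         setNames(c("A", "C", "G", "T")))
}

#' Scan region sequences with position weight matrices
#'
#' Scores every offset of every region on both strands with the log2-odds
#' score `sum_k log2(p_k(base) / bg(base))`; `N` bases contribute 0 bits.
#' Minus-strand scores are those of the PWM on the reverse complement of the
#' window, reported at the window's leftmost forward-strand offset. Hits are
#' offsets scoring at least the threshold.
#'
#' @param sequences Named character vector of region sequences (A,C,G,T,N).
#' @param pwms A single PWM (list with `motif_id`, `probs`, `background`) or
#'   a named list of them, as from [read_meme()].
#' @param min_score_frac Threshold as a fraction of each PWM's maximum
#'   attainable log-odds score (default 0.6); ignored when `threshold_bits`
#'   is given.
#' @param threshold_bits Absolute threshold in bits, applied to all PWMs.
#' @return Tibble `motif_id`, `region_id`, `offset` (0-based), `strand`,
#'   `score`.
#' @export
scan_pwm <- function(sequences, pwms, min_score_frac = 0.6,
                     threshold_bits = NULL) {
  if (!is.null(pwms$probs)) pwms <- list(pwms)
  empty <- tibble(motif_id = character(), region_id = character(),
                  offset = integer(), strand = character(), score = double())
  if (length(sequences) == 0L) return(empty)
  max_w <- max(vapply(pwms, function(p) nrow(p$probs), integer(1)))
  lens <- nchar(sequences)
  sep <- rep.int(6L, max(max_w - 1L, 1L))
  blocks <- lapply(sequences, function(s) {
    unname(BASE_CODE[strsplit(s, "", fixed = TRUE)[[1]]])
  })
  big <- unlist(lapply(blocks, function(b) c(b, sep)), use.names = FALSE)
  region_start <- cumsum(c(1L, utils::head(lens + length(sep), -1L)))
  out <- lapply(pwms, function(pwm) {
    w <- nrow(pwm$probs)
    if (all(w > lens)) return(empty)
    los <- list(`+` = logodds_matrix(pwm),
                `-` = logodds_matrix(revcomp_pwm(pwm)))
    max_score <- sum(apply(los[["+"]][1:4, , drop = FALSE], 2L, max))
    thr <- threshold_bits %||% (min_score_frac * max_score)
    n_off <- length(big) - w + 1L
    purrr::imap_dfr(los, function(lo, strand) {
      score <- numeric(n_off)
      for (k in seq_len(w)) {
        score <- score + lo[cbind(big[k:(n_off + k - 1L)], k)]
      }
      p <- unname(which(score >= thr))
      if (length(p) == 0L) return(empty)
      r <- findInterval(p, region_start)
      tibble(motif_id = pwm$motif_id,
             region_id = names(sequences)[r],
             offset = as.integer(p - region_start[r]),
             strand = strand,
             score = score[p])
    })
  })
  bind_rows(out) |> arrange(.data$motif_id, .data$region_id, .data$offset)
}

#' Count motif hits in opening vs closing ChARs and per conversion step
#'
#' `n_opening`/`n_closing` count hits in regions classed opening/closing;
#' `n_step1` counts opening-region hits in modes up-constant and up-up,
#' `n_step2` in modes constant-up and up-up (two-step regions count in
#' both).
#'
#' @param hits Output of [scan_pwm()].
#' @param labels Output of [classify_dynamics()].
#' @param motif_ids Motifs to report; defaults to those present in `hits`.
#' @return Tibble `motif_id`, `n_opening`, `n_closing`, `n_step1`,
#'   `n_step2`.
#' @export
count_by_dynamics <- function(hits, labels,
                              motif_ids = unique(hits$motif_id)) {
  d <- hits |>
    inner_join(labels |> select("region_id", "klass", "mode"),
               by = "region_id")
  agg <- d |>
    group_by(.data$motif_id) |>
    summarise(
      n_opening = sum(.data$klass == "opening"),
      n_closing = sum(.data$klass == "closing"),
      n_step1 = sum(.data$mode %in% c("up-constant", "up-up")),
      n_step2 = sum(.data$mode %in% c("constant-up", "up-up")),
      .groups = "drop")
  tibble(motif_id = motif_ids) |>
    left_join(agg, by = "motif_id") |>
    mutate(across(c("n_opening", "n_closing", "n_step1", "n_step2"),
                  ~ dplyr::coalesce(.x, 0L)))
}

#' Call patho-TFs and reg-TFs from opening/closing hit counts
#'
#' Motifs with more than `min_total` hits across opening and closing ChARs
#' are classified by the pseudocounted ratio
#' `(n_opening + 1) / (n_closing + 1)`: patho-TF above `ratio_threshold`,
#' reg-TF below its reciprocal, neither otherwise. The first-step
#' proportion `n_step1 / (n_step1 + n_step2)` supports ranking.
#'
#' @param counts Output of [count_by_dynamics()].
#' @param min_total Minimum total hits for a call (default 20, strict `>`).
#' @param ratio_threshold Opening:closing ratio threshold (default 1.5).
#' @return `counts` with `total`, `ratio`, `call`, `step1_proportion`.
#' @export
classify_tfs <- function(counts, min_total = 20, ratio_threshold = 1.5) {
  counts |>
    mutate(
      total = .data$n_opening + .data$n_closing,
      ratio = (.data$n_opening + 1) / (.data$n_closing + 1),
      call = case_when(
        .data$total <= min_total ~ "neither",
        .data$ratio > ratio_threshold ~ "patho-TF",
        .data$ratio < 1 / ratio_threshold ~ "reg-TF",
        TRUE ~ "neither"),
      step1_proportion = if_else(
        .data$n_step1 + .data$n_step2 > 0,
        .data$n_step1 / (.data$n_step1 + .data$n_step2),
        NA_real_))
}

#' Rank patho-TFs by first-step motif proportion
#'
#' @param tf_classes Output of [classify_tfs()].
#' @return The patho-TF rows sorted by descending `step1_proportion`, ties
#'   broken lexicographically by motif id.
#' @export
rank_patho_tfs <- function(tf_classes) {
  tf_classes |>
    filter(.data$call == "patho-TF") |>
    arrange(desc(.data$step1_proportion), .data$motif_id)
}

#' TSS-proximal percentage of a motif's opening-ChAR hits
#'
#' @param hits Output of [scan_pwm()].
#' @param labels Output of [classify_dynamics()].
#' @param links Region-to-gene links (for the proximal flag).
#' @param motif_id Motif to profile.
#' @return Percentage of the motif's opening-region hits that fall in
#'   TSS-proximal regions.
#' @export
motif_tss_profile <- function(hits, labels, links, motif_id) {
  opening <- labels$region_id[labels$klass == "opening"]
  h <- hits |>
    filter(.data$motif_id == !!motif_id, .data$region_id %in% opening)
  if (nrow(h) == 0L) {
    abort(sprintf("undefined-percentage error: motif %s has no opening-ChAR hits",
                  motif_id))
  }
  prox <- links$region_id[links$proximal]
  100 * sum(h$region_id %in% prox) / nrow(h)
}
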