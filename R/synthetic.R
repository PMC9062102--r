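#' Configuration for the synthetic Th17/Th1 chromatin study
#'
#' Builds and validates the parameter set for the synthetic-data generator.
#' The generator emulates the design this package analyses: three cell states
#' (regulatory Th17, pathogenic Th17, pro-inflammatory Th1) with two
#' replicates each, genes carrying a pathogenic, regulatory or neutral
#' program, and ATAC peaks whose accessibility is planted to open (or close)
#' in one of the two conversion steps.
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Chromosome length in bases. Genes are laid out in
#'   private, equal-width territories so that peaks of different genes can
#'   never overlap; the length must leave each gene a territory of at least
#'   4 kb (TSS +/-1 kb windows must not collide).
#' @param n_genes Number of genes.
#' @param frac_patho_genes,frac_reg_genes Fractions of genes assigned the
#'   pathogenic / regulatory program; the rest are neutral.
#' @param peaks_per_gene ATAC peaks generated per gene.
#' @param proximal_peak_prob Probability that a peak center falls within
#'   +/-1 kb of its gene's TSS; otherwise it is placed 5-50 kb away.
#' @param effect_frac Fraction of a program gene's peaks that carry the
#'   planted temporal accessibility effect; the rest stay flat. The default
#'   0.19 is calibrated so that opening plus closing ChARs make up roughly a
#'   third of the ChARs collected around concordant-ChAR-related genes
#'   (gene collection preferentially picks genes with more effected peaks,
#'   so the collected fraction sits well above `effect_frac` itself).
#' @param upup_frac Among effected distal peaks, the fraction planted with
#'   the two-step up-up (or down-down) mode instead of constant-up
#'   (constant-down).
#' @param open_effect Fold-change multiplier (> 1) applied to the mean count
#'   at each planted opening step.
#' @param effect_jitter Log-scale half-width of per-region effect-size
#'   heterogeneity: each effected region draws its own step multiplier as
#'   `open_effect * exp(U)`, `U ~ Uniform(-effect_jitter, effect_jitter)`
#'   (default 0.5). Real differential peaks do not share one fold change;
#'   this spread is also what lets rank-based cross-state similarity see the
#'   planted structure (a shared constant multiplier would leave sample
#'   ranks unchanged). Set to 0 for exact-recovery limits.
#' @param nb_dispersion Negative-binomial dispersion of count noise
#'   (variance = mu + mu^2 * dispersion); 0 gives Poisson noise.
#' @param base_mean Expected baseline count per peak (log-normal spread
#'   around this value across peaks).
#' @param concordance_frac Fraction of program genes whose RNA expression
#'   follows their chromatin program (>= 2-fold in the same direction).
#' @param conserved_frac Fraction of peaks flagged evolutionarily conserved
#'   (track mean in `[0.7, 1]`; others in `[0, 0.3]`).
#' @param motif_plant_rate_open Per-region probability of planting a motif's
#'   consensus in regions matching that motif's planting modes.
#' @param motif_plant_rate_bg Background per-region planting probability.
#' @param seed Integer seed; every generator is a pure function of
#'   (config, seed).
#' @return A validated `chardyn_config` list.
#' @export
chardyn_config <- function(n_chroms = 4L,
                           chrom_length = 1.2e8,
                           n_genes = 2000L,
                           frac_patho_genes = 0.15,
                           frac_reg_genes = 0.15,
                           peaks_per_gene = 5L,
                           proximal_peak_prob = 0.3,
                           effect_frac = 0.19,
                           upup_frac = 0.2,
                           open_effect = 4,
                           effect_jitter = 0.5,
                           nb_dispersion = 0.05,
                           base_mean = 100,
                           concordance_frac = 0.7,
                           conserved_frac = 0.3,
                           motif_plant_rate_open = 0.5,
                           motif_plant_rate_bg = 0.02,
                           seed = 1L) {
  cfg <- list(n_chroms = as.integer(n_chroms),
              chrom_length = as.numeric(chrom_length),
              n_genes = as.integer(n_genes),
              frac_patho_genes = frac_patho_genes,
              frac_reg_genes = frac_reg_genes,
              peaks_per_gene = as.integer(peaks_per_gene),
              proximal_peak_prob = proximal_peak_prob,
              effect_frac = effect_frac,
              upup_frac = upup_frac,
              open_effect = open_effect,
              effect_jitter = effect_jitter,
              nb_dispersion = nb_dispersion,
              base_mean = base_mean,
              concordance_frac = concordance_frac,
              conserved_frac = conserved_frac,
              motif_plant_rate_open = motif_plant_rate_open,
              motif_plant_rate_bg = motif_plant_rate_bg,
              seed = as.integer(seed))
  props <- c("frac_patho_genes", "frac_reg_genes", "proximal_peak_prob",
             "effect_frac", "upup_frac", "concordance_frac", "conserved_frac",
             "motif_plant_rate_open", "motif_plant_rate_bg")
  for (p in props) {
    if (!is.numeric(cfg[[p]]) || cfg[[p]] < 0 || cfg[[p]] > 1) {
      abort(sprintf("config error: %s must lie in [0, 1]", p))
    }
  }
  if (cfg$frac_patho_genes + cfg$frac_reg_genes > 1) {
    abort("config error: frac_patho_genes + frac_reg_genes must be <= 1")
  }
  if (cfg$open_effect <= 1) abort("config error: open_effect must be > 1")
  if (cfg$effect_jitter < 0) abort("config error: effect_jitter must be >= 0")
  if (cfg$nb_dispersion < 0) abort("config error: nb_dispersion must be >= 0")
  if (!is.finite(cfg$base_mean) || cfg$base_mean <= 0) {
    abort("config error: base_mean must be positive and finite")
  }
  if (cfg$n_genes < 1L || cfg$n_chroms < 1L || cfg$peaks_per_gene < 0L) {
    abort("config error: n_genes/n_chroms must be >= 1, peaks_per_gene >= 0")
  }
  spacing <- gene_spacing(cfg)
  if (spacing < 4000) {
    abort(sprintf(
      "sizing error: territory of %d bp per gene is too small (need >= 4000 so +/-1 kb TSS windows cannot collide); increase chrom_length or n_chroms",
      as.integer(spacing)))
  }
  structure(cfg, class = "chardyn_config")
}

# per-gene territory width, given round-robin assignment of genes to chroms
gene_spacing <- function(config) {
  genes_per_chrom <- ceiling(config$n_genes / config$n_chroms)
  floor(config$chrom_length / genes_per_chrom)
}

#' Generate a synthetic gene annotation
#'
#' Genes are laid out in equal-width territories along each chromosome with
#' a jittered TSS near the territory center, guaranteeing pairwise TSS
#' distances of at least half a territory (>= 2 kb), so +/-1 kb proximal
#' windows never overlap.
#'
#' @param config A [chardyn_config()].
#' @return Tibble `gene_id`, `chrom`, `tss` (0-based), `strand`.
#' @export
simulate_genome <- function(config) {
  spacing <- gene_spacing(config)
  withr::with_seed(config$seed, {
    chrom <- sprintf("chr%d", rep_len(seq_len(config$n_chroms), config$n_genes))
    idx <- stats::ave(seq_len(config$n_genes), chrom, FUN = seq_along)
    jitter <- floor(stats::runif(config$n_genes, -spacing / 4, spacing / 4))
    tss <- (idx - 1) * spacing + floor(spacing / 2) + jitter
    strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
    tibble(gene_id = sprintf("g%04d", seq_len(config$n_genes)),
           chrom = chrom, tss = as.numeric(tss), strand = strand) |>
      arrange(.data$chrom, .data$tss)
  })
}

#' Generate synthetic ATAC peaks around each gene
#'
#' Each gene receives `peaks_per_gene` peaks of width 200-1000 bp. With
#' probability `proximal_peak_prob` a peak center lies within +/-1 kb of the
#' TSS, otherwise 5-50 kb away (capped by the gene's territory). Peaks never
#' overlap, within or across genes, so nearest-TSS assignment has an
#' unambiguous truth. When a gene's +/-1 kb window is too crowded to fit
#' another non-overlapping proximal peak (geometrically unavoidable once a
#' few peaks occupy the 2 kb window), the peak falls back to the distal zone
#' and is recorded as distal; with the default width range this is rare.
#'
#' @param genes Output of [simulate_genome()].
#' @param config The same [chardyn_config()].
#' @return Tibble `chrom`, `start`, `end`, `name`, `gene_id`, `proximal`
#'   sorted by (chrom, start); `name` is the canonical `chrom:start-end` id.
#' @export
simulate_peaks <- function(genes, config) {
  if (config$peaks_per_gene == 0L) {
    return(tibble(chrom = character(), start = double(), end = double(),
                  name = character(), gene_id = character(),
                  proximal = logical()))
  }
  spacing <- gene_spacing(config)
  half <- floor(spacing / 4) - 1   # guaranteed clearance around each TSS
  distal_max <- min(50000, half - 600)
  if (distal_max < 5000 && config$proximal_peak_prob < 1) {
    abort("sizing error: territories too small to place distal peaks 5-50 kb from the TSS")
  }
  withr::with_seed(config$seed + 1L, {
    rows <- purrr::pmap(genes, function(gene_id, chrom, tss, strand) {
      placed_start <- numeric(0)
      placed_end <- numeric(0)
      prox <- stats::runif(config$peaks_per_gene) < config$proximal_peak_prob
      place_one <- function(is_prox) {
        for (try in 1:200) {
          width <- floor(stats::runif(1, 200, 1001))
          center <- if (is_prox) {
            tss + floor(stats::runif(1, -1000, 1001))
          } else {
            off <- floor(stats::runif(1, 5000, distal_max + 1))
            tss + sample(c(-1, 1), 1) * off
          }
          s <- center - floor(width / 2)
          # keep a >=1 bp gap so book-ended merging cannot fuse two peaks
          if (all(s + width < placed_start | s > placed_end)) {
            return(c(s, s + width))
          }
        }
        NULL
      }
      out <- vector("list", config$peaks_per_gene)
      for (i in seq_len(config$peaks_per_gene)) {
        iv <- place_one(prox[i])
        if (is.null(iv)) {      # crowded proximal window: use the distal zone
          prox[i] <- FALSE
          iv <- place_one(FALSE)
        }
        if (is.null(iv)) abort("sizing error: could not place a peak without overlap")
        placed_start <- c(placed_start, iv[1]); placed_end <- c(placed_end, iv[2])
        out[[i]] <- tibble(chrom = chrom, start = iv[1], end = iv[2],
                           gene_id = gene_id, proximal = prox[i])
      }
      bind_rows(out)
    })
    res <- bind_rows(rows)
    res$name <- region_id(res)
    res |>
      select("chrom", "start", "end", "name", "gene_id", "proximal") |>
      arrange(.data$chrom, .data$start)
  })
}

state_multipliers <- function(mode, e) {
  switch(mode,
         "up-constant"   = c(1, e, e),
         "up-up"         = c(1, e, e * e),
         "constant-up"   = c(1, 1, e),
         "down-constant" = c(e, 1, 1),
         "down-down"     = c(e * e, e, 1),
         "constant-down" = c(e, e, 1),
         "none"          = c(1, 1, 1))
}

#' Generate planted count matrices and the ground-truth table
#'
#' Assigns gene programs (patho / reg / neutral), plants temporal
#' accessibility modes on a fraction of each program gene's peaks
#' (proximal peaks open or close at the first conversion step, distal
#' peaks at the second), draws negative-binomial ATAC counts for the six
#' samples, and draws RNA counts whose TPM follows the gene's program for a
#' `concordance_frac` fraction of program genes.
#'
#' @param peaks Output of [simulate_peaks()].
#' @param genes Output of [simulate_genome()].
#' @param config The same [chardyn_config()].
#' @return A list: `atac_counts` and `rna_tpm` matrix tibbles,
#'   `design_atac`/`design_rna` sample designs, `truth` (per region:
#'   `region_id`, `gene_id`, `class`, `mode`, `concordant`, `proximal`)
#'   and `gene_truth` (`gene_id`, `program`, `concordant`).
#' @export
simulate_counts <- function(peaks, genes, config) {
  states <- c("regTh17", "pathoTh17", "Th1")
  design <- function(prefix) {
    tibble(sample_id = sprintf("%s_%s_%d", prefix, rep(states, each = 2),
                               rep(1:2, 3)),
           state = rep(states, each = 2), replicate = rep(1:2, 3))
  }
  d_atac <- design("atac"); d_rna <- design("rna")
  withr::with_seed(config$seed + 2L, {
    n_patho <- round(config$frac_patho_genes * config$n_genes)
    n_reg <- round(config$frac_reg_genes * config$n_genes)
    shuffled <- sample(genes$gene_id)
    gene_truth <- tibble(
      gene_id = shuffled,
      program = rep(c("patho", "reg", "neutral"),
                    c(n_patho, n_reg, config$n_genes - n_patho - n_reg))) |>
      mutate(concordant = .data$program != "neutral" &
               stats::runif(dplyr::n()) < config$concordance_frac) |>
      arrange(.data$gene_id)

    truth <- peaks |>
      left_join(gene_truth, by = "gene_id") |>
      mutate(
        effected = .data$program != "neutral" &
          stats::runif(dplyr::n()) < config$effect_frac,
        twostep = stats::runif(dplyr::n()) < config$upup_frac,
        mode = case_when(
          !.data$effected ~ "none",
          .data$program == "patho" & .data$proximal ~ "up-constant",
          .data$program == "patho" & .data$twostep ~ "up-up",
          .data$program == "patho" ~ "constant-up",
          .data$program == "reg" & .data$proximal ~ "down-constant",
          .data$program == "reg" & .data$twostep ~ "down-down",
          .data$program == "reg" ~ "constant-down"),
        class = case_when(
          .data$mode %in% c("up-constant", "up-up") ~ "patho-ChAR",
          .data$mode %in% c("down-constant", "down-down") ~ "reg-ChAR",
          TRUE ~ "common"),
        concordant = if_else(.data$class == "common", NA,
                             .data$concordant),
        effect = if_else(
          .data$mode == "none", 1,
          config$open_effect *
            exp(stats::runif(dplyr::n(), -config$effect_jitter,
                             config$effect_jitter))))

    # ATAC counts: per-region log-normal baseline times planted state effect
    n_r <- nrow(peaks)
    base <- stats::rlnorm(n_r, log(config$base_mean), 0.5)
    mult <- t(mapply(state_multipliers, truth$mode, truth$effect))
    mu_atac <- base * mult[, rep(1:3, each = 2)]   # 6 samples, states x 2 reps
    if (any(!is.finite(mu_atac))) abort("parameter error: non-finite count mean")
    atac <- matrix(draw_nb(mu_atac, config$nb_dispersion), nrow = n_r)
    atac_counts <- bind_cols(tibble(feature_id = peaks$name),
                             as_tibble(setNames(as.data.frame(atac),
                                                d_atac$sample_id)))

    # RNA: baseline clamped away from the expression floor; concordant
    # program genes follow their chromatin program >= open_effect-fold
    g_base <- pmax(stats::rlnorm(config$n_genes, log(config$base_mean), 0.6), 50)
    g_mult <- t(vapply(seq_len(config$n_genes), function(i) {
      if (!gene_truth$concordant[i]) return(c(1, 1, 1))
      if (gene_truth$program[i] == "patho") {
        c(1, config$open_effect, config$open_effect)
      } else {
        c(config$open_effect, 1, 1)
      }
    }, numeric(3)))
    mu_rna <- g_base * g_mult[, rep(1:3, each = 2)]
    rna <- matrix(draw_nb(mu_rna, config$nb_dispersion),
                  nrow = config$n_genes)
    rna_counts <- bind_cols(tibble(feature_id = gene_truth$gene_id),
                            as_tibble(setNames(as.data.frame(rna),
                                               d_rna$sample_id)))
    rna_tpm <- tpm_normalise(rna_counts, widths = rep(1, config$n_genes))

    list(atac_counts = atac_counts, rna_tpm = rna_tpm,
         design_atac = d_atac, design_rna = d_rna,
         truth = truth |> select(region_id = "name", "gene_id", "class",
                                 "mode", "concordant", "proximal"),
         gene_truth = gene_truth)
  })
}

# NB draw with variance mu + mu^2 * dispersion; dispersion 0 -> Poisson
draw_nb <- function(mu, dispersion) {
  if (dispersion <= 0) return(stats::rpois(length(mu), mu))
  stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
}

#' Generate a synthetic conservation track
#'
#' Each peak is flagged conserved with probability `conserved_frac`;
#' conserved peaks receive a stepwise track whose interval mean lies in
#' `[0.7, 1]`, others in `[0, 0.3]`. Bases between peaks carry no record
#' (score 0 by the bedGraph-absence convention).
#'
#' @param peaks Output of [simulate_peaks()].
#' @param config The same [chardyn_config()].
#' @return A list: `track` (bedGraph-style tibble) and `conserved`
#'   (tibble `region_id`, `conserved`).
#' @export
simulate_conservation <- function(peaks, config) {
  withr::with_seed(config$seed + 3L, {
    n <- nrow(peaks)
    conserved <- stats::runif(n) < config$conserved_frac
    target <- ifelse(conserved, stats::runif(n, 0.75, 0.95),
                     stats::runif(n, 0.05, 0.25))
    pieces <- purrr::pmap(list(peaks$chrom, peaks$start, peaks$end, target),
                          function(chrom, start, end, t) {
      cuts <- sort(c(start, end,
                     floor(stats::runif(2, start + 1, end - 1))))
      cuts <- unique(cuts)
      tibble(chrom = chrom, start = cuts[-length(cuts)], end = cuts[-1],
             score = pmin(1, pmax(0, t + stats::runif(length(cuts) - 1,
                                                      -0.05, 0.05))))
    })
    list(track = bind_rows(pieces) |> arrange(.data$chrom, .data$start),
         conserved = tibble(region_id = peaks$name, conserved = conserved))
  })
}

#' Default synthetic motif set
#'
#' Six 10-bp near-consensus PWMs with distinct planting roles: `TF_early`
#' (planted in up-constant regions), `TF_late` (constant-up), `TF_open`
#' (any opening mode), `TF_close` (any closing mode) and two background-only
#' motifs. Planting roles live in the `plant_modes` attribute of each PWM.
#' The PWMs are sharp (0.985 on the consensus base) so that, at the default
#' 60%-of-max scan threshold, only consensus occurrences score as hits and
#' planted instances are recovered unambiguously.
#'
#' @return Named list of PWMs compatible with [read_meme()] output.
#' @export
default_motifs <- function() {
  spec <- list(
    TF_early = list("ACGCGTTACA", c("up-constant")),
    TF_late  = list("CATGGTCAAT", c("constant-up")),
    TF_open  = list("GTTACGGATC", c("up-constant", "up-up", "constant-up")),
    TF_close = list("TCCAGTACCT", c("down-constant", "down-down", "constant-down")),
    TF_bg1   = list("AGGTCAAGTA", character(0)),
    TF_bg2   = list("CCTTGAGCAT", character(0)))
  purrr::imap(spec, function(s, id) {
    cons <- strsplit(s[[1]], "")[[1]]
    probs <- t(vapply(cons, function(b) {
      p <- setNames(rep(0.005, 4), c("A", "C", "G", "T")); p[b] <- 0.985; p
    }, numeric(4)))
    rownames(probs) <- NULL
    structure(list(motif_id = id, probs = probs,
                   background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)),
              consensus = s[[1]], plant_modes = s[[2]])
  })
}

#' Generate region sequences with planted motif consensus strings
#'
#' Sequences are uniform-random ACGT. For each motif, its consensus string is
#' inserted with probability `motif_plant_rate_open` in regions whose planted
#' mode matches the motif's `plant_modes` attribute, and with probability
#' `motif_plant_rate_bg` elsewhere, at a random offset and strand; multiple
#' plants in one region never overlap. A motif longer than its region is
#' skipped with a warning.
#'
#' @param peaks Output of [simulate_peaks()].
#' @param truth Region truth table from [simulate_counts()].
#' @param pwms PWM list; defaults to [default_motifs()].
#' @param config The same [chardyn_config()].
#' @return A list: `sequences` (named character vector) and `placements`
#'   (tibble `region_id`, `motif_id`, `offset`, `strand`).
#' @export
simulate_sequences <- function(peaks, truth, pwms = default_motifs(), config) {
  mode_of <- setNames(truth$mode, truth$region_id)
  withr::with_seed(config$seed + 4L, {
    lens <- as.integer(peaks$end - peaks$start)
    seqs <- vapply(lens, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1))
    names(seqs) <- peaks$name
    placements <- list()
    for (p in pwms) {
      cons <- attr(p, "consensus")
      w <- nchar(cons)
      modes <- attr(p, "plant_modes") %||% character(0)
      rate <- ifelse(mode_of[peaks$name] %in% modes,
                     config$motif_plant_rate_open, config$motif_plant_rate_bg)
      plant <- stats::runif(nrow(peaks)) < rate
      for (i in which(plant)) {
        if (w > lens[i]) {
          warn(sprintf("motif %s (%d bp) longer than region %s; skipped",
                       p$motif_id, w, peaks$name[i]))
          next
        }
        taken <- placements[
          vapply(placements, function(x) x$region_id == peaks$name[i],
                 logical(1))]
        ok <- FALSE
        for (try in 1:50) {
          off <- sample.int(lens[i] - w + 1L, 1L) - 1L
          clash <- any(vapply(taken, function(x) {
            off < x$offset + x$width && x$offset < off + w
          }, logical(1)))
          if (!clash) { ok <- TRUE; break }
        }
        if (!ok) next
        strand <- sample(c("+", "-"), 1L)
        ins <- if (strand == "+") cons else revcomp(cons)
        substr(seqs[i], off + 1L, off + w) <- ins
        placements[[length(placements) + 1L]] <-
          list(region_id = peaks$name[i], motif_id = p$motif_id,
               offset = off, strand = strand, width = w)
      }
    }
    pl <- if (length(placements) == 0L) {
      tibble(region_id = character(), motif_id = character(),
             offset = integer(), strand = character())
    } else {
      bind_rows(lapply(placements, as_tibble)) |> select(-"width")
    }
    list(sequences = seqs, placements = pl)
  })
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Generate the full synthetic study bundle
#'
#' Runs every generator in order under per-stage seeds derived from
#' `config$seed` and returns all inputs a real analysis would consume plus
#' the planted truth.
#'
#' @param config A [chardyn_config()].
#' @param pwms PWM list; defaults to [default_motifs()].
#' @return A named list: `genes`, `peaks`, `atac_counts`, `rna_tpm`,
#'   `design_atac`, `design_rna`, `track`, `sequences`, `pwms`,
#'   `placements`, `truth`, `gene_truth`, `config`.
#' @export
simulate_chardyn <- function(config = chardyn_config(), pwms = default_motifs()) {
  genes <- simulate_genome(config)
  peaks <- simulate_peaks(genes, config)
  cm <- simulate_counts(peaks, genes, config)
  cons <- simulate_conservation(peaks, config)
  sq <- simulate_sequences(peaks, cm$truth, pwms, config)
  truth <- cm$truth |> left_join(cons$conserved, by = "region_id")
  list(genes = genes, peaks = peaks,
       atac_counts = cm$atac_counts, rna_tpm = cm$rna_tpm,
       design_atac = cm$design_atac, design_rna = cm$design_rna,
       track = cons$track, sequences = sq$sequences, pwms = pwms,
       placements = sq$placements, truth = truth,
       gene_truth = cm$gene_truth, config = config)
}

#' Write a synthetic bundle to plain-text files
#'
#' Emits `peaks.bed`, `atac_counts.tsv`, `rna_tpm.tsv`, `genes.tsv`,
#' `conservation.bedGraph`, `regions.fasta`, `motifs.meme`,
#' `design_atac.tsv`, `design_rna.tsv` and `truth.tsv` under `dir`.
#'
#' @param bundle Output of [simulate_chardyn()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_chardyn_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(dir, x)
  write_bed(bundle$peaks, fp("peaks.bed"))
  write_matrix(bundle$atac_counts, fp("atac_counts.tsv"))
  write_matrix(bundle$rna_tpm, fp("rna_tpm.tsv"))
  readr::write_tsv(bundle$genes, fp("genes.tsv"), progress = FALSE)
  write_bedgraph(bundle$track, fp("conservation.bedGraph"))
  write_fasta(bundle$sequences, fp("regions.fasta"))
  write_meme(bundle$pwms, fp("motifs.meme"))
  readr::write_tsv(bundle$design_atac, fp("design_atac.tsv"), progress = FALSE)
  readr::write_tsv(bundle$design_rna, fp("design_rna.tsv"), progress = FALSE)
  readr::write_tsv(bundle$truth, fp("truth.tsv"), progress = FALSE)
  invisible(dir)
}
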