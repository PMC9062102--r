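test_that("genome generation is deterministic and keeps TSS windows apart", {
  cfg1 <- chardyn_config(n_genes = 1L, n_chroms = 1L, chrom_length = 10000,
                         seed = 3L)
  g1 <- simulate_genome(cfg1)
  expect_equal(nrow(g1), 1L)
  expect_gte(g1$tss, 1000)
  expect_lt(g1$tss, 9000)
  expect_identical(g1, simulate_genome(cfg1))

  cfg <- chardyn_config(n_genes = 2000L, n_chroms = 1L, chrom_length = 2e7,
                        peaks_per_gene = 0L, seed = 9L)
  g <- simulate_genome(cfg)
  expect_equal(nrow(g), 2000L)
  d <- diff(sort(g$tss))
  expect_true(all(d >= 2000))

  expect_error(chardyn_config(n_genes = 100L, n_chroms = 1L,
                              chrom_length = 1e5),
               "sizing error")
})

test_that("peak placement respects proximal probability and never overlaps", {
  cfg0 <- small_config(peaks_per_gene = 0L)
  expect_equal(nrow(simulate_peaks(simulate_genome(cfg0), cfg0)), 0L)

  cfg1 <- small_config(proximal_peak_prob = 1, peaks_per_gene = 2L)
  g1 <- simulate_genome(cfg1)
  p1 <- simulate_peaks(g1, cfg1)
  centers <- floor((p1$start + p1$end) / 2)
  tss <- setNames(g1$tss, g1$gene_id)
  expect_true(all(abs(centers - tss[p1$gene_id]) <= 1000))

  b <- default_bundle()   # 10,000 peaks at proximal_peak_prob = 0.3
  expect_equal(nrow(b$peaks), 10000L)
  frac <- mean(b$peaks$proximal)
  expect_gt(frac, 0.28)
  expect_lt(frac, 0.32)
  ov <- b$peaks |>
    dplyr::group_by(chrom) |>
    dplyr::summarise(ok = all(start[-1] >= end[-dplyr::n()]),
                     .groups = "drop")
  expect_true(all(ov$ok))
})

test_that("planted state means follow the configured effect in the exact-recovery limit", {
  cfg <- small_config(open_effect = 4, nb_dispersion = 0, effect_jitter = 0,
                      effect_frac = 1, frac_patho_genes = 1,
                      frac_reg_genes = 0, proximal_peak_prob = 1,
                      peaks_per_gene = 1L, n_genes = 50L)
  g <- simulate_genome(cfg)
  p <- simulate_peaks(g, cfg)
  cm <- simulate_counts(p, g, cfg)
  vals <- as.matrix(cm$atac_counts[, -1])
  m_reg <- rowMeans(vals[, 1:2]); m_pat <- rowMeans(vals[, 3:4])
  m_th1 <- rowMeans(vals[, 5:6])
  expect_true(all(cm$truth$mode == "up-constant"))
  expect_equal(mean(m_pat / m_reg), 4, tolerance = 0.1)
  expect_equal(mean(m_th1 / m_pat), 1, tolerance = 0.05)
})

test_that("neutral genes show no planted effect and seeds reproduce matrices", {
  cfg <- small_config(frac_patho_genes = 0, frac_reg_genes = 0,
                      nb_dispersion = 0, n_genes = 100L)
  g <- simulate_genome(cfg)
  p <- simulate_peaks(g, cfg)
  cm <- simulate_counts(p, g, cfg)
  vals <- as.matrix(cm$atac_counts[, -1])
  ratio <- rowMeans(vals[, 3:4]) / rowMeans(vals[, 1:2])
  expect_equal(mean(ratio), 1, tolerance = 0.05)
  expect_true(all(cm$truth$class == "common"))

  cm2 <- simulate_counts(p, g, cfg)
  expect_identical(cm$atac_counts, cm2$atac_counts)
  expect_identical(cm$rna_tpm, cm2$rna_tpm)
})

test_that("negative-binomial noise matches the configured mean and dispersion", {
  n <- 10000L
  mu <- 100; disp <- 0.05
  x <- withr::with_seed(77L, chardyn:::draw_nb(rep(mu, n), disp))
  v <- mu + mu^2 * disp
  se_mean <- sqrt(v / n)
  expect_lt(abs(mean(x) - mu), 3 * se_mean)
  # SE of the sample variance via fourth-moment normal-ish bound
  se_var <- sqrt(2 / (n - 1)) * v * 2
  expect_lt(abs(var(x) - v), 3 * se_var)
})

test_that("truth partition sizes equal the planted program allocations", {
  b <- small_bundle()
  gt <- b$gene_truth
  expect_equal(sum(gt$program == "patho"), round(0.15 * 300))
  expect_equal(sum(gt$program == "reg"), round(0.15 * 300))
  planted <- b$truth[b$truth$class != "common", ]
  by_gene <- merge(planted, gt, by = "gene_id")
  expect_true(all(
    (by_gene$class == "patho-ChAR") == (by_gene$program == "patho")))
  expect_true(all(table(b$truth$region_id) == 1))
})

test_that("conservation track planting hits the configured score bands", {
  for (cf in c(0, 1)) {
    cfg <- small_config(conserved_frac = cf, n_genes = 40L)
    g <- simulate_genome(cfg)
    p <- simulate_peaks(g, cfg)
    cons <- simulate_conservation(p, cfg)
    sc <- interval_mean_conservation(p, cons$track)
    if (cf == 1) expect_true(all(sc >= 0.7)) else expect_true(all(sc <= 0.3))
  }

  # round trip through bedGraph preserves interval means exactly
  b <- small_bundle()
  f <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(b$track, f)
  sc1 <- interval_mean_conservation(b$peaks[1:200, ], b$track)
  sc2 <- interval_mean_conservation(b$peaks[1:200, ], read_bedgraph(f))
  expect_equal(sc1, sc2)
})

test_that("motif planting is mode-targeted, rediscoverable and deterministic", {
  cfg <- small_config(motif_plant_rate_open = 1, motif_plant_rate_bg = 0,
                      n_genes = 150L)
  g <- simulate_genome(cfg)
  p <- simulate_peaks(g, cfg)
  cm <- simulate_counts(p, g, cfg)
  pw <- default_motifs()["TF_early"]
  sq <- simulate_sequences(p, cm$truth, pw, cfg)
  cons <- attr(pw$TF_early, "consensus")
  up_const <- cm$truth$region_id[cm$truth$mode == "up-constant"]
  hit_fwd <- grepl(cons, sq$sequences, fixed = TRUE)
  hit_rev <- grepl(chardyn:::revcomp(cons), sq$sequences, fixed = TRUE)
  has <- setNames(hit_fwd | hit_rev, names(sq$sequences))
  expect_true(all(has[up_const]))
  # placements are planted only in the motif's target mode; other regions
  # can contain the 10-mer only by chance (expected ~1 in ~450 kb of
  # uniform background)
  expect_true(all(sq$placements$region_id %in% up_const))
  expect_lte(sum(has[setdiff(names(sq$sequences), up_const)]), 5)

  # every recorded placement is rediscoverable by exact string search
  b <- small_bundle()
  for (i in seq_len(nrow(b$placements))) {
    pl <- b$placements[i, ]
    w <- nchar(attr(b$pwms[[pl$motif_id]], "consensus"))
    found <- substr(b$sequences[[pl$region_id]], pl$offset + 1, pl$offset + w)
    want <- attr(b$pwms[[pl$motif_id]], "consensus")
    if (pl$strand == "-") want <- chardyn:::revcomp(want)
    expect_identical(found, want)
  }

  sq2 <- simulate_sequences(p, cm$truth, pw, cfg)
  expect_identical(sq$sequences, sq2$sequences)
})

test_that("bundle files round-trip through the readers", {
  b <- small_bundle()
  dir <- withr::local_tempdir()
  write_chardyn_bundle(b, dir)
  inputs <- load_chardyn_inputs(dir)
  expect_equal(inputs$peaks$name, b$peaks$name)
  expect_equal(as.data.frame(inputs$atac_counts),
               as.data.frame(b$atac_counts))
  expect_equal(inputs$sequences, b$sequences)
  expect_equal(inputs$track, b$track)
  expect_named(inputs$pwms, names(b$pwms))
})
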