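test_that("nearest-TSS annotation handles centers, signs and windows", {
  genes <- tibble::tibble(gene_id = "g1", chrom = "chr1", tss = 1000,
                          strand = "+")
  r <- tibble::tibble(chrom = "chr1", start = 990, end = 1010,
                      name = "chr1:990-1010")
  got <- annotate_nearest_tss(r, genes)
  expect_equal(got$signed_distance, 0)
  expect_true(got$proximal)

  # center 1999 bp left of the TSS on + strand: signed -1999, distal
  r2 <- tibble::tibble(chrom = "chr1", start = 2001, end = 2001 + 2000,
                       name = "x")
  g2 <- tibble::tibble(gene_id = "g1", chrom = "chr1", tss = 5000,
                       strand = "+")
  got2 <- annotate_nearest_tss(r2, g2)
  expect_equal(got2$signed_distance, -1999)
  expect_false(got2$proximal)

  # minus strand flips the sign only
  g3 <- g2 |> dplyr::mutate(strand = "-")
  expect_equal(annotate_nearest_tss(r2, g3)$signed_distance, 1999)

  # region on a gene-less chromosome
  r4 <- tibble::tibble(chrom = "chrX", start = 0, end = 10, name = "orphan")
  expect_error(annotate_nearest_tss(r4, genes), "unlinked")
  expect_warning(
    got4 <- annotate_nearest_tss(dplyr::bind_rows(r, r4), genes,
                                 on_missing_chrom = "drop"),
    "dropping")
  expect_equal(got4$region_id, "chr1:990-1010")
})

test_that("nearest-TSS equals the brute-force all-pairs oracle with tie rule", {
  withr::with_seed(31, {
    genes <- tibble::tibble(
      gene_id = sprintf("g%02d", sample(50)),
      chrom = sample(c("chr1", "chr2"), 50, replace = TRUE),
      tss = sample.int(100000L, 50),
      strand = sample(c("+", "-"), 50, replace = TRUE))
    start <- sample.int(99000L, 500)
    regions <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 500,
                                             replace = TRUE),
                              start = start, end = start + 500)
    regions$name <- paste0("r", seq_len(500))
  })
  got <- annotate_nearest_tss(regions, genes)
  for (i in seq_len(nrow(regions))) {
    center <- floor((regions$start[i] + regions$end[i]) / 2)
    cand <- genes[genes$chrom == regions$chrom[i], ]
    d <- abs(center - cand$tss)
    best <- cand[d == min(d), ]
    best <- best[order(best$gene_id), ][1, ]
    row <- got[got$region_id == regions$name[i], ]
    expect_equal(row$gene_id, best$gene_id)
    expect_equal(abs(row$signed_distance), min(d))
  }
})

test_that("proximal profiles report exact percentages and reject empties", {
  links <- tibble::tibble(region_id = c("a", "b", "c", "d"),
                          gene_id = "g", signed_distance = c(0, 5e3, -2e4, 9e3),
                          proximal = c(TRUE, FALSE, FALSE, FALSE))
  got <- proximal_profile(links)
  expect_equal(got$proximal_pct, 25)
  expect_equal(sum(got$histogram$count), 4L)
  expect_equal(proximal_profile(links, subset = "a")$proximal_pct, 100)
  expect_error(proximal_profile(links, subset = character(0)),
               "undefined-percentage")
})

test_that("interval-mean conservation is the exact length-weighted mean0 average", {
  r <- tibble::tibble(chrom = "c", start = 0, end = 100, name = "r")
  full <- tibble::tibble(chrom = "c", start = 0, end = 100, score = 0.8)
  expect_equal(unname(interval_mean_conservation(r, full)), 0.8)

  half <- tibble::tibble(chrom = "c", start = 0, end = 50, score = 1)
  expect_equal(unname(interval_mean_conservation(r, half)), 0.5)

  # random track + random regions vs per-base summation oracle
  withr::with_seed(8, {
    starts <- sort(sample.int(9500L, 40))
    track <- tibble::tibble(chrom = "c", start = starts,
                            end = starts + sample.int(100L, 40, replace = TRUE),
                            score = round(runif(40), 3))
    track <- track[c(TRUE, diff(starts) > 100), ]  # enforce non-overlap
    rs <- sample.int(9000L, 25)
    regions <- tibble::tibble(chrom = "c", start = rs,
                              end = rs + sample.int(900L, 25, replace = TRUE),
                              name = paste0("r", 1:25))
  })
  base <- numeric(20000)
  for (i in seq_len(nrow(track))) {
    base[(track$start[i] + 1):track$end[i]] <- track$score[i]
  }
  want <- vapply(seq_len(nrow(regions)), function(i) {
    mean(base[(regions$start[i] + 1):regions$end[i]])
  }, numeric(1))
  got <- interval_mean_conservation(regions, track)
  expect_equal(unname(got), want)

  # invariant under splitting a record into adjacent equal-score pieces
  split_track <- tibble::tibble(chrom = "c", start = c(0, 30), end = c(30, 100),
                                score = 0.8)
  expect_equal(interval_mean_conservation(r, split_track),
               interval_mean_conservation(r, full))
})

test_that("conserved filtering is strict at the cutoff and recovers planted truth", {
  r <- tibble::tibble(chrom = "c", start = c(0, 100), end = c(100, 200),
                      name = c("hi", "lo"))
  tr <- tibble::tibble(chrom = "c", start = c(0, 100), end = c(100, 200),
                       score = c(0.51, 0.5))
  got <- conserved_filter(r, tr)
  expect_equal(got$conserved, c(TRUE, FALSE))

  b <- small_bundle()
  flags <- conserved_filter(b$peaks, b$track)
  joined <- merge(flags, b$truth[, c("region_id", "conserved")],
                  by = "region_id")
  expect_true(all(joined$conserved.x == joined$conserved.y))
})

test_that("correlation categories follow the signed two-fold rule", {
  chars <- tibble::tibble(region_id = c("p1", "p2", "p3", "r1"),
                          fc = c(3, 3, 3, 0.2),
                          label = c(rep("patho-ChAR", 3), "reg-ChAR"))
  gene_fc <- c(p1 = 3, p2 = 0.4, p3 = 1.3, r1 = 0.3)
  got <- correlation_category(chars, gene_fc)
  expect_equal(got$category, c("positive", "negative", "irrelevant",
                               "positive"))

  bad <- tibble::tibble(region_id = "c1", fc = 1, label = "common")
  expect_error(correlation_category(bad, c(c1 = 1)), "domain error")
})
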