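point_mass_pwm <- function(consensus, id = "pm") {
  bases <- strsplit(consensus, "")[[1]]
  probs <- t(vapply(bases, function(b) {
    p <- setNames(rep(0, 4), c("A", "C", "G", "T")); p[b] <- 1; p
  }, numeric(4)))
  rownames(probs) <- NULL
  list(motif_id = id, probs = probs,
       background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
}

test_that("log-odds scanning scores consensus hits on both strands", {
  pwm <- point_mass_pwm("ACGT")
  hits <- scan_pwm(c(r1 = "TTACGTTT"), pwm, threshold_bits = 8)
  # ACGT is its own reverse complement: one hit per strand at offset 2
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$offset, c(2L, 2L))
  expect_setequal(hits$strand, c("+", "-"))
  expect_equal(hits$score, c(8, 8))   # 4 x log2(1/0.25)

  none <- scan_pwm(c(r1 = "TTTTTTTT"), pwm, threshold_bits = 8)
  expect_equal(nrow(none), 0L)

  # motif longer than the sequence yields an empty result, not an error
  short <- scan_pwm(c(r1 = "AC"), pwm, threshold_bits = 1)
  expect_equal(nrow(short), 0L)
})

test_that("scanning equals brute-force per-offset rescoring, including N bases", {
  cases <- list(
    list(seq = random_seq(300, 101), pwm = random_pwm(6, 1), thr = 3),
    list(seq = random_seq(200, 102, with_n = TRUE), pwm = random_pwm(5, 2),
         thr = 2),
    list(seq = random_seq(400, 103), pwm = random_pwm(9, 3), thr = 5))
  for (cs in cases) {
    got <- scan_pwm(setNames(cs$seq, "r"), cs$pwm, threshold_bits = cs$thr) |>
      dplyr::arrange(offset, strand) |>
      dplyr::select(offset, strand, score)
    want <- brute_scan(cs$seq, cs$pwm, cs$thr)
    expect_equal(as.data.frame(got), as.data.frame(want), tolerance = 1e-10)
  }
})

test_that("scanning a reverse-complemented sequence swaps strands and mirrors offsets", {
  s <- random_seq(250, 77)
  pwm <- random_pwm(7, 9)
  fwd <- scan_pwm(setNames(s, "r"), pwm, threshold_bits = 4)
  rc <- chardyn:::revcomp(s)
  rev <- scan_pwm(setNames(rc, "r"), pwm, threshold_bits = 4)
  L <- nchar(s); w <- 7
  mirrored <- rev |>
    dplyr::mutate(offset = L - w - offset,
                  strand = ifelse(strand == "+", "-", "+")) |>
    dplyr::arrange(offset, strand)
  expect_equal(
    as.data.frame(fwd[, c("offset", "strand", "score")]),
    as.data.frame(mirrored[, c("offset", "strand", "score")]),
    tolerance = 1e-10)
})

test_that("hit counting by dynamics class separates steps with double counting", {
  labels <- tibble::tibble(
    region_id = c("uc", "uu", "cu", "dc", "ir"),
    gene_id = "g", expected_direction = "opening",
    fc1 = 1, fc2 = 1, step1 = "up", step2 = "up",
    klass = c("opening", "opening", "opening", "closing", "irrelevant"),
    mode = c("up-constant", "up-up", "constant-up", "down-constant", "none"))
  hits <- tibble::tibble(
    motif_id = c("m1", "m1", "m1", "m2", "m2", "m3"),
    region_id = c("uc", "uc", "ir", "uu", "dc", "cu"),
    offset = 0L, strand = "+", score = 10)
  got <- count_by_dynamics(hits, labels)
  m1 <- got[got$motif_id == "m1", ]
  expect_equal(m1$n_opening, 2L)   # the 'ir' hit does not count
  expect_equal(m1$n_step1, 2L)
  expect_equal(m1$n_step2, 0L)
  m2 <- got[got$motif_id == "m2", ]
  expect_equal(c(m2$n_opening, m2$n_closing), c(1L, 1L))
  expect_equal(m2$n_step1, m2$n_step2)   # up-up counts in both
  m3 <- got[got$motif_id == "m3", ]
  expect_equal(c(m3$n_step1, m3$n_step2), c(0L, 1L))

  # exhaustive join oracle on random assignments
  withr::with_seed(55, {
    rnd_hits <- tibble::tibble(
      motif_id = sample(c("a", "b"), 200, replace = TRUE),
      region_id = sample(labels$region_id, 200, replace = TRUE),
      offset = 0L, strand = "+", score = 1)
  })
  got2 <- count_by_dynamics(rnd_hits, labels)
  join <- merge(rnd_hits, labels, by = "region_id")
  for (m in c("a", "b")) {
    jm <- join[join$motif_id == m, ]
    expect_equal(got2$n_opening[got2$motif_id == m],
                 sum(jm$klass == "opening"))
    expect_equal(got2$n_step2[got2$motif_id == m],
                 sum(jm$mode %in% c("constant-up", "up-up")))
  }
})

test_that("TF calls use the total-hit floor and pseudocounted ratio", {
  counts <- tibble::tibble(motif_id = c("hi", "few", "lo"),
                           n_opening = c(30L, 5L, 10L),
                           n_closing = c(10L, 5L, 30L),
                           n_step1 = c(10L, 1L, 1L),
                           n_step2 = c(5L, 1L, 1L))
  got <- classify_tfs(counts)
  expect_equal(got$ratio, c(31 / 11, 1, 11 / 31))
  expect_equal(got$call, c("patho-TF", "neither", "reg-TF"))
  # total exactly 20 is excluded (strict >)
  g20 <- classify_tfs(tibble::tibble(motif_id = "x", n_opening = 18L,
                                     n_closing = 2L, n_step1 = 1L,
                                     n_step2 = 0L))
  expect_equal(g20$call, "neither")
})

test_that("patho-TF ranking is by first-step proportion with id tie-break", {
  tf <- classify_tfs(tibble::tibble(
    motif_id = c("mC", "mA", "mB", "mD"),
    n_opening = c(40L, 40L, 40L, 40L),
    n_closing = c(2L, 2L, 2L, 2L),
    n_step1 = c(36L, 20L, 20L, 4L),
    n_step2 = c(4L, 20L, 20L, 36L)))
  got <- rank_patho_tfs(tf)
  expect_equal(got$motif_id, c("mC", "mA", "mB", "mD"))
  expect_equal(nrow(rank_patho_tfs(tf[0, ])), 0L)
})

test_that("planted early motifs out-rank and out-proximal planted late motifs", {
  run <- default_run()
  rank_ids <- run$patho_rank$motif_id
  expect_true(all(c("TF_early", "TF_late") %in% rank_ids))
  expect_lt(which(rank_ids == "TF_early"), which(rank_ids == "TF_late"))
  expect_equal(run$tf_classes$call[run$tf_classes$motif_id == "TF_close"],
               "reg-TF")

  early <- motif_tss_profile(run$hits, run$dynamics, run$links, "TF_early")
  late <- motif_tss_profile(run$hits, run$dynamics, run$links, "TF_late")
  expect_gt(early, late)

  # hand-count oracle
  opening <- run$dynamics$region_id[run$dynamics$klass == "opening"]
  h <- run$hits[run$hits$motif_id == "TF_early" &
                  run$hits$region_id %in% opening, ]
  prox <- run$links$region_id[run$links$proximal]
  expect_equal(early, 100 * mean(h$region_id %in% prox))

  expect_error(motif_tss_profile(run$hits, run$dynamics, run$links,
                                 "absent_motif"), "undefined-percentage")
})
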