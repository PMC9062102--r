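# Shared synthetic fixtures, built once per test run and cached.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

small_config <- function(seed = 11L, ...) {
  defaults <- list(n_genes = 300L, n_chroms = 2L, chrom_length = 2e7,
                   seed = seed)
  do.call(chardyn_config, utils::modifyList(defaults, list(...)))
}

small_bundle <- function() cached("small_bundle", function() {
  simulate_chardyn(small_config())
})

small_run <- function() cached("small_run", function() {
  run_pipeline(small_bundle())
})

# study-scale bundle under the default configuration (the study conditions)
default_bundle <- function() cached("default_bundle", function() {
  simulate_chardyn(chardyn_config(seed = 2026L))
})

default_run <- function() cached("default_run", function() {
  run_pipeline(default_bundle())
})

# brute-force per-base union of intervals on a toy chromosome
per_base_union <- function(intervals, chrom_len) {
  covered <- logical(chrom_len)
  for (i in seq_len(nrow(intervals))) {
    covered[(intervals$start[i] + 1):intervals$end[i]] <- TRUE
  }
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  tibble::tibble(start = starts[r$values], end = ends[r$values])
}

# brute-force per-offset, per-strand PWM rescoring
brute_scan <- function(seq, pwm, threshold) {
  w <- nrow(pwm$probs)
  L <- nchar(seq)
  score_window <- function(window) {
    bases <- strsplit(window, "")[[1]]
    sum(vapply(seq_len(w), function(k) {
      b <- bases[k]
      if (b == "N") return(0)
      log2(pwm$probs[k, b] / pwm$background[b])
    }, numeric(1)))
  }
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  out <- list()
  for (off in 0:(L - w)) {
    win <- substr(seq, off + 1, off + w)
    sp <- score_window(win)
    if (sp >= threshold) {
      out[[length(out) + 1]] <- tibble::tibble(offset = off, strand = "+",
                                               score = sp)
    }
    sm <- score_window(rc(win))
    if (sm >= threshold) {
      out[[length(out) + 1]] <- tibble::tibble(offset = off, strand = "-",
                                               score = sm)
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(offset = integer(), strand = character(),
                          score = double()))
  }
  dplyr::arrange(dplyr::bind_rows(out), offset, strand)
}

random_pwm <- function(width, seed) {
  withr::with_seed(seed, {
    probs <- matrix(stats::rgamma(width * 4, 1), ncol = 4)
    probs <- probs / rowSums(probs)
    colnames(probs) <- c("A", "C", "G", "T")
    list(motif_id = sprintf("rand_w%d_s%d", width, seed), probs = probs,
         background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
  })
}

random_seq <- function(len, seed, with_n = FALSE) {
  withr::with_seed(seed, {
    alpha <- if (with_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
    paste(sample(alpha, len, replace = TRUE), collapse = "")
  })
}
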