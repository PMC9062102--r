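#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate select filter arrange group_by ungroup summarise
#'   left_join inner_join anti_join bind_rows bind_cols rename n row_number
#'   distinct pull across all_of any_of case_when if_else lag lead first desc
#'   group_modify
#' @importFrom stats setNames
NULL

# All genomic coordinates in this package are 0-based, half-open [start, end):
# the native BED/bedGraph convention. No reader or writer ever shifts them.

#' Read a BED file of genomic intervals
#'
#' Accepts BED3 or BED4+ (extra columns beyond the fourth are ignored).
#' `track` and `browser` header lines are tolerated and skipped. Malformed
#' lines are rejected with the offending line number; nothing is silently
#' repaired.
#'
#' @param path Path to a tab-separated BED file.
#' @return A tibble with columns `chrom`, `start`, `end`, `name` (`name` is
#'   `NA` for BED3 rows). Coordinates are 0-based half-open, in file order.
#' @export
read_bed <- function(path) {
  lines <- readr::read_lines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(tibble(chrom = character(), start = double(), end = double(),
                  name = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    abort(sprintf("BED parse error at line %d: fewer than 3 tab-separated fields",
                  lineno[which(nf < 3L)[1]]))
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  end   <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  name  <- ifelse(nf >= 4L, vapply(fields, function(f) f[min(4L, length(f))],
                                   character(1)), NA_character_)
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end |
                 !nzchar(chrom))
  if (length(bad) > 0L) {
    abort(sprintf(
      "BED parse error at line %d: need chrom, 0 <= start < end (got '%s')",
      lineno[bad[1]], lines[bad[1]]))
  }
  tibble(chrom = chrom, start = start, end = end, name = name)
}

#' Write intervals as BED4
#'
#' @param intervals Tibble with `chrom`, `start`, `end` and optionally `name`;
#'   missing names are auto-assigned as `chrom:start-end`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  nm <- if ("name" %in% names(intervals)) intervals$name else NA_character_
  nm <- ifelse(is.na(nm) | !nzchar(nm), region_id(intervals), nm)
  out <- sprintf("%s\t%d\t%d\t%s", intervals$chrom,
                 as.integer(intervals$start), as.integer(intervals$end), nm)
  readr::write_lines(out, path)
  invisible(path)
}

#' Canonical region identifier for intervals
#'
#' @param intervals Tibble with `chrom`, `start`, `end`.
#' @return Character vector `chrom:start-end`.
#' @export
region_id <- function(intervals) {
  sprintf("%s:%d-%d", intervals$chrom, as.integer(intervals$start),
          as.integer(intervals$end))
}

#' Read a feature-by-sample matrix from TSV
#'
#' First column holds feature identifiers, header row holds sample
#' identifiers. Duplicate ids, ragged rows, negative or non-finite values are
#' rejected.
#'
#' @param path Path to a TSV file.
#' @return A tibble whose first column is `feature_id` followed by one numeric
#'   column per sample.
#' @export
read_matrix <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  prob <- readr::problems(m)
  if (nrow(prob) > 0L) {
    abort(sprintf("matrix parse error at line %d: %s",
                  prob$row[1] + 1L, prob$expected[1]))
  }
  if (ncol(m) < 2L) abort("matrix parse error: need an id column plus >=1 sample column")
  names(m)[1] <- "feature_id"
  m$feature_id <- as.character(m$feature_id)
  if (anyDuplicated(m$feature_id)) {
    abort(sprintf("matrix parse error: duplicated feature id '%s'",
                  m$feature_id[duplicated(m$feature_id)][1]))
  }
  if (anyDuplicated(names(m))) {
    abort(sprintf("matrix parse error: duplicated sample id '%s'",
                  names(m)[duplicated(names(m))][1]))
  }
  vals <- as.matrix(m[, -1, drop = FALSE])
  if (!is.numeric(vals)) abort("matrix parse error: non-numeric sample column")
  if (any(!is.finite(vals)) || any(vals < 0)) {
    abort("matrix parse error: values must be finite and >= 0")
  }
  m
}

#' Write a feature-by-sample matrix to TSV
#'
#' Integers round-trip exactly; reals are rendered with 12 significant digits.
#'
#' @param mat Tibble as returned by [read_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(mat, path) {
  vals <- as.matrix(mat[, -1, drop = FALSE])
  body <- apply(vals, 1L, function(r) {
    paste(vapply(r, function(v) {
      if (is.finite(v) && v == round(v)) sprintf("%d", as.integer(v))
      else format(v, digits = 12, scientific = FALSE)
    }, character(1)), collapse = "\t")
  })
  header <- paste(c(names(mat)[1], names(mat)[-1]), collapse = "\t")
  readr::write_lines(c(header, paste(mat$feature_id, body, sep = "\t")), path)
  invisible(path)
}

matrix_values <- function(mat) {
  v <- as.matrix(mat[, -1, drop = FALSE])
  rownames(v) <- mat$feature_id
  v
}

#' Read a conservation track from bedGraph
#'
#' Four tab- or space-separated columns: chrom, start, end, score. Records
#' are sorted on read; overlapping records within a chromosome are an error.
#' Bases not covered by any record score 0 by convention.
#'
#' @param path Path to a bedGraph file.
#' @param strict_unit Require scores in `[0, 1]` (default `TRUE`, appropriate
#'   for phastCons-style conservation).
#' @return A tibble `chrom`, `start`, `end`, `score`, sorted by
#'   (chrom, start).
#' @export
read_bedgraph <- function(path, strict_unit = TRUE) {
  lines <- readr::read_lines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(tibble(chrom = character(), start = double(), end = double(),
                  score = double()))
  }
  fields <- strsplit(lines, "[ \t]+")
  if (any(lengths(fields) != 4L)) {
    abort(sprintf("bedGraph parse error at line %d: expected 4 columns",
                  lineno[which(lengths(fields) != 4L)[1]]))
  }
  g <- tibble(
    chrom = vapply(fields, `[[`, character(1), 1L),
    start = suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L))),
    end   = suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L))),
    score = suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 4L)))
  )
  bad <- which(is.na(g$start) | is.na(g$end) | is.na(g$score) |
                 g$start < 0 | g$start >= g$end)
  if (length(bad) > 0L) {
    abort(sprintf("bedGraph parse error at line %d: '%s'",
                  lineno[bad[1]], lines[bad[1]]))
  }
  if (strict_unit && any(g$score < 0 | g$score > 1)) {
    abort("bedGraph parse error: score outside [0, 1]")
  }
  g <- arrange(g, .data$chrom, .data$start)
  ov <- g |>
    group_by(.data$chrom) |>
    filter(row_number() > 1L, .data$start < lag(.data$end)) |>
    ungroup()
  if (nrow(ov) > 0L) {
    abort(sprintf("bedGraph parse error: overlapping records on %s near %d",
                  ov$chrom[1], as.integer(ov$start[1])))
  }
  g
}

#' Write a conservation track as bedGraph
#'
#' @param track Tibble `chrom`, `start`, `end`, `score`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  out <- sprintf("%s\t%d\t%d\t%s", track$chrom, as.integer(track$start),
                 as.integer(track$end),
                 format(track$score, digits = 10, scientific = FALSE,
                        trim = TRUE))
  readr::write_lines(out, path)
  invisible(path)
}

#' Read position weight matrices from a MEME minimal-format file
#'
#' Parses the minimal text format: a `MEME version` line, an alphabet of
#' ACGT, an optional `Background letter frequencies` block, and one or more
#' `MOTIF` blocks each carrying a `letter-probability matrix`. A missing
#' background defaults to uniform 0.25.
#'
#' @param path Path to a MEME minimal file.
#' @param tol Row-sum tolerance for probability rows (default `1e-3`).
#' @return A named list of PWMs; each element is a list with `motif_id`,
#'   `probs` (width x 4 matrix, columns A,C,G,T) and `background` (length-4
#'   named numeric).
#' @export
read_meme <- function(path, tol = 1e-3) {
  lines <- trimws(readr::read_lines(path))
  if (!any(grepl("^MEME version", lines))) {
    abort("MEME parse error: missing 'MEME version' line")
  }
  alpha_i <- grep("^ALPHABET", lines)
  if (length(alpha_i) > 0L) {
    alpha <- gsub("^ALPHABET\\s*=\\s*", "", lines[alpha_i[1]])
    if (toupper(trimws(alpha)) != "ACGT") {
      abort(sprintf("MEME parse error: alphabet '%s' is not ACGT", alpha))
    }
  }
  background <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bg_i <- grep("^Background letter frequencies", lines)
  if (length(bg_i) > 0L) {
    toks <- unlist(strsplit(paste(lines[bg_i[1] + 1L]), "\\s+"))
    toks <- toks[nzchar(toks)]
    if (length(toks) %% 2L != 0L) abort("MEME parse error: malformed background line")
    bases <- toks[seq(1, length(toks), 2)]
    freqs <- as.numeric(toks[seq(2, length(toks), 2)])
    if (!setequal(bases, c("A", "C", "G", "T")) ||
        abs(sum(freqs) - 1) > tol) {
      abort("MEME parse error: background must cover ACGT and sum to 1")
    }
    background <- setNames(freqs, bases)[c("A", "C", "G", "T")]
  }
  motif_i <- grep("^MOTIF\\b", lines)
  if (length(motif_i) == 0L) abort("MEME parse error: no MOTIF block found")
  pwms <- lapply(seq_along(motif_i), function(j) {
    i <- motif_i[j]
    stop_at <- if (j < length(motif_i)) motif_i[j + 1L] - 1L else length(lines)
    id <- strsplit(lines[i], "\\s+")[[1]][2]
    if (is.na(id)) abort(sprintf("MEME parse error: MOTIF line without id ('%s')", lines[i]))
    block <- lines[i:stop_at]
    lp <- grep("^letter-probability matrix", block)
    if (length(lp) == 0L) {
      abort(sprintf("MEME parse error: motif '%s' lacks a letter-probability matrix", id))
    }
    rows <- block[-seq_len(lp[1])]
    rows <- rows[nzchar(rows) & grepl("^[-+0-9.eE[:space:]]+$", rows)]
    if (length(rows) == 0L) {
      abort(sprintf("MEME parse error: motif '%s' has an empty matrix", id))
    }
    probs <- do.call(rbind, lapply(rows, function(r) {
      as.numeric(strsplit(r, "\\s+")[[1]])
    }))
    if (ncol(probs) != 4L || any(is.na(probs))) {
      abort(sprintf("MEME parse error: motif '%s' matrix rows must have 4 numbers", id))
    }
    if (any(abs(rowSums(probs) - 1) > tol)) {
      abort(sprintf("MEME parse error: motif '%s' has a probability row not summing to 1", id))
    }
    colnames(probs) <- c("A", "C", "G", "T")
    list(motif_id = id, probs = probs, background = background)
  })
  setNames(pwms, vapply(pwms, `[[`, character(1), "motif_id"))
}

#' Write PWMs to a MEME minimal-format file
#'
#' @param pwms Named list of PWMs as returned by [read_meme()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meme <- function(pwms, path) {
  bg <- pwms[[1]]$background
  out <- c("MEME version 4", "", "ALPHABET= ACGT", "",
           "strands: + -", "",
           "Background letter frequencies",
           sprintf("A %.6f C %.6f G %.6f T %.6f", bg[1], bg[2], bg[3], bg[4]),
           "")
  for (p in pwms) {
    out <- c(out,
             sprintf("MOTIF %s", p$motif_id),
             sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                     nrow(p$probs)),
             apply(p$probs, 1L, function(r) paste(sprintf("%.6f", r), collapse = " ")),
             "")
  }
  readr::write_lines(out, path)
  invisible(path)
}

#' Read region sequences from FASTA
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences over A,C,G,T,N.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    abort(sprintf("FASTA parse error: duplicated id '%s'",
                  ids[duplicated(ids)][1]))
  }
  seqs <- toupper(as.character(ss))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    abort(sprintf("FASTA parse error: non-ACGTN symbol in record '%s'",
                  ids[bad][1]))
  }
  setNames(seqs, ids)
}

#' Write sequences to FASTA (80-column wrapped)
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Read a sample design table
#'
#' @param path TSV with columns `sample_id`, `state`, `replicate`.
#' @return Validated tibble.
#' @export
read_design <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_design(d)
}

validate_design <- function(design) {
  stopifnot(all(c("sample_id", "state", "replicate") %in% names(design)))
  if (anyDuplicated(design$sample_id)) abort("design error: duplicated sample_id")
  bad <- setdiff(unique(design$state), c("regTh17", "pathoTh17", "Th1"))
  if (length(bad) > 0L) {
    abort(sprintf("design error: unknown state '%s' (expected regTh17, pathoTh17, Th1)",
                  bad[1]))
  }
  as_tibble(design)
}

#' Read gene sets from a GMT file
#'
#' One set per line: set id, description, then member gene ids, tab-separated.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3L)) {
    abort(sprintf("GMT parse error at line %d: need set id, description, >=1 gene",
                  which(lengths(fields) < 3L)[1]))
  }
  setNames(lapply(fields, function(f) unique(f[-(1:2)])),
           vapply(fields, `[[`, character(1), 1L))
}
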