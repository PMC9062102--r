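#' Two-sided Mann-Whitney U test
#'
#' U is computed from rank sums with average ranks for ties. For combined
#' sample sizes up to `exact_max` the two-sided p-value is computed by exact
#' enumeration of all rank assignments (valid under ties); above that, a
#' normal approximation with tie correction is used (no continuity
#' correction). When every value is identical the p-value is 1 by
#' convention.
#'
#' @param a,b Numeric sample vectors (each non-empty).
#' @param exact_max Combined size at or below which enumeration is used
#'   (default 20).
#' @return A list with `U` (statistic of the first sample) and `p_value`.
#' @export
mann_whitney_u <- function(a, b, exact_max = 20) {
  stopifnot(length(a) >= 1L, length(b) >= 1L)
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  u_a <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  if (n <= exact_max) {
    dev <- abs(u_a - mu)
    combos <- utils::combn(n, na)
    u_all <- colSums(matrix(r[combos], nrow = na)) - na * (na + 1) / 2
    p <- mean(abs(u_all - mu) >= dev - 1e-9)
  } else {
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) return(list(U = u_a, p_value = 1))
    z <- (u_a - mu) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(U = u_a, p_value = p)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Spearman rho.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) abort("spearman error: need at least 3 observations")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    abort("undefined-correlation error: constant vector")
  }
  stats::cor(x, y, method = "spearman")
}

#' Hypergeometric over-representation of gene sets in a query
#'
#' For each set, tests whether the overlap between the query and the set is
#' larger than expected when drawing `|query|` genes uniformly from the
#' universe: `p = P(X >= k)` for `X ~ Hypergeometric(N, K, n)` (upper tail,
#' so `k = 0` gives `p = 1`). Sets are intersected with the universe before
#' testing.
#'
#' @param query Character vector of query gene ids (must lie in `universe`).
#' @param sets Named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param universe Character vector of background gene ids.
#' @param p_adjust `"none"` (default; raw hypergeometric significance) or
#'   `"BH"` for Benjamini-Hochberg adjusted p-values in an extra column.
#' @return Tibble `set_id`, `universe_size`, `set_size`, `query_size`,
#'   `overlap`, `p_value` (and `p_adjusted` if requested).
#' @export
hypergeom_enrich <- function(query, sets, universe,
                             p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  universe <- unique(universe)
  query <- unique(query)
  if (length(universe) == 0L) abort("enrichment error: empty universe")
  if (length(query) == 0L) abort("enrichment error: empty query")
  stray <- setdiff(query, universe)
  if (length(stray) > 0L) {
    abort(sprintf("enrichment error: query gene(s) outside the universe: %s",
                  paste(utils::head(stray, 5), collapse = ", ")))
  }
  N <- length(universe); n <- length(query)
  res <- purrr::imap_dfr(sets, function(set, id) {
    set <- intersect(unique(set), universe)
    K <- length(set)
    k <- length(intersect(query, set))
    tibble(set_id = id, universe_size = N, set_size = K, query_size = n,
           overlap = k,
           p_value = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  })
  if (p_adjust == "BH") {
    res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
  }
  res
}
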