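## Weighted Kolmogorov-Smirnov running-sum enrichment: the engine behind
## both the concept-weighting step of WCSEA and the final pathway tests.
## Hits step the running sum up in proportion to |weight|^exponent,
## misses step it down by 1/(N - Nhit); the enrichment score (ES) is the
## signed extremum, and the normalized enrichment score (NES) divides ES
## by the mean same-sign ES of random gene subsets of equal size.

#' Construct a ranked gene list
#'
#' Sorts genes by weight, descending, with ties broken by gene id so
#' that results are deterministic. Genes must be unique.
#'
#' @param genes character vector of unique gene ids, or a named numeric
#'   vector of weights (in which case `weights` is ignored).
#' @param weights numeric vector parallel to `genes`.
#' @return a `ranked_list` with elements `genes` and `weights`.
#' @export
ranked_list <- function(genes, weights = NULL) {
  if (is.numeric(genes) && !is.null(names(genes))) {
    weights <- unname(genes)
    genes <- names(genes)
  }
  if (length(genes) != length(weights))
    stop2("genes and weights must have equal length")
  if (anyNA(genes) || anyNA(weights))
    stop2("ranked list cannot contain NA genes or weights")
  if (anyDuplicated(genes))
    stop2("duplicate gene id(s) in ranked list: %s",
          paste(unique(genes[duplicated(genes)]), collapse = ", "))
  o <- order(-weights, genes, method = "radix")
  structure(list(genes = as.character(genes)[o], weights = weights[o]),
            class = "ranked_list")
}

#' @export
length.ranked_list <- function(x) length(x$genes)

#' @export
print.ranked_list <- function(x, ...) {
  n <- length(x$genes)
  cat(sprintf("ranked_list: %d genes, weights [%.4g .. %.4g]\n",
              n, if (n) x$weights[1] else NA, if (n) x$weights[n] else NA))
  invisible(x)
}

#' Running-sum enrichment score of a gene set in a ranked list
#'
#' Walks the ranked list; members of `gene_set` ("hits") increment the
#' sum by `|w|^exponent` (normalized so hit increments total 1), the
#' remaining genes decrement it by `1/(N - Nhit)`. Returns the full
#' running sum, the signed extremum (ES) and the leading-edge genes (the
#' hits at or before the extremum for positive ES, at or after it for
#' negative ES). When every hit weight is zero under the chosen
#' exponent, hit increments fall back to equal steps `1/Nhit`.
#'
#' @param ranked a [ranked_list()].
#' @param gene_set character vector; must intersect the ranked genes.
#' @param exponent non-negative weighting exponent; 0 gives the
#'   rank-only (classic K-S) statistic, the default 1 the GSEA-style
#'   weighted statistic.
#' @return a list of class `wks_enrichment`: `es`, `running_sum`,
#'   `extremum` (position), `leading_edge`, `n_hit`.
#' @export
running_sum_es <- function(ranked, gene_set, exponent = 1) {
  stopifnot(inherits(ranked, "ranked_list"))
  gene_set <- assert_gene_set(gene_set)
  stopifnot(is.numeric(exponent), length(exponent) == 1L, exponent >= 0)
  N <- length(ranked$genes)
  hit <- ranked$genes %in% gene_set
  nh <- sum(hit)
  if (nh == 0L) stop2("gene set does not intersect the ranked list")
  steps <- numeric(N)
  if (nh == N) {
    ## all-hit list: no miss decrement exists; monotone climb to 1
    w <- abs(ranked$weights)^exponent
    steps <- if (sum(w) > 0) w / sum(w) else rep(1 / N, N)
    rs <- cumsum(steps)
    return(structure(list(es = 1, running_sum = rs, extremum = N,
                          leading_edge = ranked$genes, n_hit = nh),
                     class = "wks_enrichment"))
  }
  w <- abs(ranked$weights[hit])^exponent
  tot <- sum(w)
  steps[hit] <- if (tot > 0) w / tot else rep(1 / nh, nh)
  steps[!hit] <- -1 / (N - nh)
  rs <- cumsum(steps)
  i_star <- which.max(abs(rs))
  es <- rs[i_star]
  le <- if (es >= 0) ranked$genes[hit & seq_len(N) <= i_star]
        else ranked$genes[hit & seq_len(N) >= i_star]
  structure(list(es = es, running_sum = rs, extremum = i_star,
                 leading_edge = le, n_hit = nh),
            class = "wks_enrichment")
}

#' @export
print.wks_enrichment <- function(x, ...) {
  cat(sprintf("wks_enrichment: es = %.4f (extremum at %d), %d hits, %d leading-edge genes\n",
              x$es, x$extremum, x$n_hit, length(x$leading_edge)))
  invisible(x)
}

## Fast ES from sorted hit positions only (no O(N) running sum).
## Between hits the sum decreases linearly, so the extremum is either at
## a hit position (positive candidate) or just before one (negative
## candidate). `aw` is the precomputed |weight|^exponent vector over the
## whole ranked list. Matches running_sum_es() including the
## earliest-position tie-break on equal magnitudes.
es_from_positions <- function(pos, aw, N) {
  k <- length(pos)
  if (k == N) return(1)
  w <- aw[pos]
  tot <- sum(w)
  inc <- if (tot > 0) w / tot else rep(1 / k, k)
  d <- 1 / (N - k)
  cum <- cumsum(inc)
  at_hit <- cum - (pos - seq_len(k)) * d
  before <- at_hit - inc
  ip <- which.max(at_hit); inx <- which.min(before)
  hi <- at_hit[ip]; lo <- before[inx]
  if (abs(hi) > abs(lo)) return(hi)
  if (abs(lo) > abs(hi)) return(lo)
  ## equal magnitudes: earliest position wins, as in the full walk
  if (pos[ip] <= pos[inx] - 1) hi else lo
}

#' Permutation null distribution of the enrichment score
#'
#' Samples `n_perm` uniformly random gene subsets of `set_size` (without
#' replacement) from the ranked list and records their ES. The only null
#' model available to a tool that consumes gene-level lists (no
#' expression matrix, hence no sample-label permutation).
#'
#' @inheritParams running_sum_es
#' @param set_size size of the random subsets.
#' @param n_perm number of permutations (default 1000).
#' @param seed mandatory RNG seed; results are bit-reproducible.
#' @return a list of class `wks_null`: `es_samples`, `set_size`, `seed`.
#' @export
permutation_null <- function(ranked, set_size, exponent = 1,
                             n_perm = 1000L, seed) {
  stopifnot(inherits(ranked, "ranked_list"))
  if (!is_count(set_size)) stop2("set_size must be a positive integer")
  if (!is_count(n_perm)) stop2("n_perm must be a positive integer")
  N <- length(ranked$genes)
  if (set_size > N) stop2("set_size (%d) exceeds ranked list length (%d)",
                          set_size, N)
  aw <- abs(ranked$weights)^exponent
  es <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      pos <- sort.int(sample.int(N, set_size))
      es_from_positions(pos, aw, N)
    }, numeric(1))
  })
  structure(list(es_samples = es, set_size = as.integer(set_size),
                 seed = as.integer(seed)),
            class = "wks_null")
}

#' Normalize an enrichment score against a permutation null
#'
#' `NES = ES / mean(same-sign null ES)`, sign-matched in the GSEA
#' manner; the one-sided p-value is the add-one-smoothed frequency of
#' same-sign null samples at least as extreme, `(k + 1)/(n + 1)`.
#'
#' @param es observed enrichment score.
#' @param null a `wks_null` from [permutation_null()].
#' @return list with `nes` and `p_value`. If the null contains no
#'   same-sign samples, returns `nes = 0`, `p_value = 1` with a warning.
#' @export
normalize_es <- function(es, null) {
  stopifnot(inherits(null, "wks_null"), length(null$es_samples) >= 1L)
  s <- null$es_samples
  same <- if (es >= 0) s[s > 0] else s[s < 0]
  if (length(same) == 0L) {
    warn2("no same-sign null samples; returning nes = 0, p = 1")
    return(list(nes = 0, p_value = 1))
  }
  nes <- if (es >= 0) es / mean(same) else -(abs(es) / mean(abs(same)))
  k <- sum(abs(same) >= abs(es))
  list(nes = nes, p_value = (k + 1) / (length(same) + 1))
}

#' Multiple-testing adjustment
#'
#' Validating front-end for Bonferroni and Benjamini-Hochberg
#' correction; values are clipped to `[0, 1]` and BH applies the usual
#' step-up monotonicity.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param method `"bonferroni"` or `"benjamini_hochberg"`.
#' @return adjusted p-values in input order.
#' @export
adjust_pvalues <- function(p_values,
                           method = c("benjamini_hochberg", "bonferroni")) {
  method <- match.arg(method)
  if (length(p_values) == 0L) return(numeric(0))
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1))
    stop2("p_values must all lie in [0, 1]")
  stats::p.adjust(p_values,
                  method = switch(method,
                                  bonferroni = "bonferroni",
                                  benjamini_hochberg = "BH"))
}

#' Enrichment-curve coordinates for export or plotting
#'
#' @inheritParams running_sum_es
#' @return data.frame with `position`, `gene`, `hit`, `running_sum`.
#' @export
enrichment_curve <- function(ranked, gene_set, exponent = 1) {
  fit <- running_sum_es(ranked, gene_set, exponent)
  data.frame(position = seq_along(fit$running_sum),
             gene = ranked$genes,
             hit = ranked$genes %in% gene_set,
             running_sum = fit$running_sum,
             stringsAsFactors = FALSE)
}
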