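## Crosstalk disambiguation: a pathway ranked below a similar, stronger
## pathway is kept only if its genes outside the stronger pathway are
## still enriched on the uniConSig-ranked genome.

#' Disambiguate crosstalk among top enriched pathways
#'
#' For every ordered pair (stronger A, weaker B) among the `top_k`
#' pathways whose gene sets overlap appreciably (Ochiai >=
#' `overlap_ochiai` or at least `overlap_genes` shared genes), the
#' remainder B minus A is re-tested by WKS on the table's ranked
#' genome. Remainder p-values are batch-adjusted; B is removed when its
#' adjusted p fails `alpha`, or immediately when the remainder is too
#' small to test (nested or identical sets cannot be independently
#' enriched). Removal is greedy in rank order: a removed pathway is
#' excluded from later pairings and can never remove a stronger one.
#'
#' @param table a `pathway_table` from [run_csea()], [run_wcsea()] or
#'   [run_plain_wks()].
#' @param pathways the pathway `concept_compendium` the table was run
#'   against.
#' @param alpha significance level for independent enrichment (default
#'   0.01).
#' @param method multiplicity correction for the remainder p batch
#'   (default Bonferroni).
#' @param top_k number of top-ranked pathways to disambiguate (default
#'   min(30, table size)).
#' @param n_perm,seed permutation settings for the remainder tests
#'   (defaults: the table's own).
#' @param min_overlap smallest testable remainder (default 5).
#' @param overlap_ochiai,overlap_genes triggers for pair testing.
#' @return list of class `disambiguation`: `table` (pruned
#'   `pathway_table`, original rank order preserved), `records`
#'   (data.frame logging every test: pathway, competitor,
#'   remainder_size, remainder_p, adjusted_p, verdict), `removed` ids.
#' @export
disambiguate <- function(table, pathways, alpha = 0.01,
                         method = c("bonferroni", "benjamini_hochberg"),
                         top_k = NULL, n_perm = NULL, seed = NULL,
                         min_overlap = 5L, overlap_ochiai = 0.05,
                         overlap_genes = 3L) {
  stopifnot(inherits(table, "pathway_table"),
            inherits(pathways, "concept_compendium"))
  method <- match.arg(method)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop2("alpha must lie in (0, 1)")
  K <- nrow(table$results)
  top_k <- as.integer(top_k %||% min(30L, K))
  if (top_k > K) stop2("top_k (%d) exceeds table size (%d)", top_k, K)
  n_perm <- as.integer(n_perm %||% table$params$n_perm)
  seed <- as.integer(seed %||% (table$params$seed + 2L))
  ids <- table$results$pathway[seq_len(top_k)]
  gsets <- lapply(ids, function(id) {
    g <- table$pathway_genes[[id]]
    if (is.null(g)) g <- pathways$genes[[id]]
    if (is.null(g)) stop2("pathway %s not found in pathway collection", id)
    g
  })
  names(gsets) <- ids

  ## pass 1: find triggered ordered pairs and their remainder tests
  pairs <- list()
  for (a in seq_len(top_k)) {
    for (b in seq_len(top_k)) {
      if (b <= a) next
      shared <- length(intersect(gsets[[a]], gsets[[b]]))
      if (shared == 0) next
      oij <- shared / sqrt(length(gsets[[a]]) * length(gsets[[b]]))
      if (oij < overlap_ochiai && shared < overlap_genes) next
      pairs[[length(pairs) + 1L]] <-
        list(a = ids[a], b = ids[b],
             remainder = setdiff(gsets[[b]], gsets[[a]]))
    }
  }
  if (length(pairs) == 0L) {
    rec <- data.frame(pathway = character(0), competitor = character(0),
                      remainder_size = integer(0), remainder_p = numeric(0),
                      adjusted_p = numeric(0), verdict = character(0),
                      stringsAsFactors = FALSE)
    return(structure(list(table = table, records = rec,
                          removed = character(0)),
                     class = "disambiguation"))
  }
  rem_sets <- lapply(pairs, `[[`, "remainder")
  names(rem_sets) <- sprintf("pair%03d", seq_along(rem_sets))
  testable <- vapply(rem_sets, function(g)
    sum(g %in% table$ranked$genes) >= min_overlap, logical(1))
  p_raw <- rep(NA_real_, length(pairs))
  if (any(testable)) {
    stage <- wks_stage(table$ranked, rem_sets[testable], n_perm = n_perm,
                       seed = seed, exponent = table$params$exponent %||% 1,
                       min_overlap = 1L, keep_leading_edge = FALSE)
    p_raw[testable] <- stage$table$p_value[
      match(names(rem_sets)[testable], stage$table$id)]
  }
  p_adj <- rep(NA_real_, length(pairs))
  p_adj[testable] <- adjust_pvalues(p_raw[testable], method)

  ## pass 2: greedy removal in rank order
  removed <- character(0)
  verdicts <- character(length(pairs))
  for (i in seq_along(pairs)) {
    a <- pairs[[i]]$a; b <- pairs[[i]]$b
    if (a %in% removed || b %in% removed) {
      verdicts[i] <- "skipped"
      next
    }
    if (!testable[i]) {
      verdicts[i] <- "degenerate"
      removed <- c(removed, b)
    } else if (p_adj[i] >= alpha) {
      verdicts[i] <- "removed"
      removed <- c(removed, b)
    } else {
      verdicts[i] <- "kept"
    }
  }
  rec <- data.frame(
    pathway = vapply(pairs, `[[`, "", "b"),
    competitor = vapply(pairs, `[[`, "", "a"),
    remainder_size = vapply(pairs, function(p) length(p$remainder),
                            integer(1)),
    remainder_p = p_raw, adjusted_p = p_adj, verdict = verdicts,
    stringsAsFactors = FALSE)

  pruned <- table
  keep_rows <- !(table$results$pathway %in% removed) &
    table$results$rank <= top_k
  pruned$results <- table$results[keep_rows, , drop = FALSE]
  rownames(pruned$results) <- NULL
  pruned$pathway_genes <- table$pathway_genes[pruned$results$pathway]
  structure(list(table = pruned, records = rec, removed = removed),
            class = "disambiguation")
}

#' @export
print.disambiguation <- function(x, ...) {
  cat(sprintf("disambiguation: %d kept, %d removed, %d pair tests\n",
              nrow(x$table$results), length(x$removed), nrow(x$records)))
  if (length(x$removed))
    cat("removed:", paste(x$removed, collapse = ", "), "\n")
  invisible(x)
}

#' Write disambiguation records to TSV
#' @param x a `disambiguation` result.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_disambiguation <- function(x, path) {
  stopifnot(inherits(x, "disambiguation"))
  utils::write.table(x$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
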