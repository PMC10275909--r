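## End-to-end CSEA/WCSEA pathway enrichment on the uniConSig-sorted
## genome, plus the shared WKS testing stage reused by the concept
## weighting, the disambiguation re-tests and the plain-WKS baseline.

## Test a named list of gene sets against one ranked list. Permutation
## nulls are stratified by overlap size, generated in sorted-size order
## under a single seed, and shared among sets of equal overlap.
wks_stage <- function(ranked, sets, n_perm, seed, exponent = 1,
                      min_overlap = 1L, adjust_method = "benjamini_hochberg",
                      keep_leading_edge = TRUE) {
  stopifnot(inherits(ranked, "ranked_list"))
  ov <- vapply(sets, function(g) sum(g %in% ranked$genes), integer(1))
  skipped <- names(sets)[ov < min_overlap]
  test_ids <- names(sets)[ov >= min_overlap]
  if (length(skipped))
    message(sprintf("wks_stage: skipped %d set(s) with overlap < %d: %s",
                    length(skipped), min_overlap,
                    paste(utils::head(skipped, 10), collapse = ", ")))
  if (length(test_ids) == 0L) {
    return(list(table = data.frame(id = character(0), es = numeric(0),
                                   nes = numeric(0), p_value = numeric(0),
                                   q_value = numeric(0), n_overlap = integer(0),
                                   leading_edge = character(0),
                                   stringsAsFactors = FALSE),
                skipped = skipped, nulls = list()))
  }
  sizes <- sort(unique(ov[test_ids]))
  N <- length(ranked$genes)
  aw <- abs(ranked$weights)^exponent
  nulls <- with_seed(seed, {
    out <- vector("list", length(sizes))
    names(out) <- as.character(sizes)
    for (s in sizes) {
      out[[as.character(s)]] <- structure(
        list(es_samples = vapply(seq_len(n_perm), function(i)
               es_from_positions(sort.int(sample.int(N, s)), aw, N),
               numeric(1)),
             set_size = as.integer(s), seed = as.integer(seed)),
        class = "wks_null")
    }
    out
  })
  rows <- lapply(test_ids, function(id) {
    fit <- running_sum_es(ranked, sets[[id]], exponent)
    nz <- normalize_es(fit$es, nulls[[as.character(ov[[id]])]])
    data.frame(id = id, es = fit$es, nes = nz$nes, p_value = nz$p_value,
               n_overlap = ov[[id]],
               leading_edge = if (keep_leading_edge)
                 paste(fit$leading_edge, collapse = ";") else "",
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$q_value <- adjust_pvalues(tab$p_value, adjust_method)
  tab <- tab[, c("id", "es", "nes", "p_value", "q_value", "n_overlap",
                 "leading_edge")]
  list(table = tab, skipped = skipped, nulls = nulls)
}

## Assemble a pathway_table from a finished wks_stage.
as_pathway_table <- function(stage, ranked, scores, direction, params,
                             provenance, concept_weights = NULL,
                             pathway_genes = NULL) {
  tab <- stage$table
  names(tab)[names(tab) == "id"] <- "pathway"
  o <- order(-tab$nes, tab$pathway, method = "radix")
  tab <- tab[o, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab <- tab[, c("pathway", "es", "nes", "p_value", "q_value", "rank",
                 "n_overlap", "leading_edge")]
  structure(list(results = tab, direction = direction, ranked = ranked,
                 scores = scores, concept_weights = concept_weights,
                 pathway_genes = pathway_genes[tab$pathway],
                 skipped = stage$skipped, params = params,
                 provenance = provenance),
            class = "pathway_table")
}

## Ranked genome shared by CSEA/WCSEA: compendium universe plus any
## extra input genes, concept-less genes padding the tail at score 0,
## ties broken by gene id.
ranked_genome <- function(scores, extra_genes = character(0)) {
  genes <- scores$gene
  w <- scores$normalized
  extra <- setdiff(extra_genes, genes)
  ranked_list(c(genes, extra), c(w, rep(0, length(extra))))
}

#' CSEA pathway enrichment of a target gene list
#'
#' Full pipeline: Ochiai concept weights for the target, penalized
#' uniConSig scoring of the genome, weighted K-S test of every pathway
#' on the score-sorted genome, permutation NES/p, BH q-values, NES
#' ranking.
#'
#' @param target character vector of target genes (e.g. significantly
#'   up-regulated genes); must overlap the concept universe.
#' @param compendium molecular-concept `concept_compendium`.
#' @param pathways pathway collection (`concept_compendium` read from
#'   GMT).
#' @param n_perm permutations for the pathway null (default 1000).
#' @param seed mandatory RNG seed.
#' @param exponent WKS exponent (default 1).
#' @param min_pathway_overlap pathways overlapping the ranked genome in
#'   fewer genes are skipped (default 5).
#' @param adjust_method multiplicity correction for the q column.
#' @return a `pathway_table`; see [print.pathway_table()].
#' @export
run_csea <- function(target, compendium, pathways, n_perm = 1000L, seed,
                     exponent = 1, min_pathway_overlap = 5L,
                     adjust_method = "benjamini_hochberg") {
  target <- assert_gene_set(target, "target")
  stopifnot(inherits(pathways, "concept_compendium"))
  w <- csea_concept_weights(target, compendium)
  scores <- uniconsig_scores(w, compendium)
  ranked <- ranked_genome(scores, target)
  stage <- wks_stage(ranked, pathways$genes, n_perm = n_perm, seed = seed,
                     exponent = exponent, min_overlap = min_pathway_overlap,
                     adjust_method = adjust_method)
  params <- list(mode = "csea", n_perm = n_perm, seed = seed,
                 exponent = exponent,
                 min_pathway_overlap = min_pathway_overlap,
                 adjust_method = adjust_method)
  prov <- make_provenance(params, list(target = sort(target),
                                       compendium = compendium,
                                       pathways = pathways))
  as_pathway_table(stage, ranked, scores, direction = "up", params, prov,
                   concept_weights = w, pathway_genes = pathways$genes)
}

#' WCSEA pathway enrichment of a weighted gene list
#'
#' As [run_csea()], but concept weights are floored WKS NES values of
#' each concept in the weighted list. Over- and under-expression are
#' analyzed in separate runs: `direction = "down"` negates the weights
#' before ranking.
#'
#' @param weighted named numeric vector of signed gene weights (e.g.
#'   signed DE statistics), or a 2-column data.frame.
#' @param direction `"up"` or `"down"`.
#' @param min_concept_overlap concepts overlapping the weighted list in
#'   fewer genes are skipped during concept weighting (default 3).
#' @inheritParams run_csea
#' @return a `pathway_table`.
#' @export
run_wcsea <- function(weighted, compendium, pathways,
                      direction = c("up", "down"), n_perm = 1000L, seed,
                      exponent = 1, min_concept_overlap = 3L,
                      min_pathway_overlap = 5L,
                      adjust_method = "benjamini_hochberg") {
  direction <- match.arg(direction)
  stopifnot(inherits(pathways, "concept_compendium"))
  weighted <- as_weighted_list(weighted)
  if (length(unique(weighted)) == 1L)
    warn2("all input weights are equal; ranking falls back to the gene-id tie-break")
  if (direction == "down") weighted <- -weighted
  w <- wcsea_concept_weights(weighted, compendium, n_perm = n_perm,
                             seed = seed, exponent = exponent,
                             min_overlap = min_concept_overlap)
  scores <- uniconsig_scores(w, compendium)
  ranked <- ranked_genome(scores, names(weighted))
  stage <- wks_stage(ranked, pathways$genes, n_perm = n_perm,
                     seed = seed + 1L, exponent = exponent,
                     min_overlap = min_pathway_overlap,
                     adjust_method = adjust_method)
  params <- list(mode = "wcsea", direction = direction, n_perm = n_perm,
                 seed = seed, exponent = exponent,
                 min_concept_overlap = min_concept_overlap,
                 min_pathway_overlap = min_pathway_overlap,
                 adjust_method = adjust_method)
  prov <- make_provenance(params, list(weighted = weighted,
                                       compendium = compendium,
                                       pathways = pathways))
  as_pathway_table(stage, ranked, scores, direction, params, prov,
                   concept_weights = w, pathway_genes = pathways$genes)
}

#' Plain weighted K-S enrichment of a weighted list (GSEA-like baseline)
#'
#' Tests pathways directly against the ranked weighted list, without the
#' concept-signature scoring. Used as the comparison baseline in the
#' dropout benchmark.
#'
#' @inheritParams run_wcsea
#' @return a `pathway_table`.
#' @export
run_plain_wks <- function(weighted, pathways, direction = c("up", "down"),
                          n_perm = 1000L, seed, exponent = 1,
                          min_pathway_overlap = 5L,
                          adjust_method = "benjamini_hochberg") {
  direction <- match.arg(direction)
  stopifnot(inherits(pathways, "concept_compendium"))
  weighted <- as_weighted_list(weighted)
  if (direction == "down") weighted <- -weighted
  ranked <- ranked_list(weighted)
  stage <- wks_stage(ranked, pathways$genes, n_perm = n_perm, seed = seed,
                     exponent = exponent, min_overlap = min_pathway_overlap,
                     adjust_method = adjust_method)
  params <- list(mode = "plain_wks", direction = direction, n_perm = n_perm,
                 seed = seed, exponent = exponent,
                 min_pathway_overlap = min_pathway_overlap,
                 adjust_method = adjust_method)
  prov <- make_provenance(params, list(weighted = weighted,
                                       pathways = pathways))
  as_pathway_table(stage, ranked, scores = NULL, direction, params, prov,
                   pathway_genes = pathways$genes)
}

#' Count significant pathways at q-value cutoffs
#'
#' @param table a `pathway_table`.
#' @param q_cutoffs numeric vector of FDR cutoffs.
#' @return named integer vector of counts, one per cutoff.
#' @export
significant_count <- function(table, q_cutoffs) {
  stopifnot(inherits(table, "pathway_table"))
  if (length(q_cutoffs) == 0L) return(stats::setNames(integer(0), character(0)))
  stats::setNames(
    vapply(q_cutoffs, function(ct) sum(table$results$q_value <= ct),
           integer(1)),
    format(q_cutoffs, trim = TRUE))
}

#' @export
print.pathway_table <- function(x, n = 10L, ...) {
  cat(sprintf("pathway_table (%s, %s): %d pathways tested, %d skipped\n",
              x$params$mode %||% "wks", x$direction, nrow(x$results),
              length(x$skipped)))
  if (nrow(x$results)) {
    show <- utils::head(x$results[, c("rank", "pathway", "es", "nes",
                                      "p_value", "q_value", "n_overlap")], n)
    print(format(show, digits = 4), row.names = FALSE)
    if (nrow(x$results) > n)
      cat(sprintf("... and %d more rows\n", nrow(x$results) - n))
  }
  invisible(x)
}

#' @export
summary.pathway_table <- function(object, q_cutoffs = c(0.01, 0.05), ...) {
  cat(sprintf("%s enrichment, direction %s; seed %s, %d permutations\n",
              toupper(object$params$mode %||% "wks"), object$direction,
              object$params$seed, object$params$n_perm))
  cnt <- significant_count(object, q_cutoffs)
  for (i in seq_along(cnt))
    cat(sprintf("  q <= %-6s: %d pathways\n", names(cnt)[i], cnt[i]))
  invisible(object)
}

#' @export
as.data.frame.pathway_table <- function(x, ...) x$results

#' Enrichment-curve plot for one pathway
#'
#' Draws the WKS running sum over the ranked genome with hit positions
#' marked, as in the classic GSEA enrichment plot.
#'
#' @param x a `pathway_table`.
#' @param pathway pathway id (default: rank-1 pathway).
#' @param ... passed to [graphics::plot()].
#' @return the curve data.frame, invisibly.
#' @export
plot.pathway_table <- function(x, pathway = NULL, ...) {
  stopifnot(nrow(x$results) > 0L)
  pathway <- pathway %||% x$results$pathway[1]
  row <- x$results[x$results$pathway == pathway, , drop = FALSE]
  if (nrow(row) == 0L) stop2("pathway %s not in table", pathway)
  gs <- x$pathway_genes[[pathway]] %||% strsplit(row$leading_edge, ";")[[1]]
  curve <- enrichment_curve(x$ranked, gene_set = gs,
                            exponent = x$params$exponent %||% 1)
  graphics::plot(curve$position, curve$running_sum, type = "l",
                 xlab = "rank in uniConSig-sorted genome",
                 ylab = "running enrichment score",
                 main = sprintf("%s (ES = %.3f, NES = %.3f)",
                                pathway, row$es, row$nes), ...)
  graphics::abline(h = 0, lty = 2, col = "grey50")
  graphics::rug(curve$position[curve$hit])
  invisible(curve)
}

#' Write a pathway table (TSV + provenance JSON)
#'
#' The TSV holds pathway, es, nes, p, q, rank, n_overlap and the
#' semicolon-joined leading edge; the JSON sidecar carries the full
#' provenance (tool version, parameters, input hashes, seed) needed to
#' re-run bit-identically. No timestamps, so identical runs are
#' byte-identical.
#'
#' @param table a `pathway_table`.
#' @param path output TSV path; the JSON goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_pathway_table <- function(table, path) {
  stopifnot(inherits(table, "pathway_table"))
  utils::write.table(table$results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(table$provenance, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
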