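## Pathway-pathway functional association via CSEA: take one pathway's
## genes as the target list, score the genome, and read off the NES of
## every other pathway. Two pathways sharing many molecular concepts
## associate strongly even with little direct gene overlap.

#' Pathway association matrix
#'
#' Entry (i, j), i != j, is the NES of pathway j under a CSEA run with
#' pathway i's genes as the target list; the matrix is then symmetrized
#' (mean or max of the two directed scores) and the diagonal set to the
#' row maximum for display. A pathway disjoint from the concept
#' universe yields a zero row/column with a warning.
#'
#' @param pathway_ids at least two pathway ids to relate.
#' @param pathways pathway `concept_compendium` containing them.
#' @param compendium molecular-concept compendium for the CSEA runs.
#' @param n_perm,seed,exponent,min_pathway_overlap forwarded to
#'   [run_csea()].
#' @param symmetrize `"mean"` (default) or `"max"`.
#' @return an `association_matrix`: list with `ids`, `scores` (symmetric
#'   matrix), `directed` (raw directed NES), `symmetrize`.
#' @export
associate <- function(pathway_ids, pathways, compendium, n_perm = 1000L,
                      seed, exponent = 1, min_pathway_overlap = 5L,
                      symmetrize = c("mean", "max")) {
  stopifnot(inherits(pathways, "concept_compendium"),
            inherits(compendium, "concept_compendium"))
  symmetrize <- match.arg(symmetrize)
  pathway_ids <- unique(as.character(pathway_ids))
  if (length(pathway_ids) < 2L)
    stop2("need at least 2 pathways to compute associations")
  sub <- subset_compendium(pathways, pathway_ids)
  K <- length(pathway_ids)
  directed <- matrix(0, K, K, dimnames = list(pathway_ids, pathway_ids))
  uni <- universe(compendium)
  for (i in seq_len(K)) {
    target <- sub$genes[[pathway_ids[i]]]
    if (!any(target %in% uni)) {
      warn2("pathway %s shares no genes with the concept universe; zero association row",
            pathway_ids[i])
      next
    }
    ## one shared seed across targets: associations are then equivariant
    ## under relabeling of the pathway order
    tab <- run_csea(target, compendium, sub, n_perm = n_perm,
                    seed = seed, exponent = exponent,
                    min_pathway_overlap = min_pathway_overlap)
    hit <- match(pathway_ids, tab$results$pathway)
    directed[i, ] <- ifelse(is.na(hit), 0, tab$results$nes[hit])
  }
  sym <- switch(symmetrize,
                mean = (directed + t(directed)) / 2,
                max = pmax(directed, t(directed)))
  for (i in seq_len(K)) {
    off <- sym[i, -i]
    sym[i, i] <- if (length(off)) max(sym[i, i], max(off)) else sym[i, i]
  }
  ## re-impose exact symmetry after the diagonal convention
  structure(list(ids = pathway_ids, scores = sym, directed = directed,
                 symmetrize = symmetrize),
            class = "association_matrix")
}

#' @export
print.association_matrix <- function(x, ...) {
  cat(sprintf("association_matrix: %d pathways (%s-symmetrized)\n",
              length(x$ids), x$symmetrize))
  print(round(x$scores, 3))
  invisible(x)
}

#' Heatmap of a pathway association matrix
#' @param x an `association_matrix`.
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.association_matrix <- function(x, ...) {
  K <- length(x$ids)
  graphics::image(seq_len(K), seq_len(K), t(x$scores[K:1, , drop = FALSE]),
                  axes = FALSE, xlab = "", ylab = "",
                  main = "pathway functional associations", ...)
  graphics::axis(1, at = seq_len(K), labels = x$ids, las = 2, cex.axis = 0.7)
  graphics::axis(2, at = seq_len(K), labels = rev(x$ids), las = 2,
                 cex.axis = 0.7)
  invisible(x)
}

#' Association network edge list
#'
#' Edges (i, j, weight) for every unordered pair whose symmetrized
#' association is at or above `edge_threshold`; node attributes carry
#' each pathway's enrichment NES when a `pathway_table` is supplied
#' (node size ~ enrichment, edge weight ~ functional association).
#'
#' @param matrix an `association_matrix`.
#' @param enrichments optional `pathway_table` for node NES attributes.
#' @param edge_threshold non-negative inclusion threshold.
#' @return list with `edges` (data.frame from, to, weight) and `nodes`
#'   (data.frame id, nes).
#' @export
export_network <- function(matrix, enrichments = NULL, edge_threshold = 0) {
  stopifnot(inherits(matrix, "association_matrix"))
  if (!is.numeric(edge_threshold) || edge_threshold < 0)
    stop2("edge_threshold must be >= 0")
  ids <- matrix$ids
  K <- length(ids)
  from <- character(0); to <- character(0); wt <- numeric(0)
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      if (j <= i) next
      if (matrix$scores[i, j] >= edge_threshold) {
        from <- c(from, ids[i]); to <- c(to, ids[j])
        wt <- c(wt, matrix$scores[i, j])
      }
    }
  }
  nes <- rep(NA_real_, K)
  if (!is.null(enrichments)) {
    stopifnot(inherits(enrichments, "pathway_table"))
    hit <- match(ids, enrichments$results$pathway)
    nes <- ifelse(is.na(hit), NA_real_, enrichments$results$nes[hit])
  }
  list(edges = data.frame(from = from, to = to, weight = wt,
                          stringsAsFactors = FALSE),
       nodes = data.frame(id = ids, nes = nes, stringsAsFactors = FALSE))
}

#' Write an association matrix to TSV
#' @param matrix an `association_matrix`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_association_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "association_matrix"))
  d <- data.frame(pathway = matrix$ids, matrix$scores, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an association network (TSV edge list and GraphML)
#'
#' @param network result of [export_network()].
#' @param path_tsv edge-list TSV path.
#' @param path_graphml optional GraphML path (written via igraph).
#' @return `path_tsv`, invisibly.
#' @export
write_network <- function(network, path_tsv, path_graphml = NULL) {
  utils::write.table(network$edges, path_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(path_graphml)) {
    g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                       vertices = network$nodes)
    igraph::write_graph(g, path_graphml, format = "graphml")
  }
  invisible(path_tsv)
}
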