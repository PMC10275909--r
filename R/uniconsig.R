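## uniConSig scoring: turn a target gene list (CSEA) or weighted gene
## list (WCSEA) into genome-wide functional-relevance scores.
##
## Concept weight w_i: Ochiai(target, concept) for CSEA, floored
## permutation NES for WCSEA. Penalization eps_i: cumulated Ochiai
## similarity of concept i with the other concepts of the same gene
## (self term included, so eps >= 1). Effective weight EW_i = w_i/eps_i;
## effective concept number ECN = sum 1/eps_i. The score of gene x is
##   uniConSig(x) = sum_i EW_i / sqrt(ECN),
## the redundancy-adjusted average of the concept weights backing x,
## with the square root damping the influence of sheer concept count.

#' Concept weights for an unweighted target list (CSEA)
#'
#' Each concept is weighted by its Ochiai similarity to the target gene
#' list; concepts sharing no gene with the target get weight 0.
#'
#' @param target non-empty character vector of target genes; must
#'   overlap the compendium universe.
#' @param compendium a `concept_compendium`.
#' @return named numeric vector of concept weights (omega), one per
#'   concept.
#' @export
csea_concept_weights <- function(target, compendium) {
  target <- assert_gene_set(target, "target")
  stopifnot(inherits(compendium, "concept_compendium"))
  if (!any(target %in% universe(compendium)))
    stop2(paste("target gene list shares no identifiers with the concept",
                "universe; harmonize gene identifiers upstream"))
  nt <- length(target)
  w <- vapply(compendium$genes, function(g)
    length(intersect(target, g)) / sqrt(nt * length(g)), numeric(1))
  stats::setNames(w, compendium$ids)
}

#' Concept weights for a weighted gene list (WCSEA)
#'
#' Ranks the weighted list and runs a weighted K-S test of every concept
#' against it; a concept's weight is its NES floored at zero (depleted
#' concepts carry no signal). Permutation nulls are shared across
#' concepts of equal overlap size and generated in sorted-size order, so
#' identical gene sets receive identical weights and results do not
#' depend on concept order.
#'
#' @param weighted named numeric vector: gene id -> signed weight (e.g.
#'   a signed DE statistic).
#' @param compendium a `concept_compendium`.
#' @param n_perm permutations per null (default 1000).
#' @param seed mandatory RNG seed.
#' @param exponent WKS weighting exponent (default 1).
#' @param min_overlap concepts overlapping the list in fewer genes are
#'   skipped (absent from the result; default 3).
#' @return named numeric vector of floored NES weights with attribute
#'   `"details"` (data.frame of es/nes/p per tested concept) and
#'   `"skipped"` (ids of under-overlapping concepts).
#' @export
wcsea_concept_weights <- function(weighted, compendium, n_perm = 1000L,
                                  seed, exponent = 1, min_overlap = 3L) {
  stopifnot(inherits(compendium, "concept_compendium"))
  weighted <- as_weighted_list(weighted)
  if (sum(names(weighted) %in% universe(compendium)) < 2L)
    stop2("need at least 2 weighted genes overlapping the concept universe")
  ranked <- ranked_list(weighted)
  stage <- wks_stage(ranked, compendium$genes, n_perm = n_perm, seed = seed,
                     exponent = exponent, min_overlap = min_overlap,
                     keep_leading_edge = FALSE)
  w <- pmax(stage$table$nes, 0)
  names(w) <- stage$table$id
  structure(w, details = stage$table, skipped = stage$skipped)
}

#' Penalization factors for one gene's concepts
#'
#' For each concept i containing the gene, `eps_i` is the summed Ochiai
#' similarity of concept i with every concept containing the same gene,
#' itself included — so `eps_i >= 1`, a lone concept gets exactly 1, and
#' m mutually identical concepts get m each.
#'
#' @param gene a gene identifier with at least one associated concept.
#' @param index a `gene_concept_index`.
#' @param compendium the matching `concept_compendium`.
#' @param concept_ids optional restriction: only these concepts enter
#'   the computation (used by the scorer to drop zero-weight concepts).
#' @return named numeric vector of eps values (empty if the gene has no
#'   qualifying concept).
#' @export
penalization_factors <- function(gene, index, compendium,
                                 concept_ids = NULL) {
  stopifnot(inherits(index, "gene_concept_index"),
            inherits(compendium, "concept_compendium"))
  ids <- concepts_of(index, gene)
  if (!is.null(concept_ids)) ids <- intersect(ids, concept_ids)
  if (length(ids) == 0L) return(stats::setNames(numeric(0), character(0)))
  o <- ochiai_matrix(compendium$genes[ids])
  stats::setNames(rowSums(o), ids)
}

#' Penalized cumulative score kernel
#'
#' The scoring formula on explicit weight/penalization vectors:
#' `sum(omega/eps) / sqrt(sum(1/eps))`. Exposed so the arithmetic can be
#' checked in isolation from the membership machinery.
#'
#' @param omega non-negative concept weights.
#' @param eps penalization factors (all >= 1).
#' @return the raw cumulative score.
#' @export
uniconsig_kernel <- function(omega, eps) {
  stopifnot(length(omega) == length(eps), all(eps >= 1))
  if (length(omega) == 0L) return(0)
  sum(omega / eps) / sqrt(sum(1 / eps))
}

#' Genome-wide uniConSig scores
#'
#' Combines concept weights with per-gene penalization into the
#' cumulative score `sum(w_i/eps_i) / sqrt(sum(1/eps_i))` over the
#' positive-weight concepts of each universe gene, then min-max
#' normalizes to `[0, 1]`. Zero-weight concepts neither add signal nor
#' dilute the effective concept number. Concepts with identical gene
#' sets are collapsed to one representative per gene before the
#' penalization, which realizes exactly the intended equivalence between
#' the eps/EW/ECN scheme and removing duplicated concepts.
#'
#' @param weights named numeric concept weights (missing concepts are
#'   treated as 0; negatives are not allowed).
#' @param compendium a `concept_compendium`.
#' @param index the matching index from [build_index()]; built on the
#'   fly when `NULL`.
#' @return a data.frame of class `uniconsig_scores` with columns `gene`,
#'   `raw`, `normalized`, ordered by gene id.
#' @export
uniconsig_scores <- function(weights, compendium, index = NULL) {
  stopifnot(inherits(compendium, "concept_compendium"))
  if (is.null(index)) index <- build_index(compendium)
  stopifnot(inherits(index, "gene_concept_index"))
  if (anyNA(weights) || any(weights < 0))
    stop2("concept weights must be non-negative and non-NA")
  uni <- universe(compendium)
  w_all <- stats::setNames(numeric(length(compendium$ids)), compendium$ids)
  known <- intersect(names(weights), compendium$ids)
  w_all[known] <- weights[known]
  pos_ids <- names(w_all)[w_all > 0]
  raw <- stats::setNames(numeric(length(uni)), uni)
  if (length(pos_ids)) {
    ## collapse exact-duplicate gene sets to one representative
    key <- vapply(compendium$genes[pos_ids],
                  function(g) paste(sort(g), collapse = "\001"), "")
    rep_of <- stats::setNames(pos_ids[match(key, key)], pos_ids)
    w_rep <- tapply(w_all[pos_ids], rep_of[pos_ids], max)
    reps <- unique(unname(rep_of))
    o <- ochiai_matrix(compendium$genes[reps], vocab = uni)
    ## gene -> representative-concept rows of o
    gene_rows <- split(
      rep(match(reps, reps), lengths(compendium$genes[reps])),
      unlist(compendium$genes[reps], use.names = FALSE))
    wr <- as.numeric(w_rep[reps])
    for (g in names(gene_rows)) {
      idx <- gene_rows[[g]]
      eps <- rowSums(o[idx, idx, drop = FALSE])
      raw[g] <- uniconsig_kernel(wr[idx], eps)
    }
  }
  rng <- range(raw)
  if (rng[1] == rng[2]) {
    if (length(raw)) warn2("all raw uniConSig scores equal (%.4g); normalized scores set to 0",
                           rng[1])
    norm <- rep(0, length(raw))
  } else {
    norm <- (raw - rng[1]) / (rng[2] - rng[1])
  }
  structure(data.frame(gene = uni, raw = unname(raw), normalized = norm,
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("uniconsig_scores", "data.frame"))
}

#' Coerce to a weighted gene list
#'
#' @param x a named numeric vector or a two-column data.frame (gene,
#'   weight).
#' @return named numeric vector with unique gene names.
#' @export
as_weighted_list <- function(x) {
  if (is.data.frame(x)) {
    if (ncol(x) < 2L) stop2("weighted list data.frame needs 2 columns (gene, weight)")
    x <- stats::setNames(as.numeric(x[[2]]), as.character(x[[1]]))
  }
  if (!is.numeric(x) || is.null(names(x)))
    stop2("weighted gene list must be a named numeric vector")
  if (anyNA(x) || anyNA(names(x)) || any(names(x) == ""))
    stop2("weighted gene list contains NA weights or empty gene ids")
  if (anyDuplicated(names(x)))
    stop2("duplicate gene id(s) in weighted list: %s",
          paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  x
}

#' Read a weighted gene list from TSV
#'
#' Two tab-separated columns: gene identifier, signed real weight.
#'
#' @param path input file.
#' @param header whether the file carries a header line.
#' @return named numeric vector.
#' @export
read_weighted_list <- function(path, header = FALSE) {
  if (!file.exists(path)) stop2("weighted list file not found: %s", path)
  d <- utils::read.delim(path, header = header, stringsAsFactors = FALSE)
  if (ncol(d) < 2L) stop2("weighted list %s needs 2 tab-separated columns", path)
  if (!is.numeric(d[[2]]))
    stop2("second column of %s is not numeric (missing --header flag?)", path)
  as_weighted_list(d)
}

#' Write a weighted gene list to TSV
#' @param weighted named numeric vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_weighted_list <- function(weighted, path) {
  weighted <- as_weighted_list(weighted)
  utils::write.table(
    data.frame(gene = names(weighted), weight = unname(weighted)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
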