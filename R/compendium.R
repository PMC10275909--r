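## Molecular-concept compendia: GMT I/O, validation, indexing, and the
## Ochiai set-similarity used throughout the concept-signature method.

new_compendium <- function(ids, descriptions, genes) {
  stopifnot(length(ids) == length(descriptions),
            length(ids) == length(genes))
  if (anyDuplicated(ids))
    stop2("duplicate concept id(s): %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  genes <- lapply(genes, function(g) unique(as.character(g)))
  if (length(genes) && any(lengths(genes) == 0L))
    stop2("concepts with empty gene sets are not allowed")
  structure(
    list(ids = as.character(ids),
         descriptions = as.character(descriptions),
         genes = stats::setNames(genes, ids)),
    class = "concept_compendium")
}

#' Read a GMT gene-set collection
#'
#' Parses the Gene Matrix Transposed format (tab-separated: id,
#' description, member genes) used for both molecular-concept compendia
#' and pathway collections. Gene tokens are deduplicated per line; sets
#' whose deduplicated size falls outside `[min_size, max_size]` are
#' dropped. Line order is preserved. Gene identifiers are opaque,
#' case-sensitive strings: harmonize identifiers upstream.
#'
#' @param path path to a GMT file (UTF-8; LF or CRLF line endings).
#' @param min_size,max_size inclusive bounds on deduplicated set size.
#'   Small concepts make the Ochiai similarity unstable, hence the
#'   default floor of 5.
#' @return a `concept_compendium` object.
#' @examples
#' f <- tempfile(fileext = ".gmt")
#' writeLines(c("C1\tdesc\ta\tb", "C2\tdesc\tb\tc\tc"), f)
#' cp <- read_gmt(f, min_size = 1)
#' concept_sizes(cp)
#' @export
read_gmt <- function(path, min_size = 5L, max_size = 2500L) {
  if (!file.exists(path)) stop2("GMT file not found: %s", path)
  if (!is_count(min_size) || !is_count(max_size) || min_size > max_size)
    stop2("need 1 <= min_size <= max_size")
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("\r$", "", lines)
  keep <- nzchar(lines)
  ids <- character(0); desc <- character(0); genes <- list()
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    f <- f[nzchar(f)]
    if (length(f) < 3L)
      stop2("malformed GMT line %d in %s: fewer than 3 fields", i, path)
    g <- unique(f[-(1:2)])
    if (length(g) < min_size || length(g) > max_size) next
    ids <- c(ids, f[1]); desc <- c(desc, f[2]); genes <- c(genes, list(g))
  }
  all_ids <- vapply(lines[keep], function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], "", USE.NAMES = FALSE)
  if (anyDuplicated(all_ids))
    stop2("duplicate concept id(s) in %s: %s", path,
          paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  new_compendium(ids, desc, genes)
}

#' Write a compendium back to GMT
#'
#' @param x a `concept_compendium`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(x, path) {
  stopifnot(inherits(x, "concept_compendium"))
  lines <- vapply(seq_along(x$ids), function(i)
    paste(c(x$ids[i], x$descriptions[i], x$genes[[i]]), collapse = "\t"), "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @export
length.concept_compendium <- function(x) length(x$ids)

#' @export
print.concept_compendium <- function(x, ...) {
  cat(sprintf("concept_compendium: %d concepts, %d genes in universe\n",
              length(x$ids), length(universe(x))))
  invisible(x)
}

#' Gene universe of a compendium
#'
#' The union of all concept gene sets, sorted for determinism.
#' @param x a `concept_compendium`.
#' @return character vector of gene identifiers.
#' @export
universe <- function(x) {
  stopifnot(inherits(x, "concept_compendium"))
  g <- unlist(x$genes, use.names = FALSE)
  if (is.null(g)) character(0) else sort(unique(g))
}

#' Deduplicated concept sizes
#' @param x a `concept_compendium`.
#' @return named integer vector.
#' @export
concept_sizes <- function(x) {
  stopifnot(inherits(x, "concept_compendium"))
  stats::setNames(lengths(x$genes), x$ids)
}

#' Subset a compendium by concept id
#' @param x a `concept_compendium`.
#' @param ids concept ids to keep (order respected).
#' @return a `concept_compendium`.
#' @export
subset_compendium <- function(x, ids) {
  stopifnot(inherits(x, "concept_compendium"))
  miss <- setdiff(ids, x$ids)
  if (length(miss)) stop2("unknown concept id(s): %s",
                          paste(miss, collapse = ", "))
  i <- match(ids, x$ids)
  new_compendium(x$ids[i], x$descriptions[i], x$genes[i])
}

#' Ochiai similarity of two gene sets
#'
#' `|A n B| / sqrt(|A| |B|)` — the cosine coefficient on set indicator
#' vectors. Unlike the Jaccard index it does not vanish when a small set
#' is nested in a much larger one: for A contained in B it equals
#' `sqrt(|A|/|B|)`, always above Jaccard's `|A|/|B|`.
#'
#' @param set_a,set_b non-empty character vectors (deduplicated
#'   internally).
#' @return similarity in `[0, 1]`.
#' @examples
#' ochiai(c("g1", "g2"), c("g2", "g3", "g4"))  # 1/sqrt(6)
#' @export
ochiai <- function(set_a, set_b) {
  set_a <- assert_gene_set(set_a, "set_a")
  set_b <- assert_gene_set(set_b, "set_b")
  length(intersect(set_a, set_b)) / sqrt(length(set_a) * length(set_b))
}

## Pairwise Ochiai among a list of (already deduplicated) gene sets over
## a common gene vocabulary. Dense concepts x concepts matrix.
ochiai_matrix <- function(gene_sets, vocab = NULL) {
  n <- length(gene_sets)
  if (n == 0L) return(matrix(numeric(0), 0, 0))
  vocab <- vocab %||% sort(unique(unlist(gene_sets, use.names = FALSE)))
  m <- matrix(0, n, length(vocab))
  for (i in seq_len(n)) m[i, match(gene_sets[[i]], vocab)] <- 1
  counts <- tcrossprod(m)
  sizes <- lengths(gene_sets)
  o <- counts / sqrt(outer(sizes, sizes))
  dimnames(o) <- list(names(gene_sets), names(gene_sets))
  o
}

#' Build a gene-to-concept membership index
#'
#' Inverts a compendium: each universe gene maps to the ids of the
#' concepts containing it. Genes absent from the universe query to an
#' empty set via [concepts_of()].
#'
#' @param compendium a `concept_compendium`.
#' @return a `gene_concept_index` (named list of concept-id vectors).
#' @export
build_index <- function(compendium) {
  stopifnot(inherits(compendium, "concept_compendium"))
  gene <- unlist(compendium$genes, use.names = FALSE)
  cid <- rep(compendium$ids, lengths(compendium$genes))
  idx <- split(cid, gene)
  structure(idx, class = "gene_concept_index")
}

#' Concepts containing a gene
#' @param index a `gene_concept_index` from [build_index()].
#' @param gene a gene identifier.
#' @return character vector of concept ids (empty if the gene is
#'   unknown).
#' @export
concepts_of <- function(index, gene) {
  stopifnot(inherits(index, "gene_concept_index"))
  unclass(index)[[gene]] %||% character(0)
}

#' @export
print.gene_concept_index <- function(x, ...) {
  cat(sprintf("gene_concept_index: %d genes, %d memberships\n",
              length(x), sum(lengths(x))))
  invisible(x)
}
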