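## Dropout simulation, rank-variation benchmarking, and the synthetic
## fixture generator that makes the whole package testable without any
## external download.

#' Simulate expression dropouts on a weighted gene list
#'
#' Removes exactly `round(fraction * N)` genes uniformly at random
#' without replacement, mimicking genes whose expression goes
#' undetected in scRNA-seq and therefore never reach the DE output.
#'
#' @param weighted named numeric vector (gene -> weight).
#' @param fraction fraction of genes to delete, in `[0, 1)`.
#' @param seed mandatory RNG seed.
#' @return the surviving weighted list (original order preserved).
#' @export
simulate_dropout <- function(weighted, fraction, seed) {
  weighted <- as_weighted_list(weighted)
  if (!is.numeric(fraction) || length(fraction) != 1L || fraction < 0 ||
      fraction >= 1)
    stop2("dropout fraction must lie in [0, 1)")
  n <- length(weighted)
  if (n == 0L) stop2("weighted list is empty")
  n_drop <- round(fraction * n)
  if (n_drop == 0) return(weighted)
  drop_idx <- with_seed(seed, sample.int(n, n_drop))
  weighted[-drop_idx]
}

#' Rank variation of top pathways between two enrichment runs
#'
#' For each of the original table's `top_k` pathways, variation =
#' original rank minus perturbed rank, so negative values mean the
#' pathway lost significance. A pathway absent from the perturbed table
#' is assigned perturbed rank `nrow(perturbed) + 1`.
#'
#' @param original,perturbed `pathway_table` objects.
#' @param top_k how many top original pathways to follow (default
#'   min(30, table size)).
#' @return list of class `rank_variation`: `variation` (data.frame
#'   pathway, original_rank, perturbed_rank, variation), `top_k`,
#'   `summary` (median, IQR, fraction unchanged of |variation|).
#' @export
rank_variation <- function(original, perturbed, top_k = NULL) {
  stopifnot(inherits(original, "pathway_table"),
            inherits(perturbed, "pathway_table"))
  K <- nrow(original$results)
  top_k <- as.integer(top_k %||% min(30L, K))
  if (top_k > K) stop2("top_k (%d) exceeds original table size (%d)",
                       top_k, K)
  ids <- original$results$pathway[seq_len(top_k)]
  orig_rank <- original$results$rank[seq_len(top_k)]
  hit <- match(ids, perturbed$results$pathway)
  pert_rank <- ifelse(is.na(hit), nrow(perturbed$results) + 1L,
                      perturbed$results$rank[hit])
  variation <- orig_rank - pert_rank
  d <- data.frame(pathway = ids, original_rank = orig_rank,
                  perturbed_rank = pert_rank, variation = variation,
                  stringsAsFactors = FALSE)
  structure(list(variation = d, top_k = top_k,
                 summary = c(median = stats::median(variation),
                             iqr = stats::IQR(variation),
                             fraction_unchanged = mean(variation == 0))),
            class = "rank_variation")
}

#' @export
print.rank_variation <- function(x, ...) {
  cat(sprintf("rank_variation (top %d): median %.1f, IQR %.1f, %.0f%% unchanged\n",
              x$top_k, x$summary["median"], x$summary["iqr"],
              100 * x$summary["fraction_unchanged"]))
  invisible(x)
}

#' Generate a synthetic benchmark fixture with planted signal
#'
#' Emulates the input of a single-cell DE analysis: a weighted gene
#' list whose background weights are Normal(0, `noise_sd`) (a signed
#' z-like DE statistic) with the genes of each planted pathway shifted
#' upward by its effect size; a pathway collection of random gene sets;
#' and a concept compendium containing, for every planted pathway,
#' `n_signature` "signature" concepts drawn mostly (70%) from the
#' pathway's genes — the concept redundancy that gives the method its
#' buffer zone — plus unrelated random concepts.
#'
#' @param n_genes genome size.
#' @param n_concepts total number of concepts (must cover the signature
#'   concepts).
#' @param concept_size_range inclusive size range for concepts.
#' @param n_pathways number of pathways.
#' @param pathway_size_range inclusive size range for pathways.
#' @param planted named numeric vector: pathway id (e.g. "P01") ->
#'   additive mean shift of its genes' weights. Ids must exist in the
#'   generated collection (`P01` ... `Pnn`).
#' @param n_signature signature concepts per planted pathway.
#' @param noise_sd standard deviation of background weights.
#' @param seed mandatory RNG seed; regeneration is byte-identical.
#' @return list of class `synthetic_fixture`: `compendium`, `pathways`,
#'   `weighted`, `planted`, `seed`.
#' @export
generate_fixture <- function(n_genes = 1000L, n_concepts = 60L,
                             concept_size_range = c(10L, 60L),
                             n_pathways = 30L,
                             pathway_size_range = c(20L, 40L),
                             planted = c(P01 = 3), n_signature = 8L,
                             noise_sd = 1, seed) {
  if (!is_count(n_genes) || !is_count(n_pathways))
    stop2("n_genes and n_pathways must be positive integers")
  if (!is_count(n_concepts))
    stop2("n_concepts must be a positive integer (the compendium cannot be empty)")
  if (length(concept_size_range) != 2L ||
      concept_size_range[1] > concept_size_range[2] ||
      concept_size_range[2] > n_genes)
    stop2("concept_size_range infeasible for n_genes = %d", n_genes)
  if (length(pathway_size_range) != 2L ||
      pathway_size_range[1] > pathway_size_range[2] ||
      pathway_size_range[2] > n_genes)
    stop2("pathway_size_range infeasible for n_genes = %d", n_genes)
  planted <- planted %||% stats::setNames(numeric(0), character(0))
  pw_ids <- sprintf("P%02d", seq_len(n_pathways))
  if (length(planted) && !all(names(planted) %in% pw_ids))
    stop2("planted pathway id(s) not in the generated collection: %s",
          paste(setdiff(names(planted), pw_ids), collapse = ", "))
  n_sig_total <- length(planted) * n_signature
  if (n_sig_total > n_concepts)
    stop2("n_concepts (%d) too small for %d signature concepts",
          n_concepts, n_sig_total)
  genes <- sprintf("g%05d", seq_len(n_genes))
  with_seed(seed, {
    pw_genes <- lapply(seq_len(n_pathways), function(i) {
      size <- sample(pathway_size_range[1]:pathway_size_range[2], 1L)
      sort(sample(genes, size))
    })
    names(pw_genes) <- pw_ids
    cp_genes <- list(); cp_ids <- character(0)
    k <- 0L
    for (pid in names(planted)) {
      for (s in seq_len(n_signature)) {
        k <- k + 1L
        size <- sample(concept_size_range[1]:concept_size_range[2], 1L)
        n_core <- min(length(pw_genes[[pid]]), max(1L, round(0.7 * size)))
        core <- sample(pw_genes[[pid]], n_core)
        pad <- sample(setdiff(genes, core), size - n_core)
        cp_genes[[k]] <- sort(c(core, pad))
        cp_ids[k] <- sprintf("C%03d", k)
      }
    }
    while (k < n_concepts) {
      k <- k + 1L
      size <- sample(concept_size_range[1]:concept_size_range[2], 1L)
      cp_genes[[k]] <- sort(sample(genes, size))
      cp_ids[k] <- sprintf("C%03d", k)
    }
    weights <- stats::rnorm(n_genes, 0, noise_sd)
    names(weights) <- genes
    for (pid in names(planted))
      weights[pw_genes[[pid]]] <- weights[pw_genes[[pid]]] + planted[[pid]]
    structure(
      list(compendium = new_compendium(cp_ids,
                                       rep("synthetic concept", k), cp_genes),
           pathways = new_compendium(pw_ids,
                                     rep("synthetic pathway", n_pathways),
                                     pw_genes),
           weighted = weights,
           planted = planted,
           seed = as.integer(seed)),
      class = "synthetic_fixture")
  })
}

#' @export
print.synthetic_fixture <- function(x, ...) {
  cat(sprintf(
    "synthetic_fixture (seed %d): %d genes, %d concepts, %d pathways, planted: %s\n",
    x$seed, length(x$weighted), length(x$compendium), length(x$pathways),
    if (length(x$planted))
      paste(sprintf("%s(+%.1f)", names(x$planted), x$planted),
            collapse = ", ") else "none"))
  invisible(x)
}

#' Write a fixture to disk
#'
#' Emits `concepts.gmt`, `pathways.gmt`, `weights.tsv` and `truth.json`
#' (planted pathways, effects, seed) into `dir`.
#'
#' @param fixture a `synthetic_fixture`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "synthetic_fixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gmt(fixture$compendium, file.path(dir, "concepts.gmt"))
  write_gmt(fixture$pathways, file.path(dir, "pathways.gmt"))
  write_weighted_list(fixture$weighted, file.path(dir, "weights.tsv"))
  jsonlite::write_json(
    list(planted = as.list(fixture$planted), seed = fixture$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}

## One enrichment run for a benchmark method.
benchmark_run <- function(method, weighted, fixture, n_perm, seed,
                          top_frac = 0.1) {
  switch(method,
    wcsea = run_wcsea(weighted, fixture$compendium, fixture$pathways,
                      direction = "up", n_perm = n_perm, seed = seed),
    csea = {
      ## unweighted arm: the "DE gene list" is the top decile by weight
      n_top <- max(5L, round(top_frac * length(weighted)))
      target <- names(sort(weighted, decreasing = TRUE))[seq_len(n_top)]
      run_csea(target, fixture$compendium, fixture$pathways,
               n_perm = n_perm, seed = seed)
    },
    plain_wks = run_plain_wks(weighted, fixture$pathways, direction = "up",
                              n_perm = n_perm, seed = seed),
    stop2("unknown benchmark method: %s", method))
}

#' Dropout-robustness benchmark
#'
#' Re-runs each method on dropout-perturbed copies of the fixture's
#' weighted list and reports the rank variation of the original top
#' pathways — the reproducibility protocol used to compare the
#' concept-signature methods against a plain weighted-K-S (GSEA-like)
#' baseline.
#'
#' @param fixture a `synthetic_fixture`.
#' @param methods subset of `c("wcsea", "csea", "plain_wks")`.
#' @param fractions dropout fractions (default `c(0.2, 0.5)`).
#' @param n_reps replicate perturbations per fraction (default 5).
#' @param seed mandatory RNG seed; a fixed schedule `seed + rep index`
#'   drives the dropouts so methods see identical perturbations.
#' @param n_perm permutations per enrichment run.
#' @param top_k pathways to follow (default min(30, table size)).
#' @return list of class `dropout_benchmark`: `reports` (nested
#'   method -> "fraction:rep" -> `rank_variation`), `originals`
#'   (per-method unperturbed `pathway_table`), `summary` data.frame
#'   (method, fraction, rep, median/IQR of |variation|, planted pathway
#'   variation).
#' @export
dropout_benchmark <- function(fixture, methods = c("wcsea", "plain_wks"),
                              fractions = c(0.2, 0.5), n_reps = 5L, seed,
                              n_perm = 1000L, top_k = NULL) {
  stopifnot(inherits(fixture, "synthetic_fixture"))
  methods <- match.arg(methods, c("wcsea", "csea", "plain_wks"),
                       several.ok = TRUE)
  if (!is_count(n_reps)) stop2("n_reps must be a positive integer")
  originals <- lapply(methods, function(m)
    benchmark_run(m, fixture$weighted, fixture, n_perm, seed))
  names(originals) <- methods
  reports <- lapply(methods, function(m) list())
  names(reports) <- methods
  rows <- list()
  for (fi in seq_along(fractions)) {
    for (r in seq_len(n_reps)) {
      drop_seed <- seed + 97L * fi + r
      for (m in methods) {
        pert_weighted <- simulate_dropout(fixture$weighted, fractions[fi],
                                          seed = drop_seed)
        ## same enrichment seed as the unperturbed run: rank variation
        ## then isolates the dropout effect (and fraction 0 is exactly
        ## invariant)
        pert <- benchmark_run(m, pert_weighted, fixture, n_perm, seed)
        tk <- as.integer(top_k %||% min(30L, nrow(originals[[m]]$results)))
        rv <- rank_variation(originals[[m]], pert, top_k = tk)
        key <- sprintf("%g:%d", fractions[fi], r)
        reports[[m]][[key]] <- rv
        planted_var <- NA_real_
        if (length(fixture$planted)) {
          hit <- match(names(fixture$planted), rv$variation$pathway)
          planted_var <- stats::median(abs(rv$variation$variation[hit]),
                                       na.rm = TRUE)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          method = m, fraction = fractions[fi], rep = r,
          median_abs_variation = stats::median(abs(rv$variation$variation)),
          iqr_variation = rv$summary[["iqr"]],
          fraction_unchanged = rv$summary[["fraction_unchanged"]],
          planted_abs_variation = planted_var,
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(reports = reports, originals = originals,
                 summary = do.call(rbind, rows),
                 params = list(methods = methods, fractions = fractions,
                               n_reps = n_reps, seed = seed,
                               n_perm = n_perm)),
            class = "dropout_benchmark")
}

#' @export
print.dropout_benchmark <- function(x, ...) {
  cat("dropout_benchmark\n")
  agg <- stats::aggregate(
    cbind(median_abs_variation, planted_abs_variation) ~ method + fraction,
    data = x$summary, FUN = stats::median, na.action = stats::na.pass)
  print(agg, row.names = FALSE)
  invisible(x)
}

#' Write a benchmark summary (TSV + JSON)
#' @param benchmark a `dropout_benchmark`.
#' @param path output TSV path; JSON goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_benchmark <- function(benchmark, path) {
  stopifnot(inherits(benchmark, "dropout_benchmark"))
  utils::write.table(benchmark$summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(params = benchmark$params,
                            summary = benchmark$summary),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", pretty = TRUE)
  invisible(path)
}
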