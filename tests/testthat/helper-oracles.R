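## Independent oracles and small fixture builders shared by the tests.
## The oracles are deliberately naive (explicit walks, step-up by hand)
## so they cannot share a defect with the implementation.

make_compendium <- function(sets, descriptions = NULL) {
  wcsea:::new_compendium(names(sets),
                         descriptions %||% rep("d", length(sets)),
                         unname(sets))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Brute-force weighted K-S: walk the list one gene at a time, keep the
## whole running sum, return the element of maximal |deviation|.
brute_es <- function(genes, weights, gene_set, exponent = 1) {
  N <- length(genes)
  hit <- genes %in% gene_set
  nh <- sum(hit)
  w <- abs(weights)^exponent
  tot <- sum(w[hit])
  rs <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    cur <- if (hit[i]) {
      cur + (if (tot > 0) w[i] / tot else 1 / nh)
    } else {
      cur - 1 / (N - nh)
    }
    rs[i] <- cur
  }
  rs[which.max(abs(rs))]
}

## Compare implementation ES against the brute-force oracle. When the
## positive and negative extrema tie in magnitude to within rounding,
## the winning sign depends on summation order (cumsum accumulates in
## long double, the oracle loop in double), so only |ES| is compared.
expect_es_match <- function(rk, gs, exponent = 1) {
  a <- running_sum_es(rk, gs, exponent)
  b <- brute_es(rk$genes, rk$weights, gs, exponent)
  expect_equal(abs(a$es), abs(b), tolerance = 1e-12)
  rs <- a$running_sum
  tie <- abs(max(rs) - abs(min(rs))) < 1e-9
  if (!tie) expect_equal(a$es, b, tolerance = 1e-12)
}

## Step-up Benjamini-Hochberg written from the definition.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- prev
  }
  pmin(adj, 1)
}

## Direct evaluation of the penalized cumulative score for one gene
## given explicit omega and eps vectors.
brute_uniconsig <- function(omega, eps) {
  sum(omega / eps) / sqrt(sum(1 / eps))
}

## A small planted-signal fixture cheap enough for unit tests.
small_fixture <- function(seed, effect = 3) {
  generate_fixture(n_genes = 400L, n_concepts = 25L,
                   concept_size_range = c(8L, 30L), n_pathways = 10L,
                   pathway_size_range = c(15L, 25L),
                   planted = c(P01 = effect), n_signature = 6L, seed = seed)
}

random_gene_set <- function(universe, size) sample(universe, size)
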