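test_that("CSEA concept weights are Ochiai similarities to the target", {
  cp <- make_compendium(list(Ca = c("a", "b"), Cb = c("b", "c", "d"),
                             Cc = c("c", "d")))
  w <- csea_concept_weights(c("a", "b"), cp)
  expect_equal(unname(w["Ca"]), 1.0)
  expect_equal(unname(w["Cb"]), 1 / sqrt(6), tolerance = 1e-12)
  expect_equal(unname(w["Cc"]), 0)
  expect_error(csea_concept_weights(c("zz", "yy"), cp), "harmonize")
})

test_that("WCSEA concept weights recover planted concepts and floor depleted ones", {
  set.seed(7)
  genes <- sprintf("g%03d", 1:500)
  sig <- genes[1:20]          # top-ranked genes
  bottom <- genes[481:500]
  weights <- setNames(seq(5, 0.01, length.out = 500), genes)
  cp <- make_compendium(list(
    TOP = sig, BOTTOM = bottom,
    RAND1 = sample(genes, 25), RAND2 = sample(genes, 25),
    TINY = genes[c(3, 9)]))
  w <- suppressMessages(
    wcsea_concept_weights(weights, cp, n_perm = 1000, seed = 7))
  det <- attr(w, "details")
  expect_gt(w[["TOP"]], 1)
  expect_lt(det$p_value[det$id == "TOP"], 0.05)
  expect_equal(w[["BOTTOM"]], 0)  # negative NES floored
  expect_false("TINY" %in% names(w))  # overlap 2 < min_overlap 3
  expect_true("TINY" %in% attr(w, "skipped"))
})

test_that("penalization factors cumulate Ochiai similarity with self-inclusion", {
  cp1 <- make_compendium(list(C1 = c("g", "a", "b")))
  expect_equal(unname(penalization_factors("g", build_index(cp1), cp1)),
               1.0)

  cp2 <- make_compendium(list(C1 = c("g", "a"), C2 = c("g", "a")))
  eps <- penalization_factors("g", build_index(cp2), cp2)
  expect_equal(unname(eps), c(2.0, 2.0))

  cp3 <- make_compendium(list(C1 = c("g", "a"), C2 = c("g", "b")))
  eps3 <- penalization_factors("g", build_index(cp3), cp3)
  expect_equal(unname(eps3), c(1.5, 1.5))

  expect_length(penalization_factors("absent", build_index(cp3), cp3), 0L)
})

test_that("uniConSig scores match hand-evaluated closed forms", {
  # single concept: raw equals omega
  cp1 <- make_compendium(list(C1 = c("x", "a")))
  s1 <- uniconsig_scores(c(C1 = 0.8), cp1)
  expect_equal(s1$raw[s1$gene == "x"], 0.8, tolerance = 1e-12)

  # 4 exact duplicates collapse to the single-concept case
  cp4 <- make_compendium(list(C1 = c("x", "a"), C2 = c("x", "a"),
                              C3 = c("x", "a"), C4 = c("x", "a")))
  s4 <- uniconsig_scores(c(C1 = 0.8, C2 = 0.8, C3 = 0.8, C4 = 0.8), cp4)
  expect_equal(s4$raw[s4$gene == "x"], 0.8, tolerance = 1e-12)

  # two independent concepts at omega 0.5 and eps 1 each: the kernel
  # gives (0.5 + 0.5)/sqrt(2)
  expect_equal(uniconsig_kernel(c(0.5, 0.5), c(1, 1)), 1 / sqrt(2),
               tolerance = 1e-12)

  # concepts sharing only the gene itself: eps = 1.5 each, raw = 1/sqrt(3)
  cpd <- make_compendium(list(C1 = c("x", "a"), C2 = c("x", "b")))
  sd2 <- uniconsig_scores(c(C1 = 0.5, C2 = 0.5), cpd)
  expect_equal(sd2$raw[sd2$gene == "x"],
               brute_uniconsig(c(0.5, 0.5), c(1.5, 1.5)),
               tolerance = 1e-12)
  expect_equal(sd2$raw[sd2$gene == "x"], 1 / sqrt(3), tolerance = 1e-12)
})

test_that("zero-weight concepts neither add signal nor dilute ECN", {
  cp <- make_compendium(list(C1 = c("x", "a"), C0 = c("x", "b", "c")))
  s <- uniconsig_scores(c(C1 = 0.8, C0 = 0), cp)
  expect_equal(s$raw[s$gene == "x"], 0.8, tolerance = 1e-12)
  # gene only in the zero-weight concept scores 0
  expect_equal(s$raw[s$gene == "b"], 0)
})

test_that("appending exact concept copies never changes raw scores", {
  for (seed in 1:5) {
    fx <- small_fixture(seed)
    target <- fx$pathways$genes[["P01"]]
    w <- csea_concept_weights(target, fx$compendium)
    base <- uniconsig_scores(w, fx$compendium)
    set.seed(seed + 100)
    dup_ids <- sample(fx$compendium$ids, 3)
    for (k in c(1L, 2L, 5L)) {
      ids2 <- fx$compendium$ids
      desc2 <- fx$compendium$descriptions
      genes2 <- unname(fx$compendium$genes)
      w2 <- w
      for (d in dup_ids) {
        for (j in seq_len(k)) {
          nid <- sprintf("%s_copy%d_%d", d, k, j)
          ids2 <- c(ids2, nid)
          desc2 <- c(desc2, "copy")
          genes2 <- c(genes2, list(fx$compendium$genes[[d]]))
          w2[nid] <- w[[d]]
        }
      }
      cp2 <- wcsea:::new_compendium(ids2, desc2, genes2)
      dup <- uniconsig_scores(w2, cp2)
      expect_equal(dup$raw, base$raw, tolerance = 1e-9)
    }
  }
})

test_that("raw scores are monotone in any single concept weight", {
  fx <- small_fixture(3)
  target <- fx$pathways$genes[["P01"]]
  w <- csea_concept_weights(target, fx$compendium)
  pos <- names(w)[w > 0]
  base <- uniconsig_scores(w, fx$compendium)
  for (cid in pos[1:min(3, length(pos))]) {
    w_up <- w
    w_up[cid] <- w_up[cid] * 1.5
    bumped <- uniconsig_scores(w_up, fx$compendium)
    members <- fx$compendium$genes[[cid]]
    sel <- base$gene %in% members
    expect_true(all(bumped$raw[sel] - base$raw[sel] >= -1e-12))
  }
})

test_that("scores are invariant to concept and gene ordering", {
  fx <- small_fixture(5)
  target <- fx$pathways$genes[["P01"]]
  w <- csea_concept_weights(target, fx$compendium)
  base <- uniconsig_scores(w, fx$compendium)

  set.seed(1)
  perm <- sample(seq_along(fx$compendium$ids))
  cp_perm <- wcsea:::new_compendium(
    fx$compendium$ids[perm], fx$compendium$descriptions[perm],
    lapply(unname(fx$compendium$genes)[perm], sample))
  permuted <- uniconsig_scores(w[perm], cp_perm)
  expect_equal(permuted$raw, base$raw, tolerance = 1e-12)
  expect_identical(permuted$gene, base$gene)
})

test_that("normalization spans [0,1] and degrades gracefully when constant", {
  fx <- small_fixture(9)
  w <- csea_concept_weights(fx$pathways$genes[["P01"]], fx$compendium)
  s <- uniconsig_scores(w, fx$compendium)
  expect_equal(min(s$normalized), 0)
  expect_equal(max(s$normalized), 1)

  cp <- make_compendium(list(C1 = c("a", "b")))
  expect_warning(s0 <- uniconsig_scores(c(C1 = 0), cp), "all raw")
  expect_true(all(s0$normalized == 0))
})

test_that("weighted list I/O round-trips and validates", {
  w <- c(g1 = 1.5, g2 = -0.25, g3 = 0)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_weighted_list(w, f)
  expect_equal(read_weighted_list(f), w)
  expect_error(as_weighted_list(c(1, 2)), "named")
  expect_error(as_weighted_list(c(a = 1, a = 2)), "duplicate")
})
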