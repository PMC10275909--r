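test_that("running-sum ES matches hand-enumerated walks", {
  rk <- ranked_list(c("g1", "g2", "g3", "g4"), c(4, 3, 2, 1))

  top <- running_sum_es(rk, "g1", exponent = 1)
  expect_equal(top$es, 1.0)
  expect_equal(top$running_sum, c(1, 1 - 1/3, 1 - 2/3, 0))
  expect_identical(top$leading_edge, "g1")

  bottom <- running_sum_es(rk, "g4", exponent = 1)
  expect_equal(bottom$es, -1.0)
  expect_equal(bottom$running_sum, c(-1/3, -2/3, -1, 0))
  expect_identical(bottom$leading_edge, "g4")

  all_hit <- running_sum_es(rk, c("g1", "g2", "g3", "g4"))
  expect_equal(all_hit$es, 1.0)

  expect_error(running_sum_es(rk, c("x", "y")), "does not intersect")
})

test_that("running sum is conservative and rank-only at exponent 0", {
  set.seed(3)
  for (i in 1:20) {
    n <- sample(10:50, 1)
    genes <- sprintf("g%03d", 1:n)
    rk <- ranked_list(genes, rnorm(n))
    gs <- sample(genes, sample(2:(n - 1), 1))
    fit <- running_sum_es(rk, gs)
    expect_equal(fit$running_sum[n], 0, tolerance = 1e-12)

    # exponent 0: invariant under order-preserving weight transforms
    rk2 <- ranked_list(rk$genes, rank(rk$weights)^3)
    expect_equal(running_sum_es(rk, gs, exponent = 0)$es,
                 running_sum_es(rk2, gs, exponent = 0)$es,
                 tolerance = 1e-12)
  }
})

test_that("ES equals an independent brute-force enumeration", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(5:50, 1)
    genes <- sample(sprintf("g%03d", 1:60), n)
    weights <- round(rnorm(n), 3)
    rk <- ranked_list(genes, weights)
    gs <- sample(genes, sample(1:min(10, n - 1), 1))
    expect_es_match(rk, gs)
  }
})

test_that("fast position-based ES agrees with the full running sum", {
  set.seed(17)
  for (i in 1:100) {
    n <- sample(8:60, 1)
    genes <- sprintf("g%03d", 1:n)
    rk <- ranked_list(genes, rnorm(n))
    k <- sample(1:(n - 1), 1)
    gs <- sample(genes, k)
    pos <- sort(which(rk$genes %in% gs))
    aw <- abs(rk$weights)
    expect_equal(wcsea:::es_from_positions(pos, aw, n),
                 running_sum_es(rk, gs)$es, tolerance = 1e-12)
  }
})

test_that("permutation null is reproducible and enumerable on tiny lists", {
  rk <- ranked_list(c("g1", "g2", "g3", "g4"), c(4, 3, 2, 1))

  n1 <- permutation_null(rk, set_size = 2, n_perm = 100, seed = 5)
  n2 <- permutation_null(rk, set_size = 2, n_perm = 100, seed = 5)
  expect_identical(n1$es_samples, n2$es_samples)

  # only one subset of size 4 exists: every sample is the all-hit ES
  n_all <- permutation_null(rk, set_size = 4, n_perm = 50, seed = 1)
  expect_true(all(n_all$es_samples == 1))

  # size-1 samples live in the enumerated 4-value support
  support <- vapply(c("g1", "g2", "g3", "g4"), function(g)
    running_sum_es(rk, g)$es, numeric(1))
  n_one <- permutation_null(rk, set_size = 1, n_perm = 200, seed = 2)
  expect_true(all(n_one$es_samples %in% support))

  expect_error(permutation_null(rk, set_size = 9, n_perm = 10, seed = 1),
               "exceeds")
})

test_that("NES and p-value follow the sign-matched permutation recipe", {
  null <- structure(list(es_samples = c(0.25, 0.25, -0.5), set_size = 2L,
                         seed = 1L), class = "wks_null")
  nz <- normalize_es(0.5, null)
  expect_equal(nz$nes, 2.0)

  expect_equal(normalize_es(0, null)$nes, 0)

  # es above all 99 same-sign samples -> p = 1/100 with add-one smoothing
  null99 <- structure(list(es_samples = seq(0.001, 0.099, length.out = 99),
                           set_size = 2L, seed = 1L), class = "wks_null")
  expect_equal(normalize_es(0.5, null99)$p_value, 1 / 100)

  # no same-sign samples -> nes 0, p 1, warning
  neg_null <- structure(list(es_samples = c(-0.2, -0.4), set_size = 2L,
                             seed = 1L), class = "wks_null")
  expect_warning(nz0 <- normalize_es(0.3, neg_null), "same-sign")
  expect_equal(nz0$nes, 0)
  expect_equal(nz0$p_value, 1)
})

test_that("p-value of a random set is calibrated on exchangeable weights", {
  set.seed(123)
  n <- 60
  genes <- sprintf("g%03d", 1:n)
  p <- replicate(200, {
    rk <- ranked_list(genes, rnorm(n))
    gs <- sample(genes, 8)
    fit <- running_sum_es(rk, gs)
    null <- permutation_null(rk, 8, n_perm = 200,
                             seed = sample.int(1e6, 1))
    normalize_es(fit$es, null)$p_value
  })
  # uniform to within Monte-Carlo error: check mean and tail mass
  expect_gt(mean(p), 0.40)
  expect_lt(mean(p), 0.60)
  frac05 <- mean(p < 0.05)
  expect_lt(frac05, 0.12)
})

test_that("adjust_pvalues matches the hand-rolled step-up oracle", {
  expect_equal(adjust_pvalues(c(0.01, 0.02), "bonferroni"), c(0.02, 0.04))
  expect_equal(adjust_pvalues(0.01, "bonferroni"), 0.01)
  expect_equal(adjust_pvalues(0.01, "benjamini_hochberg"), 0.01)
  # step-up on (0.01, 0.04, 0.03): 0.03·3/2 = 0.045 is clipped down by
  # the rank-3 value 0.04·3/3 = 0.04
  expect_equal(adjust_pvalues(c(0.01, 0.04, 0.03), "benjamini_hochberg"),
               brute_bh(c(0.01, 0.04, 0.03)))
  expect_equal(adjust_pvalues(c(0.01, 0.04, 0.03), "benjamini_hochberg"),
               c(0.03, 0.04, 0.04))

  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    expect_equal(adjust_pvalues(p, "benjamini_hochberg"), brute_bh(p),
                 tolerance = 1e-12)
  }
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("ranked_list sorts by weight with deterministic gene-id tie-break", {
  rk <- ranked_list(c("b", "a", "c"), c(1, 1, 2))
  expect_identical(rk$genes, c("c", "a", "b"))
  expect_error(ranked_list(c("a", "a"), c(1, 2)), "duplicate")
  # named-vector construction
  rk2 <- ranked_list(c(b = 1, a = 1, c = 2))
  expect_identical(rk2$genes, rk$genes)
})
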