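test_that("self-comparison selects the whole list at any step size", {
  l <- base_ranked_list(230, universe = 600)
  for (step in c(25, 100, 500)) {
    r <- compare_lists(l, l, step = step)
    expect_equal(r$verdict, "significant_overlap")
    expect_equal(r$m_star, 230L)
    expect_setequal(r$common_genes, l$gene)
    expect_true(all(r$trace$k == r$trace$m))
  }
})

test_that("anti-correlated tables share no same-direction genes", {
  sim <- make_related_tables(400, 0.5, 2, 0.2, seed = 5)
  flipped <- dplyr::mutate(sim$table_a, fold_change = -fold_change)
  dc <- compare_directional(sim$table_a, flipped, step = 50)
  expect_equal(dc$up$verdict, "no_significant_overlap")
  expect_equal(dc$down$verdict, "no_significant_overlap")
  expect_equal(nrow(dc$signature), 0)
})

test_that("comparison is symmetric in its two arguments", {
  sim <- make_related_tables(800, 0.3, 2, 0.5, seed = 9)
  a <- rank_genes(sim$table_a, "up")
  b <- rank_genes(sim$table_b, "up")
  # symmetric comparisons need a common universe; rank_genes guarantees it
  expect_equal(list_universe(a), list_universe(b))
  r_ab <- compare_lists(a, b, step = 50)
  r_ba <- compare_lists(b, a, step = 50)
  expect_equal(r_ab$m_star, r_ba$m_star)
  expect_equal(r_ab$verdict, r_ba$verdict)
  expect_setequal(r_ab$common_genes, r_ba$common_genes)
  expect_equal(r_ab$trace$k, r_ba$trace$k)
})

test_that("the trace is monotone and respects k <= m", {
  sim <- make_related_tables(1000, 0.4, 2, 0.6, seed = 2)
  r <- compare_lists(
    rank_genes(sim$table_a, "down"),
    rank_genes(sim$table_b, "down"),
    step = 60, trace_full = TRUE
  )
  tr <- r$trace
  expect_true(all(diff(tr$m) > 0))
  expect_true(all(diff(tr$k) >= 0))
  expect_true(all(tr$k <= tr$m))
  expect_true(is.na(tr$increment_p[1]))
})

test_that("a failing first step yields the empty no-overlap verdict", {
  l <- base_ranked_list(1000, universe = 1000)
  shuffled <- shuffle_unconstrained(l, seed = 4)
  r <- compare_lists(l, shuffled, step = 100)
  if (r$verdict == "no_significant_overlap") {
    expect_equal(r$m_star, 0L)
    expect_length(r$common_genes, 0)
    expect_equal(r$k_star, 0L)
  }
  # the verdict contract holds for whichever outcome the draw produced
  expect_true(r$verdict %in% c("significant_overlap", "no_significant_overlap"))
})

test_that("a partial final step is evaluated when length is not a multiple of step", {
  l <- base_ranked_list(130, universe = 400)
  r <- compare_lists(l, l, step = 50)
  expect_equal(r$trace$m, c(50L, 100L, 130L))
  # step larger than the lists: single evaluation at the minimum length
  r2 <- compare_lists(l, l, step = 500)
  expect_equal(r2$trace$m, 130L)
  expect_equal(r2$m_star, 130L)
})

test_that("mismatched universes, directions, or bad parameters are contract errors", {
  a <- base_ranked_list(50, universe = 100)
  b <- base_ranked_list(50, universe = 120)
  expect_error(compare_lists(a, b), "universe")
  d <- base_ranked_list(50, universe = 100, direction = "down")
  expect_error(compare_lists(a, d), "direction")
  expect_error(compare_lists(a, a, step = 0), "positive")
  expect_error(compare_lists(a, a, alpha = 1.2), "alpha")
  empty_a <- tibble::tibble(gene = "x", fold_change = 1)
  empty_b <- tibble::tibble(gene = "y", fold_change = 1)
  expect_error(compare_directional(empty_a, empty_b), "share no genes")
})

test_that("directional comparison restricts to the shared universe", {
  sim <- make_related_tables(600, 0.4, 2, 0.4, seed = 13)
  # drop different gene subsets from the two platforms
  fc_a <- sim$table_a[-(1:50), ]
  fc_b <- sim$table_b[-(551:600), ]
  dc <- compare_directional(fc_a, fc_b, step = 50)
  expect_equal(dc$n_shared, 500)
  expect_equal(dc$up$n_universe, 500L)
  # signature genes must be measured on both platforms
  expect_true(all(dc$signature$gene %in% intersect(fc_a$gene, fc_b$gene)))
})

test_that("identical tables recover every nonzero shared gene in the signature", {
  sim <- make_related_tables(300, 0.5, 2, 0.3, seed = 21)
  dc <- compare_directional(sim$table_a, sim$table_a, step = 50)
  nonzero <- sim$table_a$gene[sim$table_a$fold_change != 0]
  expect_setequal(dc$signature$gene, nonzero)
})

test_that("venn counts follow the m* - k* arithmetic and propagate verdicts", {
  sim <- make_related_tables(800, 0.4, 2, 0.4, seed = 6)
  dc <- compare_directional(sim$table_a, sim$table_b, step = 100)
  vc <- venn_counts(dc)
  expect_equal(vc$a_only, vc$m_star - vc$common)
  expect_equal(vc$b_only, vc$a_only)
  expect_equal(vc$direction, c("up", "down"))

  flipped <- dplyr::mutate(sim$table_a, fold_change = -fold_change)
  vc0 <- venn_counts(compare_directional(sim$table_a, flipped, step = 100))
  expect_true(all(vc0$verdict == "no_significant_overlap"))
  expect_true(all(vc0$common == 0))
})

test_that("tidy, glance and autoplot expose the comparison", {
  sim <- make_related_tables(500, 0.4, 2, 0.4, seed = 8)
  dc <- compare_directional(sim$table_a, sim$table_b, step = 50)
  td <- tidy(dc)
  expect_true(all(c("direction", "m", "k", "overlap_p", "m_frac", "k_frac") %in% names(td)))
  expect_true(all(td$m_frac <= 1))
  gl <- glance(dc)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$signature_size, nrow(dc$signature))
  p <- ggplot2::autoplot(dc$up)
  expect_s3_class(p, "ggplot")
  p2 <- ggplot2::autoplot(dc)
  expect_s3_class(p2, "ggplot")
})

test_that("identical inputs give identical results", {
  sim <- make_related_tables(400, 0.3, 2, 0.5, seed = 30)
  r1 <- compare_directional(sim$table_a, sim$table_b, step = 50)
  r2 <- compare_directional(sim$table_a, sim$table_b, step = 50)
  expect_identical(r1$up$trace, r2$up$trace)
  expect_identical(r1$signature, r2$signature)
})
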