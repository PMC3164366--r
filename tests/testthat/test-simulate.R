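test_that("shuffles conserve the gene set, universe and magnitudes", {
  l <- base_ranked_list(80, universe = 150)
  for (b in list(
    shuffle_unconstrained(l, seed = 1),
    shuffle_windowed(l, window = 10, seed = 2)
  )) {
    expect_setequal(b$gene, l$gene)
    expect_equal(list_universe(b), 150L)
    expect_equal(b$fold_change, l$fold_change)
    expect_equal(list_direction(b), "up")
  }
  single <- base_ranked_list(1)
  expect_equal(shuffle_unconstrained(single, seed = 3)$gene, single$gene)
})

test_that("unconstrained shuffle is uniform over permutations", {
  l <- base_ranked_list(5)
  n_draw <- 10000
  perms <- vapply(
    seq_len(n_draw),
    function(s) paste(shuffle_unconstrained(l, seed = s)$gene, collapse = ""),
    character(1)
  )
  counts <- table(perms)
  expect_length(counts, 120)
  chi <- chisq.test(as.vector(counts))
  expect_gt(chi$p.value, 1e-4)
})

test_that("windowed shuffle never displaces a gene beyond the window", {
  l <- base_ranked_list(60)
  for (s in 1:300) {
    w <- ((s - 1) %% 10) + 1
    b <- shuffle_windowed(l, window = w, seed = s)
    disp <- abs(match(l$gene, b$gene) - seq_len(60))
    expect_lte(max(disp), w)
  }
})

test_that("a vacuous window reduces to the uniform shuffle", {
  l <- base_ranked_list(4)
  n_draw <- 6000
  perms <- vapply(
    seq_len(n_draw),
    function(s) paste(shuffle_windowed(l, window = 3, seed = s)$gene, collapse = ""),
    character(1)
  )
  counts <- table(perms)
  expect_length(counts, 24)
  chi <- chisq.test(as.vector(counts))
  expect_gt(chi$p.value, 1e-4)
})

test_that("window arguments are validated", {
  l <- base_ranked_list(10)
  expect_error(shuffle_windowed(l, window = 0, seed = 1), "at least 1")
  expect_error(shuffle_windowed(l, window = 10, seed = 1), "smaller than")
})

test_that("shuffles are reproducible from the seed", {
  l <- base_ranked_list(500)
  expect_identical(
    shuffle_windowed(l, window = 20, seed = 42)$gene,
    shuffle_windowed(l, window = 20, seed = 42)$gene
  )
  expect_false(identical(
    shuffle_windowed(l, window = 20, seed = 42)$gene,
    shuffle_windowed(l, window = 20, seed = 43)$gene
  ))
})

test_that("tight windows produce strongly related lists, loose shuffles do not", {
  l <- base_ranked_list(2000, universe = 2000)
  related <- vapply(1:20, function(s) {
    b <- shuffle_windowed(l, window = 40, seed = s)
    compare_lists(l, b, step = 100)$verdict == "significant_overlap"
  }, logical(1))
  unrelated <- vapply(1:20, function(s) {
    b <- shuffle_unconstrained(l, seed = s)
    compare_lists(l, b, step = 100)$verdict == "significant_overlap"
  }, logical(1))
  expect_gte(mean(related), 0.95)
  expect_lte(mean(unrelated), 0.25)
})

test_that("related tables plant the requested shared structure", {
  sim <- make_related_tables(500, 0.3, 2, 0.5, seed = 17)
  expect_equal(nrow(sim$planted), 150)
  expect_equal(nrow(sim$table_a), 500)
  expect_setequal(names(sim$table_a), c("gene", "fold_change"))

  # full sharing without noise: tables identical, all planted at +-effect
  exact <- make_related_tables(200, 1, 2, 0, seed = 1)
  expect_identical(exact$table_a, exact$table_b)
  expect_setequal(abs(exact$table_a$fold_change), 2)
  dc <- compare_directional(exact$table_a, exact$table_b, step = 50)
  expect_setequal(dc$signature$gene, exact$planted$gene)

  # no sharing: the two tables are independent noise
  null <- make_related_tables(300, 0, 2, 0.5, seed = 2)
  expect_equal(nrow(null$planted), 0)
  expect_false(identical(null$table_a$fold_change, null$table_b$fold_change))
})

test_that("expression matrices round-trip through preprocessing", {
  fc <- tibble::tibble(
    gene = sprintf("g%03d", 1:40),
    fold_change = round(seq(-2, 2, length.out = 40), 3)
  )
  # noiseless single-probe round trip is exact
  sim <- make_expression_matrix(fc, replicates = 3, noise_sd = 0, seed = 1)
  got <- compute_fold_changes(sim$expr, sim$design)
  expect_equal(
    got$fold_change[match(fc$gene, got$gene)],
    fc$fold_change,
    tolerance = 1e-12
  )
  # collapsing three identical probesets changes nothing
  sim3 <- make_expression_matrix(fc,
    replicates = 2, probes_per_gene = 3,
    noise_sd = 0, seed = 2
  )
  expect_equal(nrow(sim3$expr), 120)
  got3 <- compute_fold_changes(sim3$expr, sim3$design)
  expect_equal(
    got3$fold_change[match(fc$gene, got3$gene)],
    fc$fold_change,
    tolerance = 1e-12
  )
})

test_that("replicate noise leaves recovered fold-changes unbiased", {
  n <- 1000
  fc <- tibble::tibble(gene = sprintf("g%04d", 1:n), fold_change = rep(1, n))
  sim <- make_expression_matrix(fc, replicates = 3, noise_sd = 0.3, seed = 99)
  got <- compute_fold_changes(sim$expr, sim$design)
  err <- got$fold_change[match(fc$gene, got$gene)] - fc$fold_change
  # s.e. of a difference of two 3-replicate means, averaged over 1000 genes
  se <- 0.3 * sqrt(2 / 3) / sqrt(n)
  expect_lt(abs(mean(err)), 3 * se)
})
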