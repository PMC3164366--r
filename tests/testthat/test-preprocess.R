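make_mat <- function(trt_means, ctl_means, genes = NULL) {
  n <- length(trt_means)
  tibble::tibble(
    probeset = sprintf("p%02d", seq_len(n)),
    gene = if (is.null(genes)) sprintf("G%02d", seq_len(n)) else genes,
    t1 = trt_means, t2 = trt_means,
    c1 = ctl_means, c2 = ctl_means
  )
}

two_by_two_design <- tibble::tibble(
  sample = c("t1", "t2", "c1", "c2"),
  condition = c("treatment", "treatment", "control", "control")
)

test_that("low-expression filter removes only probesets low in both conditions", {
  mat <- make_mat(c(1, 2, 3, 4), c(1, 2, 3, 4))
  kept <- filter_low_expression(mat, two_by_two_design, percentile = 0.25)
  # 25th percentile of (1,2,3,4) is 1.75 (linear interpolation): only the
  # (1,1) probeset is below it in both conditions
  expect_equal(kept$probeset, c("p02", "p03", "p04"))

  # low in treatment only -> retained
  mat2 <- make_mat(c(1, 2, 3, 4), c(4, 2, 3, 1))
  kept2 <- filter_low_expression(mat2, two_by_two_design, percentile = 0.25)
  expect_equal(nrow(kept2), 4)

  # identical scores everywhere: nothing strictly below the quantile
  mat3 <- make_mat(rep(5, 6), rep(5, 6))
  expect_equal(nrow(filter_low_expression(mat3, two_by_two_design)), 6)
})

test_that("filter preserves row order and re-application can only shrink", {
  withr::with_seed(7, {
    mat <- make_mat(runif(40, 1, 10), runif(40, 1, 10))
  })
  kept <- filter_low_expression(mat, two_by_two_design, percentile = 0.25)
  expect_true(all(diff(match(kept$probeset, mat$probeset)) > 0))
  again <- filter_low_expression(kept, two_by_two_design, percentile = 0.25)
  expect_lte(nrow(again), nrow(kept))
})

test_that("the strongest probesets always survive and parameters are validated", {
  # the probeset holding the maximal mean in a condition can never sit
  # strictly below that condition's quantile, so it survives any percentile
  withr::with_seed(19, {
    mat <- make_mat(runif(20, 1, 10), runif(20, 1, 10))
  })
  for (p in c(0.1, 0.5, 0.99)) {
    kept <- filter_low_expression(mat, two_by_two_design, percentile = p)
    expect_true(mat$probeset[which.max(mat$t1)] %in% kept$probeset)
  }
  expect_error(
    filter_low_expression(mat, two_by_two_design, percentile = 0),
    "fraction"
  )
  expect_error(
    filter_low_expression(mat, two_by_two_design, percentile = 1),
    "fraction"
  )
})

test_that("fold-changes are differences of log2 means, collapsed per gene", {
  mat <- tibble::tibble(
    probeset = c("a1", "a2", "b1"),
    gene = c("gA", "gA", "gB"),
    t1 = c(6, 4, 4), t2 = c(6, 4, 4), t3 = c(6, 4, 4),
    c1 = c(4, 4, 3), c2 = c(4, 4, 3), c3 = c(4, 4, 3)
  )
  design <- tibble::tibble(
    sample = c("t1", "t2", "t3", "c1", "c2", "c3"),
    condition = rep(c("treatment", "control"), each = 3)
  )
  fc <- compute_fold_changes(mat, design)
  # gA: probesets +2 and 0 average to +1; gB single probeset +1
  expect_equal(fc$fold_change[fc$gene == "gA"], 1)
  expect_equal(fc$fold_change[fc$gene == "gB"], 1)

  # treatment == control -> all zero
  mat0 <- make_mat(c(3, 5, 7), c(3, 5, 7))
  fc0 <- compute_fold_changes(mat0, two_by_two_design)
  expect_equal(fc0$fold_change, rep(0, 3))
})

test_that("swapping condition labels negates every fold-change exactly", {
  withr::with_seed(11, {
    mat <- make_mat(runif(30, 2, 12), runif(30, 2, 12))
  })
  swapped <- tibble::tibble(
    sample = two_by_two_design$sample,
    condition = rev(two_by_two_design$condition)
  )
  fc <- compute_fold_changes(mat, two_by_two_design)
  fc_sw <- compute_fold_changes(mat, swapped)
  expect_equal(fc_sw$fold_change, -fc$fold_change)
})

test_that("raw-ratio mode takes the literal ratio of log2 means", {
  mat <- make_mat(6, 3)
  fc <- compute_fold_changes(mat, two_by_two_design, mode = "raw_ratio")
  expect_equal(fc$fold_change, 2)
})

test_that("ranking splits by sign, sorts by magnitude, breaks ties alphabetically", {
  fc <- tibble::tibble(
    gene = c("A", "B", "C", "D"),
    fold_change = c(3, -2, 1, 0)
  )
  up <- rank_genes(fc, "up")
  down <- rank_genes(fc, "down")
  expect_equal(up$gene, c("A", "C"))
  expect_equal(down$gene, "B")
  expect_equal(list_universe(up), 4L)
  expect_equal(list_universe(down), 4L)

  tied <- tibble::tibble(gene = c("zz", "aa"), fold_change = c(1.5, 1.5))
  expect_equal(rank_genes(tied, "up")$gene, c("aa", "zz"))

  all_pos <- tibble::tibble(gene = letters[1:5], fold_change = 5:1)
  expect_equal(nrow(rank_genes(all_pos, "down")), 0)
  expect_equal(nrow(rank_genes(all_pos, "up")), 5)
})

test_that("up and down lists partition nonzero genes with non-increasing magnitudes", {
  withr::with_seed(3, {
    fc <- tibble::tibble(
      gene = sprintf("g%03d", 1:200),
      fold_change = round(rnorm(200), 2)
    )
  })
  up <- rank_genes(fc, "up")
  down <- rank_genes(fc, "down")
  nonzero <- fc$gene[fc$fold_change != 0]
  expect_setequal(c(up$gene, down$gene), nonzero)
  expect_length(intersect(up$gene, down$gene), 0)
  expect_true(all(diff(abs(up$fold_change)) <= 0))
  expect_true(all(diff(abs(down$fold_change)) <= 0))
})

test_that("malformed design or matrix inputs are rejected", {
  mat <- make_mat(c(1, 2), c(1, 2))
  bad_design <- tibble::tibble(sample = c("t1", "nope"), condition = c("treatment", "control"))
  expect_error(filter_low_expression(mat, bad_design), "absent")
  no_ctl <- tibble::tibble(sample = c("t1", "t2"), condition = c("treatment", "treatment"))
  expect_error(compute_fold_changes(mat, no_ctl), "no control")
  dup <- mat
  dup$probeset <- c("p1", "p1")
  expect_error(compute_fold_changes(dup, two_by_two_design), "Duplicate")
})
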