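#' Scramble a ranked list completely
#'
#' Generates the null regime for validating the comparison algorithm: list B
#' is a uniform random permutation of list A's gene order, so the two lists
#' share their gene set and universe but carry no rank association. The
#' magnitude sequence of list A is re-attached to the new order (the gene at
#' new rank r receives the rank-r magnitude) so the output is again a valid
#' ranked list; the comparison algorithm only consumes the gene order.
#'
#' @param list_a A [ranked_gene_list()].
#' @param seed Integer seed; the draw is fully reproducible from it.
#' @return A `ranked_gene_list` over the same genes and universe.
#' @examples
#' l <- ranked_gene_list(letters[1:5], 5:1, "up", universe = 10)
#' shuffle_unconstrained(l, seed = 1)$gene
#' @export
shuffle_unconstrained <- function(list_a, seed) {
  stopifnot(inherits(list_a, "ranked_gene_list"))
  n <- nrow(list_a)
  perm <- withr::with_seed(seed, sample.int(n))
  reorder_ranked(list_a, perm)
}

#' Scramble a ranked list with bounded rank displacement
#'
#' Generates the related-lists regime: a random permutation in which no gene
#' moves more than `window` ranks away from its original position. Small
#' windows produce strongly related list pairs (the regime in which the
#' comparison algorithm should select a large common set); a window as large
#' as the list makes the constraint vacuous.
#'
#' Sampling: each rank i receives a jitter key i + Uniform(-window, window)
#' and the list is re-sorted by key. Crowding during the re-sort can push a
#' few displacements slightly past the bound, so the keys of violating genes
#' are resampled and the list re-sorted until every gene satisfies the hard
#' bound — the bound is guaranteed, at the cost of a near-uniform rather
#' than exactly uniform draw over the constrained permutations. When
#' `window >= n - 1` the constraint is vacuous and an exactly uniform
#' permutation is drawn instead.
#'
#' @inheritParams shuffle_unconstrained
#' @param window Maximum rank displacement, an integer in `[1, n - 1]`.
#' @return A `ranked_gene_list` over the same genes and universe.
#' @examples
#' l <- ranked_gene_list(letters[1:10], 10:1, "up")
#' b <- shuffle_windowed(l, window = 2, seed = 1)
#' max(abs(match(l$gene, b$gene) - seq_len(10))) # <= 2
#' @export
shuffle_windowed <- function(list_a, window, seed) {
  stopifnot(inherits(list_a, "ranked_gene_list"))
  n <- nrow(list_a)
  check_count(window, "window")
  if (window < 1) {
    rlang::abort("`window` must be at least 1 (0 would force the identity).")
  }
  if (window >= n) {
    rlang::abort("`window` must be smaller than the list length.")
  }
  perm <- withr::with_seed(seed, {
    if (window >= n - 1) {
      sample.int(n)
    } else {
      keys <- seq_len(n) + stats::runif(n, -window, window)
      res <- NULL
      for (attempt in seq_len(1000L)) {
        cand <- order(keys)
        # displacement of the gene originally at rank cand[r] is r - cand[r]
        viol <- cand[abs(seq_len(n) - cand) > window]
        if (length(viol) == 0) {
          res <- cand
          break
        }
        keys[viol] <- viol + stats::runif(length(viol), -window, window)
      }
      if (is.null(res)) {
        rlang::abort("Windowed shuffle failed to produce a valid draw.")
      }
      res
    }
  })
  reorder_ranked(list_a, perm)
}

reorder_ranked <- function(list_a, perm) {
  new_ranked_gene_list(
    tibble::tibble(
      rank = seq_len(nrow(list_a)),
      gene = list_a$gene[perm],
      fold_change = list_a$fold_change
    ),
    direction = list_direction(list_a),
    universe = list_universe(list_a)
  )
}

#' Simulate a pair of related fold-change tables
#'
#' Builds two fold-change tables over the same `N` genes with a planted
#' common signal, for power and parameter-recovery studies. A fraction
#' `frac_shared` of the genes receives the same signed effect
#' (`+effect_size` or `-effect_size`, sign drawn per gene) in both tables;
#' every table then adds independent Normal(0, `noise_sd`) noise to every
#' gene, so non-planted genes are pure noise and planted genes agree up to
#' noise. The planted set is returned for recovery scoring.
#'
#' @param N Number of genes.
#' @param frac_shared Fraction of genes carrying the shared effect, in
#'   `[0, 1]`.
#' @param effect_size Magnitude of the shared log2 effect.
#' @param noise_sd Standard deviation of the per-table noise.
#' @param seed Integer seed.
#' @return A list with `table_a`, `table_b` (fold-change tibbles) and
#'   `planted`, a tibble (`gene`, `sign`) of the shared-signal genes.
#' @examples
#' sim <- make_related_tables(1000, 0.3, 2, 0.5, seed = 42)
#' nrow(sim$planted) # 300
#' @export
make_related_tables <- function(N, frac_shared, effect_size, noise_sd, seed) {
  check_count(N, "N")
  if (frac_shared < 0 || frac_shared > 1) {
    rlang::abort("`frac_shared` must lie in [0, 1].")
  }
  genes <- sprintf("g%05d", seq_len(N))
  withr::with_seed(seed, {
    n_planted <- round(frac_shared * N)
    planted <- sort(sample(genes, n_planted))
    sign <- sample(c(-1, 1), n_planted, replace = TRUE)
    base <- stats::setNames(numeric(N), genes)
    base[planted] <- sign * effect_size
    fc_a <- base + stats::rnorm(N, 0, noise_sd)
    fc_b <- base + stats::rnorm(N, 0, noise_sd)
    list(
      table_a = tibble::tibble(gene = genes, fold_change = unname(fc_a)),
      table_b = tibble::tibble(gene = genes, fold_change = unname(fc_b)),
      planted = tibble::tibble(gene = planted, sign = sign)
    )
  })
}

#' Simulate a replicate expression matrix from a fold-change table
#'
#' End-to-end fixture: expands a fold-change table into a log2 expression
#' matrix with per-gene baselines, treatment/control replicates, optional
#' multiple probesets per gene, and replicate noise. Running the result
#' through [filter_low_expression()] (optionally), [compute_fold_changes()]
#' and [rank_genes()] recovers the input table up to noise; with
#' `noise_sd = 0` the round trip is exact.
#'
#' @param fc Fold-change table (`gene`, `fold_change`).
#' @param replicates Replicates per condition; default 3.
#' @param probes_per_gene Probesets interrogating each gene; default 1.
#' @param noise_sd Standard deviation of replicate noise on the log2 scale.
#' @param baseline_range Range of the per-gene control-mean baseline
#'   (log2 units), drawn uniformly; default `c(4, 12)`, a typical
#'   normalized-intensity range.
#' @param seed Integer seed.
#' @return A list with `expr` (tibble: `probeset`, `gene`, score columns)
#'   and `design` (tibble: `sample`, `condition`).
#' @examples
#' fc <- tibble::tibble(gene = c("g1", "g2"), fold_change = c(1, -2))
#' sim <- make_expression_matrix(fc, replicates = 3, noise_sd = 0, seed = 1)
#' compute_fold_changes(sim$expr, sim$design)
#' @export
make_expression_matrix <- function(fc, replicates = 3, probes_per_gene = 1,
                                   noise_sd = 0, baseline_range = c(4, 12),
                                   seed) {
  check_fold_change_table(fc)
  check_count(replicates, "replicates")
  check_count(probes_per_gene, "probes_per_gene")
  if (replicates < 1) rlang::abort("`replicates` must be at least 1.")
  n_gene <- nrow(fc)
  withr::with_seed(seed, {
    baseline <- stats::runif(n_gene, baseline_range[1], baseline_range[2])
    gene_idx <- rep(seq_len(n_gene), each = probes_per_gene)
    probeset <- paste0(fc$gene[gene_idx], "_p", rep(seq_len(probes_per_gene), n_gene))
    n_probe <- length(probeset)
    trt_names <- paste0("trt_", seq_len(replicates))
    ctl_names <- paste0("ctl_", seq_len(replicates))
    trt <- matrix(
      baseline[gene_idx] + fc$fold_change[gene_idx] +
        stats::rnorm(n_probe * replicates, 0, noise_sd),
      nrow = n_probe
    )
    ctl <- matrix(
      baseline[gene_idx] + stats::rnorm(n_probe * replicates, 0, noise_sd),
      nrow = n_probe
    )
    expr <- tibble::tibble(probeset = probeset, gene = fc$gene[gene_idx])
    expr[trt_names] <- as.data.frame(trt)
    expr[ctl_names] <- as.data.frame(ctl)
    design <- tibble::tibble(
      sample = c(trt_names, ctl_names),
      condition = rep(c("treatment", "control"), each = replicates)
    )
    list(expr = expr, design = design)
  })
}
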