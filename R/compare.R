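#' Compare two ranked gene lists by marching down the ranks
#'
#' The central algorithm. Starting from the top `step` genes of each list, it
#' computes the overlap `k` between the two top-`m` selections and its
#' hypergeometric tail probability, then repeatedly adds `step` genes at a
#' time. A step is retained while both criteria hold at level `alpha`:
#'
#' 1. the overlap at the current depth is statistically significant
#'    ([overlap_pvalue()]);
#' 2. the increase in the overlap since the previous step cannot be explained
#'    by chance alone ([increment_pvalue()]; not applicable at the first
#'    step).
#'
#' The algorithm stops at the first failure and reports the last depth
#' `m*` at which both criteria held, together with the `k*` genes common to
#' both top-`m*` selections. If the very first step already fails criterion
#' 1, the verdict is `"no_significant_overlap"` and the common set is empty.
#' When the list lengths are not a multiple of `step`, a final smaller step
#' is evaluated so the full lists can be selected.
#'
#' No multiple-testing adjustment is applied across steps by default (the
#' two criteria are sequential raw-probability tests); `bonferroni = TRUE`
#' divides `alpha` by the number of possible steps for a conservative
#' variant.
#'
#' @param list_a,list_b [ranked_gene_list()] objects with the same direction
#'   and the same universe `N`.
#' @param step Genes added per step; default 100.
#' @param alpha Significance level for both criteria; default 0.05.
#' @param bonferroni Divide `alpha` by the number of candidate steps?
#'   Default `FALSE`.
#' @param trace_full After termination, keep evaluating the overlap
#'   probability at the remaining depths (marked not significant) so that
#'   plots show the whole rank range. Does not affect the result. Default
#'   `FALSE`.
#' @return A `list_comparison` object: fields `verdict`
#'   (`"significant_overlap"` or `"no_significant_overlap"`), `m_star`,
#'   `k_star`, `common_genes`, `direction`, `n_universe`, `step`, `alpha`,
#'   and `trace`, a tibble with one row per evaluated step
#'   (`m`, `k`, `overlap_p`, `increment_p`, `significant`). Use [tidy()] for
#'   the trace, [glance()] for a one-row summary, [autoplot()] for the
#'   rank-rank overlap plot.
#' @examples
#' fc <- make_related_tables(500, 0.4, 2, 0.3, seed = 1)
#' up_a <- rank_genes(fc$table_a, "up")
#' up_b <- rank_genes(fc$table_b, "up")
#' compare_lists(up_a, up_b, step = 50)
#' @export
compare_lists <- function(list_a, list_b, step = 100, alpha = 0.05,
                          bonferroni = FALSE, trace_full = FALSE) {
  if (!inherits(list_a, "ranked_gene_list") || !inherits(list_b, "ranked_gene_list")) {
    rlang::abort("Both inputs must be ranked gene lists (see `ranked_gene_list()`).")
  }
  direction <- list_direction(list_a)
  if (!identical(direction, list_direction(list_b))) {
    rlang::abort("The two lists must have the same direction (both up or both down).")
  }
  n_universe <- list_universe(list_a)
  if (!identical(n_universe, list_universe(list_b))) {
    rlang::abort(
      "The two lists must share the same universe N; restrict to common genes first."
    )
  }
  if (nrow(list_a) == 0 || nrow(list_b) == 0) {
    rlang::abort("Both lists must be non-empty.")
  }
  check_count(step, "step")
  if (step <= 0) rlang::abort("`step` must be a positive integer.")
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    rlang::abort("`alpha` must be a single value in (0, 1).")
  }

  len <- min(nrow(list_a), nrow(list_b))
  depths <- if (step > len) len else unique(c(seq.int(step, len, by = step), len))
  if (bonferroni) alpha <- alpha / length(depths)

  k_at <- overlap_counter(list_a$gene, list_b$gene)

  rows <- vector("list", length(depths))
  m_star <- 0L
  prev_m <- NA_integer_
  prev_k <- NA_integer_
  stopped_at <- length(depths)
  for (i in seq_along(depths)) {
    m <- depths[i]
    k <- k_at(m)
    op <- overlap_pvalue(n_universe, m, k)
    ip <- if (i == 1L) {
      NA_real_
    } else {
      increment_pvalue(n_universe, prev_m, prev_k, m, k)
    }
    significant <- op < alpha && (i == 1L || ip < alpha)
    rows[[i]] <- tibble::tibble(
      m = m, k = k, overlap_p = op, increment_p = ip, significant = significant
    )
    if (!significant) {
      stopped_at <- i
      break
    }
    m_star <- m
    prev_m <- m
    prev_k <- k
    stopped_at <- i
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  trace <- dplyr::bind_rows(rows)

  if (trace_full && stopped_at < length(depths)) {
    extra <- depths[(stopped_at + 1L):length(depths)]
    trace <- dplyr::bind_rows(trace, purrr::map_dfr(extra, function(m) {
      k <- k_at(m)
      tibble::tibble(
        m = m, k = k, overlap_p = overlap_pvalue(n_universe, m, k),
        increment_p = NA_real_, significant = FALSE
      )
    }))
  }

  if (m_star == 0L) {
    common <- character(0)
  } else {
    common <- intersect(
      utils::head(list_a$gene, m_star),
      utils::head(list_b$gene, m_star)
    )
  }
  structure(
    list(
      verdict = if (m_star > 0L) "significant_overlap" else "no_significant_overlap",
      m_star = m_star,
      k_star = length(common),
      common_genes = common,
      direction = direction,
      n_universe = n_universe,
      step = as.integer(step),
      alpha = alpha,
      trace = trace
    ),
    class = "list_comparison"
  )
}

# Closure returning k(m) = |top-m(A) %in% top-m(B)| in O(1) after O(n) setup:
# a gene contributes to k(m) once m reaches the larger of its two ranks.
overlap_counter <- function(genes_a, genes_b) {
  pos_b <- match(genes_a, genes_b)
  shared <- which(!is.na(pos_b))
  max_rank <- pmax(shared, pos_b[shared])
  cum <- cumsum(tabulate(max_rank, nbins = max(length(genes_a), length(genes_b))))
  function(m) {
    if (length(cum) == 0 || m < 1) 0L else cum[min(m, length(cum))]
  }
}

#' @export
print.list_comparison <- function(x, ...) {
  cat("# Ranked-list comparison (", x$direction, "-regulated)\n", sep = "")
  cat(sprintf(
    "  verdict: %s | m* = %d, k* = %d of N = %d (step %d, alpha %g)\n",
    x$verdict, x$m_star, x$k_star, x$n_universe, x$step, x$alpha
  ))
  cat(sprintf("  steps evaluated: %d\n", nrow(x$trace)))
  invisible(x)
}

#' Compare two experiments in both directions of change
#'
#' Runs the marching comparison separately on the up-regulated and the
#' down-regulated lists of two fold-change tables. The two tables are first
#' restricted to their shared gene universe (genes measured on only one
#' platform are dropped; `N` is the size of the shared universe), then
#' ranked per direction with [rank_genes()] and compared with
#' [compare_lists()]. The union of the two common-gene sets, tagged by
#' direction, is the expression *signature* of the pair of experiments.
#'
#' @param fc_a,fc_b Fold-change tables (`gene`, `fold_change`).
#' @inheritParams compare_lists
#' @return A `directional_comparison` object: fields `up` and `down`
#'   (each a `list_comparison`), `signature` (tibble `gene`, `direction`),
#'   and `n_shared`, the shared-universe size.
#' @examples
#' fc <- make_related_tables(500, 0.4, 2, 0.3, seed = 1)
#' compare_directional(fc$table_a, fc$table_b, step = 50)
#' @export
compare_directional <- function(fc_a, fc_b, step = 100, alpha = 0.05,
                                bonferroni = FALSE, trace_full = FALSE) {
  check_fold_change_table(fc_a)
  check_fold_change_table(fc_b)
  shared <- intersect(fc_a$gene, fc_b$gene)
  if (length(shared) == 0) {
    rlang::abort("The two tables share no genes; nothing to compare.")
  }
  fc_a <- fc_a[fc_a$gene %in% shared, , drop = FALSE]
  fc_b <- fc_b[fc_b$gene %in% shared, , drop = FALSE]
  results <- lapply(c(up = "up", down = "down"), function(dir) {
    la <- rank_genes(fc_a, dir)
    lb <- rank_genes(fc_b, dir)
    if (nrow(la) == 0 || nrow(lb) == 0) {
      empty_comparison(dir, length(shared), step, alpha)
    } else {
      compare_lists(la, lb,
        step = step, alpha = alpha,
        bonferroni = bonferroni, trace_full = trace_full
      )
    }
  })
  signature <- dplyr::bind_rows(
    tibble::tibble(gene = results$up$common_genes, direction = "up"),
    tibble::tibble(gene = results$down$common_genes, direction = "down")
  )
  structure(
    list(
      up = results$up,
      down = results$down,
      signature = signature,
      n_shared = length(shared)
    ),
    class = "directional_comparison"
  )
}

empty_comparison <- function(direction, n_universe, step, alpha) {
  structure(
    list(
      verdict = "no_significant_overlap",
      m_star = 0L, k_star = 0L, common_genes = character(0),
      direction = direction, n_universe = as.integer(n_universe),
      step = as.integer(step), alpha = alpha,
      trace = tibble::tibble(
        m = integer(0), k = integer(0), overlap_p = numeric(0),
        increment_p = numeric(0), significant = logical(0)
      )
    ),
    class = "list_comparison"
  )
}

#' @export
print.directional_comparison <- function(x, ...) {
  cat("# Directional ranked-list comparison, shared universe N =", x$n_shared, "\n")
  for (dir in c("up", "down")) {
    r <- x[[dir]]
    cat(sprintf(
      "  %-4s: %s (m* = %d, k* = %d)\n", dir, r$verdict, r$m_star, r$k_star
    ))
  }
  cat("  signature size:", nrow(x$signature), "genes\n")
  invisible(x)
}

#' Venn counts at the selected depth
#'
#' Summarises a comparison as the three Venn compartments at the selected
#' depth `m*`: genes only in the top-`m*` of list A, the `k*` common genes,
#' and genes only in the top-`m*` of list B. By symmetry of the selection
#' each exclusive compartment holds `m* - k*` genes. For a direction with
#' verdict `"no_significant_overlap"` the counts are zero and the verdict
#' column records why.
#'
#' @param x A `list_comparison` or `directional_comparison`.
#' @return A tibble with columns `direction`, `verdict`, `m_star`, `a_only`,
#'   `common`, `b_only`.
#' @examples
#' fc <- make_related_tables(500, 0.4, 2, 0.3, seed = 1)
#' venn_counts(compare_directional(fc$table_a, fc$table_b, step = 50))
#' @export
venn_counts <- function(x) {
  UseMethod("venn_counts")
}

#' @export
venn_counts.list_comparison <- function(x) {
  tibble::tibble(
    direction = x$direction,
    verdict = x$verdict,
    m_star = x$m_star,
    a_only = x$m_star - x$k_star,
    common = x$k_star,
    b_only = x$m_star - x$k_star
  )
}

#' @export
venn_counts.directional_comparison <- function(x) {
  dplyr::bind_rows(venn_counts(x$up), venn_counts(x$down))
}
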