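#' Remove probesets with low expression in both conditions
#'
#' Microarray probesets that sit in the bottom tail of the intensity
#' distribution in *both* the treatment and the control cohort carry mostly
#' noise. Following standard practice for normalized log2 expression scores,
#' a probeset is dropped when its mean treatment score falls below the
#' `percentile` quantile of all per-probeset mean treatment scores *and* its
#' mean control score falls below the corresponding control quantile. A
#' probeset low in only one condition is retained — it may be a genuine
#' strong responder.
#'
#' Quantiles use the linear-interpolation convention (`stats::quantile`
#' type 7); the comparison is strict (`<`), so a matrix of identical scores
#' loses nothing.
#'
#' @param mat Expression tibble: column `probeset`, optional column `gene`,
#'   remaining columns one per replicate of log2 expression scores. See
#'   [read_expression_matrix()].
#' @param design Tibble with columns `sample`, `condition` mapping every
#'   score column of `mat` to `"treatment"` or `"control"`.
#' @param percentile Quantile cutoff as a fraction in (0, 1); default 0.25,
#'   the 25th percentile.
#' @return The filtered expression tibble, row order preserved.
#' @examples
#' sim <- make_expression_matrix(
#'   make_related_tables(50, 0.2, 2, 0.3, seed = 1)$table_a,
#'   replicates = 3, seed = 2
#' )
#' nrow(filter_low_expression(sim$expr, sim$design))
#' @export
filter_low_expression <- function(mat, design, percentile = 0.25) {
  check_design(mat, design)
  if (!is.numeric(percentile) || length(percentile) != 1 ||
    percentile <= 0 || percentile >= 1) {
    rlang::abort("`percentile` must be a single fraction strictly in (0, 1).")
  }
  trt_mean <- condition_means(mat, design, "treatment")
  ctl_mean <- condition_means(mat, design, "control")
  q_trt <- stats::quantile(trt_mean, percentile, names = FALSE)
  q_ctl <- stats::quantile(ctl_mean, percentile, names = FALSE)
  drop <- trt_mean < q_trt & ctl_mean < q_ctl
  kept <- mat[!drop, , drop = FALSE]
  if (nrow(kept) == 0) {
    rlang::abort("Filtering removed every probeset; the matrix is degenerate.")
  }
  kept
}

#' Collapse an expression matrix to per-gene log2 fold-changes
#'
#' Per probeset, the fold-change is the difference between the mean log2
#' treatment score and the mean log2 control score — the log2 of the
#' linear-scale ratio of geometric means (`mode = "log_diff"`, the default).
#' `mode = "raw_ratio"` instead takes the literal ratio of the two means of
#' log2 scores; it is exposed for comparison but is scale-dependent and not
#' recommended. Genes interrogated by several probesets get the arithmetic
#' mean of their probesets' fold-changes.
#'
#' @inheritParams filter_low_expression
#' @param mode Fold-change definition, `"log_diff"` (default) or
#'   `"raw_ratio"`.
#' @return A fold-change table: tibble with one row per gene symbol, columns
#'   `gene` and `fold_change`.
#' @examples
#' mat <- tibble::tibble(
#'   probeset = c("p1", "p2"), gene = c("g1", "g1"),
#'   t1 = c(5, 4), t2 = c(5, 4), c1 = c(3, 4), c2 = c(3, 4)
#' )
#' design <- tibble::tibble(
#'   sample = c("t1", "t2", "c1", "c2"),
#'   condition = c("treatment", "treatment", "control", "control")
#' )
#' compute_fold_changes(mat, design) # g1: mean(+2, 0) = +1
#' @export
compute_fold_changes <- function(mat, design, mode = c("log_diff", "raw_ratio")) {
  mode <- match.arg(mode)
  check_design(mat, design)
  trt_mean <- condition_means(mat, design, "treatment")
  ctl_mean <- condition_means(mat, design, "control")
  fc <- switch(mode,
    log_diff = trt_mean - ctl_mean,
    raw_ratio = trt_mean / ctl_mean
  )
  gene <- if ("gene" %in% names(mat)) mat$gene else mat$probeset
  tibble::tibble(gene = as.character(gene), fold_change = fc) |>
    dplyr::summarise(
      fold_change = mean(.data$fold_change),
      .by = "gene"
    )
}

#' Rank genes by magnitude of change in one direction
#'
#' Builds the directional ranked list the comparison algorithm consumes:
#' the up-list holds genes with positive fold-change sorted by fold-change
#' descending; the down-list holds negative-fold-change genes sorted by
#' absolute fold-change descending. Ties are broken alphabetically by gene
#' symbol so every run is deterministic. Genes with fold-change exactly zero
#' join neither list but are counted in the universe `N` — they were
#' measured, so they belong to the population the hypergeometric model draws
#' from.
#'
#' @param fc Fold-change table (`gene`, `fold_change`), one row per gene.
#' @param direction `"up"` or `"down"`.
#' @return A [ranked_gene_list()] with `universe = nrow(fc)`.
#' @examples
#' fc <- tibble::tibble(gene = c("A", "B", "C", "D"), fold_change = c(3, -2, 1, 0))
#' rank_genes(fc, "up") # A, C; N = 4
#' rank_genes(fc, "down") # B; N = 4
#' @export
rank_genes <- function(fc, direction = c("up", "down")) {
  direction <- match.arg(direction)
  check_fold_change_table(fc)
  sel <- if (direction == "up") fc$fold_change > 0 else fc$fold_change < 0
  sub <- fc[sel, , drop = FALSE]
  ord <- order(-abs(sub$fold_change), sub$gene)
  ranked_gene_list(
    gene = sub$gene[ord],
    fold_change = sub$fold_change[ord],
    direction = direction,
    universe = nrow(fc)
  )
}

condition_means <- function(mat, design, condition) {
  cols <- design$sample[design$condition == condition]
  scores <- as.matrix(mat[, cols, drop = FALSE])
  rowMeans(scores)
}

check_design <- function(mat, design) {
  if (!"probeset" %in% names(mat)) {
    rlang::abort("Expression matrix must have a `probeset` column.")
  }
  if (anyDuplicated(mat$probeset)) {
    dup <- unique(mat$probeset[duplicated(mat$probeset)])
    rlang::abort(sprintf(
      "Duplicate probeset id(s): %s.", paste(utils::head(dup, 5), collapse = ", ")
    ))
  }
  if (!all(c("sample", "condition") %in% names(design))) {
    rlang::abort("`design` needs columns `sample` and `condition`.")
  }
  missing <- setdiff(design$sample, names(mat))
  if (length(missing) > 0) {
    rlang::abort(sprintf(
      "Design sample(s) absent from the matrix: %s.",
      paste(missing, collapse = ", ")
    ))
  }
  bad <- setdiff(unique(design$condition), c("treatment", "control"))
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "Unknown condition label(s): %s (use \"treatment\"/\"control\").",
      paste(bad, collapse = ", ")
    ))
  }
  for (cond in c("treatment", "control")) {
    if (!any(design$condition == cond)) {
      rlang::abort(sprintf("Design has no %s sample.", cond))
    }
  }
  score_cols <- design$sample
  scores <- mat[, score_cols, drop = FALSE]
  if (!all(vapply(scores, is.numeric, logical(1))) ||
    anyNA(as.matrix(scores))) {
    rlang::abort("Expression scores must be numeric with no missing values.")
  }
  invisible(TRUE)
}

check_fold_change_table <- function(fc) {
  if (!all(c("gene", "fold_change") %in% names(fc))) {
    rlang::abort("A fold-change table needs columns `gene` and `fold_change`.")
  }
  if (nrow(fc) == 0) {
    rlang::abort("The fold-change table is empty.")
  }
  if (anyDuplicated(fc$gene)) {
    rlang::abort("A fold-change table must have one row per gene symbol.")
  }
  if (!all(is.finite(fc$fold_change))) {
    rlang::abort("All fold-changes must be finite.")
  }
  invisible(TRUE)
}
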