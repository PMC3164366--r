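#' Construct a ranked gene list
#'
#' The fundamental input of the comparison algorithm: genes ordered by the
#' magnitude of their expression change in one direction, rank 1 strongest.
#' The object is a tibble with columns `rank`, `gene`, `fold_change` plus two
#' attributes: `direction` (`"up"` or `"down"`) and `universe`, the number of
#' genes `N` that survived filtering — the population the hypergeometric
#' model draws from. Zero-change genes belong to neither directional list but
#' still count toward `universe`.
#'
#' @param gene Character vector of unique gene identifiers, strongest first.
#' @param fold_change Signed log2 fold-changes, one per gene; magnitudes must
#'   be non-increasing along the order and signs must match `direction`.
#' @param direction `"up"` or `"down"`.
#' @param universe Universe size `N`; at least `length(gene)`.
#' @return A `ranked_gene_list` tibble.
#' @examples
#' ranked_gene_list(c("a", "b"), c(3, 1.5), "up", universe = 10)
#' @export
ranked_gene_list <- function(gene, fold_change, direction = c("up", "down"),
                             universe = length(gene)) {
  direction <- match.arg(direction)
  gene <- as.character(gene)
  fold_change <- as.numeric(fold_change)
  if (length(gene) != length(fold_change)) {
    rlang::abort("`gene` and `fold_change` must have the same length.")
  }
  if (anyDuplicated(gene)) {
    rlang::abort("Gene identifiers in a ranked list must be unique.")
  }
  if (!all(is.finite(fold_change))) {
    rlang::abort("All fold-changes must be finite.")
  }
  if (direction == "up" && any(fold_change <= 0)) {
    rlang::abort("An up-list may only contain genes with positive fold-change.")
  }
  if (direction == "down" && any(fold_change >= 0)) {
    rlang::abort("A down-list may only contain genes with negative fold-change.")
  }
  mag <- abs(fold_change)
  if (length(mag) > 1 && any(diff(mag) > 0)) {
    rlang::abort("Fold-change magnitudes must be non-increasing along the ranks.")
  }
  check_count(universe, "universe")
  if (universe < length(gene)) {
    rlang::abort("`universe` cannot be smaller than the list length.")
  }
  out <- tibble::tibble(
    rank = seq_along(gene),
    gene = gene,
    fold_change = fold_change
  )
  new_ranked_gene_list(out, direction, as.integer(universe))
}

new_ranked_gene_list <- function(tbl, direction, universe) {
  structure(
    tbl,
    direction = direction,
    universe = universe,
    class = c("ranked_gene_list", class(tibble::tibble()))
  )
}

#' @export
print.ranked_gene_list <- function(x, ...) {
  cat(sprintf(
    "# Ranked gene list: %d %s-regulated genes (universe N = %d)\n",
    nrow(x), attr(x, "direction"), attr(x, "universe")
  ))
  NextMethod()
}

#' @rdname ranked_gene_list
#' @param x A `ranked_gene_list`.
#' @export
list_direction <- function(x) attr(x, "direction")

#' @rdname ranked_gene_list
#' @export
list_universe <- function(x) attr(x, "universe")
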