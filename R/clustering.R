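#' Run all pairwise directional comparisons between experiments
#'
#' Convenience driver for clustering many experimental conditions: runs
#' [compare_directional()] on every unordered pair of fold-change tables and
#' collects the common-gene counts. `k` is the total signature size
#' (up-overlap + down-overlap) unless `direction` restricts it; pairs with no
#' significant overlap contribute `k = 0`.
#'
#' @param tables Named list of fold-change tables, one per condition.
#' @inheritParams compare_lists
#' @param direction Which overlap counts enter `k`: `"both"` (default),
#'   `"up"` or `"down"`.
#' @return A tibble with columns `cond_a`, `cond_b`, `k_up`, `k_down`, `k`,
#'   one row per unordered pair.
#' @export
pairwise_overlaps <- function(tables, step = 100, alpha = 0.05,
                              direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  if (is.null(names(tables)) || anyDuplicated(names(tables))) {
    rlang::abort("`tables` must be a named list with unique condition names.")
  }
  if (length(tables) < 2) {
    rlang::abort("Need at least two conditions for pairwise comparison.")
  }
  pairs <- utils::combn(names(tables), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]
    b <- pairs[2, j]
    dc <- compare_directional(tables[[a]], tables[[b]], step = step, alpha = alpha)
    tibble::tibble(
      cond_a = a, cond_b = b,
      k_up = dc$up$k_star, k_down = dc$down$k_star,
      k = switch(direction,
        both = dc$up$k_star + dc$down$k_star,
        up = dc$up$k_star,
        down = dc$down$k_star
      )
    )
  })
}

#' Overlap-distance matrix for a set of experiments
#'
#' Converts pairwise common-gene counts \eqn{k_{ij}} into the clustering
#' metric \eqn{m_{ij} = \max_{(l,m)} (k_{lm}) - k_{ij}}: the pair with the
#' largest overlap sits at distance 0 and a pair with no common genes sits
#' at the maximum distance. The maximum is taken over off-diagonal pairs
#' only (self-overlaps are not experimental comparisons).
#'
#' @param pairs Tibble with columns `cond_a`, `cond_b`, `k` covering every
#'   unordered pair of conditions, e.g. from [pairwise_overlaps()].
#' @return An `overlap_dist` object: list with `labels`, the symmetric
#'   integer matrix `k`, and the derived distance matrix `d`.
#' @examples
#' pairs <- tibble::tibble(
#'   cond_a = c("A", "A", "B"), cond_b = c("B", "C", "C"), k = c(10, 4, 0)
#' )
#' build_distance_matrix(pairs)$d
#' @export
build_distance_matrix <- function(pairs) {
  if (!all(c("cond_a", "cond_b", "k") %in% names(pairs))) {
    rlang::abort("`pairs` needs columns `cond_a`, `cond_b`, `k`.")
  }
  labels <- sort(unique(c(pairs$cond_a, pairs$cond_b)))
  C <- length(labels)
  if (C < 2) rlang::abort("Need at least two conditions.")
  expected <- utils::combn(labels, 2)
  have <- paste(pmin(pairs$cond_a, pairs$cond_b), pmax(pairs$cond_a, pairs$cond_b))
  want <- paste(expected[1, ], expected[2, ])
  missing <- setdiff(want, have)
  if (length(missing) > 0) {
    rlang::abort(c(
      "Missing pairwise comparison(s):",
      stats::setNames(missing, rep("x", length(missing)))
    ))
  }
  if (anyDuplicated(have)) {
    rlang::abort("Duplicate pairwise comparison(s) in `pairs`.")
  }
  if (any(pairs$k < 0)) rlang::abort("Overlap counts must be non-negative.")
  k <- matrix(0, C, C, dimnames = list(labels, labels))
  ia <- match(pairs$cond_a, labels)
  ib <- match(pairs$cond_b, labels)
  k[cbind(ia, ib)] <- pairs$k
  k[cbind(ib, ia)] <- pairs$k
  kmax <- max(k[row(k) != col(k)])
  d <- kmax - k
  diag(d) <- 0
  structure(list(labels = labels, k = k, d = d), class = "overlap_dist")
}

#' @export
print.overlap_dist <- function(x, ...) {
  cat(
    "# Overlap-distance matrix over", length(x$labels), "conditions",
    "(max off-diagonal overlap:", max(x$k[row(x$k) != col(x$k)]), "genes)\n"
  )
  print(x$d)
  invisible(x)
}

#' Complete-linkage clustering of experiments by overlap distance
#'
#' Agglomerative hierarchical clustering of the conditions using the
#' overlap distance of [build_distance_matrix()] and the complete-linkage
#' criterion (the distance between clusters is the largest pairwise distance
#' between their members, so merge heights are monotone non-decreasing).
#' Conditions are ordered alphabetically before clustering so the result is
#' invariant under permutation of the input; remaining ties are resolved by
#' that fixed order.
#'
#' @param dist An `overlap_dist` object, or a symmetric numeric distance
#'   matrix with dimnames.
#' @param method Linkage criterion passed to [stats::hclust()];
#'   `"complete"` is the supported default, other criteria are available
#'   but untested against the overlap metric.
#' @return An object of class `hclust`.
#' @examples
#' pairs <- tibble::tibble(
#'   cond_a = c("A", "A", "B"), cond_b = c("B", "C", "C"), k = c(10, 4, 0)
#' )
#' hc <- complete_linkage(build_distance_matrix(pairs))
#' hc$height # 0, 10
#' @export
complete_linkage <- function(dist, method = "complete") {
  d <- if (inherits(dist, "overlap_dist")) {
    dist$d
  } else if (is.matrix(dist)) {
    dist
  } else {
    rlang::abort("`dist` must be an overlap_dist or a distance matrix.")
  }
  if (nrow(d) < 2) rlang::abort("Need at least two conditions to cluster.")
  ord <- order(rownames(d))
  d <- d[ord, ord]
  stats::hclust(stats::as.dist(d), method = method)
}

#' Serialize a dendrogram as Newick
#'
#' Writes the clustering tree in Newick format with ultrametric branch
#' lengths derived from the merge heights (leaf depths equal half the root
#' merge height, the standard dendrogram-to-phylogram convention).
#'
#' @param hc An `hclust` object, e.g. from [complete_linkage()].
#' @param path Optional file path; when `NULL` the Newick string is
#'   returned invisibly only.
#' @return The Newick string, invisibly.
#' @export
write_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
  }
  invisible(txt)
}

#' Top-level bipartition of a dendrogram
#'
#' Cuts the tree at its root merge into two groups — the first split the
#' clustering makes. Used to ask whether a known structure (for example,
#' tissue of origin) dominates the overlap pattern.
#'
#' @param hc An `hclust` object.
#' @return A list of two character vectors of condition labels.
#' @export
top_split <- function(hc) {
  grp <- stats::cutree(hc, k = 2)
  unname(split(names(grp), grp))
}
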