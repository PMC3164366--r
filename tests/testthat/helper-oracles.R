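# Shared fixtures and independent oracles used across the suite.

# A clean ranked list: genes g00001..gN ranked by decreasing magnitude.
base_ranked_list <- function(n, universe = n, direction = "up") {
  sgn <- if (direction == "up") 1 else -1
  ranked_gene_list(
    sprintf("g%05d", seq_len(n)),
    sgn * seq(n, 1) / n,
    direction,
    universe = universe
  )
}

# Exhaustive-enumeration oracle for the overlap tail probability: fix the
# first m-subset as {1..m} (exchangeability), enumerate every m-subset of
# the second list, and count overlaps of at least k_star.
enum_overlap_tail <- function(N, m, k_star) {
  subsets <- utils::combn(N, m)
  overlaps <- colSums(subsets <= m)
  mean(overlaps >= k_star)
}

# Permutation oracle for the increment test: hold the top m_prev ranks of
# both lists fixed in a canonical configuration with overlap k_prev, extend
# each list by dm random genes from its own remaining pool, and estimate
# P(overlap gain >= dk_obs) by simulation.
mc_increment_tail <- function(N, m_prev, k_prev, dm, dk_obs, nsim, seed) {
  set.seed(seed)
  s_a <- seq_len(m_prev)
  s_b <- c(seq_len(k_prev), m_prev + seq_len(m_prev - k_prev))
  pool_a <- setdiff(seq_len(N), s_a)
  pool_b <- setdiff(seq_len(N), s_b)
  in_b <- logical(N)
  in_b[s_b] <- TRUE
  hits <- 0L
  for (i in seq_len(nsim)) {
    a_new <- sample(pool_a, dm)
    b_new <- sample(pool_b, dm)
    sel_b <- in_b
    sel_b[b_new] <- TRUE
    k_new <- sum(sel_b[c(s_a, a_new)])
    if (k_new - k_prev >= dk_obs) hits <- hits + 1L
  }
  hits / nsim
}

# Hand-rolled agglomerative complete-linkage clustering, the independent
# reference for the hclust-backed implementation. Returns merge heights and
# the leaf sets joined at each merge.
naive_complete_linkage <- function(d) {
  n <- nrow(d)
  members <- lapply(seq_len(n), identity)
  cd <- d
  diag(cd) <- Inf
  active <- seq_len(n)
  heights <- numeric(n - 1)
  merged_sets <- vector("list", n - 1)
  for (s in seq_len(n - 1)) {
    sub <- cd[active, active, drop = FALSE]
    idx <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    i <- active[min(idx)]
    j <- active[max(idx)]
    heights[s] <- cd[i, j]
    members[[i]] <- sort(c(members[[i]], members[[j]]))
    merged_sets[[s]] <- members[[i]]
    # complete linkage: distance to the union is the max of the parts
    for (a in setdiff(active, c(i, j))) {
      cd[i, a] <- cd[a, i] <- max(cd[i, a], cd[j, a])
    }
    active <- setdiff(active, j)
  }
  list(heights = heights, merged_sets = merged_sets)
}

# Leaf sets joined at each merge of an hclust tree, for comparison with the
# naive reference.
hclust_merged_sets <- function(hc) {
  sets <- vector("list", nrow(hc$merge))
  for (s in seq_len(nrow(hc$merge))) {
    grab <- function(v) if (v < 0) -v else sets[[v]]
    sets[[s]] <- sort(c(grab(hc$merge[s, 1]), grab(hc$merge[s, 2])))
  }
  sets
}

# F1 score of a recovered gene set against a planted truth set.
recovery_f1 <- function(recovered, truth) {
  tp <- length(intersect(recovered, truth))
  if (tp == 0) {
    return(0)
  }
  prec <- tp / length(recovered)
  rec <- tp / length(truth)
  2 * prec * rec / (prec + rec)
}

# Planted two-tissue pairwise overlap table: conditions in the same tissue
# share many signature genes, conditions in different tissues few.
planted_tissue_pairs <- function(n_per_tissue = 3, k_within = 120,
                                 k_between = 10, seed = 1) {
  conds <- c(
    paste0("tissue1_", seq_len(n_per_tissue)),
    paste0("tissue2_", seq_len(n_per_tissue))
  )
  tissue <- rep(c("tissue1", "tissue2"), each = n_per_tissue)
  pairs <- utils::combn(seq_along(conds), 2)
  withr::with_seed(seed, {
    k <- vapply(seq_len(ncol(pairs)), function(j) {
      same <- tissue[pairs[1, j]] == tissue[pairs[2, j]]
      stats::rpois(1, if (same) k_within else k_between)
    }, numeric(1))
    list(
      pairs = tibble::tibble(
        cond_a = conds[pairs[1, ]],
        cond_b = conds[pairs[2, ]],
        k = k
      ),
      tissues = split(conds, tissue)
    )
  })
}
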