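#' Run configuration
#'
#' Bundle of the tunable parameters of the pipeline, echoed into every
#' structured output artifact so results carry their own provenance. Two
#' runs with identical configuration (including `seed`) produce
#' byte-identical outputs.
#'
#' @param step Genes added per marching step.
#' @param alpha Significance level for both stopping criteria.
#' @param percentile Low-expression filter fraction.
#' @param fold_change_mode `"log_diff"` or `"raw_ratio"`.
#' @param direction `"both"`, `"up"` or `"down"`.
#' @param seed Integer seed; required by any stochastic operation.
#' @return A `run_config` list.
#' @export
run_config <- function(step = 100, alpha = 0.05, percentile = 0.25,
                       fold_change_mode = c("log_diff", "raw_ratio"),
                       direction = c("both", "up", "down"), seed = NULL) {
  structure(
    list(
      step = as.integer(step),
      alpha = alpha,
      percentile = percentile,
      fold_change_mode = match.arg(fold_change_mode),
      direction = match.arg(direction),
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Read a tab-delimited expression matrix
#'
#' Expects a header row of sample names, a first column of probeset
#' identifiers, and numeric log2 expression scores. Rows with missing or
#' non-numeric scores are rejected with their line numbers — malformed
#' input is never silently coerced. The returned tibble has columns
#' `probeset`, `gene` (initially a copy of `probeset`; see
#' [apply_probe_map()]) and one column per sample.
#'
#' @param path Path to the TSV file.
#' @param design A design tibble (`sample`, `condition`) or a path to a
#'   two-column TSV with those columns; every design sample must appear in
#'   the header and both conditions must be present.
#' @return A list with `expr` (expression tibble) and `design` (tibble).
#' @export
read_expression_matrix <- function(path, design) {
  raw <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2) {
    rlang::abort("Expression matrix needs a probeset column plus sample columns.")
  }
  probeset <- raw[[1]]
  if (anyDuplicated(probeset)) {
    idx <- which(duplicated(probeset))[1]
    rlang::abort(sprintf(
      "Duplicate probeset id \"%s\" at line %d.", probeset[idx], idx + 1L
    ))
  }
  scores <- raw[, -1, drop = FALSE]
  numeric_scores <- suppressWarnings(
    as.data.frame(lapply(scores, as.numeric), check.names = FALSE)
  )
  bad_rows <- which(apply(is.na(numeric_scores) | scores == "", 1, any))
  if (length(bad_rows) > 0) {
    rlang::abort(sprintf(
      "Missing or non-numeric expression score(s) at line(s): %s.",
      paste(utils::head(bad_rows + 1L, 10), collapse = ", ")
    ))
  }
  if (is.character(design)) {
    design <- tibble::as_tibble(
      utils::read.delim(design, colClasses = "character")
    )
  }
  design <- tibble::as_tibble(design)
  expr <- tibble::tibble(probeset = probeset, gene = probeset)
  expr[names(numeric_scores)] <- numeric_scores
  check_design(expr, design)
  list(expr = expr, design = design)
}

#' Attach gene symbols to probesets
#'
#' Replaces the `gene` column of an expression tibble using a two-column
#' probeset-to-gene mapping. Probesets absent from the map keep their
#' probeset id as gene symbol.
#'
#' @param mat Expression tibble from [read_expression_matrix()].
#' @param map Tibble with columns `probeset`, `gene`, or a path to a
#'   two-column TSV with those columns.
#' @return The expression tibble with the `gene` column updated.
#' @export
apply_probe_map <- function(mat, map) {
  if (is.character(map)) {
    map <- tibble::as_tibble(
      utils::read.delim(map, colClasses = "character")
    )
    names(map)[1:2] <- c("probeset", "gene")
  }
  if (anyDuplicated(map$probeset)) {
    rlang::abort("Probe map must have one gene symbol per probeset.")
  }
  hit <- match(mat$probeset, map$probeset)
  mat$gene <- ifelse(is.na(hit), mat$probeset, map$gene[hit])
  mat
}

#' Write and read ranked-list TSV files
#'
#' The on-disk format is three tab-separated columns `rank`, `gene`,
#' `fold_change` preceded by a `#` provenance line carrying the direction
#' and the universe size, so a list round-trips losslessly.
#'
#' @param x A [ranked_gene_list()].
#' @param path Output file path.
#' @return `write_ranked_list()` returns `path` invisibly;
#'   `read_ranked_list()` returns a `ranked_gene_list`.
#' @export
write_ranked_list <- function(x, path) {
  stopifnot(inherits(x, "ranked_gene_list"))
  header <- sprintf(
    "# direction=%s universe=%d", list_direction(x), list_universe(x)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines("rank\tgene\tfold_change", con)
  writeLines(
    sprintf("%d\t%s\t%s", x$rank, x$gene, format_full(x$fold_change)),
    con
  )
  invisible(path)
}

#' @rdname write_ranked_list
#' @export
read_ranked_list <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2 || !startsWith(lines[1], "#")) {
    rlang::abort("Ranked-list file must start with a '# direction=... universe=...' line.")
  }
  meta <- lines[1]
  direction <- sub(".*direction=(\\w+).*", "\\1", meta)
  universe <- as.integer(sub(".*universe=(\\d+).*", "\\1", meta))
  body <- utils::read.delim(text = lines[-1], colClasses = c("integer", "character", "numeric"))
  ranked_gene_list(body$gene, body$fold_change, direction, universe)
}

#' Write and read fold-change tables
#'
#' Two tab-separated columns `gene`, `fold_change` with a header row.
#'
#' @param fc Fold-change tibble.
#' @param path File path.
#' @return `write_fold_changes()` returns `path` invisibly;
#'   `read_fold_changes()` returns a tibble.
#' @export
write_fold_changes <- function(fc, path) {
  check_fold_change_table(fc)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("gene\tfold_change", con)
  writeLines(sprintf("%s\t%s", fc$gene, format_full(fc$fold_change)), con)
  invisible(path)
}

#' @rdname write_fold_changes
#' @export
read_fold_changes <- function(path) {
  fc <- tibble::as_tibble(
    utils::read.delim(path, colClasses = c("character", "numeric"))
  )
  check_fold_change_table(fc)
  fc
}

#' Write and read a comparison result as JSON
#'
#' Serializes the verdict, the selected depth and common genes, the full
#' step trace with full-precision probabilities, and the run configuration,
#' so a result file is self-describing and round-trips losslessly through
#' [read_comparison_result()].
#'
#' @param result A `list_comparison`.
#' @param path Output path.
#' @param config Optional [run_config()] echoed into the file.
#' @return `write_comparison_result()` returns `path` invisibly;
#'   `read_comparison_result()` returns a `list_comparison`.
#' @export
write_comparison_result <- function(result, path, config = NULL) {
  stopifnot(inherits(result, "list_comparison"))
  payload <- list(
    verdict = result$verdict,
    direction = result$direction,
    m_star = result$m_star,
    k_star = result$k_star,
    n_universe = result$n_universe,
    step = result$step,
    alpha = result$alpha,
    common_genes = result$common_genes,
    trace = result$trace,
    config = if (is.null(config)) NULL else unclass(config)
  )
  jsonlite::write_json(
    payload, path,
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_comparison_result
#' @export
read_comparison_result <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  trace <- tibble::as_tibble(p$trace)
  if (nrow(trace) > 0 && !"increment_p" %in% names(trace)) {
    trace$increment_p <- NA_real_
  }
  structure(
    list(
      verdict = p$verdict,
      m_star = as.integer(p$m_star),
      k_star = as.integer(p$k_star),
      common_genes = as.character(unlist(p$common_genes)),
      direction = p$direction,
      n_universe = as.integer(p$n_universe),
      step = as.integer(p$step),
      alpha = p$alpha,
      trace = trace
    ),
    class = "list_comparison"
  )
}

#' Write and read a directional signature as JSON
#'
#' @param sig A [directional_signature()].
#' @param path File path.
#' @return `write_signature()` returns `path` invisibly;
#'   `read_signature()` returns a `directional_signature`.
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "directional_signature"))
  jsonlite::write_json(
    list(
      species = signature_species(sig),
      up = sig$gene[sig$direction == "up"],
      down = sig$gene[sig$direction == "down"]
    ),
    path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  directional_signature(
    up = as.character(unlist(p$up)),
    down = as.character(unlist(p$down)),
    species = p$species
  )
}

#' Read a homolog mapping table
#'
#' Two-column TSV (`gene_a`, `gene_b`), with an optional third `group`
#' column of homology-group identifiers; when present, pairs are expanded
#' as the within-group cross product of species-A and species-B members.
#'
#' @param path File path.
#' @param species_a,species_b Species tags for the two columns.
#' @return A [homolog_map()].
#' @export
read_homolog_map <- function(path, species_a, species_b) {
  raw <- tibble::as_tibble(utils::read.delim(path, colClasses = "character"))
  if (ncol(raw) < 2) {
    rlang::abort("Homolog map needs at least two columns (gene_a, gene_b).")
  }
  if (ncol(raw) >= 3) {
    names(raw)[1:3] <- c("gene_a", "gene_b", "group")
    expanded <- purrr::map_dfr(split(raw, raw$group), function(g) {
      tidyr::expand_grid(gene_a = unique(g$gene_a), gene_b = unique(g$gene_b))
    })
    homolog_map(expanded$gene_a, expanded$gene_b, species_a, species_b)
  } else {
    names(raw)[1:2] <- c("gene_a", "gene_b")
    homolog_map(raw$gene_a, raw$gene_b, species_a, species_b)
  }
}

# full-precision, locale-independent numeric formatting for TSV output
format_full <- function(x) {
  formatC(x, digits = 17, format = "g")
}
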