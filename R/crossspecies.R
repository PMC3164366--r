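#' Directional gene signature
#'
#' The outcome of a directional comparison reduced to two disjoint gene
#' sets: up-regulated and down-regulated. Stored as a tibble with columns
#' `gene` and `direction` plus a `species` attribute, so signatures from
#' different species can be intersected through a homolog map.
#'
#' @param up,down Character vectors of gene identifiers; must be disjoint.
#' @param species Species tag, e.g. `"fly"` or `"mouse"`.
#' @return A `directional_signature` tibble.
#' @examples
#' directional_signature(up = c("a", "b"), down = "c", species = "fly")
#' @export
directional_signature <- function(up = character(0), down = character(0),
                                  species) {
  up <- unique(as.character(up))
  down <- unique(as.character(down))
  if (length(intersect(up, down)) > 0) {
    rlang::abort("A gene cannot be both up- and down-regulated in one signature.")
  }
  structure(
    tibble::tibble(
      gene = c(up, down),
      direction = rep(c("up", "down"), c(length(up), length(down)))
    ),
    species = as.character(species)[1],
    class = c("directional_signature", class(tibble::tibble()))
  )
}

#' @rdname directional_signature
#' @param x A `directional_comparison` (see [compare_directional()]) whose
#'   signature is to be extracted.
#' @export
as_signature <- function(x, species) {
  stopifnot(inherits(x, "directional_comparison"))
  directional_signature(
    up = x$signature$gene[x$signature$direction == "up"],
    down = x$signature$gene[x$signature$direction == "down"],
    species = species
  )
}

#' @export
print.directional_signature <- function(x, ...) {
  cat(sprintf(
    "# Directional signature [%s]: %d up, %d down\n",
    attr(x, "species"), sum(x$direction == "up"), sum(x$direction == "down")
  ))
  NextMethod()
}

signature_species <- function(x) attr(x, "species")

#' Homolog mapping table
#'
#' A bidirectional correspondence between gene identifiers of two species,
#' HomoloGene-style. May be many-to-many; duplicate pairs are dropped. When
#' built from a grouped source (a homology-group id per row), pairs are the
#' within-group cross product — see [read_homolog_map()].
#'
#' @param gene_a,gene_b Character vectors of equal length: homolog pairs.
#' @param species_a,species_b Species tags matching the signature objects
#'   the map will be used with.
#' @return A `homolog_map` tibble with columns `gene_a`, `gene_b`.
#' @examples
#' homolog_map(c("f1", "f2"), c("m1", "m2"), "fly", "mouse")
#' @export
homolog_map <- function(gene_a, gene_b, species_a, species_b) {
  if (length(gene_a) != length(gene_b)) {
    rlang::abort("`gene_a` and `gene_b` must have the same length.")
  }
  tbl <- dplyr::distinct(tibble::tibble(
    gene_a = as.character(gene_a),
    gene_b = as.character(gene_b)
  ))
  structure(
    tbl,
    species_a = as.character(species_a)[1],
    species_b = as.character(species_b)[1],
    class = c("homolog_map", class(tibble::tibble()))
  )
}

#' @export
print.homolog_map <- function(x, ...) {
  cat(sprintf(
    "# Homolog map %s <-> %s: %d pairs\n",
    attr(x, "species_a"), attr(x, "species_b"), nrow(x)
  ))
  NextMethod()
}

# Which side of the map carries this signature's species?
map_side <- function(map, species) {
  if (identical(species, attr(map, "species_a"))) {
    "a"
  } else if (identical(species, attr(map, "species_b"))) {
    "b"
  } else {
    rlang::abort(sprintf(
      "Species \"%s\" is not covered by the homolog map (%s <-> %s).",
      species, attr(map, "species_a"), attr(map, "species_b")
    ))
  }
}

#' Restrict a signature to genes with a homolog in the other species
#'
#' Keeps only the signature genes that have at least one homolog on the
#' other side of the map; direction labels are untouched. An empty map
#' yields an empty signature with a warning.
#'
#' @param sig A [directional_signature()].
#' @param map A [homolog_map()] covering the signature's species.
#' @return A filtered `directional_signature`.
#' @export
restrict_to_homologs <- function(sig, map) {
  stopifnot(inherits(sig, "directional_signature"), inherits(map, "homolog_map"))
  side <- map_side(map, signature_species(sig))
  mapped <- if (side == "a") map$gene_a else map$gene_b
  if (nrow(map) == 0) {
    rlang::warn("Empty homolog map: the restricted signature is empty.")
  }
  keep <- sig$gene %in% mapped
  directional_signature(
    up = sig$gene[keep & sig$direction == "up"],
    down = sig$gene[keep & sig$direction == "down"],
    species = signature_species(sig)
  )
}

#' Conserved cross-species signature
#'
#' Intersects two species' directional signatures through a homolog map at
#' the homolog-*pair* level: a pair (g_a, g_b) is conserved-up when g_a is
#' up-regulated in species A and g_b is up-regulated in species B, and
#' likewise for down. Pairs whose endpoints are in both signatures but with
#' opposite directions are reported as *discordant* rather than silently
#' dropped. With many-to-many homology a gene enters the conserved set as
#' soon as any of its homologs agrees in direction; the pair-level table
#' keeps the full detail.
#'
#' @param sig_a,sig_b [directional_signature()] objects for the two species
#'   of the map.
#' @param map A [homolog_map()] covering both species.
#' @param report_species Which species' gene identifiers name the collapsed
#'   conserved sets: `"b"` (default) or `"a"`.
#' @return A `conserved_signature` object: `pairs`, a tibble of all homolog
#'   pairs with both endpoints in the signatures (`gene_a`, `gene_b`,
#'   `direction_a`, `direction_b`, `status` in
#'   `concordant_up`/`concordant_down`/`discordant`); `up`, `down`,
#'   `discordant`, the collapsed reporting-species gene sets; and
#'   `report_species`.
#' @examples
#' map <- homolog_map(c("f1", "f2"), c("m1", "m2"), "fly", "mouse")
#' sa <- directional_signature(up = "f1", down = "f2", species = "fly")
#' sb <- directional_signature(up = "m1", down = "m2", species = "mouse")
#' conserved_signature(sa, sb, map)
#' @export
conserved_signature <- function(sig_a, sig_b, map, report_species = c("b", "a")) {
  report_species <- match.arg(report_species)
  stopifnot(
    inherits(sig_a, "directional_signature"),
    inherits(sig_b, "directional_signature"),
    inherits(map, "homolog_map")
  )
  side_a <- map_side(map, signature_species(sig_a))
  side_b <- map_side(map, signature_species(sig_b))
  if (identical(side_a, side_b)) {
    rlang::abort("The two signatures must come from the two distinct species of the map.")
  }
  # orient the map so column 1 matches sig_a's species
  m <- if (side_a == "a") {
    tibble::tibble(gene_a = map$gene_a, gene_b = map$gene_b)
  } else {
    tibble::tibble(gene_a = map$gene_b, gene_b = map$gene_a)
  }
  dir_a <- stats::setNames(sig_a$direction, sig_a$gene)
  dir_b <- stats::setNames(sig_b$direction, sig_b$gene)
  pairs <- m |>
    dplyr::filter(.data$gene_a %in% names(dir_a), .data$gene_b %in% names(dir_b)) |>
    dplyr::mutate(
      direction_a = unname(dir_a[.data$gene_a]),
      direction_b = unname(dir_b[.data$gene_b]),
      status = dplyr::case_when(
        .data$direction_a == "up" & .data$direction_b == "up" ~ "concordant_up",
        .data$direction_a == "down" & .data$direction_b == "down" ~ "concordant_down",
        TRUE ~ "discordant"
      )
    )
  report_col <- if (report_species == "a") "gene_a" else "gene_b"
  collapse <- function(status) {
    sort(unique(pairs[[report_col]][pairs$status == status]))
  }
  structure(
    list(
      pairs = pairs,
      up = collapse("concordant_up"),
      down = collapse("concordant_down"),
      discordant = collapse("discordant"),
      report_species = if (report_species == "a") {
        signature_species(sig_a)
      } else {
        signature_species(sig_b)
      }
    ),
    class = "conserved_signature"
  )
}

#' @export
print.conserved_signature <- function(x, ...) {
  cat(sprintf(
    "# Conserved signature (reported as %s genes)\n", x$report_species
  ))
  cat(sprintf(
    "  %d up-regulated in both, %d down-regulated in both, %d discordant pairs\n",
    length(x$up), length(x$down),
    sum(x$pairs$status == "discordant")
  ))
  invisible(x)
}
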