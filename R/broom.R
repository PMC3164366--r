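#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the step trace of a list comparison
#'
#' One row per evaluated step, augmented with the plotting coordinates
#' `m_frac = m/N` (fraction of genes selected) and `k_frac = k/m` (fraction
#' of selected genes in common).
#'
#' @param x A `list_comparison`.
#' @param ... Unused.
#' @return A tibble with columns `m`, `k`, `overlap_p`, `increment_p`,
#'   `significant`, `m_frac`, `k_frac`.
#' @export
tidy.list_comparison <- function(x, ...) {
  dplyr::mutate(
    x$trace,
    m_frac = .data$m / x$n_universe,
    k_frac = ifelse(.data$m > 0, .data$k / .data$m, NA_real_)
  )
}

#' One-row summary of a list comparison
#'
#' @inheritParams tidy.list_comparison
#' @return A tibble with columns `direction`, `verdict`, `m_star`, `k_star`,
#'   `n_universe`, `step`, `alpha`, `n_steps`.
#' @export
glance.list_comparison <- function(x, ...) {
  tibble::tibble(
    direction = x$direction,
    verdict = x$verdict,
    m_star = x$m_star,
    k_star = x$k_star,
    n_universe = x$n_universe,
    step = x$step,
    alpha = x$alpha,
    n_steps = nrow(x$trace)
  )
}

#' @rdname tidy.list_comparison
#' @export
tidy.directional_comparison <- function(x, ...) {
  dplyr::bind_rows(
    up = tidy(x$up),
    down = tidy(x$down),
    .id = "direction"
  )
}

#' @rdname glance.list_comparison
#' @export
glance.directional_comparison <- function(x, ...) {
  tibble::tibble(
    n_shared = x$n_shared,
    up_verdict = x$up$verdict,
    up_m_star = x$up$m_star,
    up_k_star = x$up$k_star,
    down_verdict = x$down$verdict,
    down_m_star = x$down$m_star,
    down_k_star = x$down$k_star,
    signature_size = nrow(x$signature)
  )
}

#' @rdname tidy.list_comparison
#' @export
tidy.conserved_signature <- function(x, ...) {
  x$pairs
}

#' @rdname glance.list_comparison
#' @export
glance.conserved_signature <- function(x, ...) {
  tibble::tibble(
    n_up = length(x$up),
    n_down = length(x$down),
    n_discordant = sum(x$pairs$status == "discordant"),
    n_pairs = nrow(x$pairs),
    report_species = x$report_species
  )
}
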