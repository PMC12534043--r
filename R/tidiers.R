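#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a pairing-type chi-square contrast
#'
#' @param x A `tcr_pairing_test` from [compare_pairing()].
#' @param ... Unused.
#' @return A tibble with one row per contrast: `contrast`, `statistic`,
#'   `df`, `p_value`, `method`.
#' @method tidy tcr_pairing_test
#' @export
tidy.tcr_pairing_test <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "tcr_pairing_test")
  out
}

#' Glance at a pairing-type chi-square contrast
#'
#' @param x A `tcr_pairing_test` from [compare_pairing()].
#' @param ... Unused.
#' @return A one-row tibble: the contrasted groups and the
#'   single-vs-dual test statistics.
#' @method glance tcr_pairing_test
#' @export
glance.tcr_pairing_test <- function(x, ...) {
  groups <- attr(x, "groups")
  sd <- as_tibble(x) %>% filter(.data$contrast == "single_vs_dual")
  tibble(
    group_a = groups[1],
    group_b = groups[2],
    statistic = sd$statistic,
    df = sd$df,
    p_value = sd$p_value,
    n_contrasts = nrow(x)
  )
}

#' Tidy a dual-vs-single marker ranking
#'
#' @param x A `tcr_markers` from [rank_markers()].
#' @param ... Unused.
#' @return The per-gene result tibble.
#' @method tidy tcr_markers
#' @export
tidy.tcr_markers <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "tcr_markers")
  out
}

#' Glance at a dual-vs-single marker ranking
#'
#' @param x A `tcr_markers` from [rank_markers()].
#' @param alpha Significance threshold on `q_value` (default 0.05).
#' @param ... Unused.
#' @return A one-row tibble: group, compartment sizes, genes tested and
#'   genes significant at `alpha`.
#' @method glance tcr_markers
#' @export
glance.tcr_markers <- function(x, alpha = 0.05, ...) {
  tibble(
    group = attr(x, "group"),
    n_dual = attr(x, "n_dual"),
    n_single = attr(x, "n_single"),
    n_genes = nrow(x),
    n_significant = sum(x$q_value < alpha, na.rm = TRUE),
    skipped = isTRUE(attr(x, "skipped")),
    method = attr(x, "method")
  )
}
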