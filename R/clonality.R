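#' Build paired-chain clonotypes per (group, compartment) stratum
#'
#' Cells sharing an identical canonical chain-key tuple within one stratum
#' form one clonotype. The key is the lexicographically sorted set of the
#' cell's chain keys (`locus|v_gene|j_gene|cdr3_nt`), so chain enumeration
#' order never affects identity, and a dual cell can never share a
#' clonotype with a single cell (different tuple lengths). Single and dual
#' compartments are never merged. Excluded cells are dropped.
#'
#' @param pairing A pairing tibble from [classify_repertoire()].
#' @param by Stratification columns in addition to `compartment`
#'   (default `"group"`).
#' @param clonotype_by `"chainkey"` (default, full V/J/CDR3nt paired
#'   identity) or `"cdr3aa"` (looser identity on the sorted CDR3
#'   amino-acid strings only).
#' @return A clonotype tibble (class `tcr_clonotypes`): one row per
#'   clonotype with stratum columns, `clonotype` key and `size` (number of
#'   cells). Within a stratum, sizes sum to the stratum's cell count.
#' @export
build_clonotypes <- function(pairing, by = "group",
                             clonotype_by = c("chainkey", "cdr3aa")) {
  clonotype_by <- match.arg(clonotype_by)
  chains <- tcr_chains(pairing) %>% filter(!is.na(.data$compartment))
  key_part <- if (clonotype_by == "chainkey") {
    paste(chains$locus, chains$v_gene, chains$j_gene, chains$cdr3_nt, sep = "|")
  } else {
    paste(chains$locus, chains$cdr3_aa, sep = "|")
  }
  keys <- tibble(barcode = chains$barcode, part = key_part) %>%
    group_by(.data$barcode) %>%
    summarise(clonotype = paste(sort(.data$part), collapse = ";"),
              .groups = "drop")

  out <- as_tibble(pairing) %>%
    filter(!is.na(.data$compartment)) %>%
    inner_join(keys, by = "barcode") %>%
    count(across(all_of(c(by, "compartment", "clonotype"))), name = "size") %>%
    arrange(across(all_of(c(by, "compartment"))), dplyr::desc(.data$size),
            .data$clonotype)
  class(out) <- c("tcr_clonotypes", class(out))
  out
}

#' Inverse Simpson diversity of a clonotype size vector
#'
#' With clonotype frequencies \eqn{p_i = n_i / \sum n_i}, returns
#' \eqn{1 / \sum p_i^2} (often written 1/DS). The value lies in
#' \eqn{[1, k]} for \eqn{k} clonotypes and equals \eqn{k} for a uniform
#' repertoire; it is invariant to rescaling all sizes by a constant.
#'
#' @param sizes Positive clonotype sizes (cells per clonotype).
#' @return A single numeric diversity value.
#' @examples
#' inverse_simpson(c(1, 1, 1, 1))  # 4: uniform equals richness
#' inverse_simpson(c(2, 1, 1))     # 2.6667
#' @export
inverse_simpson <- function(sizes) {
  if (length(sizes) == 0) {
    abort("cannot compute inverse Simpson diversity of an empty repertoire")
  }
  if (any(is.na(sizes)) || any(sizes < 1)) {
    abort("clonotype sizes must all be >= 1")
  }
  p <- sizes / sum(sizes)
  1 / sum(p^2)
}

#' Clonal-expansion fraction
#'
#' Clonal expansion is defined as a clonotype observed in at least two
#' cells. The default basis is cell-level: the fraction of cells belonging
#' to expanded clonotypes, \eqn{\sum_i n_i [n_i \ge 2] / \sum_i n_i}.
#' `basis = "clonotypes"` instead reports the fraction of clonotypes that
#' are expanded.
#'
#' @param sizes Positive clonotype sizes.
#' @param basis `"cells"` (default) or `"clonotypes"`.
#' @return A fraction in `[0, 1]`.
#' @examples
#' expansion_fraction(c(3, 1, 1))  # 0.6
#' @export
expansion_fraction <- function(sizes, basis = c("cells", "clonotypes")) {
  basis <- match.arg(basis)
  if (length(sizes) == 0) {
    abort("cannot compute an expansion fraction for an empty stratum")
  }
  if (any(is.na(sizes)) || any(sizes < 1)) {
    abort("clonotype sizes must all be >= 1")
  }
  if (basis == "cells") {
    sum(sizes[sizes >= 2]) / sum(sizes)
  } else {
    mean(sizes >= 2)
  }
}

#' Per-stratum diversity and clonality summary
#'
#' Computes, for every (group, compartment) stratum of a clonotype table,
#' the cell and clonotype counts, inverse Simpson diversity and
#' clonal-expansion fraction. Because strata with very different cell
#' counts are not directly comparable on raw diversity, an optional
#' rarefaction reports the mean inverse Simpson over seeded bootstrap
#' subsamples of a fixed number of cells.
#'
#' @param clonotypes A clonotype tibble from [build_clonotypes()].
#' @param expansion_basis Passed to [expansion_fraction()].
#' @param rarefy_to Optional number of cells to subsample each stratum to
#'   (strata with fewer cells report `NA`); default `NULL` (off).
#' @param n_boot Bootstrap draws for rarefaction (default 100).
#' @param seed Seed for the rarefaction bootstrap.
#' @return A tibble with one row per stratum: `n_cells`, `n_clonotypes`,
#'   `inv_simpson`, `expansion`, and `inv_simpson_rarefied` when requested.
#' @export
diversity_summary <- function(clonotypes, expansion_basis = c("cells", "clonotypes"),
                              rarefy_to = NULL, n_boot = 100, seed = 1L) {
  expansion_basis <- match.arg(expansion_basis)
  strata_cols <- setdiff(names(clonotypes), c("clonotype", "size"))
  out <- as_tibble(clonotypes) %>%
    group_by(across(all_of(strata_cols))) %>%
    summarise(
      n_cells = sum(.data$size),
      n_clonotypes = dplyr::n(),
      inv_simpson = inverse_simpson(.data$size),
      expansion = expansion_fraction(.data$size, basis = expansion_basis),
      .groups = "drop"
    )
  if (!is.null(rarefy_to)) {
    sizes_by_stratum <- as_tibble(clonotypes) %>%
      group_by(across(all_of(strata_cols))) %>%
      summarise(sizes = list(.data$size), .groups = "drop")
    set.seed(seed)
    out$inv_simpson_rarefied <- vapply(sizes_by_stratum$sizes, function(sz) {
      total <- sum(sz)
      if (total < rarefy_to) return(NA_real_)
      labels <- rep.int(seq_along(sz), sz)
      mean(vapply(seq_len(n_boot), function(i) {
        sub <- sample(labels, rarefy_to, replace = FALSE)
        inverse_simpson(as.integer(table(sub)))
      }, numeric(1)))
    }, numeric(1))
  }
  out
}
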