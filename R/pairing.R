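PAIRING_CLASSES <- c("A_B", "A_B1B2", "B_A1A2", "A1A2_B1B2",
                     "excluded_unpaired", "excluded_multiplet")
DUAL_CLASSES <- c("A_B1B2", "B_A1A2", "A1A2_B1B2")
PAIRED_CLASSES <- c("A_B", DUAL_CLASSES)

#' Classify a cell's pairing type from its distinct chain counts
#'
#' Maps the number of distinct productive alpha and beta chains of a cell to
#' the pairing taxonomy. A cell with exactly one chain of each locus is a
#' single TCR cell (`A_B`); a cell with one alpha and two betas, one beta
#' and two alphas, or two of each is a dual TCR cell (`A_B1B2`, `B_A1A2`,
#' `A1A2_B1B2`). Cells lacking a productive chain at either locus cannot
#' pair and are `excluded_unpaired` (this takes precedence even when the
#' other locus carries more than two chains); cells with more than two
#' distinct chains at a locus fall outside the taxonomy and are
#' `excluded_multiplet` (likely droplet doublets).
#'
#' @param n_alpha,n_beta Integer vectors (recycled to common length) of
#'   distinct productive chain counts per locus.
#' @return A factor with levels `r paste(PAIRING_CLASSES, collapse = ", ")`.
#' @examples
#' classify_cell(1, 1)      # A_B
#' classify_cell(1, 2)      # A_B1B2
#' classify_cell(2:0, 1)    # B_A1A2, A_B, excluded_unpaired
#' @export
classify_cell <- function(n_alpha, n_beta) {
  if (any(n_alpha < 0 | n_beta < 0, na.rm = TRUE)) {
    abort("chain counts must be non-negative")
  }
  cls <- dplyr::case_when(
    n_alpha == 0 | n_beta == 0 ~ "excluded_unpaired",
    n_alpha > 2 | n_beta > 2 ~ "excluded_multiplet",
    n_alpha == 1 & n_beta == 1 ~ "A_B",
    n_alpha == 1 & n_beta == 2 ~ "A_B1B2",
    n_alpha == 2 & n_beta == 1 ~ "B_A1A2",
    TRUE ~ "A1A2_B1B2"
  )
  factor(cls, levels = PAIRING_CLASSES)
}

#' Collapse a contig table to distinct productive chains per barcode
#'
#' Drops non-productive contigs and non-alpha/beta loci (counting both), and
#' reduces the remaining contigs of each barcode to its distinct chains. Two
#' contig rows describe the same chain if and only if they agree on locus, V
#' gene, J gene and CDR3 nucleotide sequence; UMI and read counts never
#' enter chain identity. Chain identity is at the nucleotide level: two
#' chains with identical CDR3 amino-acid sequence but different nucleotide
#' sequence are distinct (allelic inclusion is a DNA-level event).
#'
#' @param contigs Canonical contig tibble ([read_contigs()]).
#' @param require_full_length If `TRUE`, additionally require
#'   `full_length` for a contig to be retained (default `FALSE`:
#'   productivity alone decides functional inclusion).
#' @return A tibble with one row per barcode (`barcode`, `n_alpha`,
#'   `n_beta`, `dropped_nonproductive`, `dropped_other_locus`) carrying the
#'   retained chains as the `"chains"` attribute (one row per distinct
#'   chain: `barcode`, `locus`, `v_gene`, `j_gene`, `cdr3_nt`, `cdr3_aa`).
#' @export
collapse_chains <- function(contigs, require_full_length = FALSE) {
  contigs <- as_tibble(contigs)
  barcodes <- unique(contigs$barcode)

  ab <- contigs$locus %in% c("TRA", "TRB")
  keep <- ab & contigs$productive
  if (require_full_length) keep <- keep & contigs$full_length

  chains <- contigs[keep, , drop = FALSE] %>%
    distinct(.data$barcode, .data$locus, .data$v_gene, .data$j_gene,
             .data$cdr3_nt, .keep_all = TRUE) %>%
    select("barcode", "locus", "v_gene", "j_gene", "cdr3_nt", "cdr3_aa")

  counts <- chains %>%
    count(.data$barcode, .data$locus) %>%
    tidyr::pivot_wider(names_from = "locus", values_from = "n", values_fill = 0L)
  if (!"TRA" %in% names(counts)) counts$TRA <- 0L
  if (!"TRB" %in% names(counts)) counts$TRB <- 0L

  dropped <- tibble(
    barcode = contigs$barcode,
    nonprod = ab & !keep,
    other = !ab
  ) %>%
    group_by(.data$barcode) %>%
    summarise(dropped_nonproductive = sum(.data$nonprod),
              dropped_other_locus = sum(.data$other), .groups = "drop")

  cells <- tibble(barcode = barcodes) %>%
    left_join(counts, by = "barcode") %>%
    left_join(dropped, by = "barcode") %>%
    mutate(
      n_alpha = dplyr::coalesce(.data$TRA, 0L),
      n_beta = dplyr::coalesce(.data$TRB, 0L),
      dropped_nonproductive = dplyr::coalesce(.data$dropped_nonproductive, 0L),
      dropped_other_locus = dplyr::coalesce(.data$dropped_other_locus, 0L)
    ) %>%
    select("barcode", "n_alpha", "n_beta",
           "dropped_nonproductive", "dropped_other_locus")

  attr(cells, "chains") <- chains
  cells
}

#' Classify every cell of a repertoire into pairing types
#'
#' Runs [collapse_chains()] and [classify_cell()] over a whole contig table
#' and attaches group labels, yielding one row per distinct barcode.
#'
#' @param contigs Canonical contig tibble; may already carry a `group`
#'   column (as emitted by [simulate_repertoire()]).
#' @param groups Optional barcode-to-group map: a data frame with columns
#'   `barcode` and `group`. When `NULL`, an existing `group` column in
#'   `contigs` is used; barcodes covered by neither are labelled
#'   `"unassigned"`.
#' @param require_full_length Passed to [collapse_chains()].
#' @return A pairing tibble (class `tcr_pairing`): one row per barcode with
#'   `barcode`, `group`, `class` (factor over the six pairing classes),
#'   `compartment` (`"single"`, `"dual"` or `NA` for excluded cells),
#'   `n_alpha`, `n_beta` and the dropped-contig counts. The distinct
#'   retained chains (with group and class joined on) are available via
#'   [tcr_chains()].
#' @examples
#' sim <- simulate_repertoire(sim_config(n_cells = 200, groups = c("spleen", "skin")))
#' pairing <- classify_repertoire(sim$contigs)
#' pairing_summary(pairing)
#' @export
classify_repertoire <- function(contigs, groups = NULL,
                                require_full_length = FALSE) {
  contigs <- as_tibble(contigs)
  if (is.null(groups)) {
    if ("group" %in% names(contigs)) {
      groups <- distinct(contigs, .data$barcode, .data$group)
    } else {
      groups <- tibble(barcode = character(), group = character())
    }
  } else {
    groups <- as_tibble(groups)
    if (!all(c("barcode", "group") %in% names(groups))) {
      abort("`groups` must have columns 'barcode' and 'group'")
    }
    groups <- distinct(groups, .data$barcode, .data$group)
  }
  if (anyDuplicated(groups$barcode)) {
    abort(sprintf("barcode '%s' maps to more than one group",
                  groups$barcode[duplicated(groups$barcode)][1]))
  }

  cells <- collapse_chains(contigs, require_full_length = require_full_length)
  chains <- attr(cells, "chains")

  pairing <- cells %>%
    left_join(groups, by = "barcode") %>%
    mutate(
      group = dplyr::coalesce(.data$group, "unassigned"),
      class = classify_cell(.data$n_alpha, .data$n_beta),
      compartment = dplyr::case_when(
        .data$class == "A_B" ~ "single",
        .data$class %in% DUAL_CLASSES ~ "dual",
        TRUE ~ NA_character_
      )
    ) %>%
    select("barcode", "group", "class", "compartment", "n_alpha", "n_beta",
           "dropped_nonproductive", "dropped_other_locus")

  attr(pairing, "chains") <- chains %>%
    left_join(select(pairing, "barcode", "group", "class", "compartment"),
              by = "barcode")
  class(pairing) <- c("tcr_pairing", class(pairing))
  pairing
}

#' Retained chains of a classified repertoire
#'
#' @param pairing A pairing tibble from [classify_repertoire()].
#' @return A tibble of distinct productive chains (one row per chain) with
#'   the owning cell's group, class and compartment.
#' @export
tcr_chains <- function(pairing) {
  chains <- attr(pairing, "chains")
  if (is.null(chains)) {
    abort("no chain table attached; was this object produced by classify_repertoire()?")
  }
  chains
}

#' Per-group pairing-type proportions
#'
#' Summarises a classified repertoire into per-group counts and percentages
#' of the four retained pairing classes. Denominators are paired cells only
#' (`A_B`, `A_B1B2`, `B_A1A2`, `A1A2_B1B2`); excluded cells are counted but
#' never enter percentages. For a group with zero paired cells the
#' percentages are `NA`, not 0.
#'
#' @param pairing A pairing tibble, or any data frame with a `class` column
#'   over the pairing taxonomy.
#' @param by Grouping column name (default `"group"`).
#' @return A tibble with one row per group: `n_cells`, `n_paired`, counts
#'   `n_<class>`, excluded counts, percentages `pct_<class>` (of paired
#'   cells) and `pct_dual` (sum of the three dual-class percentages).
#' @export
pairing_summary <- function(pairing, by = "group") {
  if (!by %in% names(pairing)) {
    abort(sprintf("grouping column '%s' not found", by))
  }
  counts <- as_tibble(pairing) %>%
    count(!!sym(by), .data$class, .drop = FALSE) %>%
    tidyr::pivot_wider(names_from = "class", values_from = "n",
                       values_fill = 0L, names_prefix = "n_") %>%
    filter(!is.na(!!sym(by)))
  for (cl in PAIRING_CLASSES) {
    col <- paste0("n_", cl)
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  out <- counts %>%
    mutate(
      n_paired = .data$n_A_B + .data$n_A_B1B2 + .data$n_B_A1A2 + .data$n_A1A2_B1B2,
      n_cells = .data$n_paired + .data$n_excluded_unpaired + .data$n_excluded_multiplet,
      denom = ifelse(.data$n_paired > 0, .data$n_paired, NA_integer_),
      pct_A_B = 100 * .data$n_A_B / .data$denom,
      pct_A_B1B2 = 100 * .data$n_A_B1B2 / .data$denom,
      pct_B_A1A2 = 100 * .data$n_B_A1A2 / .data$denom,
      pct_A1A2_B1B2 = 100 * .data$n_A1A2_B1B2 / .data$denom,
      pct_dual = .data$pct_A_B1B2 + .data$pct_B_A1A2 + .data$pct_A1A2_B1B2
    ) %>%
    select(all_of(by), "n_cells", "n_paired",
           "n_A_B", "n_A_B1B2", "n_B_A1A2", "n_A1A2_B1B2",
           "n_excluded_unpaired", "n_excluded_multiplet",
           "pct_A_B", "pct_A_B1B2", "pct_B_A1A2", "pct_A1A2_B1B2", "pct_dual")
  out
}

#' Chi-square contrasts of pairing-type composition between two groups
#'
#' Compares two groups on (a) the single-vs-dual 2x2 contingency and (b)
#' the 2x3 contingency over the three dual pairing types, using Pearson's
#' chi-square (no continuity correction by default, as conventionally
#' reported; set `yates = TRUE` for the corrected 2x2 statistic).
#'
#' @param pairing A pairing tibble.
#' @param group_a,group_b Group labels to contrast.
#' @param by Grouping column (default `"group"`).
#' @param yates Apply Yates continuity correction (2x2 only).
#' @return An object of class `tcr_pairing_test`: a tibble with one row per
#'   contrast (`single_vs_dual`, `dual_types`) and columns `statistic`,
#'   `df`, `p_value`, `method`. Use [generics::tidy()] / [generics::glance()].
#' @export
compare_pairing <- function(pairing, group_a, group_b, by = "group",
                            yates = FALSE) {
  tab <- as_tibble(pairing) %>%
    filter(!!sym(by) %in% c(group_a, group_b),
           .data$class %in% PAIRED_CLASSES)
  for (g in c(group_a, group_b)) {
    if (sum(tab[[by]] == g) == 0) {
      abort(sprintf("group '%s' has no paired cells", g))
    }
  }
  grp <- factor(tab[[by]], levels = c(group_a, group_b))

  single_dual <- table(grp, factor(ifelse(tab$class == "A_B", "single", "dual"),
                                   levels = c("single", "dual")))
  dual_tab <- tab %>% filter(.data$class %in% DUAL_CLASSES)
  dual_types <- table(factor(dual_tab[[by]], levels = c(group_a, group_b)),
                      factor(as.character(dual_tab$class), levels = DUAL_CLASSES))

  res <- bind_rows(
    run_chisq(single_dual, "single_vs_dual", yates = yates),
    run_chisq(dual_types, "dual_types", yates = FALSE)
  )
  attr(res, "groups") <- c(group_a, group_b)
  class(res) <- c("tcr_pairing_test", class(res))
  res
}

run_chisq <- function(tab, contrast, yates = FALSE) {
  tab <- as.matrix(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) {
    abort(sprintf(
      "contrast '%s': an expected cell count is zero; pool sparse categories before testing",
      contrast
    ))
  }
  ht <- suppressWarnings(chisq.test(tab, correct = yates))
  tibble(
    contrast = contrast,
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = unname(ht$p.value),
    method = if (yates) "Pearson chi-square (Yates)" else "Pearson chi-square"
  )
}
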