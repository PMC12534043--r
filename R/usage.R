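#' V/J gene-segment usage per (group, compartment) stratum
#'
#' Counts every retained chain of the requested locus once — a dual cell's
#' two same-locus chains each contribute one count — and normalises to
#' frequencies within each (group, compartment) stratum, so frequencies sum
#' to 1 over the genes observed in that stratum.
#'
#' @param pairing A pairing tibble from [classify_repertoire()].
#' @param locus `"TRB"` or `"TRA"`.
#' @param field `"v_gene"` or `"j_gene"`.
#' @param by Grouping column (default `"group"`).
#' @return A usage tibble (class `tcr_usage`) with columns `by`,
#'   `compartment`, `gene`, `count`, `freq` and attributes `locus`/`field`.
#' @export
vj_usage <- function(pairing, locus = c("TRB", "TRA"),
                     field = c("v_gene", "j_gene"), by = "group") {
  locus <- match.arg(locus)
  field <- match.arg(field)
  chains <- tcr_chains(pairing)
  if (nrow(chains) == 0) abort("pairing has no retained chains")
  out <- chains %>%
    filter(!is.na(.data$compartment), .data$locus == !!locus) %>%
    count(across(all_of(c(by, "compartment"))), gene = !!sym(field),
          name = "count") %>%
    group_by(across(all_of(c(by, "compartment")))) %>%
    mutate(freq = .data$count / sum(.data$count)) %>%
    ungroup() %>%
    arrange(across(all_of(c(by, "compartment"))), dplyr::desc(.data$count),
            .data$gene)
  attr(out, "locus") <- locus
  attr(out, "field") <- field
  class(out) <- c("tcr_usage", class(out))
  out
}

#' Per-gene usage comparison between two strata
#'
#' For every gene observed in either stratum, tests the 2x2 contingency
#' (gene vs all other genes, stratum a vs stratum b) with Pearson's
#' chi-square (no continuity correction) and adjusts p-values by
#' Benjamini-Hochberg across the genes of the call (one family per
#' locus/field). Genes with fewer than 5 total chains across both strata
#' are flagged `low_count` (the chi-square approximation is unreliable
#' there).
#'
#' @param usage_a,usage_b Usage tibbles from [vj_usage()], each filtered to
#'   the stratum to compare (rows from several groups are pooled by
#'   summing counts).
#' @param labels Length-2 labels for the two strata in the output.
#' @return A tibble with one row per gene: counts and totals per stratum,
#'   `freq_a`/`freq_b`, `statistic`, `df`, `p_value`, `q_value`,
#'   `low_count`; sorted by `p_value` then gene name.
#' @export
vj_usage_test <- function(usage_a, usage_b, labels = c("a", "b")) {
  pool <- function(u) {
    if (nrow(u) == 0) abort("usage stratum is empty")
    u %>% group_by(.data$gene) %>%
      summarise(count = sum(.data$count), .groups = "drop")
  }
  a <- pool(usage_a)
  b <- pool(usage_b)
  total_a <- sum(a$count)
  total_b <- sum(b$count)

  merged <- full_join(a, b, by = "gene", suffix = c("_a", "_b")) %>%
    mutate(
      count_a = dplyr::coalesce(.data$count_a, 0L),
      count_b = dplyr::coalesce(.data$count_b, 0L)
    )

  # closed-form Pearson chi-square on [[a, Ta-a], [b, Tb-b]]
  x11 <- merged$count_a
  x12 <- total_a - x11
  x21 <- merged$count_b
  x22 <- total_b - x21
  n <- total_a + total_b
  gene_tot <- x11 + x21
  rest_tot <- x12 + x22
  stat <- n * (x11 * x22 - x12 * x21)^2 /
    (as.numeric(total_a) * total_b * gene_tot * rest_tot)
  stat[gene_tot == 0 | rest_tot == 0] <- NA_real_
  p <- pchisq(stat, df = 1, lower.tail = FALSE)

  out <- tibble(
    gene = merged$gene,
    count_a = merged$count_a,
    total_a = total_a,
    count_b = merged$count_b,
    total_b = total_b,
    freq_a = merged$count_a / total_a,
    freq_b = merged$count_b / total_b,
    statistic = stat,
    df = 1L,
    p_value = p,
    q_value = p.adjust(p, method = "BH"),
    low_count = gene_tot < 5
  ) %>%
    arrange(.data$p_value, .data$gene)
  names(out)[names(out) %in% c("count_a", "total_a", "freq_a")] <-
    paste0(c("count_", "total_", "freq_"), labels[1])
  names(out)[names(out) %in% c("count_b", "total_b", "freq_b")] <-
    paste0(c("count_", "total_", "freq_"), labels[2])
  out
}
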