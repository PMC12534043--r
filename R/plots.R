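#' Stacked bar chart of pairing-type proportions per group
#'
#' @param summary A tibble from [pairing_summary()].
#' @return A ggplot object.
#' @export
plot_pairing_summary <- function(summary) {
  by <- names(summary)[1]
  long <- summary %>%
    select(all_of(by), dplyr::starts_with("pct_"), -"pct_dual") %>%
    tidyr::pivot_longer(-all_of(by), names_to = "class", values_to = "pct",
                        names_prefix = "pct_") %>%
    mutate(class = factor(.data$class, levels = rev(PAIRED_CLASSES)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[by]], y = .data$pct,
                                     fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_brewer(palette = "Set2", name = "pairing type") +
    ggplot2::labs(x = NULL, y = "% of paired cells") +
    ggplot2::theme_minimal()
}

#' Bar chart of V/J segment usage by compartment
#'
#' @param usage A `tcr_usage` tibble from [vj_usage()].
#' @param top_n Show the `top_n` most used genes overall (default 15).
#' @return A ggplot object.
#' @export
plot_vj_usage <- function(usage, top_n = 15) {
  by <- setdiff(names(usage), c("compartment", "gene", "count", "freq"))[1]
  keep <- usage %>%
    group_by(.data$gene) %>%
    summarise(total = sum(.data$count), .groups = "drop") %>%
    arrange(dplyr::desc(.data$total)) %>%
    head(top_n) %>%
    pull("gene")
  dat <- filter(usage, .data$gene %in% keep) %>%
    mutate(gene = factor(.data$gene, levels = keep))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$gene, y = .data$freq,
                                    fill = .data$compartment)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(stats::as.formula(paste("~", by))) +
    ggplot2::labs(x = paste(attr(usage, "locus"), attr(usage, "field")),
                  y = "frequency", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Heatmap of a Jaccard overlap matrix
#'
#' @param object A `tcr_overlap` matrix from [overlap_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tcr_overlap
#' @export
autoplot.tcr_overlap <- function(object, ...) {
  m <- unclass(object)
  dat <- as_tibble(as.table(m), .name_repair = "minimal")
  names(dat) <- c("group_a", "group_b", "jaccard")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$group_a, y = .data$group_b,
                                    fill = .data$jaccard)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f", .data$jaccard)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1), name = "Jaccard") +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = sprintf("CDR3aa overlap, %s %s", attr(object, "locus"),
                      attr(object, "compartment"))
    ) +
    ggplot2::theme_minimal()
}

#' Volcano plot of a dual-vs-single marker ranking
#'
#' @param object A `tcr_markers` from [rank_markers()].
#' @param alpha Highlight genes with `q_value` below this (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tcr_markers
#' @export
autoplot.tcr_markers <- function(object, alpha = 0.05, ...) {
  dat <- as_tibble(object) %>%
    mutate(significant = .data$q_value < alpha)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$log2_fc,
                                    y = -log10(.data$q_value),
                                    colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                                 name = sprintf("q < %.2f", alpha)) +
    ggplot2::labs(x = "log2 fold change (dual / single)",
                  y = "-log10 BH q-value") +
    ggplot2::theme_minimal()
}

#' Diversity and expansion dot plot per stratum
#'
#' @param diversity A tibble from [diversity_summary()].
#' @return A ggplot object.
#' @export
plot_diversity <- function(diversity) {
  by <- setdiff(names(diversity),
                c("compartment", "n_cells", "n_clonotypes", "inv_simpson",
                  "expansion", "inv_simpson_rarefied"))[1]
  ggplot2::ggplot(diversity,
                  ggplot2::aes(x = .data[[by]], y = .data$inv_simpson,
                               colour = .data$compartment,
                               size = .data$expansion)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = NULL, y = "inverse Simpson (1/DS)",
                  colour = NULL, size = "expansion") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
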