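normalize_barcode <- function(x, pattern = "-\\d+$") {
  if (is.null(pattern) || identical(pattern, "")) return(x)
  sub(pattern, "", x)
}

#' Join pairing classifications to cell annotations by barcode
#'
#' Inner-joins a classified repertoire with a cell-annotation table on the
#' exact barcode string (after an optional, configurable suffix
#' normalisation, by default stripping a trailing `"-<digits>"` as added by
#' cell callers). Only cells present in both inputs are kept; the join
#' report counts cells present in both, in the TCR side only, and in the
#' annotation side only.
#'
#' @param pairing A pairing tibble from [classify_repertoire()] (or a
#'   previously joined table — the join is idempotent).
#' @param meta Cell annotation data frame with a `barcode` column and any
#'   of `group`/`tissue`, `cluster`, `treg_flag`. Barcodes must be unique.
#' @param barcode_pattern Regex stripped from barcodes on both sides before
#'   matching; `NULL` to disable.
#' @return A tibble (class `tcr_joined`) with the pairing columns plus the
#'   annotation columns, restricted to barcodes present in both. The join
#'   report is attached as attribute `"join_report"` and printed methods of
#'   [pairing_summary()] work unchanged (e.g. `by = "treg_flag"`).
#' @export
join_by_barcode <- function(pairing, meta, barcode_pattern = "-\\d+$") {
  pairing <- as_tibble(pairing)
  meta <- as_tibble(meta)
  if (!"barcode" %in% names(meta)) abort("`meta` must have a 'barcode' column")

  pairing$barcode <- normalize_barcode(pairing$barcode, barcode_pattern)
  meta$barcode <- normalize_barcode(meta$barcode, barcode_pattern)
  dup <- meta$barcode[duplicated(meta$barcode)]
  if (length(dup) > 0) {
    abort(sprintf("duplicated barcode in `meta`: '%s'", dup[1]))
  }

  # drop annotation columns already present so re-joining is a no-op
  overlap_cols <- setdiff(intersect(names(pairing), names(meta)), "barcode")
  pairing_clean <- select(pairing, -all_of(overlap_cols))

  joined <- inner_join(pairing_clean, meta, by = "barcode")
  report <- tibble(
    n_both = nrow(joined),
    n_tcr_only = sum(!pairing$barcode %in% meta$barcode),
    n_rna_only = sum(!meta$barcode %in% pairing$barcode)
  )
  attr(joined, "join_report") <- report
  attr(joined, "chains") <- attr(pairing, "chains")
  class(joined) <- unique(c("tcr_joined", class(joined)))
  joined
}

#' Join report of a barcode join
#'
#' @param joined A table from [join_by_barcode()].
#' @return A one-row tibble: `n_both`, `n_tcr_only`, `n_rna_only`.
#' @export
join_report <- function(joined) {
  rep <- attr(joined, "join_report")
  if (is.null(rep)) abort("no join report attached; use join_by_barcode()")
  rep
}

match_expr_cells <- function(expr, barcodes, barcode_pattern = "-\\d+$") {
  cols <- normalize_barcode(colnames(expr), barcode_pattern)
  idx <- match(barcodes, cols)
  if (anyNA(idx)) {
    abort(sprintf("%d joined barcode(s) missing from the expression matrix (first: '%s')",
                  sum(is.na(idx)), barcodes[which(is.na(idx))[1]]))
  }
  expr[, idx, drop = FALSE]
}

#' Signature-gene expression summary by compartment and group
#'
#' For each requested gene, reports the mean normalised expression and the
#' fraction of cells with expression > 0 within every (group, compartment)
#' stratum of the joined table. Genes absent from the matrix are collected
#' in the `"missing_genes"` attribute and reported with a message, not an
#' error.
#'
#' @param joined A table from [join_by_barcode()].
#' @param expr Genes-by-cells matrix of normalised expression (gene names
#'   as rownames, barcodes as colnames).
#' @param genes Character vector of gene names to summarise.
#' @param by Grouping column (default `"group"`).
#' @param barcode_pattern Barcode normalisation applied to `expr` colnames.
#' @return A tibble: `gene`, group, `compartment`, `n_cells`, `mean_expr`,
#'   `frac_pos`; attribute `"missing_genes"`.
#' @export
signature_summary <- function(joined, expr, genes, by = "group",
                              barcode_pattern = "-\\d+$") {
  cells <- as_tibble(joined) %>% filter(!is.na(.data$compartment))
  missing <- setdiff(genes, rownames(expr))
  if (length(missing) > 0) {
    inform(sprintf("gene(s) absent from expression matrix: %s",
                   paste(missing, collapse = ", ")))
  }
  genes_ok <- setdiff(genes, missing)
  expr_cells <- match_expr_cells(expr, cells$barcode, barcode_pattern)

  out <- purrr::map_dfr(genes_ok, function(g) {
    cells %>%
      mutate(value = as.numeric(expr_cells[g, ])) %>%
      group_by(across(all_of(c(by, "compartment")))) %>%
      summarise(gene = g, n_cells = dplyr::n(),
                mean_expr = mean(.data$value),
                frac_pos = mean(.data$value > 0), .groups = "drop")
  }) %>%
    select("gene", all_of(by), "compartment", "n_cells", "mean_expr", "frac_pos")
  attr(out, "missing_genes") <- missing
  out
}

#' Rank genes differentiating dual from single TCR cells
#'
#' Contrasts dual against single TCR cells (within one group, or overall)
#' on every gene of the expression matrix: the effect is the log2 fold
#' change of compartment means (with a pseudocount), significance is the
#' Wilcoxon rank-sum test with Benjamini-Hochberg adjustment across genes.
#' Results are sorted by descending effect, ties broken by gene name, so a
#' "top N in dual" extraction is deterministic.
#'
#' @param joined A table from [join_by_barcode()].
#' @param expr Genes-by-cells matrix of normalised expression.
#' @param group Optional single group label to restrict the contrast to;
#'   default uses all non-excluded cells.
#' @param min_cells Minimum cells required in each compartment (default
#'   10); below it the contrast is skipped with a message and a zero-row
#'   result.
#' @param pseudocount Added to both means before the log ratio (default 1).
#' @param by Grouping column (default `"group"`).
#' @param barcode_pattern Barcode normalisation applied to `expr` colnames.
#' @return An object of class `tcr_markers`: a tibble with `gene`,
#'   `mean_dual`, `mean_single`, `log2_fc`, `statistic`, `p_value`,
#'   `q_value`; attributes `group`, `n_dual`, `n_single`, `method`. Use
#'   [generics::tidy()] / [generics::glance()].
#' @export
rank_markers <- function(joined, expr, group = NULL, min_cells = 10,
                         pseudocount = 1, by = "group",
                         barcode_pattern = "-\\d+$") {
  cells <- as_tibble(joined) %>% filter(!is.na(.data$compartment))
  if (!is.null(group)) cells <- filter(cells, !!sym(by) == !!group)
  n_dual <- sum(cells$compartment == "dual")
  n_single <- sum(cells$compartment == "single")

  empty <- tibble(gene = character(), mean_dual = numeric(),
                  mean_single = numeric(), log2_fc = numeric(),
                  statistic = numeric(), p_value = numeric(),
                  q_value = numeric())
  if (n_dual < min_cells || n_single < min_cells) {
    inform(sprintf(
      "contrast skipped%s: %d dual / %d single cells (need >= %d each)",
      if (is.null(group)) "" else paste0(" for group '", group, "'"),
      n_dual, n_single, min_cells
    ))
    return(new_tcr_markers(empty, group, n_dual, n_single, skipped = TRUE))
  }

  expr_cells <- match_expr_cells(expr, cells$barcode, barcode_pattern)
  is_dual <- cells$compartment == "dual"
  m <- as.matrix(expr_cells)

  mean_dual <- rowMeans(m[, is_dual, drop = FALSE])
  mean_single <- rowMeans(m[, !is_dual, drop = FALSE])
  tests <- apply(m, 1, function(v) {
    ht <- suppressWarnings(wilcox.test(v[is_dual], v[!is_dual], exact = FALSE))
    c(ht$statistic, ht$p.value)
  })

  out <- tibble(
    gene = rownames(m),
    mean_dual = unname(mean_dual),
    mean_single = unname(mean_single),
    log2_fc = log2((mean_dual + pseudocount) / (mean_single + pseudocount)),
    statistic = unname(tests[1, ]),
    p_value = unname(tests[2, ]),
    q_value = p.adjust(unname(tests[2, ]), method = "BH")
  ) %>%
    arrange(dplyr::desc(.data$log2_fc), .data$gene)
  new_tcr_markers(out, group, n_dual, n_single, skipped = FALSE)
}

new_tcr_markers <- function(tbl, group, n_dual, n_single, skipped) {
  attr(tbl, "group") <- group %||% "all"
  attr(tbl, "n_dual") <- n_dual
  attr(tbl, "n_single") <- n_single
  attr(tbl, "skipped") <- skipped
  attr(tbl, "method") <- "Wilcoxon rank-sum on normalised expression; BH-adjusted; effect = log2 fold change of compartment means"
  class(tbl) <- c("tcr_markers", class(tbl))
  tbl
}

#' Read a normalised expression matrix
#'
#' Reads either a MatrixMarket triple (`matrix.mtx` + `genes.tsv` +
#' `barcodes.tsv` in one directory) or a dense TSV (first column gene
#' names, remaining columns one cell per barcode).
#'
#' @param path Directory containing MTX + index TSVs, or a dense TSV file.
#' @return A base genes-by-cells matrix with dimnames.
#' @export
read_expression <- function(path) {
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
    genes <- file.path(path, "genes.tsv")
    cells <- file.path(path, "barcodes.tsv")
    for (f in c(mtx, genes, cells)) {
      if (!file.exists(f)) abort(sprintf("expression directory is missing '%s'", basename(f)))
    }
    m <- as.matrix(Matrix::readMM(mtx))
    rownames(m) <- readr::read_tsv(genes, col_names = "gene",
                                   show_col_types = FALSE)$gene
    colnames(m) <- readr::read_tsv(cells, col_names = "barcode",
                                   show_col_types = FALSE)$barcode
    m
  } else {
    df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    m
  }
}

#' Write an expression matrix as MatrixMarket + index TSVs
#'
#' @param expr Genes-by-cells matrix with dimnames.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_expression <- function(expr, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(expr, sparse = TRUE), file.path(dir, "matrix.mtx"))
  writeLines(rownames(expr), file.path(dir, "genes.tsv"))
  writeLines(colnames(expr), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}
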