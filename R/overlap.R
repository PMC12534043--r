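#' CDR3 amino-acid set of one (group, compartment, locus) stratum
#'
#' Collects the CDR3 amino-acid strings of every retained chain of the
#' requested locus in the stratum. Membership is presence/absence over
#' unique strings; the accompanying cell counts record how many cells carry
#' each string (a dual cell whose two same-locus chains share one
#' amino-acid sequence — convergent at the protein level but distinct at
#' the DNA level — contributes that string once and counts as one cell).
#'
#' @param pairing A pairing tibble from [classify_repertoire()].
#' @param group Group label.
#' @param compartment `"single"` or `"dual"`.
#' @param locus `"TRA"` or `"TRB"`.
#' @param by Grouping column (default `"group"`).
#' @return A tibble (class `cdr3_set`) with columns `cdr3_aa`, `n_cells`,
#'   sorted by descending count; attributes `group`, `compartment`,
#'   `locus`. An empty stratum yields a valid zero-row set.
#' @export
cdr3_set <- function(pairing, group, compartment = c("single", "dual"),
                     locus = c("TRA", "TRB"), by = "group") {
  compartment <- match.arg(compartment)
  locus <- match.arg(locus)
  chains <- tcr_chains(pairing)
  out <- chains %>%
    filter(.data$locus == !!locus,
           !is.na(.data$compartment), .data$compartment == !!compartment,
           !!sym(by) == !!group,
           !is.na(.data$cdr3_aa)) %>%
    distinct(.data$barcode, .data$cdr3_aa) %>%
    count(.data$cdr3_aa, name = "n_cells") %>%
    arrange(dplyr::desc(.data$n_cells), .data$cdr3_aa)
  attr(out, "group") <- group
  attr(out, "compartment") <- compartment
  attr(out, "locus") <- locus
  class(out) <- c("cdr3_set", class(out))
  out
}

#' Jaccard index of two CDR3 sets
#'
#' \eqn{|A \cap B| / |A \cup B|} over unique CDR3 amino-acid strings
#' (presence/absence, not frequency-weighted). When both sets are empty the
#' index is undefined and `NA` is returned (never 0).
#'
#' @param a,b Character vectors of sequences, or [cdr3_set()] tibbles.
#' @return A value in `[0, 1]`, or `NA` if both sets are empty.
#' @examples
#' jaccard(c("a", "b", "c"), c("b", "c", "d"))  # 0.5
#' @export
jaccard <- function(a, b) {
  members <- function(x) {
    if (is.data.frame(x)) unique(x$cdr3_aa) else unique(as.character(x))
  }
  a <- members(a)
  b <- members(b)
  union_n <- length(union(a, b))
  if (union_n == 0) {
    warn("both sets are empty: Jaccard index is undefined, returning NA")
    return(NA_real_)
  }
  length(intersect(a, b)) / union_n
}

#' Pairwise Jaccard overlap matrix across groups
#'
#' Computes all pairwise Jaccard indices between the CDR3 amino-acid sets
#' of the groups of one (locus, compartment) stratum. The matrix is
#' symmetric with unit diagonal for non-empty sets.
#'
#' @inheritParams cdr3_set
#' @param groups Group labels to include; default all groups in `pairing`.
#' @return A symmetric numeric matrix (class `tcr_overlap`) with group
#'   dimnames and attributes `locus`/`compartment`. Entries involving an
#'   empty set are `NA`.
#' @export
overlap_matrix <- function(pairing, locus = c("TRA", "TRB"),
                           compartment = c("single", "dual"),
                           groups = NULL, by = "group") {
  locus <- match.arg(locus)
  compartment <- match.arg(compartment)
  groups <- groups %||% sort(unique(as_tibble(pairing)[[by]]))
  if (length(groups) < 2) abort("need at least two groups for an overlap matrix")
  sets <- lapply(groups, function(g) {
    unique(cdr3_set(pairing, g, compartment, locus, by = by)$cdr3_aa)
  })
  names(sets) <- groups
  m <- matrix(NA_real_, length(groups), length(groups),
              dimnames = list(groups, groups))
  for (i in seq_along(groups)) {
    for (j in seq_len(i)) {
      u <- length(union(sets[[i]], sets[[j]]))
      val <- if (u == 0) NA_real_ else length(intersect(sets[[i]], sets[[j]])) / u
      m[i, j] <- val
      m[j, i] <- val
    }
  }
  attr(m, "locus") <- locus
  attr(m, "compartment") <- compartment
  class(m) <- c("tcr_overlap", class(m))
  m
}

#' Track the top shared CDR3 sequences across groups
#'
#' Candidate sequences are CDR3 amino-acid strings present in at least two
#' groups of the (locus, compartment) stratum. They are ranked by the total
#' number of cells carrying them across all groups (descending), ties
#' broken lexicographically by sequence, and the top `n` are reported with
#' per-group cell counts and within-stratum frequencies.
#'
#' @inheritParams overlap_matrix
#' @param n Number of sequences to keep (default 10).
#' @return A tibble with `min(n, candidates)` rows: `cdr3_aa`, `n_groups`,
#'   `total_cells`, then one `n_<group>` and one `freq_<group>` column per
#'   group. No shared sequence yields a valid zero-row table.
#' @export
top_shared_sequences <- function(pairing, locus = c("TRA", "TRB"),
                                 compartment = c("single", "dual"),
                                 n = 10, groups = NULL, by = "group") {
  locus <- match.arg(locus)
  compartment <- match.arg(compartment)
  groups <- groups %||% sort(unique(as_tibble(pairing)[[by]]))
  if (length(groups) < 2) abort("need at least two groups to track shared sequences")

  long <- purrr::map_dfr(groups, function(g) {
    s <- cdr3_set(pairing, g, compartment, locus, by = by)
    if (nrow(s) == 0) return(tibble(group = character(), cdr3_aa = character(),
                                    n_cells = integer(), freq = numeric()))
    tibble(group = g, cdr3_aa = s$cdr3_aa, n_cells = s$n_cells,
           freq = s$n_cells / sum(s$n_cells))
  })
  if (nrow(long) == 0) return(empty_tracking(groups))

  ranked <- long %>%
    group_by(.data$cdr3_aa) %>%
    summarise(n_groups = dplyr::n(), total_cells = sum(.data$n_cells),
              .groups = "drop") %>%
    filter(.data$n_groups >= 2) %>%
    arrange(dplyr::desc(.data$total_cells), .data$cdr3_aa) %>%
    head(n)
  if (nrow(ranked) == 0) return(empty_tracking(groups))

  counts <- long %>%
    semi_join(ranked, by = "cdr3_aa") %>%
    select("group", "cdr3_aa", "n_cells") %>%
    tidyr::pivot_wider(names_from = "group", values_from = "n_cells",
                       values_fill = 0L, names_prefix = "n_")
  freqs <- long %>%
    semi_join(ranked, by = "cdr3_aa") %>%
    select("group", "cdr3_aa", "freq") %>%
    tidyr::pivot_wider(names_from = "group", values_from = "freq",
                       values_fill = 0, names_prefix = "freq_")
  ranked %>%
    left_join(counts, by = "cdr3_aa") %>%
    left_join(freqs, by = "cdr3_aa")
}

empty_tracking <- function(groups) {
  cols <- c(list(cdr3_aa = character(), n_groups = integer(),
                 total_cells = integer()),
            setNames(rep(list(integer()), length(groups)), paste0("n_", groups)),
            setNames(rep(list(numeric()), length(groups)), paste0("freq_", groups)))
  as_tibble(cols)
}
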