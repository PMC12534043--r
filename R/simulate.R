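#' Configure a synthetic paired-chain repertoire
#'
#' Builds and validates the configuration for [simulate_repertoire()]. The
#' defaults describe a repertoire with the statistical structure seen in
#' mouse Treg scTCR-seq: a dual TCR rate in the low teens split across the
#' three dual pairing types with B+A1+A2 most and A1+A2+B1+B2 least
#' frequent, a geometric clone-size law that is mostly singletons with a
#' tail of expanded clones, mildly skewed V/J multinomials over a built-in
#' mouse segment vocabulary, a cross-tissue shared CDR3 pool, and a
#' fraction of non-productive noise contigs.
#'
#' @param n_cells Cells per group.
#' @param groups Character vector of group (tissue) labels.
#' @param dual_rate Probability that a cell is a dual TCR cell.
#' @param dual_split Length-3 probability vector over
#'   (`A_B1B2`, `B_A1A2`, `A1A2_B1B2`); must sum to 1.
#' @param clone_p Success parameter of the geometric clone-size law
#'   (sizes are `1 + Geom(clone_p)`; larger is closer to all singletons).
#' @param usage_bias Optional data frame (`group`, `locus`, `field`,
#'   `gene`, `weight`) of multiplicative weights applied on top of the
#'   baseline V/J multinomials, for tissue-biased usage.
#' @param shared_pool_size Number of CDR3 amino-acid sequences per locus in
#'   the pool shared across groups.
#' @param sharing_rate Probability that a clonotype draws its CDR3s from
#'   the shared pool rather than privately.
#' @param noise_rate Non-productive extra contigs as a fraction of
#'   productive contig rows.
#' @param seed Integer seed; every downstream draw is a deterministic
#'   function of it (per-group streams are split, so adding a group never
#'   perturbs existing groups at the same seed).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_cells = 2000,
                       groups = c("spleen", "iLN", "mLN"),
                       dual_rate = 0.15,
                       dual_split = c(A_B1B2 = 0.35, B_A1A2 = 0.45, A1A2_B1B2 = 0.20),
                       clone_p = 0.7,
                       usage_bias = NULL,
                       shared_pool_size = 200,
                       sharing_rate = 0.10,
                       noise_rate = 0.05,
                       seed = 1L) {
  check <- function(ok, field, msg) {
    if (!ok) abort(sprintf("invalid sim_config field '%s': %s", field, msg))
  }
  check(is.numeric(n_cells) && length(n_cells) == 1 && n_cells >= 1,
        "n_cells", "must be a single positive integer")
  check(is.character(groups) && length(groups) >= 1 && !anyDuplicated(groups),
        "groups", "must be distinct non-empty labels")
  check(is.numeric(dual_rate) && dual_rate >= 0 && dual_rate <= 1,
        "dual_rate", "must be a probability in [0, 1]")
  check(is.numeric(dual_split) && length(dual_split) == 3 &&
          all(dual_split >= 0) && abs(sum(dual_split) - 1) < 1e-12,
        "dual_split", "must be 3 non-negative probabilities summing to 1")
  check(is.numeric(clone_p) && clone_p > 0 && clone_p <= 1,
        "clone_p", "must be in (0, 1]")
  check(is.numeric(shared_pool_size) && shared_pool_size >= 1,
        "shared_pool_size", "must be a positive integer")
  check(is.numeric(sharing_rate) && sharing_rate >= 0 && sharing_rate <= 1,
        "sharing_rate", "must be a probability in [0, 1]")
  check(is.numeric(noise_rate) && noise_rate >= 0 && noise_rate <= 1,
        "noise_rate", "must be a fraction in [0, 1]")
  check(is.numeric(seed) && length(seed) == 1 && abs(seed) < 2^31,
        "seed", "must be a 32-bit integer")
  if (!is.null(usage_bias)) {
    check(is.data.frame(usage_bias) &&
            all(c("group", "locus", "field", "gene", "weight") %in% names(usage_bias)),
          "usage_bias", "must have columns group, locus, field, gene, weight")
  }
  structure(
    list(
      n_cells = as.integer(n_cells), groups = groups, dual_rate = dual_rate,
      dual_split = setNames(as.numeric(dual_split),
                            c("A_B1B2", "B_A1A2", "A1A2_B1B2")),
      clone_p = clone_p, usage_bias = usage_bias,
      shared_pool_size = as.integer(shared_pool_size),
      sharing_rate = sharing_rate, noise_rate = noise_rate,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# deterministic 31-bit stream seed from (seed, label); polynomial string
# hash keeps streams independent of group ordering
stream_seed <- function(seed, label) {
  m <- 2147483647
  h <- 0
  for (c in utf8ToInt(label)) h <- (h * 31 + c) %% m
  as.integer((h + (seed %% m) * 97003) %% m)
}

random_cdr3_aa <- function(n) {
  if (n == 0) return(character(0))
  lens <- sample(10:16, n, replace = TRUE) - 2L
  flat <- sample(AA_ALPHABET, sum(lens), replace = TRUE)
  grp <- factor(rep.int(seq_len(n), lens), levels = seq_len(n))
  mid <- unname(vapply(split(flat, grp), paste, character(1), collapse = ""))
  paste0("C", mid, "F")
}

chain_counts_for_class <- function(class) {
  switch(class,
         A_B = c(1L, 1L), A_B1B2 = c(1L, 2L),
         B_A1A2 = c(2L, 1L), A1A2_B1B2 = c(2L, 2L),
         abort(sprintf("unknown pairing class '%s'", class)))
}

segment_weights <- function(config, group, locus, field) {
  vocab <- segment_vocab(locus, field)
  w <- 0.85^(seq_along(vocab) - 1)  # mild rank-skew, every family observed
  names(w) <- vocab
  bias <- config$usage_bias
  if (!is.null(bias)) {
    rows <- bias[bias$group == group & bias$locus == locus & bias$field == field, ]
    hit <- match(rows$gene, names(w))
    if (anyNA(hit)) {
      abort(sprintf("usage_bias gene '%s' is not in the built-in %s %s vocabulary",
                    rows$gene[which(is.na(hit))[1]], locus, field))
    }
    w[hit] <- w[hit] * rows$weight
  }
  w / sum(w)
}

#' Generate a synthetic paired-chain scTCR-seq repertoire with ground truth
#'
#' Simulates, per group: a pairing class for every cell (single with
#' probability `1 - dual_rate`, else one of the three dual types by
#' `dual_split`); clonotypes formed by partitioning the cells of each class
#' with the geometric clone-size law; for every clonotype, distinct chains
#' (one or two per locus as its class requires) with V and J segments drawn
#' from the group's multinomials, a CDR3 amino-acid sequence drawn either
#' from the cross-group shared pool (probability `sharing_rate`) or
#' privately, and an in-frame, stop-free CDR3 nucleotide sequence obtained
#' by sampling synonymous codons. All cells of a clonotype share identical
#' chains at the nucleotide level. Non-productive noise contigs are
#' appended at `noise_rate`. The output is fully deterministic given the
#' config seed.
#'
#' @param config A [sim_config()].
#' @return A list of class `tcr_sim` with elements `contigs` (canonical
#'   contig tibble, all groups, with a `group` column), `truth` (one row
#'   per barcode: `barcode`, `group`, `true_class`, `clonotype_id`,
#'   `shared`) and `config`.
#' @examples
#' sim <- simulate_repertoire(sim_config(n_cells = 300, seed = 42))
#' table(sim$truth$true_class)
#' @export
simulate_repertoire <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)

  set.seed(stream_seed(config$seed, "shared_pool"))
  pool <- list(TRA = random_cdr3_aa(config$shared_pool_size),
               TRB = random_cdr3_aa(config$shared_pool_size))

  per_group <- lapply(config$groups, function(g) {
    simulate_group(config, g, pool)
  })
  out <- list(
    contigs = bind_rows(lapply(per_group, `[[`, "contigs")),
    truth = bind_rows(lapply(per_group, `[[`, "truth")),
    config = config
  )
  attr(out$truth, "seed") <- config$seed
  class(out) <- "tcr_sim"
  out
}

simulate_group <- function(config, group, pool) {
  set.seed(stream_seed(config$seed, group))
  n <- config$n_cells
  class_prob <- c(A_B = 1 - config$dual_rate, config$dual_rate * config$dual_split)
  cell_class <- sample(names(class_prob), n, replace = TRUE, prob = class_prob)

  weights <- list(
    TRA = list(v_gene = segment_weights(config, group, "TRA", "v_gene"),
               j_gene = segment_weights(config, group, "TRA", "j_gene")),
    TRB = list(v_gene = segment_weights(config, group, "TRB", "v_gene"),
               j_gene = segment_weights(config, group, "TRB", "j_gene"))
  )

  clone_id <- character(n)
  clone_of_class <- list()
  for (cl in unique(cell_class)) {
    idx <- which(cell_class == cl)
    m <- length(idx)
    sizes <- pmin(rgeom(m, config$clone_p) + 1L, m)
    k <- which(cumsum(sizes) >= m)[1]
    sizes <- sizes[seq_len(k)]
    sizes[k] <- m - sum(sizes[-k])
    sizes <- sizes[sizes > 0]
    ids <- sprintf("%s_%s_c%04d", group, cl, seq_along(sizes))
    clone_id[idx] <- rep.int(ids, sizes)
    clone_of_class[[cl]] <- ids
  }

  clones <- unique(clone_id)
  clone_class <- setNames(sub("^.*_(A_B|A_B1B2|B_A1A2|A1A2_B1B2)_c\\d+$", "\\1", clones), clones)
  clone_shared <- setNames(runif(length(clones)) < config$sharing_rate, clones)

  counts <- vapply(clone_class, chain_counts_for_class, integer(2))
  chain_tbl <- bind_rows(
    generate_chains(clones, counts[1, ], "TRA", weights$TRA, pool$TRA, clone_shared),
    generate_chains(clones, counts[2, ], "TRB", weights$TRB, pool$TRB, clone_shared)
  )

  # shuffle cells, then assign barcodes in final order
  ord <- sample.int(n)
  cells <- tibble(
    barcode = sprintf("%s_%05d-1", group, seq_len(n)),
    clone_id = clone_id[ord],
    true_class = cell_class[ord]
  )

  contigs <- cells %>%
    inner_join(chain_tbl, by = "clone_id", relationship = "many-to-many") %>%
    mutate(
      umis = 1L + rpois(dplyr::n(), 2),
      reads = .data$umis * (30L + rpois(dplyr::n(), 20)),
      productive = TRUE,
      full_length = TRUE,
      d_gene = NA_character_,
      group = group
    ) %>%
    select("barcode", "locus", "v_gene", "d_gene", "j_gene", "cdr3_nt",
           "cdr3_aa", "productive", "full_length", "umis", "reads", "group")

  n_noise <- round(config$noise_rate * nrow(contigs))
  if (n_noise > 0) {
    noise_locus <- sample(c("TRA", "TRB"), n_noise, replace = TRUE)
    pick_segment <- function(field) {
      out <- character(n_noise)
      for (l in c("TRA", "TRB")) {
        sel <- noise_locus == l
        out[sel] <- sample(segment_vocab(l, field), sum(sel), replace = TRUE)
      }
      out
    }
    noise <- tibble(
      barcode = sample(cells$barcode, n_noise, replace = TRUE),
      locus = noise_locus,
      v_gene = pick_segment("v_gene"),
      d_gene = NA_character_,
      j_gene = pick_segment("j_gene"),
      cdr3_nt = NA_character_,
      cdr3_aa = NA_character_,
      productive = FALSE,
      full_length = FALSE,
      umis = 1L,
      reads = 30L,
      group = group
    )
    contigs <- bind_rows(contigs, noise) %>% arrange(.data$barcode)
  }

  truth <- cells %>%
    mutate(group = group,
           shared = unname(clone_shared[.data$clone_id])) %>%
    select("barcode", "group", "true_class", clonotype_id = "clone_id", "shared")

  list(contigs = contigs, truth = truth)
}

# Vectorised chain generation for one locus across all clonotypes of a
# group; `k` is the per-clone chain count (1 or 2).
generate_chains <- function(clones, k, locus, w, pool_aa, clone_shared) {
  clone_rep <- rep.int(clones, k)
  n <- length(clone_rep)
  shared <- clone_shared[clone_rep]
  aa <- character(n)
  aa[shared] <- sample(pool_aa, sum(shared), replace = TRUE)
  aa[!shared] <- random_cdr3_aa(sum(!shared))
  tbl <- tibble(
    clone_id = clone_rep,
    locus = locus,
    v_gene = sample(names(w$v_gene), n, replace = TRUE, prob = w$v_gene),
    j_gene = sample(names(w$j_gene), n, replace = TRUE, prob = w$j_gene),
    cdr3_nt = backtranslate_aa(aa),
    cdr3_aa = aa
  )
  # the chains of one cell must be distinct at the nucleotide level;
  # resample the junction of any within-clone duplicate (rare)
  repeat {
    key <- paste(tbl$clone_id, tbl$v_gene, tbl$j_gene, tbl$cdr3_nt)
    dup <- duplicated(key)
    if (!any(dup)) break
    tbl$cdr3_nt[dup] <- backtranslate_aa(tbl$cdr3_aa[dup])
  }
  tbl
}

#' Generate cell annotations and a toy expression matrix for a simulation
#'
#' Emits, for every barcode of the simulation truth, a metadata row (group,
#' cluster label, Treg/nonTreg flag) and a column of normalised expression:
#' each gene is drawn as `base + dual_shift * [cell is dual] + N(0, sigma)`,
#' clipped at zero. The default marker panel carries the Treg signature
#' genes at a common baseline, with a small positive dual shift on Foxp3,
#' Foxo1 and Ctla4.
#'
#' @param truth Truth tibble from [simulate_repertoire()] (or a `tcr_sim`).
#' @param markers Data frame with columns `gene`, `base`, `dual_shift`.
#' @param sigma Gaussian noise standard deviation (default 1).
#' @param nontreg_rate Probability a cell is flagged `nonTreg` (default 0).
#' @param seed Seed; defaults to the simulation seed offset by one so
#'   expression draws never reuse the repertoire stream.
#' @return A list with `meta` (tibble: `barcode`, `group`, `cluster`,
#'   `treg_flag`) and `expr` (genes-by-cells matrix, barcodes as colnames).
#' @export
simulate_expression <- function(truth, markers = default_markers(), sigma = 1,
                                nontreg_rate = 0, seed = NULL) {
  if (inherits(truth, "tcr_sim")) truth <- truth$truth
  if (!all(c("gene", "base", "dual_shift") %in% names(markers))) {
    abort("`markers` must have columns gene, base, dual_shift")
  }
  seed <- seed %||% (attr(truth, "seed") %||% 0L)
  set.seed(stream_seed(as.integer(seed), "expression"))

  n <- nrow(truth)
  is_dual <- truth$true_class %in% DUAL_CLASSES
  expr <- matrix(0, nrow = nrow(markers), ncol = n,
                 dimnames = list(markers$gene, truth$barcode))
  for (i in seq_len(nrow(markers))) {
    expr[i, ] <- pmax(0, markers$base[i] + markers$dual_shift[i] * is_dual +
                        rnorm(n, sd = sigma))
  }
  meta <- tibble(
    barcode = truth$barcode,
    group = truth$group,
    cluster = paste0("c", sample.int(5, n, replace = TRUE)),
    treg_flag = ifelse(runif(n) < nontreg_rate, "nonTreg", "Treg")
  )
  list(meta = meta, expr = expr)
}

#' Default Treg signature marker panel for the expression simulator
#'
#' @return A tibble with `gene`, `base`, `dual_shift`.
#' @export
default_markers <- function() {
  genes <- c("Tnfrsf9", "Stat3", "Tnfrsf4", "Cd27", "Icos", "Il2ra", "Ikzf2",
             "Lrrc32", "Sh3rf1", "Cd81", "Smad2", "Foxo3", "Foxp3", "Foxo1",
             "Ctla4")
  tibble(
    gene = genes,
    base = 1.5,
    dual_shift = ifelse(genes %in% c("Foxp3", "Foxo1", "Ctla4"), 0.25, 0)
  )
}

#' Write a simulated repertoire to disk in 10x-style layout
#'
#' Emits, per group, `filtered_contig_annotations.csv`, plus shared
#' `cell_meta.tsv`, `truth.tsv` and an `expr/` MatrixMarket directory.
#'
#' @param sim A `tcr_sim` from [simulate_repertoire()].
#' @param dir Output directory.
#' @param expression Optional result of [simulate_expression()].
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, expression = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (g in sim$config$groups) {
    gd <- file.path(dir, g)
    if (!dir.exists(gd)) dir.create(gd)
    write_contigs(filter(sim$contigs, .data$group == g),
                  file.path(gd, "filtered_contig_annotations.csv"), "tenx_csv")
  }
  write_table(sim$truth, file.path(dir, "truth.tsv"), "tsv")
  if (!is.null(expression)) {
    write_table(expression$meta, file.path(dir, "cell_meta.tsv"), "tsv")
    write_expression(expression$expr, file.path(dir, "expr"))
  }
  invisible(dir)
}
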