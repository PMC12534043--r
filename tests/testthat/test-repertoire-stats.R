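test_that("inverse Simpson matches hand-checked values and its invariants", {
  expect_equal(inverse_simpson(c(1, 1, 1, 1)), 4)
  expect_equal(inverse_simpson(5), 1)
  expect_equal(inverse_simpson(c(2, 1, 1)), 2.6667, tolerance = 1e-4)
  expect_error(inverse_simpson(numeric(0)), "empty")

  # uniform repertoire equals richness exactly
  for (n in c(1, 2, 7, 33, 100)) {
    expect_equal(inverse_simpson(rep(1, n)), n)
  }
  # scale invariance
  set.seed(42)
  for (i in 1:20) {
    sizes <- sample(1:20, sample(1:15, 1), replace = TRUE)
    k <- sample(2:9, 1)
    expect_equal(inverse_simpson(sizes * k), inverse_simpson(sizes))
    # bounded by [1, richness]
    v <- inverse_simpson(sizes)
    expect_gte(v, 1); expect_lte(v, length(sizes))
    # reordering clonotypes changes nothing
    expect_equal(inverse_simpson(rev(sizes)), v)
    expect_equal(expansion_fraction(rev(sizes)), expansion_fraction(sizes))
  }
})

test_that("inverse Simpson agrees with an independent ecology implementation", {
  skip_if_not_installed("vegan")
  set.seed(11)
  for (i in 1:10) {
    sizes <- sample(1:30, sample(2:20, 1), replace = TRUE)
    expect_equal(inverse_simpson(sizes),
                 unname(vegan::diversity(sizes, index = "invsimpson")),
                 tolerance = 1e-12)
  }
})

test_that("expansion fraction counts cells in clones of size >= 2", {
  expect_equal(expansion_fraction(c(3, 1, 1)), 0.6)
  expect_equal(expansion_fraction(rep(1, 10)), 0)
  expect_equal(expansion_fraction(7), 1)
  expect_equal(expansion_fraction(c(3, 1, 1), basis = "clonotypes"), 1 / 3)
  expect_error(expansion_fraction(numeric(0)), "empty")
})

test_that("clonotype keys are canonical and strata are never merged", {
  # three cells of one clone, one distinct single cell, one dual cell
  # sharing the same alpha and one beta as the clone
  clone_cells <- dplyr::bind_rows(lapply(c("b1", "b2", "b3"), function(b) {
    dplyr::bind_rows(
      contig_row(b, "TRA", v = "Trav1", j = "Traj2", nt = "TGTAAATTT", aa = "CKF"),
      contig_row(b, "TRB", v = "Trbv5", j = "Trbj1-2", nt = "TGTCCCTTT", aa = "CPF")
    )
  }))
  other_single <- dplyr::bind_rows(
    contig_row("b4", "TRA", v = "Trav2", j = "Traj5", nt = "TGTGGGTTT", aa = "CGF"),
    contig_row("b4", "TRB", v = "Trbv19", j = "Trbj2-3", nt = "TGTTTGTTT", aa = "CLF")
  )
  dual <- dplyr::bind_rows(
    contig_row("b5", "TRA", v = "Trav1", j = "Traj2", nt = "TGTAAATTT", aa = "CKF"),
    contig_row("b5", "TRB", v = "Trbv5", j = "Trbj1-2", nt = "TGTCCCTTT", aa = "CPF"),
    contig_row("b5", "TRB", v = "Trbv19", j = "Trbj2-3", nt = "TGTACGTTT", aa = "CTF")
  )
  pairing <- classify_repertoire(
    dplyr::bind_rows(clone_cells, other_single, dual),
    groups = tibble::tibble(barcode = paste0("b", 1:5), group = "g1")
  )
  ct <- build_clonotypes(pairing)
  single <- ct[ct$compartment == "single", ]
  expect_equal(sort(single$size), c(1L, 3L))
  # dual cell shares chains with the clone but has a different key tuple
  expect_equal(ct$size[ct$compartment == "dual"], 1L)
  # sizes partition cells within each stratum
  expect_equal(sum(ct$size), 5L)

  # generator ground truth: clonotype size spectra agree exactly
  sim <- simulate_repertoire(sim_config(n_cells = 800, groups = "g", seed = 13))
  p <- classify_repertoire(sim$contigs)
  ct2 <- build_clonotypes(p)
  truth_sizes <- sort(as.integer(table(sim$truth$clonotype_id)))
  expect_equal(sort(ct2$size), truth_sizes)
})

test_that("diversity_summary reproduces per-stratum statistics from sizes", {
  ct <- tibble::tibble(
    group = "g1",
    compartment = rep(c("single", "dual"), c(3, 2)),
    clonotype = paste0("k", 1:5),
    size = c(2L, 1L, 1L, 4L, 1L)
  )
  class(ct) <- c("tcr_clonotypes", class(ct))
  ds <- diversity_summary(ct)
  expect_equal(ds$inv_simpson[ds$compartment == "single"], inverse_simpson(c(2, 1, 1)))
  expect_equal(ds$expansion[ds$compartment == "dual"], 4 / 5)
  expect_equal(ds$n_cells, c(5L, 4L))

  # rarefaction to the smaller stratum is reproducible under a seed
  r1 <- diversity_summary(ct, rarefy_to = 4, n_boot = 20, seed = 9)
  r2 <- diversity_summary(ct, rarefy_to = 4, n_boot = 20, seed = 9)
  expect_equal(r1$inv_simpson_rarefied, r2$inv_simpson_rarefied)
  expect_true(all(r1$inv_simpson_rarefied >= 1, na.rm = TRUE))
})

test_that("V/J usage counts every retained chain once per stratum", {
  cells <- dplyr::bind_rows(
    paired_cell("b1", beta_v = "Trbv5"),
    paired_cell("b2", beta_v = "Trbv5", beta_nt = "TGTAAGAAGTTT"),
    paired_cell("b3", beta_v = "Trbv19", beta_nt = "TGTAAGGGGTTT")
  )
  pairing <- classify_repertoire(cells)
  u <- vj_usage(pairing, locus = "TRB", field = "v_gene")
  expect_equal(u$freq[u$gene == "Trbv5"], 2 / 3)
  # frequencies sum to one within each stratum
  expect_equal(sum(u$freq), 1)

  # a dual-alpha cell contributes two TRA V counts and one TRB count
  dual <- dplyr::bind_rows(
    contig_row("d1", "TRA", v = "Trav1", nt = "TGTAAATTT"),
    contig_row("d1", "TRA", v = "Trav2", nt = "TGTGGGTTT"),
    contig_row("d1", "TRB", v = "Trbv5", nt = "TGTCCCTTT")
  )
  pd <- classify_repertoire(dual)
  expect_equal(sum(vj_usage(pd, "TRA", "v_gene")$count), 2L)
  expect_equal(sum(vj_usage(pd, "TRB", "v_gene")$count), 1L)
})

test_that("per-gene usage tests match the hand computation and are label-stable", {
  mk_usage <- function(genes, counts) {
    u <- tibble::tibble(group = "g", compartment = "single",
                        gene = genes, count = counts)
    u$freq <- u$count / sum(u$count)
    u
  }
  # 20/100 vs 0/100 for the focal gene
  a <- mk_usage(c("Trbv5", "Trbv19"), c(20L, 80L))
  b <- mk_usage("Trbv19", 100L)
  res <- vj_usage_test(a, b)
  focal <- res[res$gene == "Trbv5", ]
  expect_equal(focal$statistic, 22.2222, tolerance = 1e-4)
  expect_equal(focal$df, 1L)

  # identical usage vectors: all statistics 0, all p = 1
  res0 <- vj_usage_test(a, a)
  expect_equal(res0$statistic, c(0, 0))
  expect_equal(res0$p_value, c(1, 1))

  # permuting gene row order leaves per-gene results unchanged
  a_perm <- a[rev(seq_len(nrow(a))), ]
  res_perm <- vj_usage_test(a_perm, b)
  expect_equal(dplyr::arrange(res, gene), dplyr::arrange(res_perm, gene))

  # low-count flag
  tiny <- vj_usage_test(mk_usage(c("x", "y"), c(2L, 50L)), mk_usage("y", 50L))
  expect_true(tiny$low_count[tiny$gene == "x"])
})

test_that("a tissue-biased V multinomial shows up in usage frequencies", {
  bias <- tibble::tibble(group = "skin", locus = "TRB", field = "v_gene",
                         gene = "Trbv13-1", weight = 8)
  sim <- simulate_repertoire(sim_config(
    n_cells = 4000, groups = c("spleen", "skin"), usage_bias = bias, seed = 17
  ))
  pairing <- classify_repertoire(sim$contigs)
  u <- vj_usage(pairing, "TRB", "v_gene")
  f <- function(g, comp = "single") u$freq[u$group == g & u$compartment == comp & u$gene == "Trbv13-1"]
  expect_gt(f("skin"), f("spleen"))
})
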