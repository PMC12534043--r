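test_that("collapse_chains drops non-productive and non-alpha/beta contigs and dedups chains", {
  contigs <- dplyr::bind_rows(
    contig_row("b1", "TRA", nt = "TGTAAATTT"),
    contig_row("b1", "TRB", nt = "TGTCCCTTT"),
    contig_row("b1", "TRB", nt = "TGTGGGTTT", productive = FALSE)
  )
  cells <- collapse_chains(contigs)
  expect_equal(cells$n_alpha, 1L)
  expect_equal(cells$n_beta, 1L)
  expect_equal(cells$dropped_nonproductive, 1L)

  # identical V/J/CDR3nt contigs collapse to one chain
  dup <- dplyr::bind_rows(
    contig_row("b2", "TRA", nt = "TGTAAATTT", umis = 5L),
    contig_row("b2", "TRA", nt = "TGTAAATTT", umis = 1L)
  )
  expect_equal(collapse_chains(dup)$n_alpha, 1L)

  # same CDR3aa, different CDR3nt: distinct chains (DNA-level identity)
  twin <- dplyr::bind_rows(
    contig_row("b3", "TRA", nt = "TGTAAATTT", aa = "CKF"),
    contig_row("b3", "TRA", nt = "TGCAAATTT", aa = "CKF"),
    contig_row("b3", "TRB", nt = "TGTCCCTTT")
  )
  expect_equal(collapse_chains(twin)$n_alpha, 2L)

  # one alpha plus two distinct betas: a dual-beta cell's chains
  dual <- dplyr::bind_rows(
    contig_row("b4", "TRA", nt = "TGTAAATTT"),
    contig_row("b4", "TRB", nt = "TGTCCCTTT"),
    contig_row("b4", "TRB", nt = "TGTGGGTTT")
  )
  cc <- collapse_chains(dual)
  expect_equal(c(cc$n_alpha, cc$n_beta), c(1L, 2L))
})

test_that("classification is a pure function of chain counts", {
  expect_equal(as.character(classify_cell(1, 1)), "A_B")
  expect_equal(as.character(classify_cell(1, 2)), "A_B1B2")
  expect_equal(as.character(classify_cell(2, 1)), "B_A1A2")
  expect_equal(as.character(classify_cell(2, 2)), "A1A2_B1B2")
  expect_equal(as.character(classify_cell(2, 0)), "excluded_unpaired")
  expect_equal(as.character(classify_cell(3, 1)), "excluded_multiplet")
  expect_error(classify_cell(-1, 1), "non-negative")
})

test_that("classify_repertoire yields one row per barcode and is order-invariant", {
  contigs <- dplyr::bind_rows(lapply(paste0("b", 1:5), paired_cell))
  # add contig multiplicity for one barcode
  contigs <- dplyr::bind_rows(contigs, contigs[contigs$barcode == "b1", ])
  pairing <- classify_repertoire(contigs)
  expect_equal(nrow(pairing), 5L)
  expect_true(all(pairing$class == "A_B"))

  # empty input -> empty classification
  expect_equal(nrow(classify_repertoire(contigs[0, ])), 0L)

  # shuffling contig rows never changes any classification
  sim <- simulate_repertoire(sim_config(n_cells = 300, groups = "g", seed = 5))
  p1 <- classify_repertoire(sim$contigs)
  shuffled <- sim$contigs[sample.int(nrow(sim$contigs)), ]
  p2 <- classify_repertoire(shuffled)
  m <- dplyr::inner_join(tibble::as_tibble(p1), tibble::as_tibble(p2), by = "barcode")
  expect_equal(as.character(m$class.x), as.character(m$class.y))

  # partition: the six classes cover every distinct barcode exactly once
  expect_equal(sum(table(p1$class)), dplyr::n_distinct(sim$contigs$barcode))

  # unmapped barcodes fall into the 'unassigned' group
  p3 <- classify_repertoire(dplyr::select(sim$contigs, -"group"))
  expect_true(all(p3$group == "unassigned"))
})

test_that("pairing_summary reports percentages over paired cells only", {
  pairing <- tibble::tibble(
    group = "g1",
    class = factor(
      c(rep("A_B", 8), "A_B1B2", "B_A1A2", "excluded_unpaired"),
      levels = levels(classify_cell(1, 1))
    )
  )
  s <- pairing_summary(pairing)
  expect_equal(s$n_paired, 10L)
  expect_equal(s$n_cells, 11L)
  expect_equal(s$pct_dual, 20)
  expect_equal(s$pct_A_B + s$pct_A_B1B2 + s$pct_B_A1A2 + s$pct_A1A2_B1B2, 100)

  only_single <- tibble::tibble(
    group = "g1", class = factor(rep("A_B", 4), levels = levels(pairing$class)))
  expect_equal(pairing_summary(only_single)$pct_dual, 0)

  # a group with zero paired cells keeps NA percentages, not 0
  none_paired <- tibble::tibble(
    group = "g2",
    class = factor(rep("excluded_unpaired", 3), levels = levels(pairing$class)))
  s2 <- pairing_summary(none_paired)
  expect_equal(s2$n_paired, 0L)
  expect_true(is.na(s2$pct_dual))
})

test_that("compare_pairing matches the hand-computed Pearson statistic", {
  # group a: 20 dual / 80 single; group b: 40 dual / 60 single
  mk <- function(group, n_single, duals) {
    tibble::tibble(
      group = group,
      class = factor(c(rep("A_B", n_single),
                       rep(c("A_B1B2", "B_A1A2", "A1A2_B1B2"), duals)),
                     levels = levels(classify_cell(1, 1)))
    )
  }
  pairing <- dplyr::bind_rows(mk("a", 80, c(10, 6, 4)), mk("b", 60, c(20, 12, 8)))
  res <- compare_pairing(pairing, "a", "b")
  sd <- res[res$contrast == "single_vs_dual", ]
  expect_equal(sd$statistic, 9.5238, tolerance = 1e-4)
  expect_equal(sd$df, 1L)
  expect_equal(sd$p_value, pchisq(sd$statistic, 1, lower.tail = FALSE))

  # identical composition: statistic 0, p = 1, in both contrasts
  same <- dplyr::bind_rows(mk("a", 60, c(10, 6, 4)), mk("b", 60, c(10, 6, 4)))
  res0 <- compare_pairing(same, "a", "b")
  expect_equal(res0$statistic, c(0, 0))
  expect_equal(res0$p_value, c(1, 1))

  # tidy/glance accessors
  expect_s3_class(generics::tidy(res), "tbl_df")
  expect_equal(generics::glance(res)$group_a, "a")

  # an empty dual category in both groups has expected count 0
  sparse <- dplyr::bind_rows(mk("a", 50, c(5, 5, 0)), mk("b", 50, c(5, 5, 0)))
  expect_error(compare_pairing(sparse, "a", "b"), "pool")
})

test_that("estimated dual proportions track the configured rate and stay monotone", {
  est <- vapply(c(0.05, 0.20), function(rate) {
    sim <- simulate_repertoire(sim_config(n_cells = 4000, groups = "g",
                                          dual_rate = rate, seed = 31))
    pairing_summary(classify_repertoire(sim$contigs))$pct_dual / 100
  }, numeric(1))
  iv1 <- binom_interval99(4000, 0.05)
  iv2 <- binom_interval99(4000, 0.20)
  expect_gt(est[1], iv1[1]); expect_lt(est[1], iv1[2])
  expect_gt(est[2], iv2[1]); expect_lt(est[2], iv2[2])
  expect_lt(est[1], est[2])
})
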