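test_that("jaccard matches set algebra and its invariants", {
  expect_equal(jaccard(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(jaccard(c("x", "y"), c("x", "y")), 1)
  expect_equal(jaccard("x", "y"), 0)
  expect_warning(v <- jaccard(character(0), character(0)), "undefined")
  expect_true(is.na(v))

  set.seed(7)
  pool <- replicate(40, paste(sample(LETTERS, 5), collapse = ""))
  for (i in 1:25) {
    a <- sample(pool, sample(0:30, 1))
    b <- sample(pool, sample(1:30, 1))
    expect_identical(jaccard(a, b), jaccard(b, a))
    expect_identical(jaccard(a, b), oracle_jaccard(a, b))
    if (length(a) > 0) expect_equal(jaccard(a, a), 1)
    # a sequence added to both sides never decreases the index;
    # added to one side only, never increases it
    s <- paste(sample(letters, 6), collapse = "")
    expect_gte(jaccard(c(a, s), c(b, s)), jaccard(a, b))
    if (length(b) > 0) expect_lte(jaccard(c(a, s), b), jaccard(a, b))
  }
})

test_that("cdr3_set counts cells and collapses convergent amino-acid chains", {
  cells <- dplyr::bind_rows(
    paired_cell("b1", beta_aa = "CASSXF", beta_nt = "TGTAAATTT"),
    paired_cell("b2", beta_aa = "CASSYF", beta_nt = "TGTCCCTTT")
  )
  s <- cdr3_set(classify_repertoire(cells), "g1", "single", "TRB")
  expect_setequal(s$cdr3_aa, c("CASSXF", "CASSYF"))
  expect_true(all(s$n_cells == 1L))

  # dual cell with two betas convergent at the protein level: one member,
  # one cell
  conv <- dplyr::bind_rows(
    contig_row("d1", "TRA", nt = "TGTAAATTT", aa = "CAF"),
    contig_row("d1", "TRB", nt = "TGTCCATTT", aa = "CASSXF"),
    contig_row("d1", "TRB", nt = "TGCCCTTTT", aa = "CASSXF")
  )
  sc <- cdr3_set(classify_repertoire(conv), "unassigned", "dual", "TRB")
  expect_equal(sc$cdr3_aa, "CASSXF")
  expect_equal(sc$n_cells, 1L)

  # a dual-alpha cell contributes both TRA strings
  dual_a <- dplyr::bind_rows(
    contig_row("d2", "TRA", nt = "TGTAAATTT", aa = "CA1F"),
    contig_row("d2", "TRA", nt = "TGTGGGTTT", aa = "CA2F"),
    contig_row("d2", "TRB", nt = "TGTCCCTTT", aa = "CBF")
  )
  sa <- cdr3_set(classify_repertoire(dual_a), "unassigned", "dual", "TRA")
  expect_setequal(sa$cdr3_aa, c("CA1F", "CA2F"))

  # empty stratum is a valid empty set
  expect_equal(nrow(cdr3_set(classify_repertoire(cells), "nope", "dual", "TRA")), 0L)
})

test_that("overlap matrices are symmetric with unit diagonal", {
  cells <- dplyr::bind_rows(
    paired_cell("b1", group = "t1", beta_aa = "CS1F", beta_nt = "TGTAAATTT"),
    paired_cell("b2", group = "t1", beta_aa = "CS2F", beta_nt = "TGTCCCTTT"),
    paired_cell("b3", group = "t2", beta_aa = "CS2F", beta_nt = "TGTCCCTTT"),
    paired_cell("b4", group = "t2", beta_aa = "CS3F", beta_nt = "TGTGGGTTT"),
    paired_cell("b5", group = "t3", beta_aa = "CS9F", beta_nt = "TGTTTGTTT")
  )
  m <- overlap_matrix(classify_repertoire(cells), "TRB", "single")
  expect_equal(unname(diag(unclass(m))), c(1, 1, 1))
  expect_equal(unclass(m), t(unclass(m)))
  expect_equal(m["t1", "t2"], 1 / 3)   # {CS1,CS2} vs {CS2,CS3}
  expect_equal(m["t1", "t3"], 0)
  expect_error(overlap_matrix(classify_repertoire(cells), "TRB", "single",
                              groups = "t1"), "two groups")
})

test_that("higher sharing rates give higher cross-group overlap", {
  mean_offdiag <- function(rate, seed) {
    sim <- simulate_repertoire(sim_config(
      n_cells = 1200, groups = c("g1", "g2"), sharing_rate = rate,
      shared_pool_size = 60, seed = seed
    ))
    m <- unclass(overlap_matrix(classify_repertoire(sim$contigs), "TRB", "single"))
    m["g1", "g2"]
  }
  vals <- vapply(c(0, 0.1, 0.3), function(r) {
    mean(vapply(1:3, function(s) mean_offdiag(r, 100 + s), numeric(1)))
  }, numeric(1))
  # with no shared pool, only chance collisions in a ~19^10 string space
  expect_lt(vals[1], 0.001)
  expect_lt(vals[1], vals[2])
  expect_lt(vals[2], vals[3])
})

test_that("top shared sequences rank by total cells with lexicographic ties", {
  mk <- function(barcode, group, aa, n = 1) {
    dplyr::bind_rows(lapply(seq_len(n), function(i) {
      paired_cell(paste0(barcode, "_", i), group = group, beta_aa = aa,
                  beta_nt = paste0("TGT", paste(rep(c("AAA", "CCC", "GGG"), 4)[i + 0:3], collapse = ""), "TTT"))
    }))
  }
  cells <- dplyr::bind_rows(
    mk("a", "t1", "CPUBLICF", n = 3), mk("b", "t2", "CPUBLICF", n = 2),
    mk("c", "t1", "CAAAF", n = 2),    mk("d", "t2", "CAAAF", n = 3),
    mk("e", "t1", "CPRIVF", n = 4)    # private: never tracked
  )
  pairing <- classify_repertoire(cells)
  top <- top_shared_sequences(pairing, "TRB", "single", n = 10)
  expect_equal(nrow(top), 2L)
  # equal totals (5, 5): lexicographic order breaks the tie
  expect_equal(top$cdr3_aa, c("CAAAF", "CPUBLICF"))
  expect_false("CPRIVF" %in% top$cdr3_aa)
  expect_equal(top$n_t1[top$cdr3_aa == "CPUBLICF"], 3L)

  # no shared sequence -> valid empty table
  lonely <- dplyr::bind_rows(mk("x", "t1", "CXF"), mk("y", "t2", "CYF"))
  expect_equal(nrow(top_shared_sequences(classify_repertoire(lonely), "TRB", "single")), 0L)

  # a planted high-frequency public clone ranks first in simulation
  sim <- simulate_repertoire(sim_config(n_cells = 500, groups = c("g1", "g2"),
                                        sharing_rate = 0.2, seed = 23))
  planted <- dplyr::bind_rows(lapply(c(outer(c("g1", "g2"), 1:6, paste0)), function(b) {
    paired_cell(b, group = substr(b, 1, 2), beta_aa = "CPLANTEDPUBLICF",
                beta_nt = "TGTCCGTTAGCGAATACCGAAGACCCGTTAGCGATCTTT")
  }))
  p2 <- classify_repertoire(dplyr::bind_rows(sim$contigs, planted))
  top2 <- top_shared_sequences(p2, "TRB", "single", n = 10)
  expect_equal(top2$cdr3_aa[1], "CPLANTEDPUBLICF")
})
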