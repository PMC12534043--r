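# dualtcr

Single and dual TCR classification and repertoire statistics for
paired-chain single-cell TCR sequencing.

Allelic exclusion should leave each T cell with one productive alpha (TRA)
and one beta (TRB) chain, but a sizeable minority of T cells — regulatory T
cells especially — carry two productive rearrangements at one or both loci
and express **dual TCRs**. Paired-chain scTCR-seq resolves every assembled
chain per cell barcode, so these cells can be counted and characterised
directly. `dualtcr` is for immunologists and computational biologists who
have 10x Genomics (`filtered_contig_annotations.csv`) or AIRR Rearrangement
contig tables — typically of sorted Treg or T cell populations from several
tissues — and want the dual-TCR analysis chain as tested, scriptable R
functions.

## What it computes

Each barcode's productive chains are collapsed to distinct chain keys
(locus, V, J, CDR3 nucleotide sequence) and the cell is classified from its
chain counts $(n_\alpha, n_\beta)$:

* `A_B` (1, 1) — single TCR;
* `A_B1B2` (1, 2), `B_A1A2` (2, 1), `A1A2_B1B2` (2, 2) — the three dual
  TCR types;
* `excluded_unpaired` (no chain at a locus) and `excluded_multiplet`
  (> 2 chains at a locus) — reported but never in percentage denominators.

On top of the classification: per-group pairing proportions with Pearson
chi-square contrasts (single-vs-dual 2×2 and the 2×3 over dual types);
paired-chain clonotypes with inverse Simpson diversity
$1/\sum_i p_i^2$ and the cell-level clonal-expansion fraction
(clonotype size ≥ 2); V/J segment usage with per-gene 2×2 chi-square tests
(BH-adjusted); cross-tissue CDR3 amino-acid overlap as Jaccard indices
$|A \cap B| / |A \cup B|$ per locus and compartment, with tracking of the
top shared sequences; and a barcode-level join onto cell annotations and
normalised expression, with a Wilcoxon rank-sum ranking of dual-vs-single
marker genes. A seeded synthetic repertoire generator with full ground
truth (`simulate_repertoire()`, `simulate_expression()`) backs the test
suite and makes every statistic verifiable end to end.

## Worked example

```r
library(dualtcr)
library(dplyr)

cfg <- sim_config(n_cells = 3000, groups = c("spleen", "iLN", "skin"),
                  dual_rate = 0.18, seed = 7)
sim <- simulate_repertoire(cfg)
pairing <- classify_repertoire(sim$contigs)   # or read_contigs("..._contig_annotations.csv")

pairing_summary(pairing) |>
  select(group, n_paired, pct_A_B, pct_B_A1A2, pct_dual)
#> # A tibble: 3 × 5
#>   group  n_paired pct_A_B pct_B_A1A2 pct_dual
#>   <chr>     <int>   <dbl>      <dbl>    <dbl>
#> 1 iLN        3000    83.6       7.93     16.4
#> 2 skin       3000    82.5       7.4      17.5
#> 3 spleen     3000    83.0       7.5      17.0
```

Each row is one tissue: of 3000 paired cells, ~17% are dual TCR cells
(sampling noise around the configured 18%), with dual-alpha (`B_A1A2`)
the largest dual type as configured. Composition differences between two
tissues are tested directly:

```r
compare_pairing(pairing, "spleen", "skin")
#>   contrast       statistic    df p_value method
#> 1 single_vs_dual     0.262     1   0.609 Pearson chi-square
#> 2 dual_types         1.21      2   0.546 Pearson chi-square
```

Here the two simulated tissues share one dual rate, so both contrasts are
null. Diversity and clonality per (tissue, compartment) stratum:

```r
build_clonotypes(pairing) |> diversity_summary()
#>   group  compartment n_cells n_clonotypes inv_simpson expansion
#> 1 iLN    dual            491          346        271.     0.503
#> 2 iLN    single         2509         1716       1303.     0.535
#> ...
```

`inv_simpson` is the inverse Simpson index of the stratum's clonotype
frequencies (1303 effective clonotypes among 2509 iLN single cells);
`expansion` is the fraction of cells in clonotypes of size ≥ 2. Overlap and
marker ranking follow the same pattern:

```r
overlap_matrix(pairing, locus = "TRA", compartment = "single")
#>               iLN       skin     spleen
#> iLN    1.00000000 0.01996928 0.01702645
#> skin   0.01996928 1.00000000 0.01889668
#> spleen 0.01702645 0.01889668 1.00000000

ex <- simulate_expression(sim)
joined <- join_by_barcode(pairing, ex$meta)
mk <- rank_markers(joined, ex$expr)
head(tidy(mk), 3)
#>   gene  mean_dual mean_single log2_fc statistic  p_value  q_value
#> 1 Foxp3      1.79        1.51  0.153   6664515  5.10e-25 7.66e-24
#> 2 Ctla4      1.78        1.52  0.145   6583814. 3.12e-21 2.34e-20
#> 3 Foxo1      1.73        1.52  0.115   6424390  1.03e-14 5.14e-14
```

The off-diagonal Jaccard (~0.02) reflects the simulator's shared CDR3
pool; the top-ranked markers are exactly the genes the expression
simulator shifts upward in dual cells. `plot_pairing_summary()`,
`plot_vj_usage()`, `plot_diversity()` and `autoplot()` on overlap matrices
and marker tables give the corresponding figures.

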