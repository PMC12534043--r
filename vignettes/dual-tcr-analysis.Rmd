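---
title: "Classifying and characterising dual TCR T cells from paired-chain scTCR-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying and characterising dual TCR T cells from paired-chain scTCR-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualtcr)
library(dplyr)
```

## The problem

Allelic exclusion is supposed to guarantee that a T cell expresses a single
T cell receptor: one alpha (TRA) and one beta (TRB) chain. In practice a
substantial minority of T cells — regulatory T cells in particular — carry
two productive rearrangements at one or both loci ("allelic inclusion"),
and so express dual TCRs. Paired-chain single-cell TCR sequencing resolves
both chains per cell barcode and makes these cells directly countable.

`dualtcr` implements the analysis chain for that question: read per-contig
annotation tables, collapse each barcode's productive chains, classify
every cell into a pairing type, and compute the statistics used to compare
single and dual TCR compartments across tissues — pairing-type proportions
with chi-square contrasts, paired-chain clonotypes with inverse Simpson
diversity and clonal-expansion fractions, V/J segment usage comparisons,
cross-tissue CDR3 amino-acid overlap (Jaccard), and a barcode-level join
onto cell annotations and normalised expression.

## The pairing taxonomy

After dropping non-productive contigs and non-alpha/beta loci, the distinct
chains of a barcode are counted per locus. Chain identity is the tuple
(locus, V gene, J gene, CDR3 nucleotide sequence): identity is deliberately
at the DNA level, because allelic inclusion is a DNA-level event — two
chains that converge to the same amino-acid CDR3 from different
rearrangements are different chains. UMI and read counts never enter
identity.

The class of a cell is a pure function of its chain counts
$(n_\alpha, n_\beta)$:

| $n_\alpha$ | $n_\beta$ | class |
|---|---|---|
| 1 | 1 | `A_B` (single TCR) |
| 1 | 2 | `A_B1B2` (dual beta) |
| 2 | 1 | `B_A1A2` (dual alpha) |
| 2 | 2 | `A1A2_B1B2` (dual at both loci) |
| 0 at either locus | — | `excluded_unpaired` |
| >2 at either locus | — | `excluded_multiplet` |

Two boundary decisions were genuinely open and are fixed as follows. A cell
with zero chains at one locus and more than two at the other satisfies both
exclusion rules; it is classed `excluded_unpaired`, because without both
loci it cannot pair regardless of how the extra chains arose. Cells with
more than two distinct productive chains at a locus fall outside the
two-allele taxonomy entirely; they are most plausibly droplet doublets that
upstream doublet removal missed, so they are reported separately as
`excluded_multiplet` rather than forced into a dual class. All printed
percentages use paired cells (the four retained classes) as denominator; a
group with no paired cells reports `NA`, never a fabricated 0.

Productivity is the inclusion criterion; `full_length` is parsed but not
required by default (a `require_full_length` switch enables the stricter
filter). The 10x `productive` vocabulary is mapped conservatively: only a
literal true value counts, `"None"` and empty map to false.

## Statistics

**Proportion contrasts.** Between-group composition is tested with
Pearson's chi-square without continuity correction — the conventional
headline statistic for these tables — on (a) the single-vs-dual 2×2 and (b)
the 2×3 over the three dual classes; `yates = TRUE` switches on the
correction for the 2×2. An expected-zero cell raises an error advising
category pooling rather than returning a misleading statistic. Raw p-values
are reported (per-gene usage tests additionally carry Benjamini–Hochberg
q-values, one family per locus/field).

**Clonotypes and diversity.** A clonotype is the lexicographically sorted
tuple of a cell's chain keys, so enumeration order cannot affect identity
and dual cells can never merge with single cells. Diversity is the inverse
Simpson index $1/\sum_i p_i^2$ over clonotype frequencies within a (group,
compartment) stratum; it equals richness for a uniform repertoire and is
invariant to rescaling sizes. Clonal expansion is a clonotype of size ≥ 2;
the reported fraction is cell-level (cells in expanded clones over all
cells), matching per-cell bar-chart conventions, with the clonotype-level
alternative available via `basis = "clonotypes"`. Because strata with very
different cell counts are not comparable on raw diversity, an optional
seeded bootstrap rarefaction (default 100 draws) to a common cell count is
provided, off by default.

**Overlap.** Cross-group overlap is presence/absence Jaccard over unique
CDR3 amino-acid strings per (locus, compartment) — the public-repertoire
convention — not frequency-weighted; cell counts are carried only to rank
shared sequences. "Top shared" tracking ranks sequences present in ≥ 2
groups by total cells across groups, with lexicographic tie-breaks so
output is deterministic. Single and dual compartments are never pooled. The
Jaccard of two empty sets is undefined and reported `NA`.

**Expression join and markers.** scTCR and scRNA results are joined by
exact barcode string after stripping a configurable trailing `-<digits>`
suffix; duplicate annotation barcodes are an error, and the join report
counts both-side/one-side barcodes. The dual-vs-single marker ranking uses
the Wilcoxon rank-sum test with BH adjustment on already-normalised
expression, with effect = log2 fold change of compartment means under a
pseudocount of 1; the method is stated in the result object so these
numbers are never mistaken for a negative-binomial model's Wald statistics.
Contrasts with fewer than `min_cells` (default 10) cells in either
compartment are skipped, not computed.

## What the simulator emulates

`simulate_repertoire()` is the package's test bed and emits full ground
truth (true class, clonotype id, shared-pool membership per barcode). Its
defaults describe the study conditions the package targets:

* `dual_rate = 0.15` — mid-range of dual Treg proportions observed across
  mouse tissues (roughly 11–21%).
* `dual_split = (0.35, 0.45, 0.20)` — dual-alpha (`B_A1A2`) most frequent,
  four-chain cells least, as observed in tissue Tregs.
* geometric clone-size law with `clone_p = 0.7` — mostly singletons with a
  tail of expanded clones heavy enough to exercise expansion statistics.
* mildly rank-skewed V/J multinomials over a built-in vocabulary of real
  mouse TRAV/TRAJ/TRBV/TRBJ family names, with per-tissue multiplicative
  biases available through `usage_bias`.
* a cross-group shared CDR3 pool (default 200 sequences per locus, drawn
  by 10% of clonotypes) creating public sequences for overlap analyses.
* 5% non-productive noise contigs.

CDR3s are generated as amino-acid strings (10–16 residues, canonical
C...F frame) and back-translated through sampled synonymous codons of the
standard genetic code, so every productive junction is in-frame, stop-free
nucleotide sequence whose translation equals its amino-acid annotation.
Per-group random streams are split by hashing the group label with the
seed, so adding a group never perturbs existing groups.

What it does **not** emulate: ambient/doublet contamination beyond simple
non-productive noise (no multiplet cells are generated), sequencing errors,
locus-dependent CDR3 length differences, correlation between clone size and
phenotype, and any biophysical V(D)J recombination model. Passing tests on
simulated data therefore validate the *computations* — classification,
counting, set algebra, test statistics — not the biological fidelity of any
upstream processing on real data.

`simulate_expression()` draws each gene as
`base + dual_shift · [cell is dual] + N(0, sigma)` clipped at zero — a
deliberately simple carrier for testing the join and the rank test (type-I
error on null genes, recovery of planted shifts), not a model of scRNA-seq
counts.

## Numerical choices and problem sizes

Validation uses three scales, chosen to keep the full suite under a minute
while leaving no statistic untested: exhaustive enumeration where the
domain is finite (all chain-count pairs 0–4 × 0–4); brute-force oracle
comparison at 1e-12 on 100 random repertoires of ≤ 50 cells for inverse
Simpson, expansion, Jaccard and chi-square; and seeded simulations at
n = 20 000 cells for parameter recovery (the realised dual proportion must
land in the 99% binomial interval of the configured rate, and estimates
must increase strictly across rates 0.05–0.30), with n = 5000 cells and 200
null + 5 planted two-fold genes for the marker test's error behaviour.
`scripts/acceptance.R` re-runs the same quantities from scratch against the
installed package.

## Limitations

* Chain identity at the CDR3-nucleotide level is the strictest reading;
  public datasets summarised at amino-acid level will merge convergent
  chains (use `clonotype_by = "cdr3aa"` to reproduce looser definitions).
  Whether published per-tissue percentages used filtered or unfiltered
  contig sets, or additionally required full-length contigs, is generally
  not stated; both switches exist, and reproduced numbers can shift by
  fractions of a percentage point between settings.
* Diversity values across strata of very different sizes should be
  compared only after rarefaction.
* The marker ranking is a rank-test stand-in suitable for log-normalised
  values; it is not a count-model differential-expression method.
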