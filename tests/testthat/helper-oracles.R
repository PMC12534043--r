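# Independent brute-force oracles: direct enumeration, no shared code with
# the implementation under test.

# Simpson's concentration by enumerating all ordered cell pairs: the
# probability two cells drawn with replacement share a clonotype.
oracle_inv_simpson <- function(sizes) {
  labels <- rep.int(seq_along(sizes), sizes)
  n <- length(labels)
  matches <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (labels[i] == labels[j]) matches <- matches + 1L
    }
  }
  n^2 / matches
}

# Cell-level expansion: walk every cell, count how many cells share its
# clonotype.
oracle_expansion <- function(sizes) {
  labels <- rep.int(seq_along(sizes), sizes)
  expanded <- vapply(labels, function(l) sum(labels == l) >= 2, logical(1))
  mean(expanded)
}

oracle_jaccard <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  both <- 0L
  any_of <- unique(c(a, b))
  for (s in any_of) {
    if (s %in% a && s %in% b) both <- both + 1L
  }
  if (length(any_of) == 0) return(NA_real_)
  both / length(any_of)
}

# Pearson chi-square by explicit expected counts.
oracle_chisq <- function(tab) {
  tab <- as.matrix(tab)
  total <- sum(tab)
  stat <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      e <- sum(tab[i, ]) * sum(tab[, j]) / total
      stat <- stat + (tab[i, j] - e)^2 / e
    }
  }
  stat
}

# 99% equal-tailed binomial acceptance interval for phat at given n, p.
binom_interval99 <- function(n, p) {
  c(qbinom(0.005, n, p), qbinom(0.995, n, p)) / n
}
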