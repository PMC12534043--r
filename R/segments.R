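# Built-in mouse TRA/TRB gene-segment vocabulary and a standard-code
# back-translation table. Segment names are family-level (allele suffixes
# such as "*01" are never part of the vocabulary); the lists cover the
# families commonly reported in mouse Treg repertoires so that realistic
# names (Trbv13-1, Trbv5, Trbv19, Trbj1-2, Trbj2-3, ...) appear in
# simulated data without any reference download.

MOUSE_TRAV <- c(
  "Trav1", "Trav2", "Trav3-3", "Trav4-3", "Trav5-4", "Trav6-3", "Trav7-2",
  "Trav8-1", "Trav9-4", "Trav10", "Trav12-1", "Trav13-2", "Trav14-1",
  "Trav16", "Trav19", "Trav21"
)

MOUSE_TRAJ <- c(
  "Traj2", "Traj5", "Traj9", "Traj12", "Traj15", "Traj21", "Traj23",
  "Traj26", "Traj27", "Traj31", "Traj33", "Traj37", "Traj40", "Traj42",
  "Traj45", "Traj49", "Traj52", "Traj56", "Traj58"
)

MOUSE_TRBV <- c(
  "Trbv1", "Trbv2", "Trbv3", "Trbv4", "Trbv5", "Trbv10", "Trbv12-1",
  "Trbv13-1", "Trbv13-2", "Trbv13-3", "Trbv14", "Trbv15", "Trbv16",
  "Trbv17", "Trbv19", "Trbv20", "Trbv23", "Trbv26", "Trbv29", "Trbv31"
)

MOUSE_TRBJ <- c(
  "Trbj1-1", "Trbj1-2", "Trbj1-3", "Trbj1-4", "Trbj1-5", "Trbj2-1",
  "Trbj2-2", "Trbj2-3", "Trbj2-4", "Trbj2-5", "Trbj2-7"
)

segment_vocab <- function(locus, field) {
  switch(
    paste(locus, field, sep = "."),
    TRA.v_gene = MOUSE_TRAV,
    TRA.j_gene = MOUSE_TRAJ,
    TRB.v_gene = MOUSE_TRBV,
    TRB.j_gene = MOUSE_TRBJ,
    abort(sprintf("no built-in vocabulary for locus '%s', field '%s'", locus, field))
  )
}

# Standard genetic code grouped by amino acid (stop codons excluded); used
# by the simulator to back-translate CDR3 amino-acid strings into in-frame,
# stop-free nucleotide junctions.
AA_CODONS <- list(
  A = c("GCT", "GCC", "GCA", "GCG"),
  C = c("TGT", "TGC"),
  D = c("GAT", "GAC"),
  E = c("GAA", "GAG"),
  F = c("TTT", "TTC"),
  G = c("GGT", "GGC", "GGA", "GGG"),
  H = c("CAT", "CAC"),
  I = c("ATT", "ATC", "ATA"),
  K = c("AAA", "AAG"),
  L = c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG"),
  M = "ATG",
  N = c("AAT", "AAC"),
  P = c("CCT", "CCC", "CCA", "CCG"),
  Q = c("CAA", "CAG"),
  R = c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG"),
  S = c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC"),
  T = c("ACT", "ACC", "ACA", "ACG"),
  V = c("GTT", "GTC", "GTA", "GTG"),
  W = "TGG",
  Y = c("TAT", "TAC")
)

AA_ALPHABET <- names(AA_CODONS)

# codon lookup matrix for vectorised back-translation: row = amino acid,
# column = synonymous codon slot
CODON_MAT <- {
  m <- matrix(NA_character_, nrow = length(AA_CODONS),
              ncol = max(lengths(AA_CODONS)),
              dimnames = list(names(AA_CODONS), NULL))
  for (a in names(AA_CODONS)) m[a, seq_along(AA_CODONS[[a]])] <- AA_CODONS[[a]]
  m
}

# Back-translate amino-acid strings, sampling synonymous codons uniformly.
backtranslate_aa <- function(aa) {
  if (length(aa) == 0) return(character(0))
  residues <- strsplit(aa, "")
  nres <- lengths(residues)
  flat <- unlist(residues, use.names = FALSE)
  idx <- match(flat, rownames(CODON_MAT))
  if (anyNA(idx)) {
    abort(sprintf("cannot back-translate residue '%s'", flat[which(is.na(idx))[1]]))
  }
  ncod <- lengths(AA_CODONS)[idx]
  pick <- floor(runif(length(flat)) * ncod) + 1L
  codons <- CODON_MAT[cbind(idx, pick)]
  grp <- factor(rep.int(seq_along(aa), nres), levels = seq_along(aa))
  unname(vapply(split(codons, grp), paste, character(1), collapse = ""))
}
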