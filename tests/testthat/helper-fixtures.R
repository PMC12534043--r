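# Compact builders for canonical contig rows and small repertoires.

contig_row <- function(barcode, locus, v = "Trbv5", j = "Trbj1-2",
                       nt = "TGTGCT", aa = "CA", productive = TRUE,
                       full_length = TRUE, umis = 3L, reads = 90L,
                       group = NULL) {
  row <- tibble::tibble(
    barcode = barcode, locus = locus, v_gene = v, d_gene = NA_character_,
    j_gene = j, cdr3_nt = nt, cdr3_aa = aa, productive = productive,
    full_length = full_length, umis = umis, reads = reads
  )
  if (!is.null(group)) row$group <- group
  row
}

# One paired cell: a TRA and a TRB chain with distinct junctions.
paired_cell <- function(barcode, group = "g1",
                        beta_v = "Trbv5", beta_j = "Trbj1-2",
                        beta_nt = paste0("TGT", barcode_tag(barcode), "TTT"),
                        beta_aa = NULL,
                        alpha_nt = paste0("TGC", barcode_tag(barcode), "TTC"),
                        alpha_aa = NULL) {
  dplyr::bind_rows(
    contig_row(barcode, "TRA", v = "Trav1", j = "Traj2", nt = alpha_nt,
               aa = alpha_aa %||% paste0("Ca_", barcode), group = group),
    contig_row(barcode, "TRB", v = beta_v, j = beta_j, nt = beta_nt,
               aa = beta_aa %||% paste0("Cb_", barcode), group = group)
  )
}

barcode_tag <- function(barcode) {
  toupper(gsub("[^ACGT]", "A", substr(barcode, 1, 6)))
}

`%||%` <- rlang::`%||%`

# A 10x-style CSV written from literal text lines (independent of
# write_contigs) for parser tests.
write_tenx_fixture <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}
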