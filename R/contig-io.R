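#' Read a per-contig scTCR-seq annotation table
#'
#' Reads a 10x Genomics `filtered_contig_annotations.csv`-style file or an
#' AIRR Rearrangement TSV and normalises it into the canonical contig tibble
#' used throughout the package: one row per assembled chain per cell barcode
#' with columns `barcode`, `locus` (`"TRA"`, `"TRB"` or `"other"`), `v_gene`,
#' `d_gene`, `j_gene`, `cdr3_nt`, `cdr3_aa`, `productive`, `full_length`,
#' `umis` and `reads`. Row order is preserved.
#'
#' Column mapping is fixed per dialect:
#'
#' * `tenx_csv`: `barcode`, `chain` -> `locus`, `v_gene`, `d_gene`, `j_gene`,
#'   `cdr3` -> `cdr3_aa`, `cdr3_nt`, `productive`, `full_length`, `umis`,
#'   `reads`.
#' * `airr_tsv`: `cell_id` -> `barcode`, `locus`, `v_call` -> `v_gene`,
#'   `d_call` -> `d_gene`, `j_call` -> `j_gene`, `junction` -> `cdr3_nt`,
#'   `junction_aa` -> `cdr3_aa`, `productive`, `duplicate_count` -> `umis`,
#'   `consensus_count` -> `reads`.
#'
#' Productivity vocabularies differ between dialects and are normalised
#' conservatively: only a literal `"True"`/`"TRUE"`/`"true"`/`"T"` (10x) or
#' `"T"`/`"TRUE"` (AIRR) maps to `TRUE`; `"None"`, `"False"`, `"F"` and
#' empty values all map to `FALSE`. Allele suffixes (`"*01"`) are stripped
#' from V and J calls so gene names are family-level.
#'
#' @param path Path to the contig file.
#' @param dialect `"tenx_csv"`, `"airr_tsv"`, or `"auto"` to detect from the
#'   header. Auto-detection errors if the header matches both dialects.
#' @param sample_id Optional sample label stored as the `sample_id`
#'   attribute; defaults to the file name without extension.
#'
#' @return A tibble of contig records (class `tcr_contigs`) with attributes
#'   `sample_id` and `dialect`.
#' @examples
#' path <- tempfile(fileext = ".csv")
#' sim <- simulate_repertoire(sim_config(n_cells = 50, groups = "spleen"))
#' write_contigs(sim$contigs, path, dialect = "tenx_csv")
#' contigs <- read_contigs(path)
#' dplyr::count(contigs, locus, productive)
#' @seealso [write_contigs()], [validate_contigs()], [classify_repertoire()]
#' @export
read_contigs <- function(path, dialect = c("auto", "tenx_csv", "airr_tsv"),
                         sample_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(sprintf("contig file does not exist: '%s'", path))
  }
  header_line <- readLines(path, n = 1L)
  delim_guess <- if (grepl("\t", header_line)) "\t" else ","
  header <- strsplit(header_line, delim_guess, fixed = TRUE)[[1]]
  header <- gsub("^\"|\"$", "", trimws(header))

  looks_tenx <- all(c("barcode", "chain") %in% header)
  looks_airr <- all(c("cell_id", "locus") %in% header)
  if (dialect == "auto") {
    if (looks_tenx && looks_airr) {
      abort("ambiguous header: matches both dialects 'tenx_csv' and 'airr_tsv'; pass `dialect` explicitly")
    }
    if (looks_tenx) dialect <- "tenx_csv"
    else if (looks_airr) dialect <- "airr_tsv"
    else abort("cannot detect dialect: header has neither 10x ('barcode','chain') nor AIRR ('cell_id','locus') columns")
  }

  spec <- contig_dialect_spec(dialect)
  missing <- setdiff(spec$required, header)
  if (length(missing) > 0) {
    abort(sprintf(
      "%s contig table is missing required column(s): %s",
      dialect, paste(missing, collapse = ", ")
    ))
  }

  raw <- readr::read_delim(
    path,
    delim = spec$delim,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    abort(sprintf("unreadable row %d in '%s': %s", prob$row[1], path, prob$expected[1]))
  }

  out <- canonicalise_contigs(raw, spec, path)
  attr(out, "sample_id") <- sample_id %||% sub("\\.[^.]*$", "", basename(path))
  attr(out, "dialect") <- dialect
  class(out) <- c("tcr_contigs", class(out))
  out
}

contig_dialect_spec <- function(dialect) {
  if (dialect == "tenx_csv") {
    list(
      delim = ",",
      required = c("barcode", "chain", "v_gene", "j_gene", "cdr3", "productive"),
      map = c(
        barcode = "barcode", locus = "chain", v_gene = "v_gene",
        d_gene = "d_gene", j_gene = "j_gene", cdr3_aa = "cdr3",
        cdr3_nt = "cdr3_nt", productive = "productive",
        full_length = "full_length", umis = "umis", reads = "reads"
      )
    )
  } else {
    list(
      delim = "\t",
      required = c("cell_id", "locus", "v_call", "j_call", "junction_aa", "productive"),
      map = c(
        barcode = "cell_id", locus = "locus", v_gene = "v_call",
        d_gene = "d_call", j_gene = "j_call", cdr3_aa = "junction_aa",
        cdr3_nt = "junction", productive = "productive",
        full_length = "complete_vdj", umis = "duplicate_count",
        reads = "consensus_count"
      )
    )
  }
}

canonicalise_contigs <- function(raw, spec, path) {
  get_col <- function(canon) {
    src <- spec$map[[canon]]
    if (!is.null(src) && src %in% names(raw)) raw[[src]] else rep(NA_character_, nrow(raw))
  }
  none_to_na <- function(x) {
    x <- trimws(x)
    x[x %in% c("", "None", "none", "NA")] <- NA_character_
    x
  }
  parse_int <- function(x, name) {
    x <- none_to_na(x)
    out <- suppressWarnings(as.integer(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad) > 0) {
      abort(sprintf("unreadable row %d in '%s': column '%s' value '%s' is not an integer",
                    bad[1], path, name, x[bad[1]]))
    }
    out[is.na(out)] <- 0L
    neg <- which(out < 0L)
    if (length(neg) > 0) {
      abort(sprintf("unreadable row %d in '%s': column '%s' is negative", neg[1], path, name))
    }
    out
  }

  barcode <- trimws(get_col("barcode"))
  if (anyNA(barcode) || any(barcode == "")) {
    abort(sprintf("unreadable row %d in '%s': empty barcode",
                  which(is.na(barcode) | barcode == "")[1], path))
  }
  locus_raw <- toupper(trimws(get_col("locus")))
  locus <- ifelse(locus_raw %in% c("TRA", "TRB"), locus_raw, "other")

  tibble(
    barcode = barcode,
    locus = locus,
    v_gene = strip_allele(none_to_na(get_col("v_gene"))),
    d_gene = strip_allele(none_to_na(get_col("d_gene"))),
    j_gene = strip_allele(none_to_na(get_col("j_gene"))),
    cdr3_nt = none_to_na(get_col("cdr3_nt")),
    cdr3_aa = none_to_na(get_col("cdr3_aa")),
    productive = parse_productive(get_col("productive")),
    full_length = parse_productive(get_col("full_length")),
    umis = parse_int(get_col("umis"), "umis"),
    reads = parse_int(get_col("reads"), "reads")
  )
}

# Conservative boolean vocabulary shared by both dialects: only an explicit
# true value is TRUE; "None", "False", "F", empty and missing are FALSE.
parse_productive <- function(x) {
  tolower(trimws(ifelse(is.na(x), "", x))) %in% c("true", "t")
}

strip_allele <- function(x) sub("\\*.*$", "", x)

#' Summarise productivity and locus composition of a contig table
#'
#' Partitions every contig record into one of four categories: productive
#' TRA, productive TRB, non-productive (alpha/beta locus but not productive),
#' and non-alpha/beta locus. This only reports composition; the exclusion of
#' cells from pairing happens in [classify_repertoire()].
#'
#' @param contigs A contig tibble from [read_contigs()] or
#'   [simulate_repertoire()].
#' @return A tibble with columns `category` and `n`; counts sum to
#'   `nrow(contigs)`.
#' @export
validate_contigs <- function(contigs) {
  if (nrow(contigs) == 0) {
    abort("contig table is empty: nothing to validate")
  }
  category <- dplyr::case_when(
    !contigs$locus %in% c("TRA", "TRB") ~ "non_ab_locus",
    !contigs$productive ~ "nonproductive",
    contigs$locus == "TRA" ~ "productive_tra",
    TRUE ~ "productive_trb"
  )
  cats <- c("productive_tra", "productive_trb", "nonproductive", "non_ab_locus")
  counts <- as.integer(table(factor(category, levels = cats)))
  tibble(category = cats, n = counts)
}

#' Write a contig tibble in 10x CSV or AIRR TSV dialect
#'
#' Serialises the canonical contig tibble back to either on-disk dialect so
#' simulated repertoires can round-trip through [read_contigs()]. Booleans
#' are written in each dialect's native vocabulary (10x `productive`:
#' `"True"`/`"None"`; AIRR: `"T"`/`"F"`), missing CDR3s as `"None"` (10x) or
#' empty (AIRR).
#'
#' @param contigs Canonical contig tibble.
#' @param path Output file path.
#' @param dialect `"tenx_csv"` or `"airr_tsv"`.
#' @return `path`, invisibly.
#' @export
write_contigs <- function(contigs, path, dialect = c("tenx_csv", "airr_tsv")) {
  dialect <- match.arg(dialect)
  na_none <- function(x) ifelse(is.na(x), "None", x)
  if (dialect == "tenx_csv") {
    out <- tibble(
      barcode = contigs$barcode,
      is_cell = "True",
      contig_id = paste0(contigs$barcode, "_contig_", seq_len(nrow(contigs))),
      chain = ifelse(contigs$locus == "other", "Multi", contigs$locus),
      v_gene = na_none(contigs$v_gene),
      d_gene = na_none(contigs$d_gene),
      j_gene = na_none(contigs$j_gene),
      cdr3 = na_none(contigs$cdr3_aa),
      cdr3_nt = na_none(contigs$cdr3_nt),
      productive = ifelse(contigs$productive, "True", "None"),
      full_length = ifelse(contigs$full_length, "True", "False"),
      umis = contigs$umis,
      reads = contigs$reads
    )
    readr::write_csv(out, path, progress = FALSE)
  } else {
    out <- tibble(
      cell_id = contigs$barcode,
      sequence_id = paste0(contigs$barcode, "_seq_", seq_len(nrow(contigs))),
      locus = ifelse(contigs$locus == "other", "TRG", contigs$locus),
      v_call = ifelse(is.na(contigs$v_gene), "", contigs$v_gene),
      d_call = ifelse(is.na(contigs$d_gene), "", contigs$d_gene),
      j_call = ifelse(is.na(contigs$j_gene), "", contigs$j_gene),
      junction = ifelse(is.na(contigs$cdr3_nt), "", contigs$cdr3_nt),
      junction_aa = ifelse(is.na(contigs$cdr3_aa), "", contigs$cdr3_aa),
      productive = ifelse(contigs$productive, "T", "F"),
      complete_vdj = ifelse(contigs$full_length, "T", "F"),
      duplicate_count = contigs$umis,
      consensus_count = contigs$reads
    )
    readr::write_tsv(out, path, progress = FALSE)
  }
  invisible(path)
}

#' Write a tabular result deterministically
#'
#' Writes any rectangular result as TSV or JSON with bit-stable output:
#' fixed column order (as given), doubles at 6 significant digits, LF line
#' endings. Writing the same table twice yields byte-identical files.
#'
#' @param rows A data frame.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  rows <- as.data.frame(rows)
  if (format == "tsv") {
    fmt <- lapply(rows, function(col) {
      if (is.double(col)) {
        out <- formatC(col, digits = 6, format = "g")
        out[is.na(col)] <- "NA"
        out
      } else {
        as.character(col)
      }
    })
    lines <- c(
      paste(names(rows), collapse = "\t"),
      if (nrow(rows) > 0) do.call(paste, c(fmt, sep = "\t"))
    )
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(lines, con, sep = "\n", useBytes = TRUE)
  } else {
    json <- jsonlite::toJSON(rows, dataframe = "rows", digits = 6, na = "null", pretty = TRUE)
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(json, con, sep = "\n", useBytes = TRUE)
  }
  invisible(path)
}
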