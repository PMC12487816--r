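# Readers and writers for the external tables the tool touches. All files are
# tab-separated with a header; the missing marker is the literal string "NA"
# (empty cells are also accepted on read, "NA" is emitted on write); missing
# values are never coerced to 0.

# Column dialects for DE result tables. Each maps external column names to the
# internal (gene_id, log_fc, p_value, adj_p, base_mean) schema.
de_dialects <- list(
  deseq2 = c(
    log_fc = "log2FoldChange",
    p_value = "pvalue",
    adj_p = "padj",
    base_mean = "baseMean"
  )
)

read_tsv_chr <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE, show_col_types = FALSE
  )
}

# Parse a character column to double, treating "NA" and "" as missing and
# raising on anything else non-numeric, with the offending row and column.
parse_numeric_col <- function(x, col) {
  x[x == "NA" | x == ""] <- NA_character_
  val <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(val))
  if (length(bad) > 0) {
    abort(sprintf(
      "unparseable numeric value %s in column '%s', data row %d",
      dQuote(x[bad[1]], q = FALSE), col, bad[1]
    ))
  }
  val
}

strip_gene_version <- function(ids) sub("\\.[0-9]+$", "", ids)

#' Read a differential-expression result table
#'
#' Reads a tab-separated DE result table in the DESeq2 column dialect
#' (`log2FoldChange`, `pvalue`, `padj`, optionally `baseMean`; the first
#' column holds the gene identifier) into the internal schema. `"NA"` and
#' empty cells become missing values; unknown extra columns are ignored.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param dialect Column dialect; only `"deseq2"` is currently defined.
#' @param strip_version If `TRUE`, a trailing `.N` version suffix is removed
#'   from gene identifiers (Ensembl-style versioned ids). Default `FALSE`.
#' @return A tibble with columns `gene_id`, `log_fc`, `p_value`, `adj_p`,
#'   `base_mean`; one row per gene, gene ids unique.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c(
#'   "gene\tbaseMean\tlog2FoldChange\tpvalue\tpadj",
#'   "g1\t100\t1.5\t0.001\t0.01",
#'   "g2\t5\t-0.2\t0.5\tNA"
#' ), tf)
#' read_de_table(tf)
read_de_table <- function(path, dialect = "deseq2", strip_version = FALSE) {
  dialect <- match.arg(dialect, names(de_dialects))
  map <- de_dialects[[dialect]]
  raw <- read_tsv_chr(path)
  required <- map[c("log_fc", "p_value", "adj_p")]
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("DE table %s lacks required column(s): %s",
                  path, paste(missing_cols, collapse = ", ")))
  }
  gene_id <- as.character(raw[[1]])
  if (strip_version) gene_id <- strip_gene_version(gene_id)
  if (anyDuplicated(gene_id)) {
    abort(sprintf("duplicate gene id in DE table: %s", gene_id[duplicated(gene_id)][1]))
  }
  out <- tibble::tibble(
    gene_id = gene_id,
    log_fc = parse_numeric_col(raw[[map[["log_fc"]]]], map[["log_fc"]]),
    p_value = parse_numeric_col(raw[[map[["p_value"]]]], map[["p_value"]]),
    adj_p = parse_numeric_col(raw[[map[["adj_p"]]]], map[["adj_p"]]),
    base_mean = if (map[["base_mean"]] %in% names(raw)) {
      parse_numeric_col(raw[[map[["base_mean"]]]], map[["base_mean"]])
    } else NA_real_
  )
  validate_de_table(out)
  out
}

validate_de_table <- function(de) {
  if (any(!is.finite(de$log_fc))) {
    abort(sprintf("non-finite log fold change for gene %s",
                  de$gene_id[which(!is.finite(de$log_fc))[1]]))
  }
  bad_p <- which(!is.na(de$p_value) & (de$p_value < 0 | de$p_value > 1))
  if (length(bad_p) > 0) {
    abort(sprintf("p-value outside [0,1] for gene %s", de$gene_id[bad_p[1]]))
  }
  bad_q <- which(!is.na(de$adj_p) & (de$adj_p < 0 | de$adj_p > 1))
  if (length(bad_q) > 0) {
    abort(sprintf("adjusted p-value outside [0,1] for gene %s", de$gene_id[bad_q[1]]))
  }
  invisible(de)
}

#' Write a differential-expression result table
#'
#' Inverse of [read_de_table()]: emits the DESeq2 column dialect with `"NA"`
#' as the missing marker, so a write/read round trip reproduces the table
#' exactly.
#'
#' @param de A DE tibble as returned by [read_de_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de, path) {
  out <- tibble::tibble(
    gene = de$gene_id,
    baseMean = de$base_mean,
    log2FoldChange = de$log_fc,
    pvalue = de$p_value,
    padj = de$adj_p
  )
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read a gene-by-tissue matrix
#'
#' Reads a tab-separated matrix whose header row names tissues and whose
#' first column holds gene identifiers. Missing cells (`"NA"` or empty) are
#' preserved as `NA`, never as zero. Value constraints depend on `kind`:
#' TPM expression values must be non-negative, V^G variance estimates must be
#' strictly positive, wherever present.
#'
#' @param path Path to the TSV file.
#' @param kind `"expression_tpm"` or `"vg"`.
#' @param strip_version If `TRUE`, trailing `.N` suffixes are removed from
#'   gene ids.
#' @return A tibble with a `gene_id` column followed by one numeric column
#'   per tissue.
#' @export
read_gene_tissue_matrix <- function(path, kind = c("expression_tpm", "vg"),
                                    strip_version = FALSE) {
  kind <- match.arg(kind)
  raw <- read_tsv_chr(path)
  if (ncol(raw) < 2) abort(sprintf("matrix %s has no tissue columns", path))
  gene_id <- as.character(raw[[1]])
  if (strip_version) gene_id <- strip_gene_version(gene_id)
  if (anyDuplicated(gene_id)) {
    abort(sprintf("duplicate gene id in matrix: %s", gene_id[duplicated(gene_id)][1]))
  }
  tissues <- names(raw)[-1]
  if (anyDuplicated(tissues)) {
    abort(sprintf("duplicate tissue id in matrix: %s", tissues[duplicated(tissues)][1]))
  }
  vals <- lapply(tissues, function(t) parse_numeric_col(raw[[t]], t))
  names(vals) <- tissues
  out <- dplyr::bind_cols(tibble::tibble(gene_id = gene_id), tibble::as_tibble(vals))
  validate_gene_tissue_matrix(out, kind)
  out
}

validate_gene_tissue_matrix <- function(x, kind) {
  m <- gt_to_matrix(x)
  if (kind == "expression_tpm") {
    bad <- which(!is.na(m) & m < 0, arr.ind = TRUE)
    if (nrow(bad) > 0) {
      abort(sprintf("negative TPM value at gene %s, tissue %s",
                    rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
    }
  } else if (kind == "vg") {
    bad <- which(!is.na(m) & m <= 0, arr.ind = TRUE)
    if (nrow(bad) > 0) {
      abort(sprintf("non-positive V^G value at gene %s, tissue %s",
                    rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
    }
  }
  invisible(x)
}

#' Write a gene-by-tissue matrix
#'
#' @param x A gene x tissue tibble (or matrix with dimnames).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_tissue_matrix <- function(x, path) {
  if (is.matrix(x)) x <- matrix_to_gt(x)
  readr::write_tsv(x, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes within a
#' line are deduplicated (first occurrence kept).
#'
#' @param path Path to a GMT file.
#' @return A tibble with columns `term_id`, `description`, and a list-column
#'   `genes` of character vectors; zero rows for an empty file.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble::tibble(term_id = character(), description = character(),
                          genes = list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields < 3)) {
    abort(sprintf("GMT line %d has fewer than 3 fields", which(n_fields < 3)[1]))
  }
  ids <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate set name in GMT: %s", ids[duplicated(ids)][1]))
  }
  tibble::tibble(
    term_id = ids,
    description = vapply(fields, `[[`, character(1), 2),
    genes = lapply(fields, function(f) unique(f[-(1:2)]))
  )
}

#' Write a GMT gene-set file
#'
#' @param terms A tibble as returned by [read_gmt()], or a named list of
#'   character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(terms, path) {
  terms <- as_term_tbl(terms)
  lines <- vapply(seq_len(nrow(terms)), function(i) {
    paste(c(terms$term_id[i], terms$description[i], terms$genes[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# Canonical term-collection form: tibble(term_id, description, genes).
as_term_tbl <- function(terms) {
  if (is.data.frame(terms)) {
    stopifnot(all(c("term_id", "genes") %in% names(terms)))
    if (!"description" %in% names(terms)) terms$description <- terms$term_id
    return(terms)
  }
  if (is.list(terms) && !is.null(names(terms))) {
    return(tibble::tibble(
      term_id = names(terms),
      description = names(terms),
      genes = lapply(terms, unique)
    ))
  }
  abort("`terms` must be a (term_id, description, genes) tibble or a named list of gene vectors")
}
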