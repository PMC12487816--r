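# Internal helpers shared across modules.

# Convert a gene x tissue tibble (gene_id column + one numeric column per
# tissue) to a double matrix with gene rownames. Matrices with dimnames pass
# through untouched, so internal code can stay matrix-based.
gt_to_matrix <- function(x, arg = "x") {
  if (is.matrix(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x))) {
      abort(sprintf("`%s` must have gene rownames and tissue colnames", arg))
    }
    storage.mode(x) <- "double"
    return(x)
  }
  if (!is.data.frame(x) || ncol(x) < 2) {
    abort(sprintf("`%s` must be a gene x tissue data frame (gene_id + >=1 tissue column)", arg))
  }
  genes <- as.character(x[[1]])
  if (anyDuplicated(genes)) {
    abort(sprintf("duplicate gene id in `%s`: %s", arg, genes[duplicated(genes)][1]))
  }
  m <- as.matrix(x[, -1, drop = FALSE])
  if (!is.numeric(m)) abort(sprintf("`%s` tissue columns must be numeric", arg))
  storage.mode(m) <- "double"
  rownames(m) <- genes
  m
}

matrix_to_gt <- function(m) {
  dplyr::bind_cols(
    tibble::tibble(gene_id = rownames(m)),
    tibble::as_tibble(m)
  )
}

# Accept a per-gene map given either as a named numeric vector or as a
# two-column data frame (gene_id, value); return a named numeric vector.
as_gene_map <- function(x, arg = "x") {
  if (is.data.frame(x)) {
    if (ncol(x) < 2) abort(sprintf("`%s` must have columns (gene_id, value)", arg))
    out <- as.numeric(x[[2]])
    names(out) <- as.character(x[[1]])
  } else if (is.numeric(x) && !is.null(names(x))) {
    out <- x
  } else {
    abort(sprintf("`%s` must be a named numeric vector or a (gene_id, value) data frame", arg))
  }
  if (anyDuplicated(names(out))) {
    abort(sprintf("duplicate gene id in `%s`: %s", arg, names(out)[duplicated(names(out))][1]))
  }
  out
}

# Ordering by descending absolute value, ties broken by ascending id: the
# single tie rule used for every ranking and selection in the package.
order_desc_abs <- function(value, id) order(-abs(value), id, method = "radix")

rank_desc_abs <- function(value, id) {
  r <- integer(length(value))
  r[order_desc_abs(value, id)] <- seq_along(value)
  r
}

# Round-half-up to the nearest 100 (722 -> 700, 750 -> 800).
round_to_nearest_100 <- function(x) floor(x / 100 + 0.5) * 100

# Row-wise cumulative sums of a logical/numeric matrix, preserving shape.
row_cumsum <- function(m) {
  if (ncol(m) == 1) return(m * 1)
  t(apply(m, 1, cumsum))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
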