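# Over-representation testing and the comparison machinery used to contrast
# enrichments of nominal versus recalibrated gene selections.

#' Hypergeometric over-representation analysis
#'
#' One-sided hypergeometric upper-tail test per term: the probability of
#' drawing at least the observed overlap when `selection_size` genes are
#' sampled without replacement from the universe. Term membership is
#' restricted to the universe before computing term sizes; terms with no
#' member in the universe are dropped. P-values are Benjamini-Hochberg
#' adjusted across the tested terms.
#'
#' @param selection Character vector of selected gene ids; must be a subset
#'   of `universe`.
#' @param universe Character vector of background gene ids (the analysis
#'   universe, e.g. all genes with expression and V^G estimates).
#' @param terms Gene-set collection: a `(term_id, description, genes)`
#'   tibble (see [read_gmt()]) or a named list of gene-id vectors.
#' @param alpha Adjusted-p threshold flagging a term as enriched
#'   (default 0.05).
#' @return A tibble with one row per tested term: `term_id`, `description`,
#'   `universe_size`, `term_size`, `selection_size`, `overlap`, `p`,
#'   `adj_p`, `enriched`; ordered by `p` then `term_id`.
#' @export
hypergeometric_ora <- function(selection, universe, terms, alpha = 0.05) {
  universe <- unique(universe)
  selection <- unique(selection)
  if (length(universe) == 0) abort("`universe` must be non-empty")
  if (length(selection) == 0) abort("`selection` must be non-empty")
  outside <- setdiff(selection, universe)
  if (length(outside) > 0) {
    abort(sprintf("selection gene not in universe: %s", outside[1]))
  }
  terms <- as_term_tbl(terms)
  members <- lapply(terms$genes, intersect, y = universe)
  keep <- lengths(members) > 0
  terms <- terms[keep, ]
  members <- members[keep]
  n_u <- length(universe)
  n_s <- length(selection)
  term_size <- unname(lengths(members))
  overlap <- unname(vapply(members, function(g) length(intersect(g, selection)), integer(1)))
  p <- phyper(overlap - 1, term_size, n_u - term_size, n_s, lower.tail = FALSE)
  out <- tibble::tibble(
    term_id = terms$term_id,
    description = terms$description,
    universe_size = n_u,
    term_size = term_size,
    selection_size = n_s,
    overlap = overlap,
    p = p,
    adj_p = p.adjust(p, method = "BH")
  )
  out$enriched <- out$adj_p <= alpha
  dplyr::arrange(out, .data$p, .data$term_id)
}

#' Compare term enrichments between two gene selections
#'
#' Runs [hypergeometric_ora()] on each selection against the same universe
#' and term collection, keeps the union of terms enriched in either, and
#' imputes an adjusted p-value of 1 (with a flag) on the side where a term
#' is not enriched. Swapping the two selections exactly swaps the two
#' p-value columns.
#'
#' @param sel_nominal,sel_recal Gene selections to compare (e.g. top genes
#'   by nominal and by recalibrated absolute fold change).
#' @inheritParams hypergeometric_ora
#' @return An `enrichment_comparison` tibble: `term_id`, `description`,
#'   `adj_p_nominal`, `adj_p_recal`, `imputed_nominal`, `imputed_recal`,
#'   `keyword_group` (`NA` until [assign_keyword_group()]).
#' @export
compare_selections <- function(sel_nominal, sel_recal, universe, terms,
                               alpha = 0.05) {
  ora_n <- hypergeometric_ora(sel_nominal, universe, terms, alpha = alpha)
  ora_r <- hypergeometric_ora(sel_recal, universe, terms, alpha = alpha)
  enr <- union(ora_n$term_id[ora_n$enriched], ora_r$term_id[ora_r$enriched])
  idx_n <- match(enr, ora_n$term_id)
  idx_r <- match(enr, ora_r$term_id)
  enriched_n <- !is.na(idx_n) & ora_n$enriched[idx_n]
  enriched_r <- !is.na(idx_r) & ora_r$enriched[idx_r]
  out <- tibble::tibble(
    term_id = enr,
    description = ifelse(!is.na(idx_n), ora_n$description[idx_n],
                         ora_r$description[idx_r]),
    adj_p_nominal = ifelse(enriched_n, ora_n$adj_p[idx_n], 1),
    adj_p_recal = ifelse(enriched_r, ora_r$adj_p[idx_r], 1),
    imputed_nominal = !enriched_n,
    imputed_recal = !enriched_r,
    keyword_group = NA_character_
  )
  out <- dplyr::arrange(out, .data$term_id)
  class(out) <- c("enrichment_comparison", class(out))
  out
}

#' Assign terms to keyword groups by name matching
#'
#' Each term is assigned to the first keyword (in the given order) whose
#' string is a case-insensitive substring of the term's name; terms matching
#' no keyword keep `NA`.
#'
#' @param comparison An `enrichment_comparison` tibble.
#' @param keywords Non-empty character vector of keywords, in priority order.
#' @return The comparison with `keyword_group` filled in.
#' @export
assign_keyword_group <- function(comparison, keywords) {
  if (length(keywords) == 0) abort("`keywords` must be non-empty")
  name_lc <- tolower(comparison$description)
  group <- rep(NA_character_, nrow(comparison))
  for (kw in rev(keywords)) {
    group[grepl(tolower(kw), name_lc, fixed = TRUE)] <- kw
  }
  comparison$keyword_group <- group
  comparison
}

#' Log-mean enrichment per keyword group
#'
#' Groups compared terms by keyword ([assign_keyword_group()]) and reports
#' the geometric mean of the adjusted p-values per group and side. Keywords
#' matched by no term are reported with `n_terms = 0` and missing means.
#'
#' @inheritParams assign_keyword_group
#' @return A tibble `(keyword, n_terms, logmean_nominal, logmean_recal)` in
#'   keyword order.
#' @export
keyword_group_logmean <- function(comparison, keywords) {
  cmp <- assign_keyword_group(comparison, keywords)
  purrr::map_dfr(keywords, function(kw) {
    rows <- cmp[!is.na(cmp$keyword_group) & cmp$keyword_group == kw, ]
    tibble::tibble(
      keyword = kw,
      n_terms = nrow(rows),
      logmean_nominal = if (nrow(rows) > 0) exp(mean(log(rows$adj_p_nominal))) else NA_real_,
      logmean_recal = if (nrow(rows) > 0) exp(mean(log(rows$adj_p_recal))) else NA_real_
    )
  })
}

#' Assign each gene its rarest functional label
#'
#' When several functional labels apply to a gene, the least frequent one is
#' kept (frequency ties broken by the lexicographically smaller label).
#' Genes with no label are omitted.
#'
#' @param gene_labels Long tibble `(gene_id, label)` with one row per
#'   gene-label pair, or a named list mapping gene id to a character vector
#'   of labels.
#' @param label_freq Label frequencies: named integer vector or
#'   `(label, freq)` data frame. Every label occurring in `gene_labels` must
#'   be covered. Default `NULL` counts label occurrences in `gene_labels`
#'   itself.
#' @return A tibble `(gene_id, label)` with one row per labelled gene.
#' @export
assign_rarest_label <- function(gene_labels, label_freq = NULL) {
  if (is.list(gene_labels) && !is.data.frame(gene_labels)) {
    gene_labels <- tibble::tibble(
      gene_id = rep(names(gene_labels), lengths(gene_labels)),
      label = unlist(gene_labels, use.names = FALSE)
    )
  }
  stopifnot(all(c("gene_id", "label") %in% names(gene_labels)))
  gene_labels <- dplyr::distinct(gene_labels, .data$gene_id, .data$label)
  if (nrow(gene_labels) == 0) {
    return(tibble::tibble(gene_id = character(), label = character()))
  }
  if (is.null(label_freq)) {
    label_freq <- table(gene_labels$label)
    label_freq <- setNames(as.integer(label_freq), names(label_freq))
  } else if (is.data.frame(label_freq)) {
    label_freq <- setNames(as.integer(label_freq[[2]]), as.character(label_freq[[1]]))
  }
  missing_lab <- setdiff(unique(gene_labels$label), names(label_freq))
  if (length(missing_lab) > 0) {
    abort(sprintf("label without a frequency: %s", missing_lab[1]))
  }
  gene_labels$freq <- unname(label_freq[gene_labels$label])
  out <- gene_labels |>
    dplyr::arrange(.data$gene_id, .data$freq, .data$label) |>
    dplyr::distinct(.data$gene_id, .keep_all = TRUE)
  tibble::tibble(gene_id = out$gene_id, label = out$label)
}

#' One-sided binomial test for focal-tissue over-representation
#'
#' Given per-gene lowest-V^G tissue assignments (see [lowest_vg_tissue()]),
#' tests whether the focal tissues (e.g. the 13 GTEx brain tissues plus
#' pituitary out of 50) are assigned more often than the null proportion
#' `|focal| / n_total_tissues`, with an upper-tail binomial test
#' `P[X >= k]`.
#'
#' @param assignments Tibble `(gene_id, tissue_id)` or named character
#'   vector mapping gene to assigned tissue.
#' @param focal_tissues Character vector of focal tissue ids (non-empty).
#' @param n_total_tissues Total number of tissues the assignment was drawn
#'   from; at least `length(focal_tissues)`.
#' @return A one-row tibble `(k, n, p0, p_value)`.
#' @export
binomial_lowest_tissue_test <- function(assignments, focal_tissues,
                                        n_total_tissues) {
  if (is.data.frame(assignments)) {
    stopifnot("tissue_id" %in% names(assignments))
    tiss <- assignments$tissue_id
  } else {
    tiss <- unname(assignments)
  }
  focal_tissues <- unique(focal_tissues)
  if (length(tiss) == 0) abort("`assignments` must be non-empty")
  if (length(focal_tissues) < 1 || n_total_tissues < length(focal_tissues)) {
    abort("need 1 <= |focal_tissues| <= n_total_tissues")
  }
  k <- sum(tiss %in% focal_tissues)
  n <- length(tiss)
  p0 <- length(focal_tissues) / n_total_tissues
  tibble::tibble(
    k = k, n = n, p0 = p0,
    p_value = pbinom(k - 1, n, p0, lower.tail = FALSE)
  )
}

#' Scatter plot of nominal versus recalibrated term enrichment
#'
#' Adjusted p-values on both sides on a -log10 scale, colored by keyword
#' group when assigned; the diagonal marks equal enrichment.
#'
#' @param object An `enrichment_comparison` tibble.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.enrichment_comparison <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$x <- -log10(df$adj_p_nominal)
  df$y <- -log10(df$adj_p_recal)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y))
  if (any(!is.na(df$keyword_group))) {
    p <- p + ggplot2::geom_point(ggplot2::aes(color = .data$keyword_group), alpha = 0.7)
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.7)
  }
  p +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = "-log10 adjusted p (nominal selection)",
      y = "-log10 adjusted p (recalibrated selection)",
      color = "keyword"
    ) +
    ggplot2::theme_minimal()
}
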