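# Fold-change recalibration: the nominal log fold change of each significant
# gene is divided by the standard deviation of its genetically regulated
# expression (sqrt of V^G), turning molecular fold changes into changes
# measured in units of natural population dosage variation.

#' Recalibrate differential-expression fold changes by genetic dosage variance
#'
#' For every gene that is significant at `fdr_cutoff` and has a V^G estimate,
#' computes the recalibrated fold change
#' \deqn{\bar{FC}_g = FC_g / \sqrt{V_g}}
#' where \eqn{FC_g} is the nominal log fold change and \eqn{V_g} the genetic
#' dosage variance of gene \eqn{g} (in squared log-fold-change units, on the
#' same log base as the fold changes). Genes without a V^G estimate are
#' excluded; genes with a missing adjusted p-value are treated as
#' non-significant. Both fold-change columns are ranked by descending
#' absolute value, ties broken by ascending gene id.
#'
#' @param de DE tibble with columns `gene_id`, `log_fc`, `adj_p` (as from
#'   [read_de_table()]).
#' @param vg Per-gene V^G map: a named numeric vector or a two-column
#'   data frame `(gene_id, vg)`. Values must be strictly positive.
#' @param fdr_cutoff Significance cutoff applied to `adj_p`, in `(0, 1]`.
#'   Default 0.05.
#' @return A `recal_tbl` tibble with columns `gene_id`, `nominal_fc`, `vg`,
#'   `recal_fc`, `rank_nominal`, `rank_recal`, ordered by `rank_recal`.
#' @export
#' @examples
#' de <- tibble::tibble(gene_id = c("a", "b"), log_fc = c(1, -0.5),
#'                      p_value = 1e-5, adj_p = 1e-4)
#' recalibrate(de, c(a = 0.04, b = 1), fdr_cutoff = 0.05)
recalibrate <- function(de, vg, fdr_cutoff = 0.05) {
  stopifnot(is.data.frame(de), all(c("gene_id", "log_fc", "adj_p") %in% names(de)))
  if (!is.numeric(fdr_cutoff) || length(fdr_cutoff) != 1 ||
      fdr_cutoff <= 0 || fdr_cutoff > 1) {
    abort("`fdr_cutoff` must be a single probability in (0, 1]")
  }
  vg <- as_gene_map(vg, "vg")
  bad <- which(is.na(vg) | vg <= 0)
  if (length(bad) > 0) {
    abort(sprintf("V^G values must be strictly positive (gene %s)", names(vg)[bad[1]]))
  }
  sig <- !is.na(de$adj_p) & de$adj_p < fdr_cutoff
  keep <- sig & de$gene_id %in% names(vg)
  if (!any(keep)) {
    abort("no gene is both significant at `fdr_cutoff` and covered by `vg`")
  }
  out <- tibble::tibble(
    gene_id = de$gene_id[keep],
    nominal_fc = de$log_fc[keep],
    vg = unname(vg[de$gene_id[keep]])
  )
  out$recal_fc <- out$nominal_fc / sqrt(out$vg)
  out$rank_nominal <- rank_desc_abs(out$nominal_fc, out$gene_id)
  out$rank_recal <- rank_desc_abs(out$recal_fc, out$gene_id)
  out <- dplyr::arrange(out, .data$rank_recal)
  class(out) <- c("recal_tbl", class(out))
  out
}

#' Select the top n genes by absolute fold change
#'
#' @param table A `recal_tbl` from [recalibrate()].
#' @param n Number of genes to select; must not exceed the table size.
#' @param by Ranking column: `"recal"` (default) or `"nominal"`.
#' @return Character vector of `n` gene ids in rank order (descending
#'   absolute value, ties broken by ascending gene id).
#' @export
select_top_n <- function(table, n, by = c("recal", "nominal")) {
  by <- match.arg(by)
  stopifnot(is.data.frame(table), nrow(table) > 0)
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n)) {
    abort("`n` must be a single positive integer")
  }
  if (n > nrow(table)) {
    abort(sprintf("`n` (%d) exceeds the table size (%d)", n, nrow(table)))
  }
  value <- if (by == "recal") table$recal_fc else table$nominal_fc
  table$gene_id[order_desc_abs(value, table$gene_id)][seq_len(n)]
}

#' Select the top ~50% of genes, rounded to the nearest 100
#'
#' Implements the selection rule used for enrichment comparisons: take
#' `N = round_to_nearest_100(0.5 * n)` genes of largest absolute fold change
#' (rounding half up, so 722 becomes 700 and 750 becomes 800), with `N`
#' floored at 100 and capped at the table size.
#'
#' @inheritParams select_top_n
#' @return Character vector of gene ids in rank order.
#' @export
select_top_half_rounded <- function(table, by = c("recal", "nominal")) {
  by <- match.arg(by)
  stopifnot(is.data.frame(table), nrow(table) > 0)
  n <- nrow(table)
  n_sel <- round_to_nearest_100(0.5 * n)
  n_sel <- max(100, n_sel)
  n_sel <- min(n_sel, n)
  select_top_n(table, n_sel, by = by)
}

#' Pearson correlation of absolute values
#'
#' Correlation between two signed quantities computed on their absolute
#' values, avoiding inflation caused by shared directionality (the sign of a
#' fold change is unchanged by recalibration).
#'
#' @param x,y Equal-length finite numeric vectors, length >= 3.
#' @return A one-row tibble `(estimate, ci_low, ci_high, method, n)`;
#'   confidence limits are `NA` (no resampling is performed).
#' @export
abs_pearson <- function(x, y) {
  check_paired_vectors(x, y)
  ax <- abs(x); ay <- abs(y)
  if (sd(ax) == 0 || sd(ay) == 0) {
    abort("correlation undefined: zero variance in |x| or |y|")
  }
  tibble::tibble(
    estimate = cor(ax, ay, method = "pearson"),
    ci_low = NA_real_, ci_high = NA_real_,
    method = "pearson_abs", n = length(x)
  )
}

#' Spearman correlation with a bootstrap percentile confidence interval
#'
#' Point estimate is the Spearman rank correlation; the confidence interval
#' is the percentile interval over `n_boot` paired resamples. Resamples in
#' which a vector becomes constant contribute no estimate and are dropped.
#'
#' @param x,y Equal-length numeric vectors, length >= 3, neither constant.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed making the interval reproducible; `NULL` uses the
#'   current RNG state.
#' @return A one-row tibble `(estimate, ci_low, ci_high, method, n)`.
#' @export
spearman_bootstrap_ci <- function(x, y, n_boot = 1000, level = 0.95, seed = NULL) {
  check_paired_vectors(x, y)
  if (sd(x) == 0 || sd(y) == 0) abort("correlation undefined: constant vector")
  est <- cor(x, y, method = "spearman")
  n <- length(x)
  boot_fun <- function() {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      suppressWarnings(cor(x[idx], y[idx], method = "spearman"))
    }, numeric(1))
  }
  boots <- if (is.null(seed)) boot_fun() else withr::with_seed(seed, boot_fun())
  boots <- boots[!is.na(boots)]
  qs <- quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  tibble::tibble(
    estimate = est, ci_low = qs[1], ci_high = qs[2],
    method = "spearman", n = n
  )
}

check_paired_vectors <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  if (length(x) < 3) abort("need at least 3 paired observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) abort("`x` and `y` must be finite")
  invisible(NULL)
}

#' Filter a gene list by expression level
#'
#' Retains genes whose TPM is at least `min_tpm` (default 1, the boundary is
#' kept). Genes absent from the TPM map are dropped.
#'
#' @param genes Character vector of gene ids (order preserved).
#' @param tpm Per-gene TPM map: named numeric vector or `(gene_id, tpm)`
#'   data frame.
#' @param min_tpm Minimum TPM to keep a gene. Default 1.
#' @return Filtered character vector.
#' @export
filter_by_tpm <- function(genes, tpm, min_tpm = 1) {
  tpm <- as_gene_map(tpm, "tpm")
  vals <- tpm[genes]
  genes[!is.na(vals) & vals >= min_tpm]
}

#' Compare a gene metric between two gene sets (Mann-Whitney U)
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test of the metric values of
#' two gene sets. The exact distribution is used when the combined size is at
#' most 20 and there are no ties; otherwise the normal approximation with tie
#' correction is used.
#'
#' @param values Per-gene metric: named numeric vector or `(gene_id, value)`
#'   data frame.
#' @param set_a,set_b Character vectors of gene ids; each must intersect the
#'   value map in at least one gene.
#' @return A one-row tibble `(statistic, p_value, n_a, n_b)`.
#' @export
compare_gene_sets_mwu <- function(values, set_a, set_b) {
  values <- as_gene_map(values, "values")
  a <- unname(values[intersect(unique(set_a), names(values))])
  b <- unname(values[intersect(unique(set_b), names(values))])
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) {
    abort("both gene sets must intersect the value map in at least one gene")
  }
  use_exact <- (length(a) + length(b)) <= 20 && !anyDuplicated(c(a, b))
  wt <- wilcox.test(a, b, alternative = "two.sided", exact = use_exact)
  tibble::tibble(
    statistic = unname(wt$statistic), p_value = wt$p.value,
    n_a = length(a), n_b = length(b)
  )
}

#' @export
print.recal_tbl <- function(x, ...) {
  cat(sprintf("# Recalibrated fold changes: %d genes\n", nrow(x)))
  NextMethod()
}

#' Scatter plot of nominal versus recalibrated fold changes
#'
#' @param object A `recal_tbl` from [recalibrate()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.recal_tbl <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$nominal_fc, y = .data$recal_fc)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(
      x = "nominal log fold change",
      y = "recalibrated log fold change (sd units of genetic dosage variation)"
    ) +
    ggplot2::theme_minimal()
}
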