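# Cross-tissue inference of genetic dosage variance. Tissue-specific V^G
# estimates are missing for many (gene, tissue) cells; the procedure imputes
# them from the tissues whose V^G profiles correlate best with the target
# tissue, after normalising measured estimates to each gene's mean expression
# level:
#   (1) add a pseudocount (smallest positive TPM) to expression;
#   (2) per tissue, OLS of log(expression) on log(V^G) giving (beta0, beta1);
#   (3) adjust measured V^G to mean expression:
#         v_hat[g,t] = V[g,t] * (mean_r E[g,r] / E[g,t])^beta1[t];
#   (4) tissue similarity = Spearman correlation of V^G over shared genes;
#   (5) per cell, up to k most-similar tissues (positive similarity, V
#       defined) form the neighbor set;
#   (6) v_dot[g,t] = similarity-weighted mean of neighbor v_hat values;
#   (7) v_tilde[g,t] = (E[g,t] / mean_r E[g,r])^beta1[t] * v_dot[g,t],
# and the combined matrix keeps measured values where they exist, inferred
# ones elsewhere. Natural logarithms are used throughout; beta1 and the
# adjustment factors are invariant to the common log base.

#' Add a pseudocount to an expression matrix
#'
#' Adds the smallest positive expression value observed anywhere in the
#' matrix to every present cell, so that logarithms are defined for
#' zero-expression cells. Missing cells stay missing; the pseudocount is
#' computed over present cells only.
#'
#' @param expr Gene x tissue expression tibble (or matrix with dimnames),
#'   TPM units, values >= 0 where present.
#' @return The shifted matrix, in the same form as the input.
#' @export
apply_pseudocount <- function(expr) {
  tib_in <- is.data.frame(expr)
  m <- gt_to_matrix(expr, "expr")
  pos <- m[!is.na(m) & m > 0]
  if (length(pos) == 0) abort("expression matrix has no positive entry")
  m <- m + min(pos)
  if (tib_in) matrix_to_gt(m) else m
}

#' Fit the per-tissue expression-variance model
#'
#' Ordinary least squares of `log(e_bar)` on `log(v)` over the genes present
#' in both maps: `log(E) = beta0 + beta1 * log(V) + eps`. Because lowly
#' expressed genes tend to have larger dosage variance, `beta1` is typically
#' negative.
#'
#' @param e_bar Per-gene pseudocounted expression: named numeric vector (or
#'   `(gene_id, value)` data frame), strictly positive.
#' @param v Per-gene V^G: named numeric vector (or data frame), strictly
#'   positive.
#' @param tissue_id Optional tissue label carried into the result.
#' @return A one-row tibble `(tissue_id, beta0, beta1, n_genes_fit)`.
#' @export
fit_expression_variance_model <- function(e_bar, v, tissue_id = NA_character_) {
  e_bar <- as_gene_map(e_bar, "e_bar")
  v <- as_gene_map(v, "v")
  shared <- intersect(names(e_bar)[!is.na(e_bar)], names(v)[!is.na(v)])
  if (length(shared) < 3) {
    abort(sprintf("need >= 3 genes with both expression and V^G (got %d)", length(shared)))
  }
  lv <- log(v[shared]); le <- log(e_bar[shared])
  if (sd(lv) == 0) abort("zero variance of log(V^G): slope undefined")
  fit <- lm(le ~ lv)
  tibble::tibble(
    tissue_id = tissue_id,
    beta0 = unname(coef(fit)[1]),
    beta1 = unname(coef(fit)[2]),
    n_genes_fit = length(shared)
  )
}

#' Fit the expression-variance model for every tissue
#'
#' @param vg Gene x tissue V^G tibble or matrix.
#' @param expr_bar Gene x tissue pseudocounted expression tibble or matrix
#'   (see [apply_pseudocount()]).
#' @return A tibble of per-tissue fits, one row per tissue.
#' @export
fit_tissue_models <- function(vg, expr_bar) {
  V <- gt_to_matrix(vg, "vg")
  Eb <- gt_to_matrix(expr_bar, "expr_bar")
  stopifnot(identical(rownames(V), rownames(Eb)), identical(colnames(V), colnames(Eb)))
  purrr::map_dfr(colnames(V), function(t) {
    fit_expression_variance_model(Eb[, t], V[, t], tissue_id = t)
  })
}

# Per-gene mean expression across tissues with a present value.
row_mean_expression <- function(Eb) rowMeans(Eb, na.rm = TRUE)

#' Adjust measured V^G estimates to mean expression level
#'
#' Rescales each measured estimate to the variance expected if the tissue's
#' expression equalled the gene's cross-tissue mean expression:
#' `v_hat[g,t] = V[g,t] * (mean_r E[g,r] / E[g,t])^beta1[t]`. The cross-tissue
#' mean is taken over tissues where expression is present for that gene.
#' Cells where V^G or expression is missing stay missing.
#'
#' @param vg Gene x tissue V^G tibble or matrix.
#' @param expr_bar Pseudocounted expression, same genes and tissues.
#' @param fits Per-tissue fits from [fit_tissue_models()].
#' @return Adjusted matrix in the same form as `vg`.
#' @export
adjust_to_mean_expression <- function(vg, expr_bar, fits) {
  tib_in <- is.data.frame(vg)
  V <- gt_to_matrix(vg, "vg")
  Eb <- gt_to_matrix(expr_bar, "expr_bar")
  stopifnot(identical(dimnames(V), dimnames(Eb)))
  beta1 <- setNames(fits$beta1, fits$tissue_id)
  if (!all(colnames(V) %in% names(beta1))) {
    abort("`fits` must cover every tissue in `vg`")
  }
  gm <- row_mean_expression(Eb)
  factor_mat <- sweep(gm / Eb, 2, beta1[colnames(V)], `^`)
  out <- V * factor_mat
  if (tib_in) matrix_to_gt(out) else out
}

#' Spearman similarity between tissue V^G profiles
#'
#' Pairwise Spearman correlation of V^G across genes, computed over the
#' pairwise-complete genes of each tissue pair. Pairs sharing fewer than
#' `min_shared` genes get a missing similarity (and are never used as
#' inference neighbors). The diagonal is 1.
#'
#' @param vg Gene x tissue V^G tibble or matrix with >= 2 tissues.
#' @param min_shared Minimum pairwise-complete genes (default 3).
#' @return A symmetric tissue x tissue matrix with dimnames.
#' @export
tissue_similarity <- function(vg, min_shared = 3) {
  V <- gt_to_matrix(vg, "vg")
  if (ncol(V) < 2) abort("need at least 2 tissues")
  rho <- suppressWarnings(
    cor(V, method = "spearman", use = "pairwise.complete.obs")
  )
  shared <- crossprod(!is.na(V))
  rho[shared < min_shared] <- NA_real_
  diag(rho) <- 1
  rho
}

#' Select the most similar tissues for one (gene, tissue) cell
#'
#' Returns up to `k` tissues other than `target`, ranked by descending
#' similarity to `target`, among tissues where the gene's V^G is defined and
#' the similarity is present and strictly positive. If fewer than `k`
#' qualify, all of them are returned; ties are broken by ascending tissue id.
#'
#' @param vg Gene x tissue V^G tibble or matrix (the neighbor-qualification
#'   matrix; in the full pipeline the adjusted estimates).
#' @param sim Similarity matrix from [tissue_similarity()].
#' @param gene Gene id.
#' @param target Target tissue id.
#' @param k Maximum number of neighbors (default 5).
#' @return Character vector of tissue ids, possibly empty.
#' @export
select_similar_tissues <- function(vg, sim, gene, target, k = 5) {
  V <- gt_to_matrix(vg, "vg")
  if (!target %in% colnames(V)) abort(sprintf("unknown tissue: %s", target))
  if (!gene %in% rownames(V)) abort(sprintf("unknown gene: %s", gene))
  cand <- setdiff(colnames(V), target)
  rho <- sim[target, cand]
  ok <- !is.na(rho) & rho > 0 & !is.na(V[gene, cand])
  cand <- cand[ok]
  rho <- rho[ok]
  cand[order(-rho, cand, method = "radix")][seq_len(min(k, length(cand)))]
}

#' Similarity-weighted mean of neighbor estimates
#'
#' `v_dot[g,t] = sum_s rho(t,s) * v_hat[g,s] / sum_s rho(t,s)` over the
#' neighbor tissues `s`. All weights must be strictly positive.
#'
#' @param vg_hat Adjusted V^G matrix ([adjust_to_mean_expression()]).
#' @param sim Similarity matrix.
#' @param gene Gene id.
#' @param target Target tissue id.
#' @param neighbors Non-empty character vector of neighbor tissue ids.
#' @return The weighted mean, a positive scalar.
#' @export
infer_weighted_mean <- function(vg_hat, sim, gene, target, neighbors) {
  if (length(neighbors) == 0) abort("`neighbors` must be non-empty")
  Vh <- gt_to_matrix(vg_hat, "vg_hat")
  w <- sim[target, neighbors]
  vals <- Vh[gene, neighbors]
  if (any(is.na(w)) || any(w <= 0)) abort("neighbor similarities must be > 0")
  if (any(is.na(vals))) abort("neighbor estimates must be defined")
  sum(w * vals) / sum(w)
}

#' Re-adjust an inferred estimate to the target tissue's expression
#'
#' The multiplicative inverse of the [adjust_to_mean_expression()] factor at
#' the target tissue:
#' `v_tilde[g,t] = (E[g,t] / mean_r E[g,r])^beta1[t] * v_dot[g,t]`.
#'
#' @param v_dot Unadjusted inferred estimate (positive scalar).
#' @param expr_bar Pseudocounted expression tibble or matrix.
#' @param fits Per-tissue fits from [fit_tissue_models()].
#' @param gene Gene id.
#' @param target Target tissue id.
#' @return The adjusted inferred estimate.
#' @export
readjust_to_tissue_expression <- function(v_dot, expr_bar, fits, gene, target) {
  Eb <- gt_to_matrix(expr_bar, "expr_bar")
  beta1 <- unname(setNames(fits$beta1, fits$tissue_id)[target])
  e <- Eb[gene, target]
  if (is.na(e)) abort(sprintf("expression missing for gene %s in tissue %s", gene, target))
  gm <- unname(row_mean_expression(Eb)[gene])
  (e / gm)^beta1 * v_dot
}

#' Infer tissue-specific V^G estimates for missing cells
#'
#' Runs the full inference pipeline (pseudocount, per-tissue fits,
#' expression adjustment, tissue similarity, neighbor selection, weighted
#' mean, re-adjustment) for every (gene, tissue) cell, and combines measured
#' with inferred estimates, measured values taking precedence. The
#' computation is deterministic.
#'
#' @param vg Gene x tissue V^G tibble or matrix (missing cells `NA`).
#' @param expr Gene x tissue raw TPM expression over the same genes and
#'   tissues.
#' @param k Maximum number of neighbor tissues per cell (default 5).
#' @return A `vg_inference` object: a list with tibbles `v_hat` (adjusted
#'   measured), `v_dot` (unadjusted inferred), `v_tilde` (inferred),
#'   `v_hi` (measured-with-inferred fallback), the per-tissue `fits`, the
#'   `similarity` matrix, a long `neighbors` tibble
#'   `(gene_id, tissue_id, neighbor_id, weight)`, and the inputs.
#' @export
infer_vg <- function(vg, expr, k = 5) {
  V <- gt_to_matrix(vg, "vg")
  E <- gt_to_matrix(expr, "expr")
  if (!setequal(rownames(V), rownames(E)) || !setequal(colnames(V), colnames(E))) {
    abort("`vg` and `expr` must share the same genes and tissues")
  }
  E <- E[rownames(V), colnames(V), drop = FALSE]
  if (ncol(V) < 2) abort("need at least 2 tissues")
  if (!is.numeric(k) || length(k) != 1 || k < 1) abort("`k` must be a positive integer")

  Eb <- apply_pseudocount(E)
  fits <- fit_tissue_models(V, Eb)
  beta1 <- setNames(fits$beta1, fits$tissue_id)
  gm <- row_mean_expression(Eb)
  Vhat <- adjust_to_mean_expression(V, Eb, fits)
  sim <- tissue_similarity(V)

  tissues <- colnames(V)
  Vdot <- matrix(NA_real_, nrow(V), ncol(V), dimnames = dimnames(V))
  nb_list <- vector("list", length(tissues))
  for (ti in seq_along(tissues)) {
    t <- tissues[ti]
    cand <- setdiff(tissues, t)
    rho <- sim[t, cand]
    ok <- !is.na(rho) & rho > 0
    cand <- cand[ok]; rho <- rho[ok]
    if (length(cand) == 0) next
    ord <- order(-rho, cand, method = "radix")
    cand <- cand[ord]; rho <- rho[ord]
    M <- Vhat[, cand, drop = FALSE]
    D <- !is.na(M)
    # rank of each defined candidate within its row, in similarity order
    incl <- D & (row_cumsum(D) <= k)
    W <- sweep(incl * 1, 2, rho, `*`)
    M0 <- M; M0[!incl] <- 0
    den <- rowSums(W)
    num <- rowSums(W * M0)
    Vdot[, ti] <- ifelse(den > 0, num / den, NA_real_)
    sel <- which(incl, arr.ind = TRUE)
    if (nrow(sel) > 0) {
      nb_list[[ti]] <- tibble::tibble(
        gene_id = rownames(M)[sel[, 1]],
        tissue_id = t,
        neighbor_id = cand[sel[, 2]],
        weight = rho[sel[, 2]]
      )
    }
  }
  neighbors <- dplyr::bind_rows(nb_list)
  if (nrow(neighbors) > 0) {
    neighbors <- dplyr::arrange(neighbors, .data$gene_id, .data$tissue_id,
                                dplyr::desc(.data$weight), .data$neighbor_id)
  }

  back_factor <- sweep(Eb / gm, 2, beta1[tissues], `^`)
  Vtilde <- Vdot * back_factor  # NA wherever expression is missing
  Vhi <- ifelse(!is.na(V), V, Vtilde)

  structure(
    list(
      v_hat = matrix_to_gt(Vhat),
      v_dot = matrix_to_gt(Vdot),
      v_tilde = matrix_to_gt(Vtilde),
      v_hi = matrix_to_gt(Vhi),
      fits = fits,
      similarity = sim,
      neighbors = neighbors,
      vg = matrix_to_gt(V),
      expr_bar = matrix_to_gt(Eb),
      k = k
    ),
    class = "vg_inference"
  )
}

#' @export
print.vg_inference <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "V^G inference: %d genes x %d tissues; %d measured cells, %d inferred (k = %d)\n",
    g$n_genes, g$n_tissues, g$n_measured, g$n_inferred, x$k
  ))
  invisible(x)
}

#' Tidy the result of V^G inference into a long tibble
#'
#' @param x A `vg_inference` object.
#' @param ... Ignored.
#' @return A tibble with one row per (gene, tissue) cell and columns `v`
#'   (measured), `v_hat`, `v_dot`, `v_tilde`, `v_hi`, and `source`
#'   (`"measured"`, `"inferred"`, or `NA` where no estimate exists).
#' @export
tidy.vg_inference <- function(x, ...) {
  long <- function(tb, name) {
    tidyr::pivot_longer(tb, -"gene_id", names_to = "tissue_id", values_to = name)
  }
  out <- long(x$vg, "v")
  out$v_hat <- long(x$v_hat, "z")$z
  out$v_dot <- long(x$v_dot, "z")$z
  out$v_tilde <- long(x$v_tilde, "z")$z
  out$v_hi <- long(x$v_hi, "z")$z
  out$source <- dplyr::case_when(
    !is.na(out$v) ~ "measured",
    !is.na(out$v_tilde) ~ "inferred",
    TRUE ~ NA_character_
  )
  out
}

#' One-row summary of a V^G inference
#'
#' @param x A `vg_inference` object.
#' @param ... Ignored.
#' @return A one-row tibble with cell counts and coverage.
#' @export
glance.vg_inference <- function(x, ...) {
  V <- gt_to_matrix(x$vg)
  Vhi <- gt_to_matrix(x$v_hi)
  tibble::tibble(
    n_genes = nrow(V),
    n_tissues = ncol(V),
    n_measured = sum(!is.na(V)),
    n_inferred = sum(is.na(V) & !is.na(Vhi)),
    coverage = mean(!is.na(Vhi)),
    k = x$k
  )
}

#' Heatmap of the tissue similarity used for inference
#'
#' @param object A `vg_inference` object.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.vg_inference <- function(object, ...) {
  sim <- object$similarity
  df <- tibble::as_tibble(sim, rownames = "tissue_a")
  df <- tidyr::pivot_longer(df, -"tissue_a", names_to = "tissue_b", values_to = "rho")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tissue_a, y = .data$tissue_b,
                                   fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman rho") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Weighted harmonic mean of V^G across tissues
#'
#' Aggregates tissue-specific V^G estimates into a single per-gene value as
#' a weighted harmonic mean, `sum_t w[g,t] / sum_t (w[g,t] / V[g,t])`,
#' with per-tissue expression (TPM) as the canonical weight. The sum runs
#' over tissues where both the estimate and the weight are present; genes
#' with no tissue carrying a positive weight are omitted.
#'
#' @param vg Gene x tissue V^G tibble or matrix.
#' @param weights Gene x tissue non-negative weights over the same genes and
#'   tissues (typically the TPM expression matrix).
#' @return A tibble `(gene_id, vg)` covering every gene with a defined mean.
#' @export
weighted_harmonic_mean_vg <- function(vg, weights) {
  V <- gt_to_matrix(vg, "vg")
  W <- gt_to_matrix(weights, "weights")
  if (!setequal(rownames(V), rownames(W)) || !setequal(colnames(V), colnames(W))) {
    abort("`vg` and `weights` must share the same genes and tissues")
  }
  W <- W[rownames(V), colnames(V), drop = FALSE]
  if (any(W < 0, na.rm = TRUE)) abort("weights must be non-negative")
  use <- !is.na(V) & !is.na(W)
  Wu <- ifelse(use, W, 0)
  num <- rowSums(Wu)
  den <- rowSums(ifelse(use, Wu / V, 0))
  ok <- den > 0
  tibble::tibble(gene_id = rownames(V)[ok], vg = unname(num[ok] / den[ok]))
}

#' Tissue with the lowest V^G per gene
#'
#' @param vg Gene x tissue V^G tibble or matrix (typically the combined
#'   measured-plus-inferred matrix).
#' @param genes Genes to report; default all genes with at least one defined
#'   value. Requesting a gene with no defined value is an error.
#' @return A tibble `(gene_id, tissue_id, vg)`; ties broken by ascending
#'   tissue id.
#' @export
lowest_vg_tissue <- function(vg, genes = NULL) {
  V <- gt_to_matrix(vg, "vg")
  any_def <- rownames(V)[rowSums(!is.na(V)) > 0]
  if (is.null(genes)) {
    genes <- any_def
  } else {
    unknown <- setdiff(genes, rownames(V))
    if (length(unknown) > 0) abort(sprintf("unknown gene: %s", unknown[1]))
    empty <- setdiff(genes, any_def)
    if (length(empty) > 0) {
      abort(sprintf("gene %s has no defined V^G in any tissue", empty[1]))
    }
  }
  tissues <- colnames(V)
  picks <- vapply(genes, function(g) {
    vals <- V[g, ]
    ok <- which(!is.na(vals))
    ok[order(vals[ok], tissues[ok], method = "radix")][1]
  }, integer(1))
  tibble::tibble(
    gene_id = genes,
    tissue_id = tissues[picks],
    vg = V[cbind(match(genes, rownames(V)), picks)]
  )
}
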