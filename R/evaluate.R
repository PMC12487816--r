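# Held-out recovery evaluation: how well does cross-tissue inference
# reconstruct masked V^G cells, compared with simply copying the value from
# the single most-similar tissue?

#' Evaluate inference recovery on held-out cells
#'
#' For every held-out cell of a masked synthetic study, compares the
#' inferred estimate with the true value (Spearman correlation), and
#' likewise for a naive baseline that copies the V^G value of the single
#' most-similar tissue (positive similarity, value observed) for each cell.
#'
#' @param truth A `vg_sim` with a `held_out` tibble (see
#'   [mask_additional()]).
#' @param inference A `vg_inference` fitted on `truth$vg_observed` (see
#'   [infer_vg()]); if `NULL`, it is computed here with `k` neighbors.
#' @param k Neighbor count if the inference is computed here (default 5).
#' @return A one-row tibble: `spearman_inferred`, `n_inferred`,
#'   `spearman_baseline`, `n_baseline`.
#' @export
evaluate_recovery <- function(truth, inference = NULL, k = 5) {
  stopifnot(inherits(truth, "vg_sim"))
  if (is.null(truth$held_out) || nrow(truth$held_out) == 0) {
    abort("`truth` has no held-out cells; call mask_additional() first")
  }
  if (is.null(inference)) {
    inference <- infer_vg(truth$vg_observed, truth$expression, k = k)
  }
  Vtilde <- gt_to_matrix(inference$v_tilde)
  Vobs <- gt_to_matrix(truth$vg_observed)
  sim <- inference$similarity
  held <- truth$held_out
  ij <- cbind(match(held$gene_id, rownames(Vtilde)),
              match(held$tissue_id, colnames(Vtilde)))
  inferred <- Vtilde[ij]

  baseline <- vapply(seq_len(nrow(held)), function(i) {
    g <- ij[i, 1]; t <- ij[i, 2]
    rho <- sim[t, ]
    ok <- !is.na(rho) & rho > 0 & !is.na(Vobs[g, ]) & seq_along(rho) != t
    if (!any(ok)) return(NA_real_)
    cand <- which(ok)
    best <- cand[order(-rho[cand], colnames(Vobs)[cand], method = "radix")][1]
    Vobs[g, best]
  }, numeric(1))

  ok_inf <- !is.na(inferred)
  ok_base <- !is.na(baseline)
  tibble::tibble(
    spearman_inferred = cor(inferred[ok_inf], held$vg_true[ok_inf],
                            method = "spearman"),
    n_inferred = sum(ok_inf),
    spearman_baseline = cor(baseline[ok_base], held$vg_true[ok_base],
                            method = "spearman"),
    n_baseline = sum(ok_base)
  )
}
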