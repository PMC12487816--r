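# Small in-code fixtures shared across test files.

make_de <- function(gene_id, log_fc, adj_p = rep(0.01, length(gene_id)),
                    p_value = adj_p / 2, base_mean = NA_real_) {
  tibble::tibble(gene_id = gene_id, log_fc = log_fc, p_value = p_value,
                 adj_p = adj_p, base_mean = base_mean)
}

# gene x tissue tibble from a matrix-like specification
make_gt <- function(values, genes = NULL, tissues = NULL) {
  m <- as.matrix(values)
  rownames(m) <- genes %||% sprintf("g%02d", seq_len(nrow(m)))
  colnames(m) <- tissues %||% sprintf("t%02d", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(gene_id = rownames(m)), tibble::as_tibble(m))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

matrix_to_tib <- function(m) {
  dplyr::bind_cols(tibble::tibble(gene_id = rownames(m)), tibble::as_tibble(m))
}

gt_mat <- function(x) {
  m <- as.matrix(x[, -1])
  rownames(m) <- x$gene_id
  storage.mode(m) <- "double"
  m
}

write_tsv_lines <- function(lines) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(lines, tf)
  tf
}

# Textbook Pearson correlation from sums, independent of stats::cor.
pearson_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# Spearman as rank-transform-then-Pearson.
spearman_oracle <- function(x, y) pearson_oracle(rank(x), rank(y))

# Independent straight-line re-implementation of the inference pipeline,
# used as the oracle: per-cell direct evaluation with normal-equation fits
# and rank-transform Spearman, sharing no code with the package internals.
oracle_infer <- function(V, E, k = 5) {
  G <- nrow(V); Tn <- ncol(V)
  tissues <- colnames(V)
  Eb <- E + min(E[!is.na(E) & E > 0])
  beta <- matrix(NA_real_, Tn, 2)
  for (t in seq_len(Tn)) {
    ok <- !is.na(V[, t]) & !is.na(Eb[, t])
    X <- cbind(1, log(V[ok, t]))
    y <- log(Eb[ok, t])
    beta[t, ] <- solve(t(X) %*% X, t(X) %*% y)
  }
  gm <- apply(Eb, 1, function(r) mean(r[!is.na(r)]))
  Vhat <- matrix(NA_real_, G, Tn, dimnames = dimnames(V))
  for (g in seq_len(G)) for (t in seq_len(Tn)) {
    if (!is.na(V[g, t]) && !is.na(Eb[g, t])) {
      Vhat[g, t] <- V[g, t] * (gm[g] / Eb[g, t])^beta[t, 2]
    }
  }
  sim <- matrix(NA_real_, Tn, Tn, dimnames = list(tissues, tissues))
  for (t1 in seq_len(Tn)) for (t2 in seq_len(Tn)) {
    both <- !is.na(V[, t1]) & !is.na(V[, t2])
    if (sum(both) >= 3) {
      sim[t1, t2] <- pearson_oracle(rank(V[both, t1]), rank(V[both, t2]))
    }
  }
  diag(sim) <- 1
  Vdot <- matrix(NA_real_, G, Tn, dimnames = dimnames(V))
  Vtilde <- Vdot
  for (g in seq_len(G)) for (t in seq_len(Tn)) {
    cand <- setdiff(seq_len(Tn), t)
    cand <- cand[!is.na(sim[t, cand]) & sim[t, cand] > 0 & !is.na(Vhat[g, cand])]
    if (length(cand) == 0) next
    ord <- order(-sim[t, cand], tissues[cand], method = "radix")
    nb <- cand[ord][seq_len(min(k, length(cand)))]
    w <- sim[t, nb]
    Vdot[g, t] <- sum(w * Vhat[g, nb]) / sum(w)
    if (!is.na(Eb[g, t])) {
      Vtilde[g, t] <- (Eb[g, t] / gm[g])^beta[t, 2] * Vdot[g, t]
    }
  }
  list(v_hat = Vhat, v_dot = Vdot, v_tilde = Vtilde,
       v_hi = ifelse(!is.na(V), V, Vtilde), sim = sim, beta = beta)
}
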