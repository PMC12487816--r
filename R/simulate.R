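# Synthetic data with the statistical structure the method assumes: a
# gene x tissue V^G matrix and an expression matrix linked by a per-tissue
# log-log linear relationship, correlated tissue blocks,
# missing-not-at-random V^G cells concentrated in lowly expressed genes, and
# a DE table whose fold changes correlate positively with V^G, with
# designated low-variance "driver" and high-variance "responder" gene sets.

#' Configuration for the synthetic study generator
#'
#' Defaults define the reference simulation used throughout the test suite:
#' 2000 genes x 10 tissues, lognormal V^G centred on 0.01 (squared
#' log-fold-change units), two correlated tissue blocks, an expression model
#' `log E = 2 - 0.5 log V + noise` (lowly expressed genes are more
#' variable), 20% missing V^G cells concentrated (2x) in the bottom
#' expression quartile, 5% driver and 15% responder genes.
#'
#' @param seed Integer seed; the single source of randomness.
#' @param n_genes,n_tissues Matrix dimensions (both >= 2).
#' @param log_vg_mean,log_vg_sd Mean and sd of the per-gene baseline of
#'   log V^G (natural log).
#' @param tissue_block_count Number of tissue blocks sharing gene-level
#'   effects (induces positive inter-tissue correlation, higher within
#'   blocks).
#' @param tissue_effect_sd Sd of the gene-by-block effects on log V^G.
#' @param cell_noise_sd Sd of independent cell-level noise on log V^G.
#' @param beta0,beta1 Intercept and slope of the expression model
#'   `log E = beta0 + beta1 log V + eps`.
#' @param expr_noise_sd Sd of `eps` in the expression model.
#' @param missing_rate Expected overall fraction of masked V^G cells.
#' @param low_expr_missing_boost Multiplier on the masking probability for
#'   cells in the bottom expression quartile (masking rates are renormalised
#'   so the expected overall fraction stays `missing_rate`).
#' @param frac_drivers Fraction of genes designated drivers (low V^G, small
#'   but consistent fold changes).
#' @param frac_responders Fraction designated responders (high V^G, fold
#'   changes proportional to sqrt(V^G)).
#' @param fc_scale Scale factor on responder fold changes.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000L,
                       n_tissues = 10L,
                       log_vg_mean = log(0.01),
                       log_vg_sd = 1.0,
                       tissue_block_count = 2L,
                       tissue_effect_sd = 0.3,
                       cell_noise_sd = 0.3,
                       beta0 = 2.0,
                       beta1 = -0.5,
                       expr_noise_sd = 0.3,
                       missing_rate = 0.2,
                       low_expr_missing_boost = 2.0,
                       frac_drivers = 0.05,
                       frac_responders = 0.15,
                       fc_scale = 1.0) {
  cfg <- list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    n_tissues = as.integer(n_tissues), log_vg_mean = log_vg_mean,
    log_vg_sd = log_vg_sd, tissue_block_count = as.integer(tissue_block_count),
    tissue_effect_sd = tissue_effect_sd, cell_noise_sd = cell_noise_sd,
    beta0 = beta0, beta1 = beta1, expr_noise_sd = expr_noise_sd,
    missing_rate = missing_rate,
    low_expr_missing_boost = low_expr_missing_boost,
    frac_drivers = frac_drivers, frac_responders = frac_responders,
    fc_scale = fc_scale
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) abort(sprintf("invalid sim_config: %s", msg))
  chk(cfg$n_genes >= 2, "n_genes must be >= 2")
  chk(cfg$n_tissues >= 2, "n_tissues must be >= 2")
  chk(cfg$tissue_block_count >= 1 && cfg$tissue_block_count <= cfg$n_tissues,
      "tissue_block_count must be in [1, n_tissues]")
  for (f in c("log_vg_sd", "tissue_effect_sd", "cell_noise_sd",
              "expr_noise_sd")) {
    chk(cfg[[f]] >= 0, sprintf("%s must be >= 0", f))
  }
  chk(cfg$missing_rate >= 0 && cfg$missing_rate <= 1,
      "missing_rate must be in [0,1]")
  chk(cfg$low_expr_missing_boost >= 0, "low_expr_missing_boost must be >= 0")
  chk(cfg$frac_drivers >= 0 && cfg$frac_drivers <= 0.25,
      "frac_drivers must be in [0, 0.25]")
  chk(cfg$frac_responders >= 0 && cfg$frac_responders <= 0.25,
      "frac_responders must be in [0, 0.25]")
  chk(cfg$fc_scale > 0, "fc_scale must be > 0")
  invisible(cfg)
}

#' Generate a synthetic V^G / expression / DE study
#'
#' Draws, in a deterministic order fixed by `config$seed` (genes outer,
#' tissues inner):
#' `log V[g,t] = base_g + blockeffect_{g,block(t)} + cellnoise_{g,t}` with
#' `base_g ~ N(log_vg_mean, log_vg_sd)`;
#' `log E[g,t] = beta0 + beta1 * log V[g,t] + eps_{g,t}`;
#' a missing-not-at-random mask whose per-cell probability is boosted for
#' the bottom expression quartile and renormalised to an expected overall
#' fraction of `missing_rate`; and a DE table in which drivers (drawn from
#' the bottom quartile of gene-level V^G) get `|log_fc| ~ |N(0.3, 0.1)|`,
#' responders (top quartile) get `|log_fc| = fc_scale * sqrt(vg_g) *
#' |N(1, 0.3)|`, and null genes `log_fc ~ N(0, 0.05)`. Adjusted p-values are
#' assigned, not computed: below 0.001 for drivers/responders, uniform on
#' (0.1, 1) for null genes. The gene-level `vg_g` is the expression-weighted
#' harmonic mean of the true tissue values.
#'
#' @param config A [sim_config()].
#' @return A `vg_sim` list: tibbles `vg_true` (complete), `vg_observed`
#'   (masked), `expression` (TPM), `de`, `labels`
#'   (`gene_id`, `label`, `gene_vg`), and the `config`.
#' @export
simulate_vg_study <- function(config = sim_config()) {
  validate_sim_config(config)
  withr::with_seed(config$seed, simulate_vg_study_impl(config))
}

simulate_vg_study_impl <- function(cfg) {
  G <- cfg$n_genes; Tn <- cfg$n_tissues; B <- cfg$tissue_block_count
  genes <- sprintf("g%05d", seq_len(G))
  tissues <- sprintf("t%02d", seq_len(Tn))
  block <- sort(rep_len(seq_len(B), Tn))

  base <- rnorm(G, cfg$log_vg_mean, cfg$log_vg_sd)
  block_eff <- matrix(rnorm(G * B, 0, cfg$tissue_effect_sd), G, B, byrow = TRUE)
  cell_noise <- matrix(rnorm(G * Tn, 0, cfg$cell_noise_sd), G, Tn, byrow = TRUE)
  log_v <- base + block_eff[, block, drop = FALSE] + cell_noise
  V <- exp(log_v)
  dimnames(V) <- list(genes, tissues)

  expr_noise <- matrix(rnorm(G * Tn, 0, cfg$expr_noise_sd), G, Tn, byrow = TRUE)
  E <- exp(cfg$beta0 + cfg$beta1 * log_v + expr_noise)
  dimnames(E) <- list(genes, tissues)

  # Missing-not-at-random mask: bottom expression quartile masked `boost`
  # times more often, base rate renormalised so the expectation stays at
  # missing_rate.
  low <- E < quantile(E, 0.25)
  base_rate <- cfg$missing_rate / (0.75 + 0.25 * cfg$low_expr_missing_boost)
  rate <- ifelse(low, pmin(1, base_rate * cfg$low_expr_missing_boost),
                 pmin(1, base_rate))
  u <- matrix(runif(G * Tn), G, Tn, byrow = TRUE)
  Vobs <- V
  Vobs[u < rate] <- NA_real_

  # Gene-level V^G: expression-weighted harmonic mean of the true values.
  gene_vg <- rowSums(E) / rowSums(E / V)

  n_drv <- round(cfg$frac_drivers * G)
  n_rsp <- round(cfg$frac_responders * G)
  q25 <- quantile(gene_vg, 0.25)
  q75 <- quantile(gene_vg, 0.75)
  drivers <- sample(which(gene_vg <= q25), n_drv)
  responders <- sample(setdiff(which(gene_vg >= q75), drivers), n_rsp)
  label <- rep("null", G)
  label[drivers] <- "driver"
  label[responders] <- "responder"

  log_fc <- numeric(G)
  log_fc[drivers] <- sample(c(-1, 1), n_drv, replace = TRUE) *
    abs(rnorm(n_drv, 0.3, 0.1))
  log_fc[responders] <- sample(c(-1, 1), n_rsp, replace = TRUE) *
    cfg$fc_scale * sqrt(gene_vg[responders]) * abs(rnorm(n_rsp, 1, 0.3))
  nulls <- which(label == "null")
  log_fc[nulls] <- rnorm(length(nulls), 0, 0.05)

  adj_p <- numeric(G)
  adj_p[c(drivers, responders)] <- runif(n_drv + n_rsp, 0, 0.001)
  adj_p[nulls] <- runif(length(nulls), 0.1, 1)

  de <- tibble::tibble(
    gene_id = genes,
    log_fc = log_fc,
    p_value = adj_p / 2,
    adj_p = adj_p,
    base_mean = rowMeans(E)
  )

  structure(
    list(
      vg_true = matrix_to_gt(V),
      vg_observed = matrix_to_gt(Vobs),
      expression = matrix_to_gt(E),
      de = de,
      labels = tibble::tibble(gene_id = genes, label = label, gene_vg = gene_vg),
      config = cfg
    ),
    class = "vg_sim"
  )
}

#' @export
print.vg_sim <- function(x, ...) {
  V <- gt_to_matrix(x$vg_observed)
  cat(sprintf(
    "Synthetic V^G study: %d genes x %d tissues; %.1f%% of V^G cells missing; %d drivers, %d responders\n",
    nrow(V), ncol(V), 100 * mean(is.na(V)),
    sum(x$labels$label == "driver"), sum(x$labels$label == "responder")
  ))
  invisible(x)
}

#' Mask additional observed V^G cells for held-out evaluation
#'
#' Masks the given fraction of currently observed cells of `vg_observed`
#' uniformly at random (the true values stay available in `vg_true` for
#' scoring) and records them in a `held_out` tibble.
#'
#' @param truth A `vg_sim` object.
#' @param fraction Fraction of currently observed cells to mask, in (0, 1).
#' @param seed Integer seed for the mask.
#' @return The modified `vg_sim` with an added/extended `held_out` tibble
#'   `(gene_id, tissue_id, vg_true)`.
#' @export
mask_additional <- function(truth, fraction, seed) {
  stopifnot(inherits(truth, "vg_sim"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    abort("`fraction` must be in (0, 1)")
  }
  Vobs <- gt_to_matrix(truth$vg_observed)
  Vtrue <- gt_to_matrix(truth$vg_true)
  obs <- which(!is.na(Vobs))
  if (length(obs) == 0) abort("no observed cell left to mask")
  n_new <- max(1L, round(fraction * length(obs)))
  idx <- withr::with_seed(seed, sample(obs, n_new))
  Vobs[idx] <- NA_real_
  held <- tibble::tibble(
    gene_id = rownames(Vobs)[(idx - 1) %% nrow(Vobs) + 1],
    tissue_id = colnames(Vobs)[(idx - 1) %/% nrow(Vobs) + 1],
    vg_true = Vtrue[idx]
  )
  truth$vg_observed <- matrix_to_gt(Vobs)
  truth$held_out <- dplyr::bind_rows(truth$held_out, held)
  truth
}
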