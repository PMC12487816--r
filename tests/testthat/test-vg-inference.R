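test_that("pseudocount is the smallest positive entry; missing cells stay missing", {
  e <- make_gt(rbind(c(0, 2), c(5, 1)))
  out <- apply_pseudocount(e)
  expect_equal(gt_mat(out), gt_mat(make_gt(rbind(c(1, 3), c(6, 2)))))

  e2 <- make_gt(rbind(c(0.5, 2), c(NA, 1)))
  out2 <- gt_mat(apply_pseudocount(e2))
  expect_equal(out2[1, 1], 1.0)
  expect_true(is.na(out2[2, 1]))

  expect_error(apply_pseudocount(make_gt(rbind(c(0, 0)))), "no positive")
})

test_that("the expression-variance fit recovers exact and degenerate slopes", {
  v <- c(g1 = 0.01, g2 = 0.04, g3 = 0.16)
  e <- setNames(exp(2 + 0.5 * log(v)), names(v))
  fit <- fit_expression_variance_model(e, v)
  expect_equal(fit$beta0, 2, tolerance = 1e-10)
  expect_equal(fit$beta1, 0.5, tolerance = 1e-10)
  expect_equal(fit$n_genes_fit, 3L)

  const <- setNames(rep(7.5, 3), names(v))
  fit0 <- fit_expression_variance_model(const, v)
  expect_equal(fit0$beta1, 0, tolerance = 1e-12)
  expect_equal(fit0$beta0, log(7.5), tolerance = 1e-12)

  expect_error(fit_expression_variance_model(e[1:2], v[1:2]), ">= 3")
  expect_error(fit_expression_variance_model(e, setNames(rep(0.01, 3), names(v))),
               "zero variance")
})

test_that("the fit equals an independent normal-equation solution on noisy data", {
  set.seed(3)
  n <- 50
  v <- setNames(rlnorm(n, log(0.01), 1), sprintf("g%02d", 1:n))
  e <- setNames(exp(2 - 0.5 * log(v) + rnorm(n, 0, 0.3)), names(v))
  fit <- fit_expression_variance_model(e, v)
  X <- cbind(1, log(v))
  beta <- solve(t(X) %*% X, t(X) %*% log(e))
  expect_equal(fit$beta0, beta[1], tolerance = 1e-10)
  expect_equal(fit$beta1, beta[2], tolerance = 1e-10)
})

test_that("adjustment to mean expression applies the fitted power factor", {
  # single gene, two tissues: E = (2, 8), mean 5 -> ratio mean/E = 2.5, 0.625
  e <- make_gt(rbind(c(2, 8)))
  v <- make_gt(rbind(c(0.02, 0.02)))
  fits <- tibble::tibble(tissue_id = c("t01", "t02"), beta0 = 0,
                         beta1 = c(0.5, -1), n_genes_fit = 3L)
  out <- gt_mat(adjust_to_mean_expression(v, e, fits))
  expect_equal(out[1, 1], 0.02 * 2.5^0.5)
  expect_equal(out[1, 2], 0.02 * 0.625^-1)
  # expression equal to the cross-tissue mean leaves V unchanged
  e_flat <- make_gt(rbind(c(4, 4)))
  out2 <- gt_mat(adjust_to_mean_expression(v, e_flat, fits))
  expect_equal(out2[1, ], c(t01 = 0.02, t02 = 0.02))
})

test_that("tissue similarity is Spearman over pairwise-complete genes", {
  m <- make_gt(cbind(c(1, 2, 3, 4), c(2, 4, 6, 8), c(4, 3, 2, 1)))
  sim <- tissue_similarity(m)
  expect_equal(sim["t01", "t02"], 1)
  expect_equal(sim["t01", "t03"], -1)
  expect_equal(diag(sim), c(t01 = 1, t02 = 1, t03 = 1))
  expect_equal(sim, t(sim))

  set.seed(8)
  r <- make_gt(cbind(rlnorm(10), rlnorm(10)))
  sim_r <- tissue_similarity(r)
  expect_equal(sim_r["t01", "t02"],
               spearman_oracle(gt_mat(r)[, 1], gt_mat(r)[, 2]),
               tolerance = 1e-12)

  # fewer than 3 shared genes -> missing similarity
  sparse <- make_gt(cbind(c(1, 2, 4, NA), c(NA, NA, 1, 2), c(1, 2, 3, 4)))
  sim_s <- tissue_similarity(sparse)
  expect_true(is.na(sim_s["t01", "t02"]))
  expect_false(is.na(sim_s["t01", "t03"]))
})

test_that("neighbor selection honors availability, positivity, k, and ties", {
  set.seed(9)
  base <- rnorm(8, log(0.01), 1)
  V <- exp(base + matrix(rnorm(64, 0, 0.3), 8, 8))  # positively correlated tissues
  dimnames(V) <- list(sprintf("g%02d", 1:8), sprintf("t%02d", 1:8))
  sim <- tissue_similarity(V)
  stopifnot(all(sim > 0))
  # gene defined in only 3 other tissues -> those 3
  V2 <- V
  V2["g01", c("t03", "t04", "t05", "t06")] <- NA
  nb <- select_similar_tissues(V2, sim, "g01", "t01", k = 5)
  expect_setequal(nb, c("t02", "t07", "t08"))
  # full availability: top-5 matches exhaustive sort
  nb5 <- select_similar_tissues(V, sim, "g01", "t01", k = 5)
  rho <- sim["t01", setdiff(colnames(V), "t01")]
  expected <- names(sort(rho, decreasing = TRUE))[1:5]
  expect_equal(nb5, expected)
  # equal similarity at the cut -> lexicographically smaller tissue kept
  sim_tie <- sim
  sim_tie["t01", ] <- c(1, rep(0.5, 7))
  sim_tie[, "t01"] <- c(1, rep(0.5, 7))
  nb_tie <- select_similar_tissues(V, sim_tie, "g01", "t01", k = 3)
  expect_equal(nb_tie, c("t02", "t03", "t04"))
  # negative similarities never qualify
  sim_neg <- sim_tie
  sim_neg["t01", -1] <- -0.5
  expect_length(select_similar_tissues(V, sim_neg, "g01", "t01"), 0)
})

test_that("the similarity-weighted mean interpolates neighbor estimates", {
  Vh <- matrix(c(0.03, 0.01, 0.03, 0.01, 0.06), 1,
               dimnames = list("g", sprintf("t%d", 1:5)))
  sim <- matrix(1, 6, 6, dimnames = list(c("t0", colnames(Vh)), c("t0", colnames(Vh))))
  expect_equal(infer_weighted_mean(Vh, sim, "g", "t0", "t1"), 0.03)
  expect_equal(infer_weighted_mean(Vh, sim, "g", "t0", c("t2", "t3")), 0.02)
  sim["t0", c("t4", "t5")] <- c(0.8, 0.2)
  expect_equal(infer_weighted_mean(Vh, sim, "g", "t0", c("t4", "t5")), 0.02)
  expect_error(infer_weighted_mean(Vh, sim, "g", "t0", character()), "non-empty")
})

test_that("re-adjustment inverts the mean-expression adjustment", {
  e <- make_gt(rbind(c(2, 8)))
  fits <- tibble::tibble(tissue_id = c("t01", "t02"), beta0 = 0,
                         beta1 = c(0.5, 0.5), n_genes_fit = 3L)
  # E/mean = 8/5 at t02; ratio 4 example: mean 5 -> build directly
  e4 <- make_gt(rbind(c(1, 4)))  # means 2.5; t02 ratio = 1.6
  expect_equal(readjust_to_tissue_expression(0.02, make_gt(rbind(c(4, 4))),
                                             fits, "g01", "t01"), 0.02)
  # composing adjust then readjust at the same tissue returns the input
  v <- make_gt(rbind(c(0.02, 0.05)))
  vhat <- adjust_to_mean_expression(v, e, fits)
  back <- readjust_to_tissue_expression(gt_mat(vhat)[1, 2], e, fits, "g01", "t02")
  expect_equal(back, 0.05, tolerance = 1e-12)
})

test_that("full inference equals the per-cell oracle on a synthetic instance", {
  truth <- simulate_vg_study(sim_config(seed = 42, n_genes = 200, n_tissues = 6))
  V <- gt_mat(truth$vg_observed)
  E <- gt_mat(truth$expression)
  res <- infer_vg(truth$vg_observed, truth$expression, k = 5)
  orc <- oracle_infer(V, E, k = 5)
  expect_equal(gt_mat(res$v_hat), orc$v_hat, tolerance = 1e-10)
  expect_equal(gt_mat(res$v_dot), orc$v_dot, tolerance = 1e-10)
  expect_equal(gt_mat(res$v_tilde), orc$v_tilde, tolerance = 1e-10)
  expect_equal(gt_mat(res$v_hi), orc$v_hi, tolerance = 1e-10)
  expect_equal(res$similarity, orc$sim, tolerance = 1e-10)
})

test_that("measured values take precedence in the combined matrix", {
  truth <- simulate_vg_study(sim_config(seed = 7, n_genes = 100, n_tissues = 5))
  res <- infer_vg(truth$vg_observed, truth$expression)
  V <- gt_mat(truth$vg_observed)
  Vhi <- gt_mat(res$v_hi)
  meas <- !is.na(V)
  expect_identical(Vhi[meas], V[meas])
  Vtilde <- gt_mat(res$v_tilde)
  expect_true(all(Vtilde[!is.na(Vtilde)] > 0))
})

test_that("constant-expression genes reduce to the rho-weighted mean of raw values", {
  set.seed(13)
  G <- 30
  base <- rnorm(G, log(0.01), 1)
  V <- exp(base + matrix(rnorm(G * 4, 0, 0.3), G, 4))  # correlated tissues
  dimnames(V) <- list(sprintf("g%02d", 1:G), sprintf("t%02d", 1:4))
  E <- matrix(rep(exp(2 - 0.5 * base), 4), G, 4, dimnames = dimnames(V))
  V[1, 1] <- NA  # cell to infer
  res <- infer_vg(matrix_to_tib(V), matrix_to_tib(E), k = 5)
  sim <- res$similarity
  nb <- setdiff(colnames(V), "t01")
  w <- sim["t01", nb]
  keep <- !is.na(w) & w > 0
  expected <- sum(w[keep] * V[1, nb[keep]]) / sum(w[keep])
  expect_equal(gt_mat(res$v_tilde)[1, 1], expected, tolerance = 1e-12)
})

test_that("inference is deterministic and inference values stay in neighbor hulls", {
  truth <- simulate_vg_study(sim_config(seed = 5, n_genes = 150, n_tissues = 6))
  r1 <- infer_vg(truth$vg_observed, truth$expression)
  r2 <- infer_vg(truth$vg_observed, truth$expression)
  expect_identical(r1$v_tilde, r2$v_tilde)
  # v_dot within [min, max] of neighbor v_hat values
  Vdot <- gt_mat(r1$v_dot)
  Vhat <- gt_mat(r1$v_hat)
  nbs <- r1$neighbors
  for (i in sample(nrow(nbs), 50)) {
    g <- nbs$gene_id[i]; t <- nbs$tissue_id[i]
    nb <- nbs$neighbor_id[nbs$gene_id == g & nbs$tissue_id == t]
    expect_gte(Vdot[g, t], min(Vhat[g, nb]) - 1e-12)
    expect_lte(Vdot[g, t], max(Vhat[g, nb]) + 1e-12)
  }
})

test_that("weighted harmonic mean matches hand arithmetic and its bounds", {
  v <- make_gt(rbind(c(0.01, 0.02)))
  expect_equal(weighted_harmonic_mean_vg(v, make_gt(rbind(c(1, 1))))$vg, 2 / 150)
  expect_equal(weighted_harmonic_mean_vg(v, make_gt(rbind(c(3, 1))))$vg, 4 / 350)
  same <- make_gt(rbind(c(0.05, 0.05, 0.05)))
  expect_equal(weighted_harmonic_mean_vg(same, make_gt(rbind(c(1, 2, 3))))$vg, 0.05)

  set.seed(17)
  V <- make_gt(matrix(rlnorm(40, log(0.01), 1), 10, 4))
  W <- make_gt(matrix(runif(40, 0, 100), 10, 4))
  hm <- weighted_harmonic_mean_vg(V, W)
  Vm <- gt_mat(V)
  expect_true(all(hm$vg >= apply(Vm, 1, min) - 1e-12))
  expect_true(all(hm$vg <= apply(Vm, 1, max) + 1e-12))

  # gene with all-zero weights is omitted
  W0 <- gt_mat(W); W0[1, ] <- 0
  hm0 <- weighted_harmonic_mean_vg(V, matrix_to_tib(W0))
  expect_false(rownames(Vm)[1] %in% hm0$gene_id)
})

test_that("lowest-V^G tissue assignment breaks ties lexicographically", {
  v <- make_gt(rbind(c(0.01, 0.02), c(0.01, 0.01), c(NA, 0.03)))
  out <- lowest_vg_tissue(v)
  expect_equal(out$tissue_id, c("t01", "t01", "t02"))
  expect_equal(out$vg, c(0.01, 0.01, 0.03))
  v_missing <- make_gt(rbind(c(NA, NA), c(1, 2)))
  expect_error(lowest_vg_tissue(v_missing, genes = "g01"), "no defined")
})

test_that("tidy and glance summarise an inference", {
  truth <- simulate_vg_study(sim_config(seed = 6, n_genes = 50, n_tissues = 4))
  res <- infer_vg(truth$vg_observed, truth$expression)
  td <- tidy(res)
  expect_equal(nrow(td), 200)
  expect_setequal(unique(td$source[!is.na(td$source)]), c("measured", "inferred"))
  gl <- glance(res)
  expect_equal(gl$n_measured + gl$n_inferred, sum(!is.na(td$v_hi)))
  expect_s3_class(autoplot(res), "ggplot")
})
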