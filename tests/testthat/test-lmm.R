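test_that("GLS reduces to OLS under scalar covariance and matches the textbook formula", {
  # V = I, intercept only: the GLS estimate is the sample mean
  fit <- gls_fit(c(1, 2, 3), matrix(1, 3, 1), diag(3))
  expect_equal(unname(fit$coefficients), 2)

  # scale invariance of the point estimate: V = cI gives the same beta
  set.seed(4)
  X <- cbind(1, rnorm(8))
  y <- rnorm(8)
  b1 <- gls_fit(y, X, diag(8))$coefficients
  b2 <- gls_fit(y, X, 7.3 * diag(8))$coefficients
  expect_equal(b1, b2, tolerance = 1e-12)

  # random SPD V vs explicit-inverse textbook computation
  set.seed(5)
  X6 <- cbind(1, rnorm(6))
  y6 <- rnorm(6)
  A <- matrix(rnorm(36), 6)
  V <- crossprod(A) + diag(6)
  fit6 <- gls_fit(y6, X6, V)
  Vinv <- solve(V)
  beta_naive <- solve(t(X6) %*% Vinv %*% X6, t(X6) %*% Vinv %*% y6)
  expect_lt(max(abs(fit6$coefficients - drop(beta_naive))), 1e-10)
  expect_lt(max(abs(fit6$vcov - solve(t(X6) %*% Vinv %*% X6))), 1e-10)

  # singular covariance raises a structured linear-algebra error
  expect_error(gls_fit(y6, X6, matrix(1, 6, 6)),
               class = "famlmm_linalg_error")
})

test_that("spectral restricted likelihood equals the dense likelihood", {
  set.seed(21)
  ped <- random_pedigree(seed = 8)
  K <- kinship_from_pedigree(ped)
  n <- nrow(K)
  X <- cbind(1, rnorm(n))
  y <- rnorm(n)
  lambdas <- exp(runif(20, -4, 4))
  for (lam in lambdas) {
    spectral <- restricted_loglik(y, X, K, sigma2_mu = lam * 0.7,
                                  sigma2_eps = 0.7)
    dense <- dense_restricted_loglik(y, X, K, lam * 0.7, 0.7)
    expect_lt(abs(spectral - as.numeric(dense)), 1e-8)
  }
})

test_that("REML agrees with an independent dense-likelihood optimizer", {
  set.seed(31)
  K <- exchangeable_family_matrix(40, 5, 0.5)  # n = 200
  L <- famlmm:::kinship_sqrt(K)
  n <- 200
  X <- cbind(1, rnorm(n))
  y <- drop(X %*% c(1, 0.5)) + sqrt(2) * drop(L %*% rnorm(n)) + rnorm(n)
  est <- reml_variance_components(y, X, K)
  oracle <- dense_reml_oracle(y, X, K)
  expect_equal(est$sigma2_mu, oracle$sigma2_mu, tolerance = 1e-3)
  expect_equal(est$sigma2_eps, oracle$sigma2_eps, tolerance = 1e-3)
  spectral_ll <- restricted_loglik(y, X, K, est$sigma2_mu, est$sigma2_eps)
  expect_gte(spectral_ll, oracle$loglik - 1e-6)
})

test_that("REML degenerate inputs follow the documented contracts", {
  K <- exchangeable_family_matrix(10, 3, 0.5)
  n <- 30
  # constant response: both components zero
  vc0 <- reml_variance_components(rep(2, n), matrix(1, n, 1), K)
  expect_equal(vc0$sigma2_mu, 0)
  expect_equal(vc0$sigma2_eps, 0)
  expect_true(vc0$converged)

  # K = I: ratio unidentifiable, documented boundary tie-break
  set.seed(6)
  y <- rnorm(n)
  X <- matrix(1, n, 1)
  vci <- reml_variance_components(y, X, kinship_matrix(diag(n),
                                                       validate = FALSE))
  expect_true(vci$boundary)
  expect_equal(vci$sigma2_mu, 0)
  expect_equal(vci$sigma2_eps, sum(stats::lm.fit(X, y)$residuals^2) / (n - 1))

  # rank-deficient design
  expect_error(reml_variance_components(y, cbind(1, 1), K),
               class = "famlmm_rank_error")
})

test_that("moment (Haseman-Elston) variance components behave as documented", {
  # independent data: the family component shrinks to zero on average
  # (n large enough that the O(1/n) residual-centering bias is inside the
  # Monte-Carlo band)
  K <- exchangeable_family_matrix(200, 5, 0.5)
  n <- 1000
  X <- matrix(1, n, 1)
  set.seed(41)
  ests <- replicate(100,
                    anova_variance_components(rnorm(n), X, K)$sigma2_mu_raw)
  se <- stats::sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests)), 3 * se + 1e-12)
  # the reported (clamped) component is never negative
  expect_gte(min(replicate(5,
    anova_variance_components(rnorm(n), X, K)$sigma2_mu)), 0)

  # family-structured data with unequal sibship sizes: near-truth on
  # average, wider spread than REML across replicates
  set.seed(42)
  sizes <- sample(c(2, 3, 5, 8), 60, replace = TRUE)
  nu <- sum(sizes)
  fam <- rep(paste0("G", seq_along(sizes)), sizes)
  Ku <- matrix(0, nu, nu)
  pos <- 0
  for (s in sizes) {
    idx <- pos + seq_len(s)
    Ku[idx, idx] <- 0.5 + 0.5 * diag(s)
    pos <- pos + s
  }
  Ku <- kinship_matrix(Ku, ids = paste0(fam, "_", unlist(lapply(sizes, seq_len))),
                       family = fam, validate = FALSE)
  L <- famlmm:::kinship_sqrt(Ku)
  eig <- famlmm:::kin_eigen(Ku)
  Xu <- matrix(1, nu, 1)
  both <- replicate(60, {
    y <- sqrt(2) * drop(L %*% rnorm(nu)) + rnorm(nu)
    c(mom = anova_variance_components(y, Xu, Ku)$sigma2_mu,
      reml = reml_variance_components(y, Xu, Ku, eig = eig)$sigma2_mu)
  })
  se_mom <- stats::sd(both["mom", ]) / sqrt(ncol(both))
  expect_lt(abs(mean(both["mom", ]) - 2), 3 * se_mom)
  expect_gte(stats::sd(both["mom", ]), stats::sd(both["reml", ]))

  # constant response and degenerate kinship contracts
  expect_equal(anova_variance_components(rep(1, n), X, K)$sigma2_mu, 0)
  expect_error(
    anova_variance_components(rnorm(10), matrix(1, 10, 1),
                              kinship_matrix(diag(10), validate = FALSE)),
    class = "famlmm_degenerate_error")
})

test_that("the kinship option collapses to independence when K = I", {
  set.seed(51)
  n <- 60
  ids <- sprintf("F%02d_%d", rep(1:12, each = 5), rep(1:5, 12))
  fam <- rep(sprintf("F%02d", 1:12), each = 5)
  Ki <- kinship_matrix(diag(n), ids = ids, family = fam, validate = FALSE)
  y <- rnorm(n)
  X <- matrix(1, n, 1, dimnames = list(ids, "(Intercept)"))
  p_kin <- fit_marker(y, X, covariance_spec("kinship", Ki))$p_value
  p_ind <- fit_marker(y, X, covariance_spec("independence", Ki))$p_value
  expect_lt(abs(p_kin - p_ind), 1e-8)
})

test_that("fit_marker output satisfies the association-result invariants", {
  set.seed(52)
  K <- exchangeable_family_matrix(20, 5, 0.5)
  fam <- attr(K, "family")
  ids <- rownames(K)
  L <- famlmm:::kinship_sqrt(K)
  y <- setNames(0.5 + drop(L %*% rnorm(100)) + rnorm(100), ids)
  X <- matrix(1, 100, 1, dimnames = list(ids, "(Intercept)"))

  for (opt in c("kinship", "independence")) {
    row <- fit_marker(y, X, covariance_spec(opt, K))
    expect_equal(row$statistic, row$estimate / row$std_error)
    expect_equal(row$p_value, 2 * stats::pnorm(-abs(row$statistic)))
    expect_gt(row$p_value, 0)
    expect_lte(row$p_value, 1)
    expect_equal(row$n_used, 100)
  }

  reps <- select_representatives(setNames(fam, ids), seed = 2)
  spec_rep <- covariance_spec("representative", K, representatives = reps)
  row_rep <- fit_marker(y, X, spec_rep, full_ids = ids)
  expect_equal(row_rep$n_used, 20)
  # t reference is wider-tailed than the normal reference
  row_t <- fit_marker(y, X, spec_rep, full_ids = ids, rep_reference = "t")
  expect_gte(row_t$p_value, row_rep$p_value)
  expect_equal(row_t$estimate, row_rep$estimate)
})

test_that("fit_all is deterministic and uses one representative per family", {
  cfg <- small_config(seed = 13)
  ds <- simulate_dataset(cfg)
  r1 <- fit_all(ds, "representative", representative_seed = 5)
  r2 <- fit_all(ds, "representative", representative_seed = 5)
  expect_identical(r1, r2)
  expect_true(all(r1$n_used == cfg$n_families))
  expect_equal(nrow(r1), cfg$m_markers)
  r3 <- fit_all(ds, "representative", representative_seed = 6)
  expect_false(identical(attr(r1, "representatives"),
                         attr(r3, "representatives")))

  kin <- fit_all(ds, "kinship")
  expect_true(all(kin$p_value > 0 & kin$p_value <= 1))
  expect_identical(kin, fit_all(ds, "kinship"))
})

test_that("strong signals occupy the smallest kinship p-values", {
  cfg <- small_config(m_markers = 100, m_causal = 10, effect_delta = 4,
                      seed = 17)
  ds <- simulate_dataset(cfg)
  res <- fit_all(ds, "kinship")
  top10 <- res$marker_id[order(res$p_value)][1:10]
  expect_setequal(top10, ds$causal)
})

test_that("kinship-option p-values are calibrated under the null", {
  cfg <- sim_config(n_families = 100, family_size = 5, m_markers = 2000,
                    m_causal = 0, sigma2_mu = 1, sigma2_eps = 1, seed = 23)
  ds <- simulate_dataset(cfg)
  res <- fit_all(ds, "kinship")
  alpha <- mean(res$p_value < 0.05)
  band <- 3 * sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(alpha - 0.05), band)
  # p-value distribution is uniform across null markers
  ks <- stats::ks.test(res$p_value, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("kinship power is at least representative power across replicates", {
  tps <- vapply(1:20, function(r) {
    cfg <- sim_config(n_families = 60, family_size = 5, m_markers = 150,
                      m_causal = 10, effect_delta = 0.5, seed = 300 + r)
    ds <- simulate_dataset(cfg)
    kin <- top_k(fit_all(ds, "kinship"), 15)
    rep_ <- top_k(fit_all(ds, "representative",
                          representative_seed = 700 + r), 15)
    c(kin = recovery(kin, ds$causal)$true_positives,
      rep = recovery(rep_, ds$causal)$true_positives)
  }, numeric(2))
  expect_gte(mean(tps["kin", ]), mean(tps["rep", ]))
})
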