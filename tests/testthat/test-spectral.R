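test_that("eigendecomposition: identity, duo blocks, reconstruction", {
  sp_i <- eigendecompose(diag(5), trace_normalize = FALSE)
  expect_equal(sp_i$eigenvalues, rep(1, 5))
  expect_lt(max(abs(crossprod(sp_i$vectors) - diag(5))), 1e-8)

  k <- simulate_duo_coancestry(4)
  sp <- eigendecompose(k, trace_normalize = FALSE)
  ## each [[1, .5], [.5, 1]] block contributes eigenvalues 1.5 and 0.5
  expect_equal(sp$eigenvalues, c(rep(1.5, 4), rep(0.5, 4)))
  expect_lt(max(abs(reconstruct_k(sp) - k$values)), 1e-6)

  g <- small_genotypes(n = 10, m = 15)
  spg <- spectrum_of(g)
  expect_lt(max(abs(reconstruct_k(spg) -
                      compute_similarity(standardize_genotypes(g))$values *
                      (10 / sum(diag(compute_similarity(standardize_genotypes(g))$values))))),
            1e-6)
  expect_equal(sum(spg$eigenvalues), 10, tolerance = 1e-8)  # trace normalized
})

test_that("rotation preserves norms", {
  g <- small_genotypes(n = 25, m = 50, seed = 5)
  sp <- spectrum_of(g)
  y <- simulate_null_phenotype(25, seed = 9)
  expect_equal(sqrt(sum(crossprod(sp$vectors, y)^2)), sqrt(sum(y^2)),
               tolerance = 1e-10)
})

test_that("empty PC set reduces to ordinary least squares", {
  set.seed(31)
  n <- 18
  g <- small_genotypes(n = n, m = 30, seed = 8)
  sp <- spectrum_of(g)
  x <- rnorm(n)
  y <- 1 + 0.5 * x + rnorm(n)
  W <- cbind(1, x)
  out <- rotated_loglik(y, W, sp, integer(0), delta = 1, method = "ML")
  expect_equal(out$loglik, as.numeric(logLik(lm(y ~ x))), tolerance = 1e-8)
  expect_equal(unname(out$fixed_effects), unname(coef(lm(y ~ x))),
               tolerance = 1e-8)
})

test_that("rotated likelihood equals the dense multivariate-normal oracle", {
  set.seed(101)
  for (rep in 1:20) {
    n <- sample(8:50, 1)
    g <- small_genotypes(n = n, m = n + 20, seed = rep)
    sp <- spectrum_of(g)
    K <- reconstruct_k(sp)
    y <- rnorm(n)
    W <- cbind(1, rnorm(n))
    delta <- exp(runif(1, -2, 2))
    S <- if (rep %% 3 == 0) sort(sample(n, n %/% 2)) else seq_len(n)
    for (method in c("ML", "REML")) {
      out <- rotated_loglik(y, W, sp, S, delta, method)
      Ks <- sp$vectors[, S, drop = FALSE] %*%
        (sp$eigenvalues[S] * t(sp$vectors[, S, drop = FALSE]))
      dense <- dense_loglik(y, W, Ks, out$sigma_g2, out$sigma_e2, method)
      expect_equal(out$loglik, dense, tolerance = 1e-8)
    }
  }
})

test_that("full-rank fit is invariant to K reconstruction (fixed vs random PC equivalence)", {
  g <- small_genotypes(n = 20, m = 40, seed = 13)
  k <- compute_similarity(standardize_genotypes(g))
  sp1 <- eigendecompose(k)
  k2 <- k; k2$values <- reconstruct_k(sp1) # already trace-normalized
  sp2 <- eigendecompose(k2, trace_normalize = FALSE)
  y <- simulate_null_phenotype(20, seed = 4) + sp1$vectors[, 1]
  f1 <- fit_lmm(y, spectrum = sp1)
  f2 <- fit_lmm(y, spectrum = sp2)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
})

test_that("large delta limit approaches OLS; profiled variances stay non-negative", {
  g <- small_genotypes(n = 16, m = 30, seed = 21)
  sp <- spectrum_of(g)
  y <- simulate_null_phenotype(16, seed = 5)
  ols <- rotated_loglik(y, NULL, sp, integer(0), 1, "ML")
  near <- rotated_loglik(y, NULL, sp, seq_len(16), 1e12, "ML")
  expect_equal(near$loglik, ols$loglik, tolerance = 1e-6)
  for (delta in 10^seq(-4, 4, by = 2)) {
    out <- rotated_loglik(y, NULL, sp, seq_len(16), delta, "ML")
    expect_gte(out$sigma_g2, 0)
    expect_gte(out$sigma_e2, 0)
  }
})

test_that("profiled likelihood beats +/-10% variance perturbations", {
  g <- small_genotypes(n = 14, m = 25, seed = 17)
  sp <- spectrum_of(g)
  K <- reconstruct_k(sp)
  y <- simulate_null_phenotype(14, seed = 6)
  W <- matrix(1, 14, 1)
  for (delta in c(0.1, 1, 10)) {
    out <- rotated_loglik(y, W, sp, seq_len(14), delta, "ML")
    for (f in c(0.9, 1.1)) {
      perturbed <- dense_loglik(y, W, K, out$sigma_g2 * f, out$sigma_e2 * f)
      expect_gte(out$loglik, perturbed - 1e-10)
    }
  }
})

test_that("fit_lmm recovers heritability and detects its absence", {
  ## moderate-scale recovery: mean estimate near the generating value
  h2s <- sapply(1:15, function(i) {
    g <- simulate_structured_genotypes(300, 800, n_pops = 1, seed = 40 + i)
    sp <- spectrum_of(g)
    sim <- simulate_phenotype(g, sp, confounding = list(type = "none"),
                              n_causal = 150, h2_total = 0.5, seed = 90 + i)
    fit_lmm(unname(sim$y), spectrum = sp)$h2
  })
  expect_lt(abs(mean(h2s) - 0.5), 0.08)
  ## pure noise: h2 and edf near zero
  g <- simulate_structured_genotypes(200, 400, n_pops = 1, seed = 77)
  sp <- spectrum_of(g)
  fit0 <- fit_lmm(simulate_null_phenotype(200, seed = 78), spectrum = sp)
  expect_lt(fit0$h2, 0.1)
  expect_lt(fit0$edf, 25)
})

test_that("the per-marker LMM estimates exactly 4 free parameters", {
  g <- small_genotypes(n = 30, m = 20, seed = 19)
  sp <- spectrum_of(g)
  s <- standardize_genotypes(g)
  y <- simulate_null_phenotype(30, seed = 20)
  marker <- s$values[, 1]
  fit <- fit_lmm(y, covariates = cbind(marker), spectrum = sp)
  expect_identical(n_free_parameters(fit), 4L)
})
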