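test_that("structured genotypes are deterministic, bounded and Fst-validated", {
  g1 <- simulate_structured_genotypes(30, 50, seed = 61)
  g2 <- simulate_structured_genotypes(30, 50, seed = 61)
  expect_identical(g1$dosages, g2$dosages)
  expect_true(all(g1$dosages %in% c(0, 1, 2)))
  expect_error(simulate_structured_genotypes(10, 10, fst = 0), "fst")
  expect_error(simulate_structured_genotypes(10, 10, fst = 1.2), "fst")
  ## markers carry usable positions for clustering
  expect_true(all(!is.na(g1$markers$pos)))
})

test_that("three differentiated populations dominate the leading eigenvalues", {
  g <- simulate_structured_genotypes(300, 2000, n_pops = 3, fst = 0.05,
                                     seed = 62)
  sp <- spectrum_of(g)
  ## with column centering, k - 1 = 2 structure axes separate from the bulk
  expect_gt(sp$eigenvalues[2] / sp$eigenvalues[3], 5)
})

test_that("vanishing Fst leaves no separated structure axis", {
  ratios <- sapply(1:10, function(i) {
    g <- simulate_structured_genotypes(100, 500, n_pops = 3, fst = 1e-6,
                                       seed = 1600 + i)
    sp <- spectrum_of(g)
    sp$eigenvalues[1] / sp$eigenvalues[2]
  })
  expect_gte(mean(ratios < 2), 0.9)
})

test_that("duo coancestry blocks have the closed-form long-tailed spectrum", {
  k <- simulate_duo_coancestry(33)
  expect_equal(dim(k$values), c(66L, 66L))
  lam <- eigen(k$values, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(lam, c(rep(1.5, 33), rep(0.5, 33)), tolerance = 1e-12)
  expect_true(all(lam > 0))  # every eigenvalue nonzero: kinship fills the tail
  expect_equal(eigen(simulate_duo_coancestry(1)$values,
                     only.values = TRUE)$values, c(1.5, 0.5))
  ## weighted sum with a structured matrix: dominant leaders plus a long tail
  g <- simulate_structured_genotypes(66, 400, n_pops = 3, fst = 0.2, seed = 63)
  ks <- compute_similarity(standardize_genotypes(g))
  mix <- 0.5 * ks$values + 0.5 * k$values
  lam_mix <- eigen(mix, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(lam_mix[2] / lam_mix[3], 3)       # leaders dominate
  expect_gt(lam_mix[60], 0.01 * lam_mix[3])   # yet the tail stays fat
})

test_that("phenotype components hit their variance fractions exactly", {
  g <- simulate_structured_genotypes(200, 600, seed = 64)
  sp <- spectrum_of(g)
  sim <- simulate_phenotype(
    g, sp, confounding = list(type = "pc_based", k_relevant = 10,
                              pool_size = 30, var_frac = 0.15),
    n_causal = 10, h2_total = 0.4, seed = 65)
  comp <- sim$truth$components
  vy <- var(sim$y)
  expect_equal(var(comp$confounding) / vy, 0.15, tolerance = 1e-10)
  expect_equal(var(comp$causal) / vy, 0.25, tolerance = 1e-10)
  expect_equal(var(comp$noise) / vy, 0.6, tolerance = 1e-10)
  ## orthogonalized components: variances add up to var(y)
  expect_equal(var(comp$confounding) + var(comp$causal) + var(comp$noise),
               vy, tolerance = 1e-10)
  expect_equal(length(sim$truth$causal_marker_ids), 10L)
  expect_equal(length(sim$truth$relevant_pc_indices), 10L)
  expect_true(all(sim$truth$relevant_pc_indices <= 30))
})

test_that("stratified confounding picks distinct PC-correlated markers", {
  g <- simulate_structured_genotypes(150, 500, seed = 66)
  sp <- spectrum_of(g)
  sim <- simulate_phenotype(
    g, sp, confounding = list(type = "stratified", n_per_pc = 5, n_pcs = 10,
                              var_frac = 0.15),
    n_causal = 10, h2_total = 0.4, seed = 67)
  expect_equal(length(sim$truth$stratified_marker_ids), 50L)
  expect_equal(anyDuplicated(sim$truth$stratified_marker_ids), 0L)
  ## causal markers avoid the stratified set
  expect_length(intersect(sim$truth$causal_marker_ids,
                          sim$truth$stratified_marker_ids), 0)
})

test_that("degenerate phenotype settings behave as limits", {
  g <- simulate_structured_genotypes(300, 1000, n_pops = 1, seed = 68)
  sp <- spectrum_of(g)
  sim0 <- simulate_phenotype(g, sp, confounding = list(type = "none"),
                             h2_total = 0, seed = 69)
  expect_equal(var(sim0$y), var(sim0$truth$components$noise), tolerance = 1e-12)
  fit <- fit_lmm(unname(sim0$y), spectrum = sp)
  expect_lt(fit$h2, 0.15)
  expect_error(
    simulate_phenotype(g, sp,
                       confounding = list(type = "pc_based", k_relevant = 2,
                                          pool_size = 5, var_frac = 0.5),
                       h2_total = 0.3, seed = 70),
    "exceeds")
})

test_that("null phenotypes are standard normal and seed-stable", {
  y1 <- simulate_null_phenotype(1000, seed = 71)
  y2 <- simulate_null_phenotype(1000, seed = 71)
  expect_identical(y1, y2)
  expect_lt(abs(mean(y1)), 4 / sqrt(1000))
  expect_lt(abs(var(y1) - 1), 4 * sqrt(2 / 999))
})
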