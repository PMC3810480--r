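## Small in-code fixtures shared across tests.

## 3-sample, 2-marker PLINK .raw text
plink_raw_fixture <- function(dosage_override = NULL) {
  dos <- matrix(c(0, 1, 2, 2, 1, 0), nrow = 3)
  if (!is.null(dosage_override)) dos[1, 1] <- dosage_override
  lines <- c("FID IID PAT MAT SEX PHENOTYPE rs1_A rs2_G",
             sprintf("f%d i%d 0 0 1 -9 %s %s", 1:3, 1:3, dos[, 1], dos[, 2]))
  path <- tempfile(fileext = ".raw")
  writeLines(lines, path)
  path
}

## random small genotype_matrix with marker positions
small_genotypes <- function(n = 20, m = 40, seed = 7, n_pops = 2, fst = 0.1) {
  simulate_structured_genotypes(n, m, n_pops = n_pops, fst = fst, seed = seed)
}

## spectrum of the standardized GRM
spectrum_of <- function(g) {
  eigendecompose(compute_similarity(standardize_genotypes(g)))
}

## dense multivariate-normal log-likelihood by direct inversion (test oracle,
## independent of the rotated code path)
dense_loglik <- function(y, W, K, sigma_g2, sigma_e2, method = "ML") {
  n <- length(y)
  cc <- ncol(W)
  V <- sigma_g2 * K + sigma_e2 * diag(n)
  Vi <- solve(V)
  b <- solve(t(W) %*% Vi %*% W, t(W) %*% Vi %*% y)
  r <- y - W %*% b
  quad <- drop(t(r) %*% Vi %*% r)
  ldV <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  if (method == "ML") {
    -0.5 * (n * log(2 * pi) + ldV + quad)
  } else {
    ldWVW <- as.numeric(determinant(t(W) %*% Vi %*% W)$modulus)
    ldWW <- as.numeric(determinant(t(W) %*% W)$modulus)
    -0.5 * ((n - cc) * log(2 * pi) + ldV + ldWVW + quad) + 0.5 * ldWW
  }
}

## reconstruct the similarity matrix used by a spectrum
reconstruct_k <- function(sp) {
  sp$vectors %*% (sp$eigenvalues * t(sp$vectors))
}
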