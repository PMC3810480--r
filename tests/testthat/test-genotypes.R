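test_that("PLINK .raw round-trips with marker metadata from column names", {
  g <- read_genotypes(plink_raw_fixture(), format = "plink_raw")
  expect_equal(dim(g), c(3L, 2L))
  expect_equal(g$markers$id, c("rs1", "rs2"))
  expect_equal(g$markers$allele, c("A", "G"))
  expect_equal(unname(g$dosages[, 1]), c(0, 1, 2))
})

test_that("invalid dosage and malformed rows are rejected with context", {
  expect_error(read_genotypes(plink_raw_fixture(dosage_override = 3),
                              format = "plink_raw"),
               "invalid dosage 3.*rs1")
  path <- tempfile(fileext = ".raw")
  writeLines(c("FID IID PAT MAT SEX PHENOTYPE rs1_A",
               "f1 i1 0 0 1 -9 0 2"), path)  # extra field
  expect_error(read_genotypes(path, format = "plink_raw"), "line 2")
})

test_that("TSV genotypes pick up chrom/pos from the sidecar and round-trip", {
  g0 <- small_genotypes(n = 6, m = 4)
  geno <- tempfile(fileext = ".tsv"); side <- tempfile(fileext = ".tsv")
  write_genotypes(g0, geno, sidecar = side)
  g <- read_genotypes(geno, format = "tsv", sidecar = side)
  expect_equal(g$dosages, g0$dosages)
  expect_equal(g$markers$chrom, g0$markers$chrom)
  expect_equal(g$markers$pos, g0$markers$pos)
})

test_that("standardization centers, scales and handles missingness", {
  g <- genotype_matrix(
    cbind(c(0, 1, 2), c(2, 2, 2), c(0, NA, 2)),
    sample_ids = c("a", "b", "c"),
    markers = data.frame(id = c("m1", "m2", "m3"), chrom = "1",
                         pos = c(1, 2, 3), allele = "A"))
  s <- standardize_genotypes(g)
  ## (0,1,2): p = 0.5, centered (-1,0,1), patterson scale 1/sqrt(0.25) = 2
  expect_equal(unname(s$values[, 1]), c(-2, 0, 2))
  expect_equal(s$allele_freqs[1], 0.5)
  ## monomorphic column dropped
  expect_equal(s$kept_marker_index, c(1L, 3L))
  ## missing mean-imputed: observed mean of {0,2} = 1 -> centered to 0
  expect_equal(unname(s$values[2, 2]), 0)
  ## center_only keeps the raw scale
  s2 <- standardize_genotypes(g, scaling = "center_only")
  expect_equal(unname(s2$values[, 1]), c(-1, 0, 1))
  ## retained columns have mean zero
  expect_lt(max(abs(colMeans(s$values))), 1e-10)
})

test_that("all-monomorphic input is an error", {
  g <- genotype_matrix(cbind(c(2, 2, 2), c(0, 0, 0)),
                       sample_ids = c("a", "b", "c"),
                       markers = data.frame(id = c("m1", "m2"), chrom = "1",
                                            pos = c(1, 2), allele = "A"))
  expect_error(standardize_genotypes(g), "no informative markers")
})

test_that("standardization is idempotent in effect: re-centering is a no-op", {
  g <- small_genotypes()
  s <- standardize_genotypes(g)
  recentered <- sweep(s$values, 2, colMeans(s$values), "-")
  expect_lt(max(abs(recentered - s$values)), 1e-12)
})

test_that("standardized GRM is symmetric PSD; single marker gives rank 1", {
  g <- small_genotypes(n = 15, m = 30)
  k <- compute_similarity(standardize_genotypes(g))
  expect_lt(max(abs(k$values - t(k$values))), 1e-10)
  ev <- eigen(k$values, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8 * max(ev))
  ## one marker, column (-1, 0, 1): K is the outer product / 1
  x <- structure(list(values = matrix(c(-1, 0, 1), 3, 1),
                      sample_ids = c("a", "b", "c")),
                 class = "standardized_genotypes")
  k1 <- compute_similarity(x)
  expect_equal(unname(k1$values), tcrossprod(c(-1, 0, 1)))
  expect_equal(sum(eigen(k1$values, only.values = TRUE)$values > 1e-10), 1L)
})

test_that("Gower centering zeroes row sums and normalizes the trace to n", {
  g <- small_genotypes(n = 12, m = 25)
  k <- compute_similarity(standardize_genotypes(g), metric = "gower_centered")
  expect_lt(max(abs(rowSums(k$values))), 1e-8)
  expect_equal(sum(diag(k$values)), 12, tolerance = 1e-10)
})

test_that("top-marker similarity selects by association and degenerates to the full GRM", {
  g <- small_genotypes(n = 30, m = 20, seed = 11)
  s <- standardize_genotypes(g)
  ## phenotype equal to one standardized marker: that marker ranks first
  y <- s$values[, 5]
  k1 <- similarity_from_top_markers(g, y, n_top = 1)
  expect_equal(attr(k1, "selected_markers"), s$markers$id[5])
  ## n_top = all retained markers reproduces compute_similarity exactly
  y2 <- simulate_null_phenotype(30, seed = 2)
  m_kept <- ncol(s$values)
  k_all <- similarity_from_top_markers(g, y2, n_top = m_kept)
  expect_equal(k_all$values, compute_similarity(s)$values)
  expect_error(similarity_from_top_markers(g, y2, n_top = 0), "n_top")
})

test_that("GRM text format round-trips and rejects asymmetry", {
  g <- small_genotypes(n = 5, m = 12, seed = 3)
  k <- compute_similarity(standardize_genotypes(g))
  path <- tempfile(fileext = ".grm")
  write_grm(k, path)
  k2 <- read_grm(path)
  expect_lt(max(abs(k2$values - k$values)), 1e-12)
  expect_equal(k2$sample_ids, k$sample_ids)
  ## corrupt one off-diagonal entry
  lines <- readLines(path)
  f <- strsplit(lines[4], "\t")[[1]]
  f[4] <- as.character(as.numeric(f[4]) + 0.5)  # off-diagonal entry K[2,3]
  lines[4] <- paste(f, collapse = "\t")
  writeLines(lines, path)
  expect_error(read_grm(path), "asymmetric")
})

test_that("phenotype files round-trip as FID IID VALUE", {
  y <- c(a = 1.5, b = -0.25, c = 3)
  path <- tempfile()
  write_phenotype(y, path)
  expect_equal(read_phenotype(path), y)
})
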