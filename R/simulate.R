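## Synthetic-data generators.
##
## Structured genotypes follow the Balding-Nichols model: each marker has an
## ancestral frequency, per-population frequencies are Beta-distributed
## around it with dispersion governed by Fst, and dosages are Binomial(2, p)
## within populations. Phenotypes combine principal-component confounding
## (or stratified-marker confounding), causal marker effects and Gaussian
## noise, with components orthogonalized in-sample and rescaled so the
## stated variance fractions hold exactly in every replicate.

#' Simulate Balding-Nichols structured genotypes
#'
#' Ancestral allele frequencies are Uniform on `maf_range`; population
#' frequencies are `Beta(p(1-F)/F, (1-p)(1-F)/F)`; dosages are
#' `Binomial(2, p_pop)`. Samples are split evenly across populations.
#' Markers are laid out in contiguous blocks over `n_chrom` chromosomes at
#' `spacing_bp` intervals so positional clustering rules can be exercised.
#'
#' @param n_samples,n_markers matrix dimensions.
#' @param n_pops number of populations (default 3).
#' @param fst Balding-Nichols differentiation parameter, in (0, 1).
#' @param maf_range support of the ancestral frequency (default
#'   `c(0.05, 0.95)`, avoiding near-monomorphic markers).
#' @param n_chrom,spacing_bp marker layout (defaults: 22 chromosomes,
#'   20 kb spacing).
#' @param seed integer seed; the result is a deterministic function of the
#'   arguments.
#' @return A [genotype_matrix()] whose markers carry a `population` attribute
#'   mapping samples to populations.
#' @export
simulate_structured_genotypes <- function(n_samples, n_markers, n_pops = 3,
                                          fst = 0.05,
                                          maf_range = c(0.05, 0.95),
                                          n_chrom = 22, spacing_bp = 20000,
                                          seed = NULL) {
  if (fst <= 0 || fst >= 1) stop_value("fst must lie in (0, 1)")
  with_seed(seed, {
    p_anc <- stats::runif(n_markers, maf_range[1], maf_range[2])
    pop <- rep(seq_len(n_pops), length.out = n_samples)
    pop <- sort(pop)  # contiguous, near-equal blocks
    a <- p_anc * (1 - fst) / fst
    b <- (1 - p_anc) * (1 - fst) / fst
    dos <- matrix(0, n_samples, n_markers)
    for (k in seq_len(n_pops)) {
      idx <- which(pop == k)
      p_k <- stats::rbeta(n_markers, a, b)
      dos[idx, ] <- matrix(stats::rbinom(length(idx) * n_markers, 2,
                                         rep(p_k, each = length(idx))),
                           nrow = length(idx))
    }
    per_chrom <- ceiling(n_markers / n_chrom)
    chrom <- rep(seq_len(n_chrom), each = per_chrom)[seq_len(n_markers)]
    pos <- (sequence(rle(chrom)$lengths) - 1) * spacing_bp + 1
    markers <- data.frame(id = sprintf("m%05d", seq_len(n_markers)),
                          chrom = as.character(chrom), pos = pos,
                          allele = "A", stringsAsFactors = FALSE)
    g <- genotype_matrix(dos, sprintf("s%04d", seq_len(n_samples)), markers)
    attr(g, "population") <- pop
    g
  })
}

#' Idealized parent-offspring duo coancestry matrix
#'
#' Block-diagonal with 2x2 blocks `[[1, 0.5], [0.5, 1]]`: self-similarity 1,
#' parent-offspring coancestry 0.5, zero between duos. Constructed directly
#' (not from genotypes); its eigen-spectrum is `n_duos` copies of
#' `{1.5, 0.5}` — every eigenvalue nonzero, the signature of kinship as a
#' high-dimensional process.
#'
#' @param n_duos number of duos (matrix is `2*n_duos` square).
#' @return A `similarity_matrix`.
#' @export
simulate_duo_coancestry <- function(n_duos) {
  if (n_duos < 1) stop_value("n_duos must be >= 1")
  block <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  k <- kronecker(diag(n_duos), block)
  ids <- sprintf("d%03d_%s", rep(seq_len(n_duos), each = 2), c("parent", "child"))
  dimnames(k) <- list(ids, ids)
  structure(list(values = k, metric_name = "duo_coancestry",
                 n_markers_used = NA_integer_, sample_ids = ids),
            class = "similarity_matrix")
}

#' Simulate a phenotype with genetic confounding
#'
#' The phenotype is the sum of a confounding component, a causal-marker
#' component and Gaussian noise. Coefficients are standard normal draws;
#' components are then centered, orthogonalized in-sample (causal against
#' confounding, noise against both) and rescaled so the realized variance
#' fractions equal `var_frac` (confounding), `h2_total - var_frac` (causal)
#' and `1 - h2_total` (noise) exactly, with total variance 1.
#'
#' Confounding modes:
#' * `pc_based(k_relevant, pool_size, var_frac)`: `k_relevant` principal
#'   components sampled uniformly from the first `pool_size`.
#' * `stratified(n_per_pc, n_pcs, var_frac)`: for each of the first `n_pcs`
#'   principal components, the `n_per_pc` markers most correlated with it
#'   (distinct across components) contribute effects.
#' * `none`.
#'
#' @param g a [genotype_matrix()].
#' @param spectrum the `eigen_spectrum` of `g`'s GRM (required for the
#'   pc_based and stratified modes).
#' @param confounding list with element `type` (`"pc_based"`,
#'   `"stratified"` or `"none"`) plus the mode's parameters as named
#'   elements (see above); e.g.
#'   `list(type = "pc_based", k_relevant = 10, pool_size = 30, var_frac = 0.15)`.
#' @param n_causal number of causal markers (sampled uniformly among
#'   informative markers, excluding stratified markers).
#' @param h2_total total genetic variance fraction in `[0, 1)`
#'   (confounding + causal).
#' @param seed integer seed.
#' @return List with `y` (named numeric) and `truth`, a list recording
#'   `causal_marker_ids`, `relevant_pc_indices`, `stratified_marker_ids`,
#'   `var_fractions` (confounding/causal/noise) and `true_h2`, plus the
#'   realized `components` (confounding, causal, noise vectors).
#' @export
simulate_phenotype <- function(g, spectrum = NULL,
                               confounding = list(type = "none"),
                               n_causal = 0, h2_total = 0, seed = NULL) {
  n <- nrow(g$dosages)
  type <- confounding$type
  var_frac <- if (type == "none") 0 else confounding$var_frac
  if (is.null(var_frac)) var_frac <- 0
  if (var_frac > h2_total)
    stop_value("confounding var_frac (%g) exceeds h2_total (%g)",
               var_frac, h2_total)
  if (h2_total < 0 || h2_total >= 1) stop_value("h2_total must lie in [0, 1)")
  causal_frac <- h2_total - var_frac
  if (n_causal == 0 && causal_frac > 1e-12)
    stop_value("causal variance %g requested with n_causal = 0", causal_frac)
  with_seed(seed, {
    s <- standardize_genotypes(g)
    relevant <- integer(0)
    strat_ids <- character(0)
    conf <- numeric(n)
    if (type == "pc_based") {
      if (is.null(spectrum)) stop_value("pc_based confounding needs a spectrum")
      relevant <- sort(sample(seq_len(confounding$pool_size),
                              confounding$k_relevant))
      conf <- drop(spectrum$vectors[, relevant, drop = FALSE] %*%
                     stats::rnorm(length(relevant)))
    } else if (type == "stratified") {
      if (is.null(spectrum)) stop_value("stratified confounding needs a spectrum")
      xc <- scale(s$values)
      chosen <- integer(0)
      for (j in seq_len(confounding$n_pcs)) {
        r2 <- drop(stats::cor(xc, spectrum$vectors[, j]))^2
        r2[chosen] <- -Inf  # keep the stratified sets distinct
        chosen <- c(chosen, order(r2, decreasing = TRUE)[seq_len(confounding$n_per_pc)])
      }
      strat_ids <- s$markers$id[chosen]
      conf <- drop(s$values[, chosen, drop = FALSE] %*%
                     stats::rnorm(length(chosen)))
    } else if (type != "none") {
      stop_value("unknown confounding type '%s'", type)
    }
    causal_ids <- character(0)
    causal <- numeric(n)
    if (n_causal > 0) {
      pool <- setdiff(seq_len(ncol(s$values)), match(strat_ids, s$markers$id))
      ci <- sort(sample(pool, n_causal))
      causal_ids <- s$markers$id[ci]
      causal <- drop(s$values[, ci, drop = FALSE] %*% stats::rnorm(n_causal))
    }
    noise <- stats::rnorm(n)
    ## center, orthogonalize sequentially, rescale to exact variance targets
    rescale <- function(x, target_var) {
      if (target_var == 0) return(numeric(n))
      v <- stats::var(x)
      if (v == 0) stop_value("degenerate component with zero variance")
      x * sqrt(target_var / v)
    }
    conf <- conf - mean(conf)
    causal <- causal - mean(causal)
    noise <- noise - mean(noise)
    basis <- NULL
    orth <- function(x, basis) {
      if (is.null(basis) || !length(x) || all(x == 0)) return(x)
      x - basis %*% qr.coef(qr(basis), x)
    }
    if (var_frac > 0) {
      conf <- rescale(conf, var_frac)
      basis <- cbind(basis, conf)
    } else conf <- numeric(n)
    if (causal_frac > 0 && n_causal > 0) {
      causal <- drop(orth(causal, basis))
      causal <- rescale(causal, causal_frac)
      basis <- cbind(basis, causal)
    } else causal <- numeric(n)
    noise <- drop(orth(noise, basis))
    noise <- rescale(noise, 1 - h2_total)
    y <- conf + causal + noise
    names(y) <- g$sample_ids
    list(y = y,
         truth = list(causal_marker_ids = causal_ids,
                      relevant_pc_indices = relevant,
                      stratified_marker_ids = strat_ids,
                      var_fractions = c(confounding = var_frac,
                                        causal = causal_frac,
                                        noise = 1 - h2_total),
                      true_h2 = h2_total,
                      components = list(confounding = conf, causal = causal,
                                        noise = noise)))
  })
}

#' Simulate a null phenotype (i.i.d. standard normal)
#'
#' @param n sample size.
#' @param seed integer seed.
#' @return Numeric vector of length `n`.
#' @export
simulate_null_phenotype <- function(n, seed = NULL) {
  with_seed(seed, stats::rnorm(n))
}
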