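## Low-rank linear mixed model (LRLMM).
##
## The correction for genetic confounding need not be full rank: population
## structure is low dimensional while kinship fills the eigen-spectrum's
## tail. The LRLMM orders the principal components of the similarity
## matrix, fits the LMM at every rank r = 0 (ordinary linear model) up to
## r_max (full-rank LMM at r = n), and selects the rank that minimizes an
## information criterion built on the effective degrees of freedom.

#' Order principal components by relevance to a phenotype
#'
#' Four orderings: `"eigenvalue"` (marker-based only), `"corSq"` (squared
#' Pearson correlation between each principal component and the phenotype
#' residualized on the covariates), `"corSq_x_eigenvalue"` (their product),
#' and `"DF"` (the effective degrees of freedom from fitting a rank-1 LRLMM
#' to each principal component individually, each with its own optimized
#' variance ratio). Scores are sorted descending; ties break by eigenvalue,
#' then original index.
#'
#' @param spectrum an `eigen_spectrum`.
#' @param y numeric phenotype vector.
#' @param covariates fixed-effects matrix (intercept added if absent).
#' @param method one of `"eigenvalue"`, `"corSq"`, `"corSq_x_eigenvalue"`,
#'   `"DF"`.
#' @param fit_method `"ML"` or `"REML"` for the DF ordering's rank-1 fits.
#' @return Object of class `pc_ordering`: `method`, `permutation` (PC
#'   indices, most relevant first), `scores` (aligned with `permutation`).
#' @export
order_pcs <- function(spectrum, y, covariates = NULL,
                      method = c("corSq", "eigenvalue", "corSq_x_eigenvalue", "DF"),
                      fit_method = "ML") {
  method <- match.arg(method)
  n <- spectrum$n
  if (length(y) != n) stop_value("phenotype length %d != spectrum n %d",
                                 length(y), n)
  if (stats::var(y) == 0) stop_value("phenotype has zero variance")
  W <- build_design(n, covariates)
  y_res <- qr.resid(qr(W), y)
  lam <- spectrum$eigenvalues
  if (method == "eigenvalue") {
    scores <- lam
  } else if (method %in% c("corSq", "corSq_x_eigenvalue")) {
    U <- spectrum$vectors
    uc <- sweep(U, 2, colMeans(U), "-")
    yc <- y_res - mean(y_res)
    denom <- sqrt(colSums(uc^2) * sum(yc^2))
    r <- drop(crossprod(uc, yc)) / denom
    r[!is.finite(r)] <- 0  # constant principal component
    scores <- r^2
    if (method == "corSq_x_eigenvalue") scores <- scores * lam
  } else {  # DF: rank-1 fit per principal component
    yt <- drop(crossprod(spectrum$vectors, y))
    Wt <- crossprod(spectrum$vectors, W)
    scores <- vapply(seq_len(n), function(j) {
      f <- fit_rotated(yt, Wt, lam, j, fit_method)
      if (!is.finite(f$delta)) 0 else lam[j] / (lam[j] + f$delta)
    }, numeric(1))
  }
  perm <- order(-scores, -lam, seq_len(n))
  structure(list(method = method, permutation = perm, scores = scores[perm]),
            class = "pc_ordering")
}

#' @export
print.pc_ordering <- function(x, ...) {
  cat(sprintf("pc_ordering (%s): top PCs %s\n", x$method,
              paste(utils::head(x$permutation, 5), collapse = ", ")))
  invisible(x)
}

#' Scan LRLMM ranks and score each with information criteria
#'
#' Fits the low-rank LMM whose random effect spans the first `r` principal
#' components of `ordering`, for `r = 0 ... r_max`. Each rank records the
#' maximized log-likelihood, the effective degrees of freedom (EDF) of the
#' random effect and three criteria sharing the complexity measure
#' `edf + c + 2` (fixed effects plus the two variance components):
#' `aic = -2*loglik + 2*(edf + c + 2)`,
#' `bic = -2*loglik + log(n)*(edf + c + 2)`, and
#' `gcv = n * RSS / (n - edf - c)^2` with RSS the unweighted residual sum
#' of squares at the plug-in BLUP fit.
#'
#' @inheritParams fit_lmm
#' @param ordering a `pc_ordering`, or an ordering method name passed to
#'   [order_pcs()].
#' @param r_max largest rank scanned; defaults to `min(n, n - c - 2)`.
#'   Capping it (e.g. when the confounding is known to be low dimensional)
#'   reduces runtime proportionally.
#' @return Object of class `rank_scan`: `ordering`, `per_rank` data.frame
#'   (`rank`, `loglik`, `edf`, `aic`, `bic`, `gcv`, `delta`, `h2`),
#'   `fits` (list of `lmm_fit`, index r+1), `n`, `n_covariates`, `method`.
#' @export
rank_scan <- function(y, covariates = NULL, spectrum, ordering = "corSq",
                      r_max = NULL, method = c("ML", "REML")) {
  method <- match.arg(method)
  n <- length(y)
  if (n != spectrum$n) stop_value("phenotype length %d != spectrum n %d",
                                  n, spectrum$n)
  if (is.character(ordering))
    ordering <- order_pcs(spectrum, y, covariates, method = ordering,
                          fit_method = method)
  W <- build_design(n, covariates)
  cc <- ncol(W)
  if (is.null(r_max)) r_max <- min(n, n - cc - 2)
  if (r_max > n) stop_value("r_max (%d) exceeds sample size %d", r_max, n)
  yt <- drop(crossprod(spectrum$vectors, y))
  Wt <- crossprod(spectrum$vectors, W)
  lam <- spectrum$eigenvalues
  fits <- vector("list", r_max + 1)
  rows <- vector("list", r_max + 1)
  for (r in 0:r_max) {
    S <- if (r == 0) integer(0) else ordering$permutation[seq_len(r)]
    f <- fit_rotated(yt, Wt, lam, S, method)
    fit <- make_lmm_fit(f, lam, S, method, n, cc)
    edf_tot <- fit$edf + cc + 2
    gcv_den <- n - fit$edf - cc
    rows[[r + 1]] <- data.frame(
      rank = r, loglik = fit$loglik, edf = fit$edf,
      aic = -2 * fit$loglik + 2 * edf_tot,
      bic = -2 * fit$loglik + log(n) * edf_tot,
      gcv = if (gcv_den > 0) n * fit$rss_blup / gcv_den^2 else NA_real_,
      delta = fit$delta, h2 = fit$h2)
    fits[[r + 1]] <- fit
  }
  structure(list(ordering = ordering, per_rank = do.call(rbind, rows),
                 fits = fits, n = n, n_covariates = cc, method = method),
            class = "rank_scan")
}

#' @export
print.rank_scan <- function(x, ...) {
  cat(sprintf("rank_scan (%s ordering, %s): ranks 0..%d\n",
              x$ordering$method, x$method, max(x$per_rank$rank)))
  for (crit in c("AIC", "BIC", "GCV")) {
    s <- select_rank(x, crit)
    cat(sprintf("  %s-selected rank: %d (h2 = %.3f, edf = %.2f)\n",
                crit, s$rank, s$fit$h2, s$fit$edf))
  }
  invisible(x)
}

#' Select the LRLMM rank minimizing a criterion
#'
#' @param scan a `rank_scan`.
#' @param criterion `"BIC"` (default), `"AIC"`, `"GCV"` or `"neg2loglik"`.
#'   `neg2loglik` is degenerate for the eigenvalue ordering (monotone in
#'   rank) and is provided for completeness.
#' @return List with `rank`, `fit` (the `lmm_fit` at that rank) and
#'   `criterion`. Ties resolve to the smallest rank; ranks with an
#'   undefined criterion (e.g. GCV with a non-positive denominator) are
#'   skipped.
#' @export
select_rank <- function(scan, criterion = c("BIC", "AIC", "GCV", "neg2loglik")) {
  criterion <- match.arg(criterion)
  vals <- switch(criterion,
                 AIC = scan$per_rank$aic,
                 BIC = scan$per_rank$bic,
                 GCV = scan$per_rank$gcv,
                 neg2loglik = -2 * scan$per_rank$loglik)
  ok <- which(!is.na(vals))
  if (!length(ok)) stop_value("criterion %s undefined at every rank", criterion)
  best <- ok[which.min(vals[ok])]  # which.min takes the first = smallest rank
  list(rank = scan$per_rank$rank[best], fit = scan$fits[[best]],
       criterion = criterion)
}

#' Write a rank scan as TSV
#'
#' @param scan a `rank_scan`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_rank_scan <- function(scan, path) {
  utils::write.table(scan$per_rank, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
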