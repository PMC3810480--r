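## Spectral LMM machinery.
##
## The LMM  y ~ N(W b, sigma_g2 * K + sigma_e2 * I)  is fit through the
## eigendecomposition K = U diag(lambda) U'. Rotating y and W by U' makes the
## covariance diagonal with per-coordinate variance sigma_g2*lambda_j +
## sigma_e2 for coordinates whose principal components carry the random
## effect and sigma_e2 elsewhere, so the likelihood at a given variance
## ratio delta = sigma_e2/sigma_g2 is available in closed form after
## profiling out sigma_g2 and the fixed effects by generalized least
## squares. Only delta is optimized numerically (grid + golden-section
## refinement). Low-rank models restrict the random effect to an index set
## S of principal components.

#' Eigendecompose a similarity matrix
#'
#' @param k a `similarity_matrix` (or plain symmetric matrix).
#' @param trace_normalize scale `K` so its trace equals the sample size
#'   before decomposition (default `TRUE`; makes pseudo-heritability
#'   interpretable as a variance fraction).
#' @return Object of class `eigen_spectrum` with fields `vectors` (n x n
#'   orthonormal `U`, columns = principal components), `eigenvalues` (sorted
#'   non-increasing, small/negative values clipped to 0), `n`,
#'   `source_metric`, `trace_normalized`, `sample_ids`.
#' @export
eigendecompose <- function(k, trace_normalize = TRUE) {
  if (inherits(k, "similarity_matrix")) {
    vals <- k$values
    metric <- k$metric_name
    ids <- k$sample_ids
  } else {
    vals <- as.matrix(k)
    metric <- "matrix"
    ids <- rownames(vals)
  }
  n <- nrow(vals)
  if (ncol(vals) != n || max(abs(vals - t(vals))) > 1e-8 * max(1, max(abs(vals))))
    stop_value("similarity matrix must be symmetric")
  if (trace_normalize) {
    tr <- sum(diag(vals))
    if (tr <= 0) stop_value("similarity matrix has non-positive trace")
    vals <- vals * (n / tr)
  }
  e <- eigen(vals, symmetric = TRUE)
  lam <- e$values
  lam[lam < 1e-10 * max(lam[1], 0)] <- 0  # clip numerically-zero eigenvalues
  structure(list(vectors = e$vectors, eigenvalues = lam, n = n,
                 source_metric = metric, trace_normalized = trace_normalize,
                 sample_ids = ids),
            class = "eigen_spectrum")
}

#' @export
print.eigen_spectrum <- function(x, ...) {
  cat(sprintf("eigen_spectrum: n = %d, %d nonzero eigenvalues, top = %.4g\n",
              x$n, sum(x$eigenvalues > 0), x$eigenvalues[1]))
  invisible(x)
}

## ---- internal rotated-likelihood core -------------------------------------
## yt, Wt: phenotype and design rotated by U'. lambda: all n eigenvalues.
## S: integer index set of principal components carrying the random effect.

## Ordinary least squares limit (no random effect / delta -> Inf)
ols_profile <- function(yt, Wt, method) {
  n <- length(yt)
  cc <- ncol(Wt)
  q <- qr(Wt)
  if (q$rank < cc) stop_value("rank-deficient fixed-effects design")
  b <- qr.coef(q, yt)
  rss <- sum(qr.resid(q, yt)^2)
  if (method == "ML") {
    s2 <- rss / n
    ll <- -0.5 * (n * log(2 * pi * s2) + n)
  } else {
    s2 <- rss / (n - cc)
    ll <- -0.5 * ((n - cc) * log(2 * pi * s2) + (n - cc))
  }
  list(loglik = ll, sigma_g2 = 0, sigma_e2 = s2, fixed_effects = b,
       rss_blup = rss)
}

## Profile likelihood at a fixed finite delta with a non-empty S.
## Parametrization: cov(y) = sigma_g2 * diag(v), v_j = lambda_j + delta for
## j in S, v_j = delta otherwise (so sigma_e2 = delta * sigma_g2).
rot_profile <- function(yt, Wt, lambda, S, delta, method) {
  n <- length(yt)
  cc <- ncol(Wt)
  v <- rep(delta, n)
  v[S] <- lambda[S] + delta
  w <- 1 / sqrt(v)
  yw <- yt * w
  Ww <- Wt * w
  q <- qr(Ww)
  if (q$rank < cc) stop_value("rank-deficient rotated design")
  b <- qr.coef(q, yw)
  r <- qr.resid(q, yw)
  rss <- sum(r^2)
  if (method == "ML") {
    s2 <- rss / n
    ll <- -0.5 * (n * log(2 * pi * s2) + sum(log(v)) + n)
  } else {
    s2 <- rss / (n - cc)
    ## Harville restricted likelihood, incl. +0.5 log|W'W| so the value is
    ## invariant to the fixed-effects basis
    ll <- -0.5 * ((n - cc) * log(2 * pi * s2) + sum(log(v)) +
                    logdet_crossprod(q) + (n - cc)) +
      0.5 * logdet_crossprod(qr(Wt))
  }
  ## unweighted residual after subtracting the BLUP random-effect prediction:
  ## coordinate j in S is shrunk by delta/(lambda_j + delta)
  rfix <- yt - drop(Wt %*% b)
  shrink <- rep(1, n)
  shrink[S] <- delta / (lambda[S] + delta)
  list(loglik = ll, sigma_g2 = s2, sigma_e2 = delta * s2, fixed_effects = b,
       rss_blup = sum((rfix * shrink)^2))
}

#' Rotated LMM log-likelihood at a fixed variance ratio
#'
#' Evaluates the (profiled) Gaussian log-likelihood of the model
#' `y ~ N(W b, sigma_g2 * U_S diag(lambda_S) U_S' + sigma_e2 * I)` at a given
#' `delta = sigma_e2/sigma_g2`, profiling out `sigma_g2` and the fixed
#' effects in closed form. With an empty `included_pcs` the model is
#' ordinary least squares and `delta` is ignored.
#'
#' @param y numeric phenotype vector.
#' @param covariates fixed-effects matrix (intercept added if absent);
#'   `NULL` means intercept only.
#' @param spectrum an `eigen_spectrum`.
#' @param included_pcs integer indices of principal components in the
#'   random effect.
#' @param delta variance ratio `sigma_e2 / sigma_g2` (>= 0; `Inf` allowed).
#' @param method `"ML"` or `"REML"`.
#' @return List with `loglik`, `sigma_g2`, `sigma_e2`, `fixed_effects`.
#' @export
rotated_loglik <- function(y, covariates = NULL, spectrum, included_pcs,
                           delta, method = c("ML", "REML")) {
  method <- match.arg(method)
  n <- length(y)
  if (n != spectrum$n) stop_value("phenotype length %d != spectrum n %d",
                                  n, spectrum$n)
  W <- build_design(n, covariates)
  yt <- drop(crossprod(spectrum$vectors, y))
  Wt <- crossprod(spectrum$vectors, W)
  S <- as.integer(included_pcs)
  if (!length(S) || !is.finite(delta)) {
    out <- ols_profile(yt, Wt, method)
  } else {
    if (delta < 0) stop_value("delta must be >= 0")
    out <- rot_profile(yt, Wt, spectrum$eigenvalues, S, delta, method)
  }
  out[c("loglik", "sigma_g2", "sigma_e2", "fixed_effects")]
}

## Optimize delta for rotated data; returns the full profile at the optimum.
## Grid of `grid_size` log-spaced points followed by golden-section
## refinement between the neighbors of the best grid point; falls back to
## the OLS limit when that has higher likelihood.
fit_rotated <- function(yt, Wt, lambda, S, method,
                        grid = c(1e-5, 1e5), grid_size = 100) {
  ols <- ols_profile(yt, Wt, method)
  if (!length(S)) {
    return(c(ols, list(delta = Inf, converged = TRUE)))
  }
  ld <- seq(log(grid[1]), log(grid[2]), length.out = grid_size)
  ll <- vapply(ld, function(l)
    rot_profile(yt, Wt, lambda, S, exp(l), method)$loglik, numeric(1))
  i <- which.max(ll)
  lo <- ld[max(1L, i - 1L)]
  hi <- ld[min(grid_size, i + 1L)]
  best_l <- ld[i]
  best_ll <- ll[i]
  if (hi > lo) {
    opt <- tryCatch(
      stats::optimize(function(l)
        rot_profile(yt, Wt, lambda, S, exp(l), method)$loglik,
        c(lo, hi), maximum = TRUE, tol = 1e-8),
      error = function(e) NULL)
    if (!is.null(opt) && opt$objective > best_ll) {
      best_l <- opt$maximum
      best_ll <- opt$objective
    } else if (is.null(opt)) {
      warning("delta refinement failed; using best grid point")
    }
  }
  if (ols$loglik >= best_ll) {
    ## boundary solution: no genetic variance
    return(c(ols, list(delta = Inf, converged = TRUE)))
  }
  out <- rot_profile(yt, Wt, lambda, S, exp(best_l), method)
  c(out, list(delta = exp(best_l), converged = TRUE))
}

## Assemble an lmm_fit object from a fit_rotated() result
make_lmm_fit <- function(fit, lambda, S, method, n, n_cov) {
  lam_S <- lambda[S]
  if (!length(S) || !is.finite(fit$delta) || fit$sigma_g2 == 0) {
    edf <- 0
    h2 <- 0
  } else {
    edf <- sum(lam_S / (lam_S + fit$delta))
    ## pseudo-heritability: genetic variance sigma_g2 * tr(K_S)/n over total
    h2 <- 1 / (1 + fit$delta * n / sum(lam_S))
  }
  structure(list(included_pcs = as.integer(S), delta = fit$delta,
                 sigma_g2 = if (is.finite(fit$delta)) fit$sigma_g2 else 0,
                 sigma_e2 = fit$sigma_e2,
                 fixed_effects = fit$fixed_effects, loglik = fit$loglik,
                 method = method, edf = edf, h2 = h2, n = n,
                 n_covariates = n_cov, lambda_sum = sum(lam_S),
                 rss_blup = fit$rss_blup),
            class = "lmm_fit")
}

#' Fit a (possibly low-rank) linear mixed model
#'
#' Maximizes the profile likelihood over the variance ratio
#' `delta = sigma_e2/sigma_g2` on a log-spaced grid (default 100 points on
#' `1e-5 ... 1e5`) followed by golden-section refinement between the best
#' grid neighbors. The random effect spans the principal components in
#' `included_pcs`; the full set gives the standard full-rank LMM, the empty
#' set ordinary least squares.
#'
#' @inheritParams rotated_loglik
#' @param included_pcs indices of principal components in the random effect;
#'   default all.
#' @param method `"ML"` (default) or `"REML"`.
#' @param delta_grid range of the delta grid.
#' @param grid_size number of grid points.
#' @return Object of class `lmm_fit` with fields `included_pcs`, `delta`
#'   (`Inf` when the genetic variance hits zero), `sigma_g2`, `sigma_e2`,
#'   `fixed_effects`, `loglik`, `method`, `edf` (effective degrees of
#'   freedom of the random effect), `h2` (pseudo-heritability), `n`,
#'   `n_covariates`.
#' @export
fit_lmm <- function(y, covariates = NULL, spectrum,
                    included_pcs = seq_len(spectrum$n),
                    method = c("ML", "REML"),
                    delta_grid = c(1e-5, 1e5), grid_size = 100) {
  method <- match.arg(method)
  n <- length(y)
  if (n != spectrum$n) stop_value("phenotype length %d != spectrum n %d",
                                  n, spectrum$n)
  W <- build_design(n, covariates)
  yt <- drop(crossprod(spectrum$vectors, y))
  Wt <- crossprod(spectrum$vectors, W)
  S <- as.integer(included_pcs)
  fit <- fit_rotated(yt, Wt, spectrum$eigenvalues, S, method,
                     grid = delta_grid, grid_size = grid_size)
  make_lmm_fit(fit, spectrum$eigenvalues, S, method, n, ncol(W))
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("lmm_fit (%s): rank %d, loglik %.4f\n", x$method,
              length(x$included_pcs), x$loglik))
  cat(sprintf("  delta = %.4g  sigma_g2 = %.4g  sigma_e2 = %.4g\n",
              x$delta, x$sigma_g2, x$sigma_e2))
  cat(sprintf("  h2 = %.4f  edf = %.3f\n", x$h2, x$edf))
  invisible(x)
}

#' Number of free parameters of a fitted LMM
#'
#' Fixed-effect coefficients plus the two variance components; the
#' per-marker association model (intercept, marker effect, `sigma_g2`,
#' `sigma_e2`) has exactly 4.
#'
#' @param fit an `lmm_fit`.
#' @return Integer count.
#' @export
n_free_parameters <- function(fit) {
  length(fit$fixed_effects) + 2L
}

#' Write an eigen spectrum to a two-file text cache
#'
#' @param spectrum an `eigen_spectrum`.
#' @param values_path TSV for eigenvalues; `vectors_path` TSV for `U`.
#' @param vectors_path see above.
#' @return Invisibly, `values_path`.
#' @export
write_spectrum <- function(spectrum, values_path, vectors_path) {
  utils::write.table(data.frame(pc = seq_len(spectrum$n),
                                eigenvalue = spectrum$eigenvalues),
                     values_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(format(spectrum$vectors, digits = 17), vectors_path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(values_path)
}
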