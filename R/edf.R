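## Effective degrees of freedom (EDF).
##
## For any fit that is linear in the response, y_hat = H y, the EDF is
## trace(H) and generalizes the parameter count of ordinary least squares.
## For the random-effect part of the LMM the hat matrix is
## K_S (K_S + delta I)^{-1}, whose trace reduces to
## sum_j lambda_j / (lambda_j + delta) over the included principal
## components: each component contributes between 0 and 1, more when its
## eigenvalue is large and less when the variance ratio delta is large.

#' EDF of a linear smoother
#'
#' @param h square hat matrix mapping observed to fitted response.
#' @return `trace(h)`.
#' @export
edf_linear_smoother <- function(h) {
  h <- as.matrix(h)
  if (nrow(h) != ncol(h)) stop_value("hat matrix must be square")
  sum(diag(h))
}

#' EDF of the LMM random effect
#'
#' @param eigenvalues eigenvalues of the included principal components
#'   (all >= 0).
#' @param delta variance ratio `sigma_e2 / sigma_g2` (>= 0 or `Inf`).
#' @return Object of class `edf_profile`: `total_edf`, `per_pc` data.frame
#'   (`pc_index`, `eigenvalue`, `contribution`), `delta`.
#' @export
edf_mixed <- function(eigenvalues, delta) {
  if (any(eigenvalues < 0)) stop_value("negative eigenvalue")
  if (length(delta) != 1 || is.na(delta) || delta < 0)
    stop_value("delta must be a single value >= 0")
  if (is.infinite(delta)) {
    contrib <- rep(0, length(eigenvalues))
  } else if (delta == 0) {
    contrib <- as.numeric(eigenvalues > 0)
  } else {
    contrib <- eigenvalues / (eigenvalues + delta)
  }
  structure(list(total_edf = sum(contrib),
                 per_pc = data.frame(pc_index = seq_along(eigenvalues),
                                     eigenvalue = eigenvalues,
                                     contribution = contrib),
                 delta = delta),
            class = "edf_profile")
}

#' @export
print.edf_profile <- function(x, ...) {
  cat(sprintf("edf_profile: total = %.4f over %d PCs (delta = %.4g)\n",
              x$total_edf, nrow(x$per_pc), x$delta))
  invisible(x)
}

#' Write an EDF profile as TSV
#'
#' @param profile an `edf_profile`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_edf_profile <- function(profile, path) {
  utils::write.table(profile$per_pc, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Likelihood-profile confidence interval for the EDF
#'
#' Evaluates the profile log-likelihood of the fitted model on a fine
#' log-spaced grid of `delta` values around the MLE, keeps the region where
#' `2 * (loglik_max - loglik(delta))` stays below the `chi^2_1` quantile at
#' `1 - alpha`, and maps the delta interval endpoints through the
#' (monotone decreasing) EDF formula. These intervals follow a standard
#' asymptotic likelihood-ratio argument and are illustrative rather than
#' statistically optimal.
#'
#' @param fit an `lmm_fit` with a finite `delta` MLE.
#' @param spectrum the `eigen_spectrum` used for the fit.
#' @param y,covariates the data the model was fit to.
#' @param alpha type-I error of the interval (default 0.05).
#' @param n_grid number of delta grid points (default 400).
#' @param span one-sided grid span as a multiplicative factor on the MLE
#'   (default `1e4`).
#' @return List with `lower`, `upper` (EDF bounds), `delta_interval`,
#'   `censored` (logical pair flagging bounds that hit the widened grid
#'   boundary).
#' @export
edf_confidence_interval <- function(fit, spectrum, y, covariates = NULL,
                                    alpha = 0.05, n_grid = 400, span = 1e4) {
  if (!is.finite(fit$delta))
    stop_value("fit has no finite delta MLE (no genetic variance)")
  if (alpha >= 1) {  # degenerate interval at the MLE
    e <- edf_mixed(spectrum$eigenvalues[fit$included_pcs], fit$delta)$total_edf
    return(list(lower = e, upper = e,
                delta_interval = c(fit$delta, fit$delta),
                censored = c(FALSE, FALSE)))
  }
  n <- length(y)
  W <- build_design(n, covariates)
  yt <- drop(crossprod(spectrum$vectors, y))
  Wt <- crossprod(spectrum$vectors, W)
  S <- fit$included_pcs
  lam <- spectrum$eigenvalues
  crit <- stats::qchisq(1 - alpha, df = 1) / 2
  scan_grid <- function(span) {
    ld <- sort(unique(c(log(fit$delta),
                        seq(log(fit$delta / span), log(fit$delta * span),
                            length.out = n_grid))))
    ll <- vapply(ld, function(l)
      rot_profile(yt, Wt, lam, S, exp(l), fit$method)$loglik, numeric(1))
    list(ld = ld, ll = ll)
  }
  g <- scan_grid(span)
  llmax <- max(g$ll, fit$loglik)
  ok <- g$ll >= llmax - crit
  censored <- c(ok[1], ok[length(ok)])
  if (any(censored)) {
    warning("confidence interval hit the delta grid boundary; widening")
    g <- scan_grid(span^2)
    ok <- g$ll >= max(g$ll, fit$loglik) - crit
    censored <- c(ok[1], ok[length(ok)])
  }
  if (!any(ok)) {  # alpha = 1 degenerate case: interval collapses at the MLE
    d_lo <- d_hi <- fit$delta
  } else {
    d_lo <- exp(min(g$ld[ok]))
    d_hi <- exp(max(g$ld[ok]))
  }
  ## EDF is decreasing in delta: small delta -> upper EDF bound
  list(lower = edf_mixed(lam[S], d_hi)$total_edf,
       upper = edf_mixed(lam[S], d_lo)$total_edf,
       delta_interval = c(d_lo, d_hi),
       censored = censored)
}
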