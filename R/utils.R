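#' @keywords internal
"_PACKAGE"

## Run an expression under a local RNG seed, restoring the caller's
## .Random.seed afterwards so generators never leak global state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

stop_value <- function(...) stop(sprintf(...), call. = FALSE)

## log|A'A| from a QR decomposition of A (sum of log squared R diagonals)
logdet_crossprod <- function(qr_obj) {
  d <- abs(diag(qr.R(qr_obj)))
  2 * sum(log(d))
}

## Build the fixed-effects design matrix: intercept always first.
build_design <- function(n, covariates = NULL) {
  if (is.null(covariates)) return(matrix(1, n, 1, dimnames = list(NULL, "intercept")))
  covariates <- as.matrix(covariates)
  if (nrow(covariates) != n)
    stop_value("covariates have %d rows but phenotype has length %d",
               nrow(covariates), n)
  ## add an intercept unless some column is already constant
  has_const <- any(apply(covariates, 2, function(x) all(x == x[1])))
  if (!has_const) covariates <- cbind(intercept = 1, covariates)
  covariates
}
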