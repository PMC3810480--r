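## Genotype, phenotype and similarity-matrix I/O plus marker standardization.
##
## Genotypes are additive minor-allele dosages in {0, 1, 2}; NA encodes a
## missing call. Two on-disk formats are supported: PLINK `--recode A` (.raw)
## and a plain sample x marker TSV with a marker-metadata sidecar.

#' Construct a genotype matrix object
#'
#' Container for an n x m additive dosage matrix with per-marker metadata.
#' Non-missing dosages must be 0, 1 or 2 (number of copies of the minor
#' allele); `NA` encodes a missing call.
#'
#' @param dosages numeric matrix, samples in rows, markers in columns.
#' @param sample_ids character vector of unique sample identifiers.
#' @param markers data.frame with columns `id`, `chrom`, `pos` (1-based bp)
#'   and `allele`; `id` must be unique.
#' @return An object of class `genotype_matrix` with fields `dosages`,
#'   `sample_ids`, `markers`.
#' @export
genotype_matrix <- function(dosages, sample_ids, markers) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (length(sample_ids) != nrow(dosages))
    stop_value("%d sample ids for %d rows", length(sample_ids), nrow(dosages))
  if (anyDuplicated(sample_ids)) stop_value("duplicate sample ids")
  if (anyDuplicated(markers$id)) stop_value("duplicate marker ids")
  if (nrow(markers) != ncol(dosages))
    stop_value("%d marker records for %d columns", nrow(markers), ncol(dosages))
  bad <- which(!is.na(dosages) & !(dosages %in% c(0, 1, 2)))
  if (length(bad)) {
    j <- ((bad[1] - 1) %/% nrow(dosages)) + 1
    stop_value("invalid dosage %s for marker '%s' (allowed: 0, 1, 2, NA)",
               format(dosages[bad[1]]), markers$id[j])
  }
  if (any(!is.na(markers$pos) & markers$pos < 0))
    stop_value("negative marker position")
  dimnames(dosages) <- list(sample_ids, markers$id)
  structure(list(dosages = dosages, sample_ids = as.character(sample_ids),
                 markers = markers),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d markers (%.2f%% missing)\n",
              nrow(x$dosages), ncol(x$dosages),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Read genotype dosages from disk
#'
#' Supports PLINK additive coding (`--recode A`, header
#' `FID IID PAT MAT SEX PHENOTYPE` followed by one `markerid_allele` column
#' per marker) and a plain TSV (first column `sample_id`, one column per
#' marker) with an optional sidecar TSV holding marker metadata
#' (columns `id`, `chrom`, `pos`).
#'
#' @param path path to the genotype file.
#' @param format `"plink_raw"` or `"tsv"`.
#' @param sidecar optional path to the marker-metadata TSV (tsv format only).
#' @param missing_token token mapped to a missing call (default `"NA"`).
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("plink_raw", "tsv"),
                           sidecar = NULL, missing_token = "NA") {
  format <- match.arg(format)
  if (!file.exists(path)) stop_value("genotype file not found: %s", path)
  if (format == "plink_raw") {
    lines <- readLines(path)
    if (!length(lines)) stop_value("empty genotype file: %s", path)
    header <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
    fixed <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (length(header) < 7 || !identical(header[1:6], fixed))
      stop_value("not a PLINK .raw header (expected FID IID PAT MAT SEX PHENOTYPE ...)")
    marker_cols <- header[-(1:6)]
    ## column names follow the "id_allele" convention
    allele <- sub("^.*_", "", marker_cols)
    id <- sub("_[^_]*$", "", marker_cols)
    n_field <- length(header)
    rows <- lapply(seq_along(lines)[-1], function(i) {
      f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
      if (length(f) != n_field)
        stop_value("line %d has %d fields, expected %d", i, length(f), n_field)
      f
    })
    sample_ids <- vapply(rows, function(f) f[2], "")
    raw <- t(vapply(rows, function(f) f[-(1:6)], character(length(marker_cols))))
    raw[raw == missing_token] <- NA
    dos <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
    if (any(is.na(dos) & !is.na(raw)))
      stop_value("non-numeric dosage token in %s", path)
    markers <- data.frame(id = id, chrom = NA_character_, pos = NA_real_,
                          allele = allele, stringsAsFactors = FALSE)
    genotype_matrix(dos, sample_ids, markers)
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE,
                             na.strings = missing_token)
    if (ncol(tab) < 2) stop_value("TSV genotype file needs sample_id + markers")
    sample_ids <- as.character(tab[[1]])
    dos <- as.matrix(tab[, -1, drop = FALSE])
    markers <- data.frame(id = colnames(dos), chrom = NA_character_,
                          pos = NA_real_, allele = NA_character_,
                          stringsAsFactors = FALSE)
    if (!is.null(sidecar)) {
      meta <- utils::read.table(sidecar, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
      idx <- match(markers$id, meta$id)
      if (anyNA(idx))
        stop_value("sidecar is missing marker '%s'", markers$id[which(is.na(idx))[1]])
      markers$chrom <- as.character(meta$chrom[idx])
      markers$pos <- as.numeric(meta$pos[idx])
      if ("allele" %in% names(meta)) markers$allele <- meta$allele[idx]
    }
    genotype_matrix(dos, sample_ids, markers)
  }
}

#' Write genotypes as TSV + marker sidecar
#'
#' @param g a [genotype_matrix()].
#' @param path output TSV path (sample_id column + one column per marker).
#' @param sidecar optional path for the marker metadata TSV.
#' @return Invisibly, `path`.
#' @export
write_genotypes <- function(g, path, sidecar = NULL) {
  tab <- data.frame(sample_id = g$sample_ids, g$dosages,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sidecar))
    utils::write.table(g$markers, sidecar, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

#' Read a phenotype file (FID IID VALUE, whitespace-delimited, no header)
#'
#' @param path file path.
#' @return Named numeric vector of phenotype values, names = IID.
#' @export
read_phenotype <- function(path) {
  if (!file.exists(path)) stop_value("phenotype file not found: %s", path)
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 3) stop_value("phenotype file needs FID IID VALUE columns")
  y <- as.numeric(tab[[3]])
  names(y) <- as.character(tab[[2]])
  y
}

#' Write a phenotype file (FID IID VALUE)
#'
#' @param y named numeric vector (names used as both FID and IID).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_phenotype <- function(y, path) {
  ids <- names(y)
  if (is.null(ids)) ids <- as.character(seq_along(y))
  utils::write.table(data.frame(ids, ids, unname(y)), path, sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Standardize genotype dosages
#'
#' Mean-imputes missing calls, centers each marker at twice its estimated
#' allele frequency and (for `"patterson"` scaling) divides by
#' `sqrt(p*(1-p))`. Monomorphic markers carry no information about
#' relatedness and are dropped.
#'
#' @param g a [genotype_matrix()].
#' @param missing_policy only `"mean_impute"` is supported.
#' @param scaling `"patterson"` (center and scale by `sqrt(p(1-p))`) or
#'   `"center_only"`.
#' @return Object of class `standardized_genotypes` with fields `values`
#'   (n x m_kept), `allele_freqs`, `kept_marker_index`, `markers`,
#'   `sample_ids`, `scaling`, `missing_rate`.
#' @export
standardize_genotypes <- function(g, missing_policy = "mean_impute",
                                  scaling = c("patterson", "center_only")) {
  missing_policy <- match.arg(missing_policy, "mean_impute")
  scaling <- match.arg(scaling)
  if (nrow(g$dosages) < 2) stop_value("need at least 2 samples")
  x <- g$dosages
  miss_rate <- mean(is.na(x))
  ## allele frequency from non-missing dosages: p = mean(dosage)/2
  p <- unname(colMeans(x, na.rm = TRUE) / 2)
  keep <- which(!is.na(p) & p > 0 & p < 1)
  if (!length(keep)) stop_value("no informative markers")
  x <- x[, keep, drop = FALSE]
  p <- p[keep]
  ## mean imputation: missing -> 2p, i.e. 0 after centering
  ctr <- sweep(x, 2, 2 * p, "-")
  ctr[is.na(ctr)] <- 0
  if (scaling == "patterson")
    ctr <- sweep(ctr, 2, sqrt(p * (1 - p)), "/")
  structure(list(values = ctr, allele_freqs = unname(p),
                 kept_marker_index = keep,
                 markers = g$markers[keep, , drop = FALSE],
                 sample_ids = g$sample_ids, scaling = scaling,
                 missing_rate = miss_rate),
            class = "standardized_genotypes")
}

#' Build a genetic similarity matrix
#'
#' `"standardized_grm"` is the usual genetic relationship matrix
#' `X X' / m` over standardized markers. `"gower_centered"` additionally
#' applies Gower's double-centering and rescales so the trace equals the
#' sample size.
#'
#' @param x a `standardized_genotypes` object.
#' @param metric `"standardized_grm"` or `"gower_centered"`.
#' @return Object of class `similarity_matrix` with fields `values` (n x n),
#'   `metric_name`, `n_markers_used`, `sample_ids`.
#' @export
compute_similarity <- function(x, metric = c("standardized_grm", "gower_centered")) {
  metric <- match.arg(metric)
  m <- ncol(x$values)
  if (!m) stop_value("no retained markers")
  k <- tcrossprod(x$values) / m
  if (metric == "gower_centered") {
    n <- nrow(k)
    k <- k - matrix(colMeans(k), n, n, byrow = TRUE)
    k <- k - matrix(rowMeans(k), n, n)
    ## double-centering leaves row/col means at 0; rescale trace to n
    k <- k * (n / sum(diag(k)))
  }
  k <- (k + t(k)) / 2
  dimnames(k) <- list(x$sample_ids, x$sample_ids)
  structure(list(values = k, metric_name = metric, n_markers_used = m,
                 sample_ids = x$sample_ids),
            class = "similarity_matrix")
}

#' Similarity matrix from phenotype-selected top markers
#'
#' Runs an uncorrected per-marker linear scan of `y` on each standardized
#' marker and builds a standardized GRM from the `n_top` most associated
#' markers only (the marker-selection similarity used by low-rank LMM
#' variants that condition the similarity on the phenotype).
#'
#' @param g a [genotype_matrix()].
#' @param y numeric phenotype vector aligned to `g$sample_ids`.
#' @param n_top number of markers to keep (1 <= n_top <= retained markers).
#' @return A `similarity_matrix`; attribute `selected_markers` records the
#'   chosen marker ids.
#' @export
similarity_from_top_markers <- function(g, y, n_top) {
  if (n_top < 1) stop_value("n_top must be >= 1")
  s <- standardize_genotypes(g)
  m <- ncol(s$values)
  if (n_top > m) stop_value("n_top (%d) exceeds %d informative markers", n_top, m)
  n <- length(y)
  yc <- y - mean(y)
  xc <- sweep(s$values, 2, colMeans(s$values), "-")
  sxx <- colSums(xc^2)
  sxy <- drop(crossprod(xc, yc))
  beta <- sxy / sxx
  rss <- pmax(sum(yc^2) - beta * sxy, 0)  # clamp: exact fits underflow below 0
  se <- sqrt(rss / (n - 2) / sxx)
  p <- 2 * stats::pt(-abs(beta / se), df = n - 2)
  ord <- order(p, seq_len(m))[seq_len(n_top)]
  sel <- sort(ord)
  k <- tcrossprod(s$values[, sel, drop = FALSE]) / n_top
  k <- (k + t(k)) / 2
  dimnames(k) <- list(s$sample_ids, s$sample_ids)
  out <- structure(list(values = k, metric_name = "top_markers_grm",
                        n_markers_used = n_top, sample_ids = s$sample_ids),
                   class = "similarity_matrix")
  attr(out, "selected_markers") <- s$markers$id[sel]
  out
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("similarity_matrix (%s): %d x %d from %d markers\n",
              x$metric_name, nrow(x$values), ncol(x$values), x$n_markers_used))
  invisible(x)
}

#' Write a similarity matrix as text
#'
#' Format: first line is the sample count, second line a tab-separated id
#' header, then one row per sample (id followed by n values).
#'
#' @param k a `similarity_matrix`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_grm <- function(k, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(k$values)
  writeLines(as.character(n), con)
  writeLines(paste(c("id", k$sample_ids), collapse = "\t"), con)
  for (i in seq_len(n))
    writeLines(paste(c(k$sample_ids[i],
                       formatC(k$values[i, ], format = "g", digits = 17)),
                     collapse = "\t"), con)
  invisible(path)
}

#' Read a similarity matrix written by [write_grm()]
#'
#' @param path file path.
#' @param tol asymmetry tolerance.
#' @return A `similarity_matrix`.
#' @export
read_grm <- function(path, tol = 1e-8) {
  if (!file.exists(path)) stop_value("GRM file not found: %s", path)
  lines <- readLines(path)
  n <- as.integer(lines[1])
  if (is.na(n) || length(lines) < n + 2)
    stop_value("malformed GRM file: %s", path)
  header <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  ids <- header[-1]
  if (length(ids) != n) stop_value("GRM header has %d ids, expected %d",
                                   length(ids), n)
  vals <- matrix(NA_real_, n, n)
  row_ids <- character(n)
  for (i in seq_len(n)) {
    f <- strsplit(lines[i + 2], "\t", fixed = TRUE)[[1]]
    if (length(f) != n + 1) stop_value("GRM row %d is not square", i)
    row_ids[i] <- f[1]
    vals[i, ] <- as.numeric(f[-1])
  }
  if (!identical(row_ids, ids)) stop_value("GRM row ids do not match header")
  if (max(abs(vals - t(vals))) > tol)
    stop_value("GRM is asymmetric beyond tolerance %g", tol)
  vals <- (vals + t(vals)) / 2
  dimnames(vals) <- list(ids, ids)
  structure(list(values = vals, metric_name = "file", n_markers_used = NA_integer_,
                 sample_ids = ids),
            class = "similarity_matrix")
}
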