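## Scoring association scans against simulation truth.
##
## A significant marker counts as a true positive when its squared genotype
## correlation with some causal marker reaches the r^2 cutoff, and a false
## positive otherwise. Hits of either kind within 100 kb on the same
## chromosome merge into a single cluster, so one confounded region cannot
## dominate the false-positive count. Power is the number of causal markers
## tagged by at least one true positive.

## positional clustering: ids -> number of <=gap_bp-separated clusters
count_clusters <- function(chrom, pos, gap_bp) {
  if (!length(chrom)) return(0L)
  o <- order(chrom, pos)
  chrom <- chrom[o]; pos <- pos[o]
  new_cluster <- c(TRUE, chrom[-1] != chrom[-length(chrom)] |
                     diff(pos) > gap_bp)
  sum(new_cluster)
}

#' Classify significant markers against simulation truth
#'
#' @param hits character vector of significant marker ids.
#' @param truth truth list from [simulate_phenotype()] (uses
#'   `causal_marker_ids`).
#' @param g the [genotype_matrix()] the scan was run on (marker positions
#'   are required for clustering).
#' @param r2_cutoff squared-correlation threshold for a hit to tag a causal
#'   marker (default 0.1; report alongside results).
#' @param cluster_bp maximum within-cluster gap (default 100000).
#' @return List with `n_true_clusters`, `n_false_clusters`,
#'   `tagged_causal` (causal ids tagged by >= 1 true positive), `tp_ids`,
#'   `fp_ids`.
#' @export
classify_hits <- function(hits, truth, g, r2_cutoff = 0.1, cluster_bp = 1e5) {
  if (r2_cutoff <= 0 || r2_cutoff >= 1) stop_value("r2_cutoff must lie in (0,1)")
  mk <- g$markers
  idx <- match(hits, mk$id)
  if (anyNA(idx)) stop_value("hit '%s' is not a tested marker",
                             hits[which(is.na(idx))[1]])
  if (length(idx) && anyNA(mk$pos[idx]))
    stop_value("marker positions are required for clustering")
  causal <- truth$causal_marker_ids
  cidx <- match(causal, mk$id)
  if (length(hits) && length(causal)) {
    r2 <- stats::cor(g$dosages[, idx, drop = FALSE],
                     g$dosages[, cidx, drop = FALSE])^2
    r2[is.na(r2)] <- 0
    is_tp <- apply(r2, 1, max) >= r2_cutoff
    tagged <- if (any(is_tp))
      causal[apply(r2[is_tp, , drop = FALSE], 2, max) >= r2_cutoff]
    else character(0)
  } else {
    is_tp <- rep(FALSE, length(hits))
    tagged <- character(0)
  }
  tp <- idx[is_tp]; fp <- idx[!is_tp]
  list(n_true_clusters = count_clusters(mk$chrom[tp], mk$pos[tp], cluster_bp),
       n_false_clusters = count_clusters(mk$chrom[fp], mk$pos[fp], cluster_bp),
       tagged_causal = tagged,
       tp_ids = mk$id[tp], fp_ids = mk$id[fp])
}

#' Power at a cluster-level false discovery rate
#'
#' Sweeps the p-value threshold over the observed p-values; at each
#' threshold the cluster-level FDR is
#' `false_clusters / (false_clusters + true_clusters)`. The report is taken
#' at the most permissive threshold whose FDR stays at or below `fdr`;
#' power is the number of causal markers tagged by true positives there.
#'
#' @param result an `assoc_result`.
#' @param truth,g,r2_cutoff,cluster_bp as in [classify_hits()].
#' @param fdr target false discovery rate (default 0.05).
#' @return Object of class `power_report`: `fdr_target`, `p_threshold`,
#'   `n_true_clusters`, `n_false_clusters`, `power` (causal markers
#'   tagged), `tagged_causal`, `n_causal`.
#' @export
power_at_fdr <- function(result, truth, g, fdr = 0.05, r2_cutoff = 0.1,
                         cluster_bp = 1e5) {
  rec <- result$records[result$records$flag == "ok", ]
  mk <- g$markers
  idx <- match(rec$marker_id, mk$id)
  if (anyNA(mk$pos[idx])) stop_value("marker positions are required for clustering")
  causal <- truth$causal_marker_ids
  ## a marker's TP/FP label does not depend on the threshold: precompute
  if (length(causal)) {
    r2 <- stats::cor(g$dosages[, idx, drop = FALSE],
                     g$dosages[, match(causal, mk$id), drop = FALSE])^2
    r2[is.na(r2)] <- 0
    is_tp <- apply(r2, 1, max) >= r2_cutoff
  } else {
    r2 <- NULL
    is_tp <- rep(FALSE, nrow(rec))
  }
  o <- order(rec$p)
  thresholds <- unique(rec$p[o])
  best <- NULL
  for (thr in thresholds) {
    in_set <- rec$p <= thr
    tp <- which(in_set & is_tp); fp <- which(in_set & !is_tp)
    ntc <- count_clusters(mk$chrom[idx[tp]], mk$pos[idx[tp]], cluster_bp)
    nfc <- count_clusters(mk$chrom[idx[fp]], mk$pos[idx[fp]], cluster_bp)
    f <- if (ntc + nfc == 0) 0 else nfc / (ntc + nfc)
    if (f <= fdr)
      best <- list(thr = thr, ntc = ntc, nfc = nfc, tp = tp)
  }
  if (is.null(best)) {
    out <- list(fdr_target = fdr, p_threshold = NA_real_,
                n_true_clusters = 0L, n_false_clusters = 0L, power = 0L,
                tagged_causal = character(0), n_causal = length(causal))
  } else {
    tagged <- if (length(causal) && length(best$tp))
      causal[apply(r2[best$tp, , drop = FALSE], 2, max) >= r2_cutoff]
    else character(0)
    out <- list(fdr_target = fdr, p_threshold = best$thr,
                n_true_clusters = best$ntc, n_false_clusters = best$nfc,
                power = length(tagged), tagged_causal = tagged,
                n_causal = length(causal))
  }
  structure(out, class = "power_report")
}

#' @export
print.power_report <- function(x, ...) {
  cat(sprintf(
    "power_report: %d/%d causal markers tagged at FDR <= %.0f%% (p <= %s)\n",
    x$power, x$n_causal, 100 * x$fdr_target, format(x$p_threshold)))
  cat(sprintf("  clusters: %d true, %d false\n",
              x$n_true_clusters, x$n_false_clusters))
  invisible(x)
}

#' Mean squared error of heritability estimates
#'
#' @param estimates numeric vector of estimated heritabilities.
#' @param true_h2 the generating heritability.
#' @return `mean((estimates - true_h2)^2)`.
#' @export
heritability_mse <- function(estimates, true_h2) {
  if (!length(estimates)) stop_value("no estimates supplied")
  mean((estimates - true_h2)^2)
}
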