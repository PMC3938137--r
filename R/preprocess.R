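## Quantile normalization and the three probe-filtering rules.
## Retention semantics for the background filters: a probe is removed only
## when EVERY sample fails the criterion, so a transcript detected in part
## of the samples is never discarded.

#' Quantile-normalize an expression dataset
#'
#' Forces the intensity distribution of every sample to the common reference
#' distribution (the rank-wise mean across samples): after normalization the
#' multiset of values is identical in every column while the within-sample
#' rank order of probes is preserved. Ties within a column receive the mean
#' of the reference values at the ranks they occupy.
#'
#' @param data an [ExpressionDataset-class] with >= 2 samples and no missing
#'   intensities.
#' @return a new [ExpressionDataset-class] with normalized intensities
#'   (detection p-values, if any, are carried over unchanged).
#' @export
quantileNormalize <- function(data) {
  x <- intensities(data)
  if (ncol(x) < 2L) stop("quantile normalization needs >= 2 samples")
  if (anyNA(x))
    stop("missing intensities present; impute or subset before normalizing")
  ref <- rowMeans(apply(x, 2L, sort))
  out <- x
  for (j in seq_len(ncol(x))) {
    col <- x[, j]
    v <- ref[rank(col, ties.method = "first")]
    # tied input values share the mean of the reference values they occupy
    v <- stats::ave(v, match(col, col), FUN = mean)
    out[, j] <- v
  }
  ExpressionDataset(out, detection = detectionPValues(data),
                    annotation = probeAnnotation(data))
}

## internal: subset keeping probe order, build the audit record
applyProbeFilter <- function(data, keep, rule, threshold) {
  ids <- probeIds(data)
  removed <- ids[!keep]
  report <- methods::new("FilterReport", rule = rule,
                         threshold = as.numeric(threshold),
                         before = length(ids),
                         after = as.integer(sum(keep)), removed = removed)
  list(data = data[keep, ], report = report)
}

#' Filter probes by detection p-value
#'
#' A probe is removed only when its detection p-value exceeds `alpha` in
#' every sample; detection in any single sample retains the probe.
#'
#' @param data an [ExpressionDataset-class] carrying a detection assay.
#' @param alpha detection p-value threshold in (0, 1).
#' @return a list with elements `data` (filtered dataset, survivor order
#'   preserved) and `report` (a [FilterReport-class]).
#' @export
filterByDetection <- function(data, alpha) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  det <- detectionPValues(data)
  if (is.null(det))
    stop("no detection p-values available; use filterByIntensity instead")
  keep <- rowSums(det <= alpha) > 0L
  applyProbeFilter(data, keep, "detection", alpha)
}

#' Filter probes by intensity floor
#'
#' A probe is removed only when its intensity is below `floor` in every
#' sample (the background-estimate route when detection p-values are
#' unavailable).
#'
#' @param data an [ExpressionDataset-class].
#' @param floor non-negative intensity threshold.
#' @return a list with elements `data` and `report` as in
#'   [filterByDetection()].
#' @export
filterByIntensity <- function(data, floor) {
  stopifnot(is.numeric(floor), length(floor) == 1L, floor >= 0)
  x <- intensities(data)
  keep <- rowSums(x >= floor) > 0L
  applyProbeFilter(data, keep, "intensity", floor)
}

#' Filter the lowest-variance probes
#'
#' Removes the `floor(fraction * n_probes)` probes with smallest unbiased
#' across-sample variance; ties at the cut boundary are broken by stable
#' input order (the earlier probe is removed first).
#'
#' @param data an [ExpressionDataset-class] with >= 2 samples.
#' @param fraction fraction of probes to remove, in [0, 1).
#' @return a list with elements `data` and `report` as in
#'   [filterByDetection()].
#' @export
filterLowVariance <- function(data, fraction) {
  stopifnot(is.numeric(fraction), length(fraction) == 1L,
            fraction >= 0, fraction < 1)
  x <- intensities(data)
  if (ncol(x) < 2L) stop("variance filtering needs >= 2 samples")
  if (anyNA(x)) stop("missing intensities present; impute or subset first")
  v <- apply(x, 1L, var)
  k <- floor(fraction * nrow(x))
  drop_idx <- order(v, seq_along(v))[seq_len(k)]
  keep <- !(seq_len(nrow(x)) %in% drop_idx)
  applyProbeFilter(data, keep, "low_variance", fraction)
}
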