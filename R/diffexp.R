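## Two-group volcano differential expression and the time-series trend
## criterion: Pearson correlation of each probe against the sample-order
## ramp A = (1, 2, ..., n), followed by a between/within variance ranking.

#' Per-probe two-group statistics
#'
#' Fold change is the ratio of linear-scale group means
#' (test over control); the p-value comes from a two-sided two-sample t-test
#' on log2 intensities (Welch by default, pooled-variance optional).
#'
#' @param data an [ExpressionDataset-class]; intensities must be strictly
#'   positive for the probes tested.
#' @param groups a [GroupAssignment-class] covering the samples.
#' @param test_level group label of the test condition.
#' @param control_level group label of the control condition.
#' @param var_equal logical; `TRUE` uses the pooled-variance t-test.
#' @param fdr logical; add a Benjamini-Hochberg adjusted p-value column.
#' @return a data.frame with columns `probe_id`, `mean_test`, `mean_control`,
#'   `fold_change`, `log2_fold_change`, `p_value`, `significant` (all FALSE
#'   until [selectVolcano()] is applied) and optionally `adjusted_p`.
#' @export
twoGroupStats <- function(data, groups, test_level, control_level,
                          var_equal = FALSE, fdr = FALSE) {
  g <- sampleGroups(groups)
  sids <- sampleIds(data)
  missing_g <- setdiff(sids, names(g))
  if (length(missing_g))
    stop("samples without a group: ", paste(missing_g, collapse = ", "))
  g <- g[sids]
  ti <- which(g == test_level); ci <- which(g == control_level)
  if (length(ti) < 2L || length(ci) < 2L)
    stop("both groups need >= 2 samples for a variance estimate")
  x <- intensities(data)[, c(ti, ci), drop = FALSE]
  nonpos <- rowSums(!(x > 0), na.rm = TRUE) > 0 | rowSums(is.na(x)) > 0
  if (any(nonpos))
    stop("non-positive or missing intensity for probe(s): ",
         paste(head(probeIds(data)[nonpos], 5), collapse = ", "))
  xt <- intensities(data)[, ti, drop = FALSE]
  xc <- intensities(data)[, ci, drop = FALSE]
  mt <- rowMeans(xt); mc <- rowMeans(xc)
  lt <- log2(xt); lc <- log2(xc)
  p <- vapply(seq_len(nrow(xt)), function(i) {
    a <- lt[i, ]; b <- lc[i, ]
    if (sd(a) == 0 && sd(b) == 0)
      return(if (mean(a) == mean(b)) 1 else 0)
    t.test(a, b, var.equal = var_equal)$p.value
  }, numeric(1))
  res <- data.frame(probe_id = probeIds(data), mean_test = mt,
                    mean_control = mc, fold_change = mt / mc,
                    log2_fold_change = log2(mt / mc), p_value = p,
                    significant = FALSE, row.names = NULL,
                    stringsAsFactors = FALSE)
  if (fdr) res$adjusted_p <- p.adjust(p, method = "BH")
  res
}

#' Volcano double-cutoff selection
#'
#' Keeps probes changed by at least `fc_cutoff`-fold in either direction
#' (`max(fc, 1/fc) >= fc_cutoff`) at `p_value < p_cutoff`, and sets their
#' `significant` flag.
#'
#' @param results data.frame from [twoGroupStats()].
#' @param fc_cutoff linear fold-change cutoff, >= 1.
#' @param p_cutoff p-value cutoff in (0, 1].
#' @return the kept subset (input order preserved) with `significant = TRUE`.
#' @export
selectVolcano <- function(results, fc_cutoff, p_cutoff) {
  stopifnot(nrow(results) > 0)
  if (!is.numeric(fc_cutoff) || fc_cutoff < 1)
    stop("fc_cutoff must be >= 1 (fold changes count in both directions)")
  stopifnot(p_cutoff > 0, p_cutoff <= 1)
  fc <- results$fold_change
  keep <- pmax(fc, 1 / fc) >= fc_cutoff & results$p_value < p_cutoff
  out <- results[keep, , drop = FALSE]
  out$significant <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}

## internal: sample order for time-series analyses -- sort by the position of
## each sample's level in the declared level order, ties broken by input order
timeOrder <- function(data, groups) {
  g <- sampleGroups(groups)
  sids <- sampleIds(data)
  missing_g <- setdiff(sids, names(g))
  if (length(missing_g))
    stop("samples without a group: ", paste(missing_g, collapse = ", "))
  lev <- match(g[sids], groupLevels(groups))
  if (anyNA(lev)) stop("sample group not among declared levels")
  order(lev, seq_along(sids))
}

#' Time-series trend correlation
#'
#' For each probe, the Pearson correlation r between its intensity vector B
#' (samples sorted into time order) and the sample-order ramp
#' A = (1, 2, ..., n). Probes with zero variance have undefined r and are
#' excluded with a warning.
#'
#' @param data an [ExpressionDataset-class] with >= 3 samples.
#' @param groups a [GroupAssignment-class] whose level order is the time
#'   order; ties within a level keep input sample order.
#' @return a data.frame with columns `probe_id` and `r`.
#' @export
timeseriesR <- function(data, groups) {
  if (ncol(data) < 3L) stop("time-series correlation needs >= 3 samples")
  ord <- timeOrder(data, groups)
  x <- intensities(data)[, ord, drop = FALSE]
  if (anyNA(x)) stop("missing intensities present; impute or subset first")
  A <- seq_len(ncol(x))
  sds <- apply(x, 1L, sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0),
            " zero-variance probe(s) excluded (undefined correlation)")
    x <- x[sds > 0, , drop = FALSE]
  }
  r <- as.numeric(cor(t(x), A))
  data.frame(probe_id = rownames(x), r = r, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Select trending probes and rank them
#'
#' Keeps probes with `|r| >= r_threshold` (both rising and falling trends)
#' and ranks them by a signal-to-noise score: the variance of the group
#' (timepoint) means divided by the pooled within-group variance plus a
#' small guard `eps = 1e-9 * var(all intensities)`. Quiet probes with large
#' between-group differences rank first.
#'
#' @param results data.frame from [timeseriesR()].
#' @param data the [ExpressionDataset-class] the correlations came from.
#' @param groups the [GroupAssignment-class] (>= 2 levels).
#' @param r_threshold absolute-correlation threshold in (0, 1).
#' @return a data.frame with columns `probe_id`, `r`, `rank_score`, `rank`,
#'   sorted by descending `rank_score` with ranks `1..k`.
#' @export
selectAndRankTrends <- function(results, data, groups, r_threshold) {
  stopifnot(r_threshold > 0, r_threshold < 1)
  lev <- groupLevels(groups)
  if (length(lev) < 2L) stop("need >= 2 group levels")
  sel <- results[abs(results$r) >= r_threshold, , drop = FALSE]
  if (!nrow(sel))
    return(data.frame(probe_id = character(), r = numeric(),
                      rank_score = numeric(), rank = integer(),
                      stringsAsFactors = FALSE))
  x <- intensities(data)[sel$probe_id, , drop = FALSE]
  g <- sampleGroups(groups)[sampleIds(data)]
  eps <- 1e-9 * var(as.vector(intensities(data)))
  score <- vapply(seq_len(nrow(x)), function(i) {
    b <- split(x[i, ], g)
    means <- vapply(b, mean, numeric(1))
    df <- vapply(b, function(v) length(v) - 1L, numeric(1))
    wss <- vapply(b, function(v) if (length(v) > 1) (length(v) - 1) * var(v)
                                 else 0, numeric(1))
    pooled <- if (sum(df) > 0) sum(wss) / sum(df) else 0
    var(means) / (pooled + eps)
  }, numeric(1))
  ord <- order(score, decreasing = TRUE)
  out <- data.frame(probe_id = sel$probe_id[ord], r = sel$r[ord],
                    rank_score = score[ord],
                    rank = seq_along(ord), row.names = NULL,
                    stringsAsFactors = FALSE)
  out
}

#' Volcano plot coordinates
#'
#' @param results data.frame from [twoGroupStats()] (optionally after
#'   [selectVolcano()] flags were merged back).
#' @return data.frame with `probe_id`, `log2_fold_change`, `neg_log10_p`,
#'   `significant` -- the coordinates of the significance-versus-ratio
#'   scatter.
#' @export
volcanoCoordinates <- function(results) {
  data.frame(probe_id = results$probe_id,
             log2_fold_change = results$log2_fold_change,
             neg_log10_p = -log10(results$p_value),
             significant = results$significant,
             stringsAsFactors = FALSE)
}
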