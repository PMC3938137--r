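## Hierarchical clustering (stats::dist/hclust behind a deterministic
## leaf-ordering rule), a seeded Lloyd k-means with documented empty-cluster
## handling, and the heat-map display transform: log2 then gene-wise mean
## centering.

## internal: display/clustering matrix for gene-wise analyses
geneDisplayMatrix <- function(data, center_genes) {
  x <- intensities(data)
  if (center_genes) {
    if (any(x <= 0, na.rm = TRUE))
      stop("log2 centering requires strictly positive intensities")
    x <- log2(x)
    x <- x - rowMeans(x, na.rm = TRUE)
  }
  x
}

## internal: deterministic leaf order -- at each merge the subtree holding
## the smaller minimum leaf index goes left
leafOrderFromMerge <- function(merge) {
  n <- nrow(merge) + 1L
  orders <- vector("list", nrow(merge))
  minleaf <- integer(nrow(merge))
  getnode <- function(v) {
    if (v < 0) list(ord = -v, min = -v)
    else list(ord = orders[[v]], min = minleaf[v])
  }
  for (i in seq_len(nrow(merge))) {
    a <- getnode(merge[i, 1]); b <- getnode(merge[i, 2])
    if (a$min <= b$min) {
      orders[[i]] <- c(a$ord, b$ord); minleaf[i] <- a$min
    } else {
      orders[[i]] <- c(b$ord, a$ord); minleaf[i] <- b$min
    }
  }
  as.integer(orders[[nrow(merge)]])
}

#' Hierarchical clustering of genes or samples
#'
#' Distances are Euclidean or correlation (1 - Pearson r); linkage is
#' single, complete or average. With `center_genes = TRUE` the expression
#' rows are log2-transformed and mean-centered before distances are
#' computed -- the display pipeline used for gene-wise heat maps. Leaf order
#' is deterministic: at every merge the subtree containing the smaller
#' minimum leaf index is placed on the left.
#'
#' @param data an [ExpressionDataset-class] without missing values.
#' @param axis `"genes"` (cluster rows) or `"samples"` (cluster columns).
#' @param metric `"euclidean"` or `"correlation"`.
#' @param linkage `"single"`, `"complete"` or `"average"`.
#' @param center_genes logical; apply the log2 + gene-wise mean-centering
#'   display transform first.
#' @return a [LinkageTree-class].
#' @export
hierarchicalCluster <- function(data, axis = c("genes", "samples"),
                                metric = c("euclidean", "correlation"),
                                linkage = c("average", "complete", "single"),
                                center_genes = FALSE) {
  axis <- match.arg(axis)
  metric <- match.arg(metric)
  linkage <- match.arg(linkage)
  x <- geneDisplayMatrix(data, center_genes)
  if (anyNA(x)) stop("missing intensities present; impute or subset first")
  m <- if (axis == "genes") x else t(x)
  if (nrow(m) < 2L) stop("need >= 2 items on the clustered axis")
  if (metric == "euclidean") {
    d <- stats::dist(m)
  } else {
    sds <- apply(m, 1L, sd)
    if (any(sds == 0))
      stop("constant row(s) under correlation metric: ",
           paste(head(rownames(m)[sds == 0], 5), collapse = ", "))
    d <- stats::as.dist(1 - cor(t(m)))
  }
  h <- stats::hclust(d, method = linkage)
  methods::new("LinkageTree", merge = h$merge, height = h$height,
               order = leafOrderFromMerge(h$merge),
               labels = rownames(m), axis = axis, metric = metric,
               linkage = linkage)
}

#' Heat-map matrix in display order
#'
#' @param data the [ExpressionDataset-class] that was clustered.
#' @param tree a [LinkageTree-class] from [hierarchicalCluster()] with
#'   `axis = "genes"`.
#' @param center_genes logical; must match the clustering call.
#' @return the (optionally log2 mean-centered) matrix with rows in leaf
#'   order.
#' @export
heatmapMatrix <- function(data, tree, center_genes = TRUE) {
  x <- geneDisplayMatrix(data, center_genes)
  x[tree@labels[tree@order], , drop = FALSE]
}

#' Seeded k-means clustering of expression rows
#'
#' Lloyd iterations on Euclidean distance, best of `n_restarts` random
#' starts by within-cluster sum of squares; fully deterministic given
#' `seed`. If a cluster empties during an update its centroid is re-seeded
#' from the point farthest from its assigned centroid (never an error).
#'
#' @param data an [ExpressionDataset-class] (no missing values).
#' @param k number of clusters, `k <=` number of rows.
#' @param seed integer seed.
#' @param n_restarts number of random restarts, default 10.
#' @param center_genes logical; apply the log2 + mean-centering transform
#'   before clustering.
#' @param max_iter Lloyd iteration cap per restart.
#' @return a list with `cluster` (named assignment of rows to 1..k),
#'   `centers`, `tot_withinss` and `iterations`.
#' @export
kmeansCluster <- function(data, k, seed, n_restarts = 10,
                          center_genes = FALSE, max_iter = 100) {
  x <- geneDisplayMatrix(data, center_genes)
  if (anyNA(x)) stop("missing intensities present; impute or subset first")
  n <- nrow(x)
  if (k > n) stop("k must not exceed the number of items")
  set.seed(as.integer(seed))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    centers <- x[sample.int(n, k), , drop = FALSE]
    assign_old <- integer(n)
    iter <- 0L
    repeat {
      iter <- iter + 1L
      d2 <- outer(rowSums(x^2), rep(1, k)) - 2 * x %*% t(centers) +
        outer(rep(1, n), rowSums(centers^2))
      assignment <- max.col(-d2, ties.method = "first")
      for (j in seq_len(k)) {
        if (!any(assignment == j)) {
          # empty cluster: re-seed from the point farthest from its centroid
          far <- which.max(d2[cbind(seq_len(n), assignment)])
          centers[j, ] <- x[far, ]
          assignment[far] <- j
        }
      }
      for (j in seq_len(k))
        centers[j, ] <- colMeans(x[assignment == j, , drop = FALSE])
      if (identical(assignment, assign_old) || iter >= max_iter) break
      assign_old <- assignment
    }
    wss <- sum((x - centers[assignment, , drop = FALSE])^2)
    if (is.null(best) || wss < best$tot_withinss - 1e-12)
      best <- list(cluster = setNames(assignment, rownames(x)),
                   centers = centers, tot_withinss = wss, iterations = iter)
  }
  best
}
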