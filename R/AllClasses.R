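#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats var sd cor median quantile rnorm runif setNames t.test
#'   ks.test p.adjust
#' @importFrom utils head read.delim write.table
NULL

#' Probe-by-sample expression container
#'
#' `ExpressionDataset` extends
#' [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' with a mandatory `"intensities"` assay (non-negative fluorescence values,
#' `NA` permitted to support the missing-value-tolerant PPCA path) and an
#' optional `"detection"` assay of per-probe, per-sample detection p-values
#' in `[0, 1]` (no `NA`s). Probe identifiers are the rownames and must be
#' unique; an optional `symbol` column in `rowData` carries probe-to-gene
#' annotation.
#'
#' @slot ... inherited from `SummarizedExperiment`.
#' @aliases ExpressionDataset
#' @exportClass ExpressionDataset
setClass("ExpressionDataset", contains = "SummarizedExperiment")

setValidity("ExpressionDataset", function(object) {
  msgs <- character()
  anames <- SummarizedExperiment::assayNames(object)
  if (!("intensities" %in% anames))
    return("assay 'intensities' is required")
  x <- SummarizedExperiment::assay(object, "intensities")
  if (!is.numeric(x))
    msgs <- c(msgs, "intensities must be numeric")
  if (any(x < 0, na.rm = TRUE))
    msgs <- c(msgs, "intensities must be non-negative")
  ids <- rownames(object)
  if (is.null(ids) || anyNA(ids))
    msgs <- c(msgs, "probe identifiers (rownames) are required")
  else if (anyDuplicated(ids))
    msgs <- c(msgs, paste0("duplicate probe identifiers: ",
                           paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msgs <- c(msgs, "sample labels (colnames) must be present and unique")
  if ("detection" %in% anames) {
    d <- SummarizedExperiment::assay(object, "detection")
    if (!identical(dim(d), dim(x)))
      msgs <- c(msgs, "detection table must be shape-identical to intensities")
    if (anyNA(d))
      msgs <- c(msgs, "detection p-values must not be missing")
    else if (any(d < 0 | d > 1))
      msgs <- c(msgs, "detection p-values must lie in [0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an ExpressionDataset
#'
#' @param intensities numeric matrix, probes in rows (rownames = probe IDs),
#'   samples in columns (colnames = sample labels). Values are linear-scale,
#'   non-negative fluorescence intensities; `NA` marks a missing cell.
#' @param detection optional matrix of detection p-values, same shape.
#' @param annotation optional named character vector mapping probe ID to gene
#'   symbol; stored in `rowData(x)$symbol`.
#' @return an [ExpressionDataset-class] object.
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(paste0("P", 1:3), c("S1", "S2")))
#' ExpressionDataset(m)
#' @export
ExpressionDataset <- function(intensities, detection = NULL, annotation = NULL) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  assays <- list(intensities = intensities)
  if (!is.null(detection)) {
    detection <- as.matrix(detection)
    storage.mode(detection) <- "double"
    dimnames(detection) <- dimnames(intensities)
    assays$detection <- detection
  }
  rd <- S4Vectors::DataFrame(row.names = rownames(intensities))
  if (!is.null(annotation)) {
    sym <- annotation[rownames(intensities)]
    rd$symbol <- unname(as.character(sym))
  }
  se <- SummarizedExperiment::SummarizedExperiment(assays = assays, rowData = rd)
  methods::new("ExpressionDataset", se)
}

#' Sample-to-group assignment with ordered levels
#'
#' Maps each sample label to a condition or timepoint. The `levels` slot
#' carries an explicit total order; for time-series data the order is the
#' time order and drives the sample-order ramp used by [timeseriesR()].
#'
#' @slot samples character vector of sample labels.
#' @slot groups character vector, parallel to `samples`.
#' @slot levels character vector of group levels in analysis order.
#' @exportClass GroupAssignment
setClass("GroupAssignment",
  representation(samples = "character", groups = "character",
                 levels = "character"))

setValidity("GroupAssignment", function(object) {
  msgs <- character()
  if (length(object@samples) != length(object@groups))
    msgs <- c(msgs, "samples and groups must be parallel")
  if (anyDuplicated(object@samples))
    msgs <- c(msgs, "duplicate sample labels")
  if (!all(object@groups %in% object@levels))
    msgs <- c(msgs, "every group must appear in levels")
  if (anyDuplicated(object@levels))
    msgs <- c(msgs, "levels must be unique")
  if (length(msgs)) msgs else TRUE
})

#' Construct a GroupAssignment
#'
#' @param samples character vector of sample labels.
#' @param groups character vector of group labels, parallel to `samples`.
#' @param levels optional explicit level order; defaults to first-appearance
#'   order of `groups`.
#' @return a [GroupAssignment-class] object.
#' @export
GroupAssignment <- function(samples, groups, levels = NULL) {
  samples <- as.character(samples)
  groups <- as.character(groups)
  if (is.null(levels)) levels <- unique(groups)
  methods::new("GroupAssignment", samples = samples, groups = groups,
               levels = as.character(levels))
}

#' Named collection of gene sets
#'
#' @slot sets named list of character vectors (unique, upper-cased gene IDs).
#' @slot descriptions named character vector, parallel to `sets`.
#' @exportClass GeneSetCollection
setClass("GeneSetCollection",
  representation(sets = "list", descriptions = "character"))

setValidity("GeneSetCollection", function(object) {
  msgs <- character()
  if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
    msgs <- c(msgs, "set names must be present and unique")
  if (any(lengths(object@sets) == 0))
    msgs <- c(msgs, "sets must be non-empty")
  if (length(msgs)) msgs else TRUE
})

#' Construct a GeneSetCollection
#'
#' Gene identifiers are whitespace-trimmed and upper-cased so set membership
#' lookups are case-insensitive across annotation sources.
#'
#' @param sets named list of character vectors of gene IDs.
#' @param descriptions optional named character vector of set descriptions.
#' @return a [GeneSetCollection-class] object.
#' @export
GeneSetCollection <- function(sets, descriptions = NULL) {
  sets <- lapply(sets, function(g) unique(normalizeGeneIds(g)))
  if (is.null(descriptions))
    descriptions <- setNames(rep("", length(sets)), names(sets))
  methods::new("GeneSetCollection", sets = sets,
               descriptions = descriptions[names(sets)])
}

#' Ontology DAG with gene annotations
#'
#' Terms connected by child-to-parent `is_a` edges (acyclic); roots are the
#' terms with no parents. The annotation map records direct gene-to-term
#' assignments; true-path propagation to ancestors happens at enrichment
#' time, not at load time.
#'
#' @slot terms data.frame with columns `id`, `name`, `namespace`.
#' @slot parents named list: term id -> character vector of parent ids.
#' @slot annotation named list: gene id -> character vector of term ids.
#' @exportClass OntologyGraph
setClass("OntologyGraph",
  representation(terms = "data.frame", parents = "list", annotation = "list"))

setValidity("OntologyGraph", function(object) {
  msgs <- character()
  ids <- object@terms$id
  if (anyDuplicated(ids)) msgs <- c(msgs, "duplicate term ids")
  tgt <- unlist(object@parents, use.names = FALSE)
  if (length(tgt) && !all(tgt %in% ids))
    msgs <- c(msgs, "is_a edge references unknown term")
  ann <- unlist(object@annotation, use.names = FALSE)
  if (length(ann) && !all(ann %in% ids))
    msgs <- c(msgs, "annotation references unknown term")
  if (length(tgt)) {
    edges <- data.frame(
      from = rep(names(object@parents), lengths(object@parents)),
      to = tgt, stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                       vertices = data.frame(name = ids))
    if (!igraph::is_dag(g)) msgs <- c(msgs, "is_a edges contain a cycle")
  }
  if (length(msgs)) msgs else TRUE
})

#' Filtering audit record
#'
#' @slot rule name of the filtering rule applied.
#' @slot threshold numeric threshold used.
#' @slot before number of probes before filtering.
#' @slot after number of probes after filtering.
#' @slot removed character vector of removed probe IDs.
#' @exportClass FilterReport
setClass("FilterReport",
  representation(rule = "character", threshold = "numeric",
                 before = "integer", after = "integer", removed = "character"))

setValidity("FilterReport", function(object) {
  if (object@before - object@after != length(object@removed))
    "before - after must equal the number of removed probes" else TRUE
})

#' Hierarchical clustering result
#'
#' Stores the merge tree in `stats::hclust` layout plus a deterministic
#' display leaf order: at every merge the subtree containing the smaller
#' minimum leaf index is placed on the left.
#'
#' @slot merge integer matrix of merges (hclust convention).
#' @slot height numeric merge heights.
#' @slot order integer display order of leaves.
#' @slot labels character leaf labels.
#' @slot axis `"genes"` or `"samples"`.
#' @slot metric distance metric used.
#' @slot linkage linkage criterion used.
#' @exportClass LinkageTree
setClass("LinkageTree",
  representation(merge = "matrix", height = "numeric", order = "integer",
                 labels = "character", axis = "character",
                 metric = "character", linkage = "character"))

#' Probabilistic PCA model
#'
#' Isotropic-noise Gaussian factor model fitted by EM; missing observations
#' are treated as latent in the E-step, so the observed-data log-likelihood
#' is non-decreasing over iterations.
#'
#' @slot loadings feature-by-component loading matrix W.
#' @slot center feature mean vector (computed over observed entries).
#' @slot sigma2 isotropic noise variance, positive.
#' @slot scores sample-by-component posterior mean scores.
#' @slot loglik observed-data log-likelihood trace, one entry per iteration.
#' @slot converged logical.
#' @exportClass PpcaModel
setClass("PpcaModel",
  representation(loadings = "matrix", center = "numeric", sigma2 = "numeric",
                 scores = "matrix", loglik = "numeric", converged = "logical"))

setValidity("PpcaModel", function(object) {
  if (object@sigma2 <= 0) "sigma2 must be positive" else TRUE
})

## ---- generics and accessors ------------------------------------------------

#' @describeIn ExpressionDataset intensity matrix accessor
#' @param x an object.
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname ExpressionDataset
setMethod("intensities", "ExpressionDataset", function(x)
  SummarizedExperiment::assay(x, "intensities"))

#' @describeIn ExpressionDataset detection p-value matrix (or NULL)
#' @export
setGeneric("detectionPValues", function(x) standardGeneric("detectionPValues"))
#' @rdname ExpressionDataset
setMethod("detectionPValues", "ExpressionDataset", function(x) {
  if ("detection" %in% SummarizedExperiment::assayNames(x))
    SummarizedExperiment::assay(x, "detection") else NULL
})

#' @describeIn ExpressionDataset probe identifiers
#' @export
setGeneric("probeIds", function(x) standardGeneric("probeIds"))
#' @rdname ExpressionDataset
setMethod("probeIds", "ExpressionDataset", function(x) rownames(x))

#' @describeIn ExpressionDataset sample labels
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname ExpressionDataset
setMethod("sampleIds", "ExpressionDataset", function(x) colnames(x))

#' @describeIn ExpressionDataset probe-to-symbol annotation (named vector or NULL)
#' @export
setGeneric("probeAnnotation", function(x) standardGeneric("probeAnnotation"))
#' @rdname ExpressionDataset
setMethod("probeAnnotation", "ExpressionDataset", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  if ("symbol" %in% colnames(rd)) setNames(rd$symbol, rownames(x)) else NULL
})

#' @describeIn GroupAssignment group label per sample (named character)
#' @param x an object.
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))
#' @rdname GroupAssignment
setMethod("sampleGroups", "GroupAssignment", function(x)
  setNames(x@groups, x@samples))

#' @describeIn GroupAssignment ordered group levels
#' @export
setGeneric("groupLevels", function(x) standardGeneric("groupLevels"))
#' @rdname GroupAssignment
setMethod("groupLevels", "GroupAssignment", function(x) x@levels)

#' @describeIn GeneSetCollection named list of member vectors
#' @param x an object.
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))
#' @rdname GeneSetCollection
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @describeIn GeneSetCollection set descriptions
#' @export
setGeneric("setDescriptions", function(x) standardGeneric("setDescriptions"))
#' @rdname GeneSetCollection
setMethod("setDescriptions", "GeneSetCollection", function(x) x@descriptions)

#' @describeIn OntologyGraph term table accessor
#' @param x an object.
#' @export
setGeneric("ontologyTerms", function(x) standardGeneric("ontologyTerms"))
#' @rdname OntologyGraph
setMethod("ontologyTerms", "OntologyGraph", function(x) x@terms)

#' @describeIn OntologyGraph direct gene-to-term annotation map
#' @export
setGeneric("termAnnotation", function(x) standardGeneric("termAnnotation"))
#' @rdname OntologyGraph
setMethod("termAnnotation", "OntologyGraph", function(x) x@annotation)

#' @describeIn OntologyGraph ids of root terms (no outgoing is_a edge)
#' @export
setGeneric("ontologyRoots", function(x) standardGeneric("ontologyRoots"))
#' @rdname OntologyGraph
setMethod("ontologyRoots", "OntologyGraph", function(x) {
  ids <- x@terms$id
  ids[!vapply(ids, function(i) length(x@parents[[i]]) > 0, logical(1))]
})

#' All ancestors of a term (excluding the term itself)
#'
#' Transitive closure over is_a edges, used for true-path annotation
#' propagation.
#'
#' @param ontology an [OntologyGraph-class].
#' @param id a term id.
#' @return character vector of ancestor term ids (possibly empty).
#' @export
termAncestors <- function(ontology, id) {
  seen <- character()
  queue <- ontology@parents[[id]]
  while (length(queue)) {
    t1 <- queue[[1]]; queue <- queue[-1]
    if (!(t1 %in% seen)) {
      seen <- c(seen, t1)
      queue <- c(queue, ontology@parents[[t1]])
    }
  }
  seen
}

## ---- show methods ----------------------------------------------------------

setMethod("show", "GroupAssignment", function(object) {
  cat("GroupAssignment:", length(object@samples), "samples,",
      length(object@levels), "levels\n")
  cat("  levels:", paste(object@levels, collapse = " < "), "\n")
})

setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection:", length(object@sets), "sets; sizes",
      paste(range(lengths(object@sets)), collapse = "-"), "\n")
})

setMethod("show", "OntologyGraph", function(object) {
  cat("OntologyGraph:", nrow(object@terms), "terms,",
      sum(lengths(object@parents)), "is_a edges,",
      length(object@annotation), "annotated genes\n")
})

setMethod("show", "FilterReport", function(object) {
  cat(sprintf("FilterReport [%s, threshold %g]: %d -> %d probes (%d removed)\n",
              object@rule, object@threshold, object@before, object@after,
              length(object@removed)))
})

setMethod("show", "LinkageTree", function(object) {
  cat(sprintf("LinkageTree: %d leaves (%s), metric=%s, linkage=%s\n",
              length(object@labels), object@axis, object@metric,
              object@linkage))
})

setMethod("show", "PpcaModel", function(object) {
  cat(sprintf(
    "PpcaModel: %d features x %d components, sigma2=%.4g, %d EM iterations%s\n",
    nrow(object@loadings), ncol(object@loadings), object@sigma2,
    length(object@loglik), if (object@converged) " (converged)" else ""))
})

#' Convert a LinkageTree to an hclust object
#'
#' @param x a [LinkageTree-class].
#' @param ... ignored.
#' @return an object of class `hclust`.
#' @export
as.hclust.LinkageTree <- function(x, ...) {
  structure(list(merge = x@merge, height = x@height, order = x@order,
                 labels = x@labels, method = x@linkage,
                 call = match.call(), dist.method = x@metric),
            class = "hclust")
}

## internal: canonical gene-id normalization (trim + upper-case)
normalizeGeneIds <- function(x) toupper(trimws(as.character(x)))
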