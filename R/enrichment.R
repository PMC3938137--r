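## Exact hypergeometric over-representation tests. The pmf/tail pair is
## computed in log space (lchoose) so large backgrounds do not overflow;
## an over-representation call uses the upper tail P(X >= x) by default,
## with a density-only compatibility mode.

#' Hypergeometric probability mass
#'
#' P(X = x) when drawing `n` genes without replacement from a background of
#' `M` genes of which `K` are marked: `C(K,x) C(M-K,n-x) / C(M,n)`,
#' evaluated in log space.
#'
#' @param x number of marked genes drawn.
#' @param M background size.
#' @param K marked genes in the background.
#' @param n draw (query) size.
#' @return the point probability.
#' @details Arguments outside the support raise an error rather than
#'   returning zero, so caller bugs surface immediately.
#' @export
hypergeomPmf <- function(x, M, K, n) {
  stopifnot(length(x) == 1, length(M) == 1, length(K) == 1, length(n) == 1)
  if (K < 0 || K > M || n < 0 || n > M)
    stop("require 0 <= K <= M and 0 <= n <= M")
  if (x < max(0, n + K - M) || x > min(n, K))
    stop(sprintf("x = %d outside support [%d, %d]", x,
                 max(0, n + K - M), min(n, K)))
  exp(lchoose(K, x) + lchoose(M - K, n - x) - lchoose(M, n))
}

#' Hypergeometric upper tail
#'
#' P(X >= x) = sum of [hypergeomPmf()] from `x` to `min(n, K)`, clipped into
#' (0, 1]. This is the probability that at least `x` of the `n` drawn genes
#' are marked -- the over-representation p-value.
#'
#' @inheritParams hypergeomPmf
#' @return the tail probability in (0, 1].
#' @export
hypergeomTail <- function(x, M, K, n) {
  if (K < 0 || K > M || n < 0 || n > M)
    stop("require 0 <= K <= M and 0 <= n <= M")
  lo <- max(0, n + K - M)
  if (x < lo || x > min(n, K))
    stop(sprintf("x = %d outside support [%d, %d]", x, lo, min(n, K)))
  p <- sum(vapply(seq.int(x, min(n, K)), hypergeomPmf, numeric(1),
                  M = M, K = K, n = n))
  min(max(p, .Machine$double.xmin), 1)
}

## internal: shared set-up for both enrichment front ends
prepareQuery <- function(query, background) {
  query <- unique(normalizeGeneIds(query))
  background <- unique(normalizeGeneIds(background))
  if (!length(background)) stop("background set is empty")
  if (!length(query)) stop("query set is empty")
  outside <- setdiff(query, background)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the background dropped")
    query <- intersect(query, background)
    if (!length(query)) stop("query set is empty after background restriction")
  }
  list(query = query, background = background)
}

#' Gene-set over-representation test
#'
#' For every set in the collection: `K` = members present in the background,
#' `x` = members present in the query, and the p-value is the hypergeometric
#' upper tail with `M` = background size, `n` = query size. Sets absent from
#' the background (`K = 0`) are skipped. Query genes outside the background
#' are dropped with a warning.
#'
#' @param query character vector of gene ids (duplicates ignored).
#' @param background character vector of gene ids defining the universe.
#' @param collection a [GeneSetCollection-class].
#' @param p_cutoff report only records with `p_value < p_cutoff`, default 1
#'   (report everything).
#' @param pmf_mode logical; `TRUE` reproduces a density-only test, assigning
#'   P(X = x) instead of the upper tail.
#' @param fdr logical; add Benjamini-Hochberg adjusted p-values (computed
#'   across all tested sets before the cutoff is applied).
#' @return data.frame with columns `set`, `name`, `K`, `x`, `n`, `M`,
#'   `p_value` (and `adjusted_p` when `fdr`), sorted ascending by p-value.
#' @export
enrichGeneSets <- function(query, background, collection, p_cutoff = 1,
                           pmf_mode = FALSE, fdr = FALSE) {
  qb <- prepareQuery(query, background)
  sets <- geneSets(collection)
  M <- length(qb$background); n <- length(qb$query)
  K <- vapply(sets, function(s) length(intersect(s, qb$background)),
              integer(1))
  x <- vapply(sets, function(s) length(intersect(s, qb$query)), integer(1))
  keep <- K > 0L
  stat <- if (pmf_mode) hypergeomPmf else hypergeomTail
  p <- mapply(function(xi, Ki) stat(xi, M = M, K = Ki, n = n),
              x[keep], K[keep])
  res <- data.frame(set = names(sets)[keep],
                    name = unname(setDescriptions(collection)[names(sets)[keep]]),
                    K = K[keep], x = x[keep], n = n, M = M, p_value = p,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (fdr) res$adjusted_p <- p.adjust(res$p_value, method = "BH")
  res <- res[res$p_value < p_cutoff, , drop = FALSE]
  res <- res[order(res$p_value, res$set), , drop = FALSE]
  rownames(res) <- NULL
  res
}

## internal: propagate direct annotations to all ancestors (true-path rule)
propagateAnnotation <- function(ontology) {
  ids <- ontology@terms$id
  anc <- setNames(vector("list", length(ids)), ids)
  get_anc <- function(id) {
    if (!is.null(anc[[id]])) return(anc[[id]])
    ps <- ontology@parents[[id]]
    res <- ps
    for (p in ps) res <- union(res, get_anc(p))
    anc[[id]] <<- res
    res
  }
  lapply(ontology@annotation, function(tset) {
    out <- tset
    for (t1 in tset) out <- union(out, get_anc(t1))
    out
  })
}

#' GO-style over-representation test with ancestor propagation
#'
#' Direct annotations are first propagated to every ancestor (a gene
#' annotated to a term counts for all of that term's ancestors); then each
#' term is tested exactly as in [enrichGeneSets()]. Root terms are excluded
#' from the output (they annotate everything).
#'
#' @inheritParams enrichGeneSets
#' @param ontology an [OntologyGraph-class].
#' @return data.frame with columns `term`, `name`, `namespace`, `K`, `x`,
#'   `n`, `M`, `p_value` (and `adjusted_p` when `fdr`), sorted ascending by
#'   p-value.
#' @export
enrichGO <- function(query, background, ontology, p_cutoff = 1,
                     pmf_mode = FALSE, fdr = FALSE) {
  qb <- prepareQuery(query, background)
  full <- propagateAnnotation(ontology)
  # invert gene -> terms into term -> genes, restricted to the background
  genes <- intersect(names(full), qb$background)
  term_genes <- list()
  for (g in genes)
    for (t1 in full[[g]])
      term_genes[[t1]] <- c(term_genes[[t1]], g)
  roots <- ontologyRoots(ontology)
  terms <- setdiff(names(term_genes), roots)
  if (!length(terms))
    return(data.frame(term = character(), name = character(),
                      namespace = character(), K = integer(), x = integer(),
                      n = integer(), M = integer(), p_value = numeric(),
                      stringsAsFactors = FALSE))
  M <- length(qb$background); n <- length(qb$query)
  K <- vapply(term_genes[terms], length, integer(1))
  x <- vapply(term_genes[terms], function(g) length(intersect(g, qb$query)),
              integer(1))
  stat <- if (pmf_mode) hypergeomPmf else hypergeomTail
  p <- mapply(function(xi, Ki) stat(xi, M = M, K = Ki, n = n), x, K)
  info <- ontology@terms[match(terms, ontology@terms$id), ]
  res <- data.frame(term = terms, name = info$name,
                    namespace = info$namespace, K = unname(K), x = unname(x),
                    n = n, M = M, p_value = unname(p),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (fdr) res$adjusted_p <- p.adjust(res$p_value, method = "BH")
  res <- res[res$p_value < p_cutoff, , drop = FALSE]
  res <- res[order(res$p_value, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Export enriched terms and their ancestry as a DOT graph
#'
#' Writes a Graphviz DOT file containing the significant terms plus all of
#' their ancestors and the is_a edges among them. Node fill colour encodes
#' the enrichment strength in five -log10(p) buckets (darker = more
#' significant); ancestor-only nodes are grey.
#'
#' @param records data.frame from [enrichGO()].
#' @param ontology the [OntologyGraph-class] the records came from.
#' @param path output path for the DOT file.
#' @return invisibly, the path written.
#' @export
exportGoGraph <- function(records, ontology, path) {
  sig <- records$term
  nodes <- character()
  for (t1 in sig) nodes <- union(nodes, c(t1, termAncestors(ontology, t1)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("digraph ontology {", con)
  writeLines("  rankdir=BT;", con)
  writeLines("  node [style=filled, shape=box, fontsize=10];", con)
  if (length(nodes)) {
    palette <- c("#fee5d9", "#fcae91", "#fb6a4a", "#de2d26", "#a50f15")
    info <- ontology@terms
    for (nd in nodes) {
      nm <- info$name[match(nd, info$id)]
      if (nd %in% sig) {
        lp <- -log10(records$p_value[match(nd, records$term)])
        bucket <- min(5L, max(1L, ceiling(lp / 2)))
        col <- palette[bucket]
        lab <- sprintf("%s\\n%s\\np=%.2g", nd, nm,
                       records$p_value[match(nd, records$term)])
      } else {
        col <- "#d9d9d9"
        lab <- sprintf("%s\\n%s", nd, nm)
      }
      writeLines(sprintf('  "%s" [label="%s", fillcolor="%s"];', nd, lab, col),
                 con)
    }
    for (nd in nodes)
      for (p in intersect(ontology@parents[[nd]], nodes))
        writeLines(sprintf('  "%s" -> "%s";', nd, p), con)
  }
  writeLines("}", con)
  invisible(path)
}
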