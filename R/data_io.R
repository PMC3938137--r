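## Readers and writers for every external format the pipeline touches.
## Canonical interchange format is delimited text (TSV by default).

#' Read a probe-by-sample expression table
#'
#' The file must have a header row (first field names the probe-ID column,
#' remaining fields are sample labels) and one row per probe. With
#' `has_detection = TRUE` each sample contributes a paired detection column
#' named `"<sample>.detection"` immediately identifiable by that suffix.
#'
#' @param path path to a delimited text file.
#' @param delimiter field separator, default tab.
#' @param has_detection logical; if `TRUE`, detection p-value columns are
#'   expected alongside the intensity columns.
#' @return an [ExpressionDataset-class]; row and column order follow the file.
#' @details Duplicate probe IDs, ragged rows and non-numeric cells are hard
#'   errors; the error message names the offending probes or the row/column
#'   coordinates of the first bad cell. Empty intensity cells are recorded as
#'   `NA` (missing); empty detection cells are not permitted.
#' @export
readExpressionTable <- function(path, delimiter = "\t", has_detection = FALSE) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("expression table needs a header and >=1 row")
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  nf <- lengths(fields)
  if (length(unique(nf)) != 1L)
    stop("ragged rows: line(s) ", paste(which(nf != nf[1]), collapse = ", "),
         " have a different field count than the header")
  header <- fields[[1]]
  cols <- header[-1]
  body <- fields[-1]
  ids <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate probe IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  raw <- t(vapply(body, function(f) f[-1], character(length(cols))))
  if (length(cols) == 1L) raw <- matrix(raw, ncol = 1L)
  num <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw)))
  bad <- which(is.na(num) & !(raw == "" | toupper(raw) == "NA"), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric cell at row %d (probe %s), column '%s': '%s'",
                 bad[1, 1], ids[bad[1, 1]], cols[bad[1, 2]],
                 raw[bad[1, 1], bad[1, 2]]))
  dimnames(num) <- list(ids, cols)
  if (has_detection) {
    det_cols <- grep("\\.detection$", cols, value = TRUE)
    int_cols <- setdiff(cols, det_cols)
    expect <- paste0(int_cols, ".detection")
    if (!setequal(det_cols, expect))
      stop("detection columns must pair as '<sample>.detection'; missing: ",
           paste(setdiff(expect, det_cols), collapse = ", "))
    det <- num[, expect, drop = FALSE]
    colnames(det) <- int_cols
    ExpressionDataset(num[, int_cols, drop = FALSE], detection = det)
  } else {
    ExpressionDataset(num)
  }
}

#' Read a sample-to-group map
#'
#' Two-column delimited file `sample_id<TAB>group` with an optional third
#' integer column giving an explicit level order. A header row whose second
#' field is `"group"` is skipped. Levels are ordered by the order column when
#' present (ascending by each level's order value), else by first appearance.
#'
#' @param path path to the file.
#' @param delimiter field separator, default tab.
#' @return a [GroupAssignment-class].
#' @export
readGroupMap <- function(path, delimiter = "\t") {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  if (length(fields) && length(fields[[1]]) >= 2 &&
      tolower(fields[[1]][2]) == "group")
    fields <- fields[-1]
  if (!length(fields)) stop("empty group map")
  nfld <- lengths(fields)
  if (any(nfld < 2)) stop("group map lines need at least 2 fields")
  samples <- vapply(fields, `[[`, character(1), 1L)
  groups <- vapply(fields, `[[`, character(1), 2L)
  dup <- duplicated(samples)
  if (any(dup)) {
    conflict <- vapply(unique(samples[dup]), function(s)
      length(unique(groups[samples == s])) > 1, logical(1))
    if (any(conflict))
      stop("sample(s) mapped to conflicting groups: ",
           paste(names(conflict)[conflict], collapse = ", "))
    keep <- !dup
    samples <- samples[keep]; groups <- groups[keep]; fields <- fields[keep]
    nfld <- nfld[keep]
  }
  if (all(nfld >= 3)) {
    ord <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
    if (anyNA(ord)) stop("order column must be numeric")
    lev_ord <- vapply(split(ord, groups), min, numeric(1))
    levels <- names(sort(lev_ord))
  } else {
    levels <- unique(groups)
  }
  GroupAssignment(samples, groups, levels)
}

#' Read a gene-set collection in GMT format
#'
#' One set per line: `name<TAB>description<TAB>member1<TAB>member2...`.
#' Members repeated within a line are collapsed; gene identifiers are
#' trimmed and upper-cased.
#'
#' @param path path to a GMT file.
#' @return a [GeneSetCollection-class].
#' @export
readGeneSetsGmt <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  lineno <- which(keep)
  short <- lengths(fields) < 3L
  if (any(short))
    stop("GMT line(s) with fewer than 3 fields: line ",
         paste(lineno[short], collapse = ", "))
  nm <- vapply(fields, `[[`, character(1), 1L)
  desc <- vapply(fields, `[[`, character(1), 2L)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- nm
  GeneSetCollection(sets, setNames(desc, nm))
}

#' Read an ontology (OBO subset) plus a gene annotation table
#'
#' Parses `[Term]` stanzas with `id`, `name`, `namespace`, `is_a` and
#' `is_obsolete` lines. Obsolete terms are dropped together with their
#' annotations (with a warning when annotations are lost). An `is_a` edge
#' pointing at an unknown term, or a cycle, is a hard error.
#'
#' @param obo_path path to the OBO file.
#' @param annotation_path path to a two-column (gene_id, term_id) delimited
#'   file; a header row whose second field is `"term_id"` is skipped.
#' @return an [OntologyGraph-class].
#' @export
readOntology <- function(obo_path, annotation_path) {
  stopifnot(file.exists(obo_path), file.exists(annotation_path))
  lines <- trimws(readLines(obo_path))
  in_term <- FALSE
  terms <- list(); cur <- NULL
  flush <- function(cur, terms) {
    if (!is.null(cur) && !is.null(cur$id)) terms[[cur$id]] <- cur
    terms
  }
  for (ln in lines) {
    if (ln == "[Term]") {
      terms <- flush(cur, terms)
      cur <- list(parents = character(), obsolete = FALSE)
      in_term <- TRUE
    } else if (grepl("^\\[", ln)) {
      terms <- flush(cur, terms); cur <- NULL; in_term <- FALSE
    } else if (in_term && nzchar(ln)) {
      kv <- regmatches(ln, regexec("^([a-z_]+):\\s*(.*)$", ln))[[1]]
      if (length(kv) == 3) {
        val <- sub("\\s*!.*$", "", kv[3])
        switch(kv[2],
          id = cur$id <- val,
          name = cur$name <- val,
          namespace = cur$namespace <- val,
          is_a = cur$parents <- c(cur$parents, sub("\\s.*$", "", val)),
          is_obsolete = cur$obsolete <- identical(val, "true"))
      }
    }
  }
  terms <- flush(cur, terms)
  if (!length(terms)) stop("no [Term] stanzas found")
  obsolete <- names(terms)[vapply(terms, `[[`, logical(1), "obsolete")]
  live <- terms[setdiff(names(terms), obsolete)]
  ids <- names(live)
  parents <- lapply(live, function(t1) setdiff(t1$parents, obsolete))
  unknown <- setdiff(unlist(parents, use.names = FALSE), ids)
  if (length(unknown))
    stop("is_a references unknown term(s): ", paste(unknown, collapse = ", "))
  edge_to <- unlist(parents, use.names = FALSE)
  if (length(edge_to)) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = rep(names(parents), lengths(parents)), to = edge_to,
                 stringsAsFactors = FALSE),
      directed = TRUE, vertices = data.frame(name = ids))
    if (!igraph::is_dag(g)) stop("is_a edges contain a cycle")
  }
  term_df <- data.frame(
    id = ids,
    name = vapply(live, function(t1) t1$name %||% "", character(1)),
    namespace = vapply(live, function(t1) t1$namespace %||% "", character(1)),
    row.names = NULL, stringsAsFactors = FALSE)

  ann_lines <- readLines(annotation_path)
  ann_lines <- ann_lines[nzchar(trimws(ann_lines))]
  af <- strsplit(ann_lines, "\t", fixed = TRUE)
  if (length(af) && length(af[[1]]) >= 2 && tolower(af[[1]][2]) == "term_id")
    af <- af[-1]
  genes <- normalizeGeneIds(vapply(af, `[[`, character(1), 1L))
  tids <- vapply(af, `[[`, character(1), 2L)
  is_obs <- tids %in% obsolete
  if (any(is_obs)) {
    warning(sum(is_obs), " annotation(s) to obsolete terms dropped")
    genes <- genes[!is_obs]; tids <- tids[!is_obs]
  }
  bad <- !(tids %in% ids)
  if (any(bad))
    stop("annotation references unknown term(s): ",
         paste(unique(tids[bad]), collapse = ", "))
  annotation <- lapply(split(tids, genes), unique)
  methods::new("OntologyGraph", terms = term_df, parents = parents,
               annotation = annotation)
}

#' Write an ordered result table as delimited text
#'
#' Numeric columns are serialized at full precision; values below 1e-4 in
#' magnitude come out in scientific notation, and every value parses back to
#' the same double.
#'
#' @param rows a data.frame of records sharing one schema.
#' @param path output path.
#' @param delimiter field separator, default tab.
#' @return invisibly, the path written.
#' @export
writeResultTable <- function(rows, path, delimiter = "\t") {
  stopifnot(is.data.frame(rows))
  out <- rows
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- vapply(out[[j]], function(v) {
        if (is.na(v)) "NA" else format(v, digits = 17, trim = TRUE)
      }, character(1))
  }
  ok <- tryCatch({
    write.table(out, path, sep = delimiter, quote = FALSE,
                row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write to '", path, "': ",
                        conditionMessage(ok))
  invisible(path)
}

#' Read back a result table written by [writeResultTable()]
#'
#' @param path path to the file.
#' @param delimiter field separator.
#' @return a data.frame.
#' @export
readResultTable <- function(path, delimiter = "\t") {
  read.delim(path, sep = delimiter, check.names = FALSE,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
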