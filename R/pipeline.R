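## End-to-end recipes: normalize -> filter -> DE/trend -> cluster -> enrich,
## driven by a flat key=value configuration, with a manifest of every output
## written (path + md5 content hash) so runs are auditable and repeatable.

#' Read a flat key = value run configuration
#'
#' Lines of the form `key = value`; blank lines and `#` comments ignored.
#' Numeric-looking values are converted; `true`/`false` become logical.
#'
#' @param path configuration file path.
#' @return named list.
#' @export
readRunConfig <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  cfg <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(kv) != 3) stop("bad config line: '", ln, "'")
    val <- trimws(kv[3])
    num <- suppressWarnings(as.numeric(val))
    cfg[[kv[2]]] <- if (!is.na(num)) num
      else if (tolower(val) %in% c("true", "false")) tolower(val) == "true"
      else val
  }
  cfg
}

## internal: validate parameters before any stage touches data
validateConfig <- function(cfg) {
  if (is.null(cfg$expression)) stop("config needs 'expression' (input path)")
  if (!file.exists(cfg$expression))
    stop("expression file not found: ", cfg$expression)
  if (is.null(cfg$mode) || !(cfg$mode %in% c("two_group", "timecourse")))
    stop("config needs mode = two_group | timecourse")
  if (!is.null(cfg$fc_cutoff) && cfg$fc_cutoff < 1)
    stop("fc_cutoff must be >= 1")
  if (!is.null(cfg$p_cutoff) && (cfg$p_cutoff <= 0 || cfg$p_cutoff > 1))
    stop("p_cutoff must be in (0, 1]")
  if (!is.null(cfg$r_threshold) && (cfg$r_threshold <= 0 ||
                                    cfg$r_threshold >= 1))
    stop("r_threshold must be in (0, 1)")
  if (!is.null(cfg$variance_fraction) &&
      (cfg$variance_fraction < 0 || cfg$variance_fraction >= 1))
    stop("variance_fraction must be in [0, 1)")
  if (!is.null(cfg$detection_alpha) &&
      (cfg$detection_alpha <= 0 || cfg$detection_alpha >= 1))
    stop("detection_alpha must be in (0, 1)")
  for (p in c("groups", "gmt", "obo", "annotation"))
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]]))
      stop(p, " file not found: ", cfg[[p]])
  invisible(cfg)
}

## internal: write a table and append to the manifest
emitOutput <- function(tab, out_dir, name, manifest) {
  path <- file.path(out_dir, name)
  writeResultTable(tab, path)
  c(manifest, list(list(path = name, md5 = unname(tools::md5sum(path)))))
}

#' Run a full analysis recipe from a configuration
#'
#' Stages run in a fixed order: read, optional quantile normalization,
#' optional filters (detection / intensity / variance), then the
#' mode-specific analysis. `mode = "two_group"` runs the volcano
#' differential-expression recipe (plus gene-set enrichment when a GMT file
#' is configured); `mode = "timecourse"` runs trend correlation, trend
#' ranking, k-means (k = 2) on the selected probes, and GO enrichment when
#' an ontology is configured. Every output lands in `out_dir` and is listed
#' in `manifest.json` (JSON lines of path + md5). A stage failure aborts
#' with a partial manifest written.
#'
#' Recognized config keys: `expression`, `groups`, `mode`, `has_detection`,
#' `normalize`, `detection_alpha`, `intensity_floor`, `variance_fraction`,
#' `test_level`, `control_level`, `fc_cutoff`, `p_cutoff`, `r_threshold`,
#' `gmt`, `obo`, `annotation`, `enrich_p`, `seed`.
#'
#' @param config named list (e.g. from [readRunConfig()]).
#' @param out_dir output directory, created if absent.
#' @return invisibly, the manifest (list of path/md5 records).
#' @export
runPipeline <- function(config, out_dir) {
  validateConfig(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  seed <- as.integer(config$seed %||% 1)
  log_lines <- character()
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))

  data <- readExpressionTable(config$expression,
                              has_detection = isTRUE(config$has_detection))
  say("loaded %d probes x %d samples", nrow(data), ncol(data))
  groups <- if (!is.null(config$groups)) readGroupMap(config$groups) else NULL

  if (isTRUE(config$normalize) || is.null(config$normalize)) {
    data <- quantileNormalize(data)
    say("quantile normalization applied")
  }
  for (flt in list(
    list(key = "detection_alpha", fun = filterByDetection),
    list(key = "intensity_floor", fun = filterByIntensity),
    list(key = "variance_fraction", fun = filterLowVariance))) {
    thr <- config[[flt$key]]
    if (!is.null(thr)) {
      res <- flt$fun(data, thr)
      data <- res$data
      rep <- res$report
      say("filter %s (threshold %g): %d -> %d probes", rep@rule,
          rep@threshold, rep@before, rep@after)
      manifest <- emitOutput(
        data.frame(rule = rep@rule, threshold = rep@threshold,
                   before = rep@before, after = rep@after,
                   n_removed = length(rep@removed)),
        out_dir, paste0("filter_", rep@rule, ".tsv"), manifest)
    }
  }
  norm_tab <- data.frame(probe_id = probeIds(data), intensities(data),
                         check.names = FALSE)
  manifest <- emitOutput(norm_tab, out_dir, "expression_processed.tsv",
                         manifest)

  if (config$mode == "two_group") {
    if (is.null(groups)) stop("two_group mode needs a 'groups' file")
    lev <- groupLevels(groups)
    test_level <- config$test_level %||% lev[2]
    control_level <- config$control_level %||% lev[1]
    de <- twoGroupStats(data, groups, test_level, control_level)
    sel <- selectVolcano(de, config$fc_cutoff %||% 2,
                         config$p_cutoff %||% 0.05)
    de$significant <- de$probe_id %in% sel$probe_id
    say("differential expression: %d of %d probes pass (fc >= %g, p < %g)",
        nrow(sel), nrow(de), config$fc_cutoff %||% 2,
        config$p_cutoff %||% 0.05)
    manifest <- emitOutput(de, out_dir, "diffexp.tsv", manifest)
    manifest <- emitOutput(sel, out_dir, "diffexp_significant.tsv", manifest)
    manifest <- emitOutput(volcanoCoordinates(de), out_dir, "volcano.tsv",
                           manifest)
    if (!is.null(config$gmt) && nrow(sel)) {
      collection <- readGeneSetsGmt(config$gmt)
      ann <- probeAnnotation(data)
      query <- if (is.null(ann)) sel$probe_id else ann[sel$probe_id]
      background <- if (is.null(ann)) probeIds(data) else ann
      enr <- enrichGeneSets(query, background, collection,
                            p_cutoff = config$enrich_p %||% 1)
      manifest <- emitOutput(enr, out_dir, "enrichment.tsv", manifest)
      say("gene-set enrichment: %d sets tested", nrow(enr))
    }
  } else {
    if (is.null(groups)) stop("timecourse mode needs a 'groups' file")
    tr <- timeseriesR(data, groups)
    ranked <- selectAndRankTrends(tr, data, groups,
                                  config$r_threshold %||% 0.6)
    say("trend selection: %d of %d probes at |r| >= %g", nrow(ranked),
        nrow(tr), config$r_threshold %||% 0.6)
    manifest <- emitOutput(tr, out_dir, "trend_r.tsv", manifest)
    manifest <- emitOutput(ranked, out_dir, "trend_ranked.tsv", manifest)
    if (nrow(ranked) >= 2) {
      sub <- data[ranked$probe_id, ]
      km <- kmeansCluster(sub, k = 2, seed = seed, center_genes = TRUE)
      manifest <- emitOutput(
        data.frame(probe_id = names(km$cluster), cluster = km$cluster),
        out_dir, "kmeans_clusters.tsv", manifest)
      say("k-means split %d trending probes into 2 clusters", nrow(ranked))
    }
    if (!is.null(config$obo) && !is.null(config$annotation) &&
        nrow(ranked)) {
      ontology <- readOntology(config$obo, config$annotation)
      enr <- enrichGO(ranked$probe_id, probeIds(data), ontology,
                      p_cutoff = config$enrich_p %||% 1)
      manifest <- emitOutput(enr, out_dir, "go_enrichment.tsv", manifest)
      dot <- file.path(out_dir, "go_graph.dot")
      exportGoGraph(enr[enr$p_value < (config$enrich_p %||% 0.05), ,
                        drop = FALSE], ontology, dot)
      manifest <- c(manifest, list(list(path = "go_graph.dot",
                                        md5 = unname(tools::md5sum(dot)))))
      say("GO enrichment: %d terms tested", nrow(enr))
    }
  }
  writeLines(log_lines, file.path(out_dir, "run.log"))
  manifest <- c(manifest, list(list(
    path = "run.log", md5 = unname(tools::md5sum(file.path(out_dir,
                                                           "run.log"))))))
  mpath <- file.path(out_dir, "manifest.json")
  writeLines(vapply(manifest, function(m)
    jsonlite::toJSON(m, auto_unbox = TRUE), character(1)), mpath)
  invisible(manifest)
}

#' Gene description reports from an offline annotation table
#'
#' @param genes character vector of gene ids to report on.
#' @param annotation_table path to a TSV with columns gene id, symbol,
#'   description; an optional first line `# version: <string>` records the
#'   table version.
#' @return data.frame with columns `gene_id`, `symbol`, `description`,
#'   `found`, `source_version`, one row per requested gene in request
#'   order; unknown genes are flagged, never dropped.
#' @export
geneReport <- function(genes, annotation_table) {
  if (!file.exists(annotation_table))
    stop("annotation table not found: ", annotation_table)
  lines <- readLines(annotation_table)
  version <- "unversioned"
  if (length(lines) && grepl("^#", lines[1])) {
    version <- trimws(sub("^#\\s*(version:)?\\s*", "", lines[1]))
    lines <- lines[-1]
  }
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (length(fields) && tolower(fields[[1]][1]) %in% c("gene_id", "gene"))
    fields <- fields[-1]
  ids <- normalizeGeneIds(vapply(fields, `[[`, character(1), 1L))
  sym <- vapply(fields, function(f) if (length(f) >= 2) f[2] else "",
                character(1))
  desc <- vapply(fields, function(f) if (length(f) >= 3) f[3] else "",
                 character(1))
  if (!length(genes))
    return(data.frame(gene_id = character(), symbol = character(),
                      description = character(), found = logical(),
                      source_version = character(), stringsAsFactors = FALSE))
  idx <- match(normalizeGeneIds(genes), ids)
  data.frame(gene_id = as.character(genes),
             symbol = ifelse(is.na(idx), "", sym[idx]),
             description = ifelse(is.na(idx), "not found", desc[idx]),
             found = !is.na(idx), source_version = version,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Export plot-ready data tables
#'
#' * `volcano`: expects a [twoGroupStats()] data.frame; writes probe,
#'   log2 fold change, -log10 p and the significance flag.
#' * `boxplot`: expects `list(data =, groups =, probe_id = )` (probe
#'   optional -- all values pooled when absent); writes the per-group
#'   five-number summary (min, Q1, median, Q3, max) under the
#'   linear-interpolation (type 7) quantile rule.
#' * `barplot` / `heatmap`: expects a labelled numeric matrix; written as a
#'   plain TSV matrix with row labels.
#'
#' @param kind one of `"volcano"`, `"boxplot"`, `"barplot"`, `"heatmap"`.
#' @param inputs stage output matching `kind` (see Details).
#' @param path output TSV path.
#' @return invisibly, the path written.
#' @export
exportPlotData <- function(kind = c("volcano", "boxplot", "barplot",
                                    "heatmap"), inputs, path) {
  kind <- match.arg(kind)
  tab <- switch(kind,
    volcano = {
      if (!is.data.frame(inputs) || !all(c("probe_id", "p_value") %in%
                                         names(inputs)))
        stop("volcano export needs a twoGroupStats() result")
      volcanoCoordinates(inputs)
    },
    boxplot = {
      if (!is.list(inputs) || !methods::is(inputs$data, "ExpressionDataset")
          || !methods::is(inputs$groups, "GroupAssignment"))
        stop("boxplot export needs list(data = ExpressionDataset, groups = GroupAssignment)")
      x <- intensities(inputs$data)
      if (!is.null(inputs$probe_id)) x <- x[inputs$probe_id, , drop = FALSE]
      g <- sampleGroups(inputs$groups)[colnames(x)]
      vals <- split(as.vector(x), rep(g, each = nrow(x)))
      do.call(rbind, lapply(groupLevels(inputs$groups), function(lv) {
        q <- quantile(vals[[lv]], c(0, 0.25, 0.5, 0.75, 1), type = 7)
        data.frame(group = lv, min = q[1], q1 = q[2], median = q[3],
                   q3 = q[4], max = q[5], row.names = NULL)
      }))
    },
    {
      if (!is.matrix(inputs) || is.null(rownames(inputs)))
        stop(kind, " export needs a labelled numeric matrix")
      data.frame(id = rownames(inputs), inputs, check.names = FALSE)
    })
  writeResultTable(tab, path)
}
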