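## Seeded synthetic-data generators for every input class the pipeline
## touches. Each generator is a pure function of (parameters, seed) and
## returns the ground truth alongside the data, so planted signals can be
## scored exactly. Log2-scale signals are exponentiated to linear-scale
## intensities, keeping fold-change semantics exact in expectation.

#' Simulate a two-group experiment with planted fold changes
#'
#' Baseline log2 means are drawn uniformly in [6, 12]; `n_de` probes are
#' shifted by `+/- log2(fold)` (random sign) in the test group; Gaussian
#' noise with standard deviation `sigma_log2` is added on the log2 scale and
#' intensities are exponentiated back to linear scale.
#'
#' @param n_probes number of probes.
#' @param n_per_group samples per group (groups `ctrl` and `trt`).
#' @param n_de number of differentially expressed probes, `<= n_probes`.
#' @param fold planted linear fold change, > 1.
#' @param sigma_log2 log2-scale noise standard deviation.
#' @param seed integer seed; same seed, same data.
#' @return list with `data` ([ExpressionDataset-class]), `groups`
#'   ([GroupAssignment-class]) and `truth` (data.frame `probe_id`, `status`
#'   in null/up/down, `fold`).
#' @export
genTwoGroup <- function(n_probes = 2000, n_per_group = 5, n_de = 100,
                        fold = 2.5, sigma_log2 = 0.25, seed = 1) {
  stopifnot(n_de <= n_probes, fold > 1, sigma_log2 > 0)
  set.seed(as.integer(seed))
  probes <- sprintf("P%05d", seq_len(n_probes))
  samples <- c(paste0("C", seq_len(n_per_group)),
               paste0("T", seq_len(n_per_group)))
  groups <- rep(c("ctrl", "trt"), each = n_per_group)
  base <- runif(n_probes, 6, 12)
  status <- rep("null", n_probes)
  if (n_de > 0) {
    de_idx <- sample.int(n_probes, n_de)
    dir <- sample(c(1, -1), n_de, replace = TRUE)
    status[de_idx] <- ifelse(dir > 0, "up", "down")
  }
  mu <- matrix(base, n_probes, 2 * n_per_group)
  if (n_de > 0)
    mu[de_idx, groups == "trt"] <- mu[de_idx, groups == "trt"] +
      dir * log2(fold)
  logx <- mu + matrix(rnorm(n_probes * 2 * n_per_group, sd = sigma_log2),
                      n_probes)
  x <- 2^logx
  dimnames(x) <- list(probes, samples)
  list(data = ExpressionDataset(x),
       groups = GroupAssignment(samples, groups, c("ctrl", "trt")),
       truth = data.frame(probe_id = probes, status = status,
                          fold = ifelse(status == "null", 1, fold),
                          stringsAsFactors = FALSE))
}

#' Simulate a time-course experiment with planted monotone trends
#'
#' Trending probes follow a linear log2 ramp from 0 to `+/- amplitude_log2`
#' across the ordered timepoints (constant within the replicates of a
#' timepoint); all other probes are flat. Gaussian log2 noise is added and
#' intensities exponentiated to linear scale.
#'
#' @param n_probes number of probes.
#' @param timepoints ordered numeric vector of timepoint labels (days).
#' @param reps_per_timepoint replicate samples per timepoint.
#' @param n_up,n_down numbers of rising / falling probes,
#'   `n_up + n_down <= n_probes`.
#' @param sigma_log2 log2 noise standard deviation.
#' @param amplitude_log2 total log2 change across the course, default 2
#'   (four-fold).
#' @param seed integer seed.
#' @return list with `data`, `groups` (levels in time order, labels
#'   `day<t>`) and `truth` (`probe_id`, `status` in null/up/down).
#' @export
genTimecourse <- function(n_probes = 1000, timepoints = c(0, 2, 5, 8, 11, 14),
                          reps_per_timepoint = 4, n_up = 50, n_down = 50,
                          sigma_log2 = 0.25, amplitude_log2 = 2, seed = 1) {
  stopifnot(n_up + n_down <= n_probes, length(timepoints) >= 3)
  set.seed(as.integer(seed))
  nt <- length(timepoints)
  n_samp <- nt * reps_per_timepoint
  probes <- sprintf("P%05d", seq_len(n_probes))
  tp_idx <- rep(seq_len(nt), each = reps_per_timepoint)
  samples <- sprintf("d%g_r%d", timepoints[tp_idx],
                     rep(seq_len(reps_per_timepoint), nt))
  glabels <- sprintf("day%g", timepoints[tp_idx])
  levels <- sprintf("day%g", timepoints)
  base <- runif(n_probes, 6, 12)
  status <- rep("null", n_probes)
  idx <- sample.int(n_probes, n_up + n_down)
  status[idx[seq_len(n_up)]] <- "up"
  status[idx[n_up + seq_len(n_down)]] <- "down"
  ramp <- (seq_len(nt) - 1) / (nt - 1)       # 0..1 across the course
  mu <- matrix(base, n_probes, n_samp)
  slope <- ifelse(status == "up", amplitude_log2,
                  ifelse(status == "down", -amplitude_log2, 0))
  mu <- mu + outer(slope, ramp[tp_idx])
  logx <- mu + matrix(rnorm(n_probes * n_samp, sd = sigma_log2), n_probes)
  x <- 2^logx
  dimnames(x) <- list(probes, samples)
  list(data = ExpressionDataset(x),
       groups = GroupAssignment(samples, glabels, levels),
       truth = data.frame(probe_id = probes, status = status,
                          stringsAsFactors = FALSE))
}

#' Simulate gene sets, a toy ontology and a query with one planted signal
#'
#' Builds `n_sets` random gene sets plus one planted set that shares
#' `query_overlap` genes with the query; the ontology is a three-layer DAG
#' (one root, three mid-level terms, six leaves) in which the planted set's
#' genes annotate one leaf, so after true-path propagation that leaf and its
#' ancestors carry the signal.
#'
#' @param n_genes background (universe) size.
#' @param n_sets number of random, unplanted sets.
#' @param planted_set_size size of the planted set.
#' @param query_overlap planted genes injected into the query,
#'   `<= min(planted_set_size, query_size)`.
#' @param query_size total query size, default 25.
#' @param seed integer seed.
#' @return list with `collection` ([GeneSetCollection-class], planted set
#'   named `"PLANTED"`), `ontology` ([OntologyGraph-class], planted leaf in
#'   `truth`), `query`, `background` and `truth` (planted set name, planted
#'   term id, overlap).
#' @export
genGenesetsAndOntology <- function(n_genes = 400, n_sets = 20,
                                   planted_set_size = 30, query_overlap = 15,
                                   query_size = 25, seed = 1) {
  stopifnot(query_overlap <= planted_set_size, query_overlap <= query_size,
            planted_set_size <= n_genes)
  set.seed(as.integer(seed))
  genes <- sprintf("G%04d", seq_len(n_genes))
  planted <- sample(genes, planted_set_size)
  sets <- lapply(seq_len(n_sets), function(i)
    sample(genes, sample(10:40, 1)))
  names(sets) <- sprintf("SET%02d", seq_len(n_sets))
  sets$PLANTED <- planted
  query <- c(sample(planted, query_overlap),
             sample(setdiff(genes, planted), query_size - query_overlap))
  # layered DAG: root -> M1..M3, each mid term -> two leaves
  term_ids <- c("T:ROOT", paste0("T:M", 1:3), paste0("T:L", 1:6))
  parents <- c(list("T:ROOT" = character()),
               setNames(rep(list("T:ROOT"), 3), paste0("T:M", 1:3)),
               setNames(as.list(paste0("T:M", rep(1:3, each = 2))),
                        paste0("T:L", 1:6)))
  terms <- data.frame(id = term_ids,
                      name = c("root", paste0("mid ", 1:3),
                               paste0("leaf ", 1:6)),
                      namespace = "biological_process",
                      stringsAsFactors = FALSE)
  others <- setdiff(genes, planted)
  ann_genes <- c(planted, sample(others, min(length(others), 200)))
  ann_terms <- c(rep("T:L1", planted_set_size),
                 sample(paste0("T:L", 2:6),
                        length(ann_genes) - planted_set_size, replace = TRUE))
  annotation <- lapply(split(ann_terms, normalizeGeneIds(ann_genes)), unique)
  ontology <- methods::new("OntologyGraph", terms = terms, parents = parents,
                           annotation = annotation)
  list(collection = GeneSetCollection(sets),
       ontology = ontology, query = query, background = genes,
       truth = list(planted_set = "PLANTED", planted_term = "T:L1",
                    query_overlap = query_overlap))
}

## internal: single-oligo filter predicate at the given constraints
primerPasses <- function(seq, constraints) {
  gc <- gcFraction(seq)
  if (gc < constraints$gc_min || gc > constraints$gc_max) return(FALSE)
  tm <- meltingTemperature(seq, method = constraints$tm_method)
  if (tm < constraints$tm_min || tm > constraints$tm_max) return(FALSE)
  if (maxHomopolymerRun(seq) > constraints$run_max) return(FALSE)
  if (hairpinCheck(seq, constraints$hairpin_stem,
                   constraints$hairpin_loop)$hairpin) return(FALSE)
  dimerScore(seq, seq) <= constraints$dimer_max
}

## internal: one random primer-compliant oligo (rejection sampling), shaped
## AAAA + G/C core + AAAA at the minimum primer length. The A-clamps cannot
## base-pair with each other (no hairpin/dimer contribution), and in the
## template -- flanked by same-base homopolymer runs -- every enumerated
## window other than the exact planted one must extend past an A-clamp and
## therefore carries a homopolymer run > 4: the planted window is the
## unique survivor at its site by construction.
randomCompliantPrimer <- function(constraints, len = constraints$length_min,
                                  max_try = 20000) {
  core_len <- len - 8L
  if (core_len < 2L) stop("primer length too short for the clamped design")
  gc <- core_len / len
  if (gc < constraints$gc_min || gc > constraints$gc_max)
    stop("clamped design GC fraction outside the constraint window")
  for (i in seq_len(max_try)) {
    core <- sample(c("G", "C"), core_len, replace = TRUE)
    seq <- paste(c(rep("A", 4), core, rep("A", 4)), collapse = "")
    if (primerPasses(seq, constraints)) return(seq)
  }
  stop("could not sample a compliant primer in ", max_try, " tries")
}

#' Simulate a cDNA template with planted primer sites
#'
#' The background is built from short random stretches interleaved with
#' 7-base homopolymer decoys, so every window outside the planted sites
#' fails the default homopolymer-run filter. With `planted_sites = TRUE`,
#' one forward and one reverse binding site satisfying the constraints are
#' planted with a compliant amplicon span, and the generator verifies that
#' no other window overlapping the clean zones passes the single-primer
#' filters, so the planted pair is the unique feasible pair.
#'
#' @param length template length, >= 300 when planting sites.
#' @param gc_background GC probability of the random background stretches.
#' @param planted_sites logical; plant a compliant primer-site pair.
#' @param constraints primer constraints the planted sites must satisfy.
#' @param seed integer seed.
#' @return list with `template` (DNA string) and `truth` (list with
#'   `fwd_start`, `fwd_seq`, `rev_start`, `rev_end`, `rev_seq`,
#'   `amplicon_length`; `NULL`s when nothing planted).
#' @export
genTemplate <- function(length = 600, gc_background = 0.7,
                        planted_sites = TRUE,
                        constraints = primerConstraints(), seed = 1) {
  if (planted_sites && length < 300)
    stop("template length must be >= 300 when planting sites")
  set.seed(as.integer(seed))
  decoy_bg <- function(L) {
    out <- character(0)
    while (sum(nchar(out)) < L) {
      stretch <- paste(sample(c("G", "C", "A", "T"), 8, replace = TRUE,
                              prob = c(gc_background / 2, gc_background / 2,
                                       (1 - gc_background) / 2,
                                       (1 - gc_background) / 2)),
                       collapse = "")
      run <- strrep(sample(c("A", "C", "G", "T"), 1), 7)
      out <- c(out, stretch, run)
    }
    substr(paste(out, collapse = ""), 1, L)
  }
  if (!planted_sites) {
    return(list(template = decoy_bg(length),
                truth = list(fwd_start = NULL, fwd_seq = NULL,
                             rev_start = NULL, rev_end = NULL,
                             rev_seq = NULL, amplicon_length = NULL)))
  }
  # plant at the minimum primer length: no enumerated window can be a
  # proper sub-window of a planted site, and the clamp/flank construction
  # kills every window extending past one
  plen <- as.integer(constraints$length_min)
  mid <- as.integer((constraints$amplicon_min + constraints$amplicon_max)
                    %/% 2)
  fwd_start <- 101L
  rev_end <- fwd_start + mid - 1L          # amplicon == mid of the bounds
  rev_start <- rev_end - plen + 1L
  for (attempt in seq_len(200)) {
    fwd <- randomCompliantPrimer(constraints, plen)
    rev_ <- randomCompliantPrimer(constraints, plen)
    if (abs(meltingTemperature(fwd, method = constraints$tm_method) -
            meltingTemperature(rev_, method = constraints$tm_method)) >
        constraints$tm_diff_max - 0.5) next
    if (dimerScore(fwd, rev_) > constraints$dimer_max) next
    tmpl <- decoy_bg(length)
    substr(tmpl, fwd_start, fwd_start + plen - 1L) <- fwd
    substr(tmpl, rev_start, rev_end) <- reverseComplement(rev_)
    # homopolymer flanks matching each site's terminal base: any window
    # extending past a planted site carries a run > 4 and fails screening
    substr(tmpl, fwd_start - 7L, fwd_start - 1L) <- strrep("A", 7)
    substr(tmpl, fwd_start + plen, fwd_start + plen + 6L) <- strrep("A", 7)
    substr(tmpl, rev_start - 7L, rev_start - 1L) <- strrep("T", 7)
    substr(tmpl, rev_start + plen, rev_start + plen + 6L) <- strrep("T", 7)
    if (templateCleanZonesOk(tmpl, fwd_start, rev_start, plen, constraints))
      return(list(template = tmpl,
                  truth = list(fwd_start = fwd_start, fwd_seq = fwd,
                               rev_start = rev_start, rev_end = rev_end,
                               rev_seq = rev_,
                               amplicon_length = rev_end - fwd_start + 1L)))
  }
  stop("could not build a template whose planted pair is uniquely feasible")
}

## internal: verify the planted windows are the only single-primer survivors
## in/near the clean zones (the decoy background eliminates everything else)
templateCleanZonesOk <- function(template, fwd_start, rev_start, plen,
                                 constraints) {
  passes <- function(seq) {
    gc <- gcFraction(seq)
    if (gc < constraints$gc_min || gc > constraints$gc_max) return(FALSE)
    tm <- meltingTemperature(seq, method = constraints$tm_method)
    if (tm < constraints$tm_min || tm > constraints$tm_max) return(FALSE)
    if (maxHomopolymerRun(seq) > constraints$run_max) return(FALSE)
    if (hairpinCheck(seq, constraints$hairpin_stem,
                     constraints$hairpin_loop)$hairpin) return(FALSE)
    dimerScore(seq, seq) <= constraints$dimer_max
  }
  zones <- rbind(c(fwd_start, fwd_start + plen - 1L),
                 c(rev_start, rev_start + plen - 1L))
  L <- nchar(template)
  # the two exact planted windows survive on either strand interpretation;
  # pairing geometry makes the extra interpretations infeasible (amplicon
  # bounds), so only OTHER surviving windows threaten uniqueness
  for (len in seq.int(constraints$length_min, constraints$length_max)) {
    for (z in 1:2) {
      lo <- max(1L, zones[z, 1] - len)
      hi <- min(L - len + 1L, zones[z, 2])
      for (start in seq.int(lo, hi)) {
        if (start == zones[z, 1] && len == plen) next
        slice <- substr(template, start, start + len - 1L)
        if (passes(slice) || passes(reverseComplement(slice))) return(FALSE)
      }
    }
  }
  TRUE
}

#' Write a simulated template as FASTA
#'
#' @param template DNA string from [genTemplate()].
#' @param path output path.
#' @param name record name.
#' @return invisibly, the path.
#' @export
writeTemplateFasta <- function(template, path, name = "template") {
  s <- Biostrings::DNAStringSet(template)
  names(s) <- name
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}
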