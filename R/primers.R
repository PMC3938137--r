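## RT-qPCR primer enumeration and screening. Structure checks (hairpin,
## self-dimer, cross-dimer) are exact Watson-Crick complementarity run
## counts, deterministic by construction; Tm is either the Wallace rule or
## unified nearest-neighbor thermodynamics with salt correction.

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

checkDna <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1]]
  if (!length(ch)) stop("empty sequence")
  bad <- setdiff(unique(ch), names(DNA_COMPLEMENT))
  if (length(bad))
    stop("non-ACGT character(s): ", paste(bad, collapse = ", "))
  ch
}

#' Reverse complement of a DNA string
#' @param seq DNA string over A, C, G, T.
#' @return the reverse complement string.
#' @export
reverseComplement <- function(seq) {
  paste(rev(DNA_COMPLEMENT[checkDna(seq)]), collapse = "")
}

#' GC fraction of a DNA string
#'
#' @param seq DNA string over A, C, G, T.
#' @return exact (#G + #C) / length.
#' @export
gcFraction <- function(seq) {
  ch <- checkDna(seq)
  sum(ch %in% c("G", "C")) / length(ch)
}

## SantaLucia unified nearest-neighbor parameters:
## dH in kcal/mol, dS in cal/(mol K), for 5'->3' stacks.
NN_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4, CT = -7.8,
           GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
           TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2, CC = -8.0)
NN_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
           CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
           TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
           CC = -19.9)

#' Oligonucleotide melting temperature
#'
#' `method = "wallace"`: Tm = 2(#A + #T) + 4(#G + #C), the quick rule for
#' short oligos. `method = "nearest_neighbor"`: unified nearest-neighbor
#' thermodynamics -- stack enthalpies/entropies plus terminal initiation
#' terms, an entropic salt correction of `0.368 (L-1) ln[Na+]` and a
#' symmetry term for self-complementary sequences; then
#' `Tm = 1000 dH / (dS + R ln(c/4)) - 273.15` with R = 1.987 cal/(mol K).
#'
#' @param seq DNA string, length >= 2.
#' @param method `"nearest_neighbor"` (default) or `"wallace"`.
#' @param primer_conc total oligo concentration in mol/L (default 5e-7,
#'   i.e. 500 nM).
#' @param monovalent_salt monovalent cation concentration in mol/L
#'   (default 0.05).
#' @return melting temperature in degrees Celsius.
#' @export
meltingTemperature <- function(seq, method = c("nearest_neighbor", "wallace"),
                               primer_conc = 5e-7, monovalent_salt = 0.05) {
  method <- match.arg(method)
  ch <- checkDna(seq)
  L <- length(ch)
  if (L < 2L) stop("sequence must have length >= 2")
  if (method == "wallace")
    return(2 * sum(ch %in% c("A", "T")) + 4 * sum(ch %in% c("G", "C")))
  stopifnot(primer_conc > 0, monovalent_salt > 0)
  stacks <- paste0(ch[-L], ch[-1])
  dH <- sum(NN_DH[stacks])
  dS <- sum(NN_DS[stacks])
  # terminal initiation terms
  for (b in ch[c(1, L)]) {
    if (b %in% c("G", "C")) { dH <- dH + 0.1; dS <- dS - 2.8 }
    else { dH <- dH + 2.3; dS <- dS + 4.1 }
  }
  self_comp <- identical(paste(ch, collapse = ""),
                         reverseComplement(paste(ch, collapse = "")))
  if (self_comp) dS <- dS - 1.4
  dS <- dS + 0.368 * (L - 1) * log(monovalent_salt)
  conc <- if (self_comp) primer_conc else primer_conc / 4
  1000 * dH / (dS + 1.987 * log(conc)) - 273.15
}

#' Longest homopolymer run
#'
#' @param seq DNA string.
#' @return length of the longest single-base run.
#' @export
maxHomopolymerRun <- function(seq) {
  ch <- checkDna(seq)
  max(rle(ch)$lengths)
}

#' Hairpin screen by exact complementarity
#'
#' Flags a hairpin when some substring of length >= `min_stem` is the
#' reverse complement of a downstream substring separated by at least
#' `min_loop` bases.
#'
#' @param seq DNA string.
#' @param min_stem minimum stem length, >= 2.
#' @param min_loop minimum loop length, >= 3.
#' @return list with `hairpin` (logical) and `stem_length` (longest stem
#'   found, 0 when none).
#' @export
hairpinCheck <- function(seq, min_stem = 4, min_loop = 3) {
  stopifnot(min_stem >= 2, min_loop >= 3)
  ch <- checkDna(seq)
  L <- length(ch)
  best <- 0L
  max_stem <- (L - min_loop) %/% 2
  if (max_stem >= min_stem) {
    comp <- DNA_COMPLEMENT[ch]
    for (len in seq.int(max_stem, min_stem)) {
      for (i in seq_len(L - 2 * len - min_loop + 1)) {
        sub1 <- ch[i:(i + len - 1)]
        for (j in seq.int(i + len + min_loop, L - len + 1)) {
          # stem pairs antiparallel: sub1 vs revcomp of downstream window
          if (all(sub1 == rev(comp[j:(j + len - 1)]))) {
            best <- max(best, len)
            break
          }
        }
        if (best >= len) break
      }
      if (best >= len) break
    }
  }
  list(hairpin = best >= min_stem, stem_length = as.integer(best))
}

#' Dimer score between two oligos
#'
#' The longest contiguous run of Watson-Crick pairs over all antiparallel
#' alignments of `seq1` against `seq2` (i.e. against the reverse of `seq2`).
#' The self-dimer score of an oligo is `dimerScore(seq, seq)`.
#'
#' @param seq1,seq2 DNA strings.
#' @return integer run length (0 when no pairing at any offset).
#' @export
dimerScore <- function(seq1, seq2) {
  a <- checkDna(seq1)
  b <- rev(checkDna(seq2))       # antiparallel orientation
  n1 <- length(a); n2 <- length(b)
  best <- 0L
  for (shift in seq.int(-(n2 - 1L), n1 - 1L)) {
    i <- max(1L, 1L + shift):min(n1, n2 + shift)
    j <- i - shift
    match_run <- rle(a[i] == DNA_COMPLEMENT[b[j]])
    hits <- match_run$lengths[match_run$values]
    if (length(hits)) best <- max(best, max(hits))
  }
  as.integer(best)
}

#' Primer constraint set
#'
#' Defaults: length 18-25 nt, GC fraction 0.40-0.60, Tm 57-63 C,
#' Tm difference within a pair <= 3 C, homopolymer run <= 4, hairpin
#' stem >= 4 with loop >= 3 flagged, dimer runs <= 8, amplicon 70-200 bp.
#'
#' @param length_min,length_max primer length bounds (nt).
#' @param gc_min,gc_max GC-fraction bounds.
#' @param tm_min,tm_max melting-temperature bounds (Celsius).
#' @param tm_diff_max maximum |Tm(forward) - Tm(reverse)| (Celsius).
#' @param run_max maximum homopolymer run length.
#' @param hairpin_stem,hairpin_loop minimum stem/loop defining a flagged
#'   hairpin.
#' @param dimer_max maximum tolerated self/cross dimer run.
#' @param amplicon_min,amplicon_max amplicon length bounds (bp).
#' @param tm_method Tm model passed to [meltingTemperature()].
#' @return a validated list of constraints.
#' @export
primerConstraints <- function(length_min = 18, length_max = 25,
                              gc_min = 0.4, gc_max = 0.6,
                              tm_min = 57, tm_max = 63, tm_diff_max = 3,
                              run_max = 4, hairpin_stem = 4, hairpin_loop = 3,
                              dimer_max = 8, amplicon_min = 70,
                              amplicon_max = 200,
                              tm_method = "nearest_neighbor") {
  cst <- list(length_min = length_min, length_max = length_max,
              gc_min = gc_min, gc_max = gc_max, tm_min = tm_min,
              tm_max = tm_max, tm_diff_max = tm_diff_max, run_max = run_max,
              hairpin_stem = hairpin_stem, hairpin_loop = hairpin_loop,
              dimer_max = dimer_max, amplicon_min = amplicon_min,
              amplicon_max = amplicon_max, tm_method = tm_method)
  if (length_min > length_max || gc_min > gc_max || tm_min > tm_max ||
      amplicon_min > amplicon_max)
    stop("every constraint minimum must be <= its maximum")
  cst
}

## internal: enumerate and screen single-strand candidates; filters applied
## in order length -> GC -> Tm -> run -> hairpin -> self-dimer, with
## attrition counted per filter
enumerateCandidates <- function(template, strand, constraints) {
  L <- nchar(template)
  lens <- seq.int(constraints$length_min, constraints$length_max)
  lens <- lens[lens <= L]
  attrition <- c(gc = 0L, tm = 0L, run = 0L, hairpin = 0L, self_dimer = 0L)
  rows <- list()
  for (len in lens) {
    for (start in seq_len(L - len + 1L)) {
      slice <- substr(template, start, start + len - 1L)
      seq <- if (strand == "forward") slice else reverseComplement(slice)
      gc <- gcFraction(seq)
      if (gc < constraints$gc_min || gc > constraints$gc_max) {
        attrition["gc"] <- attrition["gc"] + 1L; next
      }
      tm <- meltingTemperature(seq, method = constraints$tm_method)
      if (tm < constraints$tm_min || tm > constraints$tm_max) {
        attrition["tm"] <- attrition["tm"] + 1L; next
      }
      run <- maxHomopolymerRun(seq)
      if (run > constraints$run_max) {
        attrition["run"] <- attrition["run"] + 1L; next
      }
      hp <- hairpinCheck(seq, constraints$hairpin_stem,
                         constraints$hairpin_loop)
      if (hp$hairpin) {
        attrition["hairpin"] <- attrition["hairpin"] + 1L; next
      }
      sd <- dimerScore(seq, seq)
      if (sd > constraints$dimer_max) {
        attrition["self_dimer"] <- attrition["self_dimer"] + 1L; next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = seq, strand = strand, start = start,
        end = start + len - 1L, length = len, gc_fraction = gc,
        tm_celsius = tm, max_run = run, self_dimer = sd,
        stringsAsFactors = FALSE)
    }
  }
  list(candidates = if (length(rows)) do.call(rbind, rows) else
         data.frame(sequence = character(), strand = character(),
                    start = integer(), end = integer(), length = integer(),
                    gc_fraction = numeric(), tm_celsius = numeric(),
                    max_run = integer(), self_dimer = integer(),
                    stringsAsFactors = FALSE),
       attrition = attrition)
}

#' Enumerate, screen and pair primers against a cDNA template
#'
#' All windows within the length bounds are enumerated on both strands and
#' screened filter by filter (length, GC, Tm, homopolymer run, hairpin,
#' self-dimer). Surviving forward/reverse candidates are paired under the
#' amplicon-length bounds, the pairwise Tm-difference bound and the
#' cross-dimer bound. Pairs are scored by a penalty combining |Tm
#' difference|, deviation of the amplicon length from the midpoint of its
#' bounds, and the dimer scores; the `top_k` best pairs are returned
#' together with a forward-candidate by reverse-candidate feasibility
#' matrix whose cells code the pass/fail cause (`"pass"`, `"amplicon"`,
#' `"tm_diff"`, `"cross_dimer"`) -- the data behind the two-dimensional
#' feasibility view of problematic template regions.
#'
#' Positions are 1-based template coordinates with inclusive ends;
#' `amplicon_length = reverse_end - forward_start + 1`.
#'
#' @param template DNA string (or single-record FASTA path, see
#'   [readTemplateFasta()]).
#' @param constraints from [primerConstraints()].
#' @param top_k number of pairs to return, default 5.
#' @return list with `pairs` (data.frame, best first), `candidates`
#'   (screened single-strand survivors), `feasibility` (character matrix)
#'   and `attrition` (per-filter drop counts for each strand). No surviving
#'   pair yields an empty `pairs` table, not an error.
#' @export
designPrimers <- function(template, constraints = primerConstraints(),
                          top_k = 5) {
  template <- toupper(template)
  checkDna(template)
  if (nchar(template) < constraints$amplicon_min)
    stop("template shorter than the minimum amplicon length")
  fwd <- enumerateCandidates(template, "forward", constraints)
  rev_ <- enumerateCandidates(template, "reverse", constraints)
  f <- fwd$candidates; r <- rev_$candidates
  mid <- (constraints$amplicon_min + constraints$amplicon_max) / 2
  width <- constraints$amplicon_max - constraints$amplicon_min + 1
  feas <- matrix("pass", nrow(f), nrow(r))
  if (nrow(f)) rownames(feas) <- paste0("F", f$start, ".", f$length)
  if (nrow(r)) colnames(feas) <- paste0("R", r$start, ".", r$length)
  pairs <- list()
  if (nrow(f) && nrow(r)) {
    for (i in seq_len(nrow(f))) {
      for (j in seq_len(nrow(r))) {
        amplicon <- r$end[j] - f$start[i] + 1L
        if (amplicon < constraints$amplicon_min ||
            amplicon > constraints$amplicon_max) {
          feas[i, j] <- "amplicon"; next
        }
        tmd <- abs(f$tm_celsius[i] - r$tm_celsius[j])
        if (tmd > constraints$tm_diff_max) {
          feas[i, j] <- "tm_diff"; next
        }
        xd <- dimerScore(f$sequence[i], r$sequence[j])
        if (xd > constraints$dimer_max) {
          feas[i, j] <- "cross_dimer"; next
        }
        penalty <- tmd + 2 * abs(amplicon - mid) / width +
          0.25 * (xd + f$self_dimer[i] + r$self_dimer[j])
        pairs[[length(pairs) + 1L]] <- data.frame(
          fwd_start = f$start[i], fwd_seq = f$sequence[i],
          fwd_tm = f$tm_celsius[i], rev_start = r$start[j],
          rev_end = r$end[j], rev_seq = r$sequence[j],
          rev_tm = r$tm_celsius[j], amplicon_length = amplicon,
          tm_difference = tmd, cross_dimer = xd,
          pair_score = -penalty, stringsAsFactors = FALSE)
      }
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(fwd_start = integer(), fwd_seq = character(),
               fwd_tm = numeric(), rev_start = integer(), rev_end = integer(),
               rev_seq = character(), rev_tm = numeric(),
               amplicon_length = integer(), tm_difference = numeric(),
               cross_dimer = integer(), pair_score = numeric(),
               stringsAsFactors = FALSE)
  if (nrow(pairs)) {
    pairs <- pairs[order(-pairs$pair_score, pairs$fwd_start, pairs$rev_start), ]
    rownames(pairs) <- NULL
  }
  list(pairs = head(pairs, top_k), all_pairs = pairs,
       candidates = rbind(f, r), feasibility = feas,
       attrition = list(forward = fwd$attrition, reverse = rev_$attrition))
}

#' Read a cDNA template from a FASTA file
#'
#' @param path FASTA file; the first record is used.
#' @return named character string (name = record id).
#' @export
readTemplateFasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (!length(seqs)) stop("no FASTA records in ", path)
  setNames(as.character(seqs[[1]]), names(seqs)[1])
}
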