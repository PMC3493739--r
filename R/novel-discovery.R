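# Novel miRNA candidate calling: coordinate parsing and arithmetic for
# Table-I-style records, a stem-loop restricted folding wrapper around the
# compiled DP, and the candidate caller applied to unannotated
# genome-matched tags.

#' Parse a `chrN:start:end:strand` location string
#'
#' Tolerates spaces around the strand and a Unicode minus sign for the minus
#' strand (both occur in typeset tables).
#'
#' @param text location string, e.g. `"chr4:16229484:16229558:+"`.
#' @return list with `chrom`, `start`, `end` (integers, preserved exactly),
#'   and `strand` (`"+"` or `"-"`).
#' @export
parse_location <- function(text) {
  stopifnot(length(text) == 1L)
  text <- gsub("−", "-", text)
  parts <- trimws(strsplit(text, ":", fixed = TRUE)[[1]])
  if (length(parts) != 4L) {
    stop("location must have 4 colon-separated fields, got ", length(parts))
  }
  start <- suppressWarnings(as.integer(parts[2]))
  end <- suppressWarnings(as.integer(parts[3]))
  if (!nzchar(parts[1])) stop("location field 1 (chromosome) is empty")
  if (is.na(start)) stop("location field 2 (start) is not an integer: '", parts[2], "'")
  if (is.na(end)) stop("location field 3 (end) is not an integer: '", parts[3], "'")
  if (!parts[4] %in% c("+", "-")) {
    stop("location field 4 (strand) must be + or -, got '", parts[4], "'")
  }
  if (start > end) stop("location start (", start, ") > end (", end, ")")
  list(chrom = parts[1], start = start, end = end, strand = parts[4])
}

#' Precursor length from a locus
#'
#' @param locus a locus list from [parse_location()], or anything with
#'   numeric `start` and `end` fields.
#' @return `end - start + 1` (nt).
#' @export
precursor_length <- function(locus) {
  locus$end - locus$start + 1L
}

#' Fold a candidate precursor into its best stem-loop
#'
#' Minimum-energy single stem-loop under the package's constant energy
#' scale: pair strengths G:C 3.3, A:U 0.9, G:U 1.0 kcal/mol, stacked pairs
#' contributing the mean strength of the stack's two pairs, linear penalties
#' for interior loops/bulges and for the terminal loop.  T is mapped to U on
#' input.  Deterministic; sequences with no stabilizing stem fold to an MFE
#' of 0 with no structure.
#'
#' @param sequence precursor sequence (DNA or RNA alphabet), 50-120 nt.
#' @param min_loop,max_loop terminal loop length bounds considered by the
#'   folder.
#' @param max_bulge maximum unpaired nucleotides bridged on either side of
#'   an interior loop.
#' @return list with `mfe` (kcal/mol, <= 0), `structure` (dot-bracket),
#'   `pairs` (1-based partner index per position, 0 = unpaired), and
#'   `loop_start`/`loop_end` (1-based terminal loop span, `NA` if
#'   unstructured).
#' @export
fold_hairpin <- function(sequence, min_loop = 3L, max_loop = 30L,
                         max_bulge = 6L) {
  stopifnot(length(sequence) == 1L)
  n <- nchar(sequence)
  if (n < 50L || n > 120L) stop("precursor length must be in [50, 120] nt")
  rna <- chartr("Tt", "Uu", sequence)
  if (grepl("[^ACGUacgu]", rna)) stop("non-ACGU character after T->U mapping")
  .hairpin_fold_cpp(toupper(rna), min_loop = min_loop, max_loop = max_loop,
                    max_bulge = max_bulge)
}

#' Default thresholds of the stem-loop candidate caller
#'
#' @param mfe_max maximum (most positive) accepted precursor MFE, kcal/mol.
#' @param precursor_min,precursor_max precursor length bounds, nt.
#' @param loop_min,loop_max accepted terminal loop length, nt.
#' @param min_paired_mature minimum mature bases paired in the stem.
#' @param flank_max how far the precursor window may extend past the mature
#'   locus on either side, nt.
#' @param flank_step step of the window search, nt.
#' @param max_hits_per_tag genomic hits examined per tag.
#' @return list of thresholds for [call_candidates()].
#' @export
hairpin_params <- function(mfe_max = -18, precursor_min = 60L,
                           precursor_max = 100L, loop_min = 3L,
                           loop_max = 20L, min_paired_mature = 14L,
                           flank_max = 80L, flank_step = 5L,
                           max_hits_per_tag = 4L) {
  list(mfe_max = mfe_max, precursor_min = precursor_min,
       precursor_max = precursor_max, loop_min = loop_min,
       loop_max = loop_max, min_paired_mature = min_paired_mature,
       flank_max = flank_max, flank_step = flank_step,
       max_hits_per_tag = max_hits_per_tag)
}

#' Call novel miRNA candidates from unannotated tags
#'
#' For every genomic hit of every tag, precursor windows extending up to
#' `flank_max` nt up- and downstream (on a `flank_step` grid) are folded; a
#' candidate is emitted when some window folds into a stem-loop with MFE at
#' or below `mfe_max`, a terminal loop of accepted length, the mature tag
#' entirely within one arm, and at least `min_paired_mature` mature bases
#' paired.  Per tag the single best-scoring window (lowest MFE, then
#' narrowest, then left-most) is reported; the candidate count equals the
#' tag count.
#'
#' @param tags tag data frame (`sequence`, `count`).
#' @param genome a `ToyGenome`, named character vector, or `DNAStringSet`.
#' @param hits optional precomputed [map_exact()] table for `tags`.
#' @param params thresholds from [hairpin_params()].
#' @return data frame of hairpin candidates: `name`, `sequence`, `arm`
#'   (`"5p"`/`"3p"`), `length`, `chrom`, `start`, `end`, `strand`,
#'   `precursor_length`, `mfe`, `count`; zero rows when nothing qualifies.
#' @export
call_candidates <- function(tags, genome, hits = NULL,
                            params = hairpin_params()) {
  stopifnot(is.data.frame(tags))
  seqs <- genome_sequences(genome)
  if (is.null(hits)) hits <- map_exact(tags, genome)
  out <- list()
  for (ti in seq_len(nrow(tags))) {
    tag <- tags$sequence[ti]
    h <- hits[hits$tag == tag, , drop = FALSE]
    if (!nrow(h)) next
    h <- head(h[order(h$chrom, h$start), , drop = FALSE],
              params$max_hits_per_tag)
    best <- NULL
    for (hi in seq_len(nrow(h))) {
      cand <- best_hairpin_window(tag, h[hi, ], seqs, params)
      if (is.null(cand)) next
      if (is.null(best) ||
          cand$mfe < best$mfe ||
          (cand$mfe == best$mfe && cand$precursor_length < best$precursor_length)) {
        best <- cand
      }
    }
    if (!is.null(best)) {
      best$count <- tags$count[ti]
      out[[length(out) + 1L]] <- best
    }
  }
  if (!length(out)) {
    return(data.frame(
      name = character(), sequence = character(), arm = character(),
      length = integer(), chrom = character(), start = integer(),
      end = integer(), strand = character(), precursor_length = integer(),
      mfe = numeric(), count = integer(), stringsAsFactors = FALSE
    ))
  }
  d <- do.call(rbind, lapply(out, as.data.frame, stringsAsFactors = FALSE))
  d <- d[order(-d$count, d$sequence), , drop = FALSE]
  d$name <- sprintf("candidate-%02d", seq_len(nrow(d)))
  rownames(d) <- NULL
  d[, c("name", "sequence", "arm", "length", "chrom", "start", "end",
        "strand", "precursor_length", "mfe", "count")]
}

# Search the window grid around one genomic hit; returns the best accepted
# candidate record (without count/name) or NULL.
#' @noRd
best_hairpin_window <- function(tag, hit, seqs, params) {
  chrom_seq <- seqs[[hit$chrom]]
  chrom_len <- nchar(chrom_seq)
  m_len <- nchar(tag)
  grid <- seq(0L, params$flank_max, by = params$flank_step)
  best <- NULL
  for (up in grid) {
    for (down in grid) {
      wlen <- m_len + up + down
      if (wlen < params$precursor_min || wlen > params$precursor_max) next
      wstart <- hit$start - up
      wend <- hit$end + down
      if (wstart < 1L || wend > chrom_len) next
      window <- substr(chrom_seq, wstart, wend)
      if (hit$strand == "+") {
        precursor <- window
        mstart <- up + 1L
      } else {
        precursor <- revcomp(window)
        mstart <- down + 1L
      }
      mend <- mstart + m_len - 1L
      fold <- fold_hairpin(precursor, min_loop = params$loop_min,
                           max_loop = params$loop_max)
      if (fold$mfe > params$mfe_max) next
      if (is.na(fold$loop_start)) next
      loop_len <- fold$loop_end - fold$loop_start + 1L
      if (loop_len < params$loop_min || loop_len > params$loop_max) next
      arm <- if (mend < fold$loop_start) "5p"
             else if (mstart > fold$loop_end) "3p"
             else next  # mature overlaps the terminal loop
      paired <- sum(fold$pairs[mstart:mend] > 0L)
      if (paired < params$min_paired_mature) next
      cand <- list(
        name = NA_character_, sequence = tag, arm = arm, length = m_len,
        chrom = hit$chrom, start = wstart, end = wend,
        strand = hit$strand, precursor_length = wlen, mfe = fold$mfe
      )
      if (is.null(best) ||
          cand$mfe < best$mfe ||
          (cand$mfe == best$mfe && (cand$precursor_length < best$precursor_length ||
            (cand$precursor_length == best$precursor_length && cand$start < best$start)))) {
        best <- cand
      }
    }
  }
  best
}

#' Candidates shared between two libraries
#'
#' A candidate is shared when the mature sequence is identical and the
#' precursor loci overlap on the same chromosome and strand.
#'
#' @param a,b candidate data frames from [call_candidates()].
#' @return the rows of `a` that are shared with `b`.
#' @export
intersect_candidates <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(a[integer(), , drop = FALSE])
  shared <- vapply(seq_len(nrow(a)), function(i) {
    m <- b$sequence == a$sequence[i] & b$chrom == a$chrom[i] &
      b$strand == a$strand[i] & b$start <= a$end[i] & b$end >= a$start[i]
    any(m)
  }, logical(1))
  out <- a[shared, , drop = FALSE]
  rownames(out) <- NULL
  out
}
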