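# Read cleaning: quality filter, 5' contaminant removal, 3' adapter
# trimming, length filter, and collapsing of kept inserts into unique tags.
# Each rejected read carries exactly one rejection reason, assigned in the
# fixed order quality -> 5' contaminant -> no 3' adapter -> length.

# Character matrix view of equal-length reads; variable lengths are padded
# with spaces so out-of-range comparisons never match a base.
#' @noRd
read_matrix <- function(reads, width = max(nchar(reads))) {
  padded <- formatC(reads, width = width, flag = "-")
  matrix(unlist(strsplit(padded, ""), use.names = FALSE),
         nrow = length(reads), ncol = width, byrow = TRUE)
}

#' Trim the 3' adapter from reads
#'
#' Finds the left-most adapter match in each read, allowing one mismatch per
#' 10 aligned adapter bases, and returns the insert (the read prefix before
#' the match).  A match may run off the 3' end of the read (partial adapter)
#' as long as the overlap is at least `min_overlap`.
#'
#' @param reads character vector of read sequences.
#' @param adapter 3' adapter sequence; must be at least `min_overlap` long.
#' @param min_overlap minimum aligned adapter bases required to call a match.
#' @return data frame with `insert` (the trimmed sequence; `""` when the
#'   adapter starts at position 1) and `found` (logical, adapter located).
#'   Reads where no adapter is found keep their full sequence with
#'   `found = FALSE`.
#' @export
trim_adapter3 <- function(reads, adapter, min_overlap = 6L) {
  if (nchar(adapter) < min_overlap) stop("adapter shorter than min_overlap")
  n <- length(reads)
  if (n == 0L) {
    return(data.frame(insert = character(), found = logical(),
                      stringsAsFactors = FALSE))
  }
  width <- max(nchar(reads))
  M <- read_matrix(reads, width)
  achars <- strsplit(adapter, "")[[1]]
  match_at <- rep(NA_integer_, n)
  lens <- nchar(reads)
  for (s in seq_len(width - min_overlap + 1L)) {
    ov <- pmin(length(achars), lens - s + 1L)
    cand <- is.na(match_at) & ov >= min_overlap
    if (!any(cand)) next
    span <- min(length(achars), width - s + 1L)
    cols <- s:(s + span - 1L)
    mm_all <- M[, cols, drop = FALSE] !=
      matrix(achars[seq_len(span)], n, span, byrow = TRUE)
    # only count mismatches within each read's actual overlap
    in_ov <- outer(ov, seq_len(span), ">=")
    mm <- rowSums(mm_all & in_ov)
    allowed <- floor(pmin(ov, span) / 10)
    hit <- cand & mm <= allowed
    match_at[hit] <- s
  }
  found <- !is.na(match_at)
  insert <- reads
  insert[found] <- substr(reads[found], 1L, match_at[found] - 1L)
  data.frame(insert = insert, found = found, stringsAsFactors = FALSE)
}

#' Flag 5' adapter ligation contaminants
#'
#' A read is a contaminant when its prefix matches the 5' adapter over at
#' least 8 bases with at most one mismatch.  Only the read prefix is
#' examined; an adapter occurrence at an internal position is ignored.
#'
#' @param reads character vector of read sequences.
#' @param adapter5 5' adapter sequence.
#' @return logical vector, `TRUE` for contaminant reads to reject.
#' @export
is_contaminant5 <- function(reads, adapter5) {
  n <- length(reads)
  if (n == 0L) return(logical())
  ov <- pmin(nchar(adapter5), nchar(reads))
  res <- rep(FALSE, n)
  eligible <- ov >= 8L
  if (!any(eligible)) return(res)
  width <- max(ov[eligible])
  M <- read_matrix(substr(reads[eligible], 1L, ov[eligible]), width)
  achars <- strsplit(adapter5, "")[[1]][seq_len(width)]
  mm_all <- M != matrix(achars, sum(eligible), width, byrow = TRUE)
  in_ov <- outer(ov[eligible], seq_len(width), ">=")
  res[eligible] <- rowSums(mm_all & in_ov) <= 1L
  res
}

#' Length filter for trimmed inserts
#'
#' @param inserts character vector of insert sequences.
#' @param min_len,max_len inclusive length bounds (defaults 18 and 30 nt).
#' @return logical vector, `TRUE` for inserts to keep.
#' @export
length_filter <- function(inserts, min_len = 18L, max_len = 30L) {
  n <- nchar(inserts)
  n >= min_len & n <= max_len
}

#' Collapse inserts into unique tags with counts
#'
#' @param inserts character vector of kept insert sequences.
#' @return data frame with `sequence` and `count`, ordered by decreasing
#'   count then sequence; counts sum to `length(inserts)`.
#' @export
collapse_tags <- function(inserts) {
  if (length(inserts) == 0L) {
    return(data.frame(sequence = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  tab <- table(inserts)
  d <- data.frame(sequence = names(tab), count = as.integer(tab),
                  stringsAsFactors = FALSE)
  d <- d[order(-d$count, d$sequence), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Preprocess a small-RNA library into clean tags
#'
#' Applies, in order: mean-quality/N filter, 5' contaminant removal, 3'
#' adapter trimming, and the length filter; kept inserts are collapsed into
#' unique tags.  Every input read is accounted for exactly once, either as a
#' kept read or under a single rejection reason.
#'
#' @param reads character vector of read sequences, or a FASTQ path (read
#'   via Biostrings).
#' @param adapter3 3' adapter sequence.
#' @param adapter5 optional 5' adapter for contaminant removal.
#' @param qualities optional character vector of Phred+33 quality strings
#'   (ignored when `reads` is a FASTQ path, where qualities come from the
#'   file).
#' @param min_len,max_len inclusive insert length bounds.
#' @param min_quality minimum mean Phred score; reads below it, or reads
#'   containing N, are rejected for quality.
#' @param require_adapter reject reads in which no 3' adapter is found
#'   (default); when `FALSE` the untrimmed read continues down the pipeline.
#' @param min_overlap minimum adapter overlap for [trim_adapter3()].
#' @return list with `tags` (collapsed tag data frame), `summary` (data
#'   frame of reason -> reads, including `kept`), and `n_input`.
#' @export
preprocess_reads <- function(reads, adapter3, adapter5 = NULL,
                             qualities = NULL, min_len = 18L, max_len = 30L,
                             min_quality = 20, require_adapter = TRUE,
                             min_overlap = 6L) {
  if (length(reads) == 1L && file.exists(reads) && !is_dna(reads)) {
    # the reader warns that it drops its own metadata columns; qualities are
    # extracted explicitly below, so nothing is lost
    fq <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(reads))
    qualities <- as.character(Biostrings::quality(fq))
    reads <- as.character(fq)
  }
  n <- length(reads)
  reason <- rep(NA_character_, n)

  bad_q <- grepl("N", reads, fixed = TRUE)
  if (!is.null(qualities)) {
    mean_q <- vapply(
      as(Biostrings::PhredQuality(qualities), "IntegerList"),
      mean, numeric(1)
    )
    bad_q <- bad_q | mean_q < min_quality
  }
  reason[bad_q] <- "quality"

  live <- is.na(reason)
  if (!is.null(adapter5) && any(live)) {
    contam <- is_contaminant5(reads[live], adapter5)
    reason[live][contam] <- "contaminant5"
  }

  live <- is.na(reason)
  inserts <- reads
  if (any(live)) {
    tr <- trim_adapter3(reads[live], adapter3, min_overlap = min_overlap)
    inserts[live] <- tr$insert
    if (require_adapter) reason[live][!tr$found] <- "no_adapter3"
  }

  live <- is.na(reason)
  keep <- live & length_filter(inserts, min_len, max_len)
  reason[live & !keep] <- "length"

  tags <- collapse_tags(inserts[keep])
  reasons <- c("quality", "contaminant5", "no_adapter3", "length")
  summary <- data.frame(
    reason = c("kept", reasons),
    reads = c(sum(keep), vapply(reasons, function(r) sum(reason == r, na.rm = TRUE), integer(1))),
    stringsAsFactors = FALSE
  )
  stopifnot(sum(summary$reads) == n)
  list(tags = tags, summary = summary, n_input = n)
}

#' Write collapsed tags as FASTA with count-embedded headers
#'
#' Headers follow the common small-RNA convention `>tagN_xCOUNT`.
#'
#' @param tags tag data frame from [collapse_tags()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_tag_fasta <- function(tags, path) {
  seqs <- Biostrings::DNAStringSet(tags$sequence)
  names(seqs) <- sprintf("tag%d_x%d", seq_len(nrow(tags)), tags$count)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a count-embedded tag FASTA back into a tag table
#'
#' @param path FASTA with `>tagN_xCOUNT` headers.
#' @return data frame with `sequence` and `count`.
#' @export
read_tag_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  counts <- as.integer(sub(".*_x(\\d+)$", "\\1", names(x)))
  if (anyNA(counts)) stop("tag FASTA headers must end in _xCOUNT")
  data.frame(sequence = as.character(x), count = counts,
             stringsAsFactors = FALSE)
}
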