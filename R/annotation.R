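# Exact-match genome mapping (k-mer seed index + full-length verification)
# and the priority annotation cascade that assigns each genome-matched tag
# exactly one small-RNA category.

#' Default category priority of the annotation cascade
#'
#' Interval categories are tried in this order; the first category whose
#' interval overlaps any hit of a tag (same strand, >= 1 base) wins.  Tags
#' with no interval overlap fall through to the known-miRNA sequence match,
#' then to `unannotated`.
#'
#' @return character vector of interval categories in priority order.
#' @export
category_priority <- function() {
  c("rRNA", "scRNA", "snoRNA", "snRNA", "piRNA", "tRNA", "repeat", "exon_intron")
}

#' @noRd
genome_sequences <- function(genome) {
  if (inherits(genome, "ToyGenome")) return(genome$chromosomes)
  if (is.character(genome) && !is.null(names(genome))) return(genome)
  if (methods::is(genome, "DNAStringSet")) {
    return(stats::setNames(as.character(genome), names(genome)))
  }
  stop("genome must be a ToyGenome, a named character vector, or a DNAStringSet")
}

#' Build a k-mer seed index over a genome
#'
#' Positions of every overlapping k-mer on the plus strand of each
#' chromosome; [map_exact()] seeds candidate hits from a tag's first k-mer
#' and verifies the full-length match.
#'
#' @param genome a `ToyGenome`, named character vector, or `DNAStringSet`.
#' @param k seed length (tags must be at least `k` long).
#' @return object of class `kmer_index`.
#' @export
kmer_index <- function(genome, k = 12L) {
  seqs <- genome_sequences(genome)
  idx <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(list())
    starts <- seq_len(L - k + 1L)
    kmers <- substring(s, starts, starts + k - 1L)
    split(starts, kmers)
  })
  structure(list(index = idx, seqs = seqs, k = k), class = "kmer_index")
}

#' Map tags to a genome by exact full-length match
#'
#' Reports every perfect full-length occurrence of each tag on either
#' strand.  Minus-strand hits (occurrences of the tag's reverse complement)
#' are reported in plus-strand coordinates of the matched span.  Tags
#' containing non-ACGT characters get no hits and are flagged.
#'
#' @param tags character vector of tag sequences, or a tag data frame with a
#'   `sequence` column.
#' @param genome a `ToyGenome`, named character vector, or `DNAStringSet`.
#' @param index optional prebuilt [kmer_index()].
#' @return data frame with columns `tag`, `chrom`, `start`, `end`, `strand`
#'   (1-based inclusive coordinates), duplicate-free; the attribute
#'   `"invalid"` holds tags with non-ACGT characters.
#' @export
map_exact <- function(tags, genome, index = NULL) {
  if (is.data.frame(tags)) tags <- tags$sequence
  if (is.null(index)) index <- kmer_index(genome)
  stopifnot(inherits(index, "kmer_index"))
  k <- index$k
  invalid <- unique(tags[!is_dna(tags)])
  tags <- unique(tags[is_dna(tags)])

  hit_list <- list()
  for (tag in tags) {
    if (nchar(tag) < k) next
    for (strand in c("+", "-")) {
      q <- if (strand == "+") tag else revcomp(tag)
      seed <- substr(q, 1L, k)
      for (chrom in names(index$index)) {
        starts <- index$index[[chrom]][[seed]]
        if (is.null(starts)) next
        L <- nchar(q)
        ok <- starts[substring(index$seqs[[chrom]], starts, starts + L - 1L) == q]
        if (length(ok)) {
          hit_list[[length(hit_list) + 1L]] <- data.frame(
            tag = tag, chrom = chrom, start = ok, end = ok + L - 1L,
            strand = strand, stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  hits <- if (length(hit_list)) do.call(rbind, hit_list) else data.frame(
    tag = character(), chrom = character(), start = integer(),
    end = integer(), strand = character(), stringsAsFactors = FALSE
  )
  hits <- unique(hits)
  rownames(hits) <- NULL
  attr(hits, "invalid") <- invalid
  hits
}

#' Percentage of genome-matched reads
#'
#' @param matched number of genome-matched reads (0 <= matched <= total).
#' @param total total clean reads (> 0).
#' @return `100 * matched / total`, rounded half-up to two decimals.
#' @export
genome_match_percentage <- function(matched, total) {
  if (any(total <= 0)) stop("total must be > 0")
  if (any(matched < 0 | matched > total)) stop("need 0 <= matched <= total")
  round_half_up(100 * matched / total, 2L)
}

#' Read an annotation BED file
#'
#' BED6 input (0-based half-open, category in the name column, strand in
#' column 6), validated line by line; malformed lines raise an error naming
#' the line number.  Coordinates are converted to the package-internal
#' 1-based inclusive convention.
#'
#' @param path BED file path.
#' @return `GRanges` with a `category` metadata column.
#' @export
read_annotation_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(GenomicRanges::GRanges(category = character()))
  }
  ok_cat <- c(category_priority(), "exon", "intron")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 6L) stop("BED line ", i, ": fewer than 6 fields")
    s <- suppressWarnings(as.integer(p[2])); e <- suppressWarnings(as.integer(p[3]))
    if (is.na(s) || is.na(e) || s < 0L || e <= s) {
      stop("BED line ", i, ": invalid coordinates '", p[2], "', '", p[3], "'")
    }
    if (!p[4] %in% ok_cat) stop("BED line ", i, ": unknown category '", p[4], "'")
    if (!p[6] %in% c("+", "-")) stop("BED line ", i, ": invalid strand '", p[6], "'")
  }
  m <- do.call(rbind, parts)
  category <- m[, 4]
  category[category %in% c("exon", "intron")] <- "exon_intron"
  GenomicRanges::GRanges(
    seqnames = m[, 1],
    ranges = IRanges::IRanges(start = as.integer(m[, 2]) + 1L,
                              end = as.integer(m[, 3])),
    strand = m[, 6],
    category = category
  )
}

#' Assign each tag one category via the priority cascade
#'
#' For every genome-matched tag, the first category in `priority` whose
#' interval overlaps any of the tag's hits by at least one base on the same
#' strand is assigned.  Tags with hits but no interval overlap are compared
#' by exact sequence against the known mature miRNAs (`known_miRNA`), and
#' otherwise are `unannotated`.  Tags with no genome hits carry category
#' `NA`.
#'
#' @param tags tag data frame (`sequence`, `count`).
#' @param hits hit table from [map_exact()].
#' @param annotation `GRanges` from [read_annotation_bed()] (or equivalent
#'   with a `category` column); may be empty.
#' @param known_mirnas named character vector of known mature sequences.
#' @param priority interval category order, default [category_priority()].
#' @return data frame with `sequence`, `count`, `category`, `n_hits`.
#' @export
assign_category <- function(tags, hits, annotation, known_mirnas = character(),
                            priority = category_priority()) {
  stopifnot(is.data.frame(tags), all(c("sequence", "count") %in% names(tags)))
  n_hits <- integer(nrow(tags))
  category <- rep(NA_character_, nrow(tags))
  if (nrow(tags) == 0L) {
    return(data.frame(sequence = character(), count = integer(),
                      category = character(), n_hits = integer(),
                      stringsAsFactors = FALSE))
  }
  tag_cat_from_intervals <- rep(NA_character_, nrow(tags))
  if (nrow(hits)) {
    hit_gr <- GenomicRanges::GRanges(
      seqnames = hits$chrom,
      ranges = IRanges::IRanges(start = hits$start, end = hits$end),
      strand = hits$strand
    )
    if (length(annotation)) {
      ov <- GenomicRanges::findOverlaps(hit_gr, annotation,
                                        minoverlap = 1L, ignore.strand = FALSE)
      if (length(ov)) {
        cat_rank <- match(
          annotation$category[S4Vectors::subjectHits(ov)], priority
        )
        hit_tag <- hits$tag[S4Vectors::queryHits(ov)]
        keep <- !is.na(cat_rank)  # categories outside the cascade are ignored
        if (any(keep)) {
          best <- tapply(cat_rank[keep], hit_tag[keep], min)
          idx <- match(tags$sequence, names(best))
          tag_cat_from_intervals <- priority[best[idx]]
        }
      }
    }
    n_hits <- as.integer(table(factor(hits$tag, levels = tags$sequence)))
  }
  matched <- n_hits > 0L
  category[matched] <- tag_cat_from_intervals[matched]
  fallthrough <- matched & is.na(category)
  category[fallthrough & tags$sequence %in% known_mirnas] <- "known_miRNA"
  category[fallthrough & !tags$sequence %in% known_mirnas] <- "unannotated"
  data.frame(sequence = tags$sequence, count = tags$count,
             category = category, n_hits = n_hits, stringsAsFactors = FALSE)
}

#' Summarize category assignments
#'
#' @param assignments data frame from [assign_category()].
#' @return data frame with `category`, `unique_tags`, `total_reads`; tags
#'   without genome hits appear under `unmatched`.  Read totals over all
#'   rows equal the summed input tag counts.
#' @export
summarize_categories <- function(assignments) {
  if (nrow(assignments) == 0L) {
    return(data.frame(category = character(), unique_tags = integer(),
                      total_reads = integer(), stringsAsFactors = FALSE))
  }
  cat <- assignments$category
  cat[is.na(cat)] <- "unmatched"
  levels <- c(category_priority(), "known_miRNA", "unannotated", "unmatched")
  cat <- factor(cat, levels = levels)
  d <- data.frame(
    category = levels,
    unique_tags = as.integer(table(cat)),
    total_reads = as.integer(tapply(assignments$count, cat, sum, default = 0L)),
    stringsAsFactors = FALSE
  )
  d[d$unique_tags > 0L | d$category %in% c("known_miRNA", "unannotated"), ,
    drop = FALSE] -> d
  rownames(d) <- NULL
  stopifnot(sum(d$total_reads) == sum(assignments$count))
  d
}
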