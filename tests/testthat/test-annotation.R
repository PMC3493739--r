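test_that("exact mapping uses the documented coordinate convention", {
  g <- generate_genome(1, 2000, seed = 3)
  chrom <- g$chromosomes[[1]]
  tag <- substr(chrom, 101, 122)        # offset 100 0-based, length 22
  hits <- map_exact(tag, g)
  plus <- hits[hits$strand == "+", ]
  expect_true(any(plus$start == 101 & plus$end == 122))

  rc <- revcomp(tag)
  hits_rc <- map_exact(rc, g)
  minus <- hits_rc[hits_rc$strand == "-", ]
  expect_true(any(minus$start == 101 & minus$end == 122))

  bad <- map_exact("ACGTNACGTNACGTNACGTN", g)
  expect_identical(nrow(bad), 0L)
  expect_identical(attr(bad, "invalid"), "ACGTNACGTNACGTNACGTN")
})

test_that("k-mer mapping equals the naive full scan on random tag sets", {
  g <- generate_genome(2, 5000, seed = 17)
  chroms <- g$chromosomes
  set.seed(99)
  # mix of planted substrings (guaranteed hits) and random 22-mers
  planted <- vapply(1:30, function(i) {
    c <- sample(names(chroms), 1)
    s <- sample(nchar(chroms[[c]]) - 22L, 1)
    substr(chroms[[c]], s, s + 21L)
  }, character(1))
  random <- vapply(1:100, function(i) rand_mature(22), character(1))
  tags <- unique(c(planted, revcomp(planted[1:10]), random))
  got <- sort_hits(map_exact(tags, g))
  want <- sort_hits(naive_map(tags, chroms))
  expect_identical(got, want)
})

test_that("genome match percentage rounds half-up to two decimals", {
  expect_identical(genome_match_percentage(8014466, 9772392), 82.01)
  expect_identical(genome_match_percentage(8104423, 9717633), 83.40)
  expect_identical(genome_match_percentage(0, 10), 0)
  expect_identical(genome_match_percentage(1, 16), 6.25)
  expect_identical(genome_match_percentage(625, 100000), 0.63) # 0.625 -> up
  expect_error(genome_match_percentage(5, 0))
})

test_that("the category cascade picks the highest-priority overlap", {
  g <- generate_genome(1, 3000, seed = 5)
  tag <- substr(g$chromosomes[[1]], 501, 522)
  tags <- data.frame(sequence = tag, count = 7L, stringsAsFactors = FALSE)
  hits <- map_exact(tags, g)
  # overlapping tRNA and exon intervals: tRNA outranks exon_intron
  ann <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(490, 480), c(530, 600)), strand = "+",
    category = c("exon_intron", "tRNA")
  )
  a <- assign_category(tags, hits, ann)
  expect_identical(a$category, "tRNA")

  # strand-aware: minus-strand interval does not annotate a plus-strand hit
  ann_minus <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(490, 530), strand = "-", category = "rRNA"
  )
  a2 <- assign_category(tags, hits, ann_minus, known_mirnas = tag)
  expect_identical(a2$category, "known_miRNA")

  # no interval, unknown sequence -> unannotated; unmapped tag -> NA
  a3 <- assign_category(
    data.frame(sequence = c(tag, rand_mature(22, seed = 1)),
               count = c(1L, 1L), stringsAsFactors = FALSE),
    hits, GenomicRanges::GRanges(category = character())
  )
  expect_identical(a3$category[1], "unannotated")
  expect_true(is.na(a3$category[2]))
})

test_that("random interval assignment agrees with a brute-force rederivation", {
  g <- generate_genome(1, 4000, seed = 23)
  chrom <- g$chromosomes[[1]]
  set.seed(7)
  tags <- data.frame(
    sequence = unique(vapply(1:40, function(i) {
      s <- sample(3978L, 1)
      substr(chrom, s, s + 21L)
    }, character(1))),
    stringsAsFactors = FALSE
  )
  tags$count <- seq_len(nrow(tags))
  hits <- map_exact(tags, g)
  cats <- category_priority()
  ann_df <- data.frame(
    start = sample(3900L, 60, replace = TRUE),
    category = sample(cats, 60, replace = TRUE),
    strand = sample(c("+", "-"), 60, replace = TRUE)
  )
  ann_df$end <- ann_df$start + sample(10:80, 60, replace = TRUE)
  ann <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(ann_df$start, ann_df$end),
                                strand = ann_df$strand,
                                category = ann_df$category)
  got <- assign_category(tags, hits, ann)
  # brute-force: loop categories in priority order, any same-strand overlap
  want <- vapply(seq_len(nrow(tags)), function(i) {
    h <- hits[hits$tag == tags$sequence[i], , drop = FALSE]
    if (!nrow(h)) return(NA_character_)
    for (cat in cats) {
      iv <- ann_df[ann_df$category == cat, , drop = FALSE]
      for (r in seq_len(nrow(h))) {
        ok <- iv$start <= h$end[r] & iv$end >= h$start[r] &
          iv$strand == h$strand[r]
        if (any(ok)) return(cat)
      }
    }
    "unannotated"
  }, character(1))
  expect_identical(got$category, want)
})

test_that("category summaries conserve reads and tags", {
  a <- data.frame(
    sequence = c("A", "B", "C", "D"),
    count = c(3L, 5L, 2L, 7L),
    category = c("tRNA", "tRNA", NA, "known_miRNA"),
    n_hits = c(1L, 2L, 0L, 1L),
    stringsAsFactors = FALSE
  )
  s <- summarize_categories(a)
  expect_identical(s$unique_tags[s$category == "tRNA"], 2L)
  expect_identical(s$total_reads[s$category == "tRNA"], 8L)
  expect_identical(s$total_reads[s$category == "unmatched"], 2L)
  expect_identical(sum(s$total_reads), sum(a$count))
  expect_identical(nrow(summarize_categories(a[0, ])), 0L)
})

test_that("BED parsing converts coordinates and names malformed lines", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t150\trRNA\t0\t+",
               "chr1\t200\t260\texon\t0\t-"), bed)
  gr <- read_annotation_bed(bed)
  expect_identical(GenomicRanges::start(gr), c(101L, 201L))
  expect_identical(GenomicRanges::end(gr), c(150L, 260L))
  expect_identical(gr$category, c("rRNA", "exon_intron"))

  writeLines(c("chr1\t100\t150\trRNA\t0\t+",
               "chr1\t90\t80\trRNA\t0\t+"), bed)
  expect_error(read_annotation_bed(bed), "line 2")
  writeLines("chr1\t100\t150\tnot_a_class\t0\t+", bed)
  expect_error(read_annotation_bed(bed), "line 1")
})

test_that("annotation of a simulated library matches its truth table", {
  design <- default_design()
  cfg <- read_sim_config(total_reads = 8000, error_rate = 0, seed = 4)
  ref <- build_reference(design, seed = 6)
  sim <- simulate_library(design, cfg, "A")
  pp <- preprocess_reads(sim$reads$sequence, adapter3 = cfg$adapter3)
  ann <- with(ref$annotation, GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start, end), strand = strand, category = category
  ))
  asg <- assign_category(pp$tags, map_exact(pp$tags, ref$genome), ann,
                         ref$known_mirnas)
  truth <- sim$truth[sim$truth$count > 0, ]
  class_map <- c(rRNA = "rRNA", tRNA = "tRNA", snoRNA = "snoRNA",
                 "repeat" = "repeat", exon = "exon_intron",
                 known_mirna = "known_miRNA", novel = "unannotated")
  m <- match(truth$mature, asg$sequence)
  expect_false(anyNA(m))
  expect_identical(asg$category[m], unname(class_map[truth$type]))
  expect_identical(asg$count[m], truth$count)
})

test_that("annotation BED writing and reading round-trip the intervals", {
  design <- default_design()
  ref <- build_reference(design, seed = 2)
  bed <- tempfile(fileext = ".bed")
  write_annotation_bed(ref$annotation, bed)
  gr <- read_annotation_bed(bed)
  expect_identical(GenomicRanges::start(gr), ref$annotation$start)
  expect_identical(GenomicRanges::end(gr), ref$annotation$end)
  expect_identical(gr$category, ref$annotation$category)
})
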