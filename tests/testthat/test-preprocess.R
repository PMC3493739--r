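adapter <- "TCGTATGCCGTCTTCTGCTTG"

test_that("3' adapter trimming finds the left-most tolerant match", {
  insert <- "TGAGGTAGTAGGTTGTATAGTT"
  r <- trim_adapter3(paste0(insert, adapter), adapter)
  expect_identical(r$insert, insert)
  expect_true(r$found)

  # pure adapter: empty insert
  r2 <- trim_adapter3(adapter, adapter)
  expect_true(r2$found)
  expect_identical(r2$insert, "")

  # partial adapter at the read end (overlap 8, no mismatch)
  r3 <- trim_adapter3(paste0(insert, substr(adapter, 1, 8)), adapter)
  expect_identical(r3$insert, insert)

  # one mismatch in a 12-base overlap is tolerated (1 per 10 bases)
  ad12 <- substr(adapter, 1, 12)
  mm <- paste0(substr(ad12, 1, 5), "A", substr(ad12, 7, 12))
  expect_false(substr(ad12, 6, 6) == "A")
  r4 <- trim_adapter3(paste0(insert, mm), adapter)
  expect_identical(r4$insert, insert)

  # ... but not in an 8-base overlap (0 allowed)
  ad8 <- substr(adapter, 1, 8)
  mut <- setdiff(c("A", "C", "G", "T"), substr(ad8, 5, 5))[1]
  mm8 <- paste0(substr(ad8, 1, 4), mut, substr(ad8, 6, 8))
  r5 <- trim_adapter3(paste0(insert, mm8), adapter)
  expect_false(r5$found)

  # left-most match wins against a brute-force scan over random reads
  set.seed(31)
  reads <- vapply(1:200, function(i) {
    paste0(rand_mature(sample(10:28, 1)), adapter,
           rand_mature(sample(0:6, 1)))
  }, character(1))
  got <- trim_adapter3(reads, adapter)
  naive <- vapply(reads, function(rd) {
    best <- NA_integer_
    for (s in seq_len(nchar(rd))) {
      ov <- min(nchar(adapter), nchar(rd) - s + 1L)
      if (ov < 6) next
      a <- substr(adapter, 1, ov)
      b <- substr(rd, s, s + ov - 1L)
      mm <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
      if (mm <= floor(ov / 10)) { best <- s; break }
    }
    best
  }, integer(1), USE.NAMES = FALSE)
  expect_identical(nchar(got$insert), naive - 1L)
})

test_that("5' contaminant detection is prefix-only", {
  a5 <- "GTTCAGAGTTCTACAGTCCGACGATC"
  read <- "TGAGGTAGTAGGTTGTATAGTT"
  expect_true(is_contaminant5(paste0(a5, read), a5))
  expect_true(is_contaminant5(substr(a5, 1, 12), a5))     # partial but >= 8
  expect_false(is_contaminant5(read, a5))
  # adapter at an internal position only: not a contaminant
  expect_false(is_contaminant5(paste0("ACGTACGTAC", a5), a5))
  # one mismatch tolerated
  mut <- paste0("A", substr(a5, 2, nchar(a5)))
  expect_false(substr(a5, 1, 1) == "A")
  expect_true(is_contaminant5(paste0(mut, read), a5))
  # short reads (< 8 bases overlap) are never called contaminants
  expect_false(is_contaminant5("GTTCAGA", a5))
})

test_that("length filter keeps the inclusive 18-30 range and is idempotent", {
  expect_true(length_filter(strrep("A", 22)))
  expect_true(length_filter(strrep("A", 18)))
  expect_true(length_filter(strrep("A", 30)))
  expect_false(length_filter(strrep("A", 17)))
  expect_false(length_filter(strrep("A", 31)))
  x <- vapply(1:50, function(i) strrep("A", sample(10:40, 1)), character(1))
  k1 <- x[length_filter(x)]
  expect_identical(k1[length_filter(k1)], k1)
})

test_that("tag collapsing conserves counts and is idempotent in spirit", {
  x <- c(rep(strrep("A", 20), 3), strrep("C", 20))
  tags <- collapse_tags(x)
  expect_identical(nrow(tags), 2L)
  expect_identical(sort(tags$count), c(1L, 3L))
  expect_identical(nrow(collapse_tags(character())), 0L)

  set.seed(12)
  pool <- vapply(1:40, function(i) rand_mature(20), character(1))
  big <- sample(pool, 1e5, replace = TRUE)
  tags2 <- collapse_tags(big)
  expect_identical(sum(tags2$count), 100000L)
})

test_that("every read is accounted for under exactly one rejection reason", {
  design <- default_design()
  cfg <- read_sim_config(total_reads = 4000,
                         adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
                         seed = 8)
  sim <- simulate_library(design, cfg, "A")
  # spike in some reads the filters must reject
  reads <- c(sim$reads$sequence,
             strrep("N", 36),                           # quality (N)
             paste0(rand_mature(40)),                   # no adapter
             paste0(rand_mature(10), cfg$adapter3))     # too short
  pp <- preprocess_reads(reads, adapter3 = cfg$adapter3, adapter5 = cfg$adapter5)
  expect_identical(sum(pp$summary$reads), length(reads))
  expect_gte(pp$summary$reads[pp$summary$reason == "quality"], 1L)
  expect_gte(pp$summary$reads[pp$summary$reason == "no_adapter3"], 1L)
  expect_gte(pp$summary$reads[pp$summary$reason == "length"], 1L)
  expect_gte(pp$summary$reads[pp$summary$reason == "contaminant5"], 1L)
  expect_identical(sum(pp$tags$count),
                   pp$summary$reads[pp$summary$reason == "kept"])
})

test_that("error-free preprocessing reproduces the simulation truth exactly", {
  design <- default_design()
  cfg <- read_sim_config(total_reads = 5000, error_rate = 0, seed = 13)
  sim <- simulate_library(design, cfg, "A")
  pp <- preprocess_reads(sim$reads$sequence, adapter3 = cfg$adapter3)
  truth <- sim$truth[sim$truth$count > 0, ]
  expect_identical(nrow(pp$tags), nrow(truth))
  m <- match(truth$mature, pp$tags$sequence)
  expect_false(anyNA(m))
  expect_identical(pp$tags$count[m], truth$count)
})

test_that("FASTQ and tag-FASTA round-trips preserve sequences and counts", {
  design <- default_design()
  cfg <- read_sim_config(total_reads = 500, seed = 21)
  sim <- simulate_library(design, cfg, "A")
  fq <- tempfile(fileext = ".fastq")
  write_fastq(sim, fq)
  pp_file <- preprocess_reads(fq, adapter3 = cfg$adapter3)
  pp_mem <- preprocess_reads(sim$reads$sequence, adapter3 = cfg$adapter3,
                             qualities = sim$reads$quality)
  expect_identical(pp_file$tags, pp_mem$tags)

  fa <- tempfile(fileext = ".fasta")
  write_tag_fasta(pp_mem$tags, fa)
  back <- read_tag_fasta(fa)
  expect_identical(back$sequence, pp_mem$tags$sequence)
  expect_identical(back$count, pp_mem$tags$count)
})
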