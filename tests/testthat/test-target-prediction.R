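test_that("duplex states and mismatch scores follow the wobble convention", {
  m <- "GGGAAA"
  expect_identical(duplex_states(m, perfect_site(m)), rep("WC", 6))
  expect_equal(score_mismatches(m, perfect_site(m)), 0)
  # one wobble: G at position 1 faces T
  s1 <- site_with(m, wobble_at = 1)
  expect_identical(duplex_states(m, s1)[1], "GU")
  expect_equal(score_mismatches(m, s1), 0.5)
  # 3 mismatches + 2 wobbles = 4.0
  s2 <- site_with(m, mismatch_at = 4:6, wobble_at = 1:2)
  expect_equal(score_mismatches(m, s2), 4.0)
  expect_error(duplex_states("AAA", "AAAA"), "ungapped")
})

test_that("individual rules fire on constructed violations", {
  m <- rand_mature(21, seed = 8)
  perfect <- check_rules(m, perfect_site(m))
  expect_true(perfect$pass)
  expect_equal(perfect$mfe_ratio, 1.0)

  # rule iv: mismatches at positions 10-11
  r_iv <- check_rules(m, site_with(m, mismatch_at = 10:11))
  expect_false(r_iv$rule_iv)
  # rule iii: adjacent mismatches inside positions 2-12
  r_iii <- check_rules(m, site_with(m, mismatch_at = 5:6))
  expect_false(r_iii$rule_iii)
  expect_true(r_iii$rule_ii)       # run of two is allowed globally
  # rule ii: a run of three outside the seed
  r_ii <- check_rules(m, site_with(m, mismatch_at = 14:16))
  expect_false(r_ii$rule_ii)
  # rule i: five spread mismatches
  r_i <- check_rules(m, site_with(m, mismatch_at = c(1, 3, 5, 7, 9)))
  expect_false(r_i$rule_i)
  expect_false(r_i$rule_v)         # 5.0 > 2.5 in positions 1-12 too
  # rule v only by count: three spread mismatches in 1-12
  r_v <- check_rules(m, site_with(m, mismatch_at = c(1, 3, 5)))
  expect_true(r_v$rule_i)
  expect_false(r_v$rule_v)
})

test_that("wobbles are pairs for adjacency rules unless strict mode", {
  m <- "GGGGGGGGGGGGGGGGGGGGG"  # all-G: every position can wobble
  s <- site_with(m, wobble_at = 10:11)
  default_mode <- check_rules(m, s)
  strict <- check_rules(m, s, gu_as_mismatch = TRUE)
  expect_true(default_mode$rule_iv)
  expect_false(strict$rule_iv)
})

test_that("rule engine equals the brute-force checker exhaustively", {
  # reduced alphabets against an all-G miRNA: site letters C (WC), T (GU),
  # A (mismatch).  {C,A} and {C,T} are exhaustive through length 12;
  # the full 3-letter space is exhaustive through length 7 and sampled
  # beyond.
  disagreements <- character()
  compare <- function(mirna, site) {
    rules <- c("rule_i", "rule_ii", "rule_iii", "rule_iv", "rule_v")
    got <- check_rules(mirna, site)
    want <- naive_rules(mirna, site)
    same <- identical(unlist(got[rules], use.names = FALSE),
                      unlist(want[rules], use.names = FALSE)) &&
      isTRUE(all.equal(got$score, want$score)) &&
      isTRUE(all.equal(got$mfe, naive_duplex_mfe(mirna, site)))
    if (!same) disagreements <<- c(disagreements, paste(mirna, site))
    invisible(same)
  }
  for (L in 1:12) {
    mirna <- strrep("G", L)
    for (letters2 in list(c("C", "A"), c("C", "T"))) {
      grid <- do.call(expand.grid, rep(list(letters2), L))
      sites <- do.call(paste0, grid)
      for (site in sites) compare(mirna, site)
    }
  }
  for (L in 1:7) {
    mirna <- strrep("G", L)
    grid <- do.call(expand.grid, rep(list(c("C", "T", "A")), L))
    for (site in do.call(paste0, grid)) compare(mirna, site)
  }
  set.seed(404)
  for (i in 1:300) {
    L <- sample(8:12, 1)
    compare(strrep("G", L),
            paste(sample(c("C", "T", "A"), L, replace = TRUE), collapse = ""))
  }
  # and random full-alphabet duplexes
  for (i in 1:200) {
    L <- sample(6:12, 1)
    compare(rand_mature(L), rand_mature(L))
  }
  expect_identical(disagreements, character())
})

test_that("duplex energies are monotone and orientation-consistent", {
  m <- "GCGCGCGCGCGCGCGCGCGCG"
  e_perfect <- duplex_mfe(m, perfect_site(m))
  e_mm <- duplex_mfe(m, site_with(m, mismatch_at = 10:11))
  expect_lt(e_perfect, e_mm)
  expect_identical(duplex_mfe("AC", "AC"), 0)  # no pairs at all
  # energy depends only on the stack multiset: reversing both strands
  set.seed(9)
  for (i in 1:20) {
    a <- rand_mature(15)
    b <- rand_mature(15)
    rev_str <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
    expect_equal(duplex_mfe(a, b), duplex_mfe(rev_str(a), rev_str(b)))
  }
})

test_that("adding a mismatch never converts fail to pass for rules i-v", {
  set.seed(15)
  rules <- c("rule_i", "rule_ii", "rule_iii", "rule_iv", "rule_v")
  for (i in 1:40) {
    m <- rand_mature(21)
    base_pos <- sample(21, sample(0:3, 1))
    before <- check_rules(m, site_with(m, mismatch_at = base_pos))
    extra <- sample(setdiff(1:21, base_pos), 1)
    after <- check_rules(m, site_with(m, mismatch_at = c(base_pos, extra)))
    expect_true(all(unlist(before[rules]) | !unlist(after[rules])))
  }
})

test_that("MFE ratio is 1 for perfect sites, low for random ones, inclusive at 0.75", {
  set.seed(33)
  for (i in 1:20) {
    m <- rand_mature(22)
    expect_equal(mfe_ratio(m, perfect_site(m)), 1.0)
  }
  ratios <- vapply(1:100, function(i) {
    mfe_ratio(rand_mature(22, seed = 1000 + i), rand_mature(22, seed = 5000 + i))
  }, numeric(1))
  expect_true(all(ratios < 0.75))
  # the >= comparison is inclusive
  r <- check_rules("GGG", "CCC", mfe_ratio_min = 1.0)
  expect_true(r$rule_vi)
})

test_that("target scanning finds planted antisense sites and nothing else", {
  m <- rand_mature(22, seed = 50)
  set.seed(51)
  tx <- c(
    planted = paste0(rand_mature(60), perfect_site(m), rand_mature(60)),
    sense = paste0(rand_mature(60), m, rand_mature(60)),
    background = rand_mature(142)
  )
  hits <- predict_targets(c(mir1 = m), tx)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$transcript, "planted")
  expect_identical(hits$offset, 61L)

  t2g <- data.frame(transcript = names(tx), gene = c("gA", "gB", "gC"),
                    stringsAsFactors = FALSE)
  hits2 <- predict_targets(c(mir1 = m), tx, tx2gene = t2g)
  expect_identical(hits2$gene, "gA")
  expect_error(predict_targets(c(mir1 = m), character()), "no transcripts")
})

test_that("exactly the rule-compliant planted sites are recovered", {
  # GC-rich miRNA with weak-pair islands at the designed mismatch positions,
  # so single-rule violations do not also collapse the duplex energy
  m <- "GCGGCAGCGACGGCAGTGCGGC"
  stopifnot(nchar(m) == 22)
  compliant_sites <- list(
    perfect_site(m),
    site_with(m, mismatch_at = 5),              # score 1, mid-seed
    site_with(m, wobble_at = 3),                # lone wobble
    site_with(m, mismatch_at = c(3, 14)),       # spread, score 2
    perfect_site(m),
    site_with(m, mismatch_at = 17),
    site_with(m, wobble_at = 17),
    site_with(m, mismatch_at = c(2, 13)),
    perfect_site(m),
    site_with(m, mismatch_at = 9)
  )
  violating_sites <- list(
    site_with(m, mismatch_at = c(1, 3, 5, 7, 9)),    # rule i (and v)
    site_with(m, mismatch_at = 14:16),               # rule ii
    site_with(m, mismatch_at = 5:6),                 # rule iii
    site_with(m, mismatch_at = 10),                  # rule iv
    site_with(m, mismatch_at = 11),                  # rule iv
    site_with(m, mismatch_at = c(1, 3, 12)),         # rule v
    site_with(m, mismatch_at = c(2, 4, 6, 13, 15)),  # rule i
    site_with(m, mismatch_at = 9:11),                # rules iii/iv
    site_with(m, mismatch_at = c(10, 12, 14, 16, 18)), # rules i and iv
    strrep("A", 22)                                   # nothing pairs
  )
  set.seed(52)
  embed <- function(site) paste0(rand_mature(30), site, rand_mature(30))
  tx <- vapply(c(compliant_sites, violating_sites), embed, character(1))
  names(tx) <- sprintf("tx%02d", seq_along(tx))
  hits <- predict_targets(c(mir = m), tx)
  expect_setequal(hits$transcript, sprintf("tx%02d", 1:10))
  expect_true(all(hits$offset == 31L))
})
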