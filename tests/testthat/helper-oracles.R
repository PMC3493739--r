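# Independent brute-force oracles.  These deliberately use the most naive
# algorithm available (full scans, direct summation, exhaustive subset
# enumeration) and share no code with the implementation paths they check.

# naive O(n*m) exact-match scan over both strands
naive_map <- function(tags, chroms) {
  rows <- list()
  for (tag in unique(tags)) {
    if (grepl("[^ACGT]", tag)) next
    for (chrom in names(chroms)) {
      s <- chroms[[chrom]]
      L <- nchar(tag)
      for (strand in c("+", "-")) {
        q <- if (strand == "+") tag else revcomp(tag)
        for (i in seq_len(nchar(s) - L + 1L)) {
          if (substr(s, i, i + L - 1L) == q) {
            rows[[length(rows) + 1L]] <- data.frame(
              tag = tag, chrom = chrom, start = i, end = i + L - 1L,
              strand = strand, stringsAsFactors = FALSE
            )
          }
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(tag = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  unique(do.call(rbind, rows))
}

sort_hits <- function(h) {
  h <- h[order(h$tag, h$chrom, h$start, h$strand), , drop = FALSE]
  rownames(h) <- NULL
  attr(h, "invalid") <- NULL
  h
}

# direct evaluation of the count-probability formula, scalar, no log tricks
ac_prob_naive <- function(x, y, n1, n2) {
  r <- n2 / n1
  r^y * factorial(x + y) / (factorial(x) * factorial(y)) * (1 + r)^(-(x + y + 1))
}

ac_lower_naive <- function(x, y, n1, n2) {
  sum(vapply(0:y, function(t) ac_prob_naive(x, t, n1, n2), numeric(1)))
}

# naive per-position rule checker over an explicit duplex state vector
naive_pair_state <- function(mirna, site) {
  m <- strsplit(mirna, "")[[1]]
  t <- strsplit(site, "")[[1]]
  L <- length(m)
  out <- character(L)
  for (i in seq_len(L)) {
    a <- m[i]
    b <- t[L + 1L - i]   # antiparallel partner
    out[i] <- if ((a == "A" && b == "T") || (a == "T" && b == "A") ||
                  (a == "G" && b == "C") || (a == "C" && b == "G")) "WC"
      else if ((a == "G" && b == "T") || (a == "T" && b == "G")) "GU"
      else "MM"
  }
  out
}

naive_rules <- function(mirna, site, gu_as_mismatch = FALSE) {
  st <- naive_pair_state(mirna, site)
  L <- length(st)
  score <- 0
  for (i in seq_len(L)) {
    if (st[i] == "MM") score <- score + 1
    if (st[i] == "GU") score <- score + 0.5
  }
  mm <- logical(L)
  for (i in seq_len(L)) {
    mm[i] <- st[i] == "MM" || (gu_as_mismatch && st[i] == "GU")
  }
  longest_run <- 0; run <- 0
  for (i in seq_len(L)) {
    run <- if (mm[i]) run + 1 else 0
    longest_run <- max(longest_run, run)
  }
  adj_seed <- FALSE
  for (i in 2:12) {
    if (i + 1 <= min(12, L) && i <= L && mm[i] && mm[i + 1]) adj_seed <- TRUE
  }
  mm_1011 <- FALSE
  for (i in 10:11) if (i <= L && mm[i]) mm_1011 <- TRUE
  score_head <- 0
  for (i in seq_len(min(12, L))) {
    if (st[i] == "MM") score_head <- score_head + 1
    if (st[i] == "GU") score_head <- score_head + 0.5
  }
  list(
    score = score,
    rule_i = score <= 4,
    rule_ii = longest_run <= 2,
    rule_iii = !adj_seed,
    rule_iv = !mm_1011,
    rule_v = score_head <= 2.5
  )
}

# naive duplex energy: same documented constants, written as a plain loop
naive_duplex_mfe <- function(mirna, site) {
  st <- naive_pair_state(mirna, site)
  m <- strsplit(mirna, "")[[1]]
  t <- strsplit(site, "")[[1]]
  L <- length(st)
  strength <- numeric(L)
  for (i in seq_len(L)) {
    a <- m[i]; b <- t[L + 1L - i]
    strength[i] <-
      if ((a == "G" && b == "C") || (a == "C" && b == "G")) 3.3
      else if ((a == "A" && b == "T") || (a == "T" && b == "A")) 0.9
      else if ((a == "G" && b == "T") || (a == "T" && b == "G")) 1.0
      else 0
  }
  e <- 0
  for (i in seq_len(L - 1)) {
    if (strength[i] > 0 && strength[i + 1] > 0) {
      e <- e - (strength[i] + strength[i + 1]) / 2
    }
  }
  # interior unpaired runs flanked by pairs on both sides
  i <- 1
  while (i <= L) {
    if (strength[i] == 0) {
      j <- i
      while (j < L && strength[j + 1] == 0) j <- j + 1
      if (i > 1 && j < L) e <- e + 0.5
      i <- j + 1
    } else i <- i + 1
  }
  min(e, 0)
}

# exhaustive hypergeometric tail by subset enumeration (N <= 12)
enum_hyper_tail_table <- function(N, K, n) {
  # returns P(X >= k) for k = 0..n as a vector indexed k+1
  subsets <- utils::combn(N, n)
  carriers <- seq_len(K)
  counts <- apply(subsets, 2, function(s) sum(s %in% carriers))
  vapply(0:n, function(k) mean(counts >= k), numeric(1))
}

# duplex site constructors: substitute site positions facing given miRNA
# positions with a guaranteed-mismatch base (the miRNA base itself) or a
# wobble partner (only valid where the miRNA base is G or T)
site_with <- function(mirna, mismatch_at = integer(), wobble_at = integer()) {
  m <- strsplit(mirna, "")[[1]]
  L <- length(m)
  site <- strsplit(revcomp(mirna), "")[[1]]
  for (p in mismatch_at) site[L + 1L - p] <- m[p]
  for (p in wobble_at) {
    site[L + 1L - p] <- switch(m[p], G = "T", T = "G",
                               stop("wobble needs G or T at miRNA position ", p))
  }
  paste(site, collapse = "")
}

rand_mature <- function(len = 22L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# direct upper-tail summation by the term recurrence of the same formula
# (factorial ratios cancel exactly); the cap leaves a remainder far below
# double precision for x up to a few hundred
ac_upper_naive <- function(x, y, n1, n2, cap = 2000L) {
  r <- n2 / n1
  term <- (1 + r)^(-(x + 1))   # p(x | 0)
  total <- if (y == 0) term else 0
  for (t in 1:cap) {
    term <- term * r * (x + t) / t / (1 + r)
    if (t >= y) total <- total + term
  }
  total
}
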