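# Rule-based miRNA target prediction on ungapped miRNA:site duplexes.
# Position 1 is the miRNA 5' terminal base; the site is the transcript
# window read 5'->3', bound antiparallel, so miRNA position i faces site
# position L+1-i.  G:U wobbles count 0.5 toward the numeric mismatch caps
# (rules i and v) but are pairs, not mismatches, for the adjacency rules
# (ii-iv) unless `gu_as_mismatch = TRUE`.

#' Per-position pairing states of an ungapped duplex
#'
#' @param mirna miRNA sequence, 5' to 3' (DNA or RNA alphabet).
#' @param site transcript site sequence, 5' to 3', same length.
#' @return character vector over miRNA positions 1..L with values `"WC"`,
#'   `"GU"`, or `"MM"`.
#' @export
duplex_states <- function(mirna, site) {
  if (nchar(mirna) != nchar(site)) stop("duplex must be ungapped: |site| = |miRNA|")
  m <- strsplit(chartr("Uu", "Tt", toupper(mirna)), "")[[1]]
  t <- rev(strsplit(chartr("Uu", "Tt", toupper(site)), "")[[1]])
  wc <- c(A = "T", C = "G", G = "C", T = "A")
  state <- rep("MM", length(m))
  state[t == wc[m]] <- "WC"
  state[(m == "G" & t == "T") | (m == "T" & t == "G")] <- "GU"
  state
}

#' Mismatch score of a duplex
#'
#' Mismatches count 1 and G:U wobbles count 0.5.
#'
#' @inheritParams duplex_states
#' @param states optional precomputed [duplex_states()] vector (then
#'   `mirna`/`site` are ignored).
#' @return numeric score.
#' @export
score_mismatches <- function(mirna = NULL, site = NULL, states = NULL) {
  if (is.null(states)) states <- duplex_states(mirna, site)
  sum(states == "MM") + 0.5 * sum(states == "GU")
}

# pair strengths on the same constant scale as the hairpin folder
#' @noRd
duplex_pair_strength <- function(m, t) {
  s <- numeric(length(m))
  gc <- (m == "G" & t == "C") | (m == "C" & t == "G")
  au <- (m == "A" & t == "T") | (m == "T" & t == "A")
  gu <- (m == "G" & t == "T") | (m == "T" & t == "G")
  s[gc] <- 3.3; s[au] <- 0.9; s[gu] <- 1.0
  s
}

#' Minimum free energy of an ungapped duplex
#'
#' Stacked adjacent pairs contribute the mean of their two pair strengths
#' (G:C 3.3, A:U 0.9, G:U 1.0 kcal/mol, negated); every interior run of
#' mismatches (pairs on both sides) destabilizes by +0.5; the result is
#' capped at 0.
#'
#' @inheritParams duplex_states
#' @return duplex MFE in kcal/mol (<= 0; 0 for a pairless duplex).
#' @export
duplex_mfe <- function(mirna, site) {
  m <- strsplit(chartr("Uu", "Tt", toupper(mirna)), "")[[1]]
  t <- rev(strsplit(chartr("Uu", "Tt", toupper(site)), "")[[1]])
  if (length(m) != length(t)) stop("duplex must be ungapped")
  s <- duplex_pair_strength(m, t)
  paired <- s > 0
  L <- length(s)
  if (L < 2L || !any(paired)) return(0)
  stacks <- paired[-L] & paired[-1L]
  e <- -sum((s[-L][stacks] + s[-1L][stacks]) / 2)
  # interior mismatch runs: maximal unpaired runs flanked by pairs
  r <- rle(paired)
  interior <- which(!r$values)
  interior <- interior[interior > 1L & interior < length(r$values)]
  e <- e + 0.5 * length(interior)
  min(e, 0)
}

#' Duplex MFE ratio against the perfect complement
#'
#' @inheritParams duplex_states
#' @return `duplex_mfe(mirna, site) / duplex_mfe(mirna, perfect complement)`;
#'   1 for the perfect complement itself.
#' @export
mfe_ratio <- function(mirna, site) {
  perfect <- duplex_mfe(mirna, perfect_site(mirna))
  if (perfect == 0) stop("miRNA has no self-complement energy; too short?")
  duplex_mfe(mirna, site) / perfect
}

#' Perfect antisense site of a miRNA
#'
#' @param mirna miRNA sequence (DNA alphabet).
#' @return the reverse complement, i.e. the transcript site to which the
#'   miRNA binds with all Watson-Crick pairs.
#' @export
perfect_site <- function(mirna) {
  revcomp(chartr("Uu", "Tt", mirna))
}

#' Evaluate the six target-site rules on one duplex
#'
#' Rules: (i) mismatch score at most 4 (G:U counts 0.5); (ii) no run of
#' more than two adjacent mismatches; (iii) no adjacent mismatches in
#' positions 2-12; (iv) no mismatch at positions 10-11; (v) mismatch score
#' in positions 1-12 at most 2.5; (vi) duplex MFE at least 75% of the MFE
#' of the miRNA bound to its perfect complement.  Positions count from the
#' miRNA 5' end.
#'
#' @inheritParams duplex_states
#' @param gu_as_mismatch treat G:U wobbles as mismatches for the adjacency
#'   rules ii-iv as well (strict mode); they always contribute 0.5 to the
#'   numeric caps of rules i and v.
#' @param mfe_ratio_min rule vi threshold (inclusive), default 0.75.
#' @return one-row data frame: `score`, `rule_i` .. `rule_vi`, `mfe`,
#'   `perfect_mfe`, `mfe_ratio`, `pass` (all six rules).
#' @export
check_rules <- function(mirna, site, gu_as_mismatch = FALSE,
                        mfe_ratio_min = 0.75) {
  states <- duplex_states(mirna, site)
  L <- length(states)
  mm <- states == "MM"
  if (gu_as_mismatch) mm <- mm | states == "GU"
  score <- score_mismatches(states = states)

  runs <- rle(mm)
  rule_i <- score <= 4
  rule_ii <- !any(runs$lengths[runs$values] > 2L)
  seed <- if (L >= 2L) 2L:min(12L, L) else integer(0)
  adj_in_seed <- if (length(seed) > 1L) {
    any(mm[seed[-length(seed)]] & mm[seed[-1L]])
  } else FALSE
  rule_iii <- !adj_in_seed
  rule_iv <- !any(mm[intersect(10:11, seq_len(L))])
  head_states <- states[seq_len(min(12L, L))]
  rule_v <- score_mismatches(states = head_states) <= 2.5

  mfe <- duplex_mfe(mirna, site)
  perfect_mfe <- duplex_mfe(mirna, perfect_site(mirna))
  ratio <- if (perfect_mfe < 0) mfe / perfect_mfe else 0
  rule_vi <- ratio >= mfe_ratio_min

  data.frame(
    score = score, rule_i = rule_i, rule_ii = rule_ii, rule_iii = rule_iii,
    rule_iv = rule_iv, rule_v = rule_v, rule_vi = rule_vi,
    mfe = mfe, perfect_mfe = perfect_mfe, mfe_ratio = ratio,
    pass = rule_i && rule_ii && rule_iii && rule_iv && rule_v && rule_vi,
    stringsAsFactors = FALSE
  )
}

#' Predict target sites of miRNAs in transcripts
#'
#' Slides a window of the miRNA's length along every transcript (antisense
#' binding orientation) and reports every window passing all six rules, in
#' deterministic (transcript, offset) order.
#'
#' @param mirnas named character vector of mature miRNA sequences.
#' @param transcripts named character vector of transcript sequences, or a
#'   FASTA path.
#' @param tx2gene optional data frame mapping `transcript` to `gene`.
#' @inheritParams check_rules
#' @return data frame: `mirna`, `gene` (`NA` without `tx2gene`),
#'   `transcript`, `offset` (1-based site start), `score`, the six rule
#'   flags, `mfe`, `mfe_ratio`.
#' @export
predict_targets <- function(mirnas, transcripts, tx2gene = NULL,
                            gu_as_mismatch = FALSE, mfe_ratio_min = 0.75) {
  if (is.character(transcripts) && length(transcripts) == 1L &&
      file.exists(transcripts)) {
    x <- Biostrings::readDNAStringSet(transcripts)
    transcripts <- stats::setNames(as.character(x), sub("\\s.*", "", names(x)))
  }
  if (!length(transcripts)) stop("no transcripts supplied")
  if (is.null(names(mirnas))) names(mirnas) <- sprintf("mir-%02d", seq_along(mirnas))
  out <- list()
  for (mi in seq_along(mirnas)) {
    m <- mirnas[[mi]]
    L <- nchar(m)
    for (tx in names(transcripts)) {
      tseq <- transcripts[[tx]]
      n_win <- nchar(tseq) - L + 1L
      if (n_win < 1L) next
      for (o in seq_len(n_win)) {
        site <- substr(tseq, o, o + L - 1L)
        # cheap pre-gate: rule i bounds the others' work
        states <- duplex_states(m, site)
        if (score_mismatches(states = states) > 4) next
        report <- check_rules(m, site, gu_as_mismatch = gu_as_mismatch,
                           mfe_ratio_min = mfe_ratio_min)
        if (!report$pass) next
        out[[length(out) + 1L]] <- cbind(
          data.frame(mirna = names(mirnas)[mi], transcript = tx, offset = o,
                     stringsAsFactors = FALSE),
          report[, c("score", "rule_i", "rule_ii", "rule_iii", "rule_iv",
                  "rule_v", "rule_vi", "mfe", "mfe_ratio")]
        )
      }
    }
  }
  if (!length(out)) {
    d <- data.frame(mirna = character(), transcript = character(),
                    offset = integer(), score = numeric(),
                    rule_i = logical(), rule_ii = logical(),
                    rule_iii = logical(), rule_iv = logical(),
                    rule_v = logical(), rule_vi = logical(),
                    mfe = numeric(), mfe_ratio = numeric(),
                    stringsAsFactors = FALSE)
  } else {
    d <- do.call(rbind, out)
  }
  d$gene <- if (!is.null(tx2gene)) {
    tx2gene$gene[match(d$transcript, tx2gene$transcript)]
  } else {
    NA_character_
  }
  d <- d[order(d$mirna, d$transcript, d$offset), , drop = FALSE]
  rownames(d) <- NULL
  d[, c("mirna", "gene", "transcript", "offset", "score", "rule_i",
        "rule_ii", "rule_iii", "rule_iv", "rule_v", "rule_vi", "mfe",
        "mfe_ratio")]
}
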