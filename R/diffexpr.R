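# Audic-Claverie differential expression of known miRNAs between two
# libraries: RPM normalization with a zero-count floor, the point
# probability p(x|y) of observing y counts in one library given x in the
# other under proportional library totals, cumulative one-sided tails, a
# doubled two-sided p-value, BH correction, and the three-way up/equal/down
# classification.

#' Reads-per-million normalization
#'
#' @param count read count(s) of a species.
#' @param total total small-RNA reads in the library (> 0).
#' @return `count / total * 1e6`.
#' @export
rpm <- function(count, total) {
  if (any(total <= 0)) stop("library total must be > 0")
  count / total * 1e6
}

#' Floor zero-count RPM values
#'
#' Normalized expression of 0 is replaced by 0.01 RPM so fold changes stay
#' finite; raw counts are never floored for the p-value.
#'
#' @param std RPM value(s).
#' @param floor the floor, default 0.01.
#' @return `pmax(std, floor)`.
#' @export
floor_zero <- function(std, floor = 0.01) {
  pmax(std, floor)
}

#' Log2 ratio of two normalized expression values
#'
#' @param numerator_std,denominator_std RPM values, both > 0 (after
#'   [floor_zero()]).
#' @return `log2(numerator_std / denominator_std)`.
#' @export
log2_ratio <- function(numerator_std, denominator_std) {
  if (any(numerator_std <= 0) || any(denominator_std <= 0)) {
    stop("log2_ratio needs positive inputs; apply floor_zero first")
  }
  log2(numerator_std / denominator_std)
}

#' Audic-Claverie point probability p(x|y)
#'
#' Probability of observing `y` counts of a species in a library of total
#' `N2` given `x` counts in a library of total `N1`:
#' \deqn{p(x|y) = (N2/N1)^y \frac{(x+y)!}{x!\,y!} (1 + N2/N1)^{-(x+y+1)}}
#' evaluated in log space (log-gamma) so counts of order 1e6 do not
#' overflow.
#'
#' @param x,y non-negative integer counts (vectorized).
#' @param n1,n2 library totals (> 0).
#' @param log return the log probability.
#' @return `p(x|y)` (or its log).
#' @export
ac_point_prob <- function(x, y, n1, n2, log = FALSE) {
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative")
  if (any(n1 <= 0) || any(n2 <= 0)) stop("library totals must be > 0")
  r <- n2 / n1
  lp <- y * base::log(r) + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
    (x + y + 1) * log1p(r)
  if (log) lp else exp(lp)
}

# One-sided lower tail P(Y <= y | x): sums the smaller of the two tails
# directly (never through 1 - large), so tiny tail probabilities keep full
# relative precision.
#' @noRd
ac_tail_lower <- function(x, y, n1, n2) {
  if (y < 0) return(0)
  q <- n2 / (n1 + n2)
  mode <- (x + 1) * q / (1 - q)  # mean of the induced count distribution
  if (y <= mode) {
    sum(ac_point_prob(x, 0:y, n1, n2))
  } else {
    1 - ac_tail_upper(x, y + 1, n1, n2)
  }
}

# One-sided upper tail P(Y >= y | x), by direct summation from y upward
# until the remaining geometric-dominated mass is negligible.
#' @noRd
ac_tail_upper <- function(x, y, n1, n2) {
  if (y <= 0) return(1)
  q <- n2 / (n1 + n2)
  mode <- (x + 1) * q / (1 - q)
  if (y <= mode) return(1 - ac_tail_lower(x, y - 1, n1, n2))
  # beyond the mode terms decay at least geometrically; extend in blocks
  total <- 0
  from <- y
  repeat {
    to <- from + 2047L
    terms <- ac_point_prob(x, from:to, n1, n2)
    total <- total + sum(terms)
    last <- terms[length(terms)]
    ratio <- (x + to + 1) / (to + 1) * q
    if (ratio >= 1) ratio <- 0.999
    if (last / (1 - ratio) < total * 1e-16 + 1e-320) break
    from <- to + 1L
  }
  total
}

#' Audic-Claverie p-value
#'
#' One-sided p-values are cumulative tails of [ac_point_prob()] over `y` at
#' fixed `x`; the two-sided p-value doubles the smaller tail (capped at 1).
#'
#' @param x,y observed counts (vectorized).
#' @param n1,n2 library totals of the `x` and `y` libraries.
#' @param alternative `"two.sided"` (default), `"less"` (P(Y <= y)), or
#'   `"greater"` (P(Y >= y)).
#' @return p-value(s) in (0, 1].
#' @export
ac_pvalue <- function(x, y, n1, n2,
                      alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  vapply(seq_len(n), function(i) {
    switch(alternative,
      less = ac_tail_lower(x[i], y[i], n1, n2),
      greater = ac_tail_upper(x[i], y[i], n1, n2),
      two.sided = min(1, 2 * min(ac_tail_lower(x[i], y[i], n1, n2),
                                 ac_tail_upper(x[i], y[i], n1, n2)))
    )
  }, numeric(1))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' @param pvalues numeric vector of raw p-values.
#' @return step-up adjusted values (monotone in rank, in (0, 1]).
#' @export
bh_fdr <- function(pvalues) {
  p.adjust(pvalues, method = "BH")
}

#' Classify a species as up-, equally, or down-expressed
#'
#' `up` requires `log2fc >= fc_cut` and significance; `down` requires
#' `log2fc <= -fc_cut` and significance; everything else is `equal`.
#' Significance is `pvalue <= p_cut` by default, or `fdr <= fdr_cut` when
#' `use_fdr = TRUE`.
#'
#' @param log2fc log2 fold change(s).
#' @param pvalue raw p-value(s).
#' @param fdr BH-adjusted value(s), required when `use_fdr = TRUE`.
#' @param fc_cut fold-change gate on the log2 scale (default 1).
#' @param p_cut raw p-value gate (default 0.001).
#' @param use_fdr gate on FDR instead of the raw p-value.
#' @param fdr_cut FDR gate (default 0.01).
#' @return character vector in `{"up", "equal", "down"}`.
#' @export
classify_de <- function(log2fc, pvalue, fdr = NULL, fc_cut = 1,
                        p_cut = 0.001, use_fdr = FALSE, fdr_cut = 0.01) {
  sig <- if (use_fdr) {
    if (is.null(fdr)) stop("use_fdr = TRUE needs fdr values")
    fdr <= fdr_cut
  } else {
    pvalue <= p_cut
  }
  out <- rep("equal", length(log2fc))
  out[sig & log2fc >= fc_cut] <- "up"
  out[sig & log2fc <= -fc_cut] <- "down"
  out
}

#' Differential expression of known miRNAs between two libraries
#'
#' Normalizes each library to RPM, floors zero-count RPM values, and reports
#' the fold-change column as `log2(control_std / case_std)` (the numeric
#' convention of the reference table this pipeline mirrors), the two-sided
#' Audic-Claverie p-value on the raw counts, BH FDR, and the three-way
#' class.
#'
#' @param counts_case,counts_control integer count vectors, parallel to
#'   `names`.
#' @param total_case,total_control library totals (all small-RNA reads, not
#'   just the named species).
#' @param names species names.
#' @inheritParams classify_de
#' @return data frame of class `DEResult` with columns `name`, `case_std`,
#'   `control_std`, `log2fc`, `pvalue`, `fdr`, `class`.
#' @export
diff_expression <- function(counts_case, counts_control, total_case,
                            total_control, names = NULL, fc_cut = 1,
                            p_cut = 0.001, use_fdr = FALSE, fdr_cut = 0.01) {
  stopifnot(length(counts_case) == length(counts_control))
  if (is.null(names)) names <- sprintf("mir-%03d", seq_along(counts_case))
  case_std <- floor_zero(rpm(counts_case, total_case))
  control_std <- floor_zero(rpm(counts_control, total_control))
  log2fc <- log2_ratio(control_std, case_std)
  pvalue <- ac_pvalue(counts_case, counts_control, total_case, total_control)
  fdr <- bh_fdr(pvalue)
  d <- data.frame(
    name = names, case_std = case_std, control_std = control_std,
    log2fc = log2fc, pvalue = pvalue, fdr = fdr,
    class = classify_de(log2fc, pvalue, fdr, fc_cut, p_cut, use_fdr, fdr_cut),
    stringsAsFactors = FALSE
  )
  class(d) <- c("DEResult", "data.frame")
  d
}
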