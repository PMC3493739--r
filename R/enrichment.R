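# Hypergeometric GO-term enrichment of predicted target genes against a
# background gene set, with Benjamini-Hochberg correction across terms.

#' Upper tail of the hypergeometric distribution
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability that a random
#' size-`n` draw from `N` genes, `K` of which carry the term, contains at
#' least `k` carriers.
#'
#' @param k observed carriers in the draw (0 <= k <= min(n, K)).
#' @param K background genes carrying the term.
#' @param n draw (target set) size.
#' @param N background size.
#' @return the tail probability in (0, 1].
#' @export
hypergeom_tail <- function(k, K, n, N) {
  if (any(K > N) || any(n > N)) stop("need K <= N and n <= N")
  if (any(k < 0) || any(k > pmin(n, K))) stop("need 0 <= k <= min(n, K)")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' GO-term enrichment of a target gene set
#'
#' Genes lacking any GO annotation are excluded from both the background and
#' the target set.  One result per term with at least one target carrier;
#' raw hypergeometric p-values are reported alongside BH FDR values and a
#' significance flag at `p_cut`.
#'
#' @param target_genes character vector of target gene ids (non-empty).
#' @param go_map data frame with columns `gene` and `term` (one row per
#'   annotation), or a 2-column TSV path.
#' @param background optional character vector overriding the default
#'   background (all genes in `go_map`).
#' @param p_cut significance threshold on the raw p-value (default 0.001).
#' @return data frame ordered by p-value: `term`, `k`, `K`, `n`, `N`,
#'   `pvalue`, `fdr`, `significant`.
#' @export
enrich_go <- function(target_genes, go_map, background = NULL,
                      p_cut = 0.001) {
  if (is.character(go_map) && length(go_map) == 1L) {
    go_map <- read.delim(go_map, header = TRUE, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("gene", "term") %in% names(go_map)))
  if (!length(target_genes)) stop("target gene set is empty")
  go_map <- unique(go_map[, c("gene", "term")])
  bg <- unique(if (is.null(background)) go_map$gene else background)
  go_map <- go_map[go_map$gene %in% bg, , drop = FALSE]
  bg <- unique(go_map$gene)  # drop annotation-free genes from N
  targets <- unique(target_genes)
  targets <- targets[targets %in% bg]
  if (!length(targets)) stop("no target gene carries any GO annotation")
  n <- length(targets)
  N <- length(bg)
  K_tab <- table(go_map$term)
  k_tab <- table(go_map$term[go_map$gene %in% targets])
  terms <- names(k_tab)[k_tab >= 1L]
  k <- as.integer(k_tab[terms])
  K <- as.integer(K_tab[terms])
  p <- hypergeom_tail(k, K, n, N)
  d <- data.frame(
    term = terms, k = k, K = K, n = n, N = N,
    pvalue = p, fdr = bh_fdr(p), significant = p < p_cut,
    stringsAsFactors = FALSE
  )
  d <- d[order(d$pvalue, d$term), , drop = FALSE]
  rownames(d) <- NULL
  d
}
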