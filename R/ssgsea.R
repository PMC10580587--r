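# Single-sample gene-set enrichment (ssGSEA): per-sample EMT activity score.
#
# The score for sample j and gene set S walks the genes ranked by decreasing
# expression in that sample and accumulates the difference between the
# weighted fraction of set members seen so far (weights rank^alpha, rank N
# for the highest-expressed gene) and the fraction of non-members seen so
# far. The enrichment score is the sum of that difference over all positions
# (the area between the two cumulative curves), so it depends only on the
# within-sample expression ranks.

#' Rank genes within one sample
#'
#' Orders genes by decreasing expression, breaking ties lexicographically by
#' gene id so the ordering is deterministic, and assigns integer rank weights
#' `N..1` (the highest-expressed gene gets weight `N`).
#'
#' @param x Named numeric vector of one sample's expression values (>= 2 genes).
#' @return Named integer vector of rank weights, names in ranked order.
#' @export
rank_genes_in_sample <- function(x) {
  if (length(x) < 2L || is.null(names(x)))
    stop_acetyl("domain_error", "need a named vector of at least 2 genes")
  ord <- order(-x, names(x), method = "radix")
  w <- seq.int(length(x), 1L)
  names(w) <- names(x)[ord]
  w
}

#' ssGSEA enrichment score for one ranked sample
#'
#' @param ranked Named numeric vector of rank weights in ranked order, as
#'   produced by [rank_genes_in_sample()].
#' @param gene_set Character vector of set member ids.
#' @param alpha Non-negative rank-weight exponent (default 0.25).
#' @return Single numeric enrichment score (sum of running deviations).
#' @export
ssgsea_score <- function(ranked, gene_set, alpha = 0.25) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0)
    stop_acetyl("domain_error", "alpha must be a single non-negative number")
  n <- length(ranked)
  hit <- names(ranked) %in% gene_set
  k <- sum(hit)
  if (k == 0L)
    stop_acetyl("empty_set", "gene set does not intersect the ranked genes")
  if (k == n)
    stop_acetyl("degenerate_complement", "gene set covers every ranked gene")
  inc <- numeric(n)
  inc[hit] <- ranked[hit]^alpha
  p_in <- cumsum(inc) / sum(inc)
  p_out <- cumsum(!hit) / (n - k)
  sum(p_in - p_out)
}

#' Per-sample EMT activity scores by ssGSEA
#'
#' Applies [ssgsea_score()] to every column of the expression matrix. Set
#' members absent from the matrix are dropped (count reported). With
#' `normalize = TRUE` all scores are divided by their cross-sample range
#' `max - min` (a no-op when the range is zero), the usual cross-sample
#' standardization for single-set ssGSEA.
#'
#' @param expr Numeric genes x samples matrix on the log2 scale.
#' @param gene_set Character vector of set member ids (e.g. the EMT program).
#' @param alpha Rank-weight exponent, default 0.25.
#' @param normalize Divide scores by their cross-sample range? Default `TRUE`.
#' @return Named numeric vector of scores, one per sample.
#' @examples
#' set.seed(1)
#' m <- matrix(rnorm(50), 10, 5,
#'             dimnames = list(paste0("g", 1:10), paste0("s", 1:5)))
#' emt_scores(m, c("g1", "g2", "g3"))
#' @export
emt_scores <- function(expr, gene_set, alpha = 0.25, normalize = TRUE) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  present <- intersect(gene_set, rownames(expr))
  n_absent <- length(setdiff(gene_set, rownames(expr)))
  if (n_absent > 0L)
    message(sprintf("emt_scores: %d set member(s) absent from the matrix were dropped",
                    n_absent))
  if (length(present) == 0L)
    stop_acetyl("empty_set", "no gene-set member is present in the matrix")
  scores <- vapply(seq_len(ncol(expr)), function(j) {
    ssgsea_score(rank_genes_in_sample(expr[, j]), present, alpha = alpha)
  }, numeric(1L))
  names(scores) <- colnames(expr)
  if (normalize) {
    rng <- max(scores) - min(scores)
    if (rng > 0) scores <- scores / rng
  }
  scores
}
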