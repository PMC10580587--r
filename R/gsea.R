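# Candidate validation by gene set enrichment analysis: rank every other gene
# by its Spearman correlation with the candidate, then test whether the EMT
# set is concentrated at the top of that ranking with the weighted
# Kolmogorov-Smirnov statistic and a gene-label permutation null.

#' Correlation-ranked profile for a candidate gene
#'
#' Spearman correlation between the candidate's expression and every other
#' gene in the matrix, returned in descending order (ties broken by gene id).
#'
#' @param expr Numeric genes x samples matrix with `>= 4` samples.
#' @param candidate Gene id present in the matrix.
#' @return Named numeric vector of correlations in `[-1, 1]`, descending;
#'   the candidate itself is excluded.
#' @export
correlation_profile <- function(expr, candidate) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  if (ncol(expr) < 4L)
    stop_acetyl("insufficient_samples", "need >= 4 samples for a correlation profile")
  if (!candidate %in% rownames(expr))
    stop_acetyl("key_error", sprintf("candidate gene '%s' is not in the matrix", candidate))
  ranks <- t(apply(expr, 1L, rank))                 # midranks, tie-aware
  rc <- ranks[candidate, ]
  others <- setdiff(rownames(expr), candidate)
  scc <- as.vector(cor(rc, t(ranks[others, , drop = FALSE])))
  names(scc) <- others
  scc[order(-scc, names(scc), method = "radix")]
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked profile; set members ("hits") increment the running sum by
#' `|w|^exponent` normalized by the sum of hit weights, non-members decrement
#' by `1 / (N - |S|)`. The enrichment score is the running sum's maximum-
#' magnitude deviation (signed, first such position on exact ties), bounded in
#' `[-1, 1]`. `exponent = 1` weights by the correlation magnitude
#' (Subramanian-style); `exponent = 0` is the classic unweighted KS statistic.
#'
#' @param profile Named numeric vector of weights in descending order
#'   ([correlation_profile()]).
#' @param gene_set Character vector of set members.
#' @param exponent Non-negative weight exponent, default 1.
#' @return List with `es`, `running_sum` (length-N numeric), `peak` (index of
#'   the extreme deviation), and `leading_edge` (set members at or before the
#'   peak for positive scores, at or after it for negative scores). When the
#'   largest positive and largest negative deviations tie in magnitude
#'   exactly, `|es|` is unique but the reported sign depends on
#'   floating-point accumulation order.
#' @export
gsea_es <- function(profile, gene_set, exponent = 1) {
  n <- length(profile)
  hit <- names(profile) %in% gene_set
  k <- sum(hit)
  if (k == 0L) stop_acetyl("empty_set", "gene set does not intersect the profile")
  if (k == n) stop_acetyl("degenerate_complement", "gene set covers the whole profile")
  inc <- abs(profile[hit])^exponent
  nr <- sum(inc)
  delta <- rep.int(-1 / (n - k), n)
  if (nr > 0) delta[hit] <- inc / nr else delta[hit] <- 0
  rs <- cumsum(delta)
  peak <- which.max(abs(rs))
  es <- rs[[peak]]
  le <- if (es >= 0) names(profile)[hit & seq_len(n) <= peak]
        else names(profile)[hit & seq_len(n) >= peak]
  list(es = es, running_sum = unname(rs), peak = peak, leading_edge = le)
}

# Fast ES for permutation nulls: O(k) given the sorted hit positions.
# Running-sum extremes occur right after a hit (maxima candidates) or right
# before a hit (minima candidates); between hits the sum only decreases.
gsea_es_positions <- function(absw_pow, n, positions) {
  pos <- sort.int(positions)
  k <- length(pos)
  aw <- absw_pow[pos]
  nr <- sum(aw)
  cum_in <- if (nr > 0) cumsum(aw) / nr else numeric(k)
  miss <- 1 / (n - k)
  after <- cum_in - (pos - seq_len(k)) * miss        # just after each hit
  before <- c(0, cum_in[-k]) - (pos - seq_len(k)) * miss  # just before each hit
  hi <- max(after)
  lo <- min(before, 0)
  if (hi >= -lo) hi else lo
}

#' Permutation p-value for a GSEA enrichment score
#'
#' Draws `n_perm` random same-size gene-label sets from the profile (without
#' replacement), recomputes the enrichment score for each, and reports
#' `p = (1 + #\{|ES_null| >= |ES_obs|\}) / (n_perm + 1)`, which is never zero.
#' The null permutes gene labels, not samples, because the input is a single
#' correlation profile rather than a phenotype-labelled matrix.
#'
#' @inheritParams gsea_es
#' @param n_perm Number of permutations, `>= 100`.
#' @param seed Integer seed for reproducibility (the caller's RNG state is
#'   restored afterwards); `NULL` uses the current stream.
#' @return List of class `gsea_result`: `es`, `p_perm`, `n_perm`,
#'   `leading_edge`, `peak`, `seed`, `n_hits`.
#' @export
permutation_p <- function(profile, gene_set, n_perm = 1000L, seed = NULL,
                          exponent = 1) {
  if (n_perm < 100L) stop_acetyl("domain_error", "n_perm must be >= 100")
  obs <- gsea_es(profile, gene_set, exponent = exponent)
  n <- length(profile)
  k <- sum(names(profile) %in% gene_set)
  if (k > n / 2)
    warning("permutation_p(): set covers more than half the profile; permutation null is poorly behaved")
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  absw_pow <- abs(unname(profile))^exponent
  null_es <- vapply(seq_len(n_perm), function(b) {
    gsea_es_positions(absw_pow, n, sample.int(n, k))
  }, numeric(1L))
  p <- (1 + sum(abs(null_es) >= abs(obs$es))) / (n_perm + 1)
  structure(list(es = obs$es, p_perm = p, n_perm = as.integer(n_perm),
                 leading_edge = obs$leading_edge, peak = obs$peak,
                 seed = seed, n_hits = k),
            class = "gsea_result")
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("GSEA: ES = %.4f, permutation p = %.3g (%d permutations, %d set genes)\n",
              x$es, x$p_perm, x$n_perm, x$n_hits))
  cat(sprintf("Leading edge: %d gene(s)\n", length(x$leading_edge)))
  invisible(x)
}
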