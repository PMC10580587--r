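# Independent oracles, deliberately naive: double loops and exhaustive
# enumeration, no shared code with the package internals.

# ssGSEA running-sum score by brute force (O(N^2) double loop).
naive_ssgsea <- function(weights, set, alpha) {
  genes <- names(weights)
  hit <- genes %in% set
  n <- length(weights)
  k <- sum(hit)
  denom <- sum(weights[hit]^alpha)
  es <- 0
  for (i in seq_len(n)) {
    pin <- 0
    pout <- 0
    for (j in seq_len(i)) {
      if (hit[j]) pin <- pin + weights[[j]]^alpha else pout <- pout + 1
    }
    es <- es + pin / denom - pout / (n - k)
  }
  es
}

# Weighted-KS enrichment score by a step-by-step walk.
naive_gsea_es <- function(w, set, exponent) {
  genes <- names(w)
  hit <- genes %in% set
  n <- length(w)
  k <- sum(hit)
  nr <- sum(abs(w[hit])^exponent)
  rs <- 0
  best <- 0
  for (i in seq_len(n)) {
    rs <- rs + if (hit[i]) abs(w[[i]])^exponent / nr else -1 / (n - k)
    if (abs(rs) > abs(best)) best <- rs
  }
  best
}

# Exact two-sided Wilcoxon rank-sum p by enumerating all label assignments.
enum_wilcox_p <- function(xa, xb) {
  n <- length(xa) + length(xb)
  r <- rank(c(xa, xb))
  na <- length(xa)
  w_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  picks <- utils::combn(n, na)
  w_all <- apply(picks, 2L, function(ix) sum(r[ix])) - na * (na + 1) / 2
  p_low <- mean(w_all <= w_obs)
  p_high <- mean(w_all >= w_obs)
  min(1, 2 * min(p_low, p_high))
}

# Spearman coefficient from hand-computed midranks (double-loop ranks).
brute_spearman <- function(x, y) {
  midrank <- function(v) {
    vapply(seq_along(v), function(i) {
      less <- sum(v < v[i])
      eq <- sum(v == v[i])
      less + (eq + 1) / 2
    }, numeric(1))
  }
  rx <- midrank(x)
  ry <- midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Two-group annotation over samples s1..s(na+nb): first na normal, rest cancer.
two_group_annotation <- function(na, nb) {
  data.frame(sample_id = paste0("s", seq_len(na + nb)),
             stage = rep(c("normal", "cancer"), c(na, nb)),
             state = rep(c("normal", "cancer"), c(na, nb)),
             stringsAsFactors = FALSE)
}

# Random named matrix helper.
rand_matrix <- function(n_genes, n_samples, prefix = "g") {
  matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
         dimnames = list(paste0(prefix, seq_len(n_genes)),
                         paste0("s", seq_len(n_samples))))
}

# A tiny cohort spec for fast unit tests.
small_spec <- function(seed = 1L, ...) {
  synthetic_spec(n_background_genes = 200L, emt_set_size = 40L,
                 n_acetyl_genes = 20L, n_planted = 3L, seed = seed, ...)
}
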