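# Spearman correlation screen: which acetyltransferase genes track the
# per-sample EMT score? A gene passes when p <= p_max AND |SCC| >= scc_min,
# both thresholds inclusive.

#' Spearman correlation with a two-sided p-value
#'
#' The coefficient is the Pearson correlation of average (midrank) ranks, so it
#' is tie-aware and invariant to strictly increasing transforms of either
#' argument. The p-value uses the t approximation with `n - 2` degrees of
#' freedom; `exact = TRUE` (only for `n < 10`) replaces it with the exact
#' permutation p-value obtained by enumerating all orderings.
#'
#' @param x,y Numeric vectors of equal length `>= 4`, neither constant.
#' @param exact Use the exact permutation null (requires `n < 10`)?
#' @return List with elements `scc` and `p` (clamped to `[1e-300, 1]`).
#' @examples
#' spearman_scc(1:5, c(2, 1, 4, 3, 5))  # scc = 0.8
#' @export
spearman_scc <- function(x, y, exact = FALSE) {
  n <- length(x)
  if (length(y) != n || n < 4L)
    stop_acetyl("domain_error", "x and y must have equal length >= 4")
  if (anyNA(x) || anyNA(y))
    stop_acetyl("domain_error", "missing values are not allowed")
  if (sd(x) == 0 || sd(y) == 0)
    stop_acetyl("degenerate_input", "constant vector: Spearman correlation undefined")
  rx <- rank(x)
  ry <- rank(y)
  scc <- cor(rx, ry)
  if (exact) {
    if (n >= 10L)
      stop_acetyl("domain_error", "exact permutation p only supported for n < 10")
    perms <- all_permutations(n)
    ryc <- ry - mean(ry)
    rxc <- rx - mean(rx)
    null_scc <- as.vector(rxc %*% matrix(ryc[t(perms)], nrow = n)) /
      (sqrt(sum(rxc^2)) * sqrt(sum(ryc^2)))
    p <- mean(abs(null_scc) >= abs(scc) - 1e-12)
  } else if (abs(scc) >= 1 - 1e-15) {
    p <- 1e-300
  } else {
    tstat <- scc * sqrt((n - 2) / (1 - scc^2))
    p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  list(scc = scc, p = min(max(p, 1e-300), 1))
}

# All permutations of 1..n as an n! x n integer matrix (n <= 9).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    block <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], n,
                   sub[, seq.int(pos, n - 1L)[seq_len(n - pos)], drop = FALSE])
    out[r + seq_len(nrow(sub)), ] <- as.matrix(block)
    r <- r + nrow(sub)
  }
  out
}

#' Does a (scc, p) pair pass the screen thresholds?
#'
#' Both comparisons are inclusive: `p <= p_max` and `|scc| >= scc_min`.
#'
#' @param scc Spearman coefficients.
#' @param p Two-sided p-values.
#' @param p_max P-value threshold, default 0.05.
#' @param scc_min Absolute-correlation threshold, default 0.3.
#' @return Logical vector (`FALSE` where `scc` or `p` is `NA`).
#' @export
passes_screen <- function(scc, p, p_max = 0.05, scc_min = 0.3) {
  ok <- !is.na(scc) & !is.na(p) & p <= p_max & abs(scc) >= scc_min
  ok & !is.na(ok)
}

#' Correlation screen of genes against EMT scores
#'
#' Computes the Spearman correlation between each listed gene's expression and
#' the per-sample EMT score, applies the joint filter, and reports direction.
#' Listed genes absent from the matrix are reported with `missing = TRUE` and
#' `direction = "none"` rather than dropped.
#'
#' @param expr Numeric genes x samples matrix.
#' @param emt Named numeric vector of per-sample EMT scores ([emt_scores()]);
#'   names must match the matrix columns exactly (any order).
#' @param genes Character vector of gene ids to screen; default all rows.
#' @param p_max,scc_min Inclusive thresholds (defaults 0.05 and 0.3).
#' @return `data.frame` with columns `gene_id`, `scc`, `p`, `passes`,
#'   `direction` (`positive`/`negative`/`none`), `missing`.
#' @export
screen <- function(expr, emt, genes = rownames(expr), p_max = 0.05, scc_min = 0.3) {
  stopifnot(is.matrix(expr), !is.null(colnames(expr)))
  extra <- setdiff(names(emt), colnames(expr))
  lacking <- setdiff(colnames(expr), names(emt))
  if (length(extra) || length(lacking))
    stop_acetyl("alignment_error",
                sprintf("sample ids of scores and matrix differ (scores-only: %s; matrix-only: %s)",
                        paste(c(extra, "-")[1], collapse = ","),
                        paste(c(lacking, "-")[1], collapse = ",")))
  emt <- emt[colnames(expr)]
  present <- genes %in% rownames(expr)
  scc <- p <- rep(NA_real_, length(genes))
  for (i in which(present)) {
    r <- spearman_scc(expr[genes[i], ], emt)
    scc[i] <- r$scc
    p[i] <- r$p
  }
  passes <- passes_screen(scc, p, p_max, scc_min)
  direction <- ifelse(!passes, "none", ifelse(scc > 0, "positive", "negative"))
  direction[is.na(direction)] <- "none"
  data.frame(gene_id = genes, scc = scc, p = p, passes = passes,
             direction = direction, missing = !present,
             stringsAsFactors = FALSE)
}
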