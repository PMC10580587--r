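# Two-group Wilcoxon differential expression, fold change on the log2 scale,
# and the composite rank score R = -log10(p) * log2(FC) used to order the
# acetyltransferase collection.

# Samples belonging to a group, looked up in the annotation.
group_samples <- function(annotation, group, by) {
  lab <- as.character(annotation[[by]])
  annotation$sample_id[!is.na(lab) & lab == group]
}

wilcoxon_p_one <- function(xa, xb) {
  if (max(c(xa, xb)) == min(c(xa, xb))) return(1)  # fully tied: no evidence
  exact <- min(length(xa), length(xb)) <= 8L && !anyDuplicated(c(xa, xb))
  p <- suppressWarnings(
    wilcox.test(xa, xb, alternative = "two.sided", exact = exact, correct = TRUE)$p.value)
  min(max(p, 1e-300), 1)
}

#' Per-gene two-sided Wilcoxon rank-sum p-values
#'
#' Exact enumeration p-values when the smaller group has <= 8 samples and the
#' values are untied; otherwise the normal approximation with tie and
#' continuity correction. P-values are clamped to `[1e-300, 1]`.
#'
#' @param expr Numeric genes x samples matrix.
#' @param annotation Annotation `data.frame` (see [read_annotation()]).
#' @param group_a,group_b Group labels compared (two-sided); defaults
#'   `"cancer"` vs `"normal"`.
#' @param by Annotation column holding the labels: `"state"` (default) or
#'   `"stage"`.
#' @return Named numeric vector of p-values, one per gene.
#' @export
wilcoxon_de <- function(expr, annotation, group_a = "cancer", group_b = "normal",
                        by = c("state", "stage")) {
  by <- match.arg(by)
  sa <- intersect(group_samples(annotation, group_a, by), colnames(expr))
  sb <- intersect(group_samples(annotation, group_b, by), colnames(expr))
  if (length(sa) < 2L || length(sb) < 2L)
    stop_acetyl("insufficient_samples",
                sprintf("need >= 2 samples per group (got %d '%s', %d '%s')",
                        length(sa), group_a, length(sb), group_b))
  a <- expr[, sa, drop = FALSE]
  b <- expr[, sb, drop = FALSE]
  p <- vapply(seq_len(nrow(expr)),
              function(i) wilcoxon_p_one(a[i, ], b[i, ]),
              numeric(1L))
  names(p) <- rownames(expr)
  p
}

#' Per-gene fold change between two groups
#'
#' `log2fc` is the difference of group means on the log2 scale
#' (`group_a - group_b`, cancer minus normal by default); `fc = 2^log2fc`,
#' always positive.
#'
#' @inheritParams wilcoxon_de
#' @return `data.frame` with columns `gene_id`, `fc`, `log2fc`.
#' @export
fold_change <- function(expr, annotation, group_a = "cancer", group_b = "normal",
                        by = c("state", "stage")) {
  by <- match.arg(by)
  sa <- intersect(group_samples(annotation, group_a, by), colnames(expr))
  sb <- intersect(group_samples(annotation, group_b, by), colnames(expr))
  if (length(sa) < 1L || length(sb) < 1L)
    stop_acetyl("insufficient_samples", "both groups must be non-empty")
  log2fc <- rowMeans(expr[, sa, drop = FALSE]) - rowMeans(expr[, sb, drop = FALSE])
  data.frame(gene_id = rownames(expr), fc = 2^log2fc, log2fc = unname(log2fc),
             stringsAsFactors = FALSE)
}

#' Composite rank score R
#'
#' `R = -log10(p) * log2(fc)`: large positive for strongly significant
#' up-regulation, large negative for strongly significant down-regulation,
#' zero at `p = 1`.
#'
#' @param p P-values in `(0, 1]`.
#' @param fc Linear-scale fold changes, `> 0`.
#' @return Numeric vector of R scores.
#' @examples
#' rank_score(0.05, 2)    # 1.30103
#' rank_score(0.01, 0.5)  # -2
#' @export
rank_score <- function(p, fc) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop_acetyl("domain_error", "p must lie in (0, 1]")
  if (any(!is.finite(fc)) || any(fc <= 0))
    stop_acetyl("domain_error", "fc must be positive")
  -log10(p) * log2(fc)
}

#' Differential-expression results with rank scores
#'
#' Runs [wilcoxon_de()] and [fold_change()] over a gene list (default: all
#' genes in the matrix), attaches the rank score and the DE class
#' (`up` if `p <= p_max` and `log2fc > 0`, `down` if `p <= p_max` and
#' `log2fc < 0`, else `not_de`). A Benjamini-Hochberg column is included for
#' information; the classification itself uses the raw p-value.
#'
#' @inheritParams wilcoxon_de
#' @param genes Optional character vector restricting the analysis (members
#'   absent from the matrix are dropped with a message).
#' @param p_max DE significance threshold (inclusive), default 0.05.
#' @return `data.frame` with columns `gene_id`, `p`, `p_adj`, `fc`, `log2fc`,
#'   `r_score`, `de_class`.
#' @export
de_results <- function(expr, annotation, genes = NULL, p_max = 0.05,
                       group_a = "cancer", group_b = "normal",
                       by = c("state", "stage")) {
  by <- match.arg(by)
  if (!is.null(genes)) {
    absent <- setdiff(genes, rownames(expr))
    if (length(absent))
      message(sprintf("de_results: %d listed gene(s) absent from the matrix were dropped",
                      length(absent)))
    expr <- expr[intersect(genes, rownames(expr)), , drop = FALSE]
    if (nrow(expr) == 0L) stop_acetyl("empty_set", "no listed gene present in the matrix")
  }
  p <- wilcoxon_de(expr, annotation, group_a, group_b, by)
  fcs <- fold_change(expr, annotation, group_a, group_b, by)
  r <- rank_score(p, fcs$fc)
  de_class <- ifelse(p <= p_max & fcs$log2fc > 0, "up",
                     ifelse(p <= p_max & fcs$log2fc < 0, "down", "not_de"))
  data.frame(gene_id = fcs$gene_id, p = unname(p), p_adj = unname(p.adjust(p, "BH")),
             fc = fcs$fc, log2fc = fcs$log2fc, r_score = unname(r),
             de_class = de_class, stringsAsFactors = FALSE)
}

#' Select the top fraction of genes by rank score
#'
#' Sorts by `r_score` descending (ties by gene id) and keeps the first
#' `floor(top_fraction * n)` genes, at least one.
#'
#' @param results `data.frame` from [de_results()].
#' @param top_fraction Fraction in `(0, 1]`, default 0.30.
#' @return The selected rows, sorted, with an `r_rank` column prepended.
#' @export
select_top <- function(results, top_fraction = 0.30) {
  if (!is.numeric(top_fraction) || length(top_fraction) != 1L ||
      top_fraction <= 0 || top_fraction > 1)
    stop_acetyl("domain_error", "top_fraction must lie in (0, 1]")
  if (nrow(results) == 0L) stop_acetyl("empty_set", "no results to select from")
  ord <- order(-results$r_score, results$gene_id, method = "radix")
  n_keep <- max(1L, floor(top_fraction * nrow(results)))
  out <- results[ord, , drop = FALSE][seq_len(n_keep), , drop = FALSE]
  out <- cbind(r_rank = seq_len(n_keep), out)
  rownames(out) <- NULL
  out
}
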