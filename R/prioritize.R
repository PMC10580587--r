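# Candidate prioritization: intersect the top-R-ranked genes with the genes
# passing the EMT correlation screen.

#' Overlap top-ranked genes with screen passers
#'
#' Returns the genes that are (i) in the top-ranked list, (ii) pass the
#' correlation screen (positively, when `require_positive`), and (iii) are
#' classed `up` by the differential test when `require_up` and the ranked
#' table carries a `de_class` column. An empty intersection is a valid outcome
#' and produces a warning, not an error.
#'
#' @param top_ranked Output of [select_top()] (a `data.frame` with `gene_id`,
#'   `r_rank`, `r_score`, optionally `de_class`), or a character vector already
#'   ordered by descending R.
#' @param screen_results Output of [screen()].
#' @param require_positive Keep only positively correlated passers? Default `TRUE`.
#' @param require_up Keep only `de_class == "up"` genes (when available)?
#'   Default `TRUE`.
#' @return `data.frame` of class `candidate_set`, ordered by descending
#'   `r_score`, with per-gene provenance (`r_rank`, `r_score`, `de_class`,
#'   `scc`, `scc_p`, `direction`).
#' @export
overlap <- function(top_ranked, screen_results, require_positive = TRUE,
                    require_up = TRUE) {
  if (is.character(top_ranked))
    top_ranked <- data.frame(gene_id = top_ranked, r_rank = seq_along(top_ranked),
                             r_score = rev(seq_along(top_ranked)),
                             stringsAsFactors = FALSE)
  if (nrow(top_ranked) == 0L || nrow(screen_results) == 0L)
    stop_acetyl("empty_set", "both inputs to overlap() must be non-empty")
  pass <- screen_results$passes
  if (require_positive) pass <- pass & screen_results$direction == "positive"
  passers <- screen_results$gene_id[pass]
  keep <- top_ranked$gene_id %in% passers
  if (require_up && "de_class" %in% names(top_ranked))
    keep <- keep & top_ranked$de_class == "up"
  out <- top_ranked[keep, , drop = FALSE]
  out <- out[order(-out$r_score, out$gene_id, method = "radix"), , drop = FALSE]
  idx <- match(out$gene_id, screen_results$gene_id)
  out$scc <- screen_results$scc[idx]
  out$scc_p <- screen_results$p[idx]
  out$direction <- screen_results$direction[idx]
  rownames(out) <- NULL
  if (nrow(out) == 0L)
    warning("overlap(): empty candidate set (no top-ranked gene passes the screen)")
  class(out) <- c("candidate_set", "data.frame")
  out
}
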