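# End-to-end prioritization: EMT scoring -> Wilcoxon DE + rank score ->
# top-fraction selection -> correlation screen -> overlap -> per-candidate
# GSEA validation. prioritize_hat_genes() is the package's central fitting
# function; it returns a classed object with print/summary/plot methods.

#' Prioritize acetyltransferase genes coupled to EMT activity
#'
#' Runs the full integrative procedure on an annotated expression cohort:
#' per-sample EMT activity by ssGSEA, two-group Wilcoxon differential
#' expression with the composite rank score `R = -log10(p) * log2(FC)` over
#' the acetyltransferase collection, selection of the top `top_fraction` by
#' `R`, a Spearman correlation screen of the collection against the EMT
#' scores, the overlap of top-ranked up-regulated genes with positive screen
#' passers, and (optionally) weighted-KS GSEA validation of each candidate's
#' correlation profile against the EMT set.
#'
#' @param expr Numeric genes x samples matrix, log2 scale
#'   ([read_expression()]).
#' @param annotation Sample annotation ([read_annotation()]); the Wilcoxon /
#'   fold-change comparison uses its `state` column (cancer vs normal), the
#'   scoring and screening use all samples.
#' @param gene_sets `gene_set_collection` ([read_gmt()]) holding the EMT set
#'   and the acetyltransferase collection.
#' @param hat_set,emt_set Names of the two sets inside `gene_sets`.
#' @param alpha,normalize ssGSEA parameters, see [emt_scores()].
#' @param p_max,scc_min,top_fraction Screen and selection thresholds
#'   (inclusive; defaults 0.05, 0.3, 0.30).
#' @param require_positive,require_up Candidate filters, see [overlap()].
#' @param run_gsea Validate candidates by [permutation_p()]? Default `TRUE`.
#' @param gsea_exponent,n_perm GSEA settings.
#' @param seed Integer seed for the GSEA permutation nulls (candidate `i`
#'   uses `seed + i - 1`).
#' @return Object of class `hat_prioritization`: list with `emt_scores`,
#'   `de` (full DE table for the collection), `top` (selected rows),
#'   `screen`, `candidates` ([overlap()] output), `gsea` (named list of
#'   `gsea_result`), `counts`, `params`.
#' @examples
#' cohort <- generate_cohort(synthetic_spec(n_background_genes = 200,
#'                                          emt_set_size = 40,
#'                                          n_acetyl_genes = 20, n_planted = 3))
#' fit <- prioritize_hat_genes(cohort$expression, cohort$annotation,
#'                             cohort$gene_sets, run_gsea = FALSE)
#' print(fit)
#' @export
prioritize_hat_genes <- function(expr, annotation, gene_sets,
                                 hat_set = "HAT", emt_set = "EMT",
                                 alpha = 0.25, normalize = TRUE,
                                 p_max = 0.05, scc_min = 0.3,
                                 top_fraction = 0.30,
                                 require_positive = TRUE, require_up = TRUE,
                                 run_gsea = TRUE, gsea_exponent = 1,
                                 n_perm = 1000L, seed = 1L) {
  for (nm in c(hat_set, emt_set))
    if (!nm %in% names(gene_sets))
      stop_acetyl("key_error", sprintf("gene set '%s' not found in the collection", nm))
  missing_samples <- setdiff(annotation$sample_id, colnames(expr))
  if (length(missing_samples))
    stop_acetyl("alignment_error",
                sprintf("annotated sample(s) absent from matrix: %s",
                        paste(missing_samples, collapse = ", ")))

  emt <- emt_scores(expr, gene_sets[[emt_set]], alpha = alpha, normalize = normalize)
  de <- de_results(expr, annotation, genes = gene_sets[[hat_set]], p_max = p_max)
  top <- select_top(de, top_fraction = top_fraction)
  scr <- screen(expr, emt, genes = de$gene_id, p_max = p_max, scc_min = scc_min)
  cand <- withCallingHandlers(
    overlap(top, scr, require_positive = require_positive, require_up = require_up),
    warning = function(w) invokeRestart("muffleWarning"))

  gsea <- list()
  if (run_gsea && nrow(cand) > 0L) {
    emt_members <- gene_sets[[emt_set]]
    for (i in seq_len(nrow(cand))) {
      g <- cand$gene_id[i]
      profile <- correlation_profile(expr, g)
      gsea[[g]] <- permutation_p(profile, emt_members, n_perm = n_perm,
                                 seed = seed + i - 1L, exponent = gsea_exponent)
    }
  }

  counts <- list(
    n_samples = ncol(expr), n_genes = nrow(expr),
    n_hat_genes = nrow(de),
    n_up = sum(de$de_class == "up"), n_down = sum(de$de_class == "down"),
    n_top = nrow(top),
    n_positive = sum(scr$passes & scr$direction == "positive"),
    n_negative = sum(scr$passes & scr$direction == "negative"),
    n_candidates = nrow(cand),
    empty_overlap = nrow(cand) == 0L)
  params <- list(hat_set = hat_set, emt_set = emt_set, alpha = alpha,
                 normalize = normalize, p_max = p_max, scc_min = scc_min,
                 top_fraction = top_fraction, require_positive = require_positive,
                 require_up = require_up, run_gsea = run_gsea,
                 gsea_exponent = gsea_exponent, n_perm = as.integer(n_perm),
                 seed = as.integer(seed))
  structure(list(emt_scores = emt, de = de, top = top, screen = scr,
                 candidates = cand, gsea = gsea, counts = counts,
                 params = params, emt_set_members = gene_sets[[emt_set]]),
            class = "hat_prioritization")
}

#' @export
print.hat_prioritization <- function(x, ...) {
  ct <- x$counts
  cat("Acetyltransferase / EMT prioritization\n")
  cat(sprintf("  cohort: %d genes x %d samples; collection: %d genes\n",
              ct$n_genes, ct$n_samples, ct$n_hat_genes))
  cat(sprintf("  differential expression: %d up, %d down (p <= %.3g)\n",
              ct$n_up, ct$n_down, x$params$p_max))
  cat(sprintf("  top %.0f%% by R score: %d genes\n",
              100 * x$params$top_fraction, ct$n_top))
  cat(sprintf("  EMT screen (|SCC| >= %.2f): %d positive, %d negative\n",
              x$params$scc_min, ct$n_positive, ct$n_negative))
  if (ct$n_candidates > 0L) {
    cat(sprintf("  candidates (%d): %s\n", ct$n_candidates,
                paste(x$candidates$gene_id, collapse = ", ")))
  } else {
    cat("  candidates: none (empty overlap)\n")
  }
  invisible(x)
}

#' @export
summary.hat_prioritization <- function(object, ...) {
  structure(list(fit = object), class = "summary.hat_prioritization")
}

#' @export
print.summary.hat_prioritization <- function(x, ...) {
  fit <- x$fit
  print(fit)
  if (nrow(fit$candidates) > 0L) {
    cat("\nCandidate provenance:\n")
    print(as.data.frame(fit$candidates)[, c("gene_id", "r_rank", "r_score",
                                            "log2fc", "p", "scc", "scc_p")],
          digits = 4, row.names = FALSE)
    if (length(fit$gsea)) {
      cat("\nGSEA validation against the EMT set:\n")
      tab <- gsea_table(fit)
      print(tab, digits = 4, row.names = FALSE)
    }
  }
  invisible(x)
}

# Per-candidate GSEA results as a data.frame.
gsea_table <- function(fit) {
  if (!length(fit$gsea))
    return(data.frame(gene_id = character(0), es = numeric(0),
                      p_perm = numeric(0), n_perm = integer(0),
                      n_leading_edge = integer(0), stringsAsFactors = FALSE))
  data.frame(gene_id = names(fit$gsea),
             es = vapply(fit$gsea, `[[`, numeric(1L), "es"),
             p_perm = vapply(fit$gsea, `[[`, numeric(1L), "p_perm"),
             n_perm = vapply(fit$gsea, `[[`, integer(1L), "n_perm"),
             n_leading_edge = vapply(fit$gsea, function(g) length(g$leading_edge),
                                     integer(1L)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Plot a prioritization fit
#'
#' `type = "volcano"`: log2 fold change vs `-log10(p)` for the collection,
#' coloured by DE class. `type = "screen"`: Spearman coefficient vs
#' `-log10(p)` of the EMT screen with the threshold lines. `type =
#' "running_sum"`: GSEA running sum for one candidate (requires a fitted
#' GSEA stage).
#'
#' @param x A `hat_prioritization` object.
#' @param type One of `"volcano"`, `"screen"`, `"running_sum"`.
#' @param candidate Candidate gene id for `type = "running_sum"` (default:
#'   the top candidate).
#' @param expr The expression matrix the fit was computed from; required for
#'   `type = "running_sum"` (the running sum is recomputed, fits do not store
#'   per-gene profiles).
#' @param ... Passed to the underlying plotting functions.
#' @return `x`, invisibly.
#' @export
plot.hat_prioritization <- function(x, type = c("volcano", "screen", "running_sum"),
                                    candidate = NULL, expr = NULL, ...) {
  type <- match.arg(type)
  if (type == "volcano") {
    cols <- c(up = "firebrick", down = "steelblue", not_de = "grey60")
    graphics::plot(x$de$log2fc, -log10(x$de$p), col = cols[x$de$de_class],
                   pch = 19, xlab = "log2 fold change (cancer vs normal)",
                   ylab = "-log10 Wilcoxon p", ...)
    graphics::abline(h = -log10(x$params$p_max), lty = 2)
  } else if (type == "screen") {
    ok <- !x$screen$missing
    cols <- c(positive = "firebrick", negative = "steelblue", none = "grey60")
    graphics::plot(x$screen$scc[ok], -log10(x$screen$p[ok]),
                   col = cols[x$screen$direction[ok]], pch = 19,
                   xlab = "Spearman correlation with EMT score",
                   ylab = "-log10 p", ...)
    graphics::abline(v = c(-1, 1) * x$params$scc_min, lty = 2)
    graphics::abline(h = -log10(x$params$p_max), lty = 2)
  } else {
    if (!length(x$gsea)) stop_acetyl("key_error", "fit has no GSEA stage")
    if (is.null(candidate)) candidate <- names(x$gsea)[1L]
    if (!candidate %in% names(x$gsea))
      stop_acetyl("key_error", sprintf("no GSEA result for '%s'", candidate))
    if (is.null(expr))
      stop_acetyl("validation_error", "type = 'running_sum' needs the expression matrix")
    profile <- correlation_profile(expr, candidate)
    es <- gsea_es(profile, x$emt_set_members, exponent = x$params$gsea_exponent)
    graphics::plot(es$running_sum, type = "l",
                   xlab = "rank by correlation with candidate",
                   ylab = "running enrichment", ...)
    graphics::abline(h = 0, lty = 3)
    graphics::abline(v = es$peak, lty = 2)
  }
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Writes `emt_scores.tsv`, `de_rank.tsv`, `screen.tsv`, `candidates.tsv`,
#' `gsea.tsv` and a machine-readable `report.json` (counts, parameters,
#' seeds). Reports contain no timestamps, so identical fits produce
#' byte-identical reports.
#'
#' @param fit A [prioritize_hat_genes()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(fit, dir) {
  stopifnot(inherits(fit, "hat_prioritization"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_results_table(data.frame(sample_id = names(fit$emt_scores),
                                 emt_score = unname(fit$emt_scores),
                                 stringsAsFactors = FALSE),
                      file.path(dir, "emt_scores.tsv"))
  write_results_table(fit$de, file.path(dir, "de_rank.tsv"))
  write_results_table(fit$screen, file.path(dir, "screen.tsv"))
  write_results_table(as.data.frame(fit$candidates), file.path(dir, "candidates.tsv"))
  write_results_table(gsea_table(fit), file.path(dir, "gsea.tsv"))
  report <- list(parameters = fit$params, counts = fit$counts,
                 candidates = fit$candidates$gene_id,
                 gsea = gsea_table(fit))
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Run the full pipeline from a configuration
#'
#' The configuration is a YAML file or an equivalent named list with fields
#' `expr` (path), `annotation` (path), `gene_sets` (GMT path), optional
#' `expr_format` (`tsv`/`gct`), `outdir`, and any parameter of
#' [prioritize_hat_genes()] (`hat_set`, `emt_set`, `alpha`, `normalize`,
#' `p_max`, `scc_min`, `top_fraction`, `require_positive`, `require_up`,
#' `run_gsea`, `gsea_exponent`, `n_perm`, `seed`).
#'
#' @param config Path to a YAML file, or a named list.
#' @return The `hat_prioritization` fit, invisibly (outputs are written to
#'   `outdir` when given).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop_acetyl("io_error", sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  for (f in c("expr", "annotation", "gene_sets")) {
    if (is.null(config[[f]]))
      stop_acetyl("validation_error", sprintf("config field '%s' is required", f))
    if (!file.exists(config[[f]]))
      stop_acetyl("io_error", sprintf("config field '%s': file not found: %s",
                                      f, config[[f]]))
  }
  expr <- read_expression(config$expr,
                          format = if (is.null(config$expr_format)) "tsv"
                                   else config$expr_format,
                          log2_transform = isTRUE(config$log2_transform))
  annotation <- read_annotation(config$annotation, expr = expr)
  gene_sets <- read_gmt(config$gene_sets)
  args <- config[intersect(names(config),
                           c("hat_set", "emt_set", "alpha", "normalize", "p_max",
                             "scc_min", "top_fraction", "require_positive",
                             "require_up", "run_gsea", "gsea_exponent", "n_perm",
                             "seed"))]
  fit <- do.call(prioritize_hat_genes,
                 c(list(expr = expr, annotation = annotation,
                        gene_sets = gene_sets), args))
  if (!is.null(config$outdir)) write_pipeline_outputs(fit, config$outdir)
  invisible(fit)
}
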