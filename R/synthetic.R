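# Synthetic staged-cohort generator. Emulates the statistical structure the
# pipeline assumes: 128 samples spanning normal -> CIN1-3 -> cancer, a latent
# per-sample EMT activity that rises with stage, an EMT gene program loading
# on that activity, an 88-gene acetyltransferase collection with a small
# planted subset that is both up-regulated in cancer and coupled to the EMT
# activity, and independent Gaussian noise on the log2 scale.
#
# Generative model, for sample j with stage s and activity
# a_j ~ N(mu_stage[s], sigma_activity^2):
#   EMT program gene i:      x_ij = b_i + lambda_i * a_j            + eps_ij
#   planted candidate i:     x_ij = b_i + delta*1[s = cancer]
#                                       + gamma * a_j               + eps_ij
#   acetyl null / background x_ij = b_i                             + eps_ij
# with b_i ~ N(baseline_mean, baseline_sd^2), eps_ij ~ N(0, sigma_noise^2).

#' Specification of a synthetic staged cohort
#'
#' Defaults emulate the study design the pipeline targets: 128 samples with
#' stage sizes 24/14/22/40/28 (normal/CIN1/CIN2/CIN3/cancer), ~5000 background
#' genes, a 200-gene EMT program, an 88-gene acetyltransferase collection with
#' 7 planted candidates shifted by `delta = 1` log2 unit in cancer and coupled
#' to the EMT activity with `gamma = 0.6`, latent activity means rising 0 to 2
#' across stages with `sigma_activity = 0.5`, and unit Gaussian noise.
#'
#' @param stage_sizes Named integer vector of per-stage sample counts
#'   (names `normal`, `CIN1`, `CIN2`, `CIN3`, `cancer`; each `>= 2`).
#' @param n_background_genes,emt_set_size,n_acetyl_genes,n_planted Gene counts.
#' @param delta Cancer-vs-normal mean shift of planted genes (log2 units).
#' @param gamma Loading of planted genes on the EMT activity.
#' @param lambda_range Range of EMT-gene loadings (uniform draw).
#' @param mu_stage Latent activity means per stage, non-decreasing, length 5.
#' @param sigma_activity,sigma_noise Activity and noise standard deviations.
#' @param baseline_mean,baseline_sd Log2 baseline expression distribution.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return Validated list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(stage_sizes = c(normal = 24L, CIN1 = 14L, CIN2 = 22L,
                                           CIN3 = 40L, cancer = 28L),
                           n_background_genes = 5000L,
                           emt_set_size = 200L,
                           n_acetyl_genes = 88L,
                           n_planted = 7L,
                           delta = 1.0,
                           gamma = 0.6,
                           lambda_range = c(0.5, 1.5),
                           mu_stage = c(normal = 0, CIN1 = 0.5, CIN2 = 1,
                                        CIN3 = 1.5, cancer = 2),
                           sigma_activity = 0.5,
                           sigma_noise = 1.0,
                           baseline_mean = 7,
                           baseline_sd = 2,
                           seed = 1L) {
  spec <- list(stage_sizes = stage_sizes, n_background_genes = n_background_genes,
               emt_set_size = emt_set_size, n_acetyl_genes = n_acetyl_genes,
               n_planted = n_planted, delta = delta, gamma = gamma,
               lambda_range = lambda_range, mu_stage = mu_stage,
               sigma_activity = sigma_activity, sigma_noise = sigma_noise,
               baseline_mean = baseline_mean, baseline_sd = baseline_sd,
               seed = seed)
  bad <- character(0)
  if (!identical(sort(names(stage_sizes)), sort(STAGE_LEVELS)) ||
      any(stage_sizes < 2L))
    bad <- c(bad, "stage_sizes (need all five stages, each >= 2 samples)")
  if (n_background_genes < 0L) bad <- c(bad, "n_background_genes")
  if (emt_set_size < 2L) bad <- c(bad, "emt_set_size (>= 2)")
  if (n_acetyl_genes < 1L) bad <- c(bad, "n_acetyl_genes")
  if (n_planted < 0L || n_planted > n_acetyl_genes)
    bad <- c(bad, "n_planted (0 <= n_planted <= n_acetyl_genes)")
  if (length(lambda_range) != 2L || lambda_range[2] < lambda_range[1])
    bad <- c(bad, "lambda_range")
  if (length(mu_stage) == 5L && is.null(names(mu_stage)))
    names(spec$mu_stage) <- STAGE_LEVELS
  if (length(spec$mu_stage) != 5L ||
      !all(STAGE_LEVELS %in% names(spec$mu_stage)) ||
      is.unsorted(unname(spec$mu_stage[STAGE_LEVELS])))
    bad <- c(bad, "mu_stage (length 5, non-decreasing with severity)")
  if (sigma_activity < 0) bad <- c(bad, "sigma_activity")
  if (sigma_noise < 0) bad <- c(bad, "sigma_noise")
  if (baseline_sd < 0) bad <- c(bad, "baseline_sd")
  if (length(bad))
    stop_acetyl("validation_error",
                paste0("invalid synthetic spec field(s): ", paste(bad, collapse = "; ")))
  if (is.null(names(mu_stage))) names(spec$mu_stage) <- STAGE_LEVELS
  structure(spec, class = "synthetic_spec")
}

#' Generate a synthetic staged expression cohort
#'
#' Draws a cohort from the generative model described in [synthetic_spec()],
#' fully reproducible from `spec$seed` (the caller's RNG state is restored).
#'
#' @param spec A [synthetic_spec()].
#' @return List of class `synthetic_cohort` with elements
#'   `expression` (genes x samples log2 matrix), `annotation`
#'   (see [read_annotation()]), `gene_sets` (`EMT` and `HAT` sets, GMT-style
#'   collection), and `truth` (`data.frame`: `gene_id`, `class` in
#'   `emt_program`/`planted_candidate`/`acetyl_null`/`background`, `delta`,
#'   `loading`).
#' @examples
#' cohort <- generate_cohort(synthetic_spec(n_background_genes = 50,
#'                                          emt_set_size = 10,
#'                                          n_acetyl_genes = 10, n_planted = 2))
#' dim(cohort$expression)
#' @export
generate_cohort <- function(spec = synthetic_spec()) {
  if (!inherits(spec, "synthetic_spec"))
    stop_acetyl("validation_error", "spec must come from synthetic_spec()")
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(spec$seed)

  sizes <- spec$stage_sizes[STAGE_LEVELS]
  n <- sum(sizes)
  stage <- rep(STAGE_LEVELS, times = sizes)
  sample_id <- sprintf("S%03d", seq_len(n))
  activity <- rnorm(n, mean = unname(spec$mu_stage[stage]), sd = spec$sigma_activity)

  emt_ids <- sprintf("EMT%03d", seq_len(spec$emt_set_size))
  hat_ids <- sprintf("HAT%03d", seq_len(spec$n_acetyl_genes))
  bg_ids <- if (spec$n_background_genes > 0)
    sprintf("BG%05d", seq_len(spec$n_background_genes)) else character(0)
  gene_ids <- c(emt_ids, hat_ids, bg_ids)
  g <- length(gene_ids)

  baseline <- rnorm(g, spec$baseline_mean, spec$baseline_sd)
  lambda <- runif(spec$emt_set_size, spec$lambda_range[1], spec$lambda_range[2])
  planted <- sort(sample(hat_ids, spec$n_planted))

  x <- matrix(rnorm(g * n, sd = spec$sigma_noise), g, n,
              dimnames = list(gene_ids, sample_id)) + baseline
  x[emt_ids, ] <- x[emt_ids, ] + lambda %o% activity
  if (length(planted)) {
    x[planted, ] <- x[planted, ] + spec$gamma * rep(activity, each = length(planted))
    x[planted, stage == "cancer"] <- x[planted, stage == "cancer"] + spec$delta
  }

  annotation <- make_annotation(sample_id, stage)
  gene_sets <- structure(
    list(EMT = emt_ids, HAT = hat_ids),
    description = c(EMT = "synthetic EMT program",
                    HAT = "synthetic acetyltransferase collection"),
    class = c("gene_set_collection", "list"))
  truth <- data.frame(
    gene_id = gene_ids,
    class = c(rep("emt_program", length(emt_ids)),
              ifelse(hat_ids %in% planted, "planted_candidate", "acetyl_null"),
              rep("background", length(bg_ids))),
    delta = ifelse(gene_ids %in% planted, spec$delta, 0),
    loading = c(lambda, ifelse(hat_ids %in% planted, spec$gamma, 0),
                rep(0, length(bg_ids))),
    stringsAsFactors = FALSE)

  structure(list(expression = x, annotation = annotation, gene_sets = gene_sets,
                 truth = truth, activity = setNames(activity, sample_id),
                 spec = spec),
            class = "synthetic_cohort")
}

#' Generate a matched null cohort (all effects zeroed)
#'
#' Convenience wrapper: same design as [generate_cohort()] but with
#' `delta = 0`, `gamma = 0` and all EMT loadings zero, so every gene is pure
#' baseline plus noise.
#'
#' @param spec A [synthetic_spec()]; its effect-size fields are overridden.
#' @return A `synthetic_cohort`, see [generate_cohort()].
#' @export
null_cohort <- function(spec = synthetic_spec()) {
  if (!inherits(spec, "synthetic_spec"))
    stop_acetyl("validation_error", "spec must come from synthetic_spec()")
  spec$delta <- 0
  spec$gamma <- 0
  spec$lambda_range <- c(0, 0)
  generate_cohort(spec)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d genes x %d samples (seed %s)\n",
              nrow(x$expression), ncol(x$expression), format(x$spec$seed)))
  cat("Stages:", paste(sprintf("%s=%d", STAGE_LEVELS,
                               table(x$annotation$stage)[STAGE_LEVELS]),
                       collapse = ", "), "\n")
  cls <- table(x$truth$class)
  cat("Gene classes:", paste(sprintf("%s=%d", names(cls), cls), collapse = ", "), "\n")
  invisible(x)
}
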