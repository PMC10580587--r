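test_that("the generator is reproducible and validates its spec", {
  a <- generate_cohort(small_spec(seed = 99))
  b <- generate_cohort(small_spec(seed = 99))
  expect_identical(a, b)
  c <- generate_cohort(small_spec(seed = 100))
  expect_false(identical(a$expression, c$expression))
  expect_error(synthetic_spec(stage_sizes = c(normal = 1, CIN1 = 2, CIN2 = 2,
                                              CIN3 = 2, cancer = 2)),
               "stage_sizes", class = "acetylprio_validation_error")
  expect_error(synthetic_spec(n_planted = 99, n_acetyl_genes = 10),
               "n_planted", class = "acetylprio_validation_error")
  expect_error(synthetic_spec(mu_stage = c(2, 1, 1, 1, 0)),
               "mu_stage", class = "acetylprio_validation_error")
})

test_that("generated cohorts satisfy the matrix and truth-table invariants", {
  cohort <- generate_cohort(small_spec(seed = 4))
  x <- cohort$expression
  expect_false(anyDuplicated(rownames(x)) > 0)
  expect_false(anyDuplicated(colnames(x)) > 0)
  expect_false(anyNA(x))
  expect_identical(ncol(x), 128L)
  expect_setequal(cohort$truth$gene_id, rownames(x))
  expect_setequal(unique(cohort$truth$class),
                  c("emt_program", "planted_candidate", "acetyl_null", "background"))
  expect_identical(sum(cohort$truth$class == "planted_candidate"), 3L)
  # gene sets match the truth classes
  expect_setequal(cohort$gene_sets$EMT,
                  cohort$truth$gene_id[cohort$truth$class == "emt_program"])
  expect_setequal(cohort$gene_sets$HAT,
                  cohort$truth$gene_id[cohort$truth$class %in%
                                         c("planted_candidate", "acetyl_null")])
  # annotation aligns with the matrix and the stage vocabulary
  expect_identical(cohort$annotation$sample_id, colnames(x))
  expect_identical(levels(cohort$annotation$stage),
                   c("normal", "CIN1", "CIN2", "CIN3", "cancer"))
})

test_that("marginal moments match the spec at large gene counts", {
  spec <- synthetic_spec(n_background_genes = 4000, emt_set_size = 10,
                         n_acetyl_genes = 10, n_planted = 0, seed = 8)
  cohort <- generate_cohort(spec)
  bg <- cohort$expression[cohort$truth$gene_id[cohort$truth$class == "background"], ]
  gene_means <- rowMeans(bg)
  expect_equal(mean(gene_means), spec$baseline_mean, tolerance = 0.15)
  expect_equal(sd(gene_means), spec$baseline_sd, tolerance = 0.15)
  resid_sd <- mean(apply(bg, 1, sd))
  expect_equal(resid_sd, spec$sigma_noise, tolerance = 0.05)
})

test_that("planted genes track the latent activity; nulls do not", {
  hits <- 0
  n_seeds <- 10
  for (s in seq_len(n_seeds)) {
    cohort <- generate_cohort(small_spec(seed = 200 + s))
    planted <- cohort$truth$gene_id[cohort$truth$class == "planted_candidate"]
    scc <- vapply(planted, function(g)
      spearman_scc(cohort$expression[g, ], cohort$activity)$scc, numeric(1))
    hits <- hits + sum(scc > 0.3)
  }
  expect_gte(hits / (n_seeds * 3), 0.9)
  # under the null the same correlations are centred at zero
  nullc <- null_cohort(small_spec(seed = 300))
  hat <- nullc$truth$gene_id[nullc$truth$class != "background" &
                               nullc$truth$class != "emt_program"]
  scc0 <- vapply(hat, function(g)
    spearman_scc(nullc$expression[g, ], nullc$activity)$scc, numeric(1))
  expect_lt(max(abs(scc0)), 0.45)
})

test_that("null-cohort EMT scores are exchangeable across stages", {
  pvals <- vapply(1:30, function(s) {
    nullc <- null_cohort(synthetic_spec(n_background_genes = 60, emt_set_size = 25,
                                        n_acetyl_genes = 5, n_planted = 0,
                                        seed = 500 + s))
    emt <- emt_scores(nullc$expression, nullc$gene_sets$EMT)
    stats::kruskal.test(emt, nullc$annotation$stage)$p.value
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})
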