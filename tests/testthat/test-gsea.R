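test_that("correlation_profile ranks genes by Spearman correlation with the candidate", {
  set.seed(17)
  x <- rand_matrix(6, 10)
  x["g2", ] <- x["g1", ]              # duplicate of the candidate
  x["g3", ] <- -x["g1", ]             # negated candidate
  prof <- correlation_profile(x, "g1")
  expect_false("g1" %in% names(prof))
  expect_identical(names(prof)[1], "g2")
  expect_equal(unname(prof[1]), 1)
  expect_identical(names(prof)[length(prof)], "g3")
  expect_equal(unname(prof[length(prof)]), -1)
  # pairwise brute-force oracle
  for (g in setdiff(rownames(x), "g1"))
    expect_equal(unname(prof[g]), brute_spearman(x["g1", ], x[g, ]),
                 tolerance = 1e-12)
  expect_error(correlation_profile(x, "nope"), class = "acetylprio_key_error")
  expect_error(correlation_profile(x[, 1:3], "g1"),
               class = "acetylprio_insufficient_samples")
})

test_that("gsea_es matches the brute-force walk and stays in [-1, 1]", {
  # 6-gene fixture, |S| = 2
  w <- setNames(c(0.9, 0.7, 0.3, -0.1, -0.5, -0.8), paste0("g", 1:6))
  s <- c("g1", "g5")
  expect_equal(gsea_es(w, s)$es, naive_gsea_es(w, s, 1), tolerance = 1e-12)
  set.seed(23)
  worst <- 0
  for (rep in 1:200) {
    n <- sample(5:60, 1)
    wr <- sort(runif(n, -1, 1), decreasing = TRUE)
    names(wr) <- paste0("g", seq_len(n))
    k <- sample(seq_len(n - 1), 1)
    sr <- sample(names(wr), k)
    e <- sample(c(0, 0.5, 1, 2), 1)
    got <- gsea_es(wr, sr, e)$es
    ref <- naive_gsea_es(wr, sr, e)
    # at an exact max/min magnitude tie only |es| is determined
    worst <- max(worst, min(abs(got - ref), abs(abs(got) - abs(ref))))
    expect_gte(got, -1)
    expect_lte(got, 1)
  }
  expect_lt(worst, 1e-12)
})

test_that("gsea_es behaves like a front-loaded KS statistic", {
  w <- setNames(seq(1, -1, length.out = 20), paste0("g", 1:20))
  top <- names(w)[1:4]
  expect_gt(gsea_es(w, top)$es, 0)
  # reversing the profile negates the unweighted (exponent 0) statistic
  wr <- rev(w)
  expect_equal(gsea_es(wr, top, exponent = 0)$es,
               -gsea_es(w, top, exponent = 0)$es, tolerance = 1e-12)
  expect_error(gsea_es(w, "absent"), class = "acetylprio_empty_set")
})

test_that("leading edge holds the set members up to the positive peak", {
  set.seed(29)
  for (rep in 1:25) {
    n <- 40
    w <- sort(runif(n, -1, 1), decreasing = TRUE)
    names(w) <- paste0("g", seq_len(n))
    s <- sample(names(w)[1:15], 5)    # front-loaded so es > 0
    res <- gsea_es(w, s)
    if (res$es <= 0) next
    expect_setequal(res$leading_edge,
                    intersect(names(w)[seq_len(res$peak)], s))
  }
})

test_that("the position-based ES shortcut agrees with the full running sum", {
  set.seed(37)
  for (rep in 1:200) {
    n <- sample(10:80, 1)
    w <- sort(runif(n, -1, 1), decreasing = TRUE)
    names(w) <- paste0("g", seq_len(n))
    k <- sample(seq_len(n %/% 2), 1)
    s <- sample(names(w), k)
    full <- gsea_es(w, s)$es
    fast <- acetylprio:::gsea_es_positions(abs(unname(w)), n, which(names(w) %in% s))
    expect_equal(fast, full, tolerance = 1e-12)
  }
})

test_that("gsea_es agrees with fgsea's statistic on random profiles", {
  skip_if_not_installed("fgsea")
  set.seed(41)
  for (rep in 1:50) {
    n <- sample(20:80, 1)
    w <- sort(runif(n, -1, 1), decreasing = TRUE)
    names(w) <- paste0("g", seq_len(n))
    k <- sample(2:(n %/% 3), 1)
    pos <- sort(sample.int(n, k))
    ours <- gsea_es(w, names(w)[pos])$es
    ref <- fgsea::calcGseaStat(w, pos, gseaParam = 1)
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("permutation_p is reproducible, floored, and warns on huge sets", {
  w <- sort(runif(60, -1, 1), decreasing = TRUE)
  names(w) <- paste0("g", 1:60)
  s <- names(w)[1:6]
  a <- permutation_p(w, s, n_perm = 200, seed = 5)
  b <- permutation_p(w, s, n_perm = 200, seed = 5)
  expect_identical(a, b)
  expect_gte(a$p_perm, 1 / 201)
  # maximally enriched set at the formula floor
  top <- setNames(c(rep(1, 5), seq(0.5, -1, length.out = 95)), paste0("g", 1:100))
  res <- permutation_p(top, names(top)[1:5], n_perm = 100, seed = 1)
  expect_equal(res$p_perm, 1 / 101, tolerance = 1e-14)
  expect_warning(permutation_p(w, names(w)[1:40], n_perm = 100, seed = 1),
                 "poorly behaved")
  expect_error(permutation_p(w, s, n_perm = 50), class = "acetylprio_domain_error")
})
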