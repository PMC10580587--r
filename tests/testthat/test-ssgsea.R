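test_that("within-sample ranking orders by expression with lexicographic ties", {
  w <- rank_genes_in_sample(c(A = 3, B = 1, C = 2))
  expect_identical(names(w), c("A", "C", "B"))
  expect_identical(unname(w), c(3L, 2L, 1L))
  wt <- rank_genes_in_sample(c(B = 2, A = 2))
  expect_identical(names(wt), c("A", "B"))
  # permuting the input leaves the ranking unchanged
  x <- c(D = 0.2, A = 1.5, C = 0.2, B = -1)
  expect_identical(rank_genes_in_sample(x), rank_genes_in_sample(rev(x)))
})

test_that("ssgsea_score matches the spec walk on worked examples", {
  w <- setNames(c(4, 3, 2, 1), paste0("g", 1:4))
  expect_equal(ssgsea_score(w, "g1", alpha = 1), 2.0, tolerance = 1e-14)
  w2 <- setNames(c(2, 1), c("hi", "lo"))
  expect_equal(ssgsea_score(w2, "lo", alpha = 0), -1.0, tolerance = 1e-14)
  expect_error(ssgsea_score(w, paste0("g", 1:4)),
               class = "acetylprio_degenerate_complement")
  expect_error(ssgsea_score(w, "absent"), class = "acetylprio_empty_set")
})

test_that("ssgsea_score equals the naive double-loop oracle on random instances", {
  set.seed(42)
  worst <- 0
  for (rep in 1:200) {
    n <- sample(5:50, 1)
    genes <- paste0("g", seq_len(n))
    w <- setNames(seq.int(n, 1), sample(genes))
    k <- sample(seq_len(min(20, n - 1)), 1)
    s <- sample(genes, k)
    alpha <- sample(c(0, 0.25, 0.5, 1, 1.7), 1)
    worst <- max(worst, abs(ssgsea_score(w, s, alpha) - naive_ssgsea(w, s, alpha)))
  }
  expect_lt(worst, 1e-12)
})

test_that("with unweighted ranks, promoting a set member never decreases the score", {
  set.seed(7)
  for (rep in 1:40) {
    n <- sample(6:25, 1)
    genes <- paste0("g", seq_len(n))
    w <- setNames(seq.int(n, 1), genes)
    s <- sample(genes, sample(2:4, 1))
    # find a non-member immediately above a member and swap the pair
    hit <- names(w) %in% s
    i <- which(!hit[-n] & hit[-1])[1]
    if (is.na(i)) next
    nm <- names(w)
    nm[c(i, i + 1)] <- nm[c(i + 1, i)]
    w2 <- setNames(unname(w), nm)
    expect_gte(ssgsea_score(w2, s, alpha = 0) - ssgsea_score(w, s, alpha = 0), -1e-12)
  }
})

test_that("with weighted ranks, promoting a member can lower the score (denominator dilution)", {
  # frozen counterexample: promoting the rank-6 member to rank 5 enlarges the
  # hit-weight denominator and dilutes the rank-1 member's plateau
  w <- setNames(6:1, paste0("g", 1:6))
  s <- c("g1", "g6")
  w2 <- setNames(6:1, c("g1", "g2", "g3", "g4", "g6", "g5"))
  expect_equal(ssgsea_score(w2, s, alpha = 1) - ssgsea_score(w, s, alpha = 1),
               -5 / 140, tolerance = 1e-12)
})

test_that("emt_scores are deterministic, rank-based and range-normalized", {
  set.seed(3)
  x <- rand_matrix(30, 6)
  s <- paste0("g", 1:8)
  # identical columns give identical scores
  x[, 2] <- x[, 1]
  sc <- emt_scores(x, s, normalize = FALSE)
  expect_equal(sc[["s1"]], sc[["s2"]], tolerance = 1e-14)
  # strictly increasing transform of one column leaves its raw score unchanged
  x2 <- x
  x2[, 3] <- exp(x2[, 3] / 2) + 5
  sc2 <- emt_scores(x2, s, normalize = FALSE)
  expect_equal(sc[["s3"]], sc2[["s3"]], tolerance = 1e-12)
  # a sample whose set members occupy the top |S| slots scores maximally
  x3 <- x
  x3[s, 4] <- max(x3[, 4]) + seq_along(s)
  sc3 <- emt_scores(x3, s, normalize = FALSE)
  expect_identical(names(which.max(sc3)), "s4")
  # normalization preserves the sample ordering
  scn <- emt_scores(x3, s, normalize = TRUE)
  expect_identical(order(scn), order(sc3))
  # members absent from the matrix are dropped with a message
  expect_message(emt_scores(x, c(s, "missing_gene"), normalize = FALSE),
                 "1 set member")
})
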