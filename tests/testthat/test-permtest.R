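test_that("pairwise distances match closed forms and a brute-force loop", {
  m <- rbind(a = c(1, 0), b = c(0, 1), c = c(1, 0))
  D <- pairwise_distances(m)
  expect_equal(D["a", "b"], sqrt(2))
  expect_equal(D["a", "c"], 0)
  expect_equal(diag(D), c(a = 0, b = 0, c = 0))

  set.seed(42)
  r <- matrix(runif(15), 5, 3)
  expect_equal(unname(pairwise_distances(r)), oracle_pairwise(r))

  expect_error(pairwise_distances(matrix(c(1, NA, 0, 1), 2)),
               "finite", class = "acustyle_input_error")
  expect_error(pairwise_distances(matrix(1, 1, 3)),
               class = "acustyle_input_error")
})

test_that("same-label mean distance matches explicit pair enumeration", {
  # single same-label pair
  D <- matrix(0, 4, 4)
  D[1, 2] <- D[2, 1] <- 0.5
  D[3, 4] <- D[4, 3] <- 9
  expect_equal(same_label_mean_distance(D, c("a", "a", "b", "c")), 0.5)

  # all documents identical: statistic 0 for any labels
  Z <- matrix(0, 5, 5)
  expect_equal(same_label_mean_distance(Z, c(1, 1, 2, 2, 2)), 0)

  set.seed(7)
  m <- matrix(runif(18), 6, 3)
  D6 <- pairwise_distances(m)
  labs <- c("A", "A", "B", "B", "C", "C")
  expect_equal(same_label_mean_distance(D6, labs),
               oracle_same_label(D6, labs))

  expect_error(same_label_mean_distance(D6, unique(labs)),
               class = "acustyle_input_error")
  expect_error(same_label_mean_distance(D6, c("a", "b", "c", "d", "e", "f")),
               "No pair", class = "acustyle_input_error")
})

test_that("a zero distance matrix gives p = 1 with observed = expected = 0", {
  Z <- matrix(0, 4, 4)
  pt <- permutation_test(Z, c("a", "a", "b", "b"), B = 50, seed = 1)
  expect_equal(pt$observed, 0)
  expect_equal(pt$expected, 0)
  expect_equal(pt$p_empirical, 1)
})

test_that("exhaustive enumeration reproduces the exact permutation p-value", {
  for (seed in 1:5) {
    set.seed(seed)
    m <- matrix(runif(8), 4, 2)
    D <- pairwise_distances(m)
    labs <- c("A", "A", "B", "B")
    oracle <- oracle_exhaustive_perm(D, labs)
    pt <- permutation_test(D, labs, B = 1, seed = 1)  # auto-exhaustive at n=4
    expect_true(pt$exact)
    expect_equal(pt$p_empirical, oracle$p)
    expect_equal(pt$expected, oracle$expected)
    expect_equal(pt$observed, oracle$observed)
  }
})

test_that("sampled null mean approaches the grand mean of off-diagonal distances", {
  set.seed(5)
  m <- matrix(runif(24), 8, 3)
  D <- pairwise_distances(m)
  labs <- rep(c("x", "y"), each = 4)
  pt <- permutation_test(D, labs, B = 4000, seed = 2, exact = FALSE)
  grand <- mean(D[upper.tri(D)])
  expect_lt(abs(pt$expected - grand), 3 * pt$null_sd / sqrt(pt$B))
})

test_that("the test is deterministic in (D, labels, B, seed) and validates input", {
  set.seed(9)
  m <- matrix(runif(20), 5, 4)
  D <- pairwise_distances(m)
  labs <- c("a", "a", "b", "b", "b")
  p1 <- permutation_test(D, labs, B = 500, seed = 33, exact = FALSE)
  p2 <- permutation_test(D, labs, B = 500, seed = 33, exact = FALSE)
  expect_identical(p1, p2)
  p3 <- permutation_test(D, labs, B = 500, seed = 34, exact = FALSE)
  expect_false(identical(p1$p_empirical, p3$p_empirical) &&
                 identical(p1$expected, p3$expected))

  expect_error(permutation_test(D, rep("a", 5), B = 10),
               "degenerate|Constant", class = "acustyle_input_error")
  expect_error(permutation_test(D, labs, B = 0),
               class = "acustyle_input_error")
})

test_that("p-value conventions: k/B with <1/B display, add-one variant", {
  # two tight clusters far apart: observed is the minimum over labelings
  m <- rbind(matrix(0, 3, 2), matrix(10, 3, 2)) + matrix(rnorm(12, sd = 1e-3), 6)
  D <- pairwise_distances(m)
  labs <- rep(c("u", "v"), each = 3)
  pt <- permutation_test(D, labs, B = 200, seed = 4, exact = FALSE)
  # sampled permutations that regroup the clusters give larger statistics;
  # only the 1/10 of permutations preserving the split tie the observed
  expect_true(pt$p_empirical < 0.25)
  pt_add <- permutation_test(D, labs, B = 200, seed = 4, exact = FALSE,
                             p_convention = "add_one")
  expect_equal(pt_add$p_empirical,
               (pt$p_empirical * 200 + 1) / 201)

  # a display of "<1/B" appears exactly when no null sample is <= observed
  skewD <- D
  if (pt$p_empirical > 0) {
    expect_equal(pt$p_display, format(pt$p_empirical, digits = 3))
  }
  # forcing k = 0 via an impossible observed value is not part of the API;
  # check the display rule on a case engineered to have k = 0:
  m2 <- rbind(c(0, 0), c(0, 1e-9), c(5, 0), c(0, 5), c(7, 7), c(2, 9))
  D2 <- pairwise_distances(m2)
  labs2 <- c("p", "p", "q", "q", "r", "r")
  pt2 <- permutation_test(D2, labs2, B = 1000, seed = 8, exact = FALSE)
  if (pt2$p_empirical == 0) expect_equal(pt2$p_display, "<0.001")
})

test_that("Monte-Carlo p stays within 3 standard errors of the exhaustive p", {
  for (seed in 1:10) {
    set.seed(seed)
    m <- matrix(runif(12), 6, 2)
    D <- pairwise_distances(m)
    labs <- sample(c("A", "A", "B", "B", "C", "C"))
    exact_p <- permutation_test(D, labs, B = 1)$p_empirical
    mc_p <- permutation_test(D, labs, B = 3000, seed = seed,
                             exact = FALSE)$p_empirical
    se <- sqrt(max(exact_p * (1 - exact_p), 1e-12) / 3000)
    expect_lte(abs(mc_p - exact_p), max(3 * se, 2 / 3000))
  }
})

test_that("BH adjustment matches the hand-applied step-up formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04, 0.05)),
               c(0.04, 0.04, 0.05, 0.05))
  expect_equal(bh_adjust(0.3), 0.3)                   # m = 1
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))   # all tied
  set.seed(11)
  for (i in 1:20) {
    p <- runif(sample(2:10, 1))
    expect_equal(bh_adjust(p), oracle_bh(p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), class = "acustyle_input_error")
  expect_error(bh_adjust(c(0.5, -0.1)), class = "acustyle_input_error")
})

test_that("the similarity suite has the canonical row structure", {
  sim <- simulate_corpus(seed = 77)
  suite <- run_similarity_suite(sim$corpus, B = 300, seed = 5)
  expect_equal(nrow(suite), 8)  # 2 + 2 * C(3,2)
  expect_equal(sum(suite$grouping == "same_textbook"), 4)
  expect_equal(sum(suite$grouping == "same_disease"), 4)
  expect_equal(sum(grepl("&.*&", suite$subset)), 2)  # one all-textbook block
  expect_equal(suite$p_adjusted, bh_adjust(suite$p_empirical))
  expect_true(all(suite$p_adjusted >= suite$p_empirical - 1e-12))

  two <- simulate_corpus(n_textbooks = 2, seed = 78)
  expect_equal(nrow(run_similarity_suite(two$corpus, B = 100, seed = 1)), 4)

  one_disease <- simulate_corpus(n_diseases = 1, seed = 79)
  expect_error(run_similarity_suite(one_disease$corpus, B = 10),
               class = "acustyle_input_error")
})

test_that("a strong planted style effect drives the same-textbook suite p to <1/B", {
  sim <- simulate_corpus(style_strength = 10, seed = 123)
  suite <- run_similarity_suite(sim$corpus, B = 1e5, seed = 9)
  all_tb <- suite[suite$grouping == "same_textbook" &
                    grepl("&.*&", suite$subset), ]
  expect_equal(all_tb$p_display, "<1e-05")
  all_ds <- suite[suite$grouping == "same_disease" &
                    grepl("&.*&", suite$subset), ]
  expect_gt(all_ds$p_empirical, 0.05)
})

test_that("tidy and glance summarise a permutation test", {
  set.seed(2)
  D <- pairwise_distances(matrix(runif(10), 5, 2))
  pt <- permutation_test(D, c(1, 1, 2, 2, 2), B = 100, seed = 3,
                         exact = FALSE)
  td <- tidy(pt)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  expect_named(td, c("observed", "expected", "p_empirical", "p_display",
                     "B", "exact", "n_documents"))
  expect_equal(glance(pt), td)
})
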