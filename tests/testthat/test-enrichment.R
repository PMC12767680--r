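test_that("two-set null is exactly hypergeometric and DP edge cases hold", {
  d <- null_intersection_distribution(40, c(12, 7))
  expect_equal(d$pmf, dhyper(0:7, 12, 28, 7), tolerance = 1e-12)

  zero <- null_intersection_distribution(25, c(0, 10, 5))
  expect_equal(zero$support, 0)
  expect_equal(zero$pmf, 1)

  expect_error(null_intersection_distribution(10, c(11, 3)), "sizes")
  expect_error(null_intersection_distribution(0, c(1, 1)), "positive")
  expect_error(null_intersection_distribution(10, 5), "at least 2")
})

test_that("null pmf sums to one with mean N prod(sizes/N), any size order", {
  set.seed(202)
  for (i in 1:25) {
    N <- sample(10:60, 1)
    m <- sample(2:4, 1)
    sizes <- sample.int(N, m, replace = TRUE)
    d <- null_intersection_distribution(N, sizes)
    expect_equal(sum(d$pmf), 1, tolerance = 1e-9)
    expect_equal(sum(d$support * d$pmf), N * prod(sizes / N),
                 tolerance = 1e-6 * max(1, N * prod(sizes / N)))
    dperm <- null_intersection_distribution(N, sample(sizes))
    expect_equal(d$pmf, dperm$pmf, tolerance = 1e-12)
  }
})

test_that("Blaker p-values satisfy the construction's basic identities", {
  # at the mode of a symmetric pmf the p-value is 1
  d <- null_intersection_distribution(20, c(10, 10))
  expect_equal(blaker_two_sided_p(d, 5), 1)
  expect_error(blaker_two_sided_p(d, 11), "support")
})

test_that("perfectly correlated columns give fold enrichment N over n", {
  N <- 200; n <- 40
  sets <- c(rep(list(c("E412", "E415")), n), rep(list(character(0)), N - n))
  prods <- products_from_sets(sets, group = "Sauces, Dressings & Other Dinner Condiments")
  res <- enrichment_scan(prods, B = 0, prevalence_min = 0.01,
                         expected_min = 1)
  expect_equal(nrow(res), 1)
  expect_equal(res$observed, n)
  expect_equal(res$expected, n^2 / N)
  expect_equal(res$fold_enrichment, N / n)
  expect_lt(res$p_two_sided, 1e-10)
})

test_that("enrichment scan honours the prevalence and expected-count filters", {
  set.seed(5)
  N <- 600
  sets <- lapply(1:N, function(i) {
    s <- character(0)
    if (runif(1) < 0.30) s <- c(s, "E412")
    if (runif(1) < 0.30) s <- c(s, "E415")
    if (runif(1) < 0.004) s <- c(s, "E499")  # below 1% prevalence
    if (runif(1) < 0.05) s <- c(s, "E440")   # pair expected < 10 with E499
    s
  })
  prods <- products_from_sets(sets, group = "Beverages")
  res <- enrichment_scan(prods, B = 0)
  combos <- strsplit(res$combo, "&", fixed = TRUE)
  expect_false(any(vapply(combos, function(x) "E499" %in% x, logical(1))))
  expect_true(all(res$expected >= 10))
  expect_true(all(res$p_two_sided >= 0 & res$p_two_sided <= 1))
  # q-values are a monotone BH adjustment of p within the group
  expect_equal(res$q_bh, p.adjust(res$p_two_sided, "BH"))
})

test_that("bootstrap interval collapses when the combination is ubiquitous", {
  rows <- matrix(1L, nrow = 120, ncol = 2, dimnames = list(NULL, c("A", "B")))
  ci <- bootstrap_ci_logfe(rows, c("A", "B"), B = 200, seed = 1)
  expect_equal(ci$ci_lo, ci$ci_hi)
  expect_equal(ci$ci_lo, 0)  # log FE of a constant, saturated combination
  expect_equal(ci$n_degenerate, 0)
})

test_that("bootstrap interval contains the point estimate and flags degeneracy", {
  set.seed(9)
  rows <- cbind(A = rbinom(400, 1, 0.4), B = rbinom(400, 1, 0.4))
  N <- nrow(rows)
  obs <- sum(rowSums(rows) == 2)
  logfe <- log(obs / (N * prod(colSums(rows) / N)))
  ci <- bootstrap_ci_logfe(rows, c("A", "B"), B = 500, seed = 2)
  expect_lte(ci$ci_lo, logfe)
  expect_gte(ci$ci_hi, logfe)

  sparse <- cbind(A = c(1L, rep(0L, 99)), B = c(1L, rep(0L, 99)))
  ci2 <- bootstrap_ci_logfe(sparse, c("A", "B"), B = 200, seed = 3)
  expect_gt(ci2$n_degenerate, 0)
  expect_error(bootstrap_ci_logfe(rows, c("A", "B"), B = 10), "at least 100")
})
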