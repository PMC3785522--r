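test_that("Fisher exact reproduces the published cohort p-values", {
  expect_equal(round(fisher_exact(matrix(c(12, 0, 2, 3), 2,
                                         byrow = TRUE))$p_value, 4), 0.0147)
  expect_equal(round(fisher_exact(matrix(c(8, 4, 0, 5), 2,
                                         byrow = TRUE))$p_value, 4), 0.0294)
  expect_equal(round(fisher_exact(matrix(c(7, 2, 1, 7), 2,
                                         byrow = TRUE))$p_value, 3), 0.015)
  expect_equal(round(fisher_exact(matrix(c(7, 1, 1, 3), 2,
                                         byrow = TRUE))$p_value, 3), 0.067)
  expect_equal(round(fisher_exact(matrix(c(3, 5, 0, 9), 2,
                                         byrow = TRUE))$p_value, 3), 0.082)
  expect_equal(fisher_exact(matrix(1, 2, 2))$p_value, 1)
})

test_that("Fisher equals the enumeration oracle on every table, total <= 25", {
  mism <- 0L
  checked <- 0L
  for (n in 1:25) {
    for (a in 0:n) for (b in 0:(n - a)) for (c in 0:(n - a - b)) {
      d <- n - a - b - c
      m <- matrix(c(a, b, c, d), 2, byrow = TRUE)
      checked <- checked + 1L
      if (abs(fisher_exact(m)$p_value - min(fisher_oracle(m), 1)) > 1e-9) {
        mism <- mism + 1L
      }
    }
  }
  expect_gt(checked, 20000)
  expect_equal(mism, 0L)
})

test_that("Fisher agrees with the base-R reference implementation", {
  set.seed(9)
  for (i in 1:50) {
    m <- matrix(rpois(4, 6), 2)
    if (sum(m) == 0) next
    expect_equal(fisher_exact(m)$p_value, stats::fisher.test(m)$p.value,
                 tolerance = 1e-8)
  }
})

test_that("Fisher p is invariant under transposition and row/column swaps", {
  set.seed(4)
  for (i in 1:30) {
    m <- matrix(rpois(4, 5), 2)
    if (sum(m) == 0) next
    p <- fisher_exact(m)$p_value
    expect_equal(fisher_exact(t(m))$p_value, p)
    expect_equal(fisher_exact(m[2:1, 2:1])$p_value, p)
  }
})

test_that("under the null the Fisher test is conservative at the 5% level", {
  set.seed(1234)
  rejections <- 0L
  reps <- 2000
  for (i in seq_len(reps)) {
    f1 <- runif(17) < 0.5
    f2 <- runif(17) < 0.5
    m <- matrix(c(sum(f1 & f2), sum(f1 & !f2), sum(!f1 & f2),
                  sum(!f1 & !f2)), 2, byrow = TRUE)
    if (fisher_exact(m)$p_value <= 0.05) rejections <- rejections + 1L
  }
  expect_lte(rejections / reps, 0.05)
})

test_that("odds ratio handles zero cells by sentinel values", {
  expect_equal(odds_ratio(matrix(c(2, 1, 1, 2), 2, byrow = TRUE)), 4)
  expect_equal(odds_ratio(matrix(1, 2, 2)), 1)
  expect_identical(odds_ratio(matrix(c(3, 0, 1, 4), 2, byrow = TRUE)), Inf)
  expect_true(is.nan(odds_ratio(matrix(c(0, 0, 0, 3), 2, byrow = TRUE))))
})

test_that("degenerate tables are rejected", {
  expect_error(fisher_exact(matrix(0, 2, 2)), "all-zero")
  expect_error(fisher_exact(matrix(c(1, -1, 1, 1), 2)), "non-negative")
  expect_error(fisher_exact(matrix(1, 3, 3)), "2x2")
})

test_that("Mann-Whitney exact enumeration matches hand-computed cases", {
  sep <- mann_whitney_u(c(1, 2, 3), c(10, 11, 12))
  expect_equal(sep$U, 0)
  expect_equal(sep$p_value, 0.1)  # 2 / choose(6, 3)
  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
})

test_that("normal approximation tracks exact enumeration at n = 6 + 6", {
  set.seed(77)
  for (i in 1:10) {
    x <- rnorm(6); y <- rnorm(6, 0.5)
    exact <- mann_whitney_u(x, y)$p_value
    approx <- mann_whitney_u(x, y, exact_limit = 0)$p_value
    expect_lt(abs(exact - approx), 0.02)
  }
})

test_that("Mann-Whitney agrees with the base-R reference on tied data", {
  set.seed(31)
  x <- sample(1:5, 20, replace = TRUE)
  y <- sample(2:6, 25, replace = TRUE)
  ours <- mann_whitney_u(x, y)
  ref <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE))
  expect_equal(ours$U, unname(ref$statistic))
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-8)
})

test_that("empty samples are rejected", {
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("Bonferroni and BH adjustments match hand-executed step-up", {
  expect_equal(adjust_pvalues(c(0.01, 0.02), "bonferroni"), c(0.02, 0.04))
  expect_equal(adjust_pvalues(c(0.01, 0.04, 0.03), "bh"),
               c(0.03, 0.04, 0.04))
  expect_equal(adjust_pvalues(0.2, "bonferroni"), 0.2)
  expect_equal(adjust_pvalues(0.2, "bh"), 0.2)
})

test_that("adjustments match the base-R reference and stay in range", {
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(1:12, 1))
    expect_equal(adjust_pvalues(p, "bonferroni"),
                 stats::p.adjust(p, "bonferroni"))
    expect_equal(adjust_pvalues(p, "bh"), stats::p.adjust(p, "BH"))
  }
  expect_error(adjust_pvalues(c(0.5, 1.2), "bh"), "0, 1")
})

test_that("BH output is monotone in sorted order and never below raw minimum", {
  set.seed(15)
  p <- runif(20)
  adj <- adjust_pvalues(p, "bh")
  o <- order(p)
  expect_true(all(diff(adj[o]) >= -1e-12))
  expect_true(all(adj >= p - 1e-12))
  expect_true(all(adj <= 1))
})

test_that("factor-pair association wrapper builds the right tables", {
  factors <- tibble::tibble(codel = c(rep(TRUE, 12), rep(FALSE, 5)),
                            idh1 = c(rep(TRUE, 12), TRUE, TRUE, FALSE,
                                     FALSE, FALSE))
  res <- associate_factors(factors, "codel:idh1")
  expect_equal(c(res$a, res$b, res$c, res$d), c(12, 0, 2, 3))
  expect_equal(round(res$p_value, 4), 0.0147)
  expect_error(associate_factors(factors, "codel:missing"), "missing")
})
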