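test_that("fisher_exact reproduces the glial-ablation comparison and degenerate cases", {
  # 1/8 mock-ablated vs 2/18 non-ablated re-entry
  expect_gte(fisher_exact(matrix(c(1, 7, 2, 16), 2, byrow = TRUE))$p_value,
             0.9999)
  # degenerate margin
  expect_equal(fisher_exact(c(0, 5, 0, 9))$p_value, 1)
  # matches the enumeration oracle
  expect_equal(fisher_exact(c(8, 2, 1, 9))$p_value,
               oracle_fisher_p(8, 2, 1, 9))
  expect_error(fisher_exact(c(-1, 2, 3, 4)), "non-negative")
  expect_error(fisher_exact(c(1, 2, 3)), "2x2")
})

test_that("fisher_exact agrees with stats::fisher.test on random tables", {
  set.seed(17)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 8), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact(tab)$p_value,
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
  # row swap leaves the two-sided p unchanged
  tab <- matrix(c(9, 18, 2, 16), 2, byrow = TRUE)
  expect_equal(fisher_exact(tab)$p_value,
               fisher_exact(tab[2:1, ])$p_value)
})

test_that("rank_tests dispatches Mann-Whitney / Kruskal-Wallis", {
  expect_warning(r <- rank_tests(list(rep(1, 5), rep(1, 6))), "identical")
  expect_equal(r$p_value, 1)
  # complete separation: U = 0 for the smaller-valued group listed second
  r <- rank_tests(list(11:20, 1:10))
  expect_equal(unname(r$statistic), 100) # W = n1*n2 when group1 all larger
  r <- rank_tests(list(1:10, 11:20))
  expect_equal(unname(r$statistic), 0)
  # H equals a first-principles mid-rank computation on small inputs
  set.seed(3)
  for (i in 1:20) {
    groups <- lapply(1:3, function(k) sample(1:8, sample(3:8, 1),
                                             replace = TRUE))
    r <- rank_tests(groups, force_kruskal = TRUE)
    expect_equal(unname(r$statistic), oracle_kruskal_h(groups),
                 tolerance = 1e-12)
  }
})

test_that("variance_tests computes Welch and Brown-Forsythe ANOVA", {
  set.seed(4)
  g <- list(rnorm(10), rnorm(12, 1), rnorm(8, 2, 2))
  v <- variance_tests(g)
  # Welch matches stats::oneway.test(var.equal = FALSE)
  ow <- stats::oneway.test(y ~ grp, data.frame(
    y = unlist(g), grp = factor(rep(1:3, lengths(g)))), var.equal = FALSE)
  expect_equal(v$welch$statistic, unname(ow$statistic), tolerance = 1e-12)
  expect_equal(v$welch$p_value, ow$p.value, tolerance = 1e-12)
  # two equal-n groups: Brown-Forsythe F* reduces to Welch t^2
  g2 <- list(rnorm(9), rnorm(9, 0.5))
  v2 <- variance_tests(g2)
  tt <- stats::t.test(g2[[1]], g2[[2]]) # Welch t
  expect_equal(v2$brown_forsythe$statistic, unname(tt$statistic)^2,
               tolerance = 1e-12)
  expect_equal(v2$welch$statistic, unname(tt$statistic)^2,
               tolerance = 1e-12)
  # identical groups: p = 1
  vi <- variance_tests(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(vi$welch$p_value, 1)
  # zero-variance group flagged but handled
  vz <- variance_tests(list(rep(2, 5), rnorm(5)))
  expect_true(vz$brown_forsythe$zero_variance_group)
  expect_true(is.finite(vz$brown_forsythe$statistic))
  expect_error(variance_tests(list(1, c(1, 2))), "two values")
})

test_that("paired_t and chisq_test behave per the closed forms", {
  x <- c(1, 2, 3, 4)
  r <- paired_t(x, x)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_error(paired_t(1, 2), "at least 2")
  # symmetric 2x2: chi-squared 0
  r <- chisq_test(matrix(c(5, 5, 5, 5), 2))
  expect_equal(unname(r$statistic), 0)
  # closed form N(ad-bc)^2 / (r1 r2 c1 c2) on 2x2
  a <- 12; b <- 5; cc <- 7; d <- 20
  r <- chisq_test(matrix(c(a, b, cc, d), 2, byrow = TRUE))
  n <- a + b + cc + d
  expect_equal(unname(r$statistic),
               n * (a * d - b * cc)^2 /
                 ((a + b) * (cc + d) * (a + cc) * (b + d)),
               tolerance = 1e-12)
  expect_error(chisq_test(matrix(c(0, 0, 1, 2), 2, byrow = FALSE)),
               "margin")
})

test_that("p-values live in [0,1] and swapping rows is sound across tests", {
  set.seed(6)
  for (i in 1:20) {
    g <- list(rnorm(6), rnorm(7))
    p <- rank_tests(g)$p_value
    expect_gte(p, 0); expect_lte(p, 1)
    expect_equal(p, rank_tests(rev(g))$p_value, tolerance = 1e-9)
  }
})
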