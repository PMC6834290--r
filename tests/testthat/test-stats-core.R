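test_that("fisher_exact_or reports the cross-product OR and exact p", {
  r <- fisher_exact_or(5, 5, 5, 5)
  expect_equal(unname(r$statistic), 1)
  expect_equal(r$p_value, 1)

  r <- fisher_exact_or(20, 80, 10, 90)
  expect_equal(unname(r$statistic), (20 * 90) / (80 * 10))
  expect_equal(r$p_value,
               oracle_fisher_two_sided(matrix(c(20, 10, 80, 90), 2, 2)),
               tolerance = 1e-8)

  # degenerate products
  expect_true(is.infinite(fisher_exact_or(3, 0, 0, 5)$statistic))
  expect_true(is.nan(fisher_exact_or(0, 2, 0, 3)$statistic))
  expect_error(fisher_exact_or(-1, 2, 3, 4), "non-negative")
})

test_that("fisher p matches the enumeration oracle on random small tables", {
  set.seed(42)
  for (i in 1:25) {
    m <- matrix(rpois(4, 4), 2, 2)
    if (sum(m) == 0 || sum(m) > 30) next
    expect_equal(fisher_exact_or(m)$p_value, oracle_fisher_two_sided(m),
                 tolerance = 1e-7, label = paste(m, collapse = ","))
  }
})

test_that("fisher OR is invariant to double swaps and inverts on single swaps", {
  m <- matrix(c(7, 3, 2, 9), 2, 2)
  or <- unname(fisher_exact_or(m)$statistic)
  expect_equal(unname(fisher_exact_or(m[2:1, 2:1])$statistic), or)
  expect_equal(unname(fisher_exact_or(m[2:1, ])$statistic), 1 / or)
  expect_equal(unname(fisher_exact_or(m[, 2:1])$statistic), 1 / or)
})

test_that("bh_fdr matches the hand and brute-force step-up", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(7)
  for (i in 1:10) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_fdr(p), oracle_bh(p))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("bh_fdr is monotone along sorted p-values", {
  set.seed(11)
  p <- runif(50)
  q <- bh_fdr(p)
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
  expect_true(all(q >= p - 1e-12))
})

test_that("two_sample_t reproduces hand pooled-variance computations", {
  r <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p_value, 1)

  r <- two_sample_t(c(1, 1, 2), c(5, 6, 7))
  expect_equal(unname(r$statistic), -7, tolerance = 1e-12)
  expect_equal(r$df, 4)
  expect_equal(r$mean_diff, -14 / 3)
  # two-sided p equals 2 * (1 - F_t(|t|))
  expect_equal(r$p_value, 2 * (1 - pt(7, 4)), tolerance = 1e-12)

  # degenerate zero-variance branches
  d <- two_sample_t(c(2, 2), c(2, 2))
  expect_equal(unname(d$statistic), 0); expect_equal(d$p_value, 1)
  d <- two_sample_t(c(2, 2), c(3, 3))
  expect_equal(d$p_value, 0); expect_true(d$degenerate)
})

test_that("mann_whitney_u handles exact, tied and approximate branches", {
  r <- mann_whitney_u(1, 1)
  expect_equal(unname(r$statistic), 0.5)
  expect_equal(r$p_value, 1)

  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p_value, 0.1)
  expect_equal(r$p_value, oracle_mw_exact(c(1, 2, 3), c(4, 5, 6)))

  x <- c(3, 1, 4, 1, 5)
  expect_equal(mann_whitney_u(x, x)$p_value, 1)

  set.seed(3)
  for (i in 1:10) {
    x <- sample(100, sample(3:6, 1)); y <- sample(200, sample(3:6, 1)) + 0.5
    expect_equal(mann_whitney_u(x, y)$p_value, oracle_mw_exact(x, y),
                 tolerance = 1e-9)
  }
})

test_that("chi_squared_test matches the sum((o-e)^2/e) oracle", {
  r <- chi_squared_test(matrix(c(10, 20, 30, 60), 2, 2))  # proportional rows
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p_value, 1)

  r <- chi_squared_test(matrix(c(10, 20, 20, 10), 2, 2))
  expect_equal(unname(r$statistic), 20 / 3, tolerance = 1e-9)
  expect_equal(r$df, 1)

  set.seed(5)
  for (i in 1:10) {
    tab <- matrix(rpois(6, 8) + 1, 2, 3)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(unname(chi_squared_test(tab)$statistic),
                 sum((tab - e)^2 / e), tolerance = 1e-9)
  }
  expect_error(chi_squared_test(matrix(c(0, 0, 3, 4), 2, 2)), "margin")
})

test_that("multinomial logit LRT equals the contingency G-statistic", {
  r0 <- multinomial_logit_lrt(
    data.frame(y = rep(c("a", "b", "c"), 5), x = rnorm(15)),
    "y", "x", "x")
  expect_equal(unname(r0$statistic), 0)
  expect_equal(r0$p_value, 1)

  # binary feature, outcome counts [[8,1,1],[2,4,4]] vs intercept-only
  d <- data.frame(
    y = c(rep(c("n", "s", "b"), c(8, 1, 1)), rep(c("n", "s", "b"), c(2, 4, 4))),
    x = rep(c(0, 1), each = 10))
  r <- multinomial_logit_lrt(d, "y", "x")
  g <- 2 * sum(mapply(function(nn, pc, pm) if (nn > 0) nn * log(pc / pm) else 0,
                      c(8, 1, 1, 2, 4, 4),
                      c(.8, .1, .1, .2, .4, .4),
                      c(.5, .25, .25, .5, .25, .25)))
  expect_equal(unname(r$statistic), g, tolerance = 0.01)
  expect_equal(r$df, 2)
  expect_error(multinomial_logit_lrt(d, "y", "x", "zz"), "nested")
})

test_that("LRT detects each feature when all three are informative", {
  set.seed(21)
  n <- 600
  d <- data.frame(n_paralogs = rpois(n, 2),
                  identity = runif(n, 20, 100),
                  wgd = rbinom(n, 1, 0.5))
  lp_s <- 0.4 * d$n_paralogs + 0.02 * d$identity + 0.8 * d$wgd - 1.5
  lp_b <- -0.5 * d$n_paralogs - 0.03 * d$identity - 0.9 * d$wgd + 1.0
  pr <- cbind(1, exp(lp_s), exp(lp_b))
  pr <- pr / rowSums(pr)
  d$category <- apply(pr, 1, function(p)
    sample(c("never", "sometimes", "broadly"), 1, prob = p))
  full <- c("n_paralogs", "identity", "wgd")
  for (f in full) {
    r <- multinomial_logit_lrt(d, "category", full, f)
    expect_lt(r$p_value, 0.05)
  }
})

test_that("complex_enrichment applies the hypergeometric tail with custom background", {
  cpx <- data.frame(complex_id = rep(c("C1", "C2"), c(5, 4)),
                    gene = c(paste0("g", 1:5), paste0("g", 11:14)))
  bg <- paste0("g", 1:20)

  r <- complex_enrichment(bg, bg, cpx)
  expect_true(all(r$p == 1))

  r <- complex_enrichment(paste0("g", 1:5), bg, cpx)
  row <- r[r$complex_id == "C1", ]
  expect_equal(row$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(row$p, oracle_hyper_upper(5, 5, 20, 5), tolerance = 1e-12)
  expect_error(complex_enrichment("zzz", bg, cpx), "subset")
})

test_that("stat tests are invariant to input order", {
  set.seed(9)
  x <- rnorm(15); y <- rnorm(12)
  expect_equal(two_sample_t(x, y)$p_value,
               two_sample_t(sample(x), sample(y))$p_value)
  expect_equal(mann_whitney_u(x, y)$p_value,
               mann_whitney_u(sample(x), sample(y))$p_value)
  p <- runif(20)
  o <- sample(20)
  expect_equal(bh_fdr(p)[o], bh_fdr(p[o]))
})
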