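test_that("asymptotic p-values reproduce the reference values at T=0 and T=5 with N=11", {
  # eleven paired differences, all one sign -> T = 0
  x <- c(57.1, 47.4, 74.1, 50, 62.5, 80, 33.3, 66.7, 55, 45, 71.4)
  t0 <- wilcoxon_paired(x, rep(0, 11))
  expect_equal(t0$statistic, 0)
  expect_equal(t0$n, 11)
  expect_equal(round(t0$p_value, 3), 0.003)

  # distinct magnitudes with the rank-5 difference negative -> T = 5
  d <- c(1, 2, 3, 4, -5, 6, 7, 8, 9, 10, 11)
  t5 <- wilcoxon_paired(d, rep(0, 11))
  expect_equal(t5$statistic, 5)
  expect_equal(round(t5$p_value, 3), 0.013)
})

test_that("degenerate inputs raise explicit errors", {
  expect_error(wilcoxon_paired(c(1, 2, 3), c(1, 2, 3)), "all differences are zero")
  expect_error(wilcoxon_one_sample(rep(50, 5), mu = 50), "all differences are zero")
  expect_error(wilcoxon_paired(1:3, 1:4), "equal length")
  expect_error(wilcoxon_paired(1, 2), "at least two")
})

test_that("exact p-values match closed forms in the worked cases", {
  # symmetric sample around mu: rank sums balance, p = 1
  sym <- wilcoxon_one_sample(c(48, 49, 51, 52), mu = 50, approximation = "exact")
  expect_equal(sym$statistic, sym$n * (sym$n + 1) / 4)
  expect_equal(sym$p_value, 1)
  # all six observations above mu: the most extreme of 2^6 tables
  shifted <- wilcoxon_one_sample(c(51, 53, 55, 57, 59, 61), mu = 50,
                                 approximation = "exact")
  expect_equal(shifted$p_value, 2 / 2^6)
})

test_that("exact p equals brute-force sign enumeration on random instances", {
  withr::with_seed(42, {
    for (rep in 1:40) {
      n <- sample(3:10, 1)
      d <- round(rnorm(n, sd = 3), sample(0:1, 1))  # ties likely at 0 d.p.
      d <- d[d != 0]
      if (length(d) < 3) next
      got <- wilcoxon_signed_rank(d, mu = 0, approximation = "exact")
      expect_equal(got$p_value, oracle_exact_wilcoxon_p(d), info = paste("rep", rep))
    }
  })
})

test_that("asymptotic p agrees with the standard library implementation without continuity correction", {
  withr::with_seed(99, {
    for (rep in 1:20) {
      n <- sample(6:15, 1)
      x <- rnorm(n); y <- rnorm(n)
      got <- wilcoxon_paired(x, y)
      ref <- suppressWarnings(
        stats::wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = FALSE)
      )
      expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
    }
  })
})

test_that("exact and asymptotic p-values converge as n grows", {
  # Without continuity correction the dominant asymptotic error is the
  # half-lattice step: ~ 2 * dnorm(z) * 0.5 / sigma <= 0.4 / sigma, i.e.
  # about 0.028 at n = 15 (sigma = sqrt(310)). Check that bound and that
  # the discrepancy shrinks with n.
  gap <- function(n, seeds) {
    vapply(seeds, function(s) {
      withr::with_seed(s, {
        d <- rnorm(n)
        ex <- wilcoxon_signed_rank(d, mu = 0, approximation = "exact")
        as <- wilcoxon_signed_rank(d, mu = 0, approximation = "asymptotic")
        abs(ex$p_value - as$p_value)
      })
    }, 0)
  }
  g15 <- gap(15, 1:25)
  g6 <- gap(6, 1:25)
  expect_lt(max(g15), 0.4 / sqrt(15 * 16 * 31 / 24) + 0.01)
  expect_lt(mean(g15), mean(g6))
})

test_that("one-sample test at mu = 0 on differences equals the paired test", {
  withr::with_seed(5, {
    x <- rnorm(9); y <- rnorm(9)
    a <- wilcoxon_paired(x, y)
    b <- wilcoxon_one_sample(x - y, mu = 0)
    expect_equal(a$statistic, b$statistic)
    expect_equal(a$p_value, b$p_value)
  })
})

test_that("T always lies in [0, n(n+1)/2] and p in [0, 1]", {
  withr::with_seed(31, {
    for (rep in 1:30) {
      n <- sample(2:12, 1)
      d <- rnorm(n)
      for (ap in c("asymptotic", "exact")) {
        t <- wilcoxon_signed_rank(d, mu = 0, approximation = ap)
        expect_gte(t$statistic, 0)
        expect_lte(t$statistic, t$n * (t$n + 1) / 2)
        expect_gte(t$p_value, 0)
        expect_lte(t$p_value, 1)
      }
    }
  })
})

test_that("quartile descriptions follow the linear-interpolation convention", {
  d <- describe_quartiles(c(10, 20, 30, 40))
  expect_equal(d$median, 25)
  expect_equal(d$q25, 17.5)
  expect_equal(d$q75, 32.5)
  z <- describe_quartiles(c(0, 0, 0))
  expect_equal(unlist(z[c("median", "q25", "q75")]), c(0, 0, 0),
               ignore_attr = TRUE)
  one <- describe_quartiles(7)
  expect_equal(one$median, 7)
  expect_equal(one$q25, 7)
  expect_equal(one$q75, 7)
})
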