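test_that("G statistic reproduces the published assay values at 1 decimal", {
  expect_equal(round(g_test(c(29, 1))$statistic, 1), 32.8)
  expect_equal(round(g_test(c(24, 0))$statistic, 1), 33.3)
  expect_equal(round(g_test(c(11, 20))$statistic, 1), 2.7)
  expect_equal(round(g_test(c(17, 8))$statistic, 1), 3.3)
  # (25, 0): full precision is 2 * 25 * ln 2 = 34.657, printed truncated
  expect_equal(g_test(c(25, 0))$statistic, 50 * log(2))
  expect_equal(floor(10 * g_test(c(25, 0))$statistic) / 10, 34.6)
})

test_that("exact fits give G = 0 and p = 1", {
  r <- g_test(c(15, 15))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_equal(mendelian_ratio_test(30, 10, c(3, 1))$statistic, 0)
  expect_equal(mendelian_ratio_test(24, 24)$statistic, 0)
})

test_that("Pearson statistic matches hand calculation", {
  expect_equal(pearson_test(c(29, 1))$statistic, (14^2 + 14^2) / 15)
  expect_equal(pearson_test(c(17, 8))$statistic, 3.24)
  expect_equal(pearson_test(c(10, 10))$statistic, 0)
})

test_that("first-backcross distortion: 36 vs 3 against 1:1", {
  # independent recomputation of the likelihood-ratio and Pearson statistics
  g <- mendelian_ratio_test(36, 3)
  expect_equal(round(g$statistic, 1), 32.9)
  p <- mendelian_ratio_test(36, 3, method = "pearson")
  expect_equal(round(p$statistic, 1), round((16.5^2 * 2) / 19.5, 1))
  expect_lt(g$p_value, 0.001)
})

test_that("G is invariant to rescaling expected proportions", {
  a <- g_test(c(13, 29), c(0.5, 0.5))
  b <- g_test(c(13, 29), c(5, 5))
  expect_equal(a$statistic, b$statistic)
  d <- g_test(c(13, 29, 8), c(1, 2, 1))
  e <- g_test(c(13, 29, 8), c(0.25, 0.5, 0.25))
  expect_equal(d$statistic, e$statistic)
  expect_equal(d$df, 2L)
})

test_that("G and Pearson agree asymptotically near the null", {
  o <- c(1010, 990)
  g <- g_test(o)$statistic
  x2 <- pearson_test(o)$statistic
  expect_lt(abs(g - x2) / x2, 0.01)
})

test_that("degenerate inputs are rejected", {
  expect_error(g_test(c(0, 0)), "all observed")
  expect_error(g_test(c(-1, 5)), "negative")
})

test_that("zero expected proportion with positive count is rejected", {
  expect_error(g_test(c(5, 5), c(1, 0)), "expected proportion 0")
  expect_error(pearson_test(c(5, 5), c(1, 0)), "expected proportion 0")
  expect_error(g_test(5), "length")
})

test_that("Hardy-Weinberg proportions follow p^2 : 2pq : q^2 and male hemizygosity", {
  expect_equal(unname(hwe_expected_props(0.5)), c(0.25, 0.5, 0.25))
  expect_equal(unname(hwe_expected_props(1)), c(1, 0, 0))
  expect_equal(unname(hwe_expected_props(0.2)), c(0.04, 0.32, 0.64))
  expect_equal(unname(hwe_expected_props(0.2, x_linked = TRUE, sex = "male")),
               c(0.2, 0.8))
  expect_error(hwe_expected_props(1.2), "\\[0, 1\\]")
})

test_that("summarize_assay reproduces per-replicate and pooled statistics", {
  tab <- read_mating_table(system.file("extdata", "rb_mating_assays.tsv",
                                       package = "islandswap"))
  res <- summarize_assay(tab)
  row <- function(rep, chooser) {
    res[res$replicate == rep & res$chooser == chooser, ]
  }
  expect_equal(round(row("1", "MM")$statistic, 1), 32.8)
  expect_equal(round(row("both", "MM")$statistic, 1), 64.9)
  expect_equal(row("both", "MM")$pct_assortative, 100 * 53 / 54)
  expect_equal(round(row("both", "SS")$statistic, 1), 69.3)
  expect_equal(row("both", "SS")$pct_assortative, 100)
  expect_equal(round(row("both", "M")$statistic, 1), 1.1)
  expect_equal(round(row("both", "S")$statistic, 2), 0.26)
  one <- summarize_assay(tibble::tibble(replicate = 1, chooser = "MM",
                                        offered = "M S", n_assortative = 1,
                                        n_disassortative = 1))
  expect_true(all(one$statistic == 0))
})

test_that("type-I error of the G-test matches its exact size under the null", {
  # exact size at n = 30 by enumeration over the binomial pmf
  n <- 30
  ks <- 0:n
  gs <- vapply(ks, function(k) g_test(c(k, n - k))$statistic, numeric(1))
  reject <- gs >= qchisq(0.95, 1)
  exact_size <- sum(dbinom(ks[reject], n, 0.5))
  set.seed(61)
  nsim <- 2000
  hits <- vapply(seq_len(nsim), function(i) {
    a <- simulate_mating_assay(n, 0.5)
    g_test(c(a$n_assortative, a$n_disassortative))$p_value < 0.05
  }, logical(1))
  mc_se <- sqrt(exact_size * (1 - exact_size) / nsim)
  expect_lt(abs(mean(hits) - exact_size), 3 * mc_se)
  # the exact size is close to (and below) the nominal 5% level
  expect_lte(exact_size, 0.05)
  expect_gt(exact_size, 0.02)
})

test_that("power increases with distance from the null preference", {
  n <- 30
  ks <- 0:n
  gs <- vapply(ks, function(k) g_test(c(k, n - k))$statistic, numeric(1))
  reject <- gs >= qchisq(0.95, 1)
  power <- vapply(c(0.5, 0.6, 0.7, 0.8, 0.9, 1.0), function(pref) {
    sum(dbinom(ks[reject], n, pref))
  }, numeric(1))
  expect_true(all(diff(power) >= 0))
  expect_gt(power[length(power)], 0.99)
})

test_that("tidy and glance return one-row summaries", {
  r <- g_test(c(29, 1))
  td <- tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("statistic", "df", "p.value", "method"))
  gl <- glance(r)
  expect_equal(gl$n, 30)
  expect_equal(gl$k, 2)
})
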