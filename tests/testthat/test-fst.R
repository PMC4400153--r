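test_that("heterozygosity follows 1 - sum(p_i^2)", {
  expect_equal(heterozygosity(c(1, 0)), 0)
  expect_equal(heterozygosity(c(0.5, 0.5)), 0.5)
  expect_equal(heterozygosity(c(0.8, 0.2)), 0.32)
  expect_equal(heterozygosity(0.2), 0.32)  # single alt-frequency form
  expect_equal(heterozygosity(c(0.1, 0.9, 0.5)), c(0.18, 0.18, 0.5))
})

test_that("pairwise FST hits the analytic reference points", {
  expect_equal(pairwise_fst(1, 0), 1)        # fixed difference
  expect_equal(pairwise_fst(0.3, 0.3), 0)    # identical pools
  expect_equal(pairwise_fst(0.9, 0.1), 0.64)
  # Hs = 0.18, Ht = 0.5 by hand
})

test_that("FST is symmetric and NA where total heterozygosity is zero", {
  set.seed(71)
  a <- runif(50); b <- runif(50)
  expect_equal(pairwise_fst(a, b), pairwise_fst(b, a))
  expect_true(is.na(pairwise_fst(0, 0)))
  expect_true(is.na(pairwise_fst(1, 1)))
  expect_error(pairwise_fst(0.5, 0.5, list()), "non-empty")
  expect_error(pairwise_fst(1.2, 0.5), "\\[0, 1\\]")
})

test_that("FST = 1 exactly iff the pools are reciprocally fixed", {
  set.seed(72)
  a <- runif(100); b <- runif(100)
  f <- pairwise_fst(a, b)
  at_one <- which(!is.na(f) & abs(f - 1) < 1e-12)
  expect_true(all((a[at_one] %in% c(0, 1)) & (b[at_one] == 1 - a[at_one])))
  expect_true(all(f[!is.na(f)] <= 1 + 1e-12))
  # adding an intermediate reference pool never pushes FST above 1
  f3 <- pairwise_fst(1, 0, list(1, 0, 0.5))
  expect_lte(f3, 1)
})

test_that("negative FST is reported unless clamped", {
  # Hs > Ht: heterozygous pools against skewed reference pools
  f <- pairwise_fst(0.5, 0.5, list(0.9, 0.9))
  expect_lt(f, 0)
  expect_equal(pairwise_fst(0.5, 0.5, list(0.9, 0.9), clamp = TRUE), 0)
})

test_that("smoothing preserves constants and plateau levels", {
  xs <- seq(1e5, 5e6, by = 1e4)
  const <- tibble::tibble(chrom = "X", pos = xs, raw_fst = 0.7)
  sm <- smooth_track(const)
  expect_true(all(abs(sm$smoothed_fst - 0.7) < 1e-6))
  # step 0 -> 1 at 2.5 Mb: plateau centres stay within 0.05 of their level
  step <- tibble::tibble(chrom = "X", pos = xs,
                         raw_fst = ifelse(xs < 2.5e6, 0, 1))
  sm2 <- smooth_track(step, stiffness = 1e-6)
  expect_lt(abs(sm2$smoothed_fst[sm2$pos == 1e6] - 0), 0.05)
  expect_lt(abs(sm2$smoothed_fst[sm2$pos == 4e6] - 1), 0.05)
})

test_that("infinite stiffness tends to the least-squares line", {
  set.seed(73)
  xs <- seq(1e5, 5e6, by = 5e4)
  ys <- 0.2 + 0.5 * (xs / 5e6) + rnorm(length(xs), 0, 0.05)
  tr <- tibble::tibble(chrom = "X", pos = xs, raw_fst = ys)
  sm <- smooth_track(tr, stiffness = 1e6)
  line <- unname(predict(lm(ys ~ xs), data.frame(xs = xs)))
  expect_lt(max(abs(sm$smoothed_fst - line)), 0.01)
})

test_that("too few sites fall back to raw values with a warning", {
  tr <- tibble::tibble(chrom = "X", pos = c(1, 2, 3) * 1e5, raw_fst = c(0, 1, 0))
  expect_warning(sm <- smooth_track(tr), "< 4 sites")
  expect_equal(sm$smoothed_fst, sm$raw_fst)
})

test_that("segment caller: empty, planted, and two-region cases", {
  xs <- seq(1e4, 5e6, by = 1e4)
  below <- tibble::tibble(chrom = "X", pos = xs, raw_fst = 0.1,
                          smoothed_fst = 0.1)
  expect_equal(nrow(call_segments(below)), 0)

  # two high regions separated by more than max_gap
  sm <- ifelse((xs >= 1e6 & xs <= 1.8e6) | (xs >= 3e6 & xs <= 4e6), 0.95, 0.05)
  two <- tibble::tibble(chrom = "X", pos = xs, raw_fst = sm, smoothed_fst = sm)
  segs <- call_segments(two, threshold = 0.8, max_gap = 1e5, min_span = 2e5)
  expect_equal(nrow(segs), 2)
  expect_equal(segs$start, c(1e6, 3e6))
  expect_equal(segs$end, c(1.8e6, 4e6))
  # short segments are dropped; near runs are merged
  segs2 <- call_segments(two, threshold = 0.8, max_gap = 2e6, min_span = 2e5)
  expect_equal(nrow(segs2), 1)
})

test_that("segment calling is idempotent and order-invariant", {
  set.seed(74)
  xs <- seq(1e4, 5e6, by = 1e4)
  sm <- ifelse(xs >= 2e6 & xs <= 3e6, 0.9 + rnorm(length(xs), 0, 0.01), 0.1)
  tr <- tibble::tibble(chrom = "X", pos = xs, raw_fst = sm, smoothed_fst = sm)
  a <- call_segments(tr)
  b <- call_segments(tr[sample.int(nrow(tr)), ])
  expect_equal(a, b)
  expect_true(all(a$start < a$end))
})

test_that("fst_scan filters on depth and joins pools by name", {
  tab <- tiny_pool_table()
  tab$pos <- c(100, 2000, 500)
  suppressWarnings(track <- fst_scan(tab, "a", "b", min_depth = 10))
  expect_s3_class(track, "fst_track")
  expect_equal(track$raw_fst[track$chrom == "X" & track$pos == 100], 1)
  expect_equal(track$raw_fst[track$chrom == "X" & track$pos == 2000], 0)
  suppressWarnings(deep <- fst_scan(tab, "a", "b", min_depth = 120))
  expect_equal(nrow(deep[deep$chrom == "X", ]), 2)  # 2L pool depths < 120 dropped
  expect_error(fst_scan(tab, "a", "zzz"), "not found")
})
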