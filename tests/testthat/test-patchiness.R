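test_that("patch extraction reproduces the worked presence sequences", {
  expect_equal(patch_sizes(worked_seq), c(1L, 3L, 2L))
  # the missing value bridges the two presence runs into one patch of 3
  expect_equal(patch_sizes(clean_presence(worked_seq_missing)), 3L)
  expect_equal(patch_sizes(c(1, 1)), 2L)           # trailing run counts
  expect_equal(patch_sizes(c(0, 0, 0)), integer(0))
})

test_that("sequence cleaning deletes missing values in order", {
  expect_equal(clean_presence(c(0, 1, NA, 1, 1, 0)), c(0L, 1L, 1L, 1L, 0L))
  expect_equal(clean_presence(c(1, 0, 1)), c(1L, 0L, 1L))
  expect_equal(clean_presence(c(NA, 1)), 1L)
  expect_error(clean_presence(c(NA, NA)), "no usable segments")
  expect_error(clean_presence(c(0, 2)), "0, 1 or missing")
})

test_that("presence literals parse and format round-trip", {
  expect_equal(parse_presence("10011100110"), as.integer(worked_seq))
  expect_equal(parse_presence("01*110"), as.integer(worked_seq_missing))
  expect_equal(parse_presence("01.110"), as.integer(worked_seq_missing))
  expect_equal(format_presence(worked_seq_missing), "01.110")
  expect_error(parse_presence("10x1"), "unrecognized")
})

test_that("mean patch size is the arithmetic mean and errors when empty", {
  expect_equal(mean_patch_size(c(1, 3, 2)), 2)
  expect_equal(mean_patch_size(3), 3)
  expect_equal(mean_patch_size(c(5, 5)), 5)
  expect_error(mean_patch_size(integer(0)), "no presence")
})

test_that("patch sizes conserve counts across random sequences", {
  set.seed(101)
  for (rep in 1:50) {
    n <- sample(2:60, 1)
    x <- rbinom(n, 1, runif(1, 0.1, 0.9))
    sizes <- patch_sizes(x)
    expect_equal(sum(sizes), sum(x))
    starts <- sum(x == 1 & c(0, head(x, -1)) == 0)
    expect_equal(length(sizes), starts)
    expect_equal(sizes, ref_patch_sizes(x))
  }
})

test_that("exact enumeration matches the hand-derived and reference oracles", {
  e1 <- exact_null(c(1, 1, 0))
  expect_equal(e1$p_r, 5 / 3)
  expect_equal(e1$n_arrangements, 3)

  e2 <- exact_null(c(1, 0, 1, 0))
  expect_equal(e2$p_r, 1.5)
  expect_equal(e2$p_value, 0.5)

  e3 <- exact_null(c(1, 0))
  expect_equal(e3$p_r, 1)
  expect_equal(e3$p_value, 0)

  # second, structurally different enumeration oracle over random sequences
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(3:9, 1)
    x <- rbinom(n, 1, 0.5)
    while (sum(x) %in% c(0, n)) x <- rbinom(n, 1, 0.5)
    ref <- ref_exact_null(x)
    got <- exact_null(x)
    expect_equal(got$p_r, ref$p_r)
    expect_equal(got$p_value, ref$p_value)
    expect_equal(got$n_arrangements, ref$n_arrangements)
  }
  expect_error(exact_null(c(1, 1)), "degenerate")
  expect_error(exact_null(rep(c(1, 0), 15), cap = 10), "cap")
})

test_that("randomized null converges to the exact null", {
  x <- c(1, 1, 0, 0, 1, 0, 1, 1, 1, 0)
  exact <- exact_null(x)$p_r
  est <- randomized_null(x, n_randomizations = 10000, seed = 11)$p_r
  expect_lt(abs(est - exact), 0.05)
  expect_error(randomized_null(c(1, 1, 1)), "degenerate")
})

test_that("the K statistic matches its derived values on tiny sequences", {
  k1 <- k_statistic(c(1, 1, 0), exact = TRUE)
  expect_equal(k1$p_o, 2)
  expect_equal(k1$p_r, 5 / 3)
  expect_equal(k1$k, 1.2)

  k2 <- k_statistic(c(1, 0, 1, 0), exact = TRUE)
  expect_equal(k2$k, 1 / 1.5) # regular spacing: K < 1
  expect_equal(k2$p_value, 0.5)

  expect_error(k_statistic(c(1, 1, 1)), "no zeros")
  expect_error(k_statistic(c(0, 0)), "no reef presence")
})

test_that("K is near 1 for a long i.i.d. Bernoulli sequence", {
  set.seed(21)
  x <- rbinom(3000, 1, 0.4)
  k <- k_statistic(x, n_randomizations = 500, seed = 22, keep_null = FALSE)
  expect_lt(abs(k$k - 1), 0.1)
})

test_that("results are reproducible under a seed and leave the RNG alone", {
  x <- rbinom(100, 1, 0.4)
  a <- k_statistic(x, n_randomizations = 200, seed = 5)
  b <- k_statistic(x, n_randomizations = 200, seed = 5)
  expect_identical(a$null_means, b$null_means)
  expect_identical(a$p_value, b$p_value)

  set.seed(99)
  before <- runif(3)
  set.seed(99)
  invisible(k_statistic(x, n_randomizations = 50, seed = 5))
  expect_identical(runif(3), before)
})

test_that("permuting a sequence leaves the null distribution unchanged", {
  set.seed(33)
  x <- rbinom(40, 1, 0.3)
  y <- sample(x)
  a <- randomized_null(x, n_randomizations = 300, seed = 8)
  b <- randomized_null(y, n_randomizations = 300, seed = 8)
  # same multiset of 1s and 0s, same seed: identical nulls
  expect_identical(a$null_means, b$null_means)
})

test_that("tie handling: plain, Manly-corrected and mid-p variants agree", {
  x <- c(1, 0, 1, 0)
  plain <- k_statistic(x, exact = TRUE)
  corrected <- k_statistic(x, exact = TRUE, tie_corrected = TRUE)
  # 6 arrangements: 3 strictly greater, 3 ties (means equal to p_o = 1)
  expect_equal(plain$n_ties, 3)
  expect_equal(plain$p_value, 3 / 6)
  expect_equal(corrected$p_value, (3 + 3 + 1) / (6 + 1))
  expect_equal(plain$p_value_mid, (3 + 1.5) / 6)
})

test_that("tidy and glance give the broom-shaped views", {
  k <- k_statistic(worked_seq, n_randomizations = 100, seed = 2)
  td <- tidy(k)
  expect_equal(td$size, c(1L, 3L, 2L))
  gl <- glance(k)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$p_o, 2)
  expect_equal(gl$n_patches, 3)
  expect_equal(gl$n_ones, 6)
})

test_that("autoplot builds a null-distribution plot", {
  k <- k_statistic(worked_seq, n_randomizations = 100, seed = 2)
  p <- ggplot2::autoplot(k)
  expect_s3_class(p, "ggplot")
  built <- ggplot2::ggplot_build(p)
  expect_gte(length(built$data), 3)
  k2 <- k_statistic(worked_seq, n_randomizations = 50, seed = 2,
                    keep_null = FALSE)
  expect_error(ggplot2::autoplot(k2), "keep_null")
})
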