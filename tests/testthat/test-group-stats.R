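rand_response <- function(n, p = 3, shift = 0) {
  matrix(rnorm(2 * n * p), 2 * n, p) +
    rep(c(0, shift), each = n)
}

test_that("identical groups give lambda 1, F 0, p 1", {
  set.seed(1)
  rows <- matrix(rnorm(30), 10, 3)
  X <- rbind(rows, rows)  # both groups share the same rows
  g <- rep(c("a", "b"), each = 10)
  r <- wilks_manova(X, g)
  expect_equal(r$wilks_lambda, 1, tolerance = 1e-12)
  expect_equal(r$f_stat, 0, tolerance = 1e-12)
  expect_equal(r$p, 1, tolerance = 1e-12)
})

test_that("wilks manova matches the established implementation", {
  set.seed(2)
  for (i in 1:10) {
    X <- rand_response(10, shift = runif(1, 0, 1))
    g <- factor(rep(c("a", "b"), each = 10))
    ours <- wilks_manova(X, g)
    ref <- summary(manova(X ~ g), test = "Wilks")$stats
    expect_equal(ours$wilks_lambda, unname(ref[1, "Wilks"]), tolerance = 1e-8)
    expect_equal(ours$f_stat, unname(ref[1, "approx F"]), tolerance = 1e-8)
    expect_equal(ours$p, unname(ref[1, "Pr(>F)"]), tolerance = 1e-8)
  }
})

test_that("manova guards invalid designs", {
  X <- matrix(rnorm(12), 4, 3)
  expect_error(wilks_manova(X, rep("a", 4)), class = "purkinje_invalid")
  expect_error(wilks_manova(X, c("a", "a", "b", "b")),
               class = "purkinje_invalid")  # n per group <= p
})

test_that("lambda-to-p conversion reproduces the exact two-group F identity", {
  r <- manova_p_from_lambda(0.9028, 94, 3)
  expect_equal(r$f_stat, ((1 - 0.9028) / 0.9028) * (90 / 3), tolerance = 1e-12)
  expect_equal(r$df1, 3)
  expect_equal(r$df2, 90)
})

test_that("rank-sum z matches hand computation and handles ties", {
  r <- wilcoxon_ranksum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$w, 6)
  expect_equal(r$z, (6 - 10.5) / sqrt(5.25), tolerance = 1e-12)
  expect_equal(r$p, 2 * pnorm(-abs(r$z)), tolerance = 1e-12)

  # identical multisets: symmetric
  r2 <- wilcoxon_ranksum(c(1, 2, 2, 3), c(3, 2, 1, 2))
  expect_equal(r2$z, 0)
  expect_equal(r2$p, 1)

  # all values tied across both samples
  r3 <- wilcoxon_ranksum(c(5, 5), c(5, 5, 5))
  expect_equal(r3$z, 0)
  expect_equal(r3$p, 1)
})

test_that("rank-sum p matches the established normal approximation", {
  set.seed(3)
  for (i in 1:20) {
    x <- rnorm(24); y <- rnorm(24, 0.3)
    if (i %% 2 == 0) { x <- round(x); y <- round(y) }  # force ties
    ours <- wilcoxon_ranksum(x, y)
    ref <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-8)
    # sign convention: positive z when the first sample tends larger
    expect_equal(sign(ours$z),
                 sign(mean(rank(c(x, y))[1:24]) - (24 + 24 + 1) / 2))
  }
})

test_that("Benjamini-Hochberg step-up matches hand and brute-force results", {
  r <- benjamini_hochberg(c(0.01, 0.03, 0.04), fdr = 0.2)
  expect_equal(r$critical, c(1, 2, 3) / 3 * 0.2, tolerance = 1e-12)
  expect_true(all(r$rejected))

  expect_false(any(benjamini_hochberg(c(0.9, 0.95), 0.2)$rejected))
  expect_length(benjamini_hochberg(numeric(0))$rejected, 0)

  set.seed(4)
  for (i in 1:50) {
    p <- runif(sample(1:10, 1))
    fdr <- runif(1, 0.05, 0.3)
    expect_identical(benjamini_hochberg(p, fdr)$rejected, brute_bh(p, fdr))
  }
})

test_that("BH rejections grow with fdr and form a prefix of sorted p-values", {
  set.seed(5)
  for (i in 1:20) {
    p <- runif(8)
    r1 <- benjamini_hochberg(p, 0.1)$rejected
    r2 <- benjamini_hochberg(p, 0.25)$rejected
    expect_true(all(r2[r1]))  # monotone in fdr
    o <- order(p)
    k <- sum(r2)
    expect_identical(which(r2[o]), seq_len(k))  # prefix property
  }
})

test_that("median split binarizes at the midpoint median", {
  s <- median_split(c(1, 2, 3, 4))
  expect_equal(as.character(s), c("low", "low", "high", "high"))
  expect_false(attr(s, "degenerate"))
  expect_true(attr(median_split(c(5, 5, 5)), "degenerate"))
  # odd n of distinct values: sizes differ by at most 1... the median value
  # itself goes low, so the imbalance is exactly 1
  set.seed(6)
  v <- sample(100, 9)
  s2 <- median_split(v)
  expect_equal(abs(sum(s2 == "low") - sum(s2 == "high")), 1)
})

test_that("summary t statistics match raw-data t tests", {
  set.seed(7)
  for (i in 1:10) {
    x <- rnorm(6); y <- rnorm(6, 0.5)
    ours <- t_from_summary(mean(x), sd(x) / sqrt(6), 6,
                           mean(y), sd(y) / sqrt(6), 6)
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  }
  # unequal n via the pooled-variance route
  x <- rnorm(5); y <- rnorm(9, 1)
  ours <- t_from_summary(mean(x), sd(x) / sqrt(5), 5,
                         mean(y), sd(y) / sqrt(9), 9)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-10)

  eq <- t_from_summary(3, 0.5, 3, 3, 0.5, 3)
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)
})

test_that("location shifts leave lambda, z and t invariant", {
  set.seed(8)
  X <- rand_response(10, shift = 0.8)
  g <- rep(c("a", "b"), each = 10)
  base <- wilks_manova(X, g)
  shifted <- wilks_manova(X + 100, g)
  expect_equal(shifted$wilks_lambda, base$wilks_lambda, tolerance = 1e-9)

  x <- rnorm(15); y <- rnorm(15, 1)
  expect_equal(wilcoxon_ranksum(x + 7, y + 7)$z, wilcoxon_ranksum(x, y)$z,
               tolerance = 1e-12)
})

test_that("the gated workflow runs the decision tree and skips degenerate predictors", {
  co <- gen_cohort(study_cohort_spec("awake_purkinje",
                                     n_per_group = c(control = 8, mdx = 8),
                                     master_seed = 12))
  m <- cohort_metrics(co)
  m$constant <- 1
  expect_warning(
    rep <- analysis_workflow(m, "ss",
                             predictors = c("genotype", "depth_mm", "constant")),
    "degenerate")
  expect_s3_class(rep, "stat_report")
  expect_true(rep$predictors$constant$skipped)

  gen <- rep$predictors$genotype
  expect_false(gen$skipped)
  # 19% rate effect with within-cell sampling noise only: gate passes
  expect_true(gen$gate_passed)
  expect_equal(gen$pairwise$response, c("rate_hz", "cv", "cv2"))
  expect_true(gen$pairwise$rejected[gen$pairwise$response == "rate_hz"])
  # rejection flag consistent with its BH critical value
  expect_identical(gen$pairwise$rejected,
                   brute_bh(gen$pairwise$p, 0.2))
})

test_that("cells with undefined metrics are dropped listwise and counted", {
  co <- gen_cohort(study_cohort_spec("awake_purkinje",
                                     n_per_group = c(control = 8, mdx = 8),
                                     master_seed = 13))
  m <- cohort_metrics(co)
  m$cv2[m$unit_type == "ss"][1] <- NA
  rep <- analysis_workflow(m, "ss", predictors = "genotype")
  expect_equal(rep$n_dropped, 1)
  expect_equal(rep$n_cells, 15)
})
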