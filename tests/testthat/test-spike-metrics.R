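test_that("firing rate is spikes over the analysed window", {
  expect_equal(firing_rate(spike_train(seq(0.5, 50, 0.5), 50)), 2)
  expect_equal(firing_rate(spike_train(numeric(0), 10)), 0)
  expect_error(firing_rate(c(1, 2), duration_s = 0), class = "purkinje_invalid")
})

test_that("CV and CV2 match hand arithmetic", {
  reg <- spike_train(seq(0.01, 0.1, 0.01), 0.2)
  expect_equal(isi_cv(reg), 0)
  expect_equal(isi_cv2(reg), 0)

  tr <- spike_train(c(0.010, 0.020, 0.050), 0.1)  # ISIs 10, 30 ms
  expect_equal(isi_cv(tr), sqrt(2) / 2, tolerance = 1e-12)  # 14.142/20
  expect_equal(isi_cv2(tr), 1)                              # 2*20/40

  expect_true(is.na(isi_cv(spike_train(c(0.1, 0.2), 1))))
  expect_true(is.na(isi_cv2(spike_train(0.1, 1))))
})

test_that("CV/CV2 equal a loop-based oracle on random small trains", {
  set.seed(7)
  for (i in 1:50) {
    n <- sample(3:20, 1)
    t <- sort(runif(n, 0, 5))
    st <- spike_train(t, 5)
    expect_equal(isi_cv(st), brute_cv(t), tolerance = 1e-12)
    expect_equal(isi_cv2(st), brute_cv2(t), tolerance = 1e-12)
  }
})

test_that("CV2 is bounded in [0, 2] and CV non-negative", {
  set.seed(8)
  for (i in 1:30) {
    t <- sort(runif(sample(3:50, 1), 0, 10))
    st <- spike_train(t, 10)
    expect_gte(isi_cv(st), 0)
    expect_gte(isi_cv2(st), 0)
    expect_lte(isi_cv2(st), 2)
  }
})

test_that("time rescaling leaves CV and CV2 invariant and scales rate", {
  set.seed(9)
  t <- sort(runif(40, 0, 20))
  st <- spike_train(t, 20)
  for (cfac in c(0.1, 2, 17.3)) {
    sc <- rescale_train(st, cfac)
    expect_equal(isi_cv(sc), isi_cv(st), tolerance = 1e-12)
    expect_equal(isi_cv2(sc), isi_cv2(st), tolerance = 1e-12)
    expect_equal(firing_rate(sc), firing_rate(st) / cfac, tolerance = 1e-12)
  }
})

test_that("percent difference mirrors reported effect sizes", {
  expect_equal(percent_difference(85.3, 69.1, digits = 0), 19)
  expect_equal(percent_difference(30.8, 26.8, digits = 0), 13)
  expect_equal(percent_difference(0.92, 0.76, digits = 0), 17)
  expect_equal(percent_difference(5, 5), 0)
  expect_error(percent_difference(0, 1), class = "purkinje_invalid")
})

test_that("per-cell summaries cover each spike type present", {
  co <- gen_cohort(study_cohort_spec("awake_purkinje",
                                     n_per_group = c(control = 1, mdx = 1),
                                     master_seed = 2))
  m <- summarize_cell(co[[1]])
  expect_setequal(m$unit_type, c("ss", "cs"))
  expect_equal(m$rate_hz, m$n_spikes / m$duration_s)

  cn <- gen_cohort(study_cohort_spec("nuclear",
                                     n_per_group = c(control = 1, mdx = 1),
                                     master_seed = 2))
  m2 <- summarize_cell(cn[[1]])
  expect_equal(m2$unit_type, "cn")
})

test_that("excluding complex-spike-spanning ISIs changes only the ss rows", {
  co <- gen_cohort(study_cohort_spec("awake_purkinje",
                                     n_per_group = c(control = 1, mdx = 1),
                                     master_seed = 4))
  lit <- summarize_cell(co[[1]], exclude_cs_spanning = FALSE)
  exc <- summarize_cell(co[[1]], exclude_cs_spanning = TRUE)
  expect_equal(lit[lit$unit_type == "cs", ], exc[exc$unit_type == "cs", ])
  # exclusion removes the long pause-spanning ISIs, so CV decreases
  expect_lt(exc$cv[exc$unit_type == "ss"], lit$cv[lit$unit_type == "ss"])
})

test_that("group summaries report mean, sem and n", {
  m <- data.frame(genotype = c("a", "a", "b"), unit_type = "ss",
                  rate_hz = c(2, 4, 3), cv = c(0.5, 0.5, NA),
                  cv2 = c(0.4, 0.6, 0.5))
  s <- cohort_summary(m)
  a <- s[s$genotype == "a", ]
  expect_equal(a$rate_hz_mean, 3)
  expect_equal(a$rate_hz_sem, 1)
  expect_equal(a$rate_hz_n, 2)
  b <- s[s$genotype == "b", ]
  expect_true(is.na(b$rate_hz_sem))  # single cell: sem undefined
  expect_equal(b$cv_missing, 1)
})

test_that("simulated cohort group means recover the generator spec", {
  co <- gen_cohort(study_cohort_spec("awake_purkinje",
                                     n_per_group = c(control = 12, mdx = 12),
                                     master_seed = 6))
  s <- cohort_summary(cohort_metrics(co))
  ctrl <- s[s$genotype == "control" & s$unit_type == "ss", ]
  expect_lt(abs(ctrl$rate_hz_mean - 85.3), 2 * ctrl$rate_hz_sem + 0.15)
})
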