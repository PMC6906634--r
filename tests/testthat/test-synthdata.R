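test_that("renewal generator validates its specification", {
  expect_error(process_spec(-1, 0.5), class = "purkinje_invalid")
  expect_error(process_spec(10, 0.5, duration_s = 0), class = "purkinje_invalid")
  expect_error(process_spec(10, 0.5, target_cv2 = 2.5), class = "purkinje_invalid")
  expect_error(process_spec(10, 0, target_cv2 = 0.5), class = "purkinje_infeasible")
})

test_that("degenerate and regular limits of the renewal generator", {
  st <- gen_renewal_train(process_spec(1, 0.5, duration_s = 0.01, seed = 1))
  expect_lte(length(st), 1)

  st <- gen_renewal_train(process_spec(50, 0, duration_s = 100, seed = 1))
  expect_equal(unique(round(isis(st), 9)), 0.02)
  expect_lt(isi_cv(st), 0.01)
})

test_that("renewal trains are strictly increasing, in-window, and calibrated", {
  for (seed in 1:5) {
    spec <- process_spec(30 + 10 * seed, 0.3 + 0.15 * seed, duration_s = 50,
                         seed = seed)
    st <- gen_renewal_train(spec)
    expect_true(all(diff(st) > 0))
    expect_true(all(st >= 0 & st <= spec$duration_s))
  }
  # long-run statistical calibration
  spec <- process_spec(30, 0.6, duration_s = 5000, seed = 99)
  st <- gen_renewal_train(spec)
  expect_lt(abs(firing_rate(st) - 30) / 30, 0.01)
  expect_lt(abs(isi_cv(st) - 0.6), 0.02)
})

test_that("exponential ISIs give CV near 1", {
  st <- gen_renewal_train(process_spec(30, 1, duration_s = 10000, seed = 7))
  expect_gte(isi_cv(st), 0.98)
  expect_lte(isi_cv(st), 1.02)
})

test_that("cv2-calibrated generator hits its targets", {
  # regularity forces CV2 = 0
  st <- gen_cv2_train(process_spec(40, 0, target_cv2 = 0, duration_s = 100,
                                   seed = 1))
  expect_lt(isi_cv2(st), 0.01)

  # iid exponential ISIs have E[CV2] = 1
  st <- gen_cv2_train(process_spec(40, 1, target_cv2 = 1, duration_s = 10000,
                                   seed = 2))
  expect_gte(isi_cv2(st), 0.97)
  expect_lte(isi_cv2(st), 1.03)

  # persistence regime: CV2 below the plain-renewal value at fixed CV
  st <- gen_cv2_train(process_spec(40, 0.6, target_cv2 = 0.46,
                                   duration_s = 5000, seed = 3))
  expect_gte(isi_cv2(st), 0.43)
  expect_lte(isi_cv2(st), 0.49)
  expect_lt(abs(isi_cv(st) - 0.6), 0.1)
  expect_lt(abs(firing_rate(st) - 40) / 40, 0.01)
})

test_that("infeasible cv/cv2 pairs raise an informative error", {
  err <- tryCatch(gen_cv2_train(process_spec(40, 0.3, target_cv2 = 1.5,
                                             duration_s = 10, seed = 1)),
                  error = identity)
  expect_s3_class(err, "purkinje_infeasible")
  expect_match(conditionMessage(err), "achievable")
})

test_that("complex-spike pause deletes exactly the in-window simple spikes", {
  ss <- spike_train(c(0.010, 0.025, 0.050), 0.1)
  cs <- spike_train(0.020, 0.1)
  expect_equal(as.numeric(apply_cs_pause(ss, cs, 20)), c(0.010, 0.050))
  # empty complex train passes through
  expect_equal(as.numeric(apply_cs_pause(ss, spike_train(numeric(0), 0.1), 20)),
               as.numeric(ss))
  # boundary: a spike exactly at t_cs is kept, one at t_cs + pause is removed
  ss2 <- spike_train(c(0.020, 0.040), 0.1)
  expect_equal(as.numeric(apply_cs_pause(ss2, cs, 20)), 0.020)

  # brute-force conservation on random trains
  set.seed(42)
  for (i in 1:20) {
    ss <- spike_train(sort(runif(30, 0, 10)), 10)
    cs <- spike_train(sort(runif(5, 0, 10)), 10)
    out <- apply_cs_pause(ss, cs, 20)
    inside <- vapply(as.numeric(ss), function(t)
      any(t > as.numeric(cs) & t <= as.numeric(cs) + 0.02), logical(1))
    expect_equal(length(out), length(ss) - sum(inside))
    expect_equal(as.numeric(out), as.numeric(ss)[!inside])
  }
})

test_that("pause deletion rate matches the analytic expectation", {
  ss <- gen_renewal_train(process_spec(80, 1, duration_s = 1000, seed = 5))
  cs <- gen_renewal_train(process_spec(1, 1, duration_s = 1000, seed = 6))
  removed <- length(ss) - length(apply_cs_pause(ss, cs, 20))
  # Poisson SS falling in ~1 Hz x 20 ms pause windows: ~2% of events
  expected <- length(ss) * (1 - exp(-1 * 0.02))
  expect_lt(abs(removed - expected) / expected, 0.25)
})

test_that("cohorts are deterministic and group-calibrated", {
  spec <- study_cohort_spec("awake_purkinje",
                            n_per_group = c(control = 2, mdx = 2),
                            master_seed = 11)
  co1 <- gen_cohort(spec)
  co2 <- gen_cohort(spec)
  expect_identical(co1, co2)
  expect_equal(length(co1), 4)
  expect_gt(length(unique(vapply(co1, `[[`, numeric(1), "seed"))), 1)

  # mdx multiplier 0.81 on the 85.3 Hz control spec gives the 69.1 Hz target
  mdx_cell <- co1[[3]]
  expect_equal(mdx_cell$genotype, "mdx")
  expect_equal(mdx_cell$spec$ss$mean_rate, 85.3 * 0.81, tolerance = 1e-12)
  expect_equal(round(mdx_cell$spec$ss$mean_rate, 1), 69.1)
  # complex-spike CV effect
  expect_equal(mdx_cell$spec$cs$target_cv, 0.92 * 0.83, tolerance = 1e-12)
})

test_that("purkinje cells honour the pause by construction", {
  co <- gen_cohort(study_cohort_spec("awake_purkinje",
                                     n_per_group = c(control = 2, mdx = 2),
                                     master_seed = 3))
  for (cell in co) {
    frac <- verify_cs_pause(cell$trains$ss, cell$trains$cs, 20)
    expect_equal(frac, 1.0)
  }
})

test_that("synthetic traces place templates at ground truth", {
  # no spikes, no noise -> all zeros
  tr <- synth_trace(list(ss = spike_train(numeric(0), 0.05)),
                    noise_sd_uv = 0)
  expect_true(all(as.numeric(tr) == 0))

  # one noiseless simple spike: filtered trough within 0.2 ms of truth
  tr <- synth_trace(list(ss = spike_train(1.0, 2)), noise_sd_uv = 0)
  t_min <- (which.min(as.numeric(tr)) - 1) / sampling_rate(tr)
  expect_lt(abs(t_min - 1.0), 2e-4)
})
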