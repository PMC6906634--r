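make_purkinje_trace <- function(duration_s = 20, noise_sd = 12.5, seed = 10,
                                ss_rate = 60, cs_rate = 1) {
  spec <- purkinje_spec(process_spec(ss_rate, 0.5, duration_s = duration_s),
                        process_spec(cs_rate, 0.9, duration_s = duration_s))
  cs <- gen_renewal_train(spec$cs, seed = seed)
  ss <- apply_cs_pause(gen_renewal_train(spec$ss, seed = seed + 1), cs, 20)
  synth_trace(list(ss = ss, cs = cs), amplitude_uv = 100,
              noise_sd_uv = noise_sd, seed = seed + 2)
}

test_that("degenerate traces yield no events", {
  z <- voltage_trace(numeric(2500), 25000)
  expect_length(detect_events(z), 0)
  short <- voltage_trace(numeric(10), 25000)
  expect_warning(ev <- detect_events(short), "shorter")
  expect_length(ev, 0)
})

test_that("a noiseless template is detected at its ground-truth time", {
  tr <- synth_trace(list(ss = spike_train(0.5, 1)), noise_sd_uv = 0)
  ev <- detect_events(tr)
  expect_length(ev, 1)
  expect_lt(abs(as.numeric(ev) - 0.5), 2e-4)
})

test_that("waveform extraction windows and edge handling", {
  tr <- make_purkinje_trace(duration_s = 5, noise_sd = 10, seed = 3)
  ev <- detect_events(tr)
  wf <- extract_waveforms(tr, ev, c(1, 3))
  expect_equal(ncol(wf), 100)  # (1 + 3) ms at 25 kHz
  expect_equal(nrow(wf) + attr(wf, "n_dropped"), length(ev))

  # an event too close to the start is dropped and counted
  wf2 <- extract_waveforms(tr, c(2e-5, ev[ev > 0.01][1]), c(1, 3))
  expect_equal(attr(wf2, "n_dropped"), 1L)
  expect_equal(nrow(wf2), 1)

  # empty times -> empty matrix
  wf3 <- extract_waveforms(tr, numeric(0))
  expect_equal(nrow(wf3), 0)

  # repeated identical noiseless template -> identical rows
  tr4 <- synth_trace(list(ss = spike_train(c(0.3, 0.6, 0.9), 1.2)),
                     noise_sd_uv = 0)
  wf4 <- extract_waveforms(tr4, c(0.3, 0.6, 0.9), c(1, 3))
  expect_lt(max(abs(sweep(wf4, 2, wf4[1, ]))), 1e-6)
})

test_that("simple-only recordings raise the no-complex flag", {
  spec <- process_spec(40, 0.5, duration_s = 10)
  tr <- synth_trace(list(cn = gen_renewal_train(spec, seed = 4)),
                    noise_sd_uv = 12.5, seed = 5)
  srt <- sort_spikes(tr)
  expect_true(srt$no_complex)
  expect_length(srt$cs, 0)
})

test_that("sorting recovers ground truth on a synthetic Purkinje trace", {
  tr <- make_purkinje_trace(duration_s = 20, noise_sd = 12.5, seed = 21)
  gt <- attr(tr, "ground_truth")
  srt <- sort_spikes(tr)
  expect_false(srt$no_complex)

  m_ss <- match_events(as.numeric(srt$ss), as.numeric(gt$ss))
  m_cs <- match_events(as.numeric(srt$cs), as.numeric(gt$cs))
  expect_gte(m_ss$recall, 0.99)
  expect_gte(m_ss$precision, 0.99)
  expect_gte(m_cs$recall, 0.9)
  expect_gte(m_cs$precision, 0.9)
  # ss/cs disjoint
  expect_length(intersect(round(as.numeric(srt$ss), 6),
                          round(as.numeric(srt$cs), 6)), 0)
})

test_that("recall is monotone non-increasing along a noise ladder", {
  recalls <- vapply(c(10, 25, 45, 70), function(nsd) {
    tr <- make_purkinje_trace(duration_s = 8, noise_sd = nsd, seed = 33)
    gt <- attr(tr, "ground_truth")
    ev <- detect_events(tr)
    match_events(as.numeric(ev), sort(c(as.numeric(gt$ss), as.numeric(gt$cs))))$recall
  }, numeric(1))
  # same noise seed: higher noise_sd scales the same realisation
  expect_true(all(diff(recalls) <= 1e-3))
})

test_that("pause verification counts gaps correctly", {
  expect_equal(verify_cs_pause(0.050, 0.020), 1.0)
  expect_equal(verify_cs_pause(0.025, 0.020), 0.0)
  expect_warning(frac <- verify_cs_pause(c(0.1, 0.2), numeric(0)), "undefined")
  expect_true(is.na(frac))
})
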