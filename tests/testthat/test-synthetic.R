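test_that("resting recording has the requested duration, rate and layout", {
  lay <- meg_grid_layout(4)
  rec <- generate_resting(lay, subject_params(seed = 1), duration_s = 60,
                          rate = 500)
  expect_s3_class(rec, "recording")
  expect_identical(ncol(rec$samples), 30000L + 0L)  # 60 s at 500 Hz
  expect_identical(nrow(rec$samples), 4L)
  expect_identical(rec$state, "rest")
  expect_error(generate_resting(lay, subject_params(), duration_s = -1),
               "positive")
})

test_that("zero amplitudes and zero noise give an all-zero signal", {
  lay <- meg_grid_layout(3)
  p <- subject_params(band_amp = zero_band_amp(), noise_scale = 0, seed = 1)
  rec <- generate_resting(lay, p, duration_s = 2, rate = 100)
  expect_true(all(rec$samples == 0))
})

test_that("a dominant alpha component dominates Welch alpha-band power", {
  lay <- channel_layout("occ", 0, -0.8)
  amp <- zero_band_amp()
  amp$alpha[[1]]$amp <- 5
  rec <- generate_resting(lay, subject_params(band_amp = amp,
                                              noise_scale = 0.2, seed = 2),
                          duration_s = 30, rate = 250)
  psd <- power_spectrum(rec)
  bands <- default_bands()
  bp <- vapply(seq_len(nrow(bands)), function(b)
    band_power(psd, bands$low_hz[b], bands$high_hz[b])[1], numeric(1))
  names(bp) <- bands$name
  expect_true(all(bp["alpha"] > bp[c("theta", "beta", "gamma")]))
})

test_that("generator is bit-reproducible for a fixed seed", {
  lay <- meg_grid_layout(4)
  p <- subject_params(erd_depth = 0.3, seed = 9)
  r1 <- generate_resting(lay, p, duration_s = 3, rate = 100)
  r2 <- generate_resting(lay, p, duration_s = 3, rate = 100)
  expect_identical(r1$samples, r2$samples)
  s1 <- generate_mi_session(lay, p, session_plan(1, 2), rate = 100)
  s2 <- generate_mi_session(lay, p, session_plan(1, 2), rate = 100)
  expect_identical(s1$recording$samples, s2$recording$samples)
  expect_identical(s1$events, s2$events)
})

test_that("MI session timeline matches the trial design", {
  lay <- meg_grid_layout(6)
  rate <- 100
  ses <- generate_mi_session(lay, subject_params(seed = 5), session_plan(),
                             rate = rate)
  ev <- ses$events
  expect_equal(nrow(ev), 120)                     # 3 runs x 40 trials
  counts <- table(ev$label, ev$run_id)
  expect_true(all(counts == 20))                  # 20 per class per run
  # consecutive cue onsets are separated by 7 s fixed phases + 0-2 s jitter
  gaps <- diff(ev$onset_sample) / rate - 7
  expect_true(all(gaps >= 0 - 1e-9 & gaps <= 2 + 1e-9))
  # at least the 2 s preparation precedes the first cue
  expect_gte(ev$onset_sample[1], 2 * rate)

  tiny <- generate_mi_session(lay, subject_params(seed = 5),
                              session_plan(1, 1), rate = rate)
  expect_equal(nrow(tiny$events), 2)
})

test_that("erd_depth = 0.5 halves contralateral 8-30 Hz variance during MI", {
  lay <- meg_grid_layout(24)
  rate <- 250
  p <- subject_params(erd_depth = 0.5, seed = 21)
  ses <- generate_mi_session(lay, p, session_plan(2, 15), rate = rate)
  rec <- bandpass(ses$recording, 8, 30)
  zones <- scalp_zones(lay)
  mi <- epoch(rec, ses$events, 0.3, 2.9)    # inside the ERD plateau
  prep <- epoch(rec, ses$events, -1.9, -0.1)
  band_var <- function(ep, trials, chans) {
    v <- vapply(trials, function(i) {
      m <- matrix(ep$data[i, chans, , drop = FALSE], nrow = length(chans))
      mean(apply(m, 1, stats::var))
    }, numeric(1))
    mean(v)
  }
  for (side in list(list(cls = "left", zone = zones$sm_right),
                    list(cls = "right", zone = zones$sm_left))) {
    tr <- which(ses$events$label == side$cls)
    ratio <- band_var(mi, tr, side$zone) / band_var(prep, tr, side$zone)
    expect_lt(abs(ratio - 0.5), 0.08)
  }
})

test_that("with erd_depth = 0 the class labels carry no signal", {
  lay <- meg_grid_layout(24)
  ses <- generate_mi_session(lay, subject_params(erd_depth = 0, seed = 3),
                             session_plan(1, 15), rate = 100)
  rec <- bandpass(ses$recording, 8, 30)
  mi <- epoch(rec, ses$events, 0.3, 2.9)
  zones <- scalp_zones(lay)
  v <- vapply(seq_len(n_trials(mi)), function(i) {
    m <- matrix(mi$data[i, zones$sm_right, , drop = FALSE],
                nrow = length(zones$sm_right))
    mean(apply(m, 1, stats::var))
  }, numeric(1))
  # contralateral sensorimotor variance does not differ between classes
  p <- t.test(v[mi$labels == "left"], v[mi$labels == "right"])$p.value
  expect_gt(p, 0.01)
})

test_that("cohort ground truth embeds the configured gamma couplings", {
  expect_error(cohort_config(n_subjects = 2), "n_subjects")

  cfg0 <- cohort_config(n_subjects = 12, link_slope = 0, link_noise_sd = 0,
                        layout = meg_grid_layout(6), seed = 4)
  tr0 <- draw_cohort_params(cfg0)
  expect_true(all(tr0$prefrontal_gamma_amp == tr0$prefrontal_gamma_amp[1]))

  cfg <- cohort_config(n_subjects = 20, link_slope = 1, link_noise_sd = 0.1,
                       layout = meg_grid_layout(6), seed = 4)
  tr <- draw_cohort_params(cfg)
  expect_equal(nrow(tr), 20)
  expect_gt(cor(tr$erd_depth, tr$prefrontal_gamma_amp), 0)
  expect_lt(cor(tr$erd_depth, tr$occipital_gamma_amp), 0)
  expect_true(all(tr$erd_depth >= 0.1 & tr$erd_depth <= 0.7))
})

test_that("generate_cohort returns one complete tuple per subject", {
  cfg <- cohort_config(n_subjects = 3, layout = meg_grid_layout(6),
                       plan = session_plan(1, 2), rate = 100,
                       rest_duration_s = 5, seed = 8)
  cohort <- generate_cohort(cfg)
  expect_length(cohort, 3)
  for (sub in cohort) {
    expect_s3_class(sub$rest, "recording")
    expect_s3_class(sub$task, "recording")
    expect_equal(nrow(sub$events), 4)
    expect_identical(sub$rest$state, "rest")
    expect_identical(sub$task$state, "task")
  }
  truth <- attr(cohort, "truth")
  expect_equal(cohort[[2]]$erd_depth, truth$erd_depth[2])
})
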