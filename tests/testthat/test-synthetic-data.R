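test_that("identical seeds reproduce identical spike trains and traces", {
  pr <- tonic_profile()
  a <- gen_spike_train(pr, -2, duration = 3, stimulus_onset = 0.6, seed = 11)
  b <- gen_spike_train(pr, -2, duration = 3, stimulus_onset = 0.6, seed = 11)
  c <- gen_spike_train(pr, -2, duration = 3, stimulus_onset = 0.6, seed = 12)
  expect_identical(a$times, b$times)
  expect_false(identical(a$times, c$times))
  tpl <- spike_template(20000)
  va <- gen_voltage_trace(a, tpl, 20000, noise_sd = 5, seed = 3)
  vb <- gen_voltage_trace(a, tpl, 20000, noise_sd = 5, seed = 3)
  expect_identical(va$samples, vb$samples)
})

test_that("spike trains are strictly increasing and respect the refractory period", {
  for (s in 1:20) {
    tr <- gen_spike_train(tonic_profile(evoked = 300), -2, duration = 3,
                          stimulus_onset = 0.6, seed = s)
    expect_true(all(diff(tr$times) > 0))
    expect_true(all(diff(tr$times) >= 0.002 - 1e-12))
    expect_true(all(tr$times >= 0 & tr$times < tr$duration))
  }
})

test_that("zero evoked rate leaves stimulation-window activity at baseline", {
  pr <- tonic_profile(baseline = 30, evoked = 0)
  rates <- vapply(1:400, function(s)
    firing_rate(gen_spike_train(pr, -2, duration = 3, stimulus_onset = 0.6,
                                seed = s), onset = 0.6), numeric(1))
  # baseline subtraction removes the stationary rate; mean ~ 0
  sem <- sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates)), 3 * sem)
})

test_that("realized tonic evoked rate matches the configured rate function", {
  pr <- tonic_profile(baseline = 5, evoked = 200)
  rates <- vapply(1:500, function(s)
    firing_rate(gen_spike_train(pr, -2, duration = 3, stimulus_onset = 0.6,
                                seed = s), onset = 0.6), numeric(1))
  sem <- sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - 200), 3 * sem)
})

test_that("empirical window rates match the rate-function integral (property)", {
  # phasic kernel: expected count in [onset, onset+w] is
  # baseline*w + A*tau*(1-exp(-w/tau))
  pr <- phasic_profile(baseline = 10, evoked = 150, tau = 0.15)
  w <- 0.5
  counts <- vapply(1:500, function(s)
    count_window(gen_spike_train(pr, -2, duration = 3,
                                 stimulus_onset = 0.6, seed = s), 0.6, w),
    numeric(1))
  expected <- 10 * w + 150 * 0.15 * (1 - exp(-w / 0.15))
  sem <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * sem)
})

test_that("invalid generator parameters are rejected", {
  pr <- tonic_profile()
  expect_error(gen_spike_train(pr, -2, duration = -1, stimulus_onset = 0.5),
               class = "ssr_invalid_parameter")
  expect_error(gen_spike_train(pr, -2, duration = 2, stimulus_onset = 0.5),
               class = "ssr_invalid_parameter")
  expect_error(gen_spike_train(tonic_profile(evoked = 600), -2, 3, 0.5),
               class = "ssr_invalid_parameter")
  expect_error(response_profile("Da", "x", baseline_rate = -1),
               class = "ssr_invalid_parameter")
  expect_error(response_profile("Da", "x", kernel = "phasic"),
               class = "ssr_invalid_parameter")
})

test_that("noiseless rendering places exactly one template per spike", {
  fs <- 20000
  tpl <- spike_template(fs, width_ms = 1.5, amplitude = 80)
  tr <- spike_train(c(0.5, 1.0, 2.2), duration = 3,
                    metadata = list(stimulus_onset = 0.6))
  v <- gen_voltage_trace(tr, tpl, fs, noise_sd = 0)
  expect_length(v$samples, 3 * fs)
  peak <- max(abs(tpl$waveform))
  # template extrema occur exactly at the rendered spike locations
  hits <- which(abs(v$samples) == peak)
  expect_length(hits, 3)
  expect_true(all(abs(hits / fs - c(0.5, 1.0, 2.2)) < 1.5e-3))
  # empty train, zero noise -> all-zero trace
  v0 <- gen_voltage_trace(spike_train(numeric(0), 3), tpl, fs, noise_sd = 0)
  expect_true(all(v0$samples == 0))
})

test_that("a 10 s trace at 96 kHz has 960000 samples", {
  tr <- spike_train(c(1.5, 2.0), duration = 10,
                    metadata = list(stimulus_onset = 1))
  tpl <- spike_template(96000)
  v <- gen_voltage_trace(tr, tpl, 96000, noise_sd = 0)
  expect_identical(length(v$samples), 960000L)
})

test_that("overlapping spikes warn but are rendered additively", {
  fs <- 20000
  tpl <- spike_template(fs, width_ms = 1.5)
  tr <- spike_train(c(0.5, 0.5005), duration = 2)
  expect_warning(gen_voltage_trace(tr, tpl, fs, noise_sd = 0),
                 "overlap")
})

test_that("the default response matrix has 624 cells with amine-dominated C", {
  m <- study_matrix()
  expect_identical(length(m$mean), 624L)
  expect_identical(dim(m$mean), c(104L, 6L))
  expect_true(m$replicate_compliant)
  # C column's strongest responders are the amines
  top3 <- names(sort(m$mean[, "C"], decreasing = TRUE))[1:3]
  amines <- m$odorants$odorant[m$odorants$class == "amine"]
  expect_setequal(top3, amines)
  # no carboxylic acid reaches the excitatory criterion on any sensillum
  acids <- m$odorants$class == "carboxylic_acid"
  expect_true(all(apply(m$mean[acids, ], 1, max) < 50))
})

test_that("all-zero archetypes yield only baseline noise around zero", {
  preset <- default_archetypes()
  preset$rules <- preset$rules[0, ]
  panel <- default_odorant_panel()[seq(1, 104, by = 13), ]
  m <- gen_response_matrix(preset, panel, n_replicates = 6, seed = 5)
  # baseline subtraction leaves pure counting noise: the grand mean sits
  # at zero and no cell reaches even the non-responder threshold
  cells <- as.vector(m$mean)
  expect_lt(abs(mean(cells)), 3 * sd(cells) / sqrt(length(cells)))
  expect_true(all(abs(cells) < 15))
})

test_that("matrix generation with the same seed is reproducible and validates n_replicates", {
  panel <- default_odorant_panel()[1:8, ]
  a <- gen_response_matrix(panel = panel, n_replicates = 3, seed = 9)
  b <- gen_response_matrix(panel = panel, n_replicates = 3, seed = 9)
  expect_identical(a$mean, b$mean)
  expect_error(gen_response_matrix(panel = panel, n_replicates = 0),
               class = "ssr_invalid_parameter")
})

test_that("noiseless oocyte peaks lie exactly on the configured Hill curve", {
  ec50 <- 1e-6; hill <- 1.3; emax <- 1000
  doses <- 10^seq(-9, -4)
  traces <- gen_current_trace(ec50, hill, emax, doses, noise_sd = 0)
  amps <- vapply(traces, extract_amplitude, numeric(1))
  expected <- emax / (1 + (ec50 / doses)^hill)
  expect_equal(amps, expected, tolerance = 1e-9)
  # monotonically non-decreasing with dose
  expect_true(all(diff(amps) >= 0))
  # Hill midpoint: dose = ec50 -> emax/2
  mid <- extract_amplitude(gen_current_trace(ec50, hill, emax,
                                             ec50, noise_sd = 0)[[1]])
  expect_equal(mid, emax / 2, tolerance = 1e-12)
  # dose -> 0 gives a vanishing peak
  tiny <- extract_amplitude(gen_current_trace(ec50, hill, emax, 1e-15,
                                              noise_sd = 0)[[1]])
  expect_lt(tiny, 1e-5 * emax)
  expect_error(gen_current_trace(-1, 1, 100, 1e-6),
               class = "ssr_invalid_parameter")
})
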