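test_that("passive membrane behaves as the analytic RC circuit", {
  cell <- passive_cell(capacitance = 100, g_leak = 5, e_leak = -70)
  pr <- step_protocol("current-clamp", steps = -100, step_duration = 300,
                      pre_duration = 50, post_duration = 50, dt = 0.005)
  tr <- simulate_current_clamp(cell, pr)[[1]]
  t <- trace_time(tr)
  # steady deflection -100 pA / 5 nS = -20 mV
  steady <- mean(tr$samples[t > 250 & t < 340])
  expect_equal(steady, -90, tolerance = 1e-4)
  # relaxation time constant C/g = 20 ms: at onset + 20 ms the deflection
  # has covered 1 - 1/e of its span
  v_at_tau <- tr$samples[which.min(abs(t - 70))]
  expect_equal(v_at_tau, -70 - 20 * (1 - exp(-1)), tolerance = 0.01)

  # zero current -> flat at E_leak
  pr0 <- step_protocol("current-clamp", steps = 0, step_duration = 100,
                       pre_duration = 0, post_duration = 0)
  tr0 <- simulate_current_clamp(cell, pr0)[[1]]
  expect_true(all(abs(tr0$samples + 70) < 1e-9))

  # fitted relaxation equals C/g within 1% at dt <= 0.01
  ft <- fit_tau(tr, step_onset = 50)
  expect_equal(ft$tau_m, 20, tolerance = 0.01)
})

test_that("presets fire spontaneously and are bit-reproducible", {
  for (nm in c("RAPN-like", "AId-like")) {
    tr <- simulate_spontaneous(make_preset(nm), 1500, 24)
    n_spk <- nrow(detect_spikes(tr))
    expect_gt(n_spk, 0)
    tr2 <- simulate_spontaneous(make_preset(nm), 1500, 24)
    expect_identical(tr$samples, tr2$samples)
  }
  # noisy simulations reproduce under the same protocol seed
  p <- make_preset("RAPN-like")
  pr <- step_protocol("current-clamp", steps = 100, step_duration = 200,
                      pre_duration = 20, post_duration = 20, seed = 7)
  a <- simulate_current_clamp(p, pr, noise_sd = 5)[[1]]
  b <- simulate_current_clamp(p, pr, noise_sd = 5)[[1]]
  expect_identical(a$samples, b$samples)
})

test_that("voltage-clamp currents sum linearly across conductances", {
  p <- make_preset("RAPN-like")
  pr <- step_protocol("voltage-clamp", baseline = -80, steps = 0,
                      step_duration = 100, pre_duration = 20,
                      post_duration = 20)
  full <- simulate_voltage_clamp(p, pr)[[1]]
  f <- 0.35
  blocked <- p; blocked$kv3$g <- p$kv3$g * (1 - f)
  part <- simulate_voltage_clamp(blocked, pr)[[1]]
  only_kv3 <- p
  only_kv3$nav$g <- 0; only_kv3$kv_low$g <- 0; only_kv3$kv_a$g <- 0
  only_kv3$leak$g <- 1e-12
  kv3_tr <- simulate_voltage_clamp(only_kv3, pr, leak_subtract = TRUE)[[1]]
  expect_equal(full$samples - part$samples, f * kv3_tr$samples,
               tolerance = 1e-10)

  # holding at rest with K+ channels closed: current ~ leak only
  prh <- step_protocol("voltage-clamp", baseline = -80, steps = -80,
                       step_duration = 50, pre_duration = 10,
                       post_duration = 0)
  hold <- simulate_voltage_clamp(p, prh, na_disabled = TRUE)[[1]]
  leak_na <- p$leak$g * (-80 - p$leak$e) / 1000
  expect_equal(hold$samples[length(hold$samples)], leak_na,
               tolerance = 0.02)
})

test_that("a kv_a-dominated current shows an early peak then relaxes", {
  p <- make_preset("RAPN-like")
  p$nav$g <- 0; p$kv3$g <- 0
  p$kv_low$g <- 300; p$kv_a$g <- 2000
  pr <- step_protocol("voltage-clamp", baseline = -80, steps = 0,
                      step_duration = 200, pre_duration = 20,
                      post_duration = 10)
  tr <- simulate_voltage_clamp(p, pr, na_disabled = TRUE,
                               leak_subtract = TRUE)[[1]]
  m <- vclamp_metrics(tr)
  expect_false(is.na(m$a_type_peak))
  expect_gt(m$time_to_peak, 0)
  expect_lt(m$i_sustained, m$a_type_peak)
})

test_that("temperature speeds gating and narrows spikes in both presets", {
  for (nm in c("RAPN-like", "AId-like")) {
    p <- make_preset(nm)
    hw <- vapply(c(24, 40), function(temp) {
      ft <- trace_ap_features(simulate_spontaneous(p, 1500, temp),
                              discard_ms = 300)
      mean(ft$half_width)
    }, numeric(1))
    expect_lt(hw[2], hw[1])
  }
})

test_that("integration blow-up raises a diagnostic error", {
  p <- make_preset("RAPN-like")
  pr <- step_protocol("current-clamp", steps = 1e7, step_duration = 50,
                      pre_duration = 5, post_duration = 5, dt = 0.02)
  expect_error(simulate_current_clamp(p, pr), "dt")
})

test_that("traces round-trip through the delimited-text format", {
  p <- make_preset("AId-like")
  tr <- simulate_spontaneous(p, 50, 24)
  path <- tempfile(fileext = ".txt")
  write_trace(tr, path)
  back <- read_trace(path)
  expect_equal(back$samples, tr$samples, tolerance = 1e-6)
  expect_equal(back$dt, tr$dt)
  expect_equal(back$temperature, 24)

  prv <- step_protocol("voltage-clamp", baseline = -80, steps = 0,
                       step_duration = 30, pre_duration = 5,
                       post_duration = 5)
  cur <- simulate_voltage_clamp(p, prv)[[1]]
  write_trace(cur, path)
  back2 <- read_trace(path)
  expect_s3_class(back2, "current_trace")
  expect_equal(back2$command$test, 0)
  unlink(c(path, paste0(path, ".json")))
})
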