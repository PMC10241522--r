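flat_trace <- function(vals, dt = 0.01, onset = 10, dur = 250) {
  current_trace(vals, dt, command = list(holding = -80, test = 0,
                                         step_onset = onset,
                                         step_duration = dur))
}

test_that("current subtraction is exact and validates protocols", {
  dt <- 0.01
  n <- 30000
  a <- flat_trace(rep(2.0, n))
  b <- flat_trace(rep(1.2, n))
  d <- subtract_currents(a, b)
  expect_true(all(d$samples == 0.8))
  z <- subtract_currents(a, a)
  expect_true(all(z$samples == 0))
  short <- flat_trace(rep(1, n - 1))
  expect_error(subtract_currents(a, short), "mismatch")
  other <- current_trace(rep(1, n), dt,
                         command = list(holding = -80, test = -30,
                                        step_onset = 10,
                                        step_duration = 250))
  expect_error(subtract_currents(a, other), "command")

  # additivity: subtract_currents(a + b, b) returns a exactly
  set.seed(5)
  av <- rnorm(n); bv <- rnorm(n)
  expect_equal(subtract_currents(flat_trace(av + bv),
                               flat_trace(bv))$samples, av,
               tolerance = 1e-12)
})

test_that("metrics reproduce the closed-form transient example", {
  dt <- 0.01
  onset <- 2
  tt <- seq(0, 300, by = dt)
  i <- ifelse(tt < onset, 0.05 * tt / onset,
              2 + exp(-(tt - onset - 2) / 20))
  # linear rise to the peak value 3 over the 2 ms after onset so the
  # maximum (3 nA, 2 ms after onset) is interior to the search window
  rise_idx <- tt >= onset & tt < onset + 2
  i[rise_idx] <- seq(0.05, 3, length.out = sum(rise_idx))
  tr <- current_trace(i, dt, command = list(holding = -80, test = 0,
                                            step_onset = onset,
                                            step_duration = 290))
  m <- vclamp_metrics(tr, inactivation_lag = 8, sustained_time = 200)
  expect_equal(m$time_to_peak, 2, tolerance = 0.02)
  expect_equal(m$a_type_peak, 3, tolerance = 0.001)
  expect_equal(m$inactivation_ratio, (2 + exp(-8 / 20)) / 3,
               tolerance = 1e-3)
  expect_equal(m$i_sustained, 2, tolerance = 0.001)
})

test_that("plateau currents give inactivation ratio 1", {
  dt <- 0.01
  tt <- seq(0, 300, by = dt)
  i <- ifelse(tt < 10, 0, 2 * (1 - exp(-(tt - 10) / 3)))
  tr <- current_trace(i, dt, command = list(holding = -80, test = 0,
                                            step_onset = 10,
                                            step_duration = 280))
  m <- vclamp_metrics(tr)
  expect_true(is.na(m$a_type_peak))
  expect_equal(m$inactivation_ratio, 1)
})

test_that("inactivation ratio of a pure exponential equals exp(-lag/tau)", {
  dt <- 0.002
  for (tau in c(5, 12, 30)) {
    tt <- seq(0, 250, by = dt)
    # linear rise over 1 ms to the peak, then an exact exponential decay
    i <- ifelse(tt < 1, 4 * tt, 4 * exp(-(tt - 1) / tau))
    tr <- current_trace(c(rep(0, 1000), i), dt,
                        command = list(holding = -80, test = 0,
                                       step_onset = 1000 * dt,
                                       step_duration = 249))
    m <- vclamp_metrics(tr, inactivation_lag = 8)
    # peak sits just after onset; decay from the peak is exponential
    expect_equal(m$inactivation_ratio, exp(-8 / tau), tolerance = 5e-4)
  }
})

test_that("simulated block is recovered exactly by subtraction", {
  p <- make_preset("RAPN-like")
  pr <- step_protocol("voltage-clamp", baseline = -80, steps = 0,
                      step_duration = 200, pre_duration = 20,
                      post_duration = 20)
  pre <- simulate_voltage_clamp(p, pr, na_disabled = TRUE)[[1]]
  f <- 0.8
  post <- simulate_voltage_clamp(apply_drug(p, drug_effect(
    block = list(kv3 = f))), pr, na_disabled = TRUE)[[1]]
  only <- p; only$nav$g <- 0; only$kv_low$g <- 0; only$kv_a$g <- 0
  only$leak$g <- 1e-12
  kv3 <- simulate_voltage_clamp(only, pr, leak_subtract = TRUE)[[1]]
  d <- subtract_currents(pre, post)
  expect_equal(d$samples, f * kv3$samples, tolerance = 1e-10)
})

test_that("kv3 raises the sustained current at 0 mV but not at -30 mV", {
  pr <- step_protocol("voltage-clamp", baseline = -80, steps = c(-30, 0),
                      step_duration = 200, pre_duration = 20,
                      post_duration = 20)
  i200 <- sapply(c(0.5, 1, 2), function(f) {
    p <- make_preset("RAPN-like"); p$kv3$g <- p$kv3$g * f
    tr <- simulate_voltage_clamp(p, pr, na_disabled = TRUE,
                                 leak_subtract = TRUE)
    c(at_m30 = vclamp_metrics(tr[["-30"]])$i_sustained,
      at_0 = vclamp_metrics(tr[["0"]])$i_sustained)
  })
  expect_true(all(diff(i200["at_0", ]) > 0))
  # high-threshold: quadrupling kv3 moves the -30 mV current by a sliver of
  # what it adds at 0 mV
  abs_m30 <- i200["at_m30", 3] - i200["at_m30", 1]
  abs_0 <- i200["at_0", 3] - i200["at_0", 1]
  expect_lt(abs_m30 / abs_0, 0.02)
  rel_m30 <- abs_m30 / i200["at_m30", 1]
  rel_0 <- abs_0 / i200["at_0", 1]
  expect_lt(rel_m30, rel_0 / 3)
})
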