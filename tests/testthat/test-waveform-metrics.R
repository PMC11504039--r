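test_that("ensemble averaging is exact on identical cycles and an identity at n = 1", {
  w <- gen_pulse_waveform(waveform_params(n_cycles = 10))
  avg <- ensemble_average(w, 10)
  m <- nrow(avg)
  expect_equal(avg$q_mls, w$q_mls[1:m], tolerance = 1e-12)
  expect_equal(avg$p_ao_mmHg, w$p_ao_mmHg[1:m], tolerance = 1e-12)
  one <- gen_pulse_waveform(waveform_params(n_cycles = 1))
  same <- ensemble_average(one, 1)
  expect_equal(same$q_mls, one$q_mls[1:nrow(same)], tolerance = 1e-12)
  expect_error(ensemble_average(one, 10), class = "valvebench_data_error")
})

test_that("ensemble averaging shrinks i.i.d. sample noise by about sqrt(n)", {
  set.seed(101)
  vals <- replicate(150, {
    w <- gen_pulse_waveform(waveform_params(
      n_cycles = 10, noise_sd_flow = 5, seed = sample.int(1e6, 1)))
    ensemble_average(w, 10)$q_mls[100]
  })
  expect_equal(sd(vals), 5 / sqrt(10), tolerance = 0.15)
})

test_that("forward-flow detection finds the systolic support", {
  w <- gen_pulse_waveform(waveform_params(n_cycles = 1))
  seg <- detect_forward_flow(w)
  len <- diff(seg$forward) + 1
  # independent oracle: contiguous run of samples above the 2% threshold
  expect_equal(len, sum(w$q_mls > 0.02 * max(abs(w$q_mls))), tolerance = 0)
  m <- nrow(w) - 1L
  expect_lt(abs(len - 0.35 * m), 4.5)

  # all-positive constant flow: window is the whole cycle
  const <- as_pf_waveform(
    tibble::tibble(time_s = seq(0, 1, by = 0.01),
                   p_vent_mmHg = 100, p_ao_mmHg = 95, q_mls = 50),
    cycle_period = 1)
  segc <- detect_forward_flow(const)
  expect_equal(segc$forward, c(1L, nrow(const)))

  # no positive flow anywhere is a data error
  neg <- as_pf_waveform(
    tibble::tibble(time_s = seq(0, 1, by = 0.01),
                   p_vent_mmHg = 10, p_ao_mmHg = 95, q_mls = -5),
    cycle_period = 1)
  expect_error(detect_forward_flow(neg), class = "valvebench_data_error")
})

test_that("pressure drop is the mean differential over forward flow", {
  t <- seq(0, 1, by = 0.001)
  # constant 8 mmHg differential while flowing
  w <- as_pf_waveform(
    tibble::tibble(time_s = t, p_vent_mmHg = 108, p_ao_mmHg = 100,
                   q_mls = 100),
    cycle_period = 1)
  seg <- detect_forward_flow(w)
  expect_equal(compute_delta_p(w, seg), 8, tolerance = 1e-12)
  # half-sine differential of peak A averages to 2A/pi over its support
  A <- 12
  q <- ifelse(t <= 0.35, sin(pi * t / 0.35), 0)
  w2 <- as_pf_waveform(
    tibble::tibble(time_s = t, p_vent_mmHg = 100 + A * q,
                   p_ao_mmHg = 100, q_mls = 200 * q),
    cycle_period = 1)
  seg2 <- detect_forward_flow(w2)
  expect_equal(compute_delta_p(w2, seg2), 2 * A / pi, tolerance = 0.02)
  expect_equal(compute_delta_p(w2, seg2, method = "peak"), A,
               tolerance = 1e-3)
  # generator truth recovered within 2%
  g <- gen_pulse_waveform(waveform_params(n_cycles = 1, delta_p_peak = 10))
  sg <- detect_forward_flow(g)
  expect_equal(compute_delta_p(g, sg), attr(g, "truth")$delta_p_mean_mmHg,
               tolerance = 0.02)
})

test_that("RMS forward flow matches closed forms and is homogeneous", {
  t <- seq(0, 1, by = 0.001)
  w <- as_pf_waveform(
    tibble::tibble(time_s = t, p_vent_mmHg = 105, p_ao_mmHg = 100,
                   q_mls = 100),
    cycle_period = 1)
  seg <- detect_forward_flow(w)
  expect_equal(compute_qrms(w, seg), 100, tolerance = 1e-12)
  A <- 180
  q <- ifelse(t <= 0.35, A * sin(pi * t / 0.35), 0)
  w2 <- as_pf_waveform(
    tibble::tibble(time_s = t, p_vent_mmHg = 105, p_ao_mmHg = 100,
                   q_mls = q),
    cycle_period = 1)
  seg2 <- detect_forward_flow(w2)
  expect_equal(compute_qrms(w2, seg2), A / sqrt(2), tolerance = 0.01)
  w3 <- w2
  w3$q_mls <- w3$q_mls * 3
  expect_equal(compute_qrms(w3, detect_forward_flow(w3)),
               3 * compute_qrms(w2, seg2), tolerance = 1e-9)
})

test_that("regurgitant fraction is a volume ratio, scale-invariant", {
  t <- seq(0, 1, by = 0.001)
  # square cycle: +100 mL/s for 0.5 s (50 mL), -10 mL/s for 0.5 s (5 mL)
  q <- ifelse(t < 0.5, 100, -10)
  w <- as_pf_waveform(
    tibble::tibble(time_s = t, p_vent_mmHg = 100, p_ao_mmHg = 95, q_mls = q),
    cycle_period = 1)
  seg <- detect_forward_flow(w)
  expect_equal(compute_rf(w, seg), 10, tolerance = 0.15)
  # no retrograde flow: RF = 0
  w0 <- w; w0$q_mls <- pmax(w0$q_mls, 0)
  expect_equal(compute_rf(w0, detect_forward_flow(w0)), 0)
  # doubling the whole flow trace leaves RF unchanged
  w2 <- w; w2$q_mls <- 2 * w2$q_mls
  expect_equal(compute_rf(w2, detect_forward_flow(w2)),
               compute_rf(w, seg), tolerance = 1e-12)
})

test_that("EOA reproduces benchmark closures and the square-root law", {
  expect_equal(round(compute_eoa(127.35, 6.38), 2), 0.98)
  expect_equal(round(compute_eoa(145.24, 7.37), 2), 1.04)
  e1 <- compute_eoa(100, 5)
  expect_equal(compute_eoa(100, 20), e1 / 2, tolerance = 1e-12)
  # strictly increasing in flow, decreasing in gradient
  expect_gt(compute_eoa(110, 5), e1)
  expect_lt(compute_eoa(100, 6), e1)
  expect_error(compute_eoa(100, 0), class = "valvebench_domain_error")
  expect_error(compute_eoa(100, -2), class = "valvebench_domain_error")
})

test_that("Reynolds number implements the definition with cP conversion", {
  expect_equal(compute_reynolds(1, 0.026), 1007 * 1 * 0.026 / 1.07e-3,
               tolerance = 1e-12)
  expect_equal(compute_reynolds(0, 0.026), 0)
  expect_equal(compute_reynolds(2, 0.026), 2 * compute_reynolds(1, 0.026))
  expect_error(compute_reynolds(1, 0), class = "valvebench_domain_error")
})

test_that("metric pipeline recovers generator truths within 2% and is idempotent", {
  w <- gen_pulse_waveform(waveform_params(n_cycles = 10))
  truth <- attr(w, "truth")
  m <- hydrodynamic_metrics(w)
  expect_equal(m$rf_pct, truth$rf_pct, tolerance = 0.02)
  expect_equal(m$delta_p_mmHg, truth$delta_p_mean_mmHg, tolerance = 0.02)
  expect_equal(m$q_rms_mls, truth$q_rms_mls, tolerance = 0.02)
  # averaging identical cycles then re-measuring changes nothing
  avg <- ensemble_average(w, 10)
  m2 <- hydrodynamic_metrics(avg)
  expect_equal(m2$eoa_cm2, m$eoa_cm2, tolerance = 1e-9)
})
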