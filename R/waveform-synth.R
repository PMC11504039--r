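#' Parameters for the synthetic pulse-duplicator waveform generator
#'
#' Bundles the physiological settings of a simulated pulse-duplicator run.
#' Defaults reproduce the bench conditions used throughout the package's
#' validation work: a mean arterial pressure of 100 mmHg, 70 beats per
#' minute and a flow waveform that is 35% systolic. The systolic pulse is a
#' half-sine whose area is the stroke volume; valve closure is a brief
#' negative spike carrying `closing_volume_fraction` of the stroke volume,
#' and diastolic leakage is a constant retrograde flow.
#'
#' @param heart_rate Heart rate in beats/min.
#' @param mean_arterial_pressure Target time-averaged aortic pressure, mmHg.
#' @param systolic_fraction Fraction of the cycle occupied by systole, in (0, 1).
#' @param stroke_volume Forward (positive-flow) volume per cycle, mL. The
#'   default of 35 mL, at 70 bpm and 35% systole, gives a root-mean-square
#'   forward flow near 130 mL/s — the magnitude a bioprosthetic-valve bench
#'   run at these settings produces.
#' @param closing_volume_fraction Closing (regurgitant spike) volume as a
#'   fraction of stroke volume, >= 0.
#' @param leakage_rate Constant diastolic leakage flow, mL/s, >= 0.
#' @param delta_p_peak Peak systolic ventricular-minus-aortic pressure
#'   differential, mmHg. The half-sine differential has time-mean
#'   `2 * delta_p_peak / pi` over systole, so the default of 10 mmHg gives a
#'   forward-flow mean pressure drop of about 6.4 mmHg.
#' @param closing_duration_fraction Width of the closing spike as a fraction
#'   of the cycle.
#' @param pulse_pressure Aortic pulse amplitude, mmHg (shape only; the mean
#'   is pinned to `mean_arterial_pressure`).
#' @param sampling_rate Nominal sampling rate, Hz. The actual grid step is
#'   `cycle_period / round(sampling_rate * cycle_period)` so that every
#'   cycle occupies an exact whole number of samples.
#' @param n_cycles Number of cycles to generate, >= 1.
#' @param noise_sd_pressure,noise_sd_flow Additive Gaussian noise standard
#'   deviations (mmHg, mL/s).
#' @param seed Integer seed; fixed seed gives bit-identical output.
#'
#' @return A list of class `waveform_params`.
#' @export
waveform_params <- function(heart_rate = 70,
                            mean_arterial_pressure = 100,
                            systolic_fraction = 0.35,
                            stroke_volume = 35,
                            closing_volume_fraction = 0.08,
                            leakage_rate = 1,
                            delta_p_peak = 10,
                            closing_duration_fraction = 0.05,
                            pulse_pressure = 40,
                            sampling_rate = 1000,
                            n_cycles = 10L,
                            noise_sd_pressure = 0,
                            noise_sd_flow = 0,
                            seed = 1L) {
  check_positive(heart_rate, "heart_rate")
  check_positive(mean_arterial_pressure, "mean_arterial_pressure")
  check_fraction(systolic_fraction, "systolic_fraction")
  check_positive(stroke_volume, "stroke_volume")
  check_nonneg(closing_volume_fraction, "closing_volume_fraction")
  check_nonneg(leakage_rate, "leakage_rate")
  check_positive(delta_p_peak, "delta_p_peak")
  check_fraction(closing_duration_fraction, "closing_duration_fraction")
  check_positive(pulse_pressure, "pulse_pressure")
  check_positive(sampling_rate, "sampling_rate")
  if (n_cycles < 1) stop_param("`n_cycles` must be >= 1", field = "n_cycles")
  check_nonneg(noise_sd_pressure, "noise_sd_pressure")
  check_nonneg(noise_sd_flow, "noise_sd_flow")
  period <- 60 / heart_rate
  if (sampling_rate * period < 50) {
    stop_param("`sampling_rate` must give at least 50 samples per cycle",
               field = "sampling_rate")
  }
  if (systolic_fraction + closing_duration_fraction >= 1) {
    stop_param("systole plus closing spike must fit inside one cycle",
               field = "closing_duration_fraction")
  }
  structure(
    list(heart_rate = heart_rate,
         mean_arterial_pressure = mean_arterial_pressure,
         systolic_fraction = systolic_fraction,
         stroke_volume = stroke_volume,
         closing_volume_fraction = closing_volume_fraction,
         leakage_rate = leakage_rate,
         delta_p_peak = delta_p_peak,
         closing_duration_fraction = closing_duration_fraction,
         pulse_pressure = pulse_pressure,
         sampling_rate = sampling_rate,
         n_cycles = as.integer(n_cycles),
         noise_sd_pressure = noise_sd_pressure,
         noise_sd_flow = noise_sd_flow,
         seed = as.integer(seed)),
    class = "waveform_params")
}

#' Generate a synthetic pressure/flow waveform
#'
#' Produces ventricular pressure, aortic pressure and transaortic flow on a
#' uniform time grid covering `n_cycles` cardiac cycles. Before noise, the
#' positive-flow volume per cycle equals the configured stroke volume and
#' the time-averaged aortic pressure equals the configured mean arterial
#' pressure (both exactly, on the discrete grid). The ventricular-aortic
#' differential is positive throughout systole and negative in diastole.
#'
#' @param params A [waveform_params()] object.
#' @return A tibble of class `pf_waveform` with columns `time_s`,
#'   `p_vent_mmHg`, `p_ao_mmHg`, `q_mls`, carrying attributes
#'   `cycle_period` (s) and `truth` (list of generator ground truths:
#'   stroke, closing and leakage volumes, regurgitant fraction, mean and
#'   peak forward pressure drop, RMS forward flow).
#' @export
#' @examples
#' w <- gen_pulse_waveform(waveform_params(n_cycles = 2))
#' head(w)
#' attr(w, "truth")$rf_pct
gen_pulse_waveform <- function(params = waveform_params()) {
  if (!inherits(params, "waveform_params")) {
    stop_param("`params` must be built with waveform_params()")
  }
  p <- params
  period <- 60 / p$heart_rate
  m <- round(p$sampling_rate * period)          # samples per cycle
  dt <- period / m
  n <- m * p$n_cycles
  time_s <- (seq_len(n + 1L) - 1L) * dt         # includes both endpoints
  phase <- (time_s / period) %% 1
  # wrap the terminal sample onto phase of the start of a cycle
  sf <- p$systolic_fraction
  cw <- p$closing_duration_fraction
  t_sys <- sf * period
  q_peak <- pi * p$stroke_volume / (2 * t_sys)
  closing_vol <- p$closing_volume_fraction * p$stroke_volume
  c_peak <- pi * closing_vol / (2 * cw * period)

  in_sys <- phase < sf
  in_close <- phase >= sf & phase < sf + cw
  q <- numeric(length(phase))
  q[in_sys] <- q_peak * sin(pi * phase[in_sys] / sf)
  q[in_close] <- -c_peak * sin(pi * (phase[in_close] - sf) / cw)
  q[!in_sys & !in_close] <- -p$leakage_rate

  # aortic pressure: half-sine systolic pulse, linear diastolic sag; the
  # discrete mean over one cycle is pinned exactly to MAP
  shape <- numeric(length(phase))
  shape[in_sys] <- sin(pi * phase[in_sys] / sf)
  dia <- !in_sys
  shape[dia] <- -0.5 * (phase[dia] - sf) / (1 - sf)
  shape_mean <- mean(shape[seq_len(m)])         # one full cycle on the grid
  p_ao <- p$mean_arterial_pressure + p$pulse_pressure * (shape - shape_mean)

  dp <- numeric(length(phase))
  dp[in_sys] <- p$delta_p_peak * sin(pi * phase[in_sys] / sf)
  p_vent <- ifelse(in_sys, p_ao + dp, 10)

  if (p$noise_sd_pressure > 0 || p$noise_sd_flow > 0) {
    with_seed(p$seed, {
      if (p$noise_sd_pressure > 0) {
        p_vent <- p_vent + rnorm(length(p_vent), 0, p$noise_sd_pressure)
        p_ao <- p_ao + rnorm(length(p_ao), 0, p$noise_sd_pressure)
      }
      if (p$noise_sd_flow > 0) {
        q <- q + rnorm(length(q), 0, p$noise_sd_flow)
      }
    })
  }

  leak_vol <- p$leakage_rate * (1 - sf - cw) * period
  truth <- list(
    stroke_volume_ml = p$stroke_volume,
    closing_volume_ml = closing_vol,
    leakage_volume_ml = leak_vol,
    rf_pct = 100 * (closing_vol + leak_vol) / p$stroke_volume,
    delta_p_mean_mmHg = 2 * p$delta_p_peak / pi,
    delta_p_peak_mmHg = p$delta_p_peak,
    q_rms_mls = q_peak / sqrt(2),
    q_peak_mls = q_peak,
    map_mmHg = p$mean_arterial_pressure,
    systolic_duration_s = t_sys)

  new_pf_waveform(
    tibble::tibble(time_s = time_s, p_vent_mmHg = p_vent,
                   p_ao_mmHg = p_ao, q_mls = q),
    cycle_period = period, truth = truth, params = p)
}

new_pf_waveform <- function(data, cycle_period, truth = NULL, params = NULL) {
  structure(data,
            class = c("pf_waveform", class(tibble::tibble())),
            cycle_period = cycle_period,
            truth = truth,
            params = params)
}

#' Coerce a data frame of pressure/flow samples to a waveform object
#'
#' @param data Data frame with columns `time_s`, `p_vent_mmHg`, `p_ao_mmHg`,
#'   `q_mls` on a strictly increasing uniform time grid.
#' @param cycle_period Cardiac cycle period, s.
#' @return A `pf_waveform` tibble.
#' @export
as_pf_waveform <- function(data, cycle_period) {
  cols <- c("time_s", "p_vent_mmHg", "p_ao_mmHg", "q_mls")
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    stop_data(paste0("waveform is missing columns: ",
                     paste(missing, collapse = ", ")))
  }
  t <- data$time_s
  if (length(t) < 2L || any(diff(t) <= 0)) {
    stop_data("`time_s` must be strictly increasing")
  }
  steps <- diff(t)
  if (max(steps) - min(steps) > 1e-6 * mean(steps)) {
    stop_data("`time_s` must be a uniform grid")
  }
  check_positive(cycle_period, "cycle_period")
  if (t[length(t)] - t[1] < cycle_period * (1 - 1e-6)) {
    stop_data("waveform must cover at least one full cycle")
  }
  new_pf_waveform(tibble::as_tibble(data[cols]), cycle_period = cycle_period)
}
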