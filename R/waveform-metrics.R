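#' Fluid properties of the test medium
#'
#' Density and dynamic viscosity of the working fluid. Defaults are those
#' of 0.90% w/v saline at 20 degrees C as used on a valve pulse duplicator:
#' 1007 kg/m^3 and 1.07 cP.
#'
#' @param density kg/m^3.
#' @param dynamic_viscosity cP (1 cP = 1e-3 Pa s).
#' @return A list of class `fluid_properties`.
#' @export
fluid_properties <- function(density = 1007, dynamic_viscosity = 1.07) {
  check_positive(density, "density")
  check_positive(dynamic_viscosity, "dynamic_viscosity")
  structure(list(density = density, dynamic_viscosity = dynamic_viscosity),
            class = "fluid_properties")
}

samples_per_cycle <- function(w) {
  dt <- w$time_s[2] - w$time_s[1]
  round(attr(w, "cycle_period") / dt)
}

#' Ensemble-average a multi-cycle waveform into one representative cycle
#'
#' Splits the recording into consecutive cycles and averages the aligned
#' samples, the standard pulse-duplicator reduction (10 cycles by
#' convention). With `align = "grid"` cycles are cut every
#' `cycle_period / dt` samples; with `align = "upstroke"` each cycle start
#' is re-detected from the systolic flow upstroke and resampled to a common
#' grid by linear interpolation, which tolerates phase jitter in real
#' recordings.
#'
#' @param w A `pf_waveform` covering at least `n_cycles` cycles.
#' @param n_cycles Number of cycles to average (default 10).
#' @param align `"grid"` (default) or `"upstroke"`.
#' @return A single-cycle `pf_waveform`; per-sample noise shrinks by
#'   `1/sqrt(n_cycles)`.
#' @export
ensemble_average <- function(w, n_cycles = 10L, align = c("grid", "upstroke")) {
  align <- match.arg(align)
  if (!inherits(w, "pf_waveform")) stop_data("`w` must be a pf_waveform")
  m <- samples_per_cycle(w)
  n_avail <- (nrow(w) - 1L) %/% m
  if (n_avail < n_cycles) {
    stop_data(sprintf(
      "waveform holds %d complete cycle(s) but %d were requested",
      n_avail, n_cycles), n_available = n_avail, n_requested = n_cycles)
  }
  cols <- c("p_vent_mmHg", "p_ao_mmHg", "q_mls")
  if (align == "grid") {
    seg <- function(k) as.matrix(w[((k - 1L) * m + 1L):(k * m), cols])
  } else {
    starts <- detect_upstrokes(w$q_mls, m)
    if (length(starts) < n_cycles) {
      stop_data(sprintf(
        "detected %d flow upstrokes but %d cycles were requested",
        length(starts), n_cycles))
    }
    seg <- function(k) {
      i0 <- starts[k]
      idx <- i0:(min(i0 + m, nrow(w)))
      src <- as.matrix(w[idx, cols])
      # resample to m samples over one period
      pos <- seq(0, m, length.out = nrow(src))
      vapply(seq_along(cols),
             function(j) approx(pos, src[, j], xout = seq_len(m) - 1L)$y,
             numeric(m))
    }
  }
  acc <- Reduce(`+`, lapply(seq_len(n_cycles), seg)) / n_cycles
  dt <- w$time_s[2] - w$time_s[1]
  out <- tibble::tibble(time_s = (seq_len(m) - 1L) * dt,
                        p_vent_mmHg = acc[, 1], p_ao_mmHg = acc[, 2],
                        q_mls = acc[, 3])
  new_pf_waveform(out, cycle_period = attr(w, "cycle_period"),
                  truth = attr(w, "truth"), params = attr(w, "params"))
}

# indices where flow crosses 10% of peak upwards, deduplicated to >= m/2 apart
detect_upstrokes <- function(q, m) {
  thr <- 0.1 * max(q)
  up <- which(q[-1] >= thr & q[-length(q)] < thr)
  if (!length(up)) return(integer())
  keep <- c(TRUE, diff(up) > m / 2)
  up[keep]
}

#' Locate the forward-flow window of an averaged cycle
#'
#' The forward-flow window is the maximal contiguous run of samples where
#' flow exceeds a small threshold (2% of peak absolute flow by default),
#' with short dropouts bridged (two-sample hysteresis) so that noise at the
#' crossings does not fragment the window.
#'
#' @param w Single-cycle `pf_waveform`.
#' @param threshold_frac Threshold as a fraction of `max(abs(q))`.
#' @param hysteresis Runs of below-threshold samples of at most this length
#'   inside the window are bridged.
#' @return A list of class `cycle_segmentation`: `forward` (integer index
#'   range), `threshold` (mL/s), `n` (samples in the cycle).
#' @export
detect_forward_flow <- function(w, threshold_frac = 0.02, hysteresis = 2L) {
  q <- w$q_mls
  thr <- threshold_frac * max(abs(q))
  above <- q > thr
  if (!any(above)) stop_data("no positive flow above threshold")
  r <- rle(above)
  # bridge short FALSE runs flanked by TRUE (hysteresis)
  interior <- which(!r$values & r$lengths <= hysteresis)
  interior <- interior[interior > 1L & interior < length(r$values)]
  r$values[interior] <- TRUE
  r <- rle(inverse.rle(r))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  true_runs <- which(r$values)
  best <- true_runs[which.max(r$lengths[true_runs])]
  structure(list(forward = c(starts[best], ends[best]),
                 threshold = thr, n = length(q)),
            class = "cycle_segmentation")
}

forward_idx <- function(seg) seq.int(seg$forward[1], seg$forward[2])

#' Mean transvalvular pressure drop over the forward-flow window
#'
#' @param w Single-cycle `pf_waveform`.
#' @param seg Segmentation from [detect_forward_flow()].
#' @param method `"mean"` (default; time-mean of the ventricular-aortic
#'   differential over forward flow) or `"peak"`.
#' @return Pressure drop in mmHg.
#' @export
compute_delta_p <- function(w, seg, method = c("mean", "peak")) {
  method <- match.arg(method)
  idx <- forward_idx(seg)
  if (!length(idx)) stop_data("empty forward-flow window")
  d <- w$p_vent_mmHg[idx] - w$p_ao_mmHg[idx]
  if (method == "mean") mean(d) else max(d)
}

#' Root-mean-square forward flow
#'
#' RMS of the flow over the forward-flow window, the `Q_RMS` used in
#' ISO 5840-style effective orifice area estimation.
#'
#' @inheritParams compute_delta_p
#' @return mL/s.
#' @export
compute_qrms <- function(w, seg) {
  idx <- forward_idx(seg)
  if (!length(idx)) stop_data("empty forward-flow window")
  sqrt(mean(w$q_mls[idx]^2))
}

#' Regurgitant fraction
#'
#' Retrograde (closing plus leakage) volume as a percentage of the forward
#' volume, with all volumes obtained by trapezoidal integration of the flow
#' split by sign over the full cycle.
#'
#' @inheritParams compute_delta_p
#' @return Percent.
#' @export
compute_rf <- function(w, seg) {
  t <- w$time_s
  q <- w$q_mls
  fwd <- pracma::trapz(t, pmax(q, 0))
  if (fwd <= 0) stop_data("zero forward volume")
  retro <- pracma::trapz(t, pmax(-q, 0))
  100 * retro / fwd
}

#' Effective orifice area
#'
#' The ISO 5840 / Gorlin-type expression
#' `EOA = Q_RMS / (51.6 * sqrt(delta_p / rho))` with `Q_RMS` in mL/s,
#' `delta_p` in mmHg and density in g/cm^3, giving EOA in cm^2 — the
#' pulse-duplicator convention for reducing flow and gradient to a valve
#' opening area.
#'
#' @param q_rms RMS forward flow, mL/s.
#' @param delta_p Mean forward pressure drop, mmHg (must be > 0).
#' @param fluid A [fluid_properties()] object.
#' @return EOA in cm^2.
#' @export
#' @examples
#' compute_eoa(127.35, 6.38)  # ~0.98 cm^2
compute_eoa <- function(q_rms, delta_p, fluid = fluid_properties()) {
  if (any(delta_p <= 0)) stop_domain("`delta_p` must be positive")
  if (any(q_rms < 0)) stop_domain("`q_rms` must be non-negative")
  rho_gcm3 <- fluid$density / 1000
  q_rms / (51.6 * sqrt(delta_p / rho_gcm3))
}

#' Reynolds number
#'
#' `Re = rho * v * D / mu` with viscosity converted from cP to Pa s.
#'
#' @param velocity Characteristic velocity, m/s.
#' @param diameter Characteristic diameter, m.
#' @param fluid A [fluid_properties()] object.
#' @return Dimensionless Reynolds number.
#' @export
compute_reynolds <- function(velocity, diameter, fluid = fluid_properties()) {
  if (any(velocity < 0)) stop_domain("`velocity` must be non-negative")
  if (any(diameter <= 0)) stop_domain("`diameter` must be positive")
  mu_pas <- fluid$dynamic_viscosity * 1e-3
  fluid$density * velocity * diameter / mu_pas
}

#' All four hydrodynamic functionality metrics from a waveform
#'
#' Convenience pipeline: ensemble-averages the recording (when it holds
#' more than one cycle), detects the forward-flow window and returns the
#' regurgitant fraction, mean pressure drop, RMS forward flow and effective
#' orifice area as a one-row tibble.
#'
#' @param w A `pf_waveform`.
#' @param n_cycles Cycles to average; defaults to all complete cycles
#'   available (capped at 10).
#' @param fluid A [fluid_properties()] object.
#' @return Tibble with columns `rf_pct`, `delta_p_mmHg`, `q_rms_mls`,
#'   `eoa_cm2`.
#' @export
#' @examples
#' gen_pulse_waveform(waveform_params(n_cycles = 3)) |> hydrodynamic_metrics()
hydrodynamic_metrics <- function(w, n_cycles = NULL,
                                 fluid = fluid_properties()) {
  m <- samples_per_cycle(w)
  avail <- (nrow(w) - 1L) %/% m
  if (avail < 1L) avail <- 1L
  n_cycles <- n_cycles %||% min(avail, 10L)
  cyc <- if (avail > 1L || nrow(w) - 1L > m) {
    ensemble_average(w, n_cycles = n_cycles)
  } else w
  seg <- detect_forward_flow(cyc)
  dp <- compute_delta_p(cyc, seg)
  qr <- compute_qrms(cyc, seg)
  tibble::tibble(
    rf_pct = compute_rf(cyc, seg),
    delta_p_mmHg = dp,
    q_rms_mls = qr,
    eoa_cm2 = compute_eoa(qr, dp, fluid))
}
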