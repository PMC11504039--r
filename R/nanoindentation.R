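# Hertzian contact load in muN from kPa/mum inputs.
# P[N] = 4 E sqrt(R) delta^(3/2) / (3 (1 - nu^2)) in SI; collecting the
# kPa/mum -> N unit factors leaves a clean 1e-3 in muN.
hertz_coef <- function(E_kPa, R_um, nu) {
  4 * E_kPa * sqrt(R_um) * 1e-3 / (3 * (1 - nu^2))
}

#' Hertzian contact load
#'
#' Load on a flat tissue sample from an indenter of characteristic
#' dimension `R`, under the Hertz contact model
#' `P = 4 E sqrt(R) delta^(3/2) / (3 (1 - nu^2))`.
#' `R` is treated as an opaque configured length (the probe's quoted 500 um
#' dimension) and the expression is evaluated literally.
#'
#' @param delta Indentation depth, um (>= 0, vectorised).
#' @param E Young's modulus, kPa.
#' @param R Indenter dimension, um.
#' @param nu Poisson ratio (< 0.5 physically; values >= 1 are rejected).
#' @return Load in uN.
#' @export
#' @examples
#' hertz_load(40, E = 55.10)  # ~457 uN
hertz_load <- function(delta, E, R = 500, nu = 0.30) {
  if (nu >= 1) stop_domain("`nu` must be < 1")
  if (nu < 0) stop_domain("`nu` must be >= 0")
  check_positive(E, "E")
  check_positive(R, "R")
  if (any(delta < 0)) stop_domain("`delta` must be >= 0")
  hertz_coef(E, R, nu) * delta^1.5
}

#' Parameters for the synthetic nanoindentation generator
#'
#' Emulates a flat-tip indentation protocol on soft tissue: a loading
#' segment to `max_depth` at `loading_rate`, an unloading segment back to
#' zero at the same rate, and a fast retraction. Defaults follow a typical
#' soft-tissue protocol: 40 um loading at 2 um/s, retraction at 5 um/s for
#' 5 s, probe dimension 500 um, Poisson ratio 0.30.
#'
#' @param youngs_modulus True Young's modulus, kPa.
#' @param indenter_dimension_R Probe dimension entering the Hertz model, um.
#' @param poisson_ratio Poisson ratio, in `[0, 0.5)`.
#' @param max_depth Loading depth, um.
#' @param loading_rate Loading (and unloading) speed, um/s.
#' @param retraction_rate Retraction speed, um/s.
#' @param retraction_duration Retraction time, s.
#' @param noise_sd Additive Gaussian load noise, uN.
#' @param sampling_rate Samples per second.
#' @param seed Integer seed.
#' @return A list of class `indentation_params`.
#' @export
indentation_params <- function(youngs_modulus = 55.10,
                               indenter_dimension_R = 500,
                               poisson_ratio = 0.30,
                               max_depth = 40,
                               loading_rate = 2,
                               retraction_rate = 5,
                               retraction_duration = 5,
                               noise_sd = 0,
                               sampling_rate = 10,
                               seed = 1L) {
  check_positive(youngs_modulus, "youngs_modulus")
  check_positive(indenter_dimension_R, "indenter_dimension_R")
  if (poisson_ratio < 0 || poisson_ratio >= 0.5) {
    stop_param("`poisson_ratio` must lie in [0, 0.5)", field = "poisson_ratio")
  }
  check_positive(max_depth, "max_depth")
  check_positive(loading_rate, "loading_rate")
  check_positive(retraction_rate, "retraction_rate")
  check_positive(retraction_duration, "retraction_duration")
  check_nonneg(noise_sd, "noise_sd")
  check_positive(sampling_rate, "sampling_rate")
  structure(
    list(youngs_modulus = youngs_modulus,
         indenter_dimension_R = indenter_dimension_R,
         poisson_ratio = poisson_ratio,
         max_depth = max_depth,
         loading_rate = loading_rate,
         retraction_rate = retraction_rate,
         retraction_duration = retraction_duration,
         noise_sd = noise_sd,
         sampling_rate = sampling_rate,
         seed = as.integer(seed)),
    class = "indentation_params")
}

#' Generate a synthetic load-displacement indentation record
#'
#' Three labelled segments: loading (Hertzian load plus noise), unloading
#' (elastic, same curve) and retraction (probe off the surface, zero load).
#' Displacement is monotone within each segment.
#'
#' @param params An [indentation_params()] object.
#' @return A tibble of class `indentation_record` with columns `time_s`,
#'   `displacement_um`, `load_uN`, `segment`, plus a `truth` attribute
#'   (true modulus, R, nu).
#' @export
#' @examples
#' rec <- gen_indentation_record(indentation_params())
#' dplyr::count(rec, segment)
gen_indentation_record <- function(params = indentation_params()) {
  if (!inherits(params, "indentation_params")) {
    stop_param("`params` must be built with indentation_params()")
  }
  p <- params
  dt <- 1 / p$sampling_rate
  t_load <- p$max_depth / p$loading_rate
  t_unload <- t_load
  n1 <- round(t_load / dt)
  n2 <- round(t_unload / dt)
  n3 <- round(p$retraction_duration / dt)
  t1 <- seq(0, by = dt, length.out = n1 + 1L)
  t2 <- seq(max(t1) + dt, by = dt, length.out = n2)
  t3 <- seq(max(t2) + dt, by = dt, length.out = n3)
  d1 <- p$loading_rate * t1
  d2 <- p$max_depth - p$loading_rate * (t2 - max(t1))
  d3 <- min(d2) - p$retraction_rate * (t3 - max(t2))
  delta <- c(d1, d2, d3)
  segment <- c(rep("loading", length(d1)), rep("unloading", length(d2)),
               rep("retraction", length(d3)))
  load <- ifelse(delta > 0,
                 hertz_coef(p$youngs_modulus, p$indenter_dimension_R,
                            p$poisson_ratio) * pmax(delta, 0)^1.5,
                 0)
  if (p$noise_sd > 0) {
    load <- with_seed(p$seed, load + rnorm(length(load), 0, p$noise_sd))
  }
  structure(
    tibble::tibble(time_s = c(t1, t2, t3), displacement_um = delta,
                   load_uN = load, segment = segment),
    class = c("indentation_record", class(tibble::tibble())),
    truth = list(youngs_modulus_kPa = p$youngs_modulus,
                 indenter_R_um = p$indenter_dimension_R,
                 poisson = p$poisson_ratio),
    params = p)
}

#' Label the loading / unloading / retraction segments of a record
#'
#' Segments are recovered from the sign and magnitude of the displacement
#' rate: the first positive-rate phase is loading; negative-rate samples
#' are split into unloading and retraction at the midpoint of the two
#' negative rate levels when a clear fast phase exists (rate ratio > 1.5).
#'
#' @param record Tibble with `time_s`, `displacement_um`, `load_uN`.
#' @return The record with a `segment` column replaced/added.
#' @export
split_segments <- function(record) {
  d <- record$displacement_um
  t <- record$time_s
  if (length(d) < 3L) stop_data("record too short to segment")
  # backward differences so each sample carries the rate that produced it
  rate <- c(NA, diff(d) / diff(t))
  rate[1L] <- rate[2L]
  pos <- rate > 0
  if (!any(pos)) stop_data("no monotone loading phase found")
  # loading: first contiguous positive-rate run
  r <- rle(pos)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  first_pos <- which(r$values)[1]
  load_idx <- starts[first_pos]:ends[first_pos]
  segment <- rep(NA_character_, length(d))
  segment[seq_len(max(load_idx))] <- "loading"
  rest <- setdiff(seq_along(d), seq_len(max(load_idx)))
  if (length(rest)) {
    neg_rate <- abs(rate[rest])
    lo <- min(neg_rate); hi <- max(neg_rate)
    if (hi / max(lo, 1e-12) > 1.5) {
      thr <- (lo + hi) / 2
      segment[rest] <- ifelse(neg_rate > thr, "retraction", "unloading")
      # enforce contiguity: everything after first retraction sample is retraction
      fr <- which(segment == "retraction")[1]
      if (!is.na(fr)) segment[seq(fr, length(d))] <- "retraction"
    } else {
      segment[rest] <- "unloading"
    }
  }
  out <- record
  out$segment <- segment
  class(out) <- unique(c("indentation_record", class(tibble::as_tibble(out))))
  out
}

#' Estimate the contact point of a loading curve
#'
#' Finds the displacement offset `delta0` so that the Hertz model applied
#' to `(delta - delta0)+` best fits the observed loads: a grid search over
#' candidate offsets with a linear-in-modulus least-squares fit on the
#' `delta^(3/2)` regressor at each candidate, refined by golden-section
#' optimisation.
#'
#' @param record Labelled `indentation_record` (only the loading segment is
#'   used) or a tibble of loading samples.
#' @param grid_n Number of grid candidates.
#' @return Contact offset in um (0 when the record starts at contact).
#' @export
detect_contact_point <- function(record, grid_n = 81L) {
  ld <- if ("segment" %in% names(record)) {
    dplyr::filter(record, .data$segment == "loading")
  } else record
  if (nrow(ld) < 10L) stop_data("need at least 10 loading samples")
  delta <- ld$displacement_um
  load <- ld$load_uN
  if (max(abs(load)) <= 0) stop_estimation("all-zero load: no contact found")
  rss_at <- function(d0) {
    x <- pmax(delta - d0, 0)^1.5
    sxx <- sum(x^2)
    if (sxx <= 0) return(sum(load^2))
    beta <- sum(x * load) / sxx
    if (beta < 0) beta <- 0
    sum((load - beta * x)^2)
  }
  hi <- max(delta) - (max(delta) - min(delta)) * 0.2
  cand <- seq(min(delta), hi, length.out = grid_n)
  rss <- vapply(cand, rss_at, numeric(1))
  best <- which.min(rss)
  lo_b <- cand[max(1L, best - 1L)]
  hi_b <- cand[min(length(cand), best + 1L)]
  opt <- optimize(rss_at, lower = lo_b, upper = hi_b)
  if (!is.finite(opt$objective)) stop_estimation("contact-point fit diverged")
  opt$minimum
}

#' Fit the Hertz contact model to the loading segment
#'
#' Least-squares estimate of Young's modulus from a labelled
#' load-displacement record. The model is linear in the modulus given the
#' contact offset, so the fit regresses load on `(delta - delta0)^(3/2)`
#' through the origin; with `estimate_offset = TRUE` the offset is first
#' estimated by [detect_contact_point()]. Only the loading segment may be
#' fit — requesting the unloading segment is a contract error, since the
#' model describes elastic loading.
#'
#' @param record Labelled `indentation_record`.
#' @param R Indenter dimension, um.
#' @param nu Poisson ratio.
#' @param estimate_offset Estimate the contact offset jointly (default
#'   FALSE: the record is assumed to start at contact).
#' @param segment Must be `"loading"`.
#' @return Object of class `hertz_fit`: a list with `youngs_modulus_kPa`,
#'   `contact_offset_um`, `rss_uN2`, `n_points`, `indenter_R_um`,
#'   `poisson`, and the fitted data. Supports [generics::tidy()],
#'   [generics::glance()] and `autoplot()`.
#' @export
#' @examples
#' rec <- gen_indentation_record(indentation_params(youngs_modulus = 84.79))
#' fit_hertz(rec)
fit_hertz <- function(record, R = 500, nu = 0.30, estimate_offset = FALSE,
                      segment = "loading") {
  if (!identical(segment, "loading")) {
    stop_param("the Hertz model is fit to the loading segment only",
               field = "segment")
  }
  if (!"segment" %in% names(record)) record <- split_segments(record)
  ld <- dplyr::filter(record, .data$segment == "loading")
  if (nrow(ld) < 5L) stop_data("loading segment has fewer than 5 samples")
  if (any(diff(ld$displacement_um) < -1e-9)) {
    stop_data("loading segment must be monotone nondecreasing in displacement")
  }
  d0 <- if (estimate_offset) detect_contact_point(ld) else 0
  x <- pmax(ld$displacement_um - d0, 0)^1.5
  sxx <- sum(x^2)
  if (sxx <= 0) stop_estimation("degenerate loading segment")
  slope <- sum(x * ld$load_uN) / sxx
  if (!is.finite(slope) || slope <= 0) {
    stop_estimation("Hertz fit did not converge to a positive modulus",
                    slope = slope)
  }
  E <- slope / hertz_coef(1, R, nu)
  fitted <- slope * x
  structure(
    list(youngs_modulus_kPa = E,
         contact_offset_um = d0,
         rss_uN2 = sum((ld$load_uN - fitted)^2),
         n_points = nrow(ld),
         indenter_R_um = R,
         poisson = nu,
         data = tibble::tibble(displacement_um = ld$displacement_um,
                               load_uN = ld$load_uN, fitted_uN = fitted)),
    class = "hertz_fit")
}

#' @export
print.hertz_fit <- function(x, ...) {
  cat("Hertzian contact fit (loading segment)\n")
  cat(sprintf("  E = %.2f kPa   (R = %g um, nu = %.2f)\n",
              x$youngs_modulus_kPa, x$indenter_R_um, x$poisson))
  cat(sprintf("  contact offset = %.2f um, RSS = %.3g uN^2, n = %d\n",
              x$contact_offset_um, x$rss_uN2, x$n_points))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.hertz_fit <- function(x, ...) {
  tibble::tibble(term = c("youngs_modulus_kPa", "contact_offset_um"),
                 estimate = c(x$youngs_modulus_kPa, x$contact_offset_um))
}

#' @export
glance.hertz_fit <- function(x, ...) {
  tibble::tibble(youngs_modulus_kPa = x$youngs_modulus_kPa,
                 contact_offset_um = x$contact_offset_um,
                 rss_uN2 = x$rss_uN2, n_points = x$n_points,
                 indenter_R_um = x$indenter_R_um, poisson = x$poisson)
}
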