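#' Symmetric percent difference
#'
#' `100 * |v1 - v2| / ((v1 + v2) / 2)` — the symmetric percent difference
#' used to compare paired bench and simulation values. Symmetric in its
#' arguments and invariant under common positive scaling.
#'
#' @param v1,v2 Numeric vectors (recycled).
#' @return Percent difference(s).
#' @export
#' @examples
#' percent_difference(10.84, 17.14)  # 45.03
percent_difference <- function(v1, v2) {
  denom <- (v1 + v2) / 2
  if (any(denom == 0)) stop_domain("percent difference undefined when v1 + v2 = 0")
  100 * abs(v1 - v2) / abs(denom)
}

#' Significance tier for a p-value
#'
#' The conventional star tiers: `*` below 0.05, `**` below 0.01, `***`
#' below 0.001, `****` below 0.0001, `n.s.` otherwise (thresholds strict).
#'
#' @param p P-value(s) in `[0, 1]`.
#' @return Character vector of tiers.
#' @export
significance_tier <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop_domain("p-values must lie in [0, 1]")
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 1e-4 ~ "****",
    p < 1e-3 ~ "***",
    p < 1e-2 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "n.s.")
}

# moments-based skewness/kurtosis normality screen (D'Agostino-Pearson
# omnibus K^2): the skewness Z uses D'Agostino's Johnson SU transform, the
# kurtosis Z the Anscombe-Glynn cube-root transform; K^2 = Zs^2 + Zk^2 is
# chi-squared with 2 df under normality.
dagostino_k2 <- function(x) {
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  b2 <- m4 / m2^2
  # skewness transform
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  zs <- delta * asinh(y / alpha)
  # kurtosis transform
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sb <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sb * (2 / sb + sqrt(1 + 4 / sb^2))
  v <- (1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4)))
  zk <- ((1 - 2 / (9 * a)) - sign(v) * abs(v)^(1 / 3)) / sqrt(2 / (9 * a))
  k2 <- zs^2 + zk^2
  list(statistic = k2, p_value = stats::pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = zs, z_kurt = zk)
}

#' Skewness-kurtosis normality screen
#'
#' Omnibus normality test combining standardised skewness and kurtosis
#' (the D'Agostino-Pearson K-squared statistic, chi-squared with 2 df
#' under the null). Samples smaller than `min_n` are below the omnibus
#' test's validity floor: a warning is raised and no p-value is computed.
#'
#' @param x Numeric sample.
#' @param min_n Validity floor (default 8).
#' @return One-row tibble: `statistic`, `p_value`, `tier`, `n`, `method`.
#' @export
normality_test <- function(x, min_n = 8L) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n >= 2L && stats::sd(x) == 0) stop_data("constant sample")
  if (n < min_n) {
    rlang::warn(sprintf(
      "n = %d is below the omnibus normality test's validity floor (%d); no p-value computed",
      n, min_n))
    return(tibble::tibble(statistic = NA_real_, p_value = NA_real_,
                          tier = NA_character_, n = n,
                          method = "skewness-kurtosis omnibus (skipped)"))
  }
  k2 <- dagostino_k2(x)
  tibble::tibble(statistic = k2$statistic, p_value = k2$p_value,
                 tier = significance_tier(k2$p_value), n = n,
                 method = "skewness-kurtosis omnibus (K-squared)")
}

#' Unpaired Student's t-test with tiered significance
#'
#' Two-sided pooled-variance Student's t-test between two measurement
#' groups (Welch's unequal-variance variant available by flag), with the
#' p-value mapped to the star tiers of [significance_tier()].
#'
#' @param a,b Numeric vectors (each n >= 2).
#' @param var_equal Pooled-variance Student's t (default TRUE); FALSE gives
#'   Welch.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `tier`,
#'   `mean_a`, `mean_b`, `method`.
#' @export
#' @examples
#' unpaired_t_test(c(1, 2, 3), c(4, 5, 6))
unpaired_t_test <- function(a, b, var_equal = TRUE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop_data("each group needs at least 2 finite values")
  }
  if (var_equal && stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(tibble::tibble(statistic = 0, df = length(a) + length(b) - 2,
                            p_value = 1, tier = "n.s.", mean_a = mean(a),
                            mean_b = mean(b), method = "Student's t (pooled)"))
    }
    stop_data("zero pooled variance with unequal means")
  }
  tt <- stats::t.test(a, b, var.equal = var_equal)
  tibble::tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, tier = significance_tier(tt$p.value),
                 mean_a = mean(a), mean_b = mean(b),
                 method = if (var_equal) "Student's t (pooled)" else "Welch t")
}

#' Build a bench-versus-simulation comparison table
#'
#' Joins two tidy metric tables — one of bench (in vitro) values, one of
#' simulated (in silico) values — on their metric/group keys and appends
#' the symmetric percent difference, the layout used to validate a
#' simulation against pulse-duplicator measurements.
#'
#' @param in_vitro,in_silico Tibbles with a `value` column and shared key
#'   columns (any of `metric`, `group`).
#' @return Tibble with key columns, `in_vitro`, `in_silico`,
#'   `percent_diff`.
#' @export
#' @examples
#' build_comparison_table(
#'   tibble::tibble(metric = "rf", group = "raw", value = 10.84),
#'   tibble::tibble(metric = "rf", group = "raw", value = 17.14))
build_comparison_table <- function(in_vitro, in_silico) {
  keys <- intersect(intersect(names(in_vitro), names(in_silico)),
                    c("metric", "group"))
  if (!length(keys)) stop_data("no shared key columns (metric/group)")
  if (!"value" %in% names(in_vitro) || !"value" %in% names(in_silico)) {
    stop_data("both tables need a `value` column")
  }
  a <- dplyr::rename(in_vitro[, c(keys, "value")], in_vitro = "value")
  b <- dplyr::rename(in_silico[, c(keys, "value")], in_silico = "value")
  key_str <- function(d) do.call(paste, c(d[keys], sep = "\r"))
  miss_a <- setdiff(key_str(b), key_str(a))
  miss_b <- setdiff(key_str(a), key_str(b))
  if (length(miss_a) || length(miss_b)) {
    stop_data(paste0(
      "metric keys do not match; missing: ",
      paste(gsub("\r", "/", unique(c(miss_a, miss_b))), collapse = ", ")))
  }
  dplyr::inner_join(a, b, by = keys) |>
    dplyr::mutate(percent_diff = percent_difference(.data$in_vitro,
                                                    .data$in_silico))
}
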