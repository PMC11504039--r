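# shared internal helpers

#' @importFrom rlang abort warn %||% .data
#' @importFrom stats rnorm sd approx optimize quantile median var
#' @importFrom utils head tail
NULL

# classed condition helpers: every user-facing failure carries a class so
# callers (and the tests) can distinguish parameter, data and domain errors.
stop_param <- function(msg, field = NULL) {
  rlang::abort(msg, class = "valvebench_parameter_error", field = field)
}
stop_data <- function(msg, ...) {
  rlang::abort(msg, class = "valvebench_data_error", ...)
}
stop_domain <- function(msg) {
  rlang::abort(msg, class = "valvebench_domain_error")
}
stop_estimation <- function(msg, ...) {
  rlang::abort(msg, class = "valvebench_estimation_error", ...)
}
stop_segmentation <- function(msg) {
  rlang::abort(msg, class = "valvebench_segmentation_error")
}
stop_calibration <- function(msg) {
  rlang::abort(msg, class = "valvebench_calibration_error")
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_param(sprintf("`%s` must be a single positive finite number", name),
               field = name)
  }
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    stop_param(sprintf("`%s` must be a single non-negative finite number", name),
               field = name)
  }
  invisible(x)
}

check_fraction <- function(x, name, open = TRUE) {
  check_positive(x, name)
  bad <- if (open) x >= 1 else x > 1
  if (bad) {
    stop_param(sprintf("`%s` must lie in (0, 1%s", name, if (open) ")" else "]"),
               field = name)
  }
  invisible(x)
}

# trapezoidal weights on a uniform grid of n points spanning dt * (n - 1)
trapz_weights <- function(n, dt) {
  w <- rep(dt, n)
  w[c(1L, n)] <- dt / 2
  w
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(code)
}
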