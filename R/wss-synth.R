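#' Parameters for the synthetic leaflet wall-shear-stress field generator
#'
#' The synthetic leaflet is a triangulated unit disk in which the radial
#' coordinate stands in for belly-to-free-edge position: the shear
#' amplitude ramps linearly from `belly_amplitude` at the centre to
#' `edge_amplitude` at the rim, matching the qualitative pattern on real
#' leaflets (lowest shear in the belly, higher towards the free edge).
#' Time dependence is a sample-exact square wave with forward duty `f`, so
#' the per-node ground truths have closed forms: TAWSS equals the local
#' amplitude and OSI equals `0.5 * (1 - |2f - 1|)`.
#'
#' @param n_nodes Target number of surface nodes (the ring construction
#'   may use a nearby count; the actual count is in the result).
#' @param cycle_period Cardiac cycle period, s.
#' @param n_timesteps Number of time intervals per cycle (>= 8). Sample
#'   times include both cycle endpoints.
#' @param belly_amplitude,edge_amplitude Shear amplitude at the centre and
#'   rim, dynes/cm^2.
#' @param forward_duty Fraction of the cycle with shear in the forward
#'   direction, in (0, 1]. The realised duty is quantised to
#'   `round(forward_duty * n_timesteps) / n_timesteps`.
#' @param noise_sd Additive Gaussian noise per vector component,
#'   dynes/cm^2.
#' @param seed Integer seed.
#' @return A list of class `wss_field_params`.
#' @export
wss_field_params <- function(n_nodes = 150,
                             cycle_period = 60 / 70,
                             n_timesteps = 64L,
                             belly_amplitude = 5,
                             edge_amplitude = 20,
                             forward_duty = 0.5,
                             noise_sd = 0,
                             seed = 1L) {
  check_positive(n_nodes, "n_nodes")
  check_positive(cycle_period, "cycle_period")
  if (n_timesteps < 8L) stop_param("`n_timesteps` must be >= 8",
                                   field = "n_timesteps")
  check_nonneg(belly_amplitude, "belly_amplitude")
  check_nonneg(edge_amplitude, "edge_amplitude")
  check_fraction(forward_duty, "forward_duty", open = FALSE)
  check_nonneg(noise_sd, "noise_sd")
  structure(
    list(n_nodes = n_nodes, cycle_period = cycle_period,
         n_timesteps = as.integer(n_timesteps),
         belly_amplitude = belly_amplitude, edge_amplitude = edge_amplitude,
         forward_duty = forward_duty, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "wss_field_params")
}

#' Bioreactor conditioning preset
#'
#' Wall-shear field parameters emulating an oscillatory-flow conditioning
#' environment: duty 0.5 (purely oscillatory, OSI 0.5) and a uniform
#' 3.5 dynes/cm^2 amplitude, the midpoint of the 3-4 dynes/cm^2 band such
#' bioreactors apply.
#'
#' @param ... Overrides passed to [wss_field_params()].
#' @return A `wss_field_params` object.
#' @export
bioreactor_preset <- function(...) {
  defaults <- list(belly_amplitude = 3.5, edge_amplitude = 3.5,
                   forward_duty = 0.5)
  args <- utils::modifyList(defaults, list(...))
  do.call(wss_field_params, args)
}

# triangulated unit disk: centre node + n_rings rings of n_theta nodes
disk_mesh <- function(n_rings, n_theta) {
  theta <- 2 * pi * (seq_len(n_theta) - 1L) / n_theta
  nodes <- tibble::tibble(node = 1L, x = 0, y = 0, z = 0, r = 0)
  for (j in seq_len(n_rings)) {
    rj <- j / n_rings
    nodes <- dplyr::bind_rows(nodes, tibble::tibble(
      node = NA_integer_, x = rj * cos(theta), y = rj * sin(theta),
      z = 0, r = rj))
  }
  nodes$node <- seq_len(nrow(nodes))
  ring_start <- function(j) 2L + (j - 1L) * n_theta
  tri <- list()
  # centre fan
  k <- seq_len(n_theta)
  kn <- c(k[-1], k[1])
  tri[[1]] <- cbind(1L, ring_start(1) + k - 1L, ring_start(1) + kn - 1L)
  # ring bands
  if (n_rings > 1L) {
    for (j in seq_len(n_rings - 1L)) {
      a <- ring_start(j) + k - 1L
      an <- ring_start(j) + kn - 1L
      b <- ring_start(j + 1L) + k - 1L
      bn <- ring_start(j + 1L) + kn - 1L
      tri[[j + 1L]] <- rbind(cbind(a, b, bn), cbind(a, bn, an))
    }
  }
  tri <- do.call(rbind, tri)
  list(nodes = nodes,
       triangles = tibble::tibble(n1 = tri[, 1], n2 = tri[, 2], n3 = tri[, 3]))
}

new_wss_field <- function(nodes, triangles, times, tau, truth = NULL,
                          params = NULL) {
  structure(list(nodes = nodes, triangles = triangles, times = times,
                 tau = tau, truth = truth, params = params),
            class = "wss_field")
}

#' Construct a wall-shear surface field from raw components
#'
#' @param nodes Tibble with columns `node`, `x`, `y`, `z` (mm).
#' @param triangles Tibble with columns `n1`, `n2`, `n3` (node indices);
#'   may be `NULL` for point-wise analyses that need no areas.
#' @param times Strictly increasing sample times spanning exactly one
#'   cycle (first and last sample one period apart).
#' @param tau Numeric array `[node, time, 3]` of WSS vectors, dynes/cm^2.
#' @return Object of class `wss_field`.
#' @export
wss_field <- function(nodes, triangles, times, tau) {
  if (length(times) < 3L || any(diff(times) <= 0)) {
    stop_data("`times` must be strictly increasing with >= 3 samples")
  }
  if (!is.array(tau) || length(dim(tau)) != 3L || dim(tau)[3] != 3L) {
    stop_data("`tau` must be an [node, time, 3] array")
  }
  if (dim(tau)[1] != nrow(nodes) || dim(tau)[2] != length(times)) {
    stop_data("`tau` dimensions must match nodes and times")
  }
  if (!all(is.finite(tau))) stop_data("`tau` contains non-finite values")
  if (!is.null(triangles)) {
    idx <- as.matrix(triangles[, c("n1", "n2", "n3")])
    if (any(idx < 1L | idx > nrow(nodes))) {
      stop_data("triangle indices out of range")
    }
  }
  new_wss_field(tibble::as_tibble(nodes), triangles, times, tau)
}

#' @export
print.wss_field <- function(x, ...) {
  cat(sprintf("wss_field: %d nodes, %s triangles, %d time samples over %.4g s\n",
              nrow(x$nodes),
              if (is.null(x$triangles)) "no" else nrow(x$triangles),
              length(x$times), diff(range(x$times))))
  invisible(x)
}

#' Generate a synthetic wall-shear-stress field on a leaflet-like surface
#'
#' @param params A [wss_field_params()] object.
#' @return A `wss_field` whose `truth` element is a tibble of per-node
#'   analytic `tawss_true` and `osi_true` (exact for the noiseless square
#'   wave under the package's periodic trapezoidal quadrature).
#' @export
#' @examples
#' f <- gen_wss_surface_field(wss_field_params(n_nodes = 60))
#' summarize_hemodynamics(f)
gen_wss_surface_field <- function(params = wss_field_params()) {
  if (!inherits(params, "wss_field_params")) {
    stop_param("`params` must be built with wss_field_params()")
  }
  p <- params
  n_theta <- 12L
  n_rings <- max(2L, round((p$n_nodes - 1) / n_theta))
  mesh <- disk_mesh(n_rings, n_theta)
  nodes <- mesh$nodes
  nn <- nrow(nodes)
  nt <- p$n_timesteps
  times <- seq(0, p$cycle_period, length.out = nt + 1L)
  m <- round(p$forward_duty * nt)
  if (m < 1L) m <- 1L
  s <- c(rep(1, m), rep(-1, nt - m), 1)   # terminal sample = first (periodic)
  if (m == nt) s <- rep(1, nt + 1L)
  amp <- p$belly_amplitude + (p$edge_amplitude - p$belly_amplitude) * nodes$r
  # fixed per-node direction: circumferential; x-direction at the centre
  dir <- cbind(-sin(atan2(nodes$y, nodes$x)),
               cos(atan2(nodes$y, nodes$x)), 0)
  dir[nodes$r == 0, ] <- rep(c(1, 0, 0), each = sum(nodes$r == 0))
  tau <- array(0, dim = c(nn, nt + 1L, 3L))
  for (k in 1:3) tau[, , k] <- outer(amp * dir[, k], s)
  if (p$noise_sd > 0) {
    tau <- with_seed(p$seed, tau + array(rnorm(length(tau), 0, p$noise_sd),
                                         dim = dim(tau)))
  }
  f_eff <- m / nt
  truth <- tibble::tibble(node = nodes$node, tawss_true = amp,
                          osi_true = 0.5 * (1 - abs(2 * f_eff - 1)))
  new_wss_field(nodes, mesh$triangles, times, tau, truth = truth, params = p)
}

#' Parameters are analytic velocity fields on a uniform structured grid
#'
#' Generates canonical velocity fields with a known Q-criterion: solid-body
#' `rotation` (interior Q = omega^2), simple `shear` (Q = 0), pure planar
#' `strain` (Q = -alpha^2), and a `lamb_oseen` vortex (Q > 0 in the core).
#'
#' @param kind One of `"rotation"`, `"shear"`, `"strain"`, `"lamb_oseen"`.
#' @param magnitude Rate parameter (angular velocity, shear rate or strain
#'   rate), 1/s.
#' @param grid_shape Integer vector of cells per axis (each >= 4).
#' @param spacing Grid spacing per axis, m.
#' @return A list of class `velocity_grid`: `velocity` array
#'   `[nx, ny, nz, 3]` (m/s), `spacing`, `coords` (axis coordinate
#'   vectors, centred on the origin), and `truth$q_interior` (1/s^2,
#'   NA where no closed form applies).
#' @export
gen_velocity_grid <- function(kind = c("rotation", "shear", "strain",
                                       "lamb_oseen"),
                              magnitude = 1,
                              grid_shape = c(9L, 9L, 5L),
                              spacing = 0.01) {
  kind <- match.arg(kind)
  check_positive(magnitude, "magnitude")
  if (length(grid_shape) == 1L) grid_shape <- rep(grid_shape, 3L)
  if (length(grid_shape) != 3L || any(grid_shape < 4L)) {
    stop_param("`grid_shape` must give >= 4 cells per axis",
               field = "grid_shape")
  }
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  ax <- lapply(seq_len(3L), function(i) {
    (seq_len(grid_shape[i]) - (grid_shape[i] + 1) / 2) * spacing[i]
  })
  g <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]])
  u <- switch(kind,
    rotation = cbind(-magnitude * g$y, magnitude * g$x, 0),
    shear = cbind(magnitude * g$y, 0 * g$x, 0),
    strain = cbind(magnitude * g$x, -magnitude * g$y, 0),
    lamb_oseen = {
      rc <- max(abs(ax[[1]])) / 2
      r2 <- g$x^2 + g$y^2
      r <- sqrt(pmax(r2, 1e-300))
      utheta <- magnitude * rc * (1 - exp(-r2 / rc^2)) / pmax(r / rc, 1e-12)
      cbind(-utheta * g$y / r, utheta * g$x / r, 0)
    })
  vel <- array(0, dim = c(grid_shape, 3L))
  for (k in 1:3) vel[, , , k] <- array(u[, k], dim = grid_shape)
  q_true <- switch(kind, rotation = magnitude^2, shear = 0,
                   strain = -magnitude^2, lamb_oseen = NA_real_)
  structure(list(velocity = vel, spacing = spacing, coords = ax,
                 kind = kind, truth = list(q_interior = q_true)),
            class = "velocity_grid")
}
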