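# periodic trapezoidal weights for a field's time grid (uniform dt assumed
# verified at construction; first and last samples are one period apart)
field_time_weights <- function(times) {
  n <- length(times)
  dt <- diff(times)
  w <- c(dt / 2, 0) + c(0, dt / 2)
  list(w = w, period = times[n] - times[1])
}

tau_magnitude <- function(field) {
  sqrt(field$tau[, , 1]^2 + field$tau[, , 2]^2 + field$tau[, , 3]^2)
}

#' Instantaneous wall shear stress from a near-wall velocity profile
#'
#' `tau_w = mu * du/dn` evaluated with a one-sided finite difference from
#' the wall (where the no-slip velocity is zero) to the first off-wall
#' sample, converted to dynes/cm^2 (1 cP x 1/s = 0.01 dynes/cm^2).
#'
#' @param velocity Tangential velocity samples, m/s; the first entry is at
#'   the wall and must be (numerically) zero.
#' @param offsets Wall-normal offsets of the samples, m; the first is 0 and
#'   the rest must be positive and increasing.
#' @param mu Dynamic viscosity, cP.
#' @return Wall shear stress, dynes/cm^2.
#' @export
#' @examples
#' wss_from_near_wall_profile(c(0, 1e-3), c(0, 1e-5), mu = 1.07)
wss_from_near_wall_profile <- function(velocity, offsets, mu = 1.07) {
  if (length(velocity) < 2L || length(velocity) != length(offsets)) {
    stop_data("need >= 2 matched velocity/offset samples")
  }
  if (offsets[1] != 0) stop_domain("first offset must be at the wall (0)")
  if (any(diff(offsets) <= 0) || any(offsets[-1] <= 0)) {
    stop_domain("off-wall offsets must be positive and increasing")
  }
  check_positive(mu, "mu")
  dudn <- (velocity[2] - velocity[1]) / offsets[2]   # 1/s
  tau_pa <- mu * 1e-3 * dudn
  tau_pa * 10
}

#' Time-averaged wall shear stress per node
#'
#' `TAWSS = (1/T) * integral over one cycle of |tau_w(t)|`, by periodic
#' trapezoidal quadrature over the field's time grid.
#'
#' @param field A [wss_field()].
#' @return Tibble with columns `node`, `tawss` (dynes/cm^2).
#' @export
compute_tawss <- function(field) {
  stopifnot(inherits(field, "wss_field"))
  if (!all(is.finite(field$tau))) stop_data("field contains non-finite values")
  tw <- field_time_weights(field$times)
  mag <- tau_magnitude(field)
  tibble::tibble(node = field$nodes$node,
                 tawss = as.numeric(mag %*% tw$w) / tw$period)
}

#' Oscillatory shear index per node
#'
#' `OSI = 0.5 * (1 - |integral of tau_w dt| / (T * TAWSS))`: 0 for purely
#' unidirectional shear, 0.5 for purely oscillatory zero-mean shear. The
#' numerator is the magnitude of the time-integrated WSS vector. Nodes with
#' zero TAWSS (no shear at all) are assigned OSI 0 by default.
#'
#' @param field A [wss_field()].
#' @param zero_tawss_value OSI value reported where TAWSS is numerically
#'   zero (default 0: no flow implies no oscillatory character).
#' @return Tibble with columns `node`, `osi` in `[0, 0.5]`.
#' @export
compute_osi <- function(field, zero_tawss_value = 0) {
  stopifnot(inherits(field, "wss_field"))
  tw <- field_time_weights(field$times)
  ints <- vapply(1:3, function(k) as.numeric(field$tau[, , k] %*% tw$w),
                 numeric(nrow(field$nodes)))
  num <- sqrt(rowSums(matrix(ints, ncol = 3L)^2))
  denom <- as.numeric(tau_magnitude(field) %*% tw$w)   # T * TAWSS
  osi <- ifelse(denom > .Machine$double.eps * max(denom, 1),
                0.5 * (1 - num / denom), zero_tawss_value)
  tibble::tibble(node = field$nodes$node, osi = osi)
}

triangle_areas <- function(nodes, triangles) {
  xyz <- as.matrix(nodes[, c("x", "y", "z")])
  a <- xyz[triangles$n1, , drop = FALSE]
  b <- xyz[triangles$n2, , drop = FALSE]
  c_ <- xyz[triangles$n3, , drop = FALSE]
  u <- b - a; v <- c_ - a
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

#' Area-weighted surface mean of a per-node quantity
#'
#' Each node is weighted by one third of the total area of its incident
#' triangles (the lumped-mass convention), so that the mean of a constant
#' field is that constant and linear fields are integrated consistently
#' under mesh refinement.
#'
#' @param values Numeric vector, one value per node (or a tibble with a
#'   `node` column and one value column, as returned by [compute_tawss()]).
#' @param field A [wss_field()] with a triangulation.
#' @return Scalar area-weighted mean.
#' @export
area_weighted_mean <- function(values, field) {
  stopifnot(inherits(field, "wss_field"))
  if (is.null(field$triangles)) stop_data("field has no triangulation")
  if (is.data.frame(values)) {
    vcol <- setdiff(names(values), "node")[1]
    values <- values[[vcol]][order(values$node)]
  }
  if (length(values) != nrow(field$nodes)) {
    stop_data("`values` must have one entry per node")
  }
  areas <- triangle_areas(field$nodes, field$triangles)
  if (sum(areas) <= 0) stop_data("degenerate surface: zero total area")
  w <- numeric(nrow(field$nodes))
  for (col in c("n1", "n2", "n3")) {
    tab <- tapply(areas, field$triangles[[col]], sum)
    idx <- as.integer(names(tab))
    w[idx] <- w[idx] + tab / 3
  }
  sum(w * values) / sum(w)
}

#' Summarise leaflet hemodynamics
#'
#' Per-node TAWSS and OSI plus their area-weighted surface means.
#'
#' @param field A [wss_field()].
#' @return List of class `hemodynamic_summary`: `per_node` tibble (`node`,
#'   `tawss`, `osi`), `tawss_mean`, `osi_mean`.
#' @export
summarize_hemodynamics <- function(field) {
  tw <- compute_tawss(field)
  os <- compute_osi(field)
  per_node <- dplyr::inner_join(tw, os, by = "node")
  structure(list(per_node = per_node,
                 tawss_mean = area_weighted_mean(tw, field),
                 osi_mean = area_weighted_mean(os, field)),
            class = "hemodynamic_summary")
}

#' @export
print.hemodynamic_summary <- function(x, ...) {
  cat(sprintf("hemodynamic summary: area-weighted TAWSS %.3f dynes/cm^2, OSI %.3f (%d nodes)\n",
              x$tawss_mean, x$osi_mean, nrow(x$per_node)))
  invisible(x)
}

# central-difference derivative of a 3-D array along axis `ax`
# (one-sided at the boundary slabs); works by rotating `ax` to the front
array_deriv <- function(a, ax, h) {
  perm <- c(ax, setdiff(1:3, ax))
  b <- aperm(a, perm)
  n <- dim(b)[1]
  out <- array(0, dim = dim(b))
  out[2:(n - 1), , ] <- (b[3:n, , , drop = FALSE] -
                           b[1:(n - 2), , , drop = FALSE]) / (2 * h)
  out[1, , ] <- (b[2, , ] - b[1, , ]) / h
  out[n, , ] <- (b[n, , ] - b[n - 1, , ]) / h
  aperm(out, order(perm))
}

#' Q-criterion vortex identification field
#'
#' Computes the velocity-gradient tensor by central differences on the
#' uniform grid (one-sided at boundaries) and returns
#' `Q = 0.5 * (|Omega|_F^2 - |S|_F^2)` per cell, where `S` and `Omega` are
#' the symmetric and antisymmetric parts of the gradient. Positive Q marks
#' rotation-dominated (vortical) flow.
#'
#' @param grid A `velocity_grid` (see [gen_velocity_grid()]).
#' @return List of class `q_field`: `q` array (1/s^2) with the grid's
#'   shape, plus `interior` (logical array marking cells where the stencil
#'   is fully central).
#' @export
compute_q_criterion <- function(grid) {
  stopifnot(inherits(grid, "velocity_grid"))
  d <- dim(grid$velocity)[1:3]
  if (any(d < 3L)) stop_data("grid too small for central differences")
  gradm <- vector("list", 9L)
  for (k in 1:3) {
    for (ax in 1:3) {
      gradm[[(k - 1) * 3 + ax]] <-
        array_deriv(grid$velocity[, , , k], ax, grid$spacing[ax])
    }
  }
  # S_ij = (g_ij + g_ji)/2, Omega_ij = (g_ij - g_ji)/2 with g_ij = du_i/dx_j
  g <- function(i, j) gradm[[(i - 1) * 3 + j]]
  s2 <- array(0, dim = d); o2 <- array(0, dim = d)
  for (i in 1:3) {
    for (j in 1:3) {
      sij <- (g(i, j) + g(j, i)) / 2
      oij <- (g(i, j) - g(j, i)) / 2
      s2 <- s2 + sij^2
      o2 <- o2 + oij^2
    }
  }
  interior <- array(FALSE, dim = d)
  interior[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <- TRUE
  structure(list(q = 0.5 * (o2 - s2), interior = interior,
                 spacing = grid$spacing),
            class = "q_field")
}
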