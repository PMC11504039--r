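test_that("near-wall profile WSS converts a 1/s gradient in cP to dynes/cm^2", {
  # linear profile u = 100 * n: gradient 100/s, so 1.07 cP -> 1.07 dynes/cm^2
  expect_equal(wss_from_near_wall_profile(c(0, 100 * 1e-4), c(0, 1e-4),
                                          mu = 1.07), 1.07,
               tolerance = 1e-12)
  expect_equal(wss_from_near_wall_profile(c(0, 0, 0), c(0, 1e-4, 2e-4)), 0)
  expect_equal(wss_from_near_wall_profile(c(0, 1e-2), c(0, 1e-4), mu = 2.14),
               2 * wss_from_near_wall_profile(c(0, 1e-2), c(0, 1e-4),
                                             mu = 1.07), tolerance = 1e-12)
  expect_error(wss_from_near_wall_profile(c(0, 1), c(0, -1e-4)),
               class = "valvebench_domain_error")
})

test_that("TAWSS matches closed forms for constant, sinusoidal and square signals", {
  times <- seq(0, 0.857, length.out = 65)
  expect_equal(single_node_field(rep(10, 65), times) |>
                 compute_tawss() |> dplyr::pull("tawss"), 10,
               tolerance = 1e-12)
  A <- 7
  s <- A * sin(2 * pi * times / 0.857)
  expect_equal(compute_tawss(single_node_field(s, times))$tawss, 2 * A / pi,
               tolerance = 1e-3)
  sq <- c(rep(A, 32), rep(-A, 32), A)
  expect_equal(compute_tawss(single_node_field(sq, times))$tawss, A,
               tolerance = 1e-12)
})

test_that("OSI hits its analytic limits including the duty-cycle closed form", {
  times <- seq(0, 0.857, length.out = 65)
  expect_equal(compute_osi(single_node_field(rep(5, 65), times))$osi, 0)
  sq <- c(rep(3, 32), rep(-3, 32), 3)
  expect_equal(compute_osi(single_node_field(sq, times))$osi, 0.5,
               tolerance = 1e-12)
  # duty 0.75: OSI = (1 - |2f - 1|)/2 = 0.25
  f75 <- gen_wss_surface_field(wss_field_params(forward_duty = 0.75,
                                                n_timesteps = 64))
  expect_equal(unique(round(compute_osi(f75)$osi, 10)), 0.25)
  # zero field: OSI defined as 0 (configurable)
  z <- single_node_field(rep(0, 65), times)
  expect_equal(compute_osi(z)$osi, 0)
  expect_equal(compute_osi(z, zero_tawss_value = NA_real_)$osi, NA_real_)
})

test_that("OSI and TAWSS satisfy their vector inequalities on random fields", {
  set.seed(7)
  for (i in 1:200) {
    f <- random_field()
    tw <- compute_tawss(f)$tawss
    osi <- compute_osi(f)$osi
    expect_true(all(osi >= 0 & osi <= 0.5))
    # TAWSS dominates the magnitude of the mean WSS vector
    w <- diff(f$times)
    wts <- (c(w, 0) + c(0, w)) / 2
    period <- max(f$times)
    mean_vec <- sapply(1:3, function(k) sum(f$tau[, , k] %*% wts) / period /
                         nrow(f$nodes))
    mean_per_node <- sapply(1:3, function(k)
      as.numeric(f$tau[, , k] %*% wts) / period)
    expect_true(all(tw + 1e-12 >= sqrt(rowSums(matrix(mean_per_node,
                                                      ncol = 3)^2))))
  }
})

test_that("TAWSS and OSI are invariant under a global rotation of the WSS vectors", {
  set.seed(12)
  f <- random_field(n_nodes = 20L)
  th <- 0.7
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rot <- f
  flat <- matrix(f$tau, ncol = 3)
  rotflat <- flat %*% t(Rz)
  rot$tau <- array(rotflat, dim = dim(f$tau))
  expect_equal(compute_tawss(rot)$tawss, compute_tawss(f)$tawss,
               tolerance = 1e-12)
  expect_equal(compute_osi(rot)$osi, compute_osi(f)$osi, tolerance = 1e-12)
})

test_that("time-quadrature error for TAWSS decays quadratically", {
  err <- vapply(c(32, 64, 128), function(nt) {
    times <- seq(0, 1, length.out = nt + 1)
    abs(compute_tawss(single_node_field(10 * sin(2 * pi * times),
                                        times))$tawss - 20 / pi)
  }, numeric(1))
  expect_equal(err[1] / err[2], 4, tolerance = 0.05)
  expect_equal(err[2] / err[3], 4, tolerance = 0.05)
})

test_that("area-weighted means integrate exactly on simple and refined meshes", {
  f <- two_patch_field()
  expect_equal(area_weighted_mean(rep(4.2, 4), f), 4.2, tolerance = 1e-12)
  # two equal-area disjoint patches valued 0 and 10 average to 5
  nodes <- tibble::tibble(node = 1:6, x = c(0, 1, 0, 3, 4, 3),
                          y = c(0, 0, 1, 0, 0, 1), z = 0)
  tris <- tibble::tibble(n1 = c(1L, 4L), n2 = c(2L, 5L), n3 = c(3L, 6L))
  times <- seq(0, 1, length.out = 9)
  tau <- array(1, dim = c(6, 9, 3))
  fld <- wss_field(nodes, tris, times, tau)
  expect_equal(area_weighted_mean(c(0, 0, 0, 10, 10, 10), fld), 5,
               tolerance = 1e-12)

  # refinement invariance for a linear field on the same disk boundary
  f1 <- gen_wss_surface_field(wss_field_params(n_nodes = 49))
  f2 <- gen_wss_surface_field(wss_field_params(n_nodes = 97))
  lin <- function(f) 2 + 3 * f$nodes$x
  expect_equal(area_weighted_mean(lin(f1), f1),
               area_weighted_mean(lin(f2), f2), tolerance = 1e-10)

  degenerate <- wss_field(tibble::tibble(node = 1:3, x = 0, y = 0, z = 0),
                          tibble::tibble(n1 = 1L, n2 = 2L, n3 = 3L),
                          seq(0, 1, length.out = 9),
                          array(1, dim = c(3, 9, 3)))
  expect_error(area_weighted_mean(rep(1, 3), degenerate),
               class = "valvebench_data_error")
})

test_that("Q-criterion separates rotation, shear and strain", {
  for (mag in c(1, 2.5)) {
    rot <- compute_q_criterion(gen_velocity_grid("rotation", mag))
    expect_equal(unique(round(rot$q[rot$interior], 9)), mag^2)
    sh <- compute_q_criterion(gen_velocity_grid("shear", mag))
    expect_equal(max(abs(sh$q[sh$interior])), 0)
    st <- compute_q_criterion(gen_velocity_grid("strain", mag))
    expect_equal(unique(round(st$q[st$interior], 9)), -mag^2)
  }
  # a concentrated vortex has positive core Q
  lo <- gen_velocity_grid("lamb_oseen", 10, grid_shape = c(17, 17, 5))
  qf <- compute_q_criterion(lo)
  centre <- qf$q[9, 9, 3]
  expect_gt(centre, 0)
})
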