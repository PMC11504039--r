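# shared fixtures built in code

iou <- function(a, b) sum(a & b) / sum(a | b)

# single-node field with an arbitrary x-component time signal
single_node_field <- function(signal, times) {
  tau <- array(0, dim = c(1L, length(times), 3L))
  tau[1, , 1] <- signal
  wss_field(tibble::tibble(node = 1L, x = 0, y = 0, z = 0),
            triangles = NULL, times = times, tau = tau)
}

# random multi-node field (no triangulation) for property checks
random_field <- function(n_nodes = 12L, n_times = 16L, period = 0.857) {
  times <- seq(0, period, length.out = n_times + 1L)
  tau <- array(rnorm(n_nodes * (n_times + 1L) * 3L),
               dim = c(n_nodes, n_times + 1L, 3L))
  tau[, n_times + 1L, ] <- tau[, 1L, ]   # periodic
  wss_field(tibble::tibble(node = seq_len(n_nodes),
                           x = runif(n_nodes), y = runif(n_nodes), z = 0),
            triangles = NULL, times = times, tau = tau)
}

# two-triangle square surface with constant per-node placeholder values
two_patch_field <- function() {
  nodes <- tibble::tibble(node = 1:4,
                          x = c(0, 1, 1, 0), y = c(0, 0, 1, 1), z = 0)
  triangles <- tibble::tibble(n1 = c(1L, 1L), n2 = c(2L, 3L), n3 = c(3L, 4L))
  times <- seq(0, 1, length.out = 9L)
  tau <- array(1, dim = c(4L, 9L, 3L))
  wss_field(nodes, triangles, times, tau)
}
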