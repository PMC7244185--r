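#' Random initial condition: uniform positions, isotropic orientations
#'
#' Positions are i.i.d. uniform on `[0, L)^d`; orientations are i.i.d. uniform
#' on the unit circle (2D, via a uniform angle) or unit sphere (3D, via
#' normalized Gaussian triples). Overlapping cells are permitted (the
#' singularity floor keeps the first forces finite), matching the published
#' initialization.
#'
#' @param N number of cells
#' @param params a [model_params]
#' @param seed integer RNG seed
#' @return a [cell_configuration] at time 0
#' @export
init_random <- function(N, params, seed = 1L) {
  stopifnot(N >= 1)
  set.seed(seed)
  pos <- matrix(stats::runif(N * params$d, 0, params$L), ncol = params$d)
  if (params$d == 2L) {
    th <- stats::runif(N, 0, 2 * pi)
    ori <- cbind(cos(th), sin(th))
  } else {
    g <- matrix(stats::rnorm(N * 3), ncol = 3)
    ori <- g / sqrt(rowSums(g^2))
  }
  cell_configuration(pos, ori, params$L)
}

#' Perfect flock initial condition
#'
#' All orientations equal `direction` and cells sit on an axis-aligned lattice
#' with spacing strictly above the semi-major axis `a`, which guarantees
#' every pairwise normalized distance exceeds 1 (no interactions) for *any*
#' common direction, since `r_ij >= ||x_j - x_i|| / a`. Such a state is a
#' fixed point of the relative dynamics: it is transported rigidly.
#'
#' @param N number of cells
#' @param params a [model_params]
#' @param seed RNG seed (used only to subsample lattice sites when the
#'   lattice holds more than `N` cells)
#' @param direction unit vector of length `d`; default `+x`
#' @return a [cell_configuration] with polarization exactly 1
#' @export
init_flock <- function(N, params, seed = 1L, direction = NULL) {
  if (is.null(direction)) direction <- c(1, rep(0, params$d - 1))
  direction <- direction / sqrt(sum(direction^2))
  spacing <- 1.02 * params$a
  m <- floor(params$L / spacing)
  if (m^params$d < N)
    stop(sprintf("infeasible packing: lattice holds %d cells, %d requested",
                 m^params$d, N))
  set.seed(seed)
  sites <- sort(sample.int(m^params$d, N))
  idx <- sites - 1L
  pos <- matrix(0, N, params$d)
  for (k in seq_len(params$d)) {
    pos[, k] <- (idx %% m) * spacing
    idx <- idx %/% m
  }
  ori <- matrix(rep(direction, each = N), N, params$d)
  cell_configuration(pos, ori, params$L)
}

#' Two-lane stream initial condition
#'
#' Cells are placed on the same non-overlapping lattice as [init_flock()] but
#' travel in `+direction` or `-direction` depending on which horizontal band
#' they occupy, producing a perfectly nematic (`gamma = J = 1`) but
#' unpolarized two-way stream.
#'
#' @inheritParams init_flock
#' @param n_bands number of alternating bands across the box
#' @return a [cell_configuration]
#' @export
init_stream <- function(N, params, seed = 1L, direction = NULL, n_bands = 2L) {
  if (is.null(direction)) direction <- c(1, rep(0, params$d - 1))
  direction <- direction / sqrt(sum(direction^2))
  config <- init_flock(N, params, seed = seed, direction = direction)
  band <- floor(config$positions[, params$d] / (params$L / n_bands))
  sgn <- ifelse(band %% 2 == 0, 1, -1)
  config$orientations <- config$orientations * sgn
  config
}

#' Advance a configuration by one explicit Euler step
#'
#' `x <- wrap(x + dt * dx/dt)`; `omega <- normalize(omega + dt * domega/dt)`.
#' The renormalization commits an `O(dt^2)` error per step. When a cell's
#' angular velocity is exactly zero (circular cells, or `beta = 0`) its
#' orientation is left bit-identical.
#'
#' @param config a [cell_configuration]
#' @param params a [model_params]
#' @param sim a [sim_config] (only `dt` and `epsilon` are used)
#' @return the configuration after one step of length `sim$dt`
#' @export
step_cells <- function(config, params, sim) {
  out <- simulate_cpp(config$positions, config$orientations,
                      params$a, params$b, params$c, params$alpha, params$beta,
                      params$L, sim$epsilon, sim$dt, 1L, 1L,
                      identical(params$descent, "total"))
  cell_configuration(array_slab(out$positions, 2L),
                     array_slab(out$orientations, 2L),
                     params$L, time = config$time + sim$dt)
}

# N x d slice of an N x d x n_rec array, robust to N = 1
array_slab <- function(arr, k) {
  matrix(arr[, , k], nrow = dim(arr)[1], ncol = dim(arr)[2])
}

#' Run the dynamics from an initial condition to the final time
#'
#' Integrates the equations of motion with explicit Euler steps of length
#' `sim$dt` from `t = 0` to `sim$T_final`, recording a snapshot every
#' `sim$record_every` hours (plus the initial state). The initial condition
#' is drawn according to `sim$init_mode` and `sim$seed` unless an explicit
#' `init` configuration is supplied. Runs are deterministic: identical
#' `(seed, sim, params, N)` reproduce the trajectory bit-for-bit.
#'
#' @param params a [model_params]
#' @param sim a [sim_config]
#' @param N number of cells
#' @param init optional [cell_configuration] overriding the seeded initial
#'   condition
#' @return an object of class `trajectory`: list with `times` (length n_rec),
#'   `positions` and `orientations` (`N x d x n_rec` arrays), and the
#'   provenance (`params`, `sim`, `N`)
#' @export
simulate_cells <- function(params, sim, N, init = NULL) {
  if (is.null(init)) {
    init <- switch(sim$init_mode,
                   random = init_random(N, params, sim$seed),
                   flock  = init_flock(N, params, sim$seed),
                   stream = init_stream(N, params, sim$seed))
  }
  stopifnot(inherits(init, "cell_configuration"), init$N == N,
            init$d == params$d)
  nsteps <- as.integer(round(sim$T_final / sim$dt))
  if (nsteps == 0L) {
    pos <- array(init$positions, c(N, params$d, 1L))
    ori <- array(init$orientations, c(N, params$d, 1L))
    out <- list(times = 0, positions = pos, orientations = ori)
  } else {
    stride <- max(1L, as.integer(round(sim$record_every / sim$dt)))
    out <- simulate_cpp(init$positions, init$orientations,
                        params$a, params$b, params$c, params$alpha,
                        params$beta, params$L, sim$epsilon,
                        sim$dt, nsteps, stride,
                        identical(params$descent, "total"))
  }
  structure(list(times = as.numeric(out$times),
                 positions = out$positions,
                 orientations = out$orientations,
                 params = params, sim = sim, N = N),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "trajectory: %d cells, %dD, %d snapshots over t = [0, %g] h (dt = %g, seed = %d)\n",
    x$N, x$params$d, length(x$times), max(x$times), x$sim$dt, x$sim$seed))
  invisible(x)
}

#' Extract one recorded snapshot of a trajectory
#'
#' @param traj a `trajectory`
#' @param index snapshot index (1-based); defaults to the last snapshot
#' @return a [cell_configuration]
#' @export
get_snapshot <- function(traj, index = length(traj$times)) {
  stopifnot(index >= 1, index <= length(traj$times))
  cell_configuration(array_slab(traj$positions, index),
                     array_slab(traj$orientations, index),
                     traj$params$L, time = traj$times[index])
}

#' Final configuration of a trajectory
#'
#' @param traj a `trajectory`
#' @return a [cell_configuration] at the last recorded time
#' @export
final_configuration <- function(traj) get_snapshot(traj)
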