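# Shared fixtures: small seeded configurations and finite-difference oracles.

default_params <- function(d = 2, a = 5.5, b = 3, alpha = 40, beta = 1,
                           L = 60, c = 10) {
  model_params(a = a, b = b, c = c, alpha = alpha, beta = beta, L = L, d = d)
}

# dense-ish random configuration so gradients are nonzero
dense_config <- function(N, params, seed) {
  set.seed(seed)
  pos <- matrix(stats::runif(N * params$d, 0, params$L), ncol = params$d)
  if (params$d == 2) {
    th <- stats::runif(N, 0, 2 * pi)
    ori <- cbind(cos(th), sin(th))
  } else {
    g <- matrix(stats::rnorm(N * 3), ncol = 3)
    ori <- g / sqrt(rowSums(g^2))
  }
  cell_configuration(pos, ori, params$L)
}

# all-pairs tension as a raw function of free position/orientation vectors,
# bypassing the unit-norm validation (for finite differencing in omega)
tension_free <- function(i, positions, orientations, params, epsilon = 1e-6) {
  acc <- 0
  for (j in seq_len(nrow(positions))) {
    if (j == i) next
    dvec <- minimum_image(positions[i, ], positions[j, ], params$L)
    s <- guard_singularity(
      (sum(dvec^2) - params$e^2 * sum(dvec * orientations[i, ])^2) / params$b^2,
      epsilon)
    acc <- acc + phi(s)
  }
  acc
}

fd_grad_x <- function(i, config, params, h = 1e-6) {
  vapply(seq_len(config$d), function(k) {
    pp <- config$positions; pp[i, k] <- pp[i, k] + h
    pm <- config$positions; pm[i, k] <- pm[i, k] - h
    (tension_free(i, pp, config$orientations, params) -
       tension_free(i, pm, config$orientations, params)) / (2 * h)
  }, numeric(1))
}

fd_grad_omega <- function(i, config, params, h = 1e-6) {
  vapply(seq_len(config$d), function(k) {
    wp <- config$orientations; wp[i, k] <- wp[i, k] + h
    wm <- config$orientations; wm[i, k] <- wm[i, k] - h
    (tension_free(i, config$positions, wp, params) -
       tension_free(i, config$positions, wm, params)) / (2 * h)
  }, numeric(1))
}

# frozen-geometry two-cell system (c = alpha = 0): measured instantaneous
# angular rate of the observing cell, used against the closed-form law
two_cell_theta_rate <- function(separation, theta, params, dt = 1e-6) {
  base <- c(params$L / 2, params$L / 2)
  dvec <- separation * c(1, 0)
  w <- c(cos(theta), sin(theta))
  cfg <- cell_configuration(rbind(base, base + dvec), rbind(w, c(0, 1)),
                            params$L)
  frozen <- model_params(a = params$a, b = params$b, c = 0, alpha = 0,
                         beta = params$beta, L = params$L, d = 2)
  s <- sim_config(dt = dt, T_final = dt, record_every = dt)
  nxt <- step_cells(cfg, frozen, s)
  w1 <- nxt$orientations[1, ]
  (atan2(w1[2], w1[1]) - theta) / dt
}

array_slab_test <- function(arr, k) {
  matrix(arr[, , k], nrow = dim(arr)[1], ncol = dim(arr)[2])
}

pair_dists <- function(pos, pairs, L) {
  vapply(seq_len(nrow(pairs)), function(r) {
    sqrt(sum(minimum_image(pos[pairs[r, 1], ], pos[pairs[r, 2], ], L)^2))
  }, numeric(1))
}

# relative comparison with an absolute floor for near-zero references
expect_close <- function(x, y, rel = 1e-5, floor = 1e-8) {
  expect_lt(max(abs(x - y) / pmax(abs(y), floor)), rel)
}
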