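test_that("minimum image displacement handles interior, wrapped and identical points", {
  expect_equal(minimum_image(c(0, 0), c(1, 0), 300), c(1, 0))
  expect_equal(minimum_image(c(1, 0), c(299, 0), 300), c(-2, 0))
  expect_equal(minimum_image(c(17, 230), c(17, 230), 300), c(0, 0))
  set.seed(1)
  for (k in 1:50) {
    p <- runif(3, 0, 120); q <- runif(3, 0, 120)
    v <- minimum_image(p, q, 120)
    expect_true(all(abs(v) <= 60))
  }
})

test_that("repulsion kernel matches its closed form and has compact support", {
  expect_identical(phi(1), 0)
  expect_identical(phi(2), 0)
  expect_equal(phi(0.5), 2 * exp(-2), tolerance = 1e-12)
  expect_error(phi(0), "guard_singularity")
  expect_error(phi(-1), "guard_singularity")
  # monotone decreasing on (0, 1), continuous into the support boundary
  s <- seq(0.05, 0.999, length.out = 200)
  expect_true(all(diff(phi(s)) < 0))
  expect_lt(phi(0.999), 1e-100)
})

test_that("kernel derivative is non-positive and matches finite differences", {
  expect_identical(phi_prime(1.5), 0)
  s <- c(0.1, 0.25, 0.5, 0.75, 0.9)
  expect_true(all(phi_prime(s) <= 0))
  h <- 1e-7
  fd <- (phi(s + h) - phi(s - h)) / (2 * h)
  expect_close(phi_prime(s), fd, rel = 1e-6)
  expect_error(phi_prime(0))
})

test_that("singularity guard floors s and is a no-op above the floor", {
  expect_equal(guard_singularity(0), 1e-6)
  expect_equal(guard_singularity(0.5), 0.5)
  expect_equal(guard_singularity(c(-1, 0.3), epsilon = 1e-4), c(1e-4, 0.3))
})

test_that("normalized distance: contact at the two semi-axes, circular limit", {
  p <- default_params()
  w <- c(cos(0.7), sin(0.7))
  expect_equal(normalized_distance_sq(p$a * w, w, p), 1, tolerance = 1e-12)
  wperp <- c(-w[2], w[1])
  expect_equal(normalized_distance_sq(p$b * wperp, w, p), 1, tolerance = 1e-12)
  pc <- default_params(a = 4, b = 4)
  d <- c(1.3, -2.1)
  expect_equal(normalized_distance_sq(d, w, pc), sum(d^2) / 16, tolerance = 1e-12)
})

test_that("component form and eccentricity form of r_ij^2 agree in 2D", {
  set.seed(7)
  n <- 1e4
  for (k in seq_len(n)) {
    b <- runif(1, 0.5, 6); a <- b + runif(1, 0, 6)
    p <- default_params(a = a, b = b)
    th <- runif(1, 0, 2 * pi); w <- c(cos(th), sin(th))
    d <- runif(2, -8, 8)
    r2_ecc <- normalized_distance_sq(d, w, p)
    wperp <- c(-w[2], w[1])
    r2_comp <- (sum(d * w) / a)^2 + (sum(d * wperp) / b)^2
    if (abs(r2_ecc - r2_comp) > 1e-12 * max(r2_comp, 1e-12))
      fail(sprintf("mismatch at draw %d: %.17g vs %.17g", k, r2_ecc, r2_comp))
  }
  succeed()
})

test_that("normalized distance is asymmetric for elongated cells, symmetric for circles", {
  p <- default_params()
  cfg <- cell_configuration(rbind(c(10, 10), c(13, 11)),
                            rbind(c(1, 0), c(0, 1)), p$L)
  d12 <- minimum_image(cfg$positions[1, ], cfg$positions[2, ], p$L)
  r12 <- normalized_distance_sq(d12, cfg$orientations[1, ], p)
  r21 <- normalized_distance_sq(-d12, cfg$orientations[2, ], p)
  expect_gt(abs(phi(guard_singularity(r12)) - phi(guard_singularity(r21))), 1e-6)
  pc <- default_params(a = 4, b = 4)
  expect_equal(normalized_distance_sq(d12, cfg$orientations[1, ], pc),
               normalized_distance_sq(-d12, cfg$orientations[2, ], pc),
               tolerance = 1e-15)
})

test_that("tension: isolated cell, single-pair closed form, compact support", {
  p <- default_params(L = 200)
  iso <- cell_configuration(rbind(c(10, 10), c(100, 100), c(150, 30)),
                            rbind(c(1, 0), c(0, 1), c(1, 0)), 200)
  for (i in 1:3) expect_identical(tension(i, iso, p), 0)
  w <- c(1, 0)
  two <- cell_configuration(rbind(c(50, 50), c(50 + p$a / sqrt(2), 50)),
                            rbind(w, w), 200)
  expect_equal(tension(1, two, p), phi(0.5), tolerance = 1e-12)
  # center distance >= a never contributes
  far <- cell_configuration(rbind(c(50, 50), c(50 + p$a, 50)), rbind(w, w), 200)
  expect_identical(tension(1, far, p), 0)
})

test_that("analytic gradients match central finite differences (2D and 3D)", {
  for (d in 2:3) {
    p <- default_params(d = d, L = 25)   # small box -> guaranteed interactions
    for (seed in 1:5) {
      cfg <- dense_config(10, p, seed)
      for (i in c(1, 5, 10)) {
        gx <- grad_x_tension(i, cfg, p)
        gw <- grad_omega_tension(i, cfg, p)
        if (max(abs(gx)) > 1e-6) expect_close(gx, fd_grad_x(i, cfg, p), rel = 1e-5)
        if (max(abs(gw)) > 1e-6) expect_close(gw, fd_grad_omega(i, cfg, p), rel = 1e-5)
      }
    }
  }
})

test_that("orientation gradient vanishes identically for circular cells", {
  p <- default_params(a = 4, b = 4, L = 25)
  cfg <- dense_config(12, p, 3)
  for (i in 1:12)
    expect_identical(grad_omega_tension(i, cfg, p), c(0, 0))
})

test_that("central repulsion for circles: the force pushes cells directly apart", {
  p <- default_params(a = 4, b = 4, L = 100)
  dvec <- c(2.5, 1.0)
  cfg <- cell_configuration(rbind(c(50, 50), c(50, 50) + dvec),
                            rbind(c(1, 0), c(0, 1)), 100)
  force <- -p$alpha * grad_x_tension(1, cfg, p)   # repulsion term of dx/dt
  cosang <- sum(force * dvec) / sqrt(sum(force^2) * sum(dvec^2))
  expect_equal(cosang, -1, tolerance = 1e-12)
})

test_that("tangent projection removes the normal component", {
  w <- c(1, 0)
  expect_equal(project_tangent(w, w), c(0, 0))
  expect_equal(project_tangent(w, c(0, 4)), c(0, 4))
  expect_equal(project_tangent(w, c(3, 4)), c(0, 4))
  set.seed(2)
  for (k in 1:20) {
    w <- rnorm(3); w <- w / sqrt(sum(w^2))
    v <- rnorm(3)
    expect_lt(abs(sum(project_tangent(w, v) * w)), 1e-12)
  }
})

test_that("cell-list interaction fields equal the all-pairs double loop", {
  for (d in 2:3) {
    p <- default_params(d = d, L = 40)
    cfg <- dense_config(50, p, 11)
    f <- interaction_fields(cfg, p)
    for (i in seq_len(50)) {
      expect_equal(f$tension[i], tension(i, cfg, p), tolerance = 1e-12)
      expect_equal(f$grad_x[i, ], grad_x_tension(i, cfg, p), tolerance = 1e-12)
      expect_equal(f$grad_omega[i, ], grad_omega_tension(i, cfg, p), tolerance = 1e-12)
    }
  }
})

test_that("total-potential descent adds the passive force and matches its own oracle", {
  p_tot <- default_params(L = 25)
  p_tot$descent <- "total"
  cfg <- dense_config(12, p_tot, 17)
  # finite difference of the SUMMED potential sum_k V_k with respect to x_i
  total_V <- function(positions) {
    acc <- 0
    for (k in seq_len(12))
      acc <- acc + tension_free(k, positions, cfg$orientations, p_tot)
    acc
  }
  h <- 1e-6
  for (i in c(2, 7)) {
    g <- grad_x_force(i, cfg, p_tot)
    fd <- vapply(1:2, function(k) {
      pp <- cfg$positions; pp[i, k] <- pp[i, k] + h
      pm <- cfg$positions; pm[i, k] <- pm[i, k] - h
      (total_V(pp) - total_V(pm)) / (2 * h)
    }, numeric(1))
    if (max(abs(g)) > 1e-4) expect_close(g, fd, rel = 1e-5)
  }
  # cell-list path agrees with the all-pairs reference in total mode
  f <- interaction_fields(cfg, p_tot)
  for (i in seq_len(12))
    expect_equal(f$grad_x[i, ], grad_x_force(i, cfg, p_tot), tolerance = 1e-12)
  # per-cell mode: grad_x_force reduces to the own-tension gradient
  p_per <- default_params(L = 25)
  expect_identical(grad_x_force(3, cfg, p_per), grad_x_tension(3, cfg, p_per))
})

test_that("rhs: free transport, rigid flock, and circular cells never steer", {
  p <- default_params(L = 200)
  one <- cell_configuration(matrix(c(20, 30), 1), matrix(c(0, 1), 1), 200)
  f <- rhs(one, p)
  expect_equal(f$dx[1, ], p$c * c(0, 1))
  expect_equal(f$domega[1, ], c(0, 0))

  flock <- init_flock(40, p, seed = 5, direction = c(1, 1))
  f <- rhs(flock, p)
  expect_equal(f$dx, matrix(rep(p$c * c(1, 1) / sqrt(2), each = 40), 40, 2),
               tolerance = 1e-14)
  expect_true(all(f$domega == 0))

  pc <- default_params(a = 4, b = 4, L = 30)
  crowd <- dense_config(40, pc, 9)
  f <- rhs(crowd, pc)
  expect_true(all(f$domega == 0))
  # each domega is orthogonal to its omega
  pe <- default_params(L = 30)
  f <- rhs(dense_config(40, pe, 9), pe)
  w <- dense_config(40, pe, 9)$orientations
  expect_lt(max(abs(rowSums(f$domega * w))), 1e-12)
})

test_that("coincident centers produce finite forces and states", {
  p <- default_params(L = 100)
  cfg <- cell_configuration(rbind(c(50, 50), c(50, 50)),
                            rbind(c(1, 0), c(0, 1)), 100)
  f <- rhs(cfg, p)
  expect_true(all(is.finite(f$dx)) && all(is.finite(f$domega)))
  s <- sim_config(dt = 0.05, T_final = 1, record_every = 1, seed = 1)
  traj <- simulate_cells(p, s, 2, init = cfg)
  expect_true(all(is.finite(traj$positions)) && all(is.finite(traj$orientations)))
})

test_that("interactions are invariant under global translation (mod L)", {
  p <- default_params(L = 80)
  cfg <- dense_config(30, p, 13)
  f0 <- rhs(cfg, p)
  set.seed(14)
  for (k in 1:5) {
    shift <- runif(2, -200, 200)
    cfg2 <- cell_configuration(sweep(cfg$positions, 2, -shift), cfg$orientations, 80)
    f1 <- rhs(cfg2, p)
    expect_equal(f1$dx, f0$dx, tolerance = 1e-12)
    expect_equal(f1$domega, f0$domega, tolerance = 1e-12)
  }
})

test_that("rhs is equivariant under global rotations (2D and 3D)", {
  rot2 <- function(t) matrix(c(cos(t), sin(t), -sin(t), cos(t)), 2, 2)
  rot3 <- function(t) {  # rotation about the z axis then x axis
    Rz <- rbind(c(cos(t), -sin(t), 0), c(sin(t), cos(t), 0), c(0, 0, 1))
    Rx <- rbind(c(1, 0, 0), c(0, cos(t / 2), -sin(t / 2)), c(0, sin(t / 2), cos(t / 2)))
    Rx %*% Rz
  }
  for (d in 2:3) {
    p <- default_params(d = d, L = 200)
    # cluster near the box center so no pair wraps before or after rotation
    set.seed(21)
    pos <- matrix(runif(12 * d, 95, 105), ncol = d)
    if (d == 2) { th <- runif(12, 0, 2 * pi); ori <- cbind(cos(th), sin(th)) }
    else { g <- matrix(rnorm(36), ncol = 3); ori <- g / sqrt(rowSums(g^2)) }
    cfg <- cell_configuration(pos, ori, 200)
    f0 <- rhs(cfg, p)
    R <- if (d == 2) rot2(0.83) else rot3(0.83)
    ctr <- rep(100, d)
    pos_r <- t(R %*% (t(pos) - ctr) + ctr)
    cfg_r <- cell_configuration(pos_r, t(R %*% t(ori)), 200)
    f1 <- rhs(cfg_r, p)
    expect_equal(f1$dx, t(R %*% t(f0$dx)), tolerance = 1e-10)
    expect_equal(f1$domega, t(R %*% t(f0$domega)), tolerance = 1e-10)
  }
})
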