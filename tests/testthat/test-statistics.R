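test_that("polarization: perfect flock, cancellation, and a 90-degree pair", {
  expect_equal(polarization(rbind(c(1, 0), c(1, 0), c(1, 0))), 1)
  expect_equal(polarization(rbind(c(1, 0), c(-1, 0))), 0)
  expect_equal(polarization(rbind(c(1, 0), c(0, 1))), sqrt(2) / 2,
               tolerance = 1e-12)
  expect_error(polarization(matrix(numeric(0), 0, 2)), "empty")
})

test_that("nematic polarization identifies +/- mixtures and 4-fold symmetry", {
  half <- rbind(c(1, 0), c(1, 0), c(-1, 0), c(-1, 0))
  expect_equal(nematic_polarization(half), 1, tolerance = 1e-12)
  four <- rbind(c(1, 0), c(0, 1), c(-1, 0), c(0, -1))
  expect_equal(nematic_polarization(four), 0, tolerance = 1e-12)
  pair45 <- rbind(c(1, 0), c(cos(pi / 4), sin(pi / 4)))
  expect_equal(nematic_polarization(pair45), cos(pi / 4), tolerance = 1e-12)
  expect_error(nematic_polarization(matrix(1 / sqrt(3), 2, 3)), "2D-only")
})

test_that("scalar nematic order: pure states, degenerate states, isotropic null", {
  u <- c(1, 2) / sqrt(5)
  mix <- rbind(u, -u, u, -u, u)
  res <- nematic_order(mix)
  expect_equal(res$J, 1, tolerance = 1e-12)
  expect_equal(abs(sum(res$direction * u)), 1, tolerance = 1e-12)
  expect_equal(nematic_order(rbind(c(1, 0), c(0, 1)))$J, 0, tolerance = 1e-12)
  set.seed(5)
  g <- matrix(rnorm(3e4), ncol = 3)
  iso <- g / sqrt(rowSums(g^2))
  expect_lte(nematic_order(iso)$J, 0.05)
})

test_that("gamma and J coincide in 2D and exceed the polarization bound", {
  set.seed(8)
  for (k in 1:20) {
    th <- runif(50, 0, 2 * pi)
    w <- cbind(cos(th), sin(th))
    g <- nematic_polarization(w)
    expect_equal(nematic_order(w)$J, g, tolerance = 1e-10)
    expect_gte(g + 1e-12, 2 * polarization(w)^2 - 1)
  }
})

test_that("order parameters are invariant under rotations, permutations and sign flips", {
  set.seed(9)
  th <- runif(40, 0, 2 * pi)
  w <- cbind(cos(th), sin(th))
  R <- matrix(c(cos(1.1), sin(1.1), -sin(1.1), cos(1.1)), 2, 2)
  wr <- t(R %*% t(w))
  expect_equal(polarization(wr), polarization(w), tolerance = 1e-12)
  expect_equal(nematic_polarization(wr), nematic_polarization(w), tolerance = 1e-12)
  perm <- sample(40)
  expect_equal(polarization(w[perm, ]), polarization(w), tolerance = 1e-15)
  flip <- sample(c(1, -1), 40, TRUE)
  expect_equal(nematic_polarization(w * flip), nematic_polarization(w),
               tolerance = 1e-12)
  expect_equal(nematic_order(w * flip)$J, nematic_order(w)$J, tolerance = 1e-12)
})

test_that("nematic coloring splits a two-way stream and is covariant in sign", {
  flock <- matrix(rep(c(1, 0), each = 10), 10, 2)
  expect_true(all(color_by_nematic(flock) == 1L))
  stream <- rbind(matrix(rep(c(1, 0), each = 5), 5, 2),
                  matrix(rep(c(-1, 0), each = 5), 5, 2))
  lab <- color_by_nematic(stream)
  expect_equal(sort(unique(lab)), c(-1L, 1L))
  expect_true(all(lab[1:5] == lab[1]) && all(lab[6:10] == -lab[1]))
  dir <- nematic_order(stream)$direction
  expect_identical(color_by_nematic(stream, dir), -color_by_nematic(stream, -dir))
})

test_that("cluster partition matches a brute-force components oracle", {
  skip_if_not_installed("igraph")
  set.seed(12)
  L <- 100
  for (d in 2:3) {
    pos <- matrix(runif(200 * d, 0, L), ncol = d)
    part <- cluster_partition(pos, R = 8, L = L)
    adj <- matrix(FALSE, 200, 200)
    for (i in 1:199) for (j in (i + 1):200) {
      v <- minimum_image(pos[i, ], pos[j, ], L)
      if (sqrt(sum(v^2)) <= 8) adj[i, j] <- adj[j, i] <- TRUE
    }
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    oracle <- igraph::components(g)$membership
    # same partition up to relabeling
    expect_equal(length(unique(part$labels)), length(unique(oracle)))
    expect_true(all(tapply(oracle, part$labels, function(x) length(unique(x))) == 1))
    expect_equal(sum(part$sizes), 200)
  }
})

test_that("clusters chain transitively and link across the periodic boundary", {
  pos <- rbind(c(10, 50), c(18, 50), c(26, 50), c(70, 70))
  part <- cluster_partition(pos, R = 8, L = 100)
  expect_equal(part$labels[1], part$labels[2])
  expect_equal(part$labels[2], part$labels[3])
  expect_false(part$labels[1] == part$labels[4])
  wrap <- rbind(c(1, 20), c(99, 20))
  expect_equal(length(unique(cluster_partition(wrap, R = 5, L = 100)$labels)), 1L)
  # all pairs farther than R: all singletons
  sparse <- rbind(c(10, 10), c(50, 50), c(90, 10))
  expect_equal(length(unique(cluster_partition(sparse, R = 5, L = 100)$labels)), 3L)
})

test_that("size-weighted mean cluster size follows its closed form", {
  mk <- function(sizes) structure(list(labels = rep(seq_along(sizes), sizes),
                                       sizes = sizes, R = 10),
                                  class = "cluster_partition")
  expect_equal(mean_cluster_size(mk(10)), 10)
  expect_equal(mean_cluster_size(mk(rep(1, 7))), 1)
  expect_equal(mean_cluster_size(mk(c(3, 1))), 2.5)
  set.seed(13)
  pos <- matrix(runif(100 * 2, 0, 50), ncol = 2)
  part <- cluster_partition(pos, R = 6, L = 50)
  expect_equal(mean_cluster_size(part),
               mean(tabulate(part$labels)[part$labels]))
})

test_that("mean cluster size grows monotonically with the linking radius", {
  set.seed(14)
  pos <- matrix(runif(150 * 2, 0, 80), ncol = 2)
  vals <- vapply(c(2, 4, 6, 8, 12, 20), function(R)
    mean_cluster_size(cluster_partition(pos, R, L = 80)), numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("order_stats and trajectory_stats assemble consistent summaries", {
  p <- default_params(L = 40)
  s <- sim_config(dt = 0.05, T_final = 2, record_every = 1, seed = 15)
  tr <- simulate_cells(p, s, 50)
  tab <- trajectory_stats(tr)
  expect_equal(nrow(tab), length(tr$times))
  expect_true(all(tab$psi >= 0 & tab$psi <= 1 + 1e-9))
  expect_true(all(tab$gamma >= 0 & tab$gamma <= 1 + 1e-9))
  expect_true(all(tab$J >= -1e-9 & tab$J <= 1 + 1e-9))
  st <- order_stats(final_configuration(tr), p)
  expect_equal(st$psi, tab$psi[nrow(tab)])
  expect_equal(st$total_potential, tab$total_potential[nrow(tab)])
})
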