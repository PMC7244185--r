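#' Sweep the (alpha, beta) plane at fixed density
#'
#' Runs `replicates` seeded simulations for every grid point of
#' `alpha_values x beta_values`, records the final-time order parameters and
#' cluster statistic of each run, and returns them in deterministic
#' `(alpha, beta, replicate)` order. Individual run failures are recorded in
#' the `error` column rather than aborting the sweep.
#'
#' The published protocol sweeps alpha in \[10, 200\] um^2/h and beta in
#' \[0.1, 10\] 1/h with 5 simulations per pair, reading statistics at
#' t = 1000 h.
#'
#' @param alpha_values,beta_values numeric grids (um^2/h, 1/h)
#' @param params_template a [model_params]; its `alpha`/`beta` are overridden
#'   at each grid point
#' @param sim a [sim_config]; `sim$seed` acts as the base seed of the seed
#'   table
#' @param N number of cells
#' @param replicates seeded runs per grid point (published count: 5)
#' @param R cluster linking radius (um)
#' @return object of class `phase_grid`: list with `raw` (one row per run:
#'   alpha, beta, replicate, seed, psi, gamma, J, mean_cluster_size, error),
#'   the grids, `N` and `replicates`
#' @export
run_sweep <- function(alpha_values, beta_values, params_template, sim, N,
                      replicates = 5L, R = 10) {
  grid <- expand.grid(beta = sort(beta_values), alpha = sort(alpha_values))
  grid <- grid[order(grid$alpha, grid$beta), c("alpha", "beta")]
  rows <- vector("list", nrow(grid) * replicates)
  k <- 0L
  for (g in seq_len(nrow(grid))) {
    for (rep_i in seq_len(replicates)) {
      k <- k + 1L
      seed_run <- sim$seed + (g - 1L) * replicates + (rep_i - 1L)
      p <- model_params(a = params_template$a, b = params_template$b,
                       c = params_template$c, alpha = grid$alpha[g],
                       beta = grid$beta[g], L = params_template$L,
                       d = params_template$d, descent = params_template$descent)
      s <- sim
      s$seed <- as.integer(seed_run)
      res <- tryCatch({
        traj <- simulate_cells(p, s, N)
        st <- order_stats(final_configuration(traj), p, R, s$epsilon)
        data.frame(alpha = grid$alpha[g], beta = grid$beta[g],
                   replicate = rep_i, seed = seed_run,
                   psi = st$psi, gamma = st$gamma, J = st$J,
                   mean_cluster_size = st$mean_cluster_size,
                   error = NA_character_)
      }, error = function(e) {
        data.frame(alpha = grid$alpha[g], beta = grid$beta[g],
                   replicate = rep_i, seed = seed_run,
                   psi = NA_real_, gamma = NA_real_, J = NA_real_,
                   mean_cluster_size = NA_real_,
                   error = conditionMessage(e))
      })
      rows[[k]] <- res
    }
  }
  structure(list(raw = do.call(rbind, rows),
                 alpha_values = sort(alpha_values),
                 beta_values = sort(beta_values),
                 N = N, replicates = replicates),
            class = "phase_grid")
}

#' @export
print.phase_grid <- function(x, ...) {
  cat(sprintf("phase_grid: %d x %d (alpha x beta) grid, N = %d, %d replicates (%d runs, %d failed)\n",
              length(x$alpha_values), length(x$beta_values), x$N,
              x$replicates, nrow(x$raw), sum(!is.na(x$raw$error))))
  invisible(x)
}

#' Loess-smoothed surface of a swept statistic
#'
#' Fits a local polynomial regression (degree 2, tricube weights) to raw
#' replicate points `(alpha_j, beta_j, value_j)` and evaluates it on a grid,
#' clipping fitted values to the statistic's valid range. Mirrors the
#' published use of 'loess' smoothing to de-noise replicate scatter before
#' thresholding regions.
#'
#' @param points data frame with columns `alpha`, `beta`, `value` (rows with
#'   missing values are dropped)
#' @param alpha_out,beta_out grid on which to evaluate the surface
#' @param span loess span (default 0.75)
#' @param degree local polynomial degree (default 2)
#' @param range clip fitted values into `[range[1], range[2]]`
#' @return data frame with columns `alpha`, `beta`, `value` on the grid
#' @export
smooth_surface <- function(points, alpha_out, beta_out, span = 0.75,
                           degree = 2, range = c(-Inf, Inf)) {
  points <- points[stats::complete.cases(points[, c("alpha", "beta", "value")]), ]
  if (nrow(points) < 10) stop("need at least 10 points to fit a surface")
  fit <- stats::loess(value ~ alpha + beta, data = points, span = span,
                      degree = degree, normalize = TRUE,
                      control = stats::loess.control(surface = "direct"))
  grid <- expand.grid(alpha = sort(alpha_out), beta = sort(beta_out))
  pred <- stats::predict(fit, newdata = grid)
  grid$value <- pmin(pmax(as.numeric(pred), range[1]), range[2])
  grid
}

#' Classify phase-diagram regions from smoothed surfaces
#'
#' Applies the published thresholds on a common grid: *flock* where
#' `psi > 0.8`; otherwise *stream* where the nematic statistic exceeds 0.7;
#' otherwise *unclassified*. Scattering (`mean cluster size < 600`) is
#' reported as an independent overlay flag because the published criterion
#' is not exclusive of the other two.
#'
#' @param psi data frame (`alpha`, `beta`, `value`) of smoothed polarization
#' @param nematic matching data frame of smoothed gamma (2D) or J (3D)
#' @param cluster matching data frame of smoothed mean cluster size
#' @param psi_threshold,nematic_threshold,cluster_threshold published
#'   defaults 0.8, 0.7, 600
#' @return data frame with `alpha`, `beta`, `label` (factor: flock, stream,
#'   unclassified) and logical `scatter`
#' @export
classify_regions <- function(psi, nematic, cluster,
                             psi_threshold = 0.8, nematic_threshold = 0.7,
                             cluster_threshold = 600) {
  stopifnot(nrow(psi) == nrow(nematic), nrow(psi) == nrow(cluster),
            all(psi$alpha == nematic$alpha), all(psi$beta == nematic$beta),
            all(psi$alpha == cluster$alpha), all(psi$beta == cluster$beta))
  label <- ifelse(psi$value > psi_threshold, "flock",
                  ifelse(nematic$value > nematic_threshold, "stream",
                         "unclassified"))
  data.frame(alpha = psi$alpha, beta = psi$beta,
             label = factor(label, levels = c("flock", "stream", "unclassified")),
             scatter = cluster$value < cluster_threshold)
}

#' Smooth and classify a completed sweep
#'
#' Convenience wrapper: smooths psi, the nematic statistic (gamma in 2D,
#' J in 3D) and the mean cluster size over the sweep's own grid, then labels
#' regions with [classify_regions()].
#'
#' @param grid a `phase_grid` from [run_sweep()]
#' @param span loess span
#' @return list with `psi`, `nematic`, `cluster` (smoothed surfaces) and
#'   `labels` (from [classify_regions()])
#' @export
classify_sweep <- function(grid, span = 0.75) {
  raw <- grid$raw
  d2 <- !all(is.na(raw$gamma))
  mk <- function(col) data.frame(alpha = raw$alpha, beta = raw$beta,
                                 value = raw[[col]])
  psi_s <- smooth_surface(mk("psi"), grid$alpha_values, grid$beta_values,
                          span = span, range = c(0, 1))
  nem_s <- smooth_surface(mk(if (d2) "gamma" else "J"),
                          grid$alpha_values, grid$beta_values,
                          span = span, range = c(0, 1))
  clu_s <- smooth_surface(mk("mean_cluster_size"),
                          grid$alpha_values, grid$beta_values,
                          span = span, range = c(1, grid$N))
  list(psi = psi_s, nematic = nem_s, cluster = clu_s,
       labels = classify_regions(psi_s, nem_s, clu_s))
}

#' Heat-map of a smoothed phase-diagram surface
#'
#' @param surface data frame (`alpha`, `beta`, `value`) as returned by
#'   [smooth_surface()]
#' @param contours contour levels to overlay (published thresholds 0.5 and
#'   0.8 for psi)
#' @param name legend title
#' @return a ggplot object
#' @export
plot_surface <- function(surface, contours = c(0.5, 0.8), name = "value") {
  ggplot2::ggplot(surface, ggplot2::aes(x = .data$alpha, y = .data$beta)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$value), breaks = contours,
                          colour = "white") +
    ggplot2::scale_fill_viridis_c(name = name) +
    ggplot2::labs(x = expression(alpha ~ (mu * m^2 / h)),
                  y = expression(beta ~ (h^-1))) +
    ggplot2::theme_minimal()
}
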