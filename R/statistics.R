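#' Polarization order parameter
#'
#' `psi = || (1/N) sum_i omega_i ||`: 1 when every cell moves in one common
#' direction (a flock), 0 for balanced opposing flows (a two-way stream) or
#' isotropic disorder.
#'
#' @param orientations `N x d` matrix of unit vectors
#' @return scalar in `[0, 1]`
#' @export
polarization <- function(orientations) {
  orientations <- as.matrix(orientations)
  if (nrow(orientations) == 0L) stop("empty orientation set")
  sqrt(sum(colMeans(orientations)^2))
}

#' Nematic polarization (2D)
#'
#' `gamma = sqrt(<cos 2 theta>^2 + <sin 2 theta>^2)` with `theta_i` the angle
#' of `omega_i` against the horizontal axis. Doubling the angle makes the
#' statistic blind to the sign of each orientation: a half-and-half mixture
#' of `omega` and `-omega` along one axis scores 1, so streams and flocks
#' both register as nematically ordered.
#'
#' @param orientations `N x 2` matrix of unit vectors
#' @return scalar in `[0, 1]`
#' @export
nematic_polarization <- function(orientations) {
  orientations <- as.matrix(orientations)
  if (nrow(orientations) == 0L) stop("empty orientation set")
  if (ncol(orientations) != 2L)
    stop("nematic_polarization is 2D-only; use nematic_order for d = 3")
  th <- atan2(orientations[, 2], orientations[, 1])
  sqrt(mean(cos(2 * th))^2 + mean(sin(2 * th))^2)
}

#' Scalar nematic order parameter and nematic mean direction (any dimension)
#'
#' Builds the second-moment matrix `M = (1/N) sum_i omega_i x omega_i` and
#' returns `J = (d lambda_max - 1) / (d - 1)` together with the leading
#' eigenvector (the nematic mean direction, fixed up to sign; the first
#' nonzero component is made nonnegative). `J` is 1 for any +/- mixture along
#' one axis and tends to 0 for isotropic orientations. In 2D, `J` coincides
#' with [nematic_polarization()].
#'
#' @param orientations `N x d` matrix of unit vectors
#' @return list with `J` (scalar) and `direction` (unit vector)
#' @export
nematic_order <- function(orientations) {
  orientations <- as.matrix(orientations)
  N <- nrow(orientations)
  if (N == 0L) stop("empty orientation set")
  d <- ncol(orientations)
  M <- crossprod(orientations) / N
  es <- eigen(M, symmetric = TRUE)
  v <- es$vectors[, 1]
  nz <- which(abs(v) > 1e-12)
  if (length(nz) && v[nz[1]] < 0) v <- -v
  list(J = (d * es$values[1] - 1) / (d - 1), direction = v)
}

#' Sign labels relative to the nematic mean direction
#'
#' Labels each cell `+1` if its orientation has nonnegative inner product
#' with the nematic mean direction and `-1` otherwise (an exact-zero inner
#' product is labeled `+1`; a measure-zero tie-break). Used to color
#' opposing lanes of a stream.
#'
#' @param orientations `N x d` matrix of unit vectors
#' @param direction optional nematic direction; computed via [nematic_order()]
#'   when missing
#' @return integer vector of `+1` / `-1`
#' @export
color_by_nematic <- function(orientations, direction = NULL) {
  orientations <- as.matrix(orientations)
  if (is.null(direction)) direction <- nematic_order(orientations)$direction
  ifelse(as.vector(orientations %*% direction) >= 0, 1L, -1L)
}

#' Cluster partition at a linking radius
#'
#' Two cells are linked when their minimum-image distance is at most `R`;
#' clusters are the connected components of this relation (paths of linked
#' cells). Computed exactly with union-find over grid-binned candidate pairs.
#'
#' @param positions `N x d` matrix (um)
#' @param R linking radius (um); published default 10
#' @param L periodic box side (um)
#' @return object of class `cluster_partition`: list with `labels`
#'   (cluster id per cell, 1-based), `sizes` (cells per cluster) and `R`
#' @export
cluster_partition <- function(positions, R = 10, L) {
  stopifnot(R > 0, L > 0)
  labels <- cluster_labels_cpp(as.matrix(positions), R, L)
  structure(list(labels = labels,
                 sizes = as.integer(table(labels)),
                 R = R),
            class = "cluster_partition")
}

#' Size-weighted mean cluster size
#'
#' The expected size of the cluster containing a randomly chosen *cell*:
#' `(1/N) sum_i |C(x_i)| = sum_k |C_k|^2 / N`. Not the average over clusters;
#' a single spanning cluster of N cells scores N, N singletons score 1.
#'
#' @param partition a [cluster_partition]
#' @return scalar in `[1, N]`
#' @export
mean_cluster_size <- function(partition) {
  sum(partition$sizes^2) / sum(partition$sizes)
}

#' Total potential of a configuration
#'
#' The monitored energy `sum_i V_i` (the sum of per-cell tensions; because
#' the normalized distance is asymmetric this is the sum of both ordered
#' pair contributions).
#'
#' @param config a [cell_configuration]
#' @param params a [model_params]
#' @param epsilon singularity floor
#' @return scalar
#' @export
total_potential <- function(config, params, epsilon = 1e-6) {
  sum(interaction_fields(config, params, epsilon)$tension)
}

#' Order parameters and spatial statistics of one configuration
#'
#' Computes the polarization `psi`, 2D nematic polarization `gamma` (NA in
#' 3D), scalar nematic order `J` with its mean direction, the size-weighted
#' mean cluster size at radius `R`, and the total potential.
#'
#' @param config a [cell_configuration]
#' @param params a [model_params]
#' @param R cluster linking radius (um)
#' @param epsilon singularity floor
#' @return object of class `order_stats` (a list)
#' @export
order_stats <- function(config, params, R = 10, epsilon = 1e-6) {
  w <- config$orientations
  nem <- nematic_order(w)
  part <- cluster_partition(config$positions, R, params$L)
  structure(list(
    psi = polarization(w),
    gamma = if (config$d == 2L) nematic_polarization(w) else NA_real_,
    J = nem$J,
    nematic_direction = nem$direction,
    mean_cluster_size = mean_cluster_size(part),
    total_potential = total_potential(config, params, epsilon),
    time = config$time), class = "order_stats")
}

#' @export
print.order_stats <- function(x, ...) {
  cat(sprintf(
    "order_stats (t = %g h): psi = %.3f, gamma = %s, J = %.3f, mean cluster = %.1f, potential = %.3g\n",
    x$time, x$psi,
    if (is.na(x$gamma)) "NA (3D)" else sprintf("%.3f", x$gamma),
    x$J, x$mean_cluster_size, x$total_potential))
  invisible(x)
}

#' Order-parameter time course of a trajectory
#'
#' Evaluates [order_stats()] at every recorded snapshot.
#'
#' @param traj a `trajectory`
#' @param R cluster linking radius (um)
#' @return data frame with columns `time`, `psi`, `gamma`, `J`,
#'   `mean_cluster_size`, `total_potential`
#' @export
trajectory_stats <- function(traj, R = 10) {
  rows <- lapply(seq_along(traj$times), function(k) {
    st <- order_stats(get_snapshot(traj, k), traj$params, R,
                      traj$sim$epsilon)
    data.frame(time = st$time, psi = st$psi, gamma = st$gamma, J = st$J,
               mean_cluster_size = st$mean_cluster_size,
               total_potential = st$total_potential)
  })
  do.call(rbind, rows)
}
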