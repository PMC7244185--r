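#' Minimum-image displacement in a periodic box
#'
#' Returns `q - p` with every component shifted by a multiple of `L` so that
#' it lies in `[-L/2, L/2]`; its norm is the true periodic distance.
#'
#' @param p,q numeric vectors of equal length (um)
#' @param L box side (um)
#' @return displacement vector (um)
#' @examples
#' minimum_image(c(1, 0), c(299, 0), 300)  # c(-2, 0)
#' @export
minimum_image <- function(p, q, L) {
  v <- q - p
  v - L * round(v / L)
}

#' Repulsion kernel
#'
#' The tension contributed by one neighbor at squared normalized distance `s`:
#' `(1/s) exp(-1/(1-s))` for `0 < s < 1` and `0` for `s >= 1`. The kernel is
#' smooth at `s = 1` (all derivatives vanish), monotone decreasing, and
#' diverges as `1/s` at the origin, which is why callers apply
#' [guard_singularity()] first.
#'
#' @param s squared normalized distance (dimensionless, > 0)
#' @return kernel value
#' @export
phi <- function(s) {
  if (any(s <= 0)) stop("phi is undefined for s <= 0; apply guard_singularity first")
  ifelse(s >= 1, 0, exp(-1 / (1 - s)) / s)
}

#' Derivative of the repulsion kernel
#'
#' `d/ds [(1/s) exp(-1/(1-s))]` on `(0, 1)`, `0` for `s >= 1`. Non-positive
#' everywhere on its domain, which makes the interaction purely repulsive.
#'
#' @inheritParams phi
#' @return derivative value
#' @export
phi_prime <- function(s) {
  if (any(s <= 0)) stop("phi_prime is undefined for s <= 0; apply guard_singularity first")
  ifelse(s >= 1, 0, exp(-1 / (1 - s)) * (-1 / s^2 - 1 / (s * (1 - s)^2)))
}

#' Floor the squared normalized distance away from the singularity
#'
#' The kernel diverges as 1/s when two centers coincide; random initial
#' conditions can place centers arbitrarily close. Flooring `s` at `epsilon`
#' caps the kernel and its derivative so forces stay finite.
#'
#' @param s squared normalized distance
#' @param epsilon positive floor (default 1e-6)
#' @return `max(s, epsilon)`, vectorized
#' @export
guard_singularity <- function(s, epsilon = 1e-6) {
  stopifnot(epsilon > 0)
  pmax(s, epsilon)
}

#' Squared normalized distance between an ordered pair of cells
#'
#' For displacement `dvec = x_j - x_i` (minimum image) and the orientation
#' `omega_i` of the *observing* cell,
#' `r_ij^2 = (||dvec||^2 - e^2 (dvec . omega_i)^2) / b^2`.
#' In 2D this equals the component form
#' `|<dvec, omega>/a|^2 + |<dvec, omega_perp>/b|^2`. It is not symmetric in
#' i and j unless `e = 0`, in which case it reduces to `||dvec||/a` squared.
#'
#' @param dvec minimum-image displacement `x_j - x_i` (um)
#' @param omega_i unit orientation of cell i
#' @param params a [model_params]
#' @return squared normalized distance (dimensionless)
#' @export
normalized_distance_sq <- function(dvec, omega_i, params) {
  (sum(dvec^2) - params$e^2 * sum(dvec * omega_i)^2) / params$b^2
}

#' Tension exerted on one cell by its neighbors
#'
#' `V_i = sum_{j != i} phi(r_ij^2)` with minimum-image displacements. Only
#' neighbors with center distance below `a` can contribute (compact support).
#'
#' This is the plain all-pairs reference evaluation; whole-configuration
#' quantities used by the integrator go through the cell-list path in
#' [interaction_fields()].
#'
#' @param i cell index (1-based)
#' @param config a [cell_configuration]
#' @param params a [model_params]
#' @param epsilon singularity floor
#' @return scalar tension
#' @export
tension <- function(i, config, params, epsilon = 1e-6) {
  x <- config$positions
  acc <- 0
  for (j in seq_len(config$N)) {
    if (j == i) next
    dvec <- minimum_image(x[i, ], x[j, ], params$L)
    s <- guard_singularity(
      normalized_distance_sq(dvec, config$orientations[i, ], params), epsilon)
    acc <- acc + phi(s)
  }
  acc
}

#' Spatial gradient of a cell's tension
#'
#' Analytic gradient of `V_i` with respect to `x_i`, holding all other
#' positions and all orientations fixed:
#' `grad_x r_ij^2 = (2/b^2)(-dvec + e^2 (dvec . omega_i) omega_i)`, summed
#' with weights `phi_prime(r_ij^2)`. Units 1/um.
#'
#' @inheritParams tension
#' @return gradient vector of length `d`
#' @export
grad_x_tension <- function(i, config, params, epsilon = 1e-6) {
  x <- config$positions
  w <- config$orientations[i, ]
  g <- numeric(config$d)
  for (j in seq_len(config$N)) {
    if (j == i) next
    dvec <- minimum_image(x[i, ], x[j, ], params$L)
    s <- guard_singularity(normalized_distance_sq(dvec, w, params), epsilon)
    if (s >= 1) next
    g <- g + phi_prime(s) * (2 / params$b^2) *
      (-dvec + params$e^2 * sum(dvec * w) * w)
  }
  g
}

#' Orientation gradient of a cell's tension
#'
#' Analytic gradient of `V_i` with respect to `omega_i` treated as a free
#' vector (the tangent projection is applied separately by the equations of
#' motion): `grad_omega r_ij^2 = -(2 e^2 / b^2)(dvec . omega_i) dvec`.
#' Identically zero for circular cells (`e = 0`): rotating a circle cannot
#' change its tension.
#'
#' @inheritParams tension
#' @return gradient vector of length `d`
#' @export
grad_omega_tension <- function(i, config, params, epsilon = 1e-6) {
  x <- config$positions
  w <- config$orientations[i, ]
  g <- numeric(config$d)
  for (j in seq_len(config$N)) {
    if (j == i) next
    dvec <- minimum_image(x[i, ], x[j, ], params$L)
    s <- guard_singularity(normalized_distance_sq(dvec, w, params), epsilon)
    if (s >= 1) next
    g <- g - phi_prime(s) * (2 * params$e^2 / params$b^2) * sum(dvec * w) * dvec
  }
  g
}

#' Spatial gradient entering the repulsion force
#'
#' Under `descent = "per_cell"` this is exactly [grad_x_tension()]. Under
#' `descent = "total"` it adds, for every neighbor j, the passive term
#' `grad_x_i Phi(r_ji^2) = phi_prime(r_ji^2) (2/b^2)(-dvec + e^2 (dvec . omega_j) omega_j)`
#' (with `dvec = x_j - x_i`), so that the repulsion part of the dynamics is an
#' exact gradient descent of the summed potential `sum_k V_k`.
#'
#' @inheritParams tension
#' @return gradient vector of length `d`
#' @export
grad_x_force <- function(i, config, params, epsilon = 1e-6) {
  g <- grad_x_tension(i, config, params, epsilon)
  if (identical(params$descent, "total")) {
    x <- config$positions
    for (j in seq_len(config$N)) {
      if (j == i) next
      dvec <- minimum_image(x[i, ], x[j, ], params$L)
      wj <- config$orientations[j, ]
      s <- guard_singularity(normalized_distance_sq(-dvec, wj, params), epsilon)
      if (s >= 1) next
      g <- g + phi_prime(s) * (2 / params$b^2) *
        (-dvec + params$e^2 * sum(dvec * wj) * wj)
    }
  }
  g
}

#' Project a vector onto the tangent plane of a unit orientation
#'
#' `P_omega v = v - <v, omega> omega`, the projector that keeps orientation
#' updates on the unit sphere.
#'
#' @param omega unit vector
#' @param v vector of the same length
#' @return tangent vector orthogonal to `omega`
#' @export
project_tangent <- function(omega, v) {
  v - sum(v * omega) * omega
}

#' Tension, spatial gradients and orientation gradients for all cells
#'
#' Fast whole-configuration evaluation via cell-list neighbor search
#' (bin size >= `a`, exploiting the compact support of the kernel: pairs at
#' center distance >= `a` never interact). Identical, up to floating-point
#' associativity, to looping [tension()], [grad_x_tension()] and
#' [grad_omega_tension()] over all cells.
#'
#' @param config a [cell_configuration]
#' @param params a [model_params]
#' @param epsilon singularity floor
#' @return list with `tension` (length N), `grad_x` (N x d), `grad_omega` (N x d);
#'   `grad_x` honors `params$descent` (see [grad_x_force()]), `tension` and
#'   `grad_omega` are descent-independent
#' @export
interaction_fields <- function(config, params, epsilon = 1e-6) {
  interaction_fields_cpp(config$positions, config$orientations,
                         params$a, params$b, params$L, epsilon,
                         identical(params$descent, "total"))
}

#' Right-hand side of the equations of motion
#'
#' `dx_i/dt = c omega_i - alpha grad_x` (self-propulsion plus repulsion,
#' with `grad_x` per [grad_x_force()] honoring `params$descent`) and
#' `domega_i/dt = -beta P_omega(grad_omega V_i)` (steering). Each
#' orientation velocity is orthogonal to its orientation, so the flow stays
#' on the unit sphere.
#'
#' @param config a [cell_configuration]
#' @param params a [model_params]
#' @param epsilon singularity floor
#' @return list with `dx` and `domega`, both `N x d`
#' @export
rhs <- function(config, params, epsilon = 1e-6) {
  f <- interaction_fields(config, params, epsilon)
  w <- config$orientations
  dx <- params$c * w - params$alpha * f$grad_x
  tang <- f$grad_omega - rowSums(f$grad_omega * w) * w
  list(dx = dx, domega = -params$beta * tang)
}
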