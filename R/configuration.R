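#' Cell configuration: positions and unit orientations in a periodic box
#'
#' The dynamical state of the system: an `N x d` matrix of positions wrapped
#' into `[0, L)^d` and an `N x d` matrix of unit orientation vectors, plus the
#' current time. Constructing the object validates unit norms (to 1e-9) and
#' wraps positions.
#'
#' @param positions numeric `N x d` matrix (um)
#' @param orientations numeric `N x d` matrix of unit vectors
#' @param L periodic box side (um)
#' @param time current time (h)
#' @return object of class `cell_configuration`
#' @export
cell_configuration <- function(positions, orientations, L, time = 0) {
  positions <- as.matrix(positions)
  orientations <- as.matrix(orientations)
  if (!all(dim(positions) == dim(orientations)))
    stop("positions and orientations must have identical dimensions")
  if (nrow(positions) < 1L) stop("need at least one cell")
  if (!ncol(positions) %in% c(2L, 3L)) stop("dimension must be 2 or 3")
  nrm <- sqrt(rowSums(orientations^2))
  if (any(abs(nrm - 1) > 1e-9))
    stop("orientations must be unit vectors (norm within 1e-9 of 1)")
  structure(list(positions = wrap_box(positions, L),
                 orientations = orientations,
                 L = L, time = time,
                 N = nrow(positions), d = ncol(positions)),
            class = "cell_configuration")
}

#' @export
print.cell_configuration <- function(x, ...) {
  cat(sprintf("cell_configuration: %d cells in a %dD periodic box of side %g um (t = %g h)\n",
              x$N, x$d, x$L, x$time))
  invisible(x)
}

#' Wrap coordinates into the half-open periodic box [0, L)
#'
#' @param x numeric vector or matrix of coordinates (um)
#' @param L box side (um)
#' @return same shape as `x`, componentwise reduced modulo `L` into `[0, L)`
#' @export
wrap_box <- function(x, L) {
  out <- x - L * floor(x / L)
  out[out >= L] <- out[out >= L] - L   # floor rounding can land exactly on L
  out
}
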