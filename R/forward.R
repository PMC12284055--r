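# 2D finite-element forward solver: boundary voltages for the adjacent
# protocol and the adjoint conductivity Jacobian.

#' Assemble the P1 stiffness matrix
#'
#' Standard linear-triangle assembly of the weak form of
#' `div(sigma grad u) = 0` with unit sheet thickness.
#'
#' @param mesh A [disk_mesh()].
#' @param sigma Per-element conductivity vector (S/m), all positive.
#' @return Sparse symmetric `N x N` stiffness matrix.
#' @keywords internal
assemble_stiffness <- function(mesh, sigma) {
  tri <- mesh$triangles
  m <- nrow(tri)
  if (length(sigma) != m) stop("sigma must have one value per element")
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop("conductivities must be finite and positive")
  nd <- mesh$nodes
  x <- matrix(nd[tri, 1L], ncol = 3L)
  y <- matrix(nd[tri, 2L], ncol = 3L)
  # shape-function gradient coefficients
  b <- cbind(y[, 2] - y[, 3], y[, 3] - y[, 1], y[, 1] - y[, 2])
  c_ <- cbind(x[, 3] - x[, 2], x[, 1] - x[, 3], x[, 2] - x[, 1])
  coef <- sigma / (4 * mesh$areas)
  ii <- jj <- xx <- vector("list", 9L)
  t <- 0L
  for (a in 1:3) for (bq in 1:3) {
    t <- t + 1L
    ii[[t]] <- tri[, a]
    jj[[t]] <- tri[, bq]
    xx[[t]] <- coef * (b[, a] * b[, bq] + c_[, a] * c_[, bq])
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(nrow(nd), nrow(nd)))
}

# Factorizable augmented system enforcing the zero-mean potential gauge via
# a Lagrange multiplier.  Returns node potentials for each RHS column.
.solve_gauged <- function(K, rhs) {
  n <- nrow(K)
  one <- Matrix::Matrix(1, nrow = n, ncol = 1)
  A <- rbind(cbind(K, one), cbind(Matrix::t(one), Matrix::Matrix(0, 1, 1)))
  B <- as.matrix(rbind(rhs, matrix(0, 1, ncol(rhs))))
  U <- as.matrix(Matrix::solve(A, B))
  U[seq_len(n), , drop = FALSE]
}

#' Solve the forward problem for one drive pair
#'
#' Point current injection `+I` / `-I` at the two drive electrodes of a
#' conductivity field on the disk, with the zero-mean potential gauge.
#'
#' @param mesh A [disk_mesh()].
#' @param sigma Per-element conductivity (S/m).
#' @param drive Length-2 vector of electrode indices (1-based): current
#'   enters at `drive[1]`, leaves at `drive[2]`.
#' @param current_a Drive current amplitude in amperes (> 0).
#' @return Numeric vector of node potentials (volts), zero mean.
#' @export
solve_forward <- function(mesh, sigma, drive, current_a = 1) {
  stopifnot(length(drive) == 2L, current_a > 0)
  K <- assemble_stiffness(mesh, sigma)
  rhs <- matrix(0, nrow(mesh$nodes), 1L)
  rhs[mesh$electrode_nodes[drive[1L]], 1L] <- current_a
  rhs[mesh$electrode_nodes[drive[2L]], 1L] <- -current_a
  drop(.solve_gauged(K, rhs))
}

# Potentials for all n consecutive-pair injections at current I: column p is
# the field with +I at electrode p and -I at electrode p+1 (mod n).  These
# fields serve both as drive fields and, scaled by 1/I, as the adjoint
# measurement fields of the same pairs.
.pair_fields <- function(mesh, sigma, current_a = 1) {
  n <- mesh$layout$n_electrodes
  K <- assemble_stiffness(mesh, sigma)
  rhs <- matrix(0, nrow(mesh$nodes), n)
  for (p in seq_len(n)) {
    rhs[mesh$electrode_nodes[p], p] <- rhs[mesh$electrode_nodes[p], p] + current_a
    q <- if (p == n) 1L else p + 1L
    rhs[mesh$electrode_nodes[q], p] <- rhs[mesh$electrode_nodes[q], p] - current_a
  }
  .solve_gauged(K, rhs)
}

# Signed differential voltages u(meas_b) - u(meas_a) for every pattern row.
.signed_protocol_voltages <- function(U, mesh, pattern) {
  en <- mesh$electrode_nodes
  vapply(seq_len(nrow(pattern)), function(r) {
    u <- U[, pattern$drive_index[r]]
    u[en[pattern$meas_b[r]]] - u[en[pattern$meas_a[r]]]
  }, numeric(1))
}

#' Protocol boundary voltages
#'
#' Differential voltage magnitudes for every drive/measure combination of
#' the adjacent pattern, flattened drive-major (length `n*(n-3)`, 40 for 8
#' electrodes).  Magnitudes follow the RMS-demodulator convention: the DC
#' forward model stands in for the envelope of the sinusoidal excitation on
#' a purely resistive phantom.
#'
#' @param mesh A [disk_mesh()].
#' @param sigma Per-element conductivity (S/m).
#' @param pattern An [adjacent_pattern()] consistent with the mesh layout.
#' @param current_a Drive current amplitude in amperes.
#' @return Numeric vector of voltage magnitudes (volts).
#' @export
protocol_voltages <- function(mesh, sigma, pattern = adjacent_pattern(mesh$layout),
                              current_a = 1) {
  U <- .pair_fields(mesh, sigma, current_a)
  abs(.signed_protocol_voltages(U, mesh, pattern))
}

#' Conductivity sensitivity Jacobian (adjoint method)
#'
#' `J[m, e]` is the derivative of measurement `m` (a voltage magnitude)
#' with respect to the conductivity of element `e`, evaluated at `sigma`.
#' Computed from the adjoint identity: for drive field `u` and measurement
#' field `w` (unit current through the measurement pair),
#' `dV/dsigma_e = -area_e * grad(u) . grad(w)`; rows are then signed so the
#' derivative applies to the magnitude convention of
#' [protocol_voltages()].
#'
#' @inheritParams protocol_voltages
#' @return `n_meas x n_elements` matrix (class `matrix`), with attribute
#'   `signed_v` holding the signed voltages at `sigma`.
#' @export
eit_jacobian <- function(mesh, sigma, pattern = adjacent_pattern(mesh$layout),
                         current_a = 1) {
  U <- .pair_fields(mesh, sigma, current_a)
  tri <- mesh$triangles
  nd <- mesh$nodes
  b <- cbind(nd[tri[, 2L], 2L] - nd[tri[, 3L], 2L],
             nd[tri[, 3L], 2L] - nd[tri[, 1L], 2L],
             nd[tri[, 1L], 2L] - nd[tri[, 2L], 2L])
  c_ <- cbind(nd[tri[, 3L], 1L] - nd[tri[, 2L], 1L],
              nd[tri[, 1L], 1L] - nd[tri[, 3L], 1L],
              nd[tri[, 2L], 1L] - nd[tri[, 1L], 1L])
  inv2a <- 1 / (2 * mesh$areas)
  grad_of <- function(u) {
    um <- matrix(u[tri], ncol = 3L)
    cbind(rowSums(um * b) * inv2a, rowSums(um * c_) * inv2a)
  }
  gx <- apply(U, 2L, function(u) grad_of(u)[, 1L])
  gy <- apply(U, 2L, function(u) grad_of(u)[, 2L])
  v_signed <- .signed_protocol_voltages(U, mesh, pattern)
  n_meas <- nrow(pattern)
  J <- matrix(0, n_meas, nrow(tri))
  for (r in seq_len(n_meas)) {
    d <- pattern$drive_index[r]
    p <- pattern$meas_a[r]   # pair field p drives (p, p+1), same pair as (meas_a, meas_b)
    # measurement field w = -U[, p]/I (unit current entering at meas_b),
    # so dV_signed/dsigma_e = +area_e * grad(u_d).grad(U_p) / I
    row <- mesh$areas * (gx[, d] * gx[, p] + gy[, d] * gy[, p]) / current_a
    J[r, ] <- sign(v_signed[r]) * row
  }
  attr(J, "signed_v") <- v_signed
  J
}

#' Analytic potential of a homogeneous disk with boundary point drive
#'
#' Closed-form solution of the homogeneous disk with point current injection
#' at two boundary locations: `u(x) = I/(pi*sigma) * (ln|x - x_minus| -
#' ln|x - x_plus|)` (unit sheet thickness).  A boundary source on a circle
#' is its own mirror image, so the two-logarithm field satisfies the
#' insulating boundary condition exactly away from the drive points.
#'
#' @param points n x 2 matrix of evaluation coordinates (meters).
#' @param source_xy,sink_xy Length-2 coordinates of the current injection
#'   (`+I`) and extraction (`-I`) points on the boundary.
#' @param sigma Conductivity (S/m).
#' @param current_a Drive current in amperes.
#' @return Potential at each point, volts (defined up to a constant).
#' @export
analytic_disk_potential <- function(points, source_xy, sink_xy, sigma,
                                    current_a = 1) {
  points <- matrix(as.numeric(points), ncol = 2L)
  dplus <- sqrt((points[, 1L] - source_xy[1L])^2 +
                  (points[, 2L] - source_xy[2L])^2)
  dminus <- sqrt((points[, 1L] - sink_xy[1L])^2 +
                   (points[, 2L] - sink_xy[2L])^2)
  current_a / (pi * sigma) * (log(dminus) - log(dplus))
}
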