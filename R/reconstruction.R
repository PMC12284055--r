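# Time-difference image reconstruction: normalized voltage differences, the
# linear pixel-space reconstruction operator, and iterative Gauss-Newton
# with smoothed total-variation regularization.

#' Normalized voltage differences
#'
#' Elementwise relative change of the inhomogeneous frame against the
#' homogeneous reference: `dv(k) = (vnh(k) - vh(k)) / vh(k)`.
#'
#' @param vh Reference (homogeneous) measurement vector, no zero entries.
#' @param vnh Inhomogeneous measurement vector of the same length.
#' @return Dimensionless difference vector.
#' @examples
#' normalized_difference(c(0.10, 0.20), c(0.11, 0.19))  # 0.1 -0.05
#' @export
normalized_difference <- function(vh, vnh) {
  if (length(vh) != length(vnh)) stop("vh and vnh must have equal length")
  if (any(vh == 0)) stop("reference channel dead: vh contains zero")
  (vnh - vh) / vh
}

#' Square pixel grid over the tank disk
#'
#' @param radius_m Tank radius; the grid spans `[-radius, radius]^2`.
#' @param n Pixels per side (default 32).
#' @return List with pixel-center coordinate vectors `xc`, `yc`, the pixel
#'   size, and the in-disk `mask` (n x n logical, by pixel center).
#' @export
pixel_grid <- function(radius_m, n = 32L) {
  px <- 2 * radius_m / n
  xc <- -radius_m + (seq_len(n) - 0.5) * px
  centers <- expand.grid(x = xc, y = xc)
  mask <- matrix(sqrt(centers$x^2 + centers$y^2) <= radius_m, n, n)
  list(xc = xc, yc = xc, n = as.integer(n), pixel_m = px, mask = mask)
}

# Sparse pixel <- element interpolation matrix (n^2 x n_elements): each
# pixel averages the elements found under a sub-sampled stencil of its
# area; pixels outside the disk get zero rows.
.element_pixel_map <- function(mesh, grid, subsample = 3L) {
  n <- grid$n
  off <- ((seq_len(subsample) - 0.5) / subsample - 0.5) * grid$pixel_m
  ii <- jj <- xx <- list()
  t <- 0L
  for (iy in seq_len(n)) for (ix in seq_len(n)) {
    if (!grid$mask[ix, iy]) next
    pts <- as.matrix(expand.grid(x = grid$xc[ix] + off, y = grid$yc[iy] + off))
    el <- locate_points(mesh, pts)
    el <- el[!is.na(el)]
    if (length(el) == 0L)
      el <- which.min((mesh$centroids[, 1L] - grid$xc[ix])^2 +
                        (mesh$centroids[, 2L] - grid$yc[iy])^2)
    w <- table(el) / length(el)
    t <- t + 1L
    ii[[t]] <- rep((iy - 1L) * n + ix, length(w))
    jj[[t]] <- as.integer(names(w))
    xx[[t]] <- as.numeric(w)
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(n * n, nrow(mesh$triangles)))
}

# Element adjacency (shared-edge) graph as an edge list (two columns).
.element_edges <- function(mesh) {
  tri <- mesh$triangles
  m <- nrow(tri)
  e1 <- rbind(tri[, c(1L, 2L)], tri[, c(2L, 3L)], tri[, c(3L, 1L)])
  key <- paste(pmin(e1[, 1L], e1[, 2L]), pmax(e1[, 1L], e1[, 2L]))
  el <- rep(seq_len(m), 3L)
  sp <- split(el, key)
  pairs <- sp[lengths(sp) == 2L]
  do.call(rbind, pairs)
}

# Discrete Laplacian over the element adjacency graph.
.element_laplacian <- function(mesh) {
  ed <- .element_edges(mesh)
  m <- nrow(mesh$triangles)
  A <- Matrix::sparseMatrix(i = c(ed[, 1L], ed[, 2L]),
                            j = c(ed[, 2L], ed[, 1L]), x = 1,
                            dims = c(m, m))
  Matrix::Diagonal(m, Matrix::rowSums(A)) - A
}

# Edge-difference operator (n_edges x n_elements).
.edge_difference <- function(mesh) {
  ed <- .element_edges(mesh)
  Matrix::sparseMatrix(i = rep(seq_len(nrow(ed)), 2L),
                       j = c(ed[, 1L], ed[, 2L]),
                       x = rep(c(1, -1), each = nrow(ed)),
                       dims = c(nrow(ed), nrow(mesh$triangles)))
}

#' Build the linear reconstruction operator
#'
#' One-step regularized Gauss-Newton inverse on mesh elements,
#' `B = (J'J + lambda^2 L'L)^-1 J'`, composed with the element-to-pixel
#' interpolation onto the square grid.  For the 8-electrode protocol and a
#' 32 x 32 grid the operator maps 40 normalized voltage differences to 1024
#' pixel values.
#'
#' @param J Sensitivity matrix from [eit_jacobian()] (n_meas x n_elements).
#' @param mesh The [disk_mesh()] the Jacobian was computed on.
#' @param lambda Regularization weight; default `0.05 * sigma_max(J)`
#'   (largest singular value).  Must be positive: the element space is
#'   larger than the measurement space, so the unregularized normal matrix
#'   is rank deficient.
#' @param prior `"identity"` (default) or `"laplacian"` (smoothness over
#'   element adjacency).  The identity prior is the default because the
#'   adjacency-Laplacian penalty under-constrains the low-sensitivity rim
#'   elements and can place spurious extrema at the tank boundary.
#' @param grid A [pixel_grid()]; default 32 x 32 over the mesh radius.
#' @return An object of class `eit_recon_operator`: list with the pixel
#'   operator `R` (n_pix^2 x n_meas), the element-space inverse `B`, the
#'   `grid`, `lambda` and `prior`.
#' @export
build_recon_operator <- function(J, mesh, lambda = NULL,
                                 prior = c("identity", "laplacian"),
                                 grid = pixel_grid(mesh$radius_m, 32L)) {
  prior <- match.arg(prior)
  if (is.null(lambda)) lambda <- 0.05 * .largest_sv(J)
  if (!is.finite(lambda) || lambda <= 0)
    stop("lambda must be positive: J'J alone is rank deficient")
  L <- if (prior == "laplacian") .element_laplacian(mesh)
       else Matrix::Diagonal(ncol(J))
  H <- crossprod(J) + lambda^2 * as.matrix(Matrix::crossprod(L))
  B <- solve(H, t(J))
  P <- .element_pixel_map(mesh, grid)
  R <- as.matrix(P %*% B)
  structure(list(R = R, B = B, grid = grid, lambda = lambda, prior = prior),
            class = "eit_recon_operator")
}

# Largest singular value via the thin side of the cross-product.
.largest_sv <- function(J) sqrt(max(eigen(tcrossprod(J), symmetric = TRUE,
                                          only.values = TRUE)$values))

#' @export
print.eit_recon_operator <- function(x, ...) {
  cat(sprintf("<eit_recon_operator> %d x %d, lambda = %.4g, prior = %s\n",
              nrow(x$R), ncol(x$R), x$lambda, x$prior))
  invisible(x)
}

#' Apply the reconstruction operator to a difference vector
#'
#' @param op An [build_recon_operator()] result.
#' @param dv Normalized difference vector (length = measurement count).
#' @return An object of class `eit_image`: list with `values` (n x n matrix
#'   of conductivity-change index, out-of-disk pixels zero), the logical
#'   `mask` and the `grid`.  Conductive inclusions reconstruct positive,
#'   insulating ones negative.
#' @export
apply_recon <- function(op, dv) {
  stopifnot(inherits(op, "eit_recon_operator"))
  if (length(dv) != ncol(op$R))
    stop(sprintf("difference vector has length %d, operator expects %d",
                 length(dv), ncol(op$R)))
  n <- op$grid$n
  vals <- matrix(op$R %*% as.numeric(dv), n, n)
  vals[!op$grid$mask] <- 0
  structure(list(values = vals, mask = op$grid$mask, grid = op$grid),
            class = "eit_image")
}

#' @export
print.eit_image <- function(x, ...) {
  cat(sprintf("<eit_image> %d x %d, range [%.4g, %.4g], sum %.4g\n",
              nrow(x$values), ncol(x$values), min(x$values), max(x$values),
              sum(x$values)))
  invisible(x)
}

#' Iterative Gauss-Newton reconstruction with total-variation regularization
#'
#' Minimizes `||J x - dv||^2 + lambda_ridge^2 ||x||^2 + lambda_tv * TV_beta(x)`
#' over element-space conductivity changes, where `TV_beta` is the
#' beta-smoothed total variation over mesh element edges,
#' `sum(sqrt((x_i - x_j)^2 + beta^2))`.  Solved by lagged diffusivity:
#' each iteration solves a weighted-Laplacian linear system, with
#' backtracking to keep the objective non-increasing.  With `lambda_tv = 0`
#' and one iteration this reduces to the one-step identity-prior
#' Gauss-Newton solution.
#'
#' @param J Sensitivity matrix (n_meas x n_elements).
#' @param mesh The [disk_mesh()].
#' @param dv Normalized difference vector.
#' @param lambda_tv Total-variation weight (>= 0).
#' @param lambda_ridge Small Tikhonov weight keeping the system
#'   well-posed; default `0.05 * sigma_max(J)`.
#' @param beta_frac Smoothing parameter as a fraction of the initial
#'   solution's dynamic range (default 1e-4).
#' @param max_iter Iteration cap (default 15).
#' @param tol Relative objective-decrease tolerance for convergence.
#' @return List with element-space solution `x`, per-iteration `objective`,
#'   `iterations`, and `beta`.
#' @export
gn_tv_reconstruct <- function(J, mesh, dv, lambda_tv, lambda_ridge = NULL,
                              beta_frac = 1e-4, max_iter = 15L, tol = 1e-6) {
  stopifnot(max_iter >= 1L, beta_frac > 0, lambda_tv >= 0)
  if (is.null(lambda_ridge)) lambda_ridge <- 0.05 * .largest_sv(J)
  D <- .edge_difference(mesh)
  JtJ <- crossprod(J)
  Jtv <- drop(crossprod(J, dv))
  ridge <- lambda_ridge^2 * diag(ncol(J))
  x <- drop(solve(JtJ + ridge, Jtv))          # identity-prior one-step start
  rng <- diff(range(x))
  beta <- max(beta_frac * rng, 1e-12)
  obj <- function(x) {
    r <- drop(J %*% x) - dv
    sum(r^2) + lambda_ridge^2 * sum(x^2) +
      lambda_tv * sum(sqrt(as.numeric(D %*% x)^2 + beta^2))
  }
  f <- obj(x)
  trace <- f
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    if (lambda_tv > 0) {
      w <- 1 / sqrt(as.numeric(D %*% x)^2 + beta^2)
      Wl <- as.matrix(Matrix::crossprod(D, Matrix::Diagonal(x = w) %*% D))
      H <- JtJ + ridge + (lambda_tv / 2) * Wl
    } else {
      H <- JtJ + ridge
    }
    x_new <- drop(solve(H, Jtv))
    if (any(!is.finite(x_new)))
      stop("non-finite solution at iteration ", it)
    # backtracking toward the current iterate
    t_step <- 1
    f_new <- obj(x + t_step * (x_new - x))
    while (f_new > f && t_step > 1e-6) {
      t_step <- t_step / 2
      f_new <- obj(x + t_step * (x_new - x))
    }
    if (!is.finite(f_new)) stop("non-finite objective at iteration ", it)
    x_next <- x + t_step * (x_new - x)
    converged <- (f - f_new) <= tol * abs(f)
    x <- x_next
    f <- min(f_new, f)
    trace <- c(trace, f)
    if (lambda_tv == 0 && it == 1L) break     # exact one-step reduction
    if (converged) break
  }
  list(x = x, objective = trace, iterations = iters, beta = beta,
       lambda_tv = lambda_tv, lambda_ridge = lambda_ridge)
}
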