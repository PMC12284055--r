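# Difference imaging: normalization, linear operator, pixel mapping, GN-TV.

test_that("normalized differences are elementwise relative changes", {
  vh <- c(0.10, 0.20, 0.30)
  expect_equal(normalized_difference(vh, vh), c(0, 0, 0))
  expect_equal(normalized_difference(vh, 2 * vh), c(1, 1, 1))
  expect_equal(normalized_difference(c(0.10, 0.20), c(0.11, 0.19)),
               c(0.1, -0.05))
  expect_error(normalized_difference(c(0, 1), c(1, 1)), "dead")
  expect_error(normalized_difference(1:3, 1:4), "length")
})

test_that("reconstruction operator has the 1024 x 40 pixel shape", {
  st <- tw_saline_state(1024)
  op <- build_recon_operator(st$J, st$mesh)
  expect_equal(dim(op$R), c(1024L, 40L))
  expect_equal(op$grid$n, 32L)
  # out-of-disk pixels carry zero rows
  expect_true(all(op$R[!op$grid$mask, ] == 0))
  expect_error(build_recon_operator(st$J, st$mesh, lambda = 0), "positive")
})

test_that("infinite regularization drives the operator to zero", {
  st <- tw_saline_state(200)
  op1 <- build_recon_operator(st$J, st$mesh)
  op2 <- build_recon_operator(st$J, st$mesh, lambda = 1e12)
  expect_lt(max(abs(op2$R)), 1e-9 * max(abs(op1$R)))
})

test_that("element-space inverse matches the SVD filter-factor oracle", {
  st <- tw_saline_state(200)
  lam <- 0.05 * svd(st$J)$d[1]
  op <- build_recon_operator(st$J, st$mesh, lambda = lam, prior = "identity")
  sv <- svd(st$J)
  B_oracle <- sv$v %*% diag(sv$d / (sv$d^2 + lam^2)) %*% t(sv$u)
  expect_equal(unname(as.matrix(op$B)), B_oracle, tolerance = 1e-8)
})

test_that("image application is linear and masked", {
  st <- tw_saline_state(200)
  op <- build_recon_operator(st$J, st$mesh)
  z <- apply_recon(op, rep(0, 40))
  expect_true(all(z$values == 0))
  dv <- sin(seq_len(40))
  expect_equal(apply_recon(op, 3 * dv)$values, 3 * apply_recon(op, dv)$values)
  expect_true(all(apply_recon(op, dv)$values[!op$grid$mask] == 0))
  expect_error(apply_recon(op, rep(0, 39)), "length")
})

test_that("an insulating inclusion reconstructs negative near its center", {
  # forward data from a finer mesh than the inverse mesh
  fine <- tw_mesh(4200)
  pat <- tw_pattern()
  vh <- protocol_voltages(fine, apply_phantom(make_phantom("saline-homog"), fine),
                          pat, 0.98e-3)
  v <- protocol_voltages(fine, apply_phantom(make_phantom("saline-pvc"), fine),
                         pat, 0.98e-3)
  st <- tw_saline_state(1024)
  op <- build_recon_operator(st$J, st$mesh)
  img <- apply_recon(op, normalized_difference(vh, v))
  expect_lt(min(img$values), 0)
  xy <- tw_extremum_xy(img, "min")
  expect_lt(sqrt(sum((xy - c(0.03, 0))^2)), 2 * img$grid$pixel_m)
})

test_that("GN with zero TV weight reduces to the one-step solution", {
  st <- tw_saline_state(200)
  dv <- 0.01 * sin(seq_len(40))
  sol <- gn_tv_reconstruct(st$J, st$mesh, dv, lambda_tv = 0)
  lam <- sol$lambda_ridge
  onestep <- solve(crossprod(st$J) + lam^2 * diag(ncol(st$J)),
                   crossprod(st$J, dv))
  expect_equal(sol$x, drop(onestep), tolerance = 1e-10)
  expect_equal(sol$iterations, 1L)
})

test_that("huge TV weight flattens the image", {
  st <- tw_saline_state(200)
  pat <- tw_pattern()
  v <- protocol_voltages(st$mesh,
                         apply_phantom(make_phantom("saline-pvc"), st$mesh),
                         pat, 0.98e-3)
  dv <- normalized_difference(st$vh, v)
  sol0 <- gn_tv_reconstruct(st$J, st$mesh, dv, lambda_tv = 0)
  solf <- gn_tv_reconstruct(st$J, st$mesh, dv,
                            lambda_tv = 1e9 * sol0$lambda_ridge^2)
  expect_lt(diff(range(solf$x)), 1e-4 * diff(range(sol0$x)))
})

test_that("TV sharpens edges relative to the one-step solution", {
  # piecewise-constant phantom: the TV solution concentrates its gradient
  # on fewer edges than the quadratic one-step solution
  st <- tw_agar_state(512)
  pat <- tw_pattern()
  v <- protocol_voltages(st$mesh,
                         apply_phantom(make_phantom("agar-large"), st$mesh),
                         pat, 0.98e-3)
  dv <- normalized_difference(st$vh, v)
  one <- gn_tv_reconstruct(st$J, st$mesh, dv, lambda_tv = 0)
  lam2 <- one$lambda_ridge^2
  tv <- gn_tv_reconstruct(st$J, st$mesh, dv, lambda_tv = 4 * lam2,
                          max_iter = 25)
  D <- eittwin:::.edge_difference(st$mesh)
  conc <- function(x) {
    g <- sort(abs(as.numeric(D %*% x)), decreasing = TRUE)
    sum(g[seq_len(ceiling(0.05 * length(g)))]) / sum(g)
  }
  expect_gt(conc(tv$x), conc(one$x))
  # objective is non-increasing across accepted steps
  expect_true(all(diff(tv$objective) <= 1e-10))
})
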