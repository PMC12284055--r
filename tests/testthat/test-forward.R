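# Finite-element forward model against closed-form and symmetry oracles.

test_that("homogeneous-disk potentials match the analytic log solution", {
  st <- tw_saline_state(2048)
  m <- st$mesh
  u <- solve_forward(m, st$sigma, c(1, 2), 0.98e-3)
  bn <- setdiff(m$boundary, m$electrode_nodes[c(1, 2)])
  ua <- analytic_disk_potential(m$nodes[bn, ], m$nodes[m$electrode_nodes[1], ],
                                m$nodes[m$electrode_nodes[2], ], 0.278, 0.98e-3)
  uf <- u[bn] - mean(u[bn])
  ua <- ua - mean(ua)
  expect_lt(sqrt(sum((uf - ua)^2) / sum(ua^2)), 0.02)
})

test_that("protocol voltages match the analytic differential oracle closely", {
  st <- tw_saline_state(2048)
  m <- st$mesh; p <- tw_pattern(); en <- m$electrode_nodes
  va <- vapply(seq_len(nrow(p)), function(r) {
    pts <- m$nodes[en[c(p$meas_a[r], p$meas_b[r])], ]
    u <- analytic_disk_potential(pts, m$nodes[en[p$drive_a[r]], ],
                                 m$nodes[en[p$drive_b[r]], ], 0.278, 0.98e-3)
    abs(u[2] - u[1])
  }, numeric(1))
  expect_lt(sqrt(sum((st$vh - va)^2) / sum(va^2)), 0.005)
})

test_that("reciprocity and linearity hold", {
  st <- tw_saline_state(1024)
  m <- st$mesh; en <- m$electrode_nodes
  u12 <- solve_forward(m, st$sigma, c(1, 2), 1)
  u45 <- solve_forward(m, st$sigma, c(4, 5), 1)
  expect_equal(u12[en[5]] - u12[en[4]], u45[en[2]] - u45[en[1]],
               tolerance = 1e-10)
  # doubling conductivity halves every potential
  u2 <- solve_forward(m, 2 * st$sigma, c(1, 2), 1)
  expect_equal(u2, u12 / 2, tolerance = 1e-10)
  # linearity in current
  v1 <- protocol_voltages(m, st$sigma, tw_pattern(), 1)
  expect_equal(st$vh, 0.98e-3 * v1, tolerance = 1e-10)
})

test_that("homogeneous protocol voltages carry the ring symmetry", {
  st <- tw_saline_state(1024)
  vm <- matrix(st$vh, nrow = 8, byrow = TRUE)
  # every drive sees the same five magnitudes
  spread <- apply(vm, 2, function(col) diff(range(col)) / mean(col))
  expect_true(all(spread < 1e-8))
})

test_that("a centered insulating inclusion raises all boundary voltages", {
  st <- tw_saline_state(1024)
  sigma <- st$sigma
  sigma[sqrt(rowSums(st$mesh$centroids^2)) < 0.03] <- 1e-6
  v <- protocol_voltages(st$mesh, sigma, tw_pattern(), 0.98e-3)
  expect_true(all(v >= st$vh - 1e-12))
  expect_gt(max(v - st$vh), 0)
})

test_that("adjoint Jacobian matches central finite differences", {
  st <- tw_saline_state(200)
  m <- st$mesh
  set.seed(4)
  for (e in sample(nrow(m$triangles), 4)) {
    h <- 1e-6
    sp <- st$sigma; sp[e] <- sp[e] + h
    sm <- st$sigma; sm[e] <- sm[e] - h
    fd <- (protocol_voltages(m, sp, tw_pattern(), 0.98e-3) -
             protocol_voltages(m, sm, tw_pattern(), 0.98e-3)) / (2 * h)
    expect_lt(max(abs(fd - st$J[, e])) / max(abs(fd)), 0.01)
  }
})

test_that("Jacobian rows satisfy the Euler homogeneity identity", {
  # V(c*sigma) = V/c implies sum_e sigma_e dV/dsigma_e = -V
  st <- tw_saline_state(200)
  expect_equal(rowSums(st$J) * 0.278, -st$vh, tolerance = 1e-8)
})

test_that("degenerate conductivities are rejected", {
  st <- tw_saline_state(200)
  bad <- st$sigma; bad[1] <- 0
  expect_error(solve_forward(st$mesh, bad, c(1, 2), 1), "positive")
  expect_error(solve_forward(st$mesh, st$sigma[-1], c(1, 2), 1),
               "per element")
})
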