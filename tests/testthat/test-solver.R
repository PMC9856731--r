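test_that("system assembly has conservation structure and compatible RHS", {
  head <- cube_head(8L)
  cells <- conducting_cells(head)
  dadt <- matrix(rep(c(1, 0.5, -0.25), each = length(cells)), ncol = 3)
  sys <- assemble_system(head, dadt)
  # pure Neumann: zero row sums; RHS sums to zero (compatibility)
  expect_lt(max(abs(Matrix::rowSums(sys$A))), 1e-12)
  expect_lt(abs(sum(sys$b)), 1e-10 * max(abs(sys$b), 1))
  expect_true(Matrix::isSymmetric(sys$A))
  # uniform dA/dt in a homogeneous conductor: RHS vanishes away from the
  # conductor boundary
  idx <- arrayInd(cells, head$dims)
  inner <- idx[, 1] > 2 & idx[, 1] < 9 & idx[, 2] > 2 & idx[, 2] < 9 &
           idx[, 3] > 2 & idx[, 3] < 9
  expect_lt(max(abs(sys$b[inner])), 1e-15)
  expect_gt(max(abs(sys$b[!inner])), 0)
})

test_that("a model without conducting voxels is rejected", {
  head <- cube_head(4L)
  head$labels[] <- 0L
  expect_error(assemble_system(head, matrix(0, 0, 3)), "no conducting")
})

test_that("uniform dA/dt in a homogeneous conductor induces no field", {
  head <- cube_head(8L)
  nc <- length(conducting_cells(head))
  dadt <- matrix(rep(c(1, 0.5, -0.25), each = nc), ncol = 3)
  sys <- assemble_system(head, dadt)
  sol <- solve_potential(sys, tol = 1e-10)
  expect_lt(abs(mean(sol$phi)), 1e-15)
  expect_lte(sol$residual, 1e-10)
  ef <- reconstruct_ef(sol, dadt, head)
  expect_lt(max(sqrt(rowSums(ef$E^2))) / sqrt(sum(c(1, 0.5, -0.25)^2)),
            1e-6)
})

test_that("iterative solution matches a dense direct solve", {
  head <- cube_head(10L)  # 10^3 conducting voxels
  # mixed tissue labels for conductivity contrast
  idx <- arrayInd(conducting_cells(head), head$dims)
  head$labels[conducting_cells(head)][idx[, 3] > 6] <- 3L
  head$labels[conducting_cells(head)][idx[, 3] < 4] <- 5L
  dadt <- dipole_dadt(head, c(0, 0, 20))
  sys <- assemble_system(head, dadt)
  sol <- solve_potential(sys, tol = 1e-12, max_iter = 10000L)
  ad <- as.matrix(sys$A)
  ad[1, ] <- 0; ad[, 1] <- 0; ad[1, 1] <- 1
  bd <- sys$b; bd[1] <- 0
  xd <- solve(ad, bd)
  xd <- xd - mean(xd)
  expect_lt(max(abs(xd - sol$phi)), 1e-8 * max(abs(xd)))
})

test_that("potential and field are linear in the source", {
  head <- cube_head(6L)
  dadt <- dipole_dadt(head, c(0, 0, 15))
  sys <- assemble_system(head, dadt)
  sys2 <- assemble_system(head, 2 * dadt)
  expect_equal(sys2$b, 2 * sys$b, tolerance = 1e-14)
  sol <- solve_potential(sys, tol = 1e-10)
  sol2 <- solve_potential(sys2, tol = 1e-10)
  expect_equal(sol2$phi, 2 * sol$phi, tolerance = 1e-6)
})

test_that("intensity scaling is exact through reconstruction", {
  head <- cube_head(6L)
  dadt <- dipole_dadt(head, c(0, 0, 15))
  sol <- solve_potential(assemble_system(head, dadt), tol = 1e-8)
  ef100 <- reconstruct_ef(sol, dadt, head, 100)
  ef55 <- reconstruct_ef(sol, dadt, head, 55)
  expect_identical(ef55$E, 0.55 * ef100$E)
  expect_identical(scale_ef(ef100, 55)$E, 0.55 * ef100$E)
})

test_that("induced field in a homogeneous sphere has no radial component", {
  R <- 20
  head <- sphere_head(R, h = 1)
  dadt <- dipole_dadt(head, c(0, 0, R + 15))
  ef <- reconstruct_ef(solve_potential(assemble_system(head, dadt)),
                       dadt, head)
  pts <- voxel_centers(head, ef$cells)
  rr <- sqrt(rowSums(pts^2))
  rhat <- pts / pmax(rr, 1e-9)
  frac <- abs(rowSums(ef$E * rhat)) / pmax(sqrt(rowSums(ef$E^2)), 1e-30)
  # evaluate where the central-difference stencil is complete: the
  # staircase boundary layer does not discretize the sphere's normal
  interior <- rr < R - 1
  expect_lt(unname(stats::quantile(frac[interior], 0.95)), 0.05)
})

test_that("EF is insensitive to a radially layered conductivity profile", {
  R <- 25
  hh <- sphere_head(R, h = 1)
  hl <- sphere_head(R, h = 1, layered = TRUE)
  dadt <- dipole_dadt(hh, c(0, 0, R + 15))
  ef_h <- reconstruct_ef(solve_potential(assemble_system(hh, dadt)),
                         dadt, hh)
  ef_l <- reconstruct_ef(solve_potential(assemble_system(hl, dadt)),
                         dadt, hl)
  rel <- mean(sqrt(rowSums((ef_l$E - ef_h$E)^2))) /
         mean(sqrt(rowSums(ef_h$E^2)))
  expect_lt(rel, 0.05)
})

test_that("discrete current is conserved across closed voxel boxes", {
  head <- cube_head(8L)
  dadt <- dipole_dadt(head, c(0, 0, 20))
  sys <- assemble_system(head, dadt)
  sol <- solve_potential(sys, tol = 1e-10)
  # residual r = b - A phi measures the net current imbalance per cell;
  # summing over any subset bounds the net current through its boundary
  r <- sys$b - as.numeric(sys$A %*% sol$phi)
  expect_lt(max(abs(r)), 1e-9 * max(abs(sys$b)))
})

test_that("cortical field converges under voxel refinement at desk scale", {
  m1 <- fx_run1()$maps100[["a04_s+00"]]
  sub_h <- build_synthetic_head(head_spec(voxel_size_mm = 0.5))
  pls <- placement_grid(scalp_sulcus_polyline(sub_h$head), pct_mso = 100)
  ef <- solve_placement(sub_h$head, coil_model(), pls[[10]])
  m_h <- sample_on_surface(ef, sub_h$surface)
  expect_lt(abs(max(m1$strength) / max(m_h$strength) - 1), 0.05)
})
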