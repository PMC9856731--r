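flat_placement <- function(pct = 100) {
  coil_placement(c(0, 0, 0), current_dir = c(1, 0, 0), normal = c(0, 0, 1),
                 pct_mso = pct)
}

test_that("wire path has the expected counts, planarity and winding", {
  coil <- coil_model(segments_per_loop = 72L)
  path <- coil_wire_path(coil, flat_placement())
  expect_length(path, 18L)
  expect_equal(sum(vapply(path, function(l) nrow(l$points), 0L)), 1296L)
  # placement at origin with identity triad: coil plane is z = 0
  zr <- range(vapply(path, function(l) range(l$points[, 3]), numeric(2)))
  expect_equal(zr, c(0, 0))
  # opposite winding: signed enclosed areas of the wings cancel
  signed_area <- function(p) {
    sum(p[, 1] * c(p[-1, 2], p[1, 2]) - c(p[-1, 1], p[1, 1]) * p[, 2]) / 2
  }
  a1 <- sum(vapply(path[1:9], function(l) signed_area(l$points), 0))
  a2 <- sum(vapply(path[10:18], function(l) signed_area(l$points), 0))
  expect_equal(a1, -a2, tolerance = 1e-9)
  # loop radii span the inner/outer diameters
  expect_equal(range(coil$loop_radii_mm), c(27.5, 46.0))
  expect_equal(diff(coil$loop_radii_mm),
               rep(diff(coil$loop_radii_mm)[1], 8), tolerance = 1e-12)
})

test_that("vector potential is azimuthal and linear in dI/dt", {
  one <- coil_model(loops_per_wing = 1L, inner_diameter_mm = 60,
                    outer_diameter_mm = 60, segments_per_loop = 128L)
  lp <- coil_wire_path(one, flat_placement())[1]
  cen <- colMeans(lp[[1]]$points)
  a_axis <- vector_potential(lp, rbind(cen + c(0, 0, 10)), didt = 1)
  # on the loop axis A is azimuthal, so it vanishes there by symmetry
  expect_lt(max(abs(a_axis)), 1e-12)
  p <- rbind(cen + c(5, 3, 10))
  expect_identical(vector_potential(lp, p, 2), 2 * vector_potential(lp, p, 1))
})

test_that("curl of the vector potential matches the on-axis loop field", {
  one <- coil_model(loops_per_wing = 1L, inner_diameter_mm = 60,
                    outer_diameter_mm = 60, segments_per_loop = 128L)
  lp <- coil_wire_path(one, flat_placement())[1]
  cen <- colMeans(lp[[1]]$points)
  R <- 0.030
  didt <- 1
  eps <- 0.05
  for (z in c(5, 15, 40)) {
    p0 <- cen + c(0, 0, z)
    pts <- rbind(p0 + c(eps, 0, 0), p0 - c(eps, 0, 0),
                 p0 + c(0, eps, 0), p0 - c(0, eps, 0))
    A <- vector_potential(lp, pts, didt)
    curl_z <- (A[1, 2] - A[2, 2]) / (2 * eps * 1e-3) -
              (A[3, 1] - A[4, 1]) / (2 * eps * 1e-3)
    b_z <- 4e-7 * pi * (didt * 1e6) * R^2 /
           (2 * (R^2 + (z * 1e-3)^2)^1.5)
    expect_lt(abs(curl_z / b_z - 1), 0.01)
  }
})

test_that("field decays monotonically along the coil normal", {
  coil <- coil_model()
  path <- coil_wire_path(coil, flat_placement())
  zs <- seq(5, 80, by = 2.5)
  a <- vector_potential(path, cbind(0, 0, zs), didt = 174)
  expect_true(all(diff(sqrt(rowSums(a^2))) < 0))
})

test_that("field converges in the segment count (72 vs 144 per loop)", {
  pl <- flat_placement()
  pt <- rbind(c(12, -7, 20))
  a72 <- vector_potential(coil_wire_path(coil_model(segments_per_loop = 72L), pl),
                          pt, 174)
  a144 <- vector_potential(coil_wire_path(coil_model(segments_per_loop = 144L), pl),
                           pt, 174)
  expect_lt(sqrt(sum((a72 - a144)^2)) / sqrt(sum(a144^2)), 0.005)
})

test_that("field points on the wire are refused", {
  coil <- coil_model()
  path <- coil_wire_path(coil, flat_placement())
  on_wire <- path[[1]]$points[1, , drop = FALSE]
  expect_error(vector_potential(path, on_wire, 174), "within.*coil wire")
})

test_that("reflection symmetry across the wing-separation plane", {
  # with the identity triad the wings sit at +/-46 mm along y (the handle
  # axis); |dA/dt| is symmetric under reflection through the y = 0 plane
  coil <- coil_model()
  path <- coil_wire_path(coil, flat_placement())
  p <- cbind(c(7, 7), c(11, -11), c(18, 18))
  a <- vector_potential(path, p, 174)
  expect_equal(sqrt(sum(a[1, ]^2)), sqrt(sum(a[2, ]^2)), tolerance = 1e-9)
})

test_that("placement grid reproduces the 24-point sulcus protocol", {
  head <- build_head_volume(head_spec(voxel_size_mm = 2))
  poly <- scalp_sulcus_polyline(head)
  pls <- placement_grid(poly, n_anchors = 8L, spacing_mm = 5,
                        shifts_mm = c(-5, 0, 5), pct_mso = 55)
  expect_length(pls, 24L)
  # 5 mm x 5 mm grid cells = 4 stimuli per cm^2
  expect_equal(1 / (0.5 * 0.5), 4)
  for (p in pls) {
    expect_equal(crossprod(p$triad), diag(3), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(det(p$triad), 1, tolerance = 1e-9)
    # current perpendicular to the sulcus tangent (y at the vertex)
    expect_lt(abs(sum(p$triad[, 1] * c(0, 1, 0))), 0.35)
    # coil normal outward along the scalp radial direction
    expect_gt(sum(p$triad[, 3] * p$position / sqrt(sum(p$position^2))),
              0.999)
  }
  single <- placement_grid(poly, n_anchors = 1L, shifts_mm = 0)
  expect_length(single, 1L)
  expect_error(placement_grid(poly[1:2, ], n_anchors = 8L, spacing_mm = 50),
               "too short")
  expect_error(placement_grid(poly[1, , drop = FALSE]), "degenerate")
})
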