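records_df <- function(ids, meps, muscle = "FDI", trials = 1L, pct = 55) {
  do.call(rbind, lapply(seq_along(ids), function(i) {
    data.frame(placement_id = ids[i], trial = seq_len(trials),
               muscle = muscle, mep_pp = meps[i],
               intensity_pct_mso = pct)
  }))
}

test_that("top-stimulus selection orders, deduplicates and breaks ties", {
  r <- records_df(c("A", "B"), c(2, 1))
  expect_identical(select_top_stimuli(r, "FDI", 1L), "A")
  expect_identical(select_top_stimuli(r, "FDI", 2L), c("A", "B"))
  # ties broken by placement id
  r2 <- records_df(c("C", "A", "B"), c(1, 1, 1))
  expect_identical(select_top_stimuli(r2, "FDI", 2L), c("A", "B"))
  expect_error(select_top_stimuli(r, "FDI", 3L), "exceeds")
  expect_error(select_top_stimuli(r, "ADM", 1L), "no records")
  # trial-level reduction: placement with one huge trial wins under "trial"
  r3 <- rbind(records_df("A", 1, trials = 5L), records_df("B", 0.5, trials = 4L),
              data.frame(placement_id = "B", trial = 5L, muscle = "FDI",
                         mep_pp = 10, intensity_pct_mso = 55))
  expect_identical(select_top_stimuli(r3, "FDI", 1L, reduce = "median"), "A")
  expect_identical(select_top_stimuli(r3, "FDI", 1L, reduce = "trial"), "B")
})

test_that("five distinct placements are selected from the 24-point protocol", {
  run <- fx_run2()
  rec <- run$records[run$records$intensity_pct_mso == 55, ]
  ids <- select_top_stimuli(rec, "FDI", 5L)
  expect_length(unique(ids), 5L)
  expect_true(all(ids %in% names(run$maps100)))
})

test_that("single-map hotspot equals the relative-threshold region", {
  s <- strip_surface(10L)
  v <- c(1, 0.5, 0.2, 0.09, 0.05, 1, 0.5, 0.2, 0.09, 0.05)
  hs <- multiply_maps(list(fake_map(v)), s, metric = "strength")
  expect_identical(hs$mask, v > 0.1)
  expect_equal(hs$ef_focal, v, tolerance = 1e-12)
  expect_gt(hs$area_mm2, 0)
})

test_that("product mapping is permutation and scale invariant", {
  s <- strip_surface(10L)
  set.seed(5)
  a <- fake_map(runif(10, 0.01, 1))
  b <- fake_map(runif(10, 0.01, 1))
  cc <- fake_map(runif(10, 0.01, 1))
  h1 <- multiply_maps(list(a, b, cc), s)
  h2 <- multiply_maps(list(cc, a, b), s)
  expect_equal(h1$ef_focal, h2$ef_focal, tolerance = 1e-12)
  expect_identical(h1$mask, h2$mask)
  expect_equal(h1$cog, h2$cog, tolerance = 1e-12)
  # positive scaling of any input changes nothing
  a2 <- fake_map(37.5 * a$strength)
  h3 <- multiply_maps(list(a2, b, cc), s)
  expect_equal(h3$ef_focal, h1$ef_focal, tolerance = 1e-12)
  expect_identical(h3$mask, h1$mask)
  expect_equal(h3$area_mm2, h1$area_mm2, tolerance = 1e-12)
  expect_equal(h3$cog, h1$cog, tolerance = 1e-12)
})

test_that("duplicating a map sharpens the hotspot (nested masks)", {
  s <- strip_surface(10L)
  set.seed(8)
  v <- runif(10, 0.01, 1)
  h1 <- multiply_maps(list(fake_map(v)), s)
  h2 <- multiply_maps(list(fake_map(v), fake_map(v)), s)
  # threshold on f^2 is f >= sqrt(0.1) max f
  expect_identical(h2$mask, v / max(v) > sqrt(0.1))
  expect_true(all(which(h2$mask) %in% which(h1$mask)))
  expect_lte(h2$area_mm2, h1$area_mm2)
})

test_that("center of gravity is the value-area weighted mean", {
  s2 <- strip_surface(6L)  # vertex x-coordinates 0, 1, 2 in two rows
  # vertices 3 (x = 2, y = 0) and 4 (x = 0, y = 1) have equal areas:
  # equal weights at x = 0 and x = 2 -> midpoint x = 1
  expect_equal(s2$vertex_area_mm2[3], s2$vertex_area_mm2[4])
  hs <- structure(list(ef_focal = c(0.01, 0.01, 1, 1, 0.01, 0.01),
                       mask = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE),
                       threshold = 0.1), class = "hotspot_map")
  expect_equal(center_of_gravity(hs, s2)[1], 1, tolerance = 1e-9)
  # single suprathreshold vertex -> that vertex
  hs1 <- structure(list(ef_focal = c(1, rep(0.01, 5)),
                        mask = c(TRUE, rep(FALSE, 5)), threshold = 0.1),
                   class = "hotspot_map")
  expect_equal(center_of_gravity(hs1, s2), as.numeric(s2$vertices[1, ]),
               tolerance = 1e-12)
  # 9:1 weights between x = 0 and x = 2 -> 0.1 * 2 = 0.2 interpolant
  hs9 <- structure(list(ef_focal = c(0.9, 0.01, 0.1, 0.01, 0.01, 0.01),
                        mask = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE),
                        threshold = 0.05), class = "hotspot_map")
  w <- c(0.9, 0.1) * s2$vertex_area_mm2[c(1, 3)]
  expect_equal(center_of_gravity(hs9, s2)[1],
               sum(w * c(0, 2)) / sum(w), tolerance = 1e-12)
  expect_error(center_of_gravity(structure(list(
    ef_focal = rep(0, 6), mask = rep(FALSE, 6), threshold = 0.1),
    class = "hotspot_map"), s2), "empty")
})

test_that("CoG distances are Euclidean", {
  a <- structure(list(cog = c(0, 0, 0)), class = "hotspot_map")
  b <- structure(list(cog = c(3, 4, 0)), class = "hotspot_map")
  expect_equal(cog_distance(a, b), 5)
  expect_equal(cog_distance(a, a), 0)
})

test_that("group-level maps sum normalized individual maps", {
  s <- strip_surface(6L)
  h1 <- multiply_maps(list(fake_map(c(2, rep(0, 5)))), s)
  h2 <- multiply_maps(list(fake_map(c(rep(0, 5), 2))), s)
  g1 <- group_hotspot(list(h1))
  expect_equal(g1, h1$ef_focal / max(h1$ef_focal))
  gn <- group_hotspot(list(h1, h1, h1))
  expect_equal(gn, 3 * g1, tolerance = 1e-12)
  g2 <- group_hotspot(list(h1, h2))
  expect_equal(g2[1], 1, tolerance = 1e-6)
  expect_equal(g2[6], 1, tolerance = 1e-6)
  h_bad <- h1
  h_bad$ef_focal <- h_bad$ef_focal[-1]
  expect_error(group_hotspot(list(h1, h_bad)), "topology mismatch")
})

test_that("mismatched vertex counts are rejected in map products", {
  s <- strip_surface(6L)
  expect_error(multiply_maps(list(fake_map(runif(4))), s), "vertex count")
})
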