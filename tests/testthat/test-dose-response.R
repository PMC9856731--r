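test_that("MEP simulation hits the sigmoid limits without noise", {
  run <- fx_run2()
  sub <- run$subject
  cfg <- mep_config(list(FDI = c(a = 2, b = 0.1, c = 100),
                         ADM = c(a = 1.6, b = 0.1, c = 100)),
                    noise_sigma_log = 0, noise_floor_mv = 0, seed = 1L)
  sub$sigmoid_truth <- cfg$sigmoid_truth
  m <- run$maps100[[10]]
  # saturation: field far above the turning point
  m_hi <- m
  m_hi$strength <- m$strength * 0 + 1e5
  rec <- simulate_meps(sub, list(m_hi), cfg)
  expect_equal(rec$mep_pp[rec$muscle == "FDI"], rep(2, 5), tolerance = 1e-6)
  # midpoint: field exactly at c gives a/2
  m_mid <- m
  m_mid$strength <- m$strength * 0 + 100
  rec2 <- simulate_meps(sub, list(m_mid), cfg)
  expect_equal(rec2$mep_pp[rec2$muscle == "FDI"], rep(1, 5),
               tolerance = 1e-12)
})

test_that("MEP simulation is deterministic under a fixed seed", {
  run <- fx_run2()
  cfg <- mep_config(run$subject$sigmoid_truth, noise_sigma_log = 0.3,
                    seed = 11L)
  r1 <- simulate_meps(run$subject, run$maps100[1:4], cfg)
  r2 <- simulate_meps(run$subject, run$maps100[1:4], cfg)
  expect_identical(r1, r2)
  # and does not disturb the caller's RNG
  set.seed(99)
  x <- runif(1)
  set.seed(99)
  invisible(simulate_meps(run$subject, run$maps100[1:2], cfg))
  expect_identical(runif(1), x)
})

test_that("noise-free sigmoid parameters are recovered to within 1%", {
  ef <- seq(100, 300, length.out = 20)
  mep <- sigmoid_mep(ef, 2, 0.1, 200)
  f <- fit_sigmoid(ef, mep)
  expect_false(f$divergent)
  expect_lt(abs(f$a / 2 - 1), 0.01)
  expect_lt(abs(f$b / 0.1 - 1), 0.01)
  expect_lt(abs(f$c / 200 - 1), 0.01)
  expect_gte(f$r2, 0.999)
  expect_equal(f$ef_threshold, 180, tolerance = 1e-6)
  expect_equal(f$ef_saturation, 220, tolerance = 1e-6)
})

test_that("closed-form threshold equals the numeric tangent intercept", {
  f <- fit_sigmoid(seq(100, 300, length.out = 20),
                   sigmoid_mep(seq(100, 300, length.out = 20), 2, 0.1, 200))
  g <- function(x) sigmoid_mep(x, f$a, f$b, f$c)
  eps <- 1e-4
  xs <- seq(f$c - 30, f$c + 30, by = 1e-3)
  slopes <- (g(xs + eps) - g(xs - eps)) / (2 * eps)
  xstar <- xs[which.max(slopes)]
  slope <- max(slopes)
  x_intercept <- xstar - g(xstar) / slope
  expect_lt(abs(x_intercept / (f$c - 2 / f$b) - 1), 1e-6)
})

test_that("unidentifiable recruitment data are flagged divergent", {
  expect_true(fit_sigmoid(seq(100, 300, 10), rep(1, 21))$divergent)
  expect_error(fit_sigmoid(1:3, 1:3), "at least 6")
})

test_that("parameter recovery is robust to trial noise over 20 seeds", {
  # 24 placements x 3 intensities, each pair the median of 5 noisy trials
  errs <- t(vapply(1:20, function(s) {
    set.seed(s)
    ef <- rep(seq(80, 320, length.out = 24), 3)
    mep <- vapply(ef, function(e)
      stats::median(sigmoid_mep(e, 2, 0.1, 200) * exp(rnorm(5, 0, 0.3))),
      0)
    f <- fit_sigmoid(ef, mep)
    abs(c(f$a / 2, f$b / 0.1, f$c / 200) - 1)
  }, numeric(3)))
  expect_lt(stats::median(errs[, 1]), 0.15)
  expect_lt(stats::median(errs[, 2]), 0.15)
  expect_lt(stats::median(errs[, 3]), 0.15)
})

test_that("EF at the fit point follows the hotspot argmax and scales", {
  run <- fx_run2()
  rec <- run$records[run$records$intensity_pct_mso == 55, ]
  ids <- select_top_stimuli(rec, "FDI", 3L)
  maps55 <- lapply(run$maps100, scale_map, pct_mso = 55)
  hs <- multiply_maps(maps55[ids], run$subject$surface, "strength", "FDI")
  efmax <- ef_at_fit_point(maps55, hs)
  v <- which.max(hs$ef_focal)
  expect_equal(efmax[[3]], maps55[[3]]$strength[v])
  # doubling intensity doubles EF_max for every placement
  maps110 <- lapply(maps55, function(m) scale_map(m, 110))
  expect_equal(ef_at_fit_point(maps110, hs), 2 * efmax, tolerance = 1e-12)
  # %MSO monotonicity through the linear solver scaling
  maps35 <- lapply(run$maps100, scale_map, pct_mso = 35)
  expect_true(all(ef_at_fit_point(maps55, hs) >
                  ef_at_fit_point(maps35, hs)))
})

test_that("RMT is recovered within 2 %MSO when the sigmoid is anchored", {
  run <- fx_run2()
  sub <- run$subject
  # steep sigmoid with midpoint at the field reached at 42% MSO
  v <- sub$truth_sites$FDI
  ef100 <- max(vapply(run$maps100, function(m) m$strength[v], 0))
  sub$sigmoid_truth <- list(FDI = c(a = 2, b = 1, c = 0.42 * ef100),
                            ADM = c(a = 2, b = 1, c = 0.42 * ef100))
  cfg <- mep_config(sub$sigmoid_truth, noise_sigma_log = 0.02,
                    noise_floor_mv = 0, seed = 5L)
  best <- names(which.max(vapply(run$maps100, function(m) m$strength[v], 0)))
  maps_fine <- do.call(c, lapply(seq(30, 55, by = 1), function(p)
    lapply(run$maps100[best], scale_map, pct_mso = p)))
  rec <- simulate_meps(sub, maps_fine, cfg)
  est <- estimate_rmt(rec, "FDI", criterion_mv = 0.05)
  expect_identical(est$flag, "ok")
  expect_lte(abs(est$rmt_pct_mso - 42), 2)
  # degenerate criterion: every trial responds at the lowest intensity
  est0 <- estimate_rmt(rec, "FDI", criterion_mv = 0)
  expect_equal(est0$rmt_pct_mso, 30)
  # criterion never reached
  est_hi <- estimate_rmt(rec, "FDI", criterion_mv = 1e6)
  expect_true(is.na(est_hi$rmt_pct_mso))
  expect_match(est_hi$flag, "never reached")
})
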