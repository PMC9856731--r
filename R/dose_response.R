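#' Sigmoid recruitment curve
#'
#' MEP(EF) = a / (1 + exp(-b (EF - c))): a is the saturation peak-to-peak
#' amplitude (mV), b the slope ((V/m)^-1), c the turning point (V/m).
#'
#' @param ef EF values (V/m).
#' @param a,b,c parameters.
#' @return MEP amplitudes (mV).
#' @export
sigmoid_mep <- function(ef, a, b, c) a / (1 + exp(-b * (ef - c)))

#' MEP generation configuration
#'
#' @param sigmoid_truth named list (muscle -> c(a, b, c)) of ground-truth
#'   recruitment parameters.
#' @param noise_sigma_log lognormal sigma of the multiplicative trial noise.
#' @param noise_floor_mv amplitude of the additive uniform baseline noise.
#' @param seed RNG seed for trial noise.
#' @return object of class \code{mep_config}.
#' @export
mep_config <- function(sigmoid_truth, noise_sigma_log = 0.3,
                       noise_floor_mv = 0.01, seed = 1L) {
  if (noise_sigma_log < 0) stop("noise_sigma_log must be >= 0")
  structure(list(sigmoid_truth = sigmoid_truth,
                 noise_sigma_log = noise_sigma_log,
                 noise_floor_mv = noise_floor_mv,
                 seed = as.integer(seed)),
            class = "mep_config")
}

#' Calibrate ground-truth sigmoids to the achieved field scale
#'
#' Anchors each muscle's recruitment curve to the EF its truth site actually
#' receives: the turning point c is placed at the field of the best
#' placement scaled to \code{target_rmt_pct} of stimulator output times
#' \code{c_over_rmt_ef}, and the slope is set so the tangent-line threshold
#' c - 2/b sits at \code{c / c_over_rmt_ef}. With the defaults this
#' reproduces the conventional ratio between recruitment turning point and
#' motor-threshold field.
#'
#' @param subject a \code{synthetic_subject}.
#' @param maps list of \code{ef_surface_map} at 100\% MSO, one per placement.
#' @param metric EF metric the curves are anchored to.
#' @param target_rmt_pct stimulator intensity that should correspond to the
#'   motor-threshold field.
#' @param c_over_rmt_ef ratio of turning point to threshold field.
#' @return the subject with updated \code{sigmoid_truth}.
#' @export
calibrate_sigmoid_truth <- function(subject, maps, metric = "strength",
                                    target_rmt_pct = 42,
                                    c_over_rmt_ef = 1.18) {
  for (muscle in names(subject$truth_sites)) {
    v <- subject$truth_sites[[muscle]]
    ef100 <- max(vapply(maps, function(m) map_metric(m, metric)[v],
                        numeric(1L)))
    ef_rmt <- ef100 * target_rmt_pct / 100
    cc <- ef_rmt * c_over_rmt_ef
    bb <- 2 / (cc - ef_rmt)
    aa <- subject$sigmoid_truth[[muscle]][["a"]]
    subject$sigmoid_truth[[muscle]] <- c(a = aa, b = bb, c = cc)
  }
  subject
}

#' Simulate trial-level MEPs for a set of stimuli
#'
#' For every map (one coil placement at one intensity) and trial, the MEP is
#' the ground-truth sigmoid evaluated at the EF metric of the muscle's truth
#' vertex, times multiplicative lognormal noise, plus a uniform baseline
#' noise floor. Deterministic under a fixed config seed; the caller's RNG
#' state is left untouched.
#'
#' @param subject a \code{synthetic_subject} with calibrated
#'   \code{sigmoid_truth}.
#' @param maps list of \code{ef_surface_map} (any mix of placements and
#'   intensities); names are used as placement ids if set.
#' @param cfg a \code{mep_config}.
#' @param trials_per_placement trials per stimulus.
#' @param metric EF metric driving the response.
#' @return data.frame with columns \code{placement_id}, \code{trial},
#'   \code{muscle}, \code{mep_pp}, \code{intensity_pct_mso}.
#' @export
simulate_meps <- function(subject, maps, cfg, trials_per_placement = 5L,
                          metric = "strength") {
  muscles <- names(subject$truth_sites)
  nv <- nrow(subject$surface$vertices)
  for (m in muscles) {
    if (subject$truth_sites[[m]] > nv)
      stop("truth vertex for ", m, " is missing from the surface")
  }
  rows <- with_local_seed(cfg$seed, {
    out <- vector("list", length(maps) * length(muscles))
    i <- 0L
    for (mi in seq_along(maps)) {
      map <- maps[[mi]]
      pid <- map$stimulus_id
      for (muscle in muscles) {
        p <- subject$sigmoid_truth[[muscle]]
        ef <- map_metric(map, metric)[subject$truth_sites[[muscle]]]
        base <- sigmoid_mep(ef, p[["a"]], p[["b"]], p[["c"]])
        noise <- exp(stats::rnorm(trials_per_placement, 0,
                                  cfg$noise_sigma_log))
        floorn <- stats::runif(trials_per_placement, 0, cfg$noise_floor_mv)
        i <- i + 1L
        out[[i]] <- data.frame(placement_id = pid,
                               trial = seq_len(trials_per_placement),
                               muscle = muscle,
                               mep_pp = base * noise + floorn,
                               intensity_pct_mso = map$intensity_pct_mso)
      }
    }
    out
  })
  do.call(rbind, rows)
}

#' Fit the sigmoid recruitment curve to EF-MEP pairs
#'
#' Nonlinear least squares (Levenberg-Marquardt) from a deterministic
#' multi-start grid: slopes b in \{0.01, 0.05, 0.1, 0.5\}, turning points c
#' at the EF quartiles, a at the maximum MEP. The best converged start by
#' residual sum of squares wins. Fits with non-positive slope, turning point
#' further than 50\% of the EF range outside the data, or relative
#' parameter standard error above 100\% are flagged divergent rather than
#' raising an error, mirroring how unidentifiable recruitment curves are
#' excluded from analysis.
#'
#' @param ef EF values at the fit point (V/m), one per stimulus.
#' @param mep MEP amplitudes (mV).
#' @return object of class \code{sigmoid_fit}: \code{a}, \code{b}, \code{c},
#'   \code{r2}, \code{ef_threshold} (= c - 2/b, the x-intercept of the
#'   tangent at the steepest point), \code{ef_saturation} (= c + 2/b),
#'   \code{divergent}, \code{reason}.
#' @export
fit_sigmoid <- function(ef, mep) {
  stopifnot(length(ef) == length(mep))
  if (length(ef) < 6L)
    stop("need at least 6 EF-MEP pairs")
  df <- data.frame(ef = ef, mep = mep)
  starts <- expand.grid(b = c(0.01, 0.05, 0.1, 0.5),
                        c = unname(stats::quantile(ef, c(0.25, 0.5, 0.75))))
  a0 <- max(mep)
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(mep ~ a / (1 + exp(-b * (ef - c))), data = df,
                        start = list(a = a0, b = starts$b[s],
                                     c = starts$c[s]),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12)
      best <- list(fit = fit, rss = rss)
  }
  flagged <- function(reason) {
    structure(list(a = NA_real_, b = NA_real_, c = NA_real_, r2 = NA_real_,
                   ef_threshold = NA_real_, ef_saturation = NA_real_,
                   divergent = TRUE, reason = reason),
              class = "sigmoid_fit")
  }
  if (is.null(best)) return(flagged("no start converged"))
  cf <- stats::coef(best$fit)
  a <- cf[["a"]]; b <- cf[["b"]]; cc <- cf[["c"]]
  rng <- diff(range(ef))
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3L))
  if (b <= 0) return(flagged("non-positive slope"))
  if (a <= 0) return(flagged("non-positive saturation amplitude"))
  if (cc < min(ef) - 0.5 * rng || cc > max(ef) + 0.5 * rng)
    return(flagged("turning point outside the observed EF range"))
  if (any(is.finite(se) & abs(se / cf) > 1))
    return(flagged("relative parameter standard error > 100%"))
  r2 <- 1 - best$rss / sum((mep - mean(mep))^2)
  structure(list(a = a, b = b, c = cc, r2 = r2,
                 ef_threshold = cc - 2 / b,
                 ef_saturation = cc + 2 / b,
                 divergent = FALSE, reason = NA_character_),
            class = "sigmoid_fit")
}

#' EF at the localization fit point for every stimulus
#'
#' Returns, for each surface map, the metric value at the vertex where the
#' hotspot map attains its maximum (the localized cortical coordinate).
#'
#' @param maps list of \code{ef_surface_map}.
#' @param hotspot a \code{hotspot_map}.
#' @param metric EF metric; defaults to the hotspot's metric.
#' @return numeric vector, one EF value (V/m) per map.
#' @export
ef_at_fit_point <- function(maps, hotspot, metric = hotspot$metric) {
  v <- which.max(hotspot$ef_focal)
  vapply(maps, function(m) map_metric(m, metric)[v], numeric(1L))
}

#' Resting motor threshold from graded-intensity records
#'
#' The RMT is the smallest tested stimulator intensity at which at least
#' half of the trials at the best placement exceed the MEP criterion
#' (default 50 microvolts peak-to-peak, the conventional definition).
#'
#' @param records trial-level records spanning at least 3 intensities.
#' @param muscle muscle to evaluate.
#' @param criterion_mv MEP criterion in mV.
#' @return list with \code{rmt_pct_mso} (NA when flagged), \code{flag}
#'   (\code{"ok"} or \code{"criterion never reached"}), and
#'   \code{best_placement}.
#' @export
estimate_rmt <- function(records, muscle, criterion_mv = 0.05) {
  r <- records[records$muscle == muscle, , drop = FALSE]
  ints <- sort(unique(r$intensity_pct_mso))
  if (length(ints) < 3L)
    stop("need records at >= 3 intensities")
  # best placement: highest median MEP at the top intensity
  top <- r[r$intensity_pct_mso == max(ints), , drop = FALSE]
  agg <- stats::aggregate(mep_pp ~ placement_id, data = top,
                          FUN = stats::median)
  best <- as.character(agg$placement_id[order(-agg$mep_pp,
                                              agg$placement_id)][1L])
  rb <- r[r$placement_id == best, , drop = FALSE]
  for (i in ints) {
    trials <- rb$mep_pp[rb$intensity_pct_mso == i]
    if (length(trials) && mean(trials > criterion_mv) >= 0.5)
      return(list(rmt_pct_mso = i, flag = "ok", best_placement = best))
  }
  list(rmt_pct_mso = NA_real_, flag = "criterion never reached",
       best_placement = best)
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  if (x$divergent) {
    cat(sprintf("<sigmoid_fit> divergent (%s)\n", x$reason))
  } else {
    cat(sprintf("<sigmoid_fit> a = %.3g mV, b = %.3g (V/m)^-1, c = %.1f V/m | threshold %.1f, saturation %.1f V/m, R^2 = %.3f\n",
                x$a, x$b, x$c, x$ef_threshold, x$ef_saturation, x$r2))
  }
  invisible(x)
}
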