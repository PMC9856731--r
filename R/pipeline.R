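#' MEP amplitude categories for the random-sampling study
#'
#' Thresholds are fractions of the per-subject maximum MEP; the "0" category
#' means any suprathreshold record (MEP above the detection floor).
#'
#' @return data.frame with columns \code{label} and \code{mep_fraction}.
#' @export
sampling_categories <- function() {
  data.frame(label = c("75", "50", "25", "0"),
             mep_fraction = c(0.75, 0.50, 0.25, 0))
}

#' Pipeline configuration
#'
#' @param spec a \code{head_spec} for the synthetic subject.
#' @param coil a \code{coil_model}.
#' @param intensities stimulator intensities (\% MSO) of the protocol.
#' @param eval_intensity_pct intensity used for hotspot mapping and the
#'   random-sampling study.
#' @param n_anchors,spacing_mm,shifts_mm placement grid geometry.
#' @param trials_per_placement MEP trials per stimulus.
#' @param k_strength,k_normal number of top-MEP samples multiplied for each
#'   EF metric.
#' @param noise_sigma_log,noise_floor_mv MEP noise model.
#' @param detection_floor_mv smallest MEP counted as a response.
#' @param target_rmt_pct intensity the truth sigmoids are anchored to.
#' @param tol solver tolerance.
#' @param subdiv surface subdivision level.
#' @param seed master seed; all stage seeds derive from it.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(spec = head_spec(), coil = coil_model(),
                            intensities = c(35, 45, 55),
                            eval_intensity_pct = 55,
                            n_anchors = 8L, spacing_mm = 5,
                            shifts_mm = c(-5, 0, 5),
                            trials_per_placement = 5L,
                            k_strength = 5L, k_normal = 3L,
                            noise_sigma_log = 0.3, noise_floor_mv = 0.01,
                            detection_floor_mv = 0.05,
                            target_rmt_pct = 42, tol = 1e-6,
                            subdiv = 5L, seed = 1L) {
  spec$seed <- as.integer(seed)
  structure(list(spec = spec, coil = coil, intensities = intensities,
                 eval_intensity_pct = eval_intensity_pct,
                 n_anchors = as.integer(n_anchors),
                 spacing_mm = spacing_mm, shifts_mm = shifts_mm,
                 trials_per_placement = as.integer(trials_per_placement),
                 k_strength = as.integer(k_strength),
                 k_normal = as.integer(k_normal),
                 noise_sigma_log = noise_sigma_log,
                 noise_floor_mv = noise_floor_mv,
                 detection_floor_mv = detection_floor_mv,
                 target_rmt_pct = target_rmt_pct, tol = tol,
                 subdiv = as.integer(subdiv), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Solve every placement and sample the cortical surface
#'
#' Runs the volume-conductor solve once per placement at 100\% MSO and
#' interpolates the field on the subject's cortical surface; intensities are
#' obtained afterwards by exact linear scaling.
#'
#' @param subject a \code{synthetic_subject}.
#' @param placements list of \code{coil_placement}.
#' @param coil a \code{coil_model}.
#' @param tol solver tolerance.
#' @param verbose print per-placement progress.
#' @return named list of \code{ef_surface_map} at 100\% MSO.
#' @export
solve_all_placements <- function(subject, placements, coil = coil_model(),
                                 tol = 1e-6, verbose = FALSE) {
  maps <- vector("list", length(placements))
  ids <- character(length(placements))
  for (i in seq_along(placements)) {
    p <- placements[[i]]
    t0 <- Sys.time()
    p100 <- p
    p100$intensity_pct_mso <- 100
    ef <- solve_placement(subject$head, coil, p100, tol = tol)
    maps[[i]] <- sample_on_surface(ef, subject$surface, stimulus_id = p$id)
    ids[i] <- p$id
    if (verbose)
      message(sprintf("solved %s in %.1f s", p$id,
                      as.numeric(Sys.time() - t0, units = "secs")))
  }
  names(maps) <- ids
  maps
}

#' Hotspot area as a function of the number of multiplied samples
#'
#' @param maps named list of \code{ef_surface_map} (one intensity).
#' @param records trial-level records at the same intensity.
#' @param surface the common surface.
#' @param muscle muscle label.
#' @param metric EF metric.
#' @param k_range sample counts to evaluate.
#' @return data.frame with columns \code{k}, \code{area_mm2}.
#' @export
sweep_sample_count <- function(maps, records, surface, muscle,
                               metric = "strength", k_range = 1:8) {
  out <- lapply(k_range, function(k) {
    ids <- select_top_stimuli(records, muscle, k)
    hs <- multiply_maps(maps[ids], surface, metric = metric,
                        muscle = muscle)
    data.frame(k = k, area_mm2 = hs$area_mm2)
  })
  do.call(rbind, out)
}

#' Localization error under random sample selection
#'
#' Draws \code{k} records uniformly without replacement from those whose MEP
#' exceeds the category threshold (a fraction of the maximum MEP), maps the
#' corresponding placements, and measures the CoG error against the
#' reference hotspot built from the k highest-MEP records. Repeated
#' \code{n_rep} times with a dedicated RNG stream per category.
#'
#' @param maps named list of \code{ef_surface_map} at the evaluation
#'   intensity.
#' @param records trial-level records at the same intensity.
#' @param surface the common surface.
#' @param muscle,metric hotspot settings.
#' @param category row of \code{\link{sampling_categories}} (or a label).
#' @param n_rep repetitions.
#' @param k samples per draw.
#' @param seed RNG seed for this category's stream.
#' @param detection_floor_mv suprathreshold criterion for the "0" category.
#' @return data.frame with one row per repetition (\code{category},
#'   \code{repetition}, \code{cog_error_mm}, \code{hotspot_area_mm2},
#'   \code{n_eligible}), or NULL (with a warning) when fewer than k records
#'   are eligible.
#' @export
random_category_localization <- function(maps, records, surface, muscle,
                                         metric = "strength",
                                         category = "50", n_rep = 100L,
                                         k = 5L, seed = 1L,
                                         detection_floor_mv = 0.05) {
  cats <- sampling_categories()
  if (is.character(category) || is.numeric(category)) {
    row <- cats[cats$label == as.character(category), ]
    if (nrow(row) != 1L) stop("unknown category: ", category)
  } else row <- category
  r <- records[records$muscle == muscle, , drop = FALSE]
  thr <- if (row$mep_fraction > 0) row$mep_fraction * max(r$mep_pp)
         else detection_floor_mv
  eligible <- r[r$mep_pp > thr, , drop = FALSE]
  if (nrow(eligible) < k) {
    warning(sprintf("category %s skipped: %d eligible records < k = %d",
                    row$label, nrow(eligible), k))
    return(NULL)
  }
  ref_ids <- select_top_stimuli(records, muscle, k, reduce = "trial")
  ref <- multiply_maps(maps[ref_ids], surface, metric = metric,
                       muscle = muscle)
  with_local_seed(seed, {
    out <- lapply(seq_len(n_rep), function(rep) {
      draw <- eligible[sample.int(nrow(eligible), k), , drop = FALSE]
      hs <- multiply_maps(maps[as.character(draw$placement_id)], surface,
                          metric = metric, muscle = muscle)
      data.frame(category = row$label, repetition = rep,
                 cog_error_mm = sqrt(sum((hs$cog - ref$cog)^2)),
                 hotspot_area_mm2 = hs$area_mm2,
                 n_eligible = nrow(eligible))
    })
    do.call(rbind, out)
  })
}

#' Run the full mapping pipeline on one synthetic subject
#'
#' Generates the subject, the 24-placement sulcus-aligned protocol, solves
#' all placements, calibrates and simulates trial-level MEPs at every
#' intensity, maps both muscles with both EF metrics, fits the recruitment
#' sigmoids, estimates the RMT, and (optionally) runs the sample-count
#' sweep and the random-sampling localization study. Fully reproducible
#' from the configuration and its seed.
#'
#' @param config a \code{pipeline_config}.
#' @param run_sweep include the hotspot-area vs sample-count sweep.
#' @param run_categories include the random-sampling localization study
#'   (with this many repetitions; 0 disables it).
#' @param out_dir if non-NULL, write a JSON report and CSV/PLY artifacts.
#' @param verbose print stage progress.
#' @return a list report; see the elements \code{hotspots}, \code{fits},
#'   \code{rmt}, \code{sweep}, \code{localization}, \code{records}.
#' @export
run_pipeline <- function(config = pipeline_config(), run_sweep = TRUE,
                         run_categories = 100L, out_dir = NULL,
                         verbose = FALSE) {
  stage <- function(name, expr) {
    if (verbose) message("stage: ", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline failed at stage '%s': %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  subject <- stage("synthetic head", build_synthetic_head(
    config$spec, subdiv = config$subdiv))
  placements <- stage("placement grid", {
    poly <- scalp_sulcus_polyline(subject$head)
    placement_grid(poly, n_anchors = config$n_anchors,
                   spacing_mm = config$spacing_mm,
                   shifts_mm = config$shifts_mm,
                   pct_mso = config$eval_intensity_pct)
  })
  maps100 <- stage("EF solves", solve_all_placements(
    subject, placements, config$coil, tol = config$tol, verbose = verbose))
  subject <- stage("sigmoid calibration", calibrate_sigmoid_truth(
    subject, maps100, metric = "strength",
    target_rmt_pct = config$target_rmt_pct))
  maps_by_int <- stage("intensity scaling", {
    out <- lapply(config$intensities, function(pct)
      lapply(maps100, scale_map, pct_mso = pct))
    names(out) <- as.character(config$intensities)
    out
  })
  records <- stage("MEP simulation", {
    cfg <- mep_config(subject$sigmoid_truth,
                      noise_sigma_log = config$noise_sigma_log,
                      noise_floor_mv = config$noise_floor_mv,
                      seed = config$seed)
    all_maps <- do.call(c, unname(maps_by_int))
    simulate_meps(subject, all_maps, cfg,
                  trials_per_placement = config$trials_per_placement)
  })
  ev <- as.character(config$eval_intensity_pct)
  maps_ev <- maps_by_int[[ev]]
  rec_ev <- records[records$intensity_pct_mso == config$eval_intensity_pct, ]
  hotspots <- stage("hotspot mapping", {
    out <- list()
    for (muscle in names(subject$truth_sites)) {
      for (metric in c("strength", "normal")) {
        k <- if (metric == "strength") config$k_strength else config$k_normal
        ids <- select_top_stimuli(rec_ev, muscle, k)
        out[[paste(muscle, metric, sep = "_")]] <-
          multiply_maps(maps_ev[ids], subject$surface, metric = metric,
                        muscle = muscle)
      }
    }
    out
  })
  fits <- stage("sigmoid fits", {
    out <- list()
    for (muscle in names(subject$truth_sites)) {
      for (metric in c("strength", "normal")) {
        hs <- hotspots[[paste(muscle, metric, sep = "_")]]
        all_maps <- do.call(c, unname(maps_by_int))
        efmax <- ef_at_fit_point(all_maps, hs, metric = metric)
        med <- vapply(seq_along(all_maps), function(i) {
          m <- all_maps[[i]]
          stats::median(records$mep_pp[
            records$placement_id == m$stimulus_id &
            records$intensity_pct_mso == m$intensity_pct_mso &
            records$muscle == muscle])
        }, numeric(1L))
        out[[paste(muscle, metric, sep = "_")]] <- fit_sigmoid(efmax, med)
      }
    }
    out
  })
  rmt <- stage("RMT", lapply(stats::setNames(nm = names(subject$truth_sites)),
                             function(m) estimate_rmt(records, m,
                               criterion_mv = config$detection_floor_mv)))
  sweep <- NULL
  if (isTRUE(run_sweep)) {
    sweep <- stage("sample-count sweep", {
      out <- list()
      for (muscle in names(subject$truth_sites)) {
        for (metric in c("strength", "normal")) {
          sw <- sweep_sample_count(maps_ev, rec_ev, subject$surface,
                                   muscle, metric, k_range = 1:8)
          sw$muscle <- muscle
          sw$metric <- metric
          out[[paste(muscle, metric, sep = "_")]] <- sw
        }
      }
      do.call(rbind, out)
    })
  }
  localization <- NULL
  if (run_categories > 0L) {
    localization <- stage("random-sampling localization", {
      cats <- sampling_categories()
      out <- list()
      for (ci in seq_len(nrow(cats))) {
        res <- random_category_localization(
          maps_ev, rec_ev, subject$surface, muscle = "FDI",
          metric = "strength", category = cats$label[ci],
          n_rep = as.integer(run_categories), k = config$k_strength,
          seed = config$seed + 1000L * ci,
          detection_floor_mv = config$detection_floor_mv)
        if (!is.null(res)) out[[cats$label[ci]]] <- res
      }
      do.call(rbind, out)
    })
  }
  report <- list(config = config, subject = subject,
                 placements = placements, maps100 = maps100,
                 maps_eval = maps_ev, records = records,
                 hotspots = hotspots, fits = fits, rmt = rmt,
                 sweep = sweep, localization = localization,
                 n_solves = length(placements))
  if (!is.null(out_dir)) write_report(report, out_dir)
  invisible(report)
}

#' Summarize a pipeline report as plain data
#'
#' @param report result of \code{\link{run_pipeline}}.
#' @return list of plain vectors/data.frames suitable for JSON export.
#' @export
report_summary <- function(report) {
  hs <- lapply(report$hotspots, function(h)
    list(muscle = h$muscle, metric = h$metric, k = h$k_samples,
         area_mm2 = h$area_mm2, cog = as.numeric(h$cog)))
  ft <- lapply(report$fits, function(f)
    list(a = f$a, b = f$b, c = f$c, r2 = f$r2,
         ef_threshold = f$ef_threshold, ef_saturation = f$ef_saturation,
         divergent = f$divergent))
  truth_xyz <- lapply(report$subject$truth_sites, function(v)
    as.numeric(report$subject$surface$vertices[v, ]))
  list(seed = report$config$seed,
       n_placements = length(report$placements),
       n_solves = report$n_solves,
       n_records = nrow(report$records),
       truth_sites_mm = truth_xyz,
       hotspots = hs, fits = ft,
       rmt = report$rmt,
       sweep = report$sweep,
       localization_by_category = if (is.null(report$localization)) NULL
         else stats::aggregate(cog_error_mm ~ category + n_eligible,
                               data = report$localization,
                               FUN = stats::median))
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report_summary(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", force = TRUE)
  write_records_csv(report$records, file.path(out_dir, "records.csv"))
  write_placements_csv(report$placements,
                       file.path(out_dir, "placements.csv"))
  for (nm in names(report$hotspots)) {
    h <- report$hotspots[[nm]]
    write_ply(report$subject$surface,
              file.path(out_dir, paste0("hotspot_", nm, ".ply")),
              scalars = list(ef_focal = h$ef_focal))
  }
  invisible(out_dir)
}
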