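#' Select the placements with the highest MEPs
#'
#' Reduces the repeated trials of each placement to one value (median by
#' default) and returns the \code{k} placements with the largest reduced
#' MEP, in decreasing order. Ties are broken by placement id so the
#' selection is deterministic.
#'
#' @param records data.frame of trial-level stimulus records with columns
#'   \code{placement_id}, \code{trial}, \code{muscle}, \code{mep_pp} and
#'   optionally \code{intensity_pct_mso}.
#' @param muscle muscle label to select for.
#' @param k number of placements.
#' @param reduce trial reduction: \code{"median"}, \code{"max"}, or
#'   \code{"trial"} (rank placements by their single best trial).
#' @param intensity_pct_mso if given, restrict to records at this intensity.
#' @return character vector of k placement ids, highest MEP first.
#' @export
select_top_stimuli <- function(records, muscle, k,
                               reduce = c("median", "max", "trial"),
                               intensity_pct_mso = NULL) {
  reduce <- match.arg(reduce)
  r <- records[records$muscle == muscle, , drop = FALSE]
  if (!is.null(intensity_pct_mso))
    r <- r[r$intensity_pct_mso == intensity_pct_mso, , drop = FALSE]
  if (nrow(r) == 0L) stop("no records for muscle ", muscle)
  fn <- switch(reduce, median = stats::median, max = max, trial = max)
  agg <- stats::aggregate(mep_pp ~ placement_id, data = r, FUN = fn)
  if (k > nrow(agg))
    stop(sprintf("k = %d exceeds the %d distinct placements", k, nrow(agg)))
  ord <- order(-agg$mep_pp, agg$placement_id)
  as.character(agg$placement_id[ord][seq_len(k)])
}

#' Multiplicative hotspot map
#'
#' Multiplies the per-vertex EF maps of the selected stimuli to concentrate
#' the representation of the muscle that dominated the responses. Each map
#' is first normalized to unit maximum, the product is computed as a sum of
#' logs (floored at 1e-12 to avoid underflow), and the result is
#' renormalized to maximum 1. The hotspot mask keeps vertices above 0.1 of
#' the maximum; the area sums the full area of triangles whose mean vertex
#' value is suprathreshold; the center of gravity weights suprathreshold
#' vertex positions by map value times vertex area.
#'
#' @param maps list of \code{ef_surface_map} sharing one surface.
#' @param surface the common \code{cortical_surface}.
#' @param metric \code{"strength"} or \code{"normal"}.
#' @param muscle label stored in the result.
#' @param threshold relative threshold defining the hotspot (default 0.1).
#' @return object of class \code{hotspot_map}: \code{ef_focal} (per vertex,
#'   max 1), \code{mask}, \code{area_mm2}, \code{cog} (world mm),
#'   \code{k_samples}, \code{metric}, \code{muscle}.
#' @export
multiply_maps <- function(maps, surface, metric = c("strength", "normal"),
                          muscle = NA_character_, threshold = 0.1) {
  metric <- match.arg(metric)
  if (length(maps) < 1L) stop("need at least one map")
  nv <- nrow(surface$vertices)
  logsum <- numeric(nv)
  for (m in maps) {
    v <- map_metric(m, metric)
    if (length(v) != nv)
      stop("map vertex count does not match the surface")
    v <- v / max(v)
    logsum <- logsum + log(pmax(v, 1e-12))
  }
  ef_focal <- exp(logsum - max(logsum))
  mask <- ef_focal > threshold
  hs <- structure(list(muscle = muscle, metric = metric,
                       k_samples = length(maps), ef_focal = ef_focal,
                       mask = mask, threshold = threshold),
                  class = "hotspot_map")
  hs$area_mm2 <- hotspot_area(hs, surface)
  hs$cog <- center_of_gravity(hs, surface)
  hs
}

# Area of the suprathreshold region: triangles contribute their full area
# when the mean of their vertex values exceeds the threshold.
hotspot_area <- function(hotspot, surface) {
  tri_val <- (hotspot$ef_focal[surface$triangles[, 1L]] +
              hotspot$ef_focal[surface$triangles[, 2L]] +
              hotspot$ef_focal[surface$triangles[, 3L]]) / 3
  sum(surface$triangle_area_mm2[tri_val > hotspot$threshold])
}

#' Center of gravity of a hotspot
#'
#' Weighted centroid of the suprathreshold vertices, with weights
#' ef_focal x vertex area (set \code{binary = TRUE} for the unweighted
#' mask centroid).
#'
#' @param hotspot a \code{hotspot_map}.
#' @param surface the matching \code{cortical_surface}.
#' @param binary use binary mask weights instead of map-value weights.
#' @return world mm coordinates (length 3).
#' @export
center_of_gravity <- function(hotspot, surface, binary = FALSE) {
  idx <- which(hotspot$mask)
  if (length(idx) == 0L) stop("hotspot mask is empty")
  w <- if (binary) surface$vertex_area_mm2[idx]
       else hotspot$ef_focal[idx] * surface$vertex_area_mm2[idx]
  colSums(surface$vertices[idx, , drop = FALSE] * w) / sum(w)
}

#' Euclidean distance between two hotspot centers of gravity
#' @param map_a,map_b \code{hotspot_map} objects with computed \code{cog}.
#' @return distance in mm.
#' @export
cog_distance <- function(map_a, map_b) {
  sqrt(sum((map_a$cog - map_b$cog)^2))
}

#' Group-level hotspot on a shared surface topology
#'
#' Vertex-wise sum of the unit-maximum-normalized individual hotspot maps.
#' All subjects must share the template vertex indexing (synthetic subjects
#' built from a common icosphere template do).
#'
#' @param hotspots list of \code{hotspot_map} on the same topology.
#' @return numeric per-vertex group map (max <= number of subjects).
#' @export
group_hotspot <- function(hotspots) {
  nv <- length(hotspots[[1L]]$ef_focal)
  out <- numeric(nv)
  for (h in hotspots) {
    if (length(h$ef_focal) != nv)
      stop("hotspot topology mismatch: differing vertex counts")
    out <- out + h$ef_focal / max(h$ef_focal)
  }
  out
}

#' @export
print.hotspot_map <- function(x, ...) {
  cat(sprintf("<hotspot_map> %s / %s, k = %d: area %.1f mm^2, CoG (%.1f, %.1f, %.1f)\n",
              x$muscle, x$metric, x$k_samples, x$area_mm2,
              x$cog[1L], x$cog[2L], x$cog[3L]))
  invisible(x)
}
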