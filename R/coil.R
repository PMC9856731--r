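#' Figure-8 coil model
#'
#' Thin-wire idealization of a commercial figure-8 coil: two coplanar wings
#' of concentric circular loops with opposite winding sense, tangent to each
#' other at the coil center so the currents of the two wings run in the same
#' direction under the center (where the induced field is strongest).
#'
#' @param loops_per_wing number of concentric loops per wing.
#' @param inner_diameter_mm,outer_diameter_mm diameters of the innermost and
#'   outermost loops.
#' @param segments_per_loop straight segments discretizing each loop.
#' @param didt_at_100pct coil current time derivative at 100\% stimulator
#'   output, A/microsecond.
#' @return an object of class \code{coil_model}.
#' @export
coil_model <- function(loops_per_wing = 9L, inner_diameter_mm = 55,
                       outer_diameter_mm = 92, segments_per_loop = 72L,
                       didt_at_100pct = 174) {
  radii <- seq(inner_diameter_mm / 2, outer_diameter_mm / 2,
               length.out = loops_per_wing)
  structure(list(loops_per_wing = as.integer(loops_per_wing),
                 loop_radii_mm = radii,
                 segments_per_loop = as.integer(segments_per_loop),
                 didt_at_100pct = didt_at_100pct),
            class = "coil_model")
}

#' Coil placement: rigid pose plus stimulator intensity
#'
#' The pose is given by the scalp contact position and an orthonormal,
#' right-handed triad: the induced-current direction under the coil center,
#' the handle direction (the line joining the two wing centers), and the
#' outward coil-plane normal.
#'
#' @param position world mm.
#' @param current_dir direction of the induced current under the center.
#' @param normal outward coil-plane normal.
#' @param handle_dir optional; derived as \code{normal x current_dir} when
#'   omitted.
#' @param pct_mso stimulator intensity in (0, 100].
#' @param id placement identifier.
#' @return an object of class \code{coil_placement}.
#' @export
coil_placement <- function(position, current_dir, normal, handle_dir = NULL,
                           pct_mso = 100, id = "p1") {
  unit <- function(v) v / sqrt(sum(v^2))
  c_dir <- unit(current_dir)
  n_dir <- unit(normal)
  # re-orthogonalize current against the normal
  c_dir <- unit(c_dir - sum(c_dir * n_dir) * n_dir)
  h_dir <- if (is.null(handle_dir)) cross3(n_dir, c_dir) else unit(handle_dir)
  triad <- cbind(c_dir, h_dir, n_dir, deparse.level = 0)
  g <- crossprod(triad)
  if (max(abs(g - diag(3))) > 1e-9)
    stop("placement triad is not orthonormal")
  if (det(triad) < 0)
    stop("placement triad is not right-handed")
  if (pct_mso <= 0 || pct_mso > 100)
    stop("pct_mso must be in (0, 100]")
  structure(list(position = as.numeric(position), triad = triad,
                 intensity_pct_mso = pct_mso, id = id),
            class = "coil_placement")
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Discretized wire path of a placed figure-8 coil
#'
#' Positions the two wings in the coil plane (normal = triad normal) with
#' wing centers at plus/minus the outer loop radius along the handle axis,
#' so the wings are tangent at the placement position. Winding senses are
#' opposite, making the wire currents co-directed (along the current-
#' direction triad vector) under the center.
#'
#' @param coil a \code{coil_model}.
#' @param placement a \code{coil_placement}.
#' @param standoff_mm distance from the scalp to the coil plane along the
#'   coil normal.
#' @return list of closed polylines; each element has \code{points} (n x 3,
#'   world mm, first point not repeated) and \code{sense} (+1/-1).
#' @export
coil_wire_path <- function(coil, placement, standoff_mm = 0) {
  ns <- coil$segments_per_loop
  c_dir <- placement$triad[, 1L]
  h_dir <- placement$triad[, 2L]
  n_dir <- placement$triad[, 3L]
  center <- placement$position + standoff_mm * n_dir
  r_out <- max(coil$loop_radii_mm)
  loops <- list()
  for (wing in c(1, -1)) {
    wc <- center + wing * r_out * h_dir
    for (r in coil$loop_radii_mm) {
      # wing at +h winds clockwise (sense -1), wing at -h counter-clockwise,
      # so the segments nearest the center both run along +current_dir
      theta <- if (wing > 0) -2 * pi * (0:(ns - 1)) / ns
               else 2 * pi * (0:(ns - 1)) / ns
      pts <- sweep(outer(r * cos(theta), h_dir) + outer(r * sin(theta), c_dir),
                   2L, wc, "+")
      loops[[length(loops) + 1L]] <- list(points = pts, sense = wing * -1)
    }
  }
  loops
}

# Segment midpoints and signed segment vectors (mm) of a wire path.
wire_segments <- function(path) {
  mids <- list()
  dls <- list()
  for (lp in path) {
    p <- lp$points
    pn <- rbind(p[-1L, , drop = FALSE], p[1L, , drop = FALSE])
    mids[[length(mids) + 1L]] <- (p + pn) / 2
    dls[[length(dls) + 1L]] <- pn - p
  }
  list(mids = do.call(rbind, mids), dl = do.call(rbind, dls))
}

#' Time derivative of the magnetic vector potential of a wire path
#'
#' Biot-Savart integral over the discretized wire with midpoint quadrature:
#' dA/dt(r) = (mu0 dI/dt / 4 pi) sum_j dl_j / |r - r_j|, with mu0 =
#' 4 pi x 10^-7 exactly. Linear in \code{didt}.
#'
#' @param path wire path from \code{\link{coil_wire_path}}.
#' @param points_mm field points, n x 3 world mm.
#' @param didt coil current time derivative, A/microsecond.
#' @param guard_mm minimum allowed distance from any field point to the wire.
#' @return n x 3 matrix of dA/dt in V/m.
#' @export
vector_potential <- function(path, points_mm, didt, guard_mm = 0.1) {
  seg <- wire_segments(path)
  points_mm <- rbind(points_mm)
  res <- bs_dadt_cpp(points_mm * 1e-3, seg$mids * 1e-3, seg$dl * 1e-3,
                     didt * 1e6)
  bad <- res$min_dist < guard_mm * 1e-3
  if (any(bad)) {
    w <- which.min(res$min_dist)
    stop(sprintf("field point %d at (%.2f, %.2f, %.2f) is within %.3f mm of the coil wire",
                 w, points_mm[w, 1L], points_mm[w, 2L], points_mm[w, 3L],
                 res$min_dist[w] * 1e3))
  }
  res$field
}

#' Scalp polyline along the synthetic central sulcus
#'
#' The fold of the synthetic head runs along y at x = 0; its scalp
#' projection is an arc of the great circle x = 0 on the skin sphere,
#' centered on the vertex of the head.
#'
#' @param head a \code{voxel_head} built by \code{\link{build_head_volume}}.
#' @param length_mm total arc length of the polyline.
#' @param step_mm sampling step along the arc.
#' @return matrix of world mm points ordered along the sulcus.
#' @export
scalp_sulcus_polyline <- function(head, length_mm = 60, step_mm = 1) {
  r <- scalp_radius(head)
  ang <- seq(-length_mm / 2, length_mm / 2, by = step_mm) / r
  cbind(0, r * sin(ang), r * cos(ang))
}

# Outer skin radius recovered from the label volume (max radius of skin
# voxel centers plus half a voxel).
scalp_radius <- function(head) {
  idx <- which(head$labels == 1L)
  p <- voxel_centers(head, idx)
  max(sqrt(rowSums(p^2))) + head$voxel_size_mm / 2
}

#' Sulcus-aligned grid of coil placements
#'
#' Places \code{n_anchors} anchor points at \code{spacing_mm} intervals of
#' arc length along the scalp sulcus polyline, centered on the polyline
#' middle, then shifts each anchor along the induced-current direction by
#' each of \code{shifts_mm} (re-projected onto the scalp). At every
#' placement the current direction is perpendicular to the local sulcus
#' tangent and tangent to the scalp, and the coil normal is the outward
#' scalp normal.
#'
#' @param polyline scalp sulcus polyline (ordered points, world mm).
#' @param n_anchors number of anchors along the sulcus.
#' @param spacing_mm anchor spacing (arc length).
#' @param shifts_mm perpendicular shifts applied to every anchor.
#' @param pct_mso stimulator intensity stored in each placement.
#' @return list of \code{coil_placement} (length n_anchors x length(shifts)).
#' @export
placement_grid <- function(polyline, n_anchors = 8L, spacing_mm = 5,
                           shifts_mm = c(-5, 0, 5), pct_mso = 100) {
  if (nrow(polyline) < 2L)
    stop("degenerate sulcus polyline: need at least 2 points")
  seglen <- sqrt(rowSums(diff(polyline)^2))
  s <- c(0, cumsum(seglen))
  total <- s[length(s)]
  span <- (n_anchors - 1L) * spacing_mm
  if (span > total)
    stop(sprintf("polyline too short (%.1f mm) for %d anchors at %.1f mm spacing",
                 total, n_anchors, spacing_mm))
  s0 <- (total - span) / 2
  at <- s0 + spacing_mm * (seq_len(n_anchors) - 1L)
  interp <- function(si) {
    j <- findInterval(si, s, rightmost.closed = TRUE)
    t <- (si - s[j]) / seglen[j]
    polyline[j, ] + t * (polyline[j + 1L, ] - polyline[j, ])
  }
  unit <- function(v) v / sqrt(sum(v^2))
  placements <- list()
  for (a in seq_len(n_anchors)) {
    p <- interp(at[a])
    tangent <- unit(interp(min(at[a] + 0.5, total)) -
                    interp(max(at[a] - 0.5, 0)))
    n_dir <- unit(p)          # spherical scalp: outward normal is radial
    tangent <- unit(tangent - sum(tangent * n_dir) * n_dir)
    c_dir <- unit(cross3(tangent, n_dir))
    r <- sqrt(sum(p^2))
    for (sh in shifts_mm) {
      q <- p + sh * c_dir
      q <- unit(q) * r       # re-project onto the scalp sphere
      nq <- unit(q)
      cq <- unit(c_dir - sum(c_dir * nq) * nq)
      placements[[length(placements) + 1L]] <-
        coil_placement(position = q, current_dir = cq, normal = nq,
                       pct_mso = pct_mso,
                       id = sprintf("a%02d_s%+03d", a, as.integer(sh)))
    }
  }
  placements
}

#' @export
print.coil_model <- function(x, ...) {
  cat(sprintf("<coil_model> 2 wings x %d loops (r %.1f..%.1f mm), %d segments/loop, %.0f A/us at 100%% MSO\n",
              x$loops_per_wing, min(x$loop_radii_mm), max(x$loop_radii_mm),
              x$segments_per_loop, x$didt_at_100pct))
  invisible(x)
}
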