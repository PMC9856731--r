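#' @useDynLib tmsmap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Subdivided icosahedron on the unit sphere. Returns list(vertices, triangles)
# with consistent outward (counter-clockwise) triangle orientation.
icosphere <- function(subdiv = 5L) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    cache <- new.env(hash = TRUE, parent = emptyenv())
    nv <- nrow(v)
    newv <- vector("list", 0L)
    midpoint <- function(i, j) {
      key <- if (i < j) paste0(i, "_", j) else paste0(j, "_", i)
      hit <- cache[[key]]
      if (!is.null(hit)) return(hit)
      m <- v[i, ] + v[j, ]
      m <- m / sqrt(sum(m^2))
      nv <<- nv + 1L
      newv[[length(newv) + 1L]] <<- m
      cache[[key]] <- nv
      nv
    }
    nf <- matrix(0L, nrow(f) * 4L, 3L)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1L]; b <- f[k, 2L]; c <- f[k, 3L]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      nf[(k - 1L) * 4L + 1L, ] <- c(a, ab, ca)
      nf[(k - 1L) * 4L + 2L, ] <- c(b, bc, ab)
      nf[(k - 1L) * 4L + 3L, ] <- c(c, ca, bc)
      nf[(k - 1L) * 4L + 4L, ] <- c(ab, bc, ca)
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- nf
  }
  list(vertices = v, triangles = f)
}

# Nearest-voxel label lookup at world points; 0 outside the grid.
label_at <- function(head, points) {
  h <- head$voxel_size_mm
  t0 <- head$affine[1:3, 4L]
  ii <- round(sweep(points, 2L, t0, "-") / h) + 1
  d <- head$dims
  ok <- ii[, 1L] >= 1 & ii[, 1L] <= d[1L] &
        ii[, 2L] >= 1 & ii[, 2L] <= d[2L] &
        ii[, 3L] >= 1 & ii[, 3L] <= d[3L]
  out <- integer(nrow(points))
  flat <- (ii[ok, 1L] - 1) + d[1L] * ((ii[ok, 2L] - 1) + d[2L] * (ii[ok, 3L] - 1)) + 1
  out[ok] <- head$labels[flat]
  out
}

#' Extract the cortical sampling surface from a voxel head model
#'
#' Casts a ray from outside the head toward the volume center along every
#' direction of a subdivided icosphere, locates the outer gray-matter
#' boundary on each ray, and places the surface vertex \code{depth_mm}
#' inside the gray matter along the ray. This ray-casting construction is
#' exact for the star-shaped synthetic geometries produced by
#' \code{\link{build_head_volume}} (every ray from the center crosses each
#' tissue boundary once) and avoids a full marching-cubes triangulation.
#'
#' @param head a \code{voxel_head}.
#' @param depth_mm sampling depth inside gray matter, >= 0; must be smaller
#'   than the local cortical thickness everywhere.
#' @param subdiv icosphere subdivision level (5 gives ~0.9 mm edges on the
#'   default phantom).
#' @param cap_cos keep only vertices whose direction has z-component above
#'   this value (the stimulated top of the head); use -1 for a closed
#'   surface.
#' @param smooth_passes Laplacian smoothing passes applied to the ray radii
#'   to suppress the voxelization staircase.
#' @return an object of class \code{cortical_surface} with fields
#'   \code{vertices} (world mm), \code{triangles}, \code{vertex_normals}
#'   (outward unit), \code{vertex_area_mm2}, \code{directions}.
#' @export
extract_surface <- function(head, depth_mm = 0.8, subdiv = 5L,
                            cap_cos = 0.25, smooth_passes = 2L) {
  if (depth_mm < 0) stop("depth_mm must be >= 0")
  ico <- icosphere(subdiv)
  keep <- ico$vertices[, 3L] > cap_cos
  vid <- which(keep)
  tri_keep <- matrix(keep[ico$triangles], ncol = 3L)
  tri <- ico$triangles[rowSums(tri_keep) == 3L, , drop = FALSE]
  remap <- integer(nrow(ico$vertices))
  remap[vid] <- seq_along(vid)
  tri <- matrix(remap[tri], ncol = 3L)
  dirs <- ico$vertices[vid, , drop = FALSE]

  h <- head$voxel_size_mm
  rmax <- max(abs(head$affine[1:3, 4L])) + h
  step <- h / 4
  radii <- seq(rmax, step, by = -step)
  nd <- nrow(dirs)
  outer_gray <- rep(NA_real_, nd)
  inner_gray <- rep(NA_real_, nd)
  # march inward; record the first (outermost) gray sample and the first
  # white sample, which bracket the cortical ribbon along the ray
  alive_outer <- rep(TRUE, nd)
  alive_inner <- rep(TRUE, nd)
  for (r in radii) {
    need <- alive_outer | alive_inner
    if (!any(need)) break
    lab <- integer(nd)
    lab[need] <- label_at(head, dirs[need, , drop = FALSE] * r)
    hit_g <- alive_outer & lab == 4L
    outer_gray[hit_g] <- r
    alive_outer[hit_g] <- FALSE
    hit_w <- alive_inner & lab == 5L
    inner_gray[hit_w] <- r
    alive_inner[hit_w] <- FALSE
  }
  if (anyNA(outer_gray))
    stop("no gray matter found along ", sum(is.na(outer_gray)), " rays")
  # Laplacian passes on the ray radii remove the sub-voxel staircase of the
  # label volume (quantized at step/2) without affecting structure at the
  # fold scale (mesh edges are ~1-2 mm, the fold is >10 mm wide)
  for (p in seq_len(smooth_passes))
    outer_gray <- smooth_vertex_field(outer_gray, tri, lambda = 0.5)
  thick <- outer_gray - ifelse(is.na(inner_gray), 0, inner_gray)
  bad <- depth_mm >= thick
  if (any(bad)) {
    w <- which.max(depth_mm - thick)
    p <- dirs[w, ] * outer_gray[w]
    stop(sprintf(paste0("depth %.2f mm exceeds cortical thickness at %d ",
                        "vertices; thinnest ribbon %.2f mm near world ",
                        "(%.1f, %.1f, %.1f)"),
                 depth_mm, sum(bad), min(thick), p[1L], p[2L], p[3L]))
  }
  verts <- dirs * (outer_gray - depth_mm)

  surf <- list(vertices = verts, triangles = tri, directions = dirs)
  surf <- add_surface_geometry(surf)
  if (depth_mm > 0) {
    # second pass: depth_mm is meant perpendicular to the cortical sheet;
    # where the ray meets the surface obliquely (sulcal walls), the along-ray
    # offset must be depth / cos(angle), capped for near-tangential rays
    cosang <- pmin(pmax(rowSums(dirs * surf$vertex_normals), 0.3), 1)
    depth_ray <- depth_mm / cosang
    bad2 <- depth_ray >= thick
    depth_ray[bad2] <- pmax(depth_mm, 0.9 * thick[bad2])
    surf$vertices <- dirs * (outer_gray - depth_ray)
    surf <- add_surface_geometry(surf)
  }
  class(surf) <- "cortical_surface"
  surf
}

# One umbrella-operator smoothing step of a per-vertex field:
# x <- (1 - lambda) x + lambda * mean over 1-ring neighbors.
smooth_vertex_field <- function(x, tri, lambda = 0.5) {
  edges <- rbind(tri[, c(1L, 2L)], tri[, c(2L, 3L)], tri[, c(3L, 1L)])
  edges <- rbind(edges, edges[, 2:1])
  acc <- rowsum(x[edges[, 2L]], edges[, 1L], reorder = FALSE)
  cnt <- rowsum(rep(1, nrow(edges)), edges[, 1L], reorder = FALSE)
  ids <- as.integer(rownames(acc))
  nb_mean <- x
  nb_mean[ids] <- acc[, 1L] / cnt[, 1L]
  (1 - lambda) * x + lambda * nb_mean
}

# Per-triangle areas and outward vertex normals / barycentric vertex areas.
add_surface_geometry <- function(surf) {
  v <- surf$vertices
  f <- surf$triangles
  e1 <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  e2 <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  cr <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
              e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
              e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  tri_area <- sqrt(rowSums(cr^2)) / 2
  nrm <- matrix(0, nrow(v), 3L)
  varea <- numeric(nrow(v))
  for (j in 1:3) {
    acc <- rowsum(cr / 2, f[, j], reorder = FALSE)
    ids <- as.integer(rownames(acc))
    nrm[ids, ] <- nrm[ids, ] + acc
    acc_a <- rowsum(tri_area / 3, f[, j], reorder = FALSE)
    varea[ids] <- varea[ids] + acc_a[, 1L]
  }
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  surf$vertex_normals <- nrm / len
  surf$vertex_area_mm2 <- varea
  surf$triangle_area_mm2 <- tri_area
  surf
}

#' Total surface area
#' @param surface a \code{cortical_surface}.
#' @return area in mm^2.
#' @export
surface_area <- function(surface) sum(surface$triangle_area_mm2)

#' @export
print.cortical_surface <- function(x, ...) {
  cat(sprintf("<cortical_surface> %d vertices, %d triangles, %.0f mm^2\n",
              nrow(x$vertices), nrow(x$triangles), surface_area(x)))
  invisible(x)
}
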