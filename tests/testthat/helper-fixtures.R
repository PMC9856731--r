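# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# Homogeneous gray cube of n^3 conducting voxels with a background shell.
cube_head <- function(n, h = 1) {
  dims <- rep(n + 2L, 3L)
  labels <- array(0L, dims)
  labels[2:(n + 1), 2:(n + 1), 2:(n + 1)] <- 4L
  affine <- diag(c(h, h, h, 1))
  affine[1:3, 4L] <- -(dims[1L] - 1) / 2 * h
  structure(list(dims = dims, voxel_size_mm = h, affine = affine,
                 labels = labels, conductivity = default_cond()),
            class = "voxel_head")
}

default_cond <- function() {
  c(skin = 0.465, skull = 0.010, csf = 1.654, gray = 0.275, white = 0.126)
}

# Voxelized sphere, homogeneous or 3-layer, same outer radius.
sphere_head <- function(R, h = 1, layered = FALSE) {
  n <- 2L * as.integer(ceiling((R + 2 * h) / h)) + 1L
  dims <- c(n, n, n)
  ax <- (seq_len(n) - 1 - (n - 1) / 2) * h
  r <- sqrt(outer(outer(ax^2, ax^2, "+"), ax^2, "+"))
  labels <- array(0L, dims)
  if (layered) {
    labels[r <= R] <- 1L
    labels[r <= 0.8 * R] <- 2L
    labels[r <= 0.55 * R] <- 4L
  } else {
    labels[r <= R] <- 4L
  }
  affine <- diag(c(h, h, h, 1))
  affine[1:3, 4L] <- -(n - 1) / 2 * h
  structure(list(dims = dims, voxel_size_mm = h, affine = affine,
                 labels = labels, conductivity = default_cond()),
            class = "voxel_head")
}

# dA/dt of a magnetic point dipole at pos (mm) with moment m, evaluated at
# the conducting voxel centers. A = mu0/(4 pi) m x r / |r|^3; the scale
# plays the role of the moment's time derivative.
dipole_dadt <- function(head, pos, m = c(1, 0, 0), scale = 1e5) {
  cells <- conducting_cells(head)
  p <- sweep(voxel_centers(head, cells), 2L, pos, "-") * 1e-3
  r3 <- sqrt(rowSums(p^2))^3
  scale * 1e-7 * cbind(m[2L] * p[, 3L] - m[3L] * p[, 2L],
                       m[3L] * p[, 1L] - m[1L] * p[, 3L],
                       m[1L] * p[, 2L] - m[2L] * p[, 1L]) / r3
}

# Minimal hand-made surface map for the hotspot algebra tests.
fake_map <- function(strength, normal = strength / 2, id = "m",
                     pct = 55) {
  structure(list(stimulus_id = id, E = NULL, strength = strength,
                 normal = normal, signed_normal = normal,
                 intensity_pct_mso = pct),
            class = "ef_surface_map")
}

# Minimal flat surface: nv vertices on a unit grid in the z = 0 plane,
# fan-triangulated strips, uniform vertex areas.
fake_surface <- function(vertices, triangles) {
  surf <- list(vertices = vertices, triangles = triangles)
  surf <- tmsmap:::add_surface_geometry(surf)
  class(surf) <- "cortical_surface"
  surf
}

strip_surface <- function(nv) {
  # two rows of nv/2 vertices, unit squares split into triangles
  stopifnot(nv %% 2 == 0)
  m <- nv / 2
  v <- rbind(cbind(seq_len(m) - 1, 0, 0), cbind(seq_len(m) - 1, 1, 0))
  tri <- do.call(rbind, lapply(seq_len(m - 1), function(i) {
    rbind(c(i, i + 1, m + i), c(i + 1, m + i + 1, m + i))
  }))
  fake_surface(v, tri)
}

# Default subject at desk resolution (1 mm) with its 24-placement protocol
# solved at 100% MSO -- the expensive shared fixture.
fx_run1 <- function() fx("run1", function() {
  cfg <- pipeline_config(seed = 1L)
  run_pipeline(cfg, run_sweep = TRUE, run_categories = 0L)
})

# Coarse (2 mm) subject + solved maps for cheap qualitative tests.
fx_run2 <- function() fx("run2", function() {
  cfg <- pipeline_config(spec = head_spec(voxel_size_mm = 2), seed = 3L,
                         noise_sigma_log = 0, noise_floor_mv = 0)
  run_pipeline(cfg, run_sweep = TRUE, run_categories = 0L)
})

# Noise-free records on the 1 mm fixture (same subject and maps).
fx_records1_noisefree <- function() fx("rec1nf", function() {
  run <- fx_run1()
  maps_all <- do.call(c, unname(lapply(c(35, 45, 55), function(p)
    lapply(run$maps100, scale_map, pct_mso = p))))
  cfg <- mep_config(run$subject$sigmoid_truth, noise_sigma_log = 0,
                    noise_floor_mv = 0, seed = 7L)
  simulate_meps(run$subject, maps_all, cfg)
})
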