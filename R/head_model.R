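#' Geometry specification for a synthetic layered head
#'
#' Defines a compact spherical head phantom with five nested tissue layers
#' (skin, skull, CSF, gray matter, white matter) and a single
#' central-sulcus-like fold: a sinusoidal invagination of the cortical
#' boundaries along a line across the top of the head. The fold is the
#' minimal geometry distinguishing gyral crown from sulcal wall and lip.
#'
#' All lengths are millimetres. The default head is a desk-scale phantom
#' (skin radius 40 mm, scalp-to-cortex about 12 mm) rather than an
#' adult-sized head, keeping voxel counts small while preserving the layer
#' ordering and conductivity contrasts that shape the induced field.
#'
#' @param r_skin_mm outer skin radius.
#' @param t_skin_mm,t_skull_mm,t_csf_mm,t_gray_mm layer thicknesses; white
#'   matter fills the remainder.
#' @param fold_amplitude_mm depth of the sulcal invagination (0 = smooth cap).
#' @param fold_wavelength_mm width of one full sinusoidal period; the groove
#'   occupies half a period centred on the fold line.
#' @param fold_length_mm extent of the fold along the sulcus direction (y).
#' @param voxel_size_mm isotropic voxel edge, must be >= 0.4.
#' @param conductivity named vector of tissue conductivities in S/m.
#' @param truth_offset_mm target separation between the two planted muscle
#'   representation sites along the fold.
#' @param seed integer seed controlling subject-level jitter.
#' @return an object of class \code{head_spec}.
#' @export
head_spec <- function(r_skin_mm = 40,
                      t_skin_mm = 4.5,
                      t_skull_mm = 6,
                      t_csf_mm = 1.5,
                      t_gray_mm = 3.5,
                      fold_amplitude_mm = 7,
                      fold_wavelength_mm = 12,
                      fold_length_mm = 32,
                      voxel_size_mm = 1.0,
                      conductivity = c(skin = 0.465, skull = 0.010,
                                       csf = 1.654, gray = 0.275,
                                       white = 0.126),
                      truth_offset_mm = 3,
                      seed = 1L) {
  if (voxel_size_mm < 0.4)
    stop("voxel_size_mm must be >= 0.4")
  radii <- c(skin = r_skin_mm,
             skull = r_skin_mm - t_skin_mm,
             csf = r_skin_mm - t_skin_mm - t_skull_mm,
             gray = r_skin_mm - t_skin_mm - t_skull_mm - t_csf_mm,
             white = r_skin_mm - t_skin_mm - t_skull_mm - t_csf_mm - t_gray_mm)
  nm <- names(radii)
  for (i in seq_len(length(radii) - 1L)) {
    if (radii[i + 1L] >= radii[i])
      stop(sprintf("layers not nested: %s (outer radius %.2f) must strictly contain %s (outer radius %.2f)",
                   nm[i], radii[i], nm[i + 1L], radii[i + 1L]))
  }
  if (radii["white"] <= 0)
    stop("layers not nested: white matter core has non-positive radius")
  miss <- setdiff(c("skin", "skull", "csf", "gray", "white"),
                  names(conductivity))
  if (length(miss))
    stop("conductivity table missing: ", paste(miss, collapse = ", "))
  if (any(conductivity <= 0))
    stop("all tissue conductivities must be > 0")
  spec <- list(radii = radii,
               fold_amplitude_mm = fold_amplitude_mm,
               fold_wavelength_mm = fold_wavelength_mm,
               fold_length_mm = fold_length_mm,
               voxel_size_mm = voxel_size_mm,
               conductivity = conductivity[c("skin", "skull", "csf",
                                             "gray", "white")],
               truth_offset_mm = truth_offset_mm,
               seed = as.integer(seed))
  class(spec) <- "head_spec"
  spec
}

#' Tissue labels used in the voxel head model
#' @return named integer vector mapping tissue name to label code.
#' @export
tissue_labels <- function() {
  c(background = 0L, skin = 1L, skull = 2L, csf = 3L, gray = 4L, white = 5L)
}

# Depression depth of the cortical boundaries for unit directions n (rows).
# u = arc coordinate across the fold (x), v = along the fold (y), both taken
# on the outer gray sphere; the cap weight confines the fold to the top of
# the head so it tapers smoothly to zero away from the vertex.
fold_depth <- function(n, spec) {
  rg <- spec$radii[["gray"]]
  u <- rg * n[, 1L]
  v <- rg * n[, 2L]
  lam <- spec$fold_wavelength_mm
  lhalf <- spec$fold_length_mm / 2
  cap0 <- 0.5
  capw <- pmin(pmax((n[, 3L] - cap0) / (1 - cap0), 0), 1)
  du <- ifelse(abs(u) <= lam / 2, cos(pi * u / lam)^2, 0)
  dv <- ifelse(abs(v) <= lhalf, cos(pi * v / (2 * lhalf))^2, 0)
  spec$fold_amplitude_mm * du * dv * capw
}

# Voxel-center coordinates of the regular grid, one axis.
grid_axis <- function(dim, h) (seq_len(dim) - 1 - (dim - 1) / 2) * h

#' Build the labeled voxel volume for a head specification
#'
#' Voxelizes the nested spherical layers on a regular grid with a guaranteed
#' background (air) shell at the volume border. The cortical boundaries
#' (CSF/gray and gray/white) are displaced inward by the fold depth so the
#' groove is filled by CSF, mimicking a sulcus.
#'
#' @param spec a \code{head_spec}.
#' @return an object of class \code{voxel_head} with fields \code{dims},
#'   \code{voxel_size_mm}, \code{affine} (voxel index, 0-based, to world mm,
#'   RAS), \code{labels} (integer array) and \code{conductivity}.
#' @export
build_head_volume <- function(spec) {
  h <- spec$voxel_size_mm
  half <- spec$radii[["skin"]] + 2 * h
  n <- 2L * as.integer(ceiling(half / h)) + 1L
  dims <- c(n, n, n)
  ax <- grid_axis(n, h)
  # radius of every voxel center
  r2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  r <- sqrt(r2)
  labels <- array(0L, dims)
  rad <- spec$radii
  labels[r <= rad[["skin"]]] <- 1L
  labels[r <= rad[["skull"]]] <- 2L
  labels[r <= rad[["csf"]]] <- 3L
  # fold displacement applies only to the cortical boundaries; evaluate it
  # on the voxels that could possibly be reassigned
  cand <- which(r <= rad[["csf"]] & r > 1e-9)
  idx <- arrayInd(cand, dims)
  p <- cbind(ax[idx[, 1L]], ax[idx[, 2L]], ax[idx[, 3L]])
  rc <- r[cand]
  d <- fold_depth(p / rc, spec)
  lab <- rep(3L, length(cand))
  lab[rc <= rad[["gray"]] - d] <- 4L
  lab[rc <= rad[["white"]] - d] <- 5L
  labels[cand] <- lab
  labels[r <= 1e-9] <- 5L
  affine <- diag(c(h, h, h, 1))
  affine[1:3, 4L] <- -(n - 1) / 2 * h
  head <- list(dims = dims, voxel_size_mm = h, affine = affine,
               labels = labels, conductivity = spec$conductivity)
  class(head) <- "voxel_head"
  validate_head(head)
  head
}

#' Validate a voxel head model
#'
#' Checks the structural invariants: every nonzero label has a positive
#' conductivity, the outermost voxel shell is background (insulating
#' boundary), and gray matter is present and adjoins CSF and white matter.
#'
#' @param head a \code{voxel_head}.
#' @return the head, invisibly; stops on violation.
#' @export
validate_head <- function(head) {
  labs <- sort(unique(as.integer(head$labels)))
  tl <- tissue_labels()
  unknown <- setdiff(labs, tl)
  if (length(unknown))
    stop("unknown labels in volume: ", paste(unknown, collapse = ", "))
  sig <- conductivity_by_label(head)
  for (l in setdiff(labs, 0L)) {
    if (!is.finite(sig[l + 1L]) || sig[l + 1L] <= 0)
      stop(sprintf("label %d has no conductivity", l))
  }
  d <- head$dims
  shell <- c(head$labels[c(1L, d[1L]), , ],
             head$labels[, c(1L, d[2L]), ],
             head$labels[, , c(1L, d[3L])])
  if (any(shell != 0L))
    stop("outermost voxel shell is not entirely background")
  invisible(head)
}

# sigma indexed by label + 1 (background first, sigma 0)
conductivity_by_label <- function(head) {
  c(0, head$conductivity[c("skin", "skull", "csf", "gray", "white")])
}

#' World coordinates of voxel centers
#' @param head a \code{voxel_head}.
#' @param flat_idx flat (column-major) voxel indices, 1-based.
#' @return matrix of world mm coordinates.
#' @export
voxel_centers <- function(head, flat_idx) {
  idx <- arrayInd(flat_idx, head$dims) - 1L
  sweep(idx %*% t(head$affine[1:3, 1:3]), 2L, head$affine[1:3, 4L], "+")
}

#' Generate a complete synthetic subject
#'
#' Builds the voxel head model, extracts the cortical sampling surface at
#' the requested depth inside gray matter, paints fold regions (crown, lip,
#' wall, fundus), and plants two ground-truth muscle representation sites on
#' the fold lip: an FDI-analog site and an ADM-analog site displaced along
#' the fold by \code{truth_offset_mm}. Subject-level jitter (driven by
#' \code{spec$seed}) perturbs the fold amplitude and the truth-site offset
#' slightly so that cohorts of subjects are not all identical; the same spec
#' and seed always reproduce the same subject bit for bit.
#'
#' @param spec a \code{head_spec}.
#' @param surface_depth_mm sampling depth inside gray matter (default 0.8).
#' @param subdiv icosphere subdivision level of the sampling surface.
#' @return an object of class \code{synthetic_subject} with fields
#'   \code{head}, \code{surface}, \code{truth_sites} (muscle -> vertex
#'   index), \code{sigmoid_truth}, \code{noise_sigma_log}, \code{seed}.
#' @export
build_synthetic_head <- function(spec = head_spec(), surface_depth_mm = 0.8,
                                 subdiv = 5L) {
  # subject-level jitter, isolated from the global RNG
  jit <- with_local_seed(spec$seed, {
    list(amp = stats::runif(1, -0.05, 0.05),
         off = stats::runif(1, -0.3, 0.3))
  })
  spec_j <- spec
  spec_j$fold_amplitude_mm <- spec$fold_amplitude_mm * (1 + jit$amp)
  head <- build_head_volume(spec_j)
  surface <- extract_surface(head, depth_mm = surface_depth_mm,
                             subdiv = subdiv)
  surface$region <- paint_fold_regions(surface, spec_j)
  truth <- plant_truth_sites(surface, spec_j, jitter_mm = jit$off)
  subject <- list(head = head,
                  surface = surface,
                  spec = spec_j,
                  truth_sites = truth,
                  sigmoid_truth = list(
                    FDI = c(a = 2, b = 0.05, c = 100),
                    ADM = c(a = 1.6, b = 0.05, c = 100)),
                  noise_sigma_log = 0.3,
                  seed = spec$seed)
  class(subject) <- "synthetic_subject"
  subject
}

# Evaluate RNG-dependent code under a fixed seed without disturbing the
# caller's RNG state.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Classify surface vertices by their position on the fold, using the
# relative depression f = d / amplitude at the vertex direction.
paint_fold_regions <- function(surface, spec) {
  n <- surface$vertices / sqrt(rowSums(surface$vertices^2))
  amp <- spec$fold_amplitude_mm
  if (amp <= 0) return(rep("other", nrow(surface$vertices)))
  f <- fold_depth(n, spec) / amp
  u <- spec$radii[["gray"]] * n[, 1L]
  lam <- spec$fold_wavelength_mm
  capw <- pmin(pmax((n[, 3L] - 0.5) / 0.5, 0), 1)
  region <- rep("other", nrow(surface$vertices))
  near <- abs(u) <= 1.5 * lam & capw > 0.5
  region[near & f <= 0.05] <- "crown"
  region[f > 0.05 & f <= 0.35] <- "lip"
  region[f > 0.35 & f <= 0.9] <- "wall"
  region[f > 0.9] <- "fundus"
  region
}

# Place the two ground-truth representation sites on the fold lip, separated
# along the fold (y) by truth_offset_mm. FDI-analog at the lateral position,
# ADM-analog displaced medially (+y).
plant_truth_sites <- function(surface, spec, jitter_mm = 0) {
  lip <- which(surface$region == "lip" & surface$vertices[, 1L] > 0)
  if (length(lip) < 2) {
    # degenerate fold (amplitude ~ 0): fall back to the vertices nearest the
    # nominal lip positions on the smooth cap
    lip <- seq_len(nrow(surface$vertices))
  }
  off <- spec$truth_offset_mm + jitter_mm
  pick <- function(v_target) {
    cand <- surface$vertices[lip, , drop = FALSE]
    sc <- (cand[, 2L] - v_target)^2 + (cand[, 1L] - spec$fold_wavelength_mm / 3)^2
    lip[which.min(sc)]
  }
  fdi <- pick(0)
  adm <- pick(off)
  if (adm == fdi) {
    d <- sqrt(rowSums(sweep(surface$vertices[lip, , drop = FALSE], 2L,
                            surface$vertices[fdi, ], "-")^2))
    ord <- lip[order(abs(d - abs(off)))]
    adm <- ord[ord != fdi][1L]
  }
  list(FDI = fdi, ADM = adm)
}

#' @export
print.voxel_head <- function(x, ...) {
  cat(sprintf("<voxel_head> %d x %d x %d voxels at %.2f mm\n",
              x$dims[1L], x$dims[2L], x$dims[3L], x$voxel_size_mm))
  tab <- table(factor(as.integer(x$labels), levels = 0:5,
                      labels = names(tissue_labels())))
  print(tab)
  invisible(x)
}

#' @export
print.synthetic_subject <- function(x, ...) {
  cat(sprintf("<synthetic_subject> seed %d, %d surface vertices\n",
              x$seed, nrow(x$surface$vertices)))
  cat(sprintf("  truth sites: FDI vertex %d, ADM vertex %d (%.2f mm apart)\n",
              x$truth_sites$FDI, x$truth_sites$ADM,
              sqrt(sum((x$surface$vertices[x$truth_sites$FDI, ] -
                        x$surface$vertices[x$truth_sites$ADM, ])^2))))
  invisible(x)
}
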