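#' Write a head model and surface to disk
#'
#' The label volume goes to NIfTI (affine preserved in the sform), the
#' conductivity table to JSON, and the surface to binary little-endian PLY.
#'
#' @param head a \code{voxel_head}.
#' @param dir output directory (created if needed).
#' @param surface optional \code{cortical_surface}.
#' @param prefix file name prefix.
#' @return named list of the paths written.
#' @export
write_model <- function(head, dir, surface = NULL, prefix = "head") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nii_path <- file.path(dir, paste0(prefix, "_labels.nii.gz"))
  img <- RNifti::asNifti(array(as.integer(head$labels), head$dims))
  img <- RNifti::`sform<-`(img, structure(head$affine, code = 2L))
  RNifti::writeNifti(img, nii_path, datatype = "int16")
  cond_path <- file.path(dir, paste0(prefix, "_conductivity.json"))
  jsonlite::write_json(as.list(head$conductivity), cond_path,
                       auto_unbox = TRUE, digits = NA)
  paths <- list(labels = nii_path, conductivity = cond_path)
  if (!is.null(surface)) {
    ply_path <- file.path(dir, paste0(prefix, "_surface.ply"))
    write_ply(surface, ply_path)
    paths$surface <- ply_path
  }
  paths
}

#' Read a head model (and optionally a surface) written by write_model
#'
#' @param labels path to the NIfTI label volume.
#' @param conductivity path to the JSON conductivity table.
#' @param surface optional path to the PLY surface.
#' @return list with \code{head} (\code{voxel_head}) and, if requested,
#'   \code{surface}.
#' @export
read_model <- function(labels, conductivity, surface = NULL) {
  img <- RNifti::readNifti(labels)
  arr <- array(as.integer(img), dim(img))
  affine <- matrix(as.numeric(RNifti::xform(img)), 4L, 4L)
  cond <- unlist(jsonlite::read_json(conductivity))
  labs <- setdiff(sort(unique(as.integer(arr))), 0L)
  tl <- tissue_labels()
  lab_names <- names(tl)[match(labs, tl)]
  missing <- labs[is.na(lab_names) | !(lab_names %in% names(cond))]
  if (length(missing))
    stop(sprintf("label %s has no conductivity",
                 paste(missing, collapse = ", ")))
  h <- abs(affine[1L, 1L])
  head <- list(dims = dim(arr), voxel_size_mm = h,
               affine = unclass(affine), labels = arr,
               conductivity = cond)
  class(head) <- "voxel_head"
  validate_head(head)
  out <- list(head = head)
  if (!is.null(surface)) out$surface <- read_ply(surface)
  out
}

#' Write a surface as binary little-endian PLY
#'
#' Vertex positions and normals are stored as float32; optional per-vertex
#' scalar properties (e.g. an EF metric or a hotspot map) are stored as
#' additional float32 properties.
#'
#' @param surface a \code{cortical_surface}.
#' @param path output path.
#' @param scalars optional named list of per-vertex numeric vectors.
#' @export
write_ply <- function(surface, path, scalars = NULL) {
  nv <- nrow(surface$vertices)
  nf <- nrow(surface$triangles)
  snames <- names(scalars)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ply", "format binary_little_endian 1.0",
           sprintf("element vertex %d", nv),
           "property float x", "property float y", "property float z",
           "property float nx", "property float ny", "property float nz",
           if (length(snames)) sprintf("property float %s", snames),
           sprintf("element face %d", nf),
           "property list uchar int vertex_indices",
           "end_header")
  writeLines(hdr, con, sep = "\n")
  vdat <- cbind(surface$vertices, surface$vertex_normals)
  if (length(snames))
    vdat <- cbind(vdat, do.call(cbind, scalars))
  writeBin(as.numeric(t(vdat)), con, size = 4L, endian = "little")
  fdat <- t(surface$triangles) - 1L
  for (k in seq_len(nf)) {
    writeBin(as.raw(3L), con)
    writeBin(as.integer(fdat[, k]), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Read a PLY surface written by write_ply
#' @param path input path.
#' @return a \code{cortical_surface}; extra float properties are returned in
#'   the \code{scalars} field.
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    line <- readLines(con, n = 1L)
    hdr <- c(hdr, line)
    if (line == "end_header") break
  }
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex",
                                                   hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face",
                                                 hdr, value = TRUE)))
  vi <- grep("^element vertex", hdr)
  fi <- grep("^element face", hdr)
  props <- sub("property float ", "", hdr[seq(vi + 1L, fi - 1L)])
  np <- length(props)
  vdat <- matrix(readBin(con, "numeric", n = nv * np, size = 4L,
                         endian = "little"), nv, np, byrow = TRUE)
  colnames(vdat) <- props
  tris <- matrix(0L, nf, 3L)
  for (k in seq_len(nf)) {
    cnt <- as.integer(readBin(con, "raw", n = 1L))
    tris[k, ] <- readBin(con, "integer", n = cnt, size = 4L,
                         endian = "little") + 1L
  }
  surf <- list(vertices = vdat[, c("x", "y", "z"), drop = FALSE],
               triangles = tris,
               scalars = if (np > 6L)
                 as.data.frame(vdat[, -(1:6), drop = FALSE]) else NULL)
  dimnames(surf$vertices) <- NULL
  surf <- add_surface_geometry(surf)
  # prefer the stored normals (float32) over recomputed ones
  if (all(c("nx", "ny", "nz") %in% props)) {
    nrm <- vdat[, c("nx", "ny", "nz"), drop = FALSE]
    dimnames(nrm) <- NULL
    len <- sqrt(rowSums(nrm^2))
    ok <- len > 0
    nrm[ok, ] <- nrm[ok, ] / len[ok]
    surf$vertex_normals <- nrm
  }
  class(surf) <- "cortical_surface"
  surf
}

#' Write coil placements to CSV
#' @param placements list of \code{coil_placement}.
#' @param path output path.
#' @export
write_placements_csv <- function(placements, path) {
  df <- do.call(rbind, lapply(placements, function(p) {
    data.frame(id = p$id,
               x = p$position[1L], y = p$position[2L], z = p$position[3L],
               cx = p$triad[1L, 1L], cy = p$triad[2L, 1L], cz = p$triad[3L, 1L],
               hx = p$triad[1L, 2L], hy = p$triad[2L, 2L], hz = p$triad[3L, 2L],
               nx = p$triad[1L, 3L], ny = p$triad[2L, 3L], nz = p$triad[3L, 3L],
               pct_mso = p$intensity_pct_mso)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read coil placements from CSV
#' @param path CSV with columns id, x..z, cx..cz, hx..hz, nx..nz, pct_mso.
#' @return list of \code{coil_placement}.
#' @export
read_placements_csv <- function(path) {
  df <- utils::read.csv(path)
  lapply(seq_len(nrow(df)), function(i) {
    coil_placement(position = c(df$x[i], df$y[i], df$z[i]),
                   current_dir = c(df$cx[i], df$cy[i], df$cz[i]),
                   handle_dir = c(df$hx[i], df$hy[i], df$hz[i]),
                   normal = c(df$nx[i], df$ny[i], df$nz[i]),
                   pct_mso = df$pct_mso[i], id = as.character(df$id[i]))
  })
}

#' Write / read trial-level stimulus records
#' @param records data.frame of stimulus records.
#' @param path CSV path.
#' @export
write_records_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_records_csv
#' @export
read_records_csv <- function(path) utils::read.csv(path)
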