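#' Assemble the discrete scalar-potential system
#'
#' Discretizes the magneto-quasi-static equation div(sigma grad phi) =
#' -div(sigma dA/dt) on the voxel grid with a 7-point finite-volume stencil
#' and harmonic conductivity averaging on voxel faces (the flux-conserving
#' choice for piecewise-constant sigma). One unknown per conducting voxel;
#' faces to the insulating background carry zero flux, which implements the
#' insulating exterior boundary condition exactly. The matrix is symmetric
#' positive semi-definite with the constant vector in its null space, and
#' the right-hand side (the discrete divergence of sigma dA/dt) sums to zero
#' by construction, so the singular Neumann system is compatible.
#'
#' @param head a \code{voxel_head}.
#' @param dadt_cells n_conducting x 3 matrix of dA/dt (V/m) at the
#'   conducting voxel centers, in the order given by
#'   \code{\link{conducting_cells}}.
#' @return list with \code{A} (sparse dgCMatrix, in siemens), \code{b}
#'   (right-hand side), \code{cells} (flat voxel indices), \code{dims},
#'   \code{h_m} (voxel edge in meters).
#' @export
assemble_system <- function(head, dadt_cells) {
  cells <- conducting_cells(head)
  nc <- length(cells)
  if (nc == 0L) stop("head model has no conducting voxels")
  if (nrow(dadt_cells) != nc)
    stop("dadt_cells must have one row per conducting voxel")
  sig_tab <- conductivity_by_label(head)
  sig <- sig_tab[head$labels[cells] + 1L]
  dims <- head$dims
  map <- integer(prod(dims))
  map[cells] <- seq_len(nc)
  h_m <- head$voxel_size_mm * 1e-3
  offs <- c(1L, dims[1L], dims[1L] * dims[2L])
  ti <- tj <- tx <- vector("list", 0L)
  b <- numeric(nc)
  diag_acc <- numeric(nc)
  for (ax in 1:3) {
    nb_flat <- cells + offs[ax]
    j <- map[nb_flat]
    keep <- j > 0L
    i <- which(keep)            # row index of the low-side cell
    j <- j[keep]
    sf <- 2 * sig[i] * sig[j] / (sig[i] + sig[j])
    w <- sf * h_m
    ti[[length(ti) + 1L]] <- i; tj[[length(tj) + 1L]] <- j
    tx[[length(tx) + 1L]] <- -w
    ti[[length(ti) + 1L]] <- j; tj[[length(tj) + 1L]] <- i
    tx[[length(tx) + 1L]] <- -w
    diag_acc[i] <- diag_acc[i] + w
    dtmp <- rowsum(w, j, reorder = FALSE)
    jid <- as.integer(rownames(dtmp))
    diag_acc[jid] <- diag_acc[jid] + dtmp[, 1L]
    af <- (dadt_cells[i, ax] + dadt_cells[j, ax]) / 2
    fb <- sf * h_m^2 * af
    b[i] <- b[i] + fb
    btmp <- rowsum(fb, j, reorder = FALSE)
    b[jid] <- b[jid] - btmp[, 1L]
  }
  ti[[length(ti) + 1L]] <- seq_len(nc); tj[[length(tj) + 1L]] <- seq_len(nc)
  tx[[length(tx) + 1L]] <- diag_acc
  A <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                            dims = c(nc, nc))
  list(A = A, b = b, cells = cells, dims = dims, h_m = h_m)
}

#' Flat indices of conducting voxels
#' @param head a \code{voxel_head}.
#' @return integer vector of flat (column-major) voxel indices.
#' @export
conducting_cells <- function(head) which(head$labels > 0L)

#' Solve the scalar-potential system
#'
#' Jacobi-preconditioned conjugate gradient on the singular compatible
#' system, followed by the zero-mean gauge over conducting nodes.
#'
#' @param system output of \code{\link{assemble_system}}.
#' @param tol relative residual tolerance.
#' @param max_iter iteration cap.
#' @return object of class \code{scalar_potential_solution}: \code{phi}
#'   (volts, one per conducting voxel, mean zero), \code{residual},
#'   \code{iterations}, plus the grid bookkeeping of the system.
#' @export
solve_potential <- function(system, tol = 1e-6, max_iter = 20000L) {
  res <- cg_jacobi_cpp(system$A, system$b, tol, as.integer(max_iter))
  if (res$relres > tol) {
    err <- simpleError(sprintf(
      "conjugate gradient did not reach tolerance %.1e (residual %.2e after %d iterations)",
      tol, res$relres, res$iterations))
    err$residual_history <- res$history
    stop(err)
  }
  phi <- res$x - mean(res$x)
  structure(list(phi = phi, residual = res$relres,
                 iterations = res$iterations, cells = system$cells,
                 dims = system$dims, h_m = system$h_m),
            class = "scalar_potential_solution")
}

#' Reconstruct the induced electric field
#'
#' EF = -grad(phi) - dA/dt on conducting voxels. The gradient uses central
#' differences where both axis neighbors conduct and one-sided differences
#' at tissue/air boundaries. The solve is performed at 100\% stimulator
#' output; the stored field is scaled linearly to the requested intensity.
#'
#' @param sol a \code{scalar_potential_solution}.
#' @param dadt_cells dA/dt at conducting voxel centers at 100\% MSO (V/m).
#' @param head the \code{voxel_head} the system was assembled from.
#' @param intensity_pct_mso intensity the returned field corresponds to.
#' @return object of class \code{ef_volume}: \code{E} (n_conducting x 3,
#'   V/m), \code{cells}, \code{dims}, \code{affine}, \code{voxel_size_mm},
#'   \code{intensity_pct_mso}.
#' @export
reconstruct_ef <- function(sol, dadt_cells, head, intensity_pct_mso = 100) {
  cells <- sol$cells
  if (!identical(dim(head$labels), NULL) &&
      !identical(as.integer(head$dims), as.integer(sol$dims)))
    stop("grid mismatch between solution and head model")
  nc <- length(cells)
  if (nrow(dadt_cells) != nc)
    stop("grid mismatch: dadt_cells rows != conducting voxels")
  dims <- sol$dims
  map <- integer(prod(dims))
  map[cells] <- seq_len(nc)
  offs <- c(1L, dims[1L], dims[1L] * dims[2L])
  h_m <- sol$h_m
  grad <- matrix(0, nc, 3L)
  phi <- sol$phi
  for (ax in 1:3) {
    jp <- map[cells + offs[ax]]
    jm <- map[cells - offs[ax]]
    both <- jp > 0L & jm > 0L
    ponly <- jp > 0L & jm == 0L
    monly <- jm > 0L & jp == 0L
    g <- numeric(nc)
    g[both] <- (phi[jp[both]] - phi[jm[both]]) / (2 * h_m)
    g[ponly] <- (phi[jp[ponly]] - phi[which(ponly)]) / h_m
    g[monly] <- (phi[which(monly)] - phi[jm[monly]]) / h_m
    grad[, ax] <- g
  }
  E <- (-grad - dadt_cells) * (intensity_pct_mso / 100)
  structure(list(E = E, cells = cells, dims = dims, affine = head$affine,
                 voxel_size_mm = head$voxel_size_mm,
                 intensity_pct_mso = intensity_pct_mso),
            class = "ef_volume")
}

#' dA/dt of a placed coil at the conducting voxel centers
#'
#' @param head a \code{voxel_head}.
#' @param coil a \code{coil_model}.
#' @param placement a \code{coil_placement}.
#' @param pct_mso intensity; the coil current derivative is
#'   \code{didt_at_100pct * pct_mso / 100}.
#' @param standoff_mm coil-plane standoff from the scalp.
#' @return n_conducting x 3 matrix of dA/dt (V/m).
#' @export
dadt_at_cells <- function(head, coil, placement, pct_mso = 100,
                          standoff_mm = 0) {
  cells <- conducting_cells(head)
  pts <- voxel_centers(head, cells)
  path <- coil_wire_path(coil, placement, standoff_mm = standoff_mm)
  vector_potential(path, pts, didt = coil$didt_at_100pct * pct_mso / 100)
}

#' Solve one coil placement end to end
#'
#' Assembles, solves and reconstructs the EF volume at 100\% MSO, then
#' scales to the placement intensity.
#'
#' @inheritParams dadt_at_cells
#' @param tol,max_iter solver controls.
#' @return an \code{ef_volume} at the placement's \code{intensity_pct_mso}.
#' @export
solve_placement <- function(head, coil, placement, tol = 1e-6,
                            max_iter = 20000L, standoff_mm = 0) {
  dadt <- dadt_at_cells(head, coil, placement, pct_mso = 100,
                        standoff_mm = standoff_mm)
  sys <- assemble_system(head, dadt)
  sol <- solve_potential(sys, tol = tol, max_iter = max_iter)
  reconstruct_ef(sol, dadt, head,
                 intensity_pct_mso = placement$intensity_pct_mso)
}

#' Rescale an EF volume to another stimulator intensity
#' @param ef an \code{ef_volume}.
#' @param pct_mso target intensity.
#' @return rescaled \code{ef_volume} (exact linear scaling).
#' @export
scale_ef <- function(ef, pct_mso) {
  ef$E <- ef$E * (pct_mso / ef$intensity_pct_mso)
  ef$intensity_pct_mso <- pct_mso
  ef
}

#' Export an EF volume as 4D NIfTI
#' @param ef an \code{ef_volume}.
#' @param path output path (.nii or .nii.gz).
#' @export
write_ef_nifti <- function(ef, path) {
  arr <- array(NA_real_, c(ef$dims, 3L))
  npx <- prod(ef$dims)
  for (k in 1:3) arr[ef$cells + (k - 1L) * npx] <- ef$E[, k]
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(ef$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Export a scalar potential as NIfTI
#' @param sol a \code{scalar_potential_solution}.
#' @param head the matching \code{voxel_head}.
#' @param path output path.
#' @export
write_potential_nifti <- function(sol, head, path) {
  arr <- array(NA_real_, sol$dims)
  arr[sol$cells] <- sol$phi
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(head$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @export
print.ef_volume <- function(x, ...) {
  cat(sprintf("<ef_volume> %d conducting voxels at %.2f mm, %g%% MSO, max |E| = %.1f V/m\n",
              length(x$cells), x$voxel_size_mm, x$intensity_pct_mso,
              max(sqrt(rowSums(x$E^2)))))
  invisible(x)
}
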