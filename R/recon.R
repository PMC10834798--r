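# Reconstruction: conventional FT-MRS (voxel spectra + mid-septal voxel
# selection) and compartment-constrained SLAM weighted least squares.

#' Fourier-transform (FT-MRS) reconstruction
#'
#' Inverse 3D DFT of the summed acquisition-weighted data; the acquisition
#' weighting acts as the inherent k-space apodization and no additional
#' filter is applied. Unacquired k-space points are zero-filled.
#' Normalisation (1 / N_voxels) is such that a noiseless unweighted
#' acquisition of a piecewise-constant-on-voxels object returns the true
#' per-voxel FIDs exactly.
#'
#' @param kspace a `kspace_data`
#' @return a `spectral_grid`: complex array [Nx, Ny, Nz, T] of voxel FIDs
#' @export
recon_ft <- function(kspace) {
  N <- kspace$geometry$matrix
  if (anyDuplicated(kspace$k_index)) stop_consistency("duplicate k-indices")
  nt <- ncol(kspace$samples)
  arr <- array(0i, dim = c(N, nt))
  ix <- k_to_array_index(kspace$k_index[, 1], N[1])
  iy <- k_to_array_index(kspace$k_index[, 2], N[2])
  iz <- k_to_array_index(kspace$k_index[, 3], N[3])
  lin <- ix + N[1] * (iy - 1L) + N[1] * N[2] * (iz - 1L)
  nvox <- prod(N)
  for (t in seq_len(nt)) {
    slab <- array(0i, dim = N)
    slab[lin] <- kspace$samples[, t]
    arr[, , , t] <- stats::fft(slab, inverse = TRUE) / nvox
  }
  structure(list(fids = arr, geometry = kspace$geometry, dwell_s = kspace$dwell_s,
                 log = list(shift_voxels = kspace$shift_voxels)),
            class = "spectral_grid")
}

#' Extract one voxel FID from a spectral grid
#' @param grid a `spectral_grid`
#' @param index length-3 1-based voxel index
#' @export
grid_fid <- function(grid, index) {
  fid(grid$fids[index[1], index[2], index[3], ], dwell_s = grid$dwell_s)
}

#' Select the mid-septal voxel for FT-MRS analysis
#'
#' Among voxels labelled heart that have no face-adjacent chest-wall voxel,
#' returns the one nearest (in mm) to the centroid of the heart label;
#' ties are broken deterministically by lowest linear (column-major) index.
#' The adjacency exclusion mirrors the clinical practice of avoiding voxels
#' contaminated by chest-wall PCr.
#'
#' @param grid a `spectral_grid`
#' @param mask a `compartment_mask` on the same grid
#' @param override_index optional length-3 1-based voxel index; returned as-is
#' @return list(index, fid)
#' @export
select_septal_voxel <- function(grid, mask, override_index = NULL) {
  if (!is.null(override_index)) {
    return(list(index = override_index, fid = grid_fid(grid, override_index)))
  }
  if (!all(dim(mask$labels) == grid$geometry$matrix))
    stop_consistency("mask grid does not match reconstruction grid")
  heart_lab <- mask$names[["heart"]]
  cw_lab <- if ("chest_wall" %in% names(mask$names)) mask$names[["chest_wall"]] else NA
  N <- dim(mask$labels)
  idx <- which(mask$labels == heart_lab, arr.ind = TRUE)
  if (nrow(idx) == 0) stop(errorCondition("no heart voxels in mask",
                                          class = c("slamrecon_selection_error", "error")))
  vox <- grid$geometry$voxel_mm
  centroid <- colMeans(idx)
  adjacent_cw <- function(v) {
    if (is.na(cw_lab)) return(FALSE)
    for (d in 1:3) for (s in c(-1L, 1L)) {
      w <- v; w[d] <- w[d] + s
      if (w[d] >= 1 && w[d] <= N[d] && mask$labels[w[1], w[2], w[3]] == cw_lab)
        return(TRUE)
    }
    FALSE
  }
  ok <- !apply(idx, 1, adjacent_cw)
  cand <- if (any(ok)) idx[ok, , drop = FALSE] else idx
  dist2 <- colSums((t(cand) - centroid)^2 * vox^2)
  linear <- (cand[, 1] - 1) + N[1] * (cand[, 2] - 1) + N[1] * N[2] * (cand[, 3] - 1)
  ord <- order(dist2, linear)
  best <- cand[ord[1], ]
  list(index = unname(best), fid = grid_fid(grid, best))
}

#' Build the SLAM linear system
#'
#' Encoding matrix \eqn{E_{mc} = n(k_m) \sum_{r \in c} e^{-i 2\pi k_m \cdot
#' r / N}} (the average count multiplies each row because repeats are summed)
#' and row noise weights \eqn{w_m = 1 / \sqrt{n(k_m)}} that whiten the
#' summed-average noise.
#'
#' @param mask a `compartment_mask` on the acquisition grid
#' @param kspace a `kspace_data`
#' @return `slam_system` with E, weights, compartment names and voxel counts
#' @export
build_slam_system <- function(mask, kspace) {
  N <- kspace$geometry$matrix
  if (!all(dim(mask$labels) == N))
    stop_consistency("mask grid does not equal acquisition matrix")
  labs <- sort(unique(as.vector(mask$labels)))
  lab_names <- names(mask$names)[match(labs, mask$names)]
  counts <- vapply(labs, function(l) sum(mask$labels == l), integer(1))
  present <- counts > 0
  if (!all(present)) warning("dropping compartments with zero voxels: ",
                             paste(lab_names[!present], collapse = ", "))
  labs <- labs[present]; lab_names <- lab_names[present]; counts <- counts[present]
  M <- nrow(kspace$k_index); C <- length(labs)
  if (M < C)
    stop(errorCondition(sprintf("under-determined SLAM system: M = %d encodes < C = %d compartments", M, C),
                        class = c("slamrecon_underdetermined_error", "error")))
  E <- matrix(0i, nrow = M, ncol = C)
  for (j in seq_len(C)) {
    dftj <- spatial_dft(array(as.numeric(mask$labels == labs[j]), dim = N))
    for (m in seq_len(M)) E[m, j] <- dftj(kspace$k_index[m, ])
  }
  s <- mask$subvoxel_shift %||% c(0, 0, 0)
  if (any(s != 0)) {
    # compartment support at fractional positions r + s: phase per encode
    E <- E * exp(-2i * pi * (kspace$k_index[, 1] * s[1] / N[1] +
                             kspace$k_index[, 2] * s[2] / N[2] +
                             kspace$k_index[, 3] * s[3] / N[3]))
  }
  E <- E * kspace$averages
  structure(list(E = E, weights = 1 / sqrt(kspace$averages),
                 compartments = lab_names, labels = labs,
                 voxel_counts = stats::setNames(counts, lab_names)),
            class = "slam_system")
}

#' SLAM reconstruction: one spectrum per compartment
#'
#' Solves, for every time point, the weighted least-squares problem
#' \eqn{\min_\rho \| diag(w) (s(\cdot, t) - E \rho(t)) \|_2} via the SVD
#' pseudoinverse with relative singular-value cutoff `rcond`. Because each
#' column of E sums the encoding phasors over the compartment's voxels, the
#' solution is directly the mean per-voxel FID of the compartment (for full
#' unweighted k-space it equals the mean of the FT-MRS voxel FIDs).
#'
#' @param kspace a `kspace_data`
#' @param mask a `compartment_mask`
#' @param rcond relative singular-value cutoff (default 1e-8)
#' @return `compartment_spectra`: named list of [fid()]s plus a conditioning
#'   report (singular values, effective rank)
#' @export
recon_slam <- function(kspace, mask, rcond = 1e-8) {
  sys <- build_slam_system(mask, kspace)
  A <- sys$E * sys$weights  # row-scaled
  sv <- svd(A)
  keep <- sv$d >= rcond * sv$d[1]
  if (sum(keep) < ncol(A)) {
    # name compartments dominating the discarded right-singular directions
    bad <- which(!keep)
    collapsing <- unique(unlist(lapply(bad, function(b)
      sys$compartments[which.max(Mod(sv$v[, b]))])))
    stop(errorCondition(paste0("ill-conditioned SLAM system at rcond = ", rcond,
                               "; collapsing compartments: ",
                               paste(collapsing, collapse = ", ")),
                        class = c("slamrecon_illconditioned_error", "error")))
  }
  B <- kspace$samples * sys$weights
  # rho = V S^-1 U^H B  (C x T)
  rho <- sv$v %*% ((1 / sv$d) * (Conj(t(sv$u)) %*% B))
  fids <- stats::setNames(
    lapply(seq_len(nrow(rho)), function(j) fid(rho[j, ], dwell_s = kspace$dwell_s)),
    sys$compartments)
  structure(list(fids = fids, voxel_counts = sys$voxel_counts,
                 conditioning = list(singular_values = sv$d,
                                     effective_rank = sum(keep), rcond = rcond),
                 shift_voxels = kspace$shift_voxels),
            class = "compartment_spectra")
}

#' Shift a compartment mask to match a shifted FOV
#'
#' Two compensation semantics (same direction convention as [shift_fov()]:
#' positive delta moves the object toward positive voxel index):
#'
#' * `"kspace"` (default): the integer part of the shift circularly rolls
#'   the labels (matching the shift theorem's circular wrap exactly) and the
#'   sub-voxel remainder is stored in `subvoxel_shift`, which
#'   [build_slam_system()] applies as the encoding phase
#'   \eqn{e^{-i 2\pi k \cdot s / N}} (compartment support at r + s). With
#'   this semantics [shift_fov()] + [shift_mask()] is an exact inverse pair
#'   for any shift, including fractional ones.
#' * `"rasterize"`: labels are re-rasterized from the continuous-space
#'   compartment geometry displaced by `delta_voxels * voxel_mm` (requires
#'   provenance); the integer-grid labels approximate fractional shifts to
#'   the nearest voxel boundary.
#'
#' @param mask a `compartment_mask`
#' @param delta_voxels length-3 shift in voxel units
#' @param method "kspace" or "rasterize"
#' @export
shift_mask <- function(mask, delta_voxels, method = c("kspace", "rasterize")) {
  method <- match.arg(method)
  if (all(delta_voxels == 0)) return(mask)
  if (method == "rasterize") {
    if (is.null(mask$provenance)) {
      if (any(delta_voxels != round(delta_voxels)))
        stop(errorCondition("fractional mask re-rasterization requires continuous-space provenance",
                            class = c("slamrecon_unsupported_error", "error")))
      return(roll_mask(mask, delta_voxels))
    }
    pr <- mask$provenance
    return(rasterize_masks(pr$phantom, dim(mask$labels), pr$cardiac_phase,
                           offset_mm = pr$offset_mm +
                             delta_voxels * mask$geometry$voxel_mm))
  }
  di <- round(delta_voxels)
  frac <- delta_voxels - di
  out <- if (any(di != 0)) roll_mask(mask, di) else mask
  out$subvoxel_shift <- (out$subvoxel_shift %||% c(0, 0, 0)) + frac
  out
}

roll_mask <- function(mask, d) {
  N <- dim(mask$labels)
  d <- as.integer(round(d))
  idx <- lapply(1:3, function(a) ((seq_len(N[a]) - 1 - d[a]) %% N[a]) + 1)
  mask$labels <- mask$labels[idx[[1]], idx[[2]], idx[[3]]]
  mask
}
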