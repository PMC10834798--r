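# Internal numerical helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) stop(errorCondition(paste0(...), class = c("slamrecon_param_error", "error")))
stop_consistency <- function(...) stop(errorCondition(paste0(...), class = c("slamrecon_consistency_error", "error")))

#' Shift zero-frequency component to the centre of a vector
#' @param x vector
#' @param inverse undo the shift
#' @keywords internal
fftshift1 <- function(x, inverse = FALSE) {
  n <- length(x)
  h <- if (inverse) ceiling(n / 2) else floor(n / 2)
  c(x[(h + 1):n], x[1:h])
}

#' Frequency axis (Hz, ascending) of a spectrum obtained by fftshift1(fft(fid))
#' @keywords internal
freq_axis <- function(n, dwell_s) {
  sw <- 1 / dwell_s
  (seq_len(n) - 1 - floor(n / 2)) * sw / n
}

#' Signed k-space indices -N/2 .. N/2-1 for one axis
#' @keywords internal
k_axis <- function(n) seq.int(-n %/% 2, n %/% 2 - 1)

#' Map signed k index to 1-based array index (k mod N + 1)
#' @keywords internal
k_to_array_index <- function(k, n) (k %% n) + 1L

#' Voxel-centre coordinates (mm) along one axis, FOV centred on 0
#' @keywords internal
voxel_centres <- function(fov_mm, n) -fov_mm / 2 + (seq_len(n) - 0.5) * (fov_mm / n)

#' All voxel centre positions as an N_voxels x 3 matrix (column-major order,
#' first axis fastest -- matches R array linearisation).
#' @keywords internal
voxel_centre_grid <- function(geometry) {
  ax <- lapply(1:3, function(d) voxel_centres(geometry$fov_mm[d], geometry$matrix[d]))
  as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]], KEEP.OUT.ATTRS = FALSE))
}

#' Inverse 3D DFT per time point with 1/Nvox normalisation
#' @param samp_array complex array [Nx, Ny, Nz, T]
#' @keywords internal
ifft3_time <- function(samp_array) {
  d <- dim(samp_array)
  nvox <- prod(d[1:3])
  out <- samp_array
  for (t in seq_len(d[4])) {
    out[, , , t] <- stats::fft(samp_array[, , , t, drop = TRUE], inverse = TRUE) / nvox
  }
  out
}

#' Deterministic sub-seed derivation (keeps results < 2^31)
#' @keywords internal
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  s <- 0
  for (p in parts) s <- (s * 7919 + as.numeric(p) * 104729) %% 2147483629
  as.integer(s) + 1L
}
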