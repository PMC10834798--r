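# Minimal NIfTI-1 label-volume reader/writer (uint8/uint16, single file
# .nii / .nii.gz, sform RAS affine). No NIfTI package is available in the
# target environment, so the 348-byte header is handled directly; only the
# subset needed for integer label masks is supported.

nifti_affine <- function(geometry) {
  # RAS affine mapping 0-based voxel indices to mm, FOV centred on 0
  vox <- geometry$voxel_mm
  offs <- -geometry$fov_mm / 2 + vox / 2
  rbind(c(vox[1], 0, 0, offs[1]),
        c(0, vox[2], 0, offs[2]),
        c(0, 0, vox[3], offs[3]))
}

#' Write a compartment mask as a NIfTI-1 label volume
#'
#' uint8 (or uint16 for labels > 255), sform affine encoding the FOV and
#' voxel size with the FOV centred on the origin. A sidecar
#' `<path>.labels.yaml` records the label -> compartment-name table.
#'
#' @param mask a `compartment_mask`
#' @param path output path (.nii or .nii.gz)
#' @export
write_mask <- function(mask, path) {
  dims <- dim(mask$labels)
  maxlab <- max(mask$labels)
  u16 <- maxlab > 255
  datatype <- if (u16) 512L else 2L
  bitpix <- if (u16) 16L else 8L
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con), add = TRUE)
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(348L, 4)                                   # sizeof_hdr
  writeBin(raw(36), con)                        # data_type, db_name, extents, session_error, regular, dim_info
  wi(c(3L, dims, 1L, 1L, 1L, 1L), 2)            # dim
  wf(c(0, 0, 0))                                # intent_p1..p3
  wi(0L, 2)                                     # intent_code
  wi(datatype, 2); wi(bitpix, 2); wi(0L, 2)     # datatype, bitpix, slice_start
  wf(c(1, mask$geometry$voxel_mm, 0, 0, 0, 0))  # pixdim[0..7]
  wf(352); wf(1); wf(0)                         # vox_offset, scl_slope, scl_inter
  wi(0L, 2); writeBin(raw(2), con)              # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0, 0))                             # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L), 4)                              # glmax, glmin
  writeBin(raw(104), con)                       # descrip + aux_file
  wi(0L, 2); wi(1L, 2)                          # qform_code = 0, sform_code = 1
  wf(c(0, 0, 0, 0, 0, 0))                       # quatern b,c,d, qoffset x,y,z
  aff <- nifti_affine(mask$geometry)
  wf(t(aff))                                    # srow_x, srow_y, srow_z
  writeBin(raw(16), con)                        # intent_name
  writeChar("n+1", con, nchars = 3, eos = NULL); writeBin(as.raw(c(0, 0, 0, 0, 0)), con)
  labs <- as.integer(mask$labels)
  if (u16) writeBin(labs, con, size = 2, endian = "little")
  else writeBin(as.raw(labs), con)
  yaml::write_yaml(as.list(stats::setNames(as.integer(mask$names), names(mask$names))),
                   paste0(path, ".labels.yaml"))
  invisible(path)
}

#' Read a NIfTI-1 label volume as a compartment mask
#'
#' The file's sform affine must agree with the declared geometry within
#' 0.1 mm; a grid mismatch raises a geometry error (no silent resampling --
#' use [resample_mask()] explicitly). Labels are mapped to compartment names
#' via the sidecar `<path>.labels.yaml` when present, otherwise the default
#' `{1: heart, 2: chest_wall, 0: other}`.
#'
#' @param path .nii / .nii.gz path
#' @param geometry expected [acq_geometry()]
#' @export
read_mask <- function(path, geometry) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con), add = TRUE)
  ri <- function(n, size) readBin(con, "integer", n = n, size = size, endian = "little")
  rf <- function(n) readBin(con, "numeric", n = n, size = 4, endian = "little")
  hdr_size <- ri(1, 4)
  if (!identical(hdr_size, 348L))
    stop(errorCondition("not a NIfTI-1 file (sizeof_hdr != 348)",
                        class = c("slamrecon_schema_error", "error")))
  readBin(con, "raw", 36)
  dims <- ri(8, 2)
  rf(3); ri(1, 2)
  datatype <- ri(1, 2); bitpix <- ri(1, 2); ri(1, 2)
  pixdim <- rf(8)
  vox_offset <- rf(1); rf(2)
  ri(1, 2); readBin(con, "raw", 2)
  rf(4); ri(2, 4); readBin(con, "raw", 104)
  ri(1, 2); sform_code <- ri(1, 2)
  rf(6)
  srow <- matrix(rf(12), nrow = 3, byrow = TRUE)
  readBin(con, "raw", 16 + 4)  # intent_name + magic -> byte 348
  nxyz <- dims[2:4]
  if (!all(nxyz == geometry$matrix))
    stop(errorCondition(sprintf("mask grid %s does not match acquisition matrix %s; resample explicitly",
                                paste(nxyz, collapse = "x"),
                                paste(geometry$matrix, collapse = "x")),
                        class = c("slamrecon_geometry_error", "error")))
  if (sform_code >= 1 && max(abs(srow - nifti_affine(geometry))) > 0.1)
    stop(errorCondition("NIfTI affine inconsistent with declared FOV (> 0.1 mm)",
                        class = c("slamrecon_geometry_error", "error")))
  if (vox_offset > 348) readBin(con, "raw", vox_offset - 348)
  n <- prod(nxyz)
  labs <- switch(as.character(datatype),
    "2"   = readBin(con, "integer", n = n, size = 1, signed = FALSE),
    "4"   = readBin(con, "integer", n = n, size = 2, endian = "little"),
    "512" = readBin(con, "integer", n = n, size = 2, signed = FALSE, endian = "little"),
    stop(errorCondition(paste0("unsupported NIfTI datatype for labels: ", datatype),
                        class = c("slamrecon_schema_error", "error"))))
  side <- paste0(path, ".labels.yaml")
  name_table <- if (file.exists(side)) {
    tb <- yaml::read_yaml(side)
    stats::setNames(as.integer(unlist(tb)), names(tb))
  } else c(heart = 1L, chest_wall = 2L, other = 0L)
  compartment_mask(array(labs, dim = nxyz), name_table, geometry)
}

#' Resample a label mask between grids by majority vote
#'
#' Each coarse voxel takes the most frequent fine-grid label among the fine
#' voxels it contains; ties go to the lower label. The fine matrix must be
#' an integer multiple of the target matrix on every axis.
#'
#' @param mask a `compartment_mask` on the fine grid
#' @param to_matrix target matrix (3 ints)
#' @param geometry target [acq_geometry()] (same FOV)
#' @export
resample_mask <- function(mask, to_matrix, geometry = NULL) {
  fine <- dim(mask$labels)
  ratio <- fine / to_matrix
  if (any(ratio != round(ratio)))
    stop(errorCondition("fine grid must be an integer multiple of the target grid",
                        class = c("slamrecon_geometry_error", "error")))
  out <- array(0L, dim = to_matrix)
  for (i in seq_len(to_matrix[1])) for (j in seq_len(to_matrix[2]))
    for (k in seq_len(to_matrix[3])) {
      block <- mask$labels[((i - 1) * ratio[1] + 1):(i * ratio[1]),
                           ((j - 1) * ratio[2] + 1):(j * ratio[2]),
                           ((k - 1) * ratio[3] + 1):(k * ratio[3])]
      tab <- table(block)
      winners <- as.integer(names(tab)[tab == max(tab)])
      out[i, j, k] <- min(winners)
    }
  g <- geometry %||% acq_geometry(mask$geometry$fov_mm, to_matrix)
  compartment_mask(out, mask$names, g)
}
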