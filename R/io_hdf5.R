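# HDF5 container for k-space data. rhdf5 has no native complex datatype, so
# the complex sample matrix is stored as paired float64 datasets
# `samples_real` / `samples_imag` (lossless round trip).

#' Write k-space data to HDF5
#'
#' Layout: datasets `samples_real`, `samples_imag` [M, T] float64,
#' `k_index` [M, 3] int, `averages` [M] int; root attributes `fov_mm`,
#' `matrix`, `dwell_s`, `tr_s`, `gated`, `seed`, `shift_voxels`.
#'
#' @param data a `kspace_data`
#' @param path output .h5 path (overwritten)
#' @export
write_kspace <- function(data, path) {
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(Re(data$samples), path, "samples_real")
  rhdf5::h5write(Im(data$samples), path, "samples_imag")
  rhdf5::h5write(data$k_index, path, "k_index")
  rhdf5::h5write(data$averages, path, "averages")
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  rhdf5::h5writeAttribute(data$geometry$fov_mm, fid, "fov_mm")
  rhdf5::h5writeAttribute(data$geometry$matrix, fid, "matrix")
  rhdf5::h5writeAttribute(data$dwell_s, fid, "dwell_s")
  rhdf5::h5writeAttribute(data$protocol$tr_s, fid, "tr_s")
  rhdf5::h5writeAttribute(as.integer(data$protocol$gated), fid, "gated")
  rhdf5::h5writeAttribute(data$protocol$seed, fid, "seed")
  rhdf5::h5writeAttribute(data$shift_voxels, fid, "shift_voxels")
  invisible(path)
}

h5_attr <- function(path, name) {
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  if (!rhdf5::H5Aexists(fid, name))
    stop(errorCondition(paste0("missing HDF5 attribute: ", name),
                        class = c("slamrecon_schema_error", "error")))
  aid <- rhdf5::H5Aopen(fid, name)
  on.exit(rhdf5::H5Aclose(aid), add = TRUE, after = FALSE)
  rhdf5::H5Aread(aid)
}

#' Read k-space data from HDF5
#' @param path input .h5 path
#' @return a `kspace_data`
#' @export
read_kspace <- function(path) {
  if (!file.exists(path)) stop_param("file not found: ", path)
  present <- rhdf5::h5ls(path)$name
  for (ds in c("samples_real", "samples_imag", "k_index", "averages")) {
    if (!(ds %in% present))
      stop(errorCondition(paste0("missing HDF5 dataset: ", ds),
                          class = c("slamrecon_schema_error", "error")))
  }
  re <- rhdf5::h5read(path, "samples_real")
  im <- rhdf5::h5read(path, "samples_imag")
  ki <- rhdf5::h5read(path, "k_index")
  av <- as.integer(rhdf5::h5read(path, "averages"))
  geom <- acq_geometry(fov_mm = as.numeric(h5_attr(path, "fov_mm")),
                       matrix = as.integer(h5_attr(path, "matrix")))
  proto <- protocol(tr_s = as.numeric(h5_attr(path, "tr_s")),
                    gated = as.integer(h5_attr(path, "gated")) == 1L,
                    seed = as.integer(h5_attr(path, "seed")),
                    dwell_s = as.numeric(h5_attr(path, "dwell_s")),
                    n_time = ncol(re))
  kspace_data(matrix(complex(real = re, imaginary = im), nrow = nrow(re)),
              matrix(as.integer(ki), ncol = 3), av,
              dwell_s = as.numeric(h5_attr(path, "dwell_s")),
              geometry = geom, protocol = proto,
              shift_voxels = as.numeric(h5_attr(path, "shift_voxels")))
}
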