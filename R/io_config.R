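# YAML serialization of phantom / protocol / template configuration and
# plain-text spectrum and fit exports.

component_to_list <- function(cp) {
  list(name = cp$name, freq_offset = cp$freq_offset, amplitude = cp$amplitude,
       damping = cp$damping, phase = cp$phase,
       multiplet = apply(cp$multiplet, 1, as.list, simplify = FALSE))
}

component_from_list <- function(l) {
  mp <- do.call(rbind, lapply(l$multiplet, function(r) c(r$offset, r$rel)))
  spectral_component(l$name, l$freq_offset, l$amplitude, l$damping,
                     l$phase %||% 0, mp)
}

shape_to_list <- function(sh) {
  if (sh$type == "box") list(type = "box", min = as.list(sh$min), max = as.list(sh$max))
  else list(type = "ellipsoid", centre = as.list(sh$centre),
            semiaxes = as.list(sh$semiaxes))
}

shape_from_list <- function(l) {
  if (l$type == "box") shape_box(unlist(l$min), unlist(l$max))
  else shape_ellipsoid(unlist(l$centre), unlist(l$semiaxes))
}

#' Write a phantom definition as YAML
#'
#' The motion waveform is stored by name; only the default raised-cosine
#' waveform round-trips.
#' @param phantom a [phantom_definition()]
#' @param path output .yaml path
#' @export
write_phantom_yaml <- function(phantom, path) {
  out <- list(
    geometry = list(fov_mm = as.list(phantom$geometry$fov_mm),
                    matrix = as.list(phantom$geometry$matrix)),
    compartments = lapply(unname(phantom$compartments), function(cp) list(
      name = cp$name,
      geometry = lapply(cp$geometry, shape_to_list),
      components = lapply(cp$components, component_to_list),
      t1 = if (is.null(cp$t1)) NULL else as.list(cp$t1),
      motion_amplitude = cp$motion_amplitude,
      catch_all = cp$catch_all)),
    blood = if (is.null(phantom$blood)) NULL else list(
      fraction = phantom$blood$fraction,
      components = lapply(phantom$blood$components, component_to_list)),
    saturation_slabs = phantom$saturation_slabs,
    motion = list(amplitude = phantom$motion$amplitude,
                  axis = as.list(phantom$motion$axis),
                  waveform = "raised_cosine"))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Read a phantom definition from YAML
#' @param path .yaml path written by [write_phantom_yaml()]
#' @export
read_phantom_yaml <- function(path) {
  l <- yaml::read_yaml(path)
  geom <- acq_geometry(unlist(l$geometry$fov_mm), unlist(l$geometry$matrix))
  comps <- lapply(l$compartments, function(cl)
    compartment_spec(cl$name,
                     geometry = lapply(cl$geometry, shape_from_list),
                     components = lapply(cl$components, component_from_list),
                     t1 = if (is.null(cl$t1)) NULL else unlist(cl$t1),
                     motion_amplitude = cl$motion_amplitude %||% 0,
                     catch_all = isTRUE(cl$catch_all)))
  blood <- if (is.null(l$blood)) NULL else
    list(fraction = l$blood$fraction,
         components = lapply(l$blood$components, component_from_list))
  if (!identical(l$motion$waveform %||% "raised_cosine", "raised_cosine"))
    stop_param("unsupported motion waveform: ", l$motion$waveform)
  phantom_definition(geom, comps, blood = blood,
                     saturation_slabs = l$saturation_slabs,
                     motion = motion_model(amplitude = l$motion$amplitude %||% 0,
                                           axis = unlist(l$motion$axis %||% list(0, 1, 0))))
}

#' Write a protocol as YAML
#' @param proto a [protocol()]
#' @param path output .yaml path
#' @export
write_protocol_yaml <- function(proto, path) {
  yaml::write_yaml(list(tr_s = proto$tr_s, gated = proto$gated,
                        rr_model = as.list(proto$rr_model),
                        noise_sigma = proto$noise_sigma, seed = proto$seed,
                        saturation = proto$saturation, dwell_s = proto$dwell_s,
                        n_time = proto$n_time,
                        excitation_band = as.list(proto$excitation_band)), path)
  invisible(path)
}

#' Read a protocol from YAML
#' @param path .yaml path
#' @export
read_protocol_yaml <- function(path) {
  l <- yaml::read_yaml(path)
  protocol(tr_s = l$tr_s %||% 0.9, gated = isTRUE(l$gated),
           rr_model = unlist(l$rr_model %||% list(mean = 1.0, sd = 0.05)),
           noise_sigma = l$noise_sigma %||% 0, seed = l$seed %||% 1L,
           saturation = isTRUE(l$saturation %||% TRUE),
           dwell_s = l$dwell_s %||% 2.5e-4, n_time = l$n_time %||% 512L,
           excitation_band = unlist(l$excitation_band %||% list(-1000, 500)))
}

#' Export a spectrum as CSV (freq_hz, real, imag)
#' @param f a [fid()]
#' @param path output .csv path
#' @export
write_spectrum_csv <- function(f, path) {
  sp <- fid_spectrum(f)
  utils::write.csv(data.frame(freq_hz = sp$freq_hz, real = Re(sp$spectrum),
                              imag = Im(sp$spectrum)), path, row.names = FALSE)
  invisible(path)
}

#' Export a FID in jMRUI-compatible text format
#' @param f a [fid()]
#' @param path output .txt path
#' @param name signal name written in the header
#' @export
write_jmrui_txt <- function(f, path, name = "slamrecon") {
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(c("jMRUI Data Textfile", "",
               paste0("Filename: ", basename(path)), "",
               paste0("PointsInDataset: ", length(f$signal)),
               "DatasetsInFile: 1",
               paste0("SamplingInterval: ", f$dwell_s * 1000),
               "ZeroOrderPhase: 0", "BeginTime: 0",
               "TransmitterFrequency: 49.9E6",
               "MagneticField: 3E0", "TypeOfNucleus: 31P",
               paste0("NameOfPatient: ", name), "", "Signal 1 out of 1 in file",
               "sig(real)\tsig(imag)"), con)
  utils::write.table(data.frame(Re(f$signal), Im(f$signal)), con,
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read a FID as CSV (time_s, real, imag)
#' @param f a [fid()]
#' @param path .csv path
#' @export
write_fid_csv <- function(f, path) {
  utils::write.csv(data.frame(time_s = fid_time(f), real = Re(f$signal),
                              imag = Im(f$signal)), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fid_csv
#' @export
read_fid_csv <- function(path) {
  df <- utils::read.csv(path)
  fid(complex(real = df$real, imaginary = df$imag),
      dwell_s = df$time_s[2] - df$time_s[1])
}

#' Export an AMARES fit as JSON
#' @param fit an `amares_fit`
#' @param path output .json path
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(list(
    groups = fit$groups, phi0 = fit$phi0, noise_sd = fit$noise_sd,
    rss = fit$rss, pcr_atp_ratio = fit$pcr_atp_ratio,
    ratio_crlb_pct = fit$ratio_crlb_pct,
    covariance = fit$covariance), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
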