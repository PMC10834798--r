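# Digital thorax phantom: compartment geometry, per-compartment 31P spectral
# ground truth, blood pool, saturation bands and a cardiac motion model.

#' Spectral component (one resonance or multiplet group)
#'
#' Describes one 31P resonance in the time-domain signal model
#' \eqn{y(t) = a e^{i\phi} \sum_j w_j e^{(-d + i 2\pi (f + \delta_j)) t}},
#' where the multiplet sub-offsets \eqn{\delta_j} and relative amplitudes
#' \eqn{w_j} (summing to 1) encode J-coupling structure.
#'
#' @param name component name, e.g. "PCr", "gATP"
#' @param freq_offset frequency in Hz relative to PCr (PCr = 0)
#' @param amplitude per-voxel amplitude, arbitrary units, >= 0
#' @param damping Lorentzian decay rate in s^-1 (>= 0); FWHM = damping / pi
#' @param phase phase in radians
#' @param multiplet two-column matrix (sub-offset Hz, relative amplitude);
#'   relative amplitudes must sum to 1. Default singlet.
#' @return object of class `spectral_component`
#' @export
spectral_component <- function(name, freq_offset, amplitude, damping,
                               phase = 0, multiplet = NULL) {
  if (amplitude < 0) stop_param("amplitude must be >= 0")
  if (damping < 0) stop_param("damping must be >= 0")
  if (is.null(multiplet)) multiplet <- cbind(offset = 0, rel = 1)
  multiplet <- matrix(as.numeric(multiplet), ncol = 2,
                      dimnames = list(NULL, c("offset", "rel")))
  if (abs(sum(multiplet[, "rel"]) - 1) > 1e-12)
    stop_param("multiplet relative amplitudes must sum to 1")
  structure(list(name = name, freq_offset = freq_offset, amplitude = amplitude,
                 damping = damping, phase = phase, multiplet = multiplet),
            class = "spectral_component")
}

#' Axis-aligned box in scanner mm coordinates (half-open: min <= p < max)
#' @param min,max length-3 numeric, mm
#' @export
shape_box <- function(min, max) {
  if (any(max <= min)) stop_param("box must have max > min on every axis")
  structure(list(type = "box", min = min, max = max), class = "phantom_shape")
}

#' Axis-aligned ellipsoid in scanner mm coordinates
#' @param centre length-3 numeric, mm
#' @param semiaxes length-3 numeric, mm, > 0
#' @export
shape_ellipsoid <- function(centre, semiaxes) {
  if (any(semiaxes <= 0)) stop_param("semiaxes must be > 0")
  structure(list(type = "ellipsoid", centre = centre, semiaxes = semiaxes),
            class = "phantom_shape")
}

point_in_shape <- function(p, shape, displacement = c(0, 0, 0)) {
  # p: n x 3 matrix of points; shape displaced by `displacement` (mm)
  q <- sweep(p, 2, displacement)
  if (shape$type == "box") {
    (q[, 1] >= shape$min[1] & q[, 1] < shape$max[1] &
     q[, 2] >= shape$min[2] & q[, 2] < shape$max[2] &
     q[, 3] >= shape$min[3] & q[, 3] < shape$max[3])
  } else {
    u <- sweep(q, 2, shape$centre)
    (u[, 1] / shape$semiaxes[1])^2 + (u[, 2] / shape$semiaxes[2])^2 +
      (u[, 3] / shape$semiaxes[3])^2 <= 1
  }
}

#' Tissue compartment specification
#'
#' @param name compartment name ("heart", "chest_wall", "other", ...)
#' @param geometry list of shapes ([shape_box()]/[shape_ellipsoid()]); must be
#'   non-empty unless `catch_all = TRUE`
#' @param components list of [spectral_component()]s (per-voxel signal)
#' @param t1 named numeric vector of T1s (s) per component name, > 0
#' @param motion_amplitude peak displacement in mm (cardiac motion); nonzero
#'   only for the heart by default
#' @param catch_all if TRUE the compartment is the background complement of
#'   all other compartments (mask label 0); geometry is ignored
#' @export
compartment_spec <- function(name, geometry = list(), components = list(),
                             t1 = NULL, motion_amplitude = 0, catch_all = FALSE) {
  if (!catch_all && length(geometry) == 0) stop_param("geometry must be non-empty")
  if (!is.null(t1) && any(t1 <= 0)) stop_param("t1 must be > 0")
  if (motion_amplitude < 0) stop_param("motion_amplitude must be >= 0")
  structure(list(name = name, geometry = geometry, components = components,
                 t1 = t1, motion_amplitude = motion_amplitude,
                 catch_all = catch_all),
            class = "compartment_spec")
}

#' Cardiac motion model
#'
#' Displacement at cardiac phase theta in [0,1) is
#' `amplitude * phase_function(theta) * axis`; `phase_function(0)` must be 0
#' (acquisition gated to diastasis) and |phase_function| <= 1.
#'
#' @param amplitude peak displacement, mm
#' @param axis unit direction vector, default anterior-posterior (y)
#' @param phase_function function theta -> displacement fraction in [0, 1];
#'   default smooth periodic (1 - cos(2 pi theta)) / 2
#' @export
motion_model <- function(amplitude = 0, axis = c(0, 1, 0),
                         phase_function = function(theta) (1 - cos(2 * pi * theta)) / 2) {
  if (amplitude < 0) stop_param("amplitude must be >= 0")
  if (abs(phase_function(0)) > 1e-12)
    stop_param("phase_function(0) must be 0 (diastasis)")
  axis <- axis / sqrt(sum(axis^2))
  structure(list(amplitude = amplitude, axis = axis,
                 phase_function = phase_function),
            class = "motion_model")
}

motion_displacement <- function(motion, theta) {
  frac <- motion$phase_function(theta %% 1)
  if (abs(frac) > 1 + 1e-12) stop_consistency("motion displacement exceeds amplitude")
  motion$amplitude * frac * motion$axis
}

#' Phantom definition
#'
#' @param geometry an [acq_geometry()]
#' @param compartments ordered list of [compartment_spec()]; at most one may
#'   be a catch-all (background/"other") compartment
#' @param blood list with `components` (list of [spectral_component()]) and
#'   `fraction` (blood volume fraction of the heart compartment, 0..1)
#' @param saturation_slabs list of slabs, each
#'   `list(axis =, centre_mm =, thickness_mm =, efficiency =)`; signal at
#'   voxels inside a slab is multiplied by (1 - efficiency)
#' @param motion a [motion_model()]; applied to compartments with
#'   `motion_amplitude > 0` (amplitude taken from the compartment)
#' @export
phantom_definition <- function(geometry, compartments, blood = NULL,
                               saturation_slabs = list(), motion = motion_model()) {
  if (!is.null(blood)) {
    if (blood$fraction < 0 || blood$fraction > 1)
      stop_param("blood fraction must be in [0, 1]")
  }
  for (s in saturation_slabs) {
    if (s$thickness_mm <= 0) stop_param("slab thickness must be > 0")
    if (s$efficiency < 0 || s$efficiency > 1) stop_param("slab efficiency must be in [0, 1]")
  }
  if (sum(vapply(compartments, function(cp) cp$catch_all, logical(1))) > 1)
    stop_param("at most one catch-all compartment allowed")
  names(compartments) <- vapply(compartments, function(cp) cp$name, character(1))
  structure(list(geometry = geometry, compartments = compartments, blood = blood,
                 saturation_slabs = saturation_slabs, motion = motion),
            class = "phantom_definition")
}

# Default chemical shifts (Hz relative to PCr at ~49.9 MHz 31P Larmor) and
# J-coupling multiplets. Literature-informed configuration, not fitted values.
default_shifts <- function() {
  list(PCr = 0, gATP = -128, aATP = -380, bATP = -825, DPG = 295)
}

doublet <- function(j = 8.5) cbind(offset = c(-j, j), rel = c(0.5, 0.5))
triplet <- function(j = 17) cbind(offset = c(-j, 0, j), rel = c(0.25, 0.5, 0.25))
dpg_pair <- function() cbind(offset = c(-25, 25), rel = c(0.5, 0.5))  # 2,3-DPG at +270/+320

#' Myocyte spectral components with a given true PCr/gamma-ATP ratio
#' @param pcr_atp_ratio true amplitude ratio PCr / gamma-ATP
#' @keywords internal
myocyte_components <- function(pcr_atp_ratio = 2.0) {
  sh <- default_shifts()
  list(
    spectral_component("PCr",  sh$PCr,  pcr_atp_ratio, 31.4),
    spectral_component("gATP", sh$gATP, 1.0, 47, multiplet = doublet()),
    spectral_component("aATP", sh$aATP, 1.0, 47, multiplet = doublet()),
    spectral_component("bATP", sh$bATP, 1.0, 47, multiplet = triplet())
  )
}

#' Blood-pool spectral components (2,3-DPG dominant plus blood ATP)
#'
#' Composition fixed so that the ratio of blood gamma-ATP to the mean 2,3-DPG
#' amplitude equals 0.30, the default blood-correction coefficient kappa:
#' the default correction then exactly removes the stated contamination.
#' ATP dampings match the myocyte ATP so compartment signals stay within the
#' fitted model class.
#' @keywords internal
blood_components <- function() {
  sh <- default_shifts()
  list(
    spectral_component("DPG",  sh$DPG,  2.0, 60, multiplet = dpg_pair()),
    spectral_component("gATP", sh$gATP, 0.3, 47, multiplet = doublet()),
    spectral_component("aATP", sh$aATP, 0.3, 47, multiplet = doublet()),
    spectral_component("bATP", sh$bATP, 0.3, 47, multiplet = triplet())
  )
}

scale_component <- function(comp, factor) {
  comp$amplitude <- comp$amplitude * factor
  comp
}

#' Build the default digital thorax phantom
#'
#' Three compartments on the default 8 x 16 x 8 grid (FOV 240 x 240 x 200 mm):
#' heart (myocyte PCr + ATP mixed with a blood pool of 2,3-DPG + ATP),
#' chest wall (strong skeletal-muscle PCr), and a catch-all "other"
#' compartment (ATP-dominant, no PCr, standing in for liver and remaining
#' tissue, homogenised over the whole background). Three 25-mm saturation
#' slabs null part of the chest wall and the inferior (liver) region, leaving
#' the unsaturated chest-wall row as the residual PCr contamination source.
#' The heart moves along the anterior-posterior axis with the cardiac phase.
#'
#' @param geometry an [acq_geometry()]; default [default_geometry()]
#' @param motion_amplitude_mm peak cardiac displacement of the heart (mm)
#' @param blood_fraction blood volume fraction of the heart compartment
#' @param pcr_atp_ratio true myocyte PCr/gamma-ATP amplitude ratio
#' @param seed unused (the default phantom is deterministic); kept so
#'   randomized phantom generators share the signature
#' @return a [phantom_definition()]
#' @export
build_default_phantom <- function(geometry = default_geometry(),
                                  motion_amplitude_mm = 10,
                                  blood_fraction = 0.2,
                                  pcr_atp_ratio = 2.0,
                                  seed = NULL) {
  if (motion_amplitude_mm < 0) stop_param("motion_amplitude_mm must be >= 0")
  if (blood_fraction < 0 || blood_fraction > 1)
    stop_param("blood_fraction must be in [0, 1]")
  f <- blood_fraction
  heart_comps <- c(
    lapply(myocyte_components(pcr_atp_ratio), scale_component, factor = 1 - f),
    if (f > 0) lapply(blood_components(), scale_component, factor = f)
  )
  heart_comps <- Filter(function(cp) cp$amplitude > 0, heart_comps)
  sh <- default_shifts()
  chest_comps <- list(
    spectral_component("PCr",  sh$PCr,  6.0, 35),
    spectral_component("gATP", sh$gATP, 1.5, 50, multiplet = doublet()),
    spectral_component("aATP", sh$aATP, 1.5, 50, multiplet = doublet()),
    spectral_component("bATP", sh$bATP, 1.5, 50, multiplet = triplet())
  )
  other_comps <- list(
    spectral_component("gATP", sh$gATP, 0.15, 55, multiplet = doublet()),
    spectral_component("aATP", sh$aATP, 0.15, 55, multiplet = doublet()),
    spectral_component("bATP", sh$bATP, 0.15, 55, multiplet = triplet())
  )
  t1_default <- c(PCr = 5.8, gATP = 3.1, aATP = 3.1, bATP = 3.1, DPG = 2.5)
  compartments <- list(
    compartment_spec("heart",
                     geometry = list(shape_box(c(-45, -85, -50), c(45, -25, 50))),
                     components = heart_comps, t1 = t1_default,
                     motion_amplitude = motion_amplitude_mm),
    # anterior slab plus lateral wings: in the prone position the pectoral
    # muscle wraps around at heart depth, where axis-aligned saturation
    # bands cannot reach without nulling the anterior heart row
    compartment_spec("chest_wall",
                     geometry = list(
                       shape_box(c(-120, -120, -100), c(120, -90, 100)),
                       shape_box(c(-120, -90, -100), c(-60, -75, 100)),
                       shape_box(c(60, -90, -100), c(120, -75, 100))),
                     components = chest_comps, t1 = t1_default),
    compartment_spec("other", components = other_comps, t1 = t1_default,
                     catch_all = TRUE)
  )
  # Two overlapping anterior bands suppress the flat chest slab (imperfect
  # in vivo: T1 recovery, B1 variation -> 5% residual); the lateral wings at
  # heart depth are untouched (an anterior-posterior band there would null
  # the heart row too) and remain the dominant PCr contamination source.
  # The third band saturates the inferior (liver) region.
  slabs <- list(
    list(axis = 2, centre_mm = -105,   thickness_mm = 25, efficiency = 0.95),
    list(axis = 2, centre_mm = -112.5, thickness_mm = 25, efficiency = 0.95),
    list(axis = 3, centre_mm = -90,    thickness_mm = 25, efficiency = 0.95)
  )
  phantom_definition(geometry, compartments,
                     blood = list(components = blood_components(), fraction = f),
                     saturation_slabs = slabs,
                     motion = motion_model(amplitude = motion_amplitude_mm))
}

#' Per-voxel saturation factor map (1 outside slabs, 1 - efficiency inside)
#' @keywords internal
saturation_map <- function(phantom, apply = TRUE) {
  g <- phantom$geometry
  sat <- array(1, dim = g$matrix)
  if (!apply) return(sat)
  P <- voxel_centre_grid(g)
  for (s in phantom$saturation_slabs) {
    inside <- abs(P[, s$axis] - s$centre_mm) <= s$thickness_mm / 2
    sat[inside] <- sat[inside] * (1 - s$efficiency)
  }
  sat
}

# Labels of non-catch-all compartments at a cardiac phase. Returns an integer
# vector over voxels (column-major), 0 = background.
rasterize_labels <- function(phantom, grid_shape, cardiac_phase = 0,
                             offset_mm = c(0, 0, 0)) {
  g <- phantom$geometry
  if (!all(grid_shape == g$matrix))
    stop_consistency("grid_shape does not match phantom acquisition matrix")
  P <- voxel_centre_grid(g)
  labels <- integer(nrow(P))
  lab <- 0L
  for (cp in phantom$compartments) {
    if (cp$catch_all) next
    lab <- lab + 1L
    disp <- offset_mm
    if (cp$motion_amplitude > 0 && phantom$motion$amplitude > 0) {
      m <- phantom$motion
      m$amplitude <- cp$motion_amplitude
      disp <- disp + motion_displacement(m, cardiac_phase)
    }
    inside <- Reduce(`|`, lapply(cp$geometry, function(sh) point_in_shape(P, sh, disp)))
    if (any(labels[inside] != 0L))
      stop_consistency("compartment geometries overlap after rasterization: ",
                       cp$name)
    labels[inside] <- lab
  }
  labels
}

#' Rasterize phantom compartments to an integer label mask
#'
#' Voxel-centre sampling convention: a voxel takes the label of the
#' compartment containing its centre; label 0 is the background, assigned to
#' the catch-all compartment ("other") when one exists.
#'
#' @param phantom a [phantom_definition()]
#' @param grid_shape 3 integers; must equal the phantom's acquisition matrix
#' @param cardiac_phase cardiac phase theta in [0, 1); 0 = diastasis
#' @param offset_mm rigid displacement (mm) applied to all compartments, used
#'   by FOV-shift compensation and session repositioning
#' @return a `compartment_mask`: integer label array with a name table and
#'   provenance for re-rasterization
#' @export
rasterize_masks <- function(phantom, grid_shape = phantom$geometry$matrix,
                            cardiac_phase = 0, offset_mm = c(0, 0, 0)) {
  labels <- rasterize_labels(phantom, grid_shape, cardiac_phase, offset_mm)
  non_catch <- Filter(function(cp) !cp$catch_all, phantom$compartments)
  name_table <- c(stats::setNames(seq_along(non_catch),
                                  vapply(non_catch, function(cp) cp$name, character(1))))
  catch <- Filter(function(cp) cp$catch_all, phantom$compartments)
  if (length(catch)) name_table <- c(name_table, stats::setNames(0L, catch[[1]]$name))
  compartment_mask(array(labels, dim = grid_shape), name_table, phantom$geometry,
                   provenance = list(phantom = phantom, cardiac_phase = cardiac_phase,
                                     offset_mm = offset_mm))
}

#' Compartment label mask
#' @param labels integer array on the MRSI grid
#' @param names named integer vector mapping compartment name -> label
#' @param geometry an [acq_geometry()]
#' @param provenance optional list(phantom, cardiac_phase, offset_mm) enabling
#'   fractional re-rasterization ([shift_mask()])
#' @param subvoxel_shift sub-voxel compartment-support offset (voxel units)
#'   applied as an encoding phase by [build_slam_system()]; set by
#'   [shift_mask()] for fractional FOV-shift compensation
#' @export
compartment_mask <- function(labels, names, geometry, provenance = NULL,
                             subvoxel_shift = c(0, 0, 0)) {
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, names = names, geometry = geometry,
                 provenance = provenance, subvoxel_shift = subvoxel_shift),
            class = "compartment_mask")
}

#' Time-domain signal of a list of spectral components
#'
#' Evaluates \eqn{y(t) = \sum_k a_k e^{i\phi_k} \sum_j w_{kj}
#' e^{(-d_k + i 2\pi (f_k + \delta_{kj})) t}} on a uniform time axis starting
#' at 0. Components whose centre frequency lies outside `excitation_band`
#' (when given) are attenuated to zero, modelling the ideal band-limited
#' excitation pulse.
#'
#' @param components list of [spectral_component()]
#' @param time_axis_s uniform time axis (s) starting at 0
#' @param excitation_band optional c(low, high) Hz
#' @return a [fid()]
#' @export
compartment_fid <- function(components, time_axis_s, excitation_band = NULL) {
  n <- length(time_axis_s)
  if (n < 2) stop_param("time axis must have at least 2 points")
  dt <- diff(time_axis_s)
  if (abs(time_axis_s[1]) > 1e-12 || any(abs(dt - dt[1]) > 1e-9 * dt[1]))
    stop_param("time axis must be uniform and start at 0")
  y <- complex(real = numeric(n), imaginary = numeric(n))
  for (cp in components) {
    if (!is.null(excitation_band) &&
        (cp$freq_offset < excitation_band[1] || cp$freq_offset > excitation_band[2]))
      next
    for (j in seq_len(nrow(cp$multiplet))) {
      f <- cp$freq_offset + cp$multiplet[j, "offset"]
      y <- y + cp$amplitude * cp$multiplet[j, "rel"] *
        exp(1i * cp$phase + (-cp$damping + 2i * pi * f) * time_axis_s)
    }
  }
  fid(y, dwell_s = dt[1])
}

# Per-voxel compartment FIDs for simulation/ground truth: named list of
# complex vectors, one per compartment (heart includes the blood pool already;
# amplitudes are per-voxel).
compartment_base_fids <- function(phantom, time_axis_s, excitation_band = NULL) {
  stats::setNames(
    lapply(phantom$compartments, function(cp)
      compartment_fid(cp$components, time_axis_s, excitation_band)$signal),
    names(phantom$compartments))
}
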