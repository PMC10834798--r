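# Shared fixtures, memoised so expensive simulations run once per file.

.world_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .world_cache)) {
    assign(key, force(expr), envir = .world_cache)
  }
  get(key, envir = .world_cache)
}

# Default phantom world: noiseless, gated, saturation off -> exactly
# piecewise-constant on the three compartments (the recovery-oracle world).
world_constant <- function() memo("constant", {
  ph <- build_default_phantom()
  scheme <- build_aw_scheme()
  proto <- protocol(noise_sigma = 0, gated = TRUE, saturation = FALSE)
  ks <- simulate_acquisition(ph, scheme, proto)
  list(phantom = ph, mask = rasterize_masks(ph), scheme = scheme,
       protocol = proto, kspace = ks)
})

# Default phantom with saturation on (the realistic world).
world_default <- function() memo("default", {
  ph <- build_default_phantom()
  scheme <- build_aw_scheme()
  proto <- protocol(noise_sigma = 0, gated = TRUE)
  ks <- simulate_acquisition(ph, scheme, proto)
  list(phantom = ph, mask = rasterize_masks(ph), scheme = scheme,
       protocol = proto, kspace = ks)
})

# Full unweighted k-space acquisition of the constant world (oracle grid).
world_unweighted <- function() memo("unweighted", {
  ph <- build_default_phantom()
  scheme <- build_aw_scheme(window = "uniform", max_averages = 1)
  proto <- protocol(noise_sigma = 0, gated = TRUE, saturation = FALSE,
                    n_time = 256)
  ks <- simulate_acquisition(ph, scheme, proto)
  list(phantom = ph, mask = rasterize_masks(ph), scheme = scheme,
       protocol = proto, kspace = ks)
})

default_time_axis <- function(n = 512, dwell = 2.5e-4) (0:(n - 1)) * dwell

# A random phantom that is piecewise-constant on three y-partitioned
# compartments (disjoint by construction), for randomized oracle tests.
random_partition_phantom <- function(seed) {
  set.seed(seed)
  sh <- list(PCr = 0, gATP = -128, aATP = -380)
  amp <- function() stats::runif(1, 0.2, 3)
  comps <- function() list(
    spectral_component("PCr", sh$PCr, amp(), stats::runif(1, 20, 60)),
    spectral_component("gATP", sh$gATP, amp(), stats::runif(1, 30, 80),
                       multiplet = cbind(c(-8.5, 8.5), c(0.5, 0.5))))
  cut1 <- sample(c(-60, -45, -30), 1)
  cut2 <- sample(c(15, 30, 45), 1)
  phantom_definition(
    default_geometry(),
    list(compartment_spec("heart", list(shape_box(c(-120, cut1, -100), c(120, cut2, 100))),
                          components = comps()),
         compartment_spec("chest_wall", list(shape_box(c(-120, -120, -100), c(120, cut1, 100))),
                          components = comps()),
         compartment_spec("other", components = comps(), catch_all = TRUE)))
}

# Mean of FT-reconstructed voxel FIDs over one labelled compartment.
ft_compartment_mean <- function(grid, mask, label) {
  idx <- which(mask$labels == label, arr.ind = TRUE)
  sig <- 0i * grid$fids[1, 1, 1, ]
  for (r in seq_len(nrow(idx)))
    sig <- sig + grid$fids[idx[r, 1], idx[r, 2], idx[r, 3], ]
  sig / nrow(idx)
}

# Scan-level metric pipeline shared with the experiments module.
analyze <- function(f, lb = 20, saturation_correction = FALSE) {
  cfg <- default_experiment_config()
  cfg$lb_hz <- lb
  cfg$saturation_correction <- saturation_correction
  slamrecon:::analyze_fid(f, cfg)
}
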