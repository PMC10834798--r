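# Acquisition module: AW scheme, forward simulation, FOV shift, duration.

test_that("build_aw_scheme honours the centre-average and symmetry contracts", {
  sch <- build_aw_scheme(c(8, 16, 8), max_averages = 10)
  centre <- which(rowSums(abs(sch$k_index)) == 0)
  expect_identical(sch$averages[centre], 10L)
  # symmetry: averages(k) == averages(-k) wherever both are acquired
  key <- apply(sch$k_index, 1, paste, collapse = ",")
  neg <- apply(-sch$k_index, 1, paste, collapse = ",")
  hit <- match(neg, key)
  both <- !is.na(hit)
  expect_true(any(both))
  expect_identical(sch$averages[both], sch$averages[hit[both]])
  # uniform window, max 1 -> plain CSI over the full grid
  schu <- build_aw_scheme(c(4, 4, 4), max_averages = 1, window = "uniform")
  expect_identical(nrow(schu$k_index), 64L)
  expect_true(all(schu$averages == 1L))
  expect_error(build_aw_scheme(window = "boxcar"), class = "slamrecon_param_error")
  # default window reproduces the protocol's readout budget (~700, 10.5 min)
  expect_lt(abs(sum(sch$averages) * 0.9 - 630) / 630, 0.2)
})

test_that("FT of a uniform object concentrates at DC", {
  geom <- default_geometry()
  ph <- phantom_definition(geom, list(
    compartment_spec("all", list(shape_box(c(-121, -121, -101), c(121, 121, 101))),
                     components = list(spectral_component("PCr", 0, 1, 30)))))
  ks <- simulate_acquisition(ph, build_aw_scheme(geom$matrix, 1, "uniform"),
                             protocol(noise_sigma = 0, gated = TRUE,
                                      saturation = FALSE, n_time = 256))
  dc <- which(rowSums(abs(ks$k_index)) == 0)
  others <- max(Mod(ks$samples[-dc, ]))
  expect_lt(others, 1e-10 * max(Mod(ks$samples[dc, ])))
})

test_that("gated with motion equals ungated without motion (noiseless)", {
  sch <- build_aw_scheme()
  pr_g <- protocol(noise_sigma = 0, gated = TRUE, n_time = 256)
  pr_u <- protocol(noise_sigma = 0, gated = FALSE, n_time = 256)
  ks_g <- simulate_acquisition(build_default_phantom(motion_amplitude_mm = 8), sch, pr_g)
  ks_u <- simulate_acquisition(build_default_phantom(motion_amplitude_mm = 0), sch, pr_u)
  expect_equal(ks_g$samples, ks_u$samples)
})

test_that("ungated noiseless data vary across seeds; gated do not", {
  ph <- build_default_phantom(motion_amplitude_mm = 10)
  sch <- build_aw_scheme(c(8, 16, 8), max_averages = 2)
  u1 <- simulate_acquisition(ph, sch, protocol(noise_sigma = 0, gated = FALSE,
                                               seed = 1, n_time = 256))
  u2 <- simulate_acquisition(ph, sch, protocol(noise_sigma = 0, gated = FALSE,
                                               seed = 2, n_time = 256))
  g1 <- simulate_acquisition(ph, sch, protocol(noise_sigma = 0, gated = TRUE,
                                               seed = 1, n_time = 256))
  g2 <- simulate_acquisition(ph, sch, protocol(noise_sigma = 0, gated = TRUE,
                                               seed = 2, n_time = 256))
  expect_gt(max(Mod(u1$samples - u2$samples)), 0)
  expect_equal(g1$samples, g2$samples)
  # determinism for a fixed seed
  u1b <- simulate_acquisition(ph, sch, protocol(noise_sigma = 0, gated = FALSE,
                                                seed = 1, n_time = 256))
  expect_identical(u1$samples, u1b$samples)
})

test_that("summed-average noise variance is n(k) sigma^2 per channel (Monte Carlo)", {
  # empty phantom: acquired samples are pure summed noise
  geom <- acq_geometry(c(60, 60, 60), c(2, 2, 2))
  ph <- phantom_definition(geom, list(compartment_spec("other", catch_all = TRUE)))
  sch <- build_aw_scheme(c(2, 2, 2), max_averages = 3, window = "uniform")
  sigma <- 0.7
  n_rep <- 2000
  vals <- matrix(0, n_rep, 2)
  for (r in seq_len(n_rep)) {
    ks <- simulate_acquisition(ph, sch, protocol(noise_sigma = sigma, gated = TRUE,
                                                 seed = r, n_time = 256))
    vals[r, ] <- c(Re(ks$samples[1, 1]), Im(ks$samples[1, 1]))
  }
  expect_equal(stats::var(vals[, 1]), 3 * sigma^2, tolerance = 0.05 * 3 * sigma^2)
  expect_equal(stats::var(vals[, 2]), 3 * sigma^2, tolerance = 0.05 * 3 * sigma^2)
})

test_that("shift_fov follows the shift theorem and round-trips", {
  w <- world_unweighted()
  ks <- w$kspace
  # delta = 0 -> bitwise identity
  expect_identical(shift_fov(ks, c(0, 0, 0))$samples, ks$samples)
  # integer shift: FT grid circularly shifted by one voxel along y
  ks1 <- shift_fov(ks, c(0, 1, 0))
  g0 <- recon_ft(ks)$fids
  g1 <- recon_ft(ks1)$fids
  rolled <- g0[, c(16, 1:15), , , drop = FALSE]  # new(r) = old(r - 1)
  expect_lt(max(Mod(g1 - rolled)) / max(Mod(g0)), 1e-10)
  # round trip to 1e-12
  back <- shift_fov(shift_fov(ks, c(0.5, -1, 0.25)), -c(0.5, -1, 0.25))
  expect_lt(max(Mod(back$samples - ks$samples)) / max(Mod(ks$samples)), 1e-12)
  # half-voxel shift along y is 7.5 mm of physical displacement
  expect_equal(0.5 * ks$geometry$voxel_mm[2], 7.5)
  expect_equal(ks1$shift_voxels, c(0, 1, 0))
})

test_that("scan_duration is total readouts times TR", {
  pr <- protocol(tr_s = 0.9)
  sch <- build_aw_scheme()
  expect_equal(scan_duration(sch, pr), sum(sch$averages) * 0.9)
  # the protocol's printed arithmetic: 700 readouts x 0.9 s = 630 s
  sch700 <- sch
  sch700$averages <- c(700L, rep(0L, length(sch$averages) - 1))
  expect_equal(scan_duration(sch700, pr), 630)
  # uniform max 1 on the full grid: 1024 x 0.9 s
  expect_equal(scan_duration(build_aw_scheme(c(8, 16, 8), 1, "uniform"), pr),
               1024 * 0.9)
  # doubling max_averages doubles duration up to rounding
  d1 <- scan_duration(build_aw_scheme(c(8, 16, 8), 5), pr)
  d2 <- scan_duration(build_aw_scheme(c(8, 16, 8), 10), pr)
  expect_lt(abs(d2 - 2 * d1) / d2, 0.1)
})

test_that("mismatched scheme geometry is rejected", {
  ph <- build_default_phantom()
  sch <- build_aw_scheme(c(4, 4, 4))
  expect_error(simulate_acquisition(ph, sch, protocol()),
               class = "slamrecon_consistency_error")
})
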