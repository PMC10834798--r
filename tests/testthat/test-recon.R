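# Reconstruction: FT-MRS, mid-septal voxel selection, SLAM system and solve,
# mask shifting and FOV-shift compensation.

test_that("FT recon inverts a noiseless unweighted acquisition exactly", {
  w <- world_unweighted()
  grid <- recon_ft(w$kspace)
  taxis <- default_time_axis(256)
  truth <- lapply(w$phantom$compartments, function(cp)
    compartment_fid(cp$components, taxis, c(-1000, 500))$signal)
  scale <- max(Mod(truth$heart))
  for (nm in names(w$mask$names)) {
    lab <- w$mask$names[[nm]]
    idx <- which(w$mask$labels == lab, arr.ind = TRUE)[1, ]
    got <- grid$fids[idx[1], idx[2], idx[3], ]
    expect_lt(max(Mod(got - truth[[nm]])) / scale, 1e-10)
  }
})

test_that("empty data reconstruct to an all-zero grid; duplicates rejected", {
  w <- world_unweighted()
  ks <- w$kspace
  ks$samples[] <- 0i
  expect_true(all(recon_ft(ks)$fids == 0i))
  ks2 <- w$kspace
  ks2$k_index[2, ] <- ks2$k_index[1, ]
  expect_error(recon_ft(ks2), class = "slamrecon_consistency_error")
})

test_that("AW impulse response equals the window's DFT (analytic PSF)", {
  geom <- default_geometry()
  # impulse object: one voxel along y at index 5 (centre -52.5 mm)
  ph <- phantom_definition(geom, list(
    compartment_spec("dot", list(shape_box(c(-121, -60, -101), c(121, -45, 101))),
                     components = list(spectral_component("PCr", 0, 1, 0)))))
  sch <- build_aw_scheme(geom$matrix, 10, "hann")
  ks <- simulate_acquisition(ph, sch, protocol(noise_sigma = 0, gated = TRUE,
                                               saturation = FALSE, n_time = 256))
  grid <- recon_ft(ks)
  profile <- grid$fids[1, , 1, 1]  # y-profile at t = 0 through x = z = index 1
  # oracle: the object is a y-plane at index 5 (0-based 4), so only k1 = k3 = 0
  # encodes carry signal and the profile is the 1D DFT of the y average-count
  # window centred on that plane
  n <- geom$matrix
  on_axis <- ks$k_index[, 1] == 0 & ks$k_index[, 3] == 0
  k2 <- ks$k_index[on_axis, 2]
  n2 <- ks$averages[on_axis]
  psf <- vapply(0:(n[2] - 1), function(r)
    sum(n2 * exp(2i * pi * k2 * (r - 4) / n[2])) / n[2], complex(1))
  expect_lt(max(Mod(profile - psf)) / max(Mod(psf)), 1e-10)
})

test_that("select_septal_voxel obeys its selection contract", {
  w <- world_default()
  grid <- recon_ft(w$kspace)
  sel <- select_septal_voxel(grid, w$mask)
  # selected voxel is truly heart-labelled, with no adjacent chest wall
  expect_identical(w$mask$labels[sel$index[1], sel$index[2], sel$index[3]],
                   w$mask$names[["heart"]])
  nb <- w$mask$labels[sel$index[1], sel$index[2] - 1, sel$index[3]]
  expect_false(nb == w$mask$names[["chest_wall"]])
  # override short-circuits selection
  ovr <- select_septal_voxel(grid, w$mask, override_index = c(1, 1, 1))
  expect_identical(ovr$index, c(1, 1, 1))
  # single heart voxel -> that voxel
  m1 <- w$mask
  m1$labels[] <- 0L
  m1$labels[3, 7, 4] <- w$mask$names[["heart"]]
  expect_identical(select_septal_voxel(grid, m1)$index, c(3L, 7L, 4L))
  # symmetric tie -> lowest linear index
  m2 <- w$mask
  m2$labels[] <- 0L
  m2$labels[3, 7, 4] <- m2$labels[5, 7, 4] <- w$mask$names[["heart"]]
  expect_identical(select_septal_voxel(grid, m2)$index, c(3L, 7L, 4L))
  # no heart voxels -> selection error
  m3 <- w$mask
  m3$labels[] <- 0L
  expect_error(select_septal_voxel(grid, m3), class = "slamrecon_selection_error")
})

test_that("build_slam_system matches its definition and rank contracts", {
  w <- world_unweighted()
  # C = 1 mask covering everything: E is the DFT of an all-ones image
  m_all <- compartment_mask(array(1L, dim = c(8, 16, 8)), c(everything = 1L),
                           w$kspace$geometry)
  sys1 <- build_slam_system(m_all, w$kspace)
  dc <- which(rowSums(abs(w$kspace$k_index)) == 0)
  expect_equal(sys1$E[dc, 1], 1024 + 0i)
  expect_lt(max(Mod(sys1$E[-dc, 1])), 1e-9)
  # three-compartment default mask has full column rank
  sys3 <- build_slam_system(w$mask, w$kspace)
  expect_identical(ncol(sys3$E), 3L)
  expect_gt(min(svd(sys3$E * sys3$weights)$d), 0)
  # M < C -> explicit under-determined error
  ph <- build_default_phantom()
  sch3 <- build_aw_scheme(c(8, 16, 8), 1, "uniform")
  sch3$k_index <- sch3$k_index[1:2, , drop = FALSE]
  sch3$averages <- sch3$averages[1:2]
  ks3 <- simulate_acquisition(ph, sch3, protocol(noise_sigma = 0, gated = TRUE,
                                                 n_time = 256))
  expect_error(build_slam_system(w$mask, ks3),
               class = "slamrecon_underdetermined_error")
})

test_that("noiseless SLAM recovers compartment ground truth to 1e-8", {
  w <- world_constant()
  cs <- recon_slam(w$kspace, w$mask)
  taxis <- default_time_axis()
  for (nm in c("heart", "chest_wall", "other")) {
    truth <- compartment_fid(w$phantom$compartments[[nm]]$components, taxis,
                             c(-1000, 500))$signal
    expect_lt(max(Mod(cs$fids[[nm]]$signal - truth)) / max(Mod(truth)), 1e-8)
  }
  expect_identical(cs$conditioning$effective_rank, 3L)
})

test_that("rcond = 1 truncates everything and raises the conditioning error", {
  w <- world_constant()
  expect_error(recon_slam(w$kspace, w$mask, rcond = 1),
               class = "slamrecon_illconditioned_error")
})

test_that("SLAM equals FT compartment means on full unweighted k-space (property)", {
  for (seed in 1:5) {
    ph <- random_partition_phantom(seed)
    mask <- rasterize_masks(ph)
    ks <- simulate_acquisition(ph, build_aw_scheme(c(8, 16, 8), 1, "uniform"),
                               protocol(noise_sigma = 0, gated = TRUE,
                                        saturation = FALSE, n_time = 256))
    cs <- recon_slam(ks, mask)
    grid <- recon_ft(ks)
    for (nm in names(mask$names)) {
      mean_ft <- ft_compartment_mean(grid, mask, mask$names[[nm]])
      expect_lt(max(Mod(cs$fids[[nm]]$signal - mean_ft)) / max(Mod(mean_ft)), 1e-10)
    }
  }
})

test_that("SLAM compartment noise matches the analytic WLS covariance", {
  w <- world_default()
  ks <- w$kspace
  sys <- build_slam_system(w$mask, ks)
  A <- sys$E * sys$weights
  cov_analytic <- solve(Re(Conj(t(A)) %*% A))
  sigma <- 2.0
  heart_col <- which(sys$compartments == "heart")
  n_draw <- 500
  vals <- numeric(n_draw)
  M <- nrow(ks$k_index); nt <- 64
  ks$samples <- matrix(0i, M, nt)
  set.seed(99)
  for (r in seq_len(n_draw)) {
    noise <- sqrt(ks$averages) * sigma *
      matrix(complex(real = rnorm(M * nt), imaginary = rnorm(M * nt)), M, nt)
    ks$samples <- noise
    cs <- recon_slam(ks, w$mask)
    vals[r] <- Re(cs$fids[["heart"]]$signal[1])
  }
  expect_equal(stats::sd(vals), sigma * sqrt(cov_analytic[heart_col, heart_col]),
               tolerance = 0.1)
})

test_that("shift_mask semantics: identity, rolls, rasterize oracle, errors", {
  w <- world_default()
  mask <- w$mask
  expect_identical(shift_mask(mask, c(0, 0, 0))$labels, mask$labels)
  # integer k-space shift = circular roll
  s1 <- shift_mask(mask, c(0, 1, 0))
  expect_identical(s1$labels, mask$labels[, c(16, 1:15), ])
  # rasterize method: fractional shift equals brute-force re-rasterization
  s_half <- shift_mask(mask, c(0, 0.5, 0), method = "rasterize")
  oracle <- rasterize_masks(w$phantom, offset_mm = c(0, 7.5, 0))
  expect_identical(s_half$labels, oracle$labels)
  # fractional rasterize shift without provenance is unsupported
  bare <- compartment_mask(mask$labels, mask$names, mask$geometry)
  expect_error(shift_mask(bare, c(0, 0.5, 0), method = "rasterize"),
               class = "slamrecon_unsupported_error")
  # k-space method stores the sub-voxel remainder
  s_k <- shift_mask(bare, c(0, 0.5, 0))
  expect_equal(s_k$subvoxel_shift, c(0, 0.5, 0))
})

test_that("FOV-shift compensation holds within 1% for half- and full-voxel shifts", {
  w <- world_constant()
  base <- recon_slam(w$kspace, w$mask)$fids[["heart"]]
  r0 <- analyze(base)$ratio
  for (dv in c(-1, -0.5, 0.5, 1)) {
    ks <- shift_fov(w$kspace, c(0, dv, 0))
    comp <- recon_slam(ks, shift_mask(w$mask, c(0, dv, 0)))$fids[["heart"]]
    expect_equal(analyze(comp)$ratio, r0, tolerance = 0.01)
  }
})

test_that("moving the FT voxel one voxel toward the chest wall raises PCr/ATP", {
  w <- world_default()
  grid <- recon_ft(w$kspace)
  sel <- select_septal_voxel(grid, w$mask)
  toward <- sel$index - c(0, 1, 0)  # chest wall lies at lower y index
  r_sep <- analyze(sel$fid)$ratio
  r_toward <- analyze(grid_fid(grid, toward))$ratio
  expect_gt(r_toward, r_sep)
})
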