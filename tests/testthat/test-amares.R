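# AMARES-style fitting, CRLBs, SNR and ratio corrections.

single_group_template <- function(freq = 100, damping = 40) {
  fit_template(list(slamrecon:::template_group("PCr", freq, damping)))
}

test_that("noiseless single Lorentzian is recovered to 1e-6", {
  t <- default_time_axis()
  truth <- list(a = 1, f = 100, d = 30)
  f <- compartment_fid(list(spectral_component("PCr", truth$f, truth$a, truth$d)), t)
  fit <- fit_amares(f, single_group_template())
  expect_equal(fit$groups["PCr", "amplitude"], truth$a, tolerance = 1e-6)
  expect_equal(fit$groups["PCr", "freq"], truth$f, tolerance = 1e-6 * truth$f)
  expect_equal(fit$groups["PCr", "damping"], truth$d, tolerance = 1e-6 * truth$d)
})

test_that("noiseless PCr + gamma-ATP doublet recovers the 2.0 amplitude ratio", {
  t <- default_time_axis()
  f <- compartment_fid(list(
    spectral_component("PCr", 0, 2, 31.4),
    spectral_component("gATP", -128, 1, 47, multiplet = cbind(c(-8.5, 8.5), c(0.5, 0.5)))), t)
  tpl <- fit_template(list(
    slamrecon:::template_group("PCr", 0, 40),
    slamrecon:::template_group("gATP", -128, 40, multiplet = cbind(c(-8.5, 8.5), c(0.5, 0.5)))))
  fit <- fit_amares(f, tpl)
  expect_equal(fit$pcr_atp_ratio, 2.0, tolerance = 1e-6)
})

test_that("template peaks outside the bandwidth are rejected", {
  t <- default_time_axis()
  f <- compartment_fid(list(spectral_component("PCr", 0, 1, 30)), t)
  expect_error(fit_amares(f, single_group_template(freq = 3000)),
               class = "slamrecon_param_error")
})

test_that("noiseless fits are identifiable from perturbed initializations", {
  w <- world_constant()
  f <- apodize(recon_slam(w$kspace, w$mask)$fids[["heart"]], 20)
  tpl <- default_fit_template()
  ref <- fit_amares(f, tpl)
  set.seed(31)
  for (i in 1:10) {
    init <- list(freqs = vapply(tpl$groups, `[[`, 0, "freq") + runif(5, -10, 10),
                 damps = vapply(tpl$groups, `[[`, 0, "damping") * runif(5, 0.7, 1.4),
                 phi = runif(1, -0.3, 0.3))
    fit <- fit_amares(f, tpl, init = init)
    expect_equal(fit$groups$amplitude, ref$groups$amplitude,
                 tolerance = 1e-4)
    expect_equal(fit$groups$freq, ref$groups$freq, tolerance = 1e-4 * 128)
  }
})

test_that("crlb_ratio implements the delta-method formula", {
  # hand-computed example: a1 = 2, a2 = 1, s1 = 0.1, s2 = 0.05, cov = 0
  fake <- structure(list(
    groups = data.frame(name = c("PCr", "gATP"), amplitude = c(2, 1),
                        row.names = c("PCr", "gATP")),
    covariance = matrix(c(0.01, 0, 0, 0.0025), 2, 2,
                        dimnames = list(c("a_PCr", "a_gATP"), c("a_PCr", "a_gATP")))),
    class = "amares_fit")
  expect_equal(crlb_ratio(fake), 100 * 2 * sqrt(0.0025 + 0.0025) / 2,
               tolerance = 1e-12)
  # zero variances -> 0%
  fake0 <- fake
  fake0$covariance[] <- 0
  expect_equal(crlb_ratio(fake0), 0)
  # doubling both SDs doubles CRLB% (covariance scales by 4)
  fake2 <- fake
  fake2$covariance <- 4 * fake$covariance
  expect_equal(crlb_ratio(fake2), 2 * crlb_ratio(fake))
  # zero denominator -> error
  fake$groups["gATP", "amplitude"] <- 0
  expect_error(crlb_ratio(fake), class = "slamrecon_ratio_error")
})

test_that("reported CRLB scales linearly with the noise level (R^2 > 0.99)", {
  t <- default_time_axis()
  f0 <- compartment_fid(list(
    spectral_component("PCr", 0, 2, 31.4),
    spectral_component("gATP", -128, 1, 47, multiplet = cbind(c(-8.5, 8.5), c(0.5, 0.5)))), t)
  tpl <- fit_template(list(
    slamrecon:::template_group("PCr", 0, 40),
    slamrecon:::template_group("gATP", -128, 40, multiplet = cbind(c(-8.5, 8.5), c(0.5, 0.5)))))
  sigmas <- c(0.005, 0.01, 0.02)
  crlbs <- vapply(seq_along(sigmas), function(i) {
    set.seed(100 + i)
    y <- f0$signal + sigmas[i] * complex(real = rnorm(length(t)),
                                         imaginary = rnorm(length(t)))
    fit_amares(fid(y, f0$dwell_s), tpl)$ratio_crlb_pct
  }, numeric(1))
  r2 <- summary(lm(crlbs ~ sigmas))$r.squared
  expect_gt(r2, 0.99)
})

test_that("snr_pcr: scale invariance, Monte-Carlo consistency, sentinel", {
  t <- default_time_axis()
  f <- compartment_fid(list(spectral_component("PCr", 0, 2, 31.4)), t)
  tpl <- single_group_template(0, 40)
  fit <- fit_amares(f, tpl)
  # noiseless input -> Inf sentinel
  expect_identical(snr_pcr(f, fit), Inf)
  sigma_t <- 0.02
  set.seed(5)
  noisy <- fid(f$signal + sigma_t * complex(real = rnorm(512), imaginary = rnorm(512)),
               f$dwell_s)
  fitn <- fit_amares(noisy, tpl)
  s1 <- snr_pcr(noisy, fitn)
  # scaling the FID by 3 leaves SNR unchanged
  fit3 <- fit_amares(fid(3 * noisy$signal, noisy$dwell_s), tpl)
  expect_equal(snr_pcr(fid(3 * noisy$signal, noisy$dwell_s), fit3), s1,
               tolerance = 1e-6)
  # Monte Carlo: mean SNR ~ peak height / sigma_f within 10% over 200 draws
  peak <- max(Mod(stats::fft(f$signal)))
  sigma_f <- sigma_t * sqrt(512)
  set.seed(6)
  snrs <- vapply(1:200, function(i) {
    y <- fid(f$signal + sigma_t * complex(real = rnorm(512), imaginary = rnorm(512)),
             f$dwell_s)
    snr_pcr(y, fit)
  }, numeric(1))
  expect_equal(mean(snrs), peak / sigma_f, tolerance = 0.1)
  # spectra without 104 out-of-band points are a configuration error
  short <- fid(f$signal[1:128], f$dwell_s)
  expect_error(snr_pcr(short, fit), class = "slamrecon_config_error")
})

test_that("correct_ratio implements blood and saturation corrections", {
  w <- world_constant()
  fit <- fit_amares(apodize(suppressWarnings(phase_correct(
    recon_slam(w$kspace, w$mask)$fids[["heart"]]))$fid, 20), default_fit_template())
  # kappa = 0 and TR >> T1 -> corrected equals raw
  r_raw <- fit$pcr_atp_ratio
  r0 <- correct_ratio(fit, t1_table = c(PCr = 1e-6, gATP = 1e-6),
                      blood_kappa = 0, tr_s = 10)
  expect_lt(abs(as.numeric(r0) - r_raw), 1e-9)
  # equal T1s leave the ratio unchanged by the saturation step
  r_eq <- correct_ratio(fit, t1_table = c(PCr = 3, gATP = 3), blood_kappa = 0,
                        tr_s = 0.9)
  expect_equal(as.numeric(r_eq), r_raw, tolerance = 1e-12)
  # known blood contamination (fraction 0.2) inverted with the matching kappa
  r_corr <- correct_ratio(fit, blood_kappa = 0.30, tr_s = 0.9,
                          saturation_correction = FALSE)
  expect_equal(as.numeric(r_corr), 2.0, tolerance = 0.02 * 2.0)
  # unequal T1s change the ratio by the analytic factor
  t1 <- c(PCr = 5.8, gATP = 3.1)
  alpha <- 30 * pi / 180
  fac <- function(T1) { E <- exp(-0.9 / T1); (1 - E) / (1 - E * cos(alpha)) }
  r_sat <- correct_ratio(fit, t1_table = t1, blood_kappa = 0, tr_s = 0.9)
  expect_equal(as.numeric(r_sat), r_raw * fac(t1[["gATP"]]) / fac(t1[["PCr"]]),
               tolerance = 1e-9)
  # impossible blood correction -> error
  expect_error(correct_ratio(fit, blood_kappa = 100, tr_s = 0.9),
               class = "slamrecon_correction_error")
  expect_error(correct_ratio(fit, t1_table = c(PCr = 5.8), tr_s = 0.9),
               class = "slamrecon_param_error")
})
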