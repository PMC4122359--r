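# Forward model: interaction constants, spectral densities, relaxation rates.

test_that("field spec derives consistent angular frequencies", {
  fs <- field_spec(800)
  expect_equal(fs$omega_H, 2 * pi * 800e6)
  # signed 15N/1H gyromagnetic ratio
  expect_equal(fs$omega_N / fs$omega_H, -0.101397, tolerance = 1e-4)
  expect_lt(fs$gamma_ratio, 0)
  expect_error(field_spec(-600), "positive")
})

test_that("dipolar and CSA constants match independent evaluation", {
  fs <- field_spec(800)
  cst <- dipolar_csa_constants(fs, r_NH = 1.02, delta_sigma = -160)
  orc <- oracle_rates(S2 = 1, tau_m_ns = 8, mhz = 800)
  expect_equal(cst$d2, orc$d2, tolerance = 1e-6)
  expect_equal(cst$c2, orc$c2, tolerance = 1e-6)

  # zero CSA
  expect_identical(dipolar_csa_constants(fs, delta_sigma = 0)$c2, 0)

  # c2 scales with the square of the field; d2 is field-independent
  cst2 <- dipolar_csa_constants(field_spec(1600), r_NH = 1.02,
                                delta_sigma = -160)
  expect_equal(cst2$c2 / cst$c2, 4, tolerance = 1e-12)
  expect_equal(cst2$d2, cst$d2)

  expect_error(dipolar_csa_constants(fs, r_NH = -1), "positive")
})

test_that("isotropic spectral density matches its limits and the quadrature oracle", {
  fs <- field_spec(800)
  # rigid limit: J(0) = (2/5) tau_m exactly
  expect_equal(spectral_density_iso(0, spin_params(1, "M1", S2 = 1), 8),
               0.4 * 8e-9, tolerance = 1e-14)
  # tau_e = 0 removes the internal term
  p <- spin_params(1, "M3", S2 = 0.7)
  w <- abs(fs$omega_N)
  tm <- 8e-9
  expect_equal(spectral_density_iso(w, p, 8),
               0.4 * 0.7 * tm / (1 + (w * tm)^2), tolerance = 1e-12)
  # quadrature oracle, two-timescale form
  p2 <- spin_params(1, "M2", S2 = 0.85, tau_e = 50)
  expect_equal(spectral_density_iso(w, p2, 8),
               oracle_jw(w, 0.85, 1, 50e-12, taus = 8e-9),
               tolerance = 1e-6)
  expect_error(spectral_density_iso(w, p2, -1), "tau_m")
})

test_that("J(omega) decreases monotonically in omega", {
  ws <- seq(0, 6e9, length.out = 40)
  for (s2 in c(0.3, 0.9)) {
    p <- spin_params(1, "M2", S2 = s2, tau_e = 120)
    J <- spectral_density_iso(ws, p, 8)
    expect_true(all(diff(J) < 0))
  }
})

test_that("axial spectral density: amplitudes normalize, limits hold, oracle agrees", {
  # A1 + A2 + A3 = 1 for arbitrary angles
  ct <- cos(seq(0, pi, length.out = 25))
  A <- relaxfit:::.axial_amplitudes(ct)
  expect_equal(rowSums(A), rep(1, 25), tolerance = 1e-14)

  fs <- field_spec(800)
  p <- spin_params(1, "M2", S2 = 0.9, tau_e = 30)
  iso <- diffusion_model("isotropic", tau_m = 8)
  ax1 <- diffusion_model("axial", tau_m = 8, ratio = 1)

  # ratio = 1 equals the isotropic form for random vectors and frequencies
  set.seed(42)
  for (i in 1:10) {
    v <- rnorm(3); v <- v / sqrt(sum(v^2))
    w <- runif(1, 0, 6e9)
    expect_equal(spectral_density_axial(w, p, ax1, v),
                 spectral_density_iso(w, p, 8), tolerance = 1e-12)
  }

  # axis-parallel vector: single lobe with 1/tau_1 = 6 Dperp
  ax <- diffusion_model("axial", tau_m = 8, ratio = 1.2)
  v <- c(0, 0, 1)
  t1 <- 1 / (6 * ax$D_perp)
  te <- 30e-12; tp <- t1 * te / (t1 + te)
  w <- abs(fs$omega_N)
  expect_equal(spectral_density_axial(w, p, ax, v),
               0.4 * (0.9 * t1 / (1 + (w * t1)^2) +
                      0.1 * tp / (1 + (w * tp)^2)),
               tolerance = 1e-12)

  # three-exponential quadrature oracle at omega = 0, oblique vector
  th <- pi / 3
  vob <- c(sin(th), 0, cos(th))
  lob <- oracle_axial_lobes(8, 1.2, cos(th))
  expect_equal(spectral_density_axial(0, p, ax, vob),
               oracle_jw(0, 0.9, 1, 30e-12, taus = lob$taus, A = lob$A),
               tolerance = 1e-6)
})

test_that("forward rates match independent formula evaluation", {
  fs <- field_spec(800)
  cst <- dipolar_csa_constants(fs, 1.02, -160)
  iso <- diffusion_model("isotropic", tau_m = 7.89)
  p <- spin_params(1, "M1", S2 = 0.88)
  r <- forward_rates(p, iso, NULL, cst)
  orc <- oracle_rates(S2 = 0.88, tau_m_ns = 7.89)
  expect_equal(r$R1, orc$R1, tolerance = 1e-6)
  expect_equal(r$R2, orc$R2, tolerance = 1e-6)
  expect_equal(r$NOE, orc$NOE, tolerance = 1e-6)
})

test_that("Rex enters R2 only, additively", {
  cst <- dipolar_csa_constants(field_spec(800))
  iso <- diffusion_model("isotropic", tau_m = 8)
  r0 <- forward_rates(spin_params(1, "M1", S2 = 0.9), iso, NULL, cst)
  r5 <- forward_rates(spin_params(1, "M3", S2 = 0.9, Rex = 5), iso, NULL, cst)
  expect_equal(r5$R2 - r0$R2, 5, tolerance = 1e-12)
  expect_equal(r5$R1, r0$R1)
  expect_equal(r5$NOE, r0$NOE)
})

test_that("R2/R1 grows monotonically with tau_m in the slow-tumbling regime", {
  cst <- dipolar_csa_constants(field_spec(800))
  p <- spin_params(1, "M1", S2 = 1)
  ratios <- vapply(seq(2, 15, length.out = 20), function(tm) {
    r <- forward_rates(p, diffusion_model("isotropic", tau_m = tm), NULL, cst)
    r$R2 / r$R1
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("NOE goes well below 1 for mobile residues and parameters validate", {
  cst <- dipolar_csa_constants(field_spec(800))
  iso <- diffusion_model("isotropic", tau_m = 8)
  rigid <- forward_rates(spin_params(1, "M1", S2 = 0.95), iso, NULL, cst)
  mobile <- forward_rates(spin_params(1, "M5", S2 = 0.2, Sf2 = 0.6,
                                      tau_e = 1800), iso, NULL, cst)
  expect_lt(mobile$NOE, rigid$NOE)
  expect_lt(mobile$NOE, 1)
  expect_error(spin_params(1, "M1", S2 = 1.4), "S2")
  expect_error(spin_params(1, "M5", S2 = 0.9, Sf2 = 0.5), "Sf2")
  # unused parameters forced to their fixed values
  expect_identical(spin_params(1, "M2", S2 = 0.8, tau_e = 50, Rex = 3)$Rex, 0)
  expect_identical(spin_params(1, "M3", S2 = 0.8, Rex = 3)$Sf2, 1)
})
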