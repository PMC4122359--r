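# Diffusion tensor estimation: rigid-subset selection, isotropic and axial
# fits, and isotropic-vs-axial model selection.

fs <- field_spec(800)
cst <- dipolar_csa_constants(fs)

test_that("rigid-subset selection removes flexible tails and exchange sites", {
  n <- 150
  tens <- diffusion_model("isotropic", tau_m = 8)
  nh <- random_unit_vectors(n, seed = 2)
  classes <- rep("core", n)
  classes[1:20] <- "tail"
  classes[c(60, 61, 62, 90, 91)] <- "rex"
  recs <- lapply(seq_len(n), function(i) {
    p <- switch(classes[i],
      core = spin_params(i, "M1", S2 = 0.88),
      tail = spin_params(i, "M2", S2 = 0.25, tau_e = 150),
      rex = spin_params(i, "M3", S2 = 0.88, Rex = 8))
    forward_rates(p, tens, NULL, cst)
  })
  R1 <- vapply(recs, `[[`, numeric(1), "R1")
  R2 <- vapply(recs, `[[`, numeric(1), "R2")
  NOE <- vapply(recs, `[[`, numeric(1), "NOE")
  rt <- relax_table(seq_len(n), R1, .02 * R1, R2, .02 * R2, NOE,
                    rep(.02, n), fs)
  expect_lt(max(NOE[classes == "tail"]), 0.5)
  sub <- select_rigid_subset(rt)
  expect_setequal(attr(sub, "excluded"),
                  which(classes != "core"))
  expect_equal(nrow(sub), 125)

  # homogeneous rigid set: nothing excluded
  rt2 <- relax_table(1:20, rep(R1[30], 20), rep(.02, 20), rep(R2[30], 20),
                     rep(.2, 20), rep(NOE[30], 20), rep(.02, 20), fs)
  expect_equal(nrow(select_rigid_subset(rt2)), 20)

  # degenerate threshold
  expect_error(select_rigid_subset(rt, noe_min = Inf), "insufficient")
})

test_that("isotropic tau_m is recovered exactly from clean data", {
  n <- 30
  tens <- diffusion_model("isotropic", tau_m = 8)
  nh <- random_unit_vectors(n, seed = 3)
  rt <- make_rigid_records(n, tens, cst, nh, noise = 0, seed = 1)
  fit <- fit_isotropic_tm(rt, cst, n_mc = 0)
  expect_equal(fit$tau_m, 8, tolerance = 1e-6 / 8)
})

test_that("isotropic tau_m is recovered within 2% at 2% noise", {
  n <- 120
  tens <- diffusion_model("isotropic", tau_m = 8)
  nh <- random_unit_vectors(n, seed = 4)
  rt <- make_rigid_records(n, tens, cst, nh, noise = 0.02, seed = 10)
  fit <- fit_isotropic_tm(rt, cst, n_mc = 50, seed = 2)
  expect_lt(abs(fit$tau_m / 8 - 1), 0.02)
  expect_gt(fit$tau_m_err, 0)
})

test_that("the tau_m objective is unimodal over the physical range", {
  n <- 40
  tens <- diffusion_model("isotropic", tau_m = 9)
  nh <- random_unit_vectors(n, seed = 5)
  rt <- make_rigid_records(n, tens, cst, nh, noise = 0, seed = 1)
  obs <- relaxfit:::.ratio_obs(rt)
  grid <- seq(2, 20, length.out = 120)
  chi <- vapply(grid, function(tm) {
    rc <- relaxfit:::.ratio_calc(diffusion_model("isotropic", tau_m = tm),
                                 0, cst)[1]
    sum(((obs$rho - rc) / obs$rho_err)^2)
  }, numeric(1))
  # single sign change in the finite-difference sequence
  expect_equal(sum(diff(sign(diff(chi))) != 0), 1)
  expect_equal(grid[which.min(chi)], 9, tolerance = 0.1)
})

test_that("axial tensor parameters are recovered from clean data", {
  n <- 80
  truth <- diffusion_model("axial", tau_m = 7.89, ratio = 1.19,
                           axis_theta = 0.6, axis_phi = 2.1)
  nh <- random_unit_vectors(n, seed = 6)
  rt <- make_rigid_records(n, truth, cst, nh, noise = 0, seed = 1)
  fit <- fit_axial_tensor(rt, nh, cst, n_starts = 12)
  expect_equal(fit$tensor$tau_m, 7.89, tolerance = 1e-3)
  expect_equal(fit$tensor$ratio, 1.19, tolerance = 1e-3)
  expect_equal(fit$tensor$axis_theta, 0.6, tolerance = 1e-2)
  expect_equal(fit$tensor$axis_phi, 2.1, tolerance = 1e-2)
  expect_false(fit$degenerate_axes)
})

test_that("axis orientation is canonicalized to the upper hemisphere", {
  a <- diffusion_model("axial", tau_m = 8, ratio = 1.2,
                       axis_theta = pi - 0.4, axis_phi = 0.5)
  b <- diffusion_model("axial", tau_m = 8, ratio = 1.2,
                       axis_theta = 0.4, axis_phi = 0.5 + pi)
  expect_equal(a$axis_theta, b$axis_theta, tolerance = 1e-12)
  expect_equal(a$axis_phi, b$axis_phi, tolerance = 1e-12)
  expect_lte(a$axis_theta, pi / 2)
})

test_that("near-collinear NH vectors trigger the degeneracy warning", {
  n <- 20
  v <- cbind(rep(0.01, n), rep(0.01, n), rep(1, n))
  nh <- nh_vectors(1:20, v)
  truth <- diffusion_model("axial", tau_m = 8, ratio = 1.15,
                           axis_theta = 0.3, axis_phi = 1)
  rt <- make_rigid_records(n, truth, cst, nh, noise = 0, seed = 1)
  expect_warning(fit_axial_tensor(rt, nh, cst, n_starts = 4), "collinear")
})

test_that("noiseless isotropic data give F near zero; selection is nested-consistent", {
  n <- 60
  tens <- diffusion_model("isotropic", tau_m = 8)
  nh <- random_unit_vectors(n, seed = 8)
  rt <- make_rigid_records(n, tens, cst, nh, noise = 0, seed = 1)
  iso <- fit_isotropic_tm(rt, cst, n_mc = 0)
  axi <- fit_axial_tensor(rt, nh, cst, n_starts = 6)
  # axial nests the isotropic solution: chi2 can only go down, and for
  # clean data both are ~0
  expect_lte(axi$chi2, iso$chi2 * (1 + 1e-8) + 1e-4)
  sel <- tensor_model_selection(iso, axi, n)
  expect_equal(sel$kind, "isotropic")

  # fixing ratio = 1 reproduces the isotropic tau_m through the same chi2
  expect_equal(axi$tensor$tau_m, iso$tau_m, tolerance = 0.02)
})

test_that("strong anisotropy is detected at 2% noise", {
  n <- 100
  truth <- diffusion_model("axial", tau_m = 8, ratio = 1.2,
                           axis_theta = 0.7, axis_phi = 1.2)
  nh <- random_unit_vectors(n, seed = 9)
  rt <- make_rigid_records(n, truth, cst, nh, noise = 0.02, seed = 31)
  iso <- fit_isotropic_tm(rt, cst, n_mc = 0)
  axi <- fit_axial_tensor(rt, nh, cst, n_starts = 8)
  sel <- tensor_model_selection(iso, axi, n)
  expect_equal(sel$kind, "axial")
  expect_lt(abs(sel$tensor$ratio - 1.2), 0.05)
})
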