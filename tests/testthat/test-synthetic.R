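# Synthetic-data generator: determinism, statistical structure, and
# pass-through of the forward model.

test_that("generators are pure functions of (scenario, seed)", {
  scn <- scenario(n_residues = 60, seed = 7)
  t1 <- make_template(scn)
  t2 <- make_template(scn)
  expect_identical(t1, t2)
  d1 <- assign_dynamics(t1, scn)
  d2 <- assign_dynamics(t2, scn)
  expect_identical(d1, d2)
  s1 <- simulate_relaxation(d1, t1, scn)
  s2 <- simulate_relaxation(d2, t2, scn)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$decays_r1, s2$decays_r1)

  # a different seed changes the draws
  t3 <- make_template(scenario(n_residues = 60, seed = 8))
  expect_false(identical(t1$nh, t3$nh))
})

test_that("NH vectors are unit length and roughly uniform on the sphere", {
  scn <- scenario(n_residues = 400, seed = 11)
  tpl <- make_template(scn)
  norms <- sqrt(tpl$nh$x^2 + tpl$nh$y^2 + tpl$nh$z^2)
  expect_equal(norms, rep(1, 400), tolerance = 1e-12)
  for (comp in c("x", "y", "z"))
    expect_lt(abs(mean(tpl$nh[[comp]])), 3 / sqrt(400))
})

test_that("template can pass vectors through from a structure", {
  p <- tempfile(fileext = ".pdb")
  write_synthetic_structure(p, n_residues = 10)
  s <- read_structure(p)
  scn <- scenario(n_residues = 10, segments = data.frame(
    start = 1, end = 2, class = "terminus"), seed = 1)
  tpl <- make_template(scn, structure = s)
  direct <- extract_nh_vectors(s)
  expect_equal(tpl$nh$x, direct$x)
  expect_equal(tpl$nh$z, direct$z)
})

test_that("class-conditional truth draws respect the class definitions", {
  seg <- data.frame(start = integer(0), end = integer(0),
                    class = character(0))
  scn <- scenario(n_residues = 500, segments = seg, seed = 3)  # all core
  tpl <- make_template(scn)
  truth <- assign_dynamics(tpl, scn)
  expect_true(all(vapply(truth, `[[`, character(1), "model_id") == "M1"))
  expect_true(all(vapply(truth, `[[`, numeric(1), "Rex") == 0))
  S2 <- vapply(truth, `[[`, numeric(1), "S2")
  expect_lt(abs(mean(S2) - 0.88), 0.01)
  expect_true(all(S2 >= 0.7 & S2 <= 1))

  # mixed scenario: every class draws within its stated ranges
  scn2 <- scenario(n_residues = 150, seed = 5)
  tpl2 <- make_template(scn2)
  truth2 <- assign_dynamics(tpl2, scn2)
  df <- data.frame(class = tpl2$classes,
                   model = vapply(truth2, `[[`, character(1), "model_id"),
                   S2 = vapply(truth2, `[[`, numeric(1), "S2"),
                   Rex = vapply(truth2, `[[`, numeric(1), "Rex"),
                   tau_e = vapply(truth2, `[[`, numeric(1), "tau_e"))
  expect_true(all(df$model[df$class == "loop"] == "M2"))
  expect_true(all(df$model[df$class == "terminus"] == "M5"))
  expect_true(all(df$model[df$class == "rex_patch"] %in% c("M3", "M4")))
  expect_true(all(df$Rex[df$class == "rex_patch"] >= 2 &
                  df$Rex[df$class == "rex_patch"] <= 15))
  expect_true(all(df$S2[df$class == "terminus"] <= 0.7))
  expect_true(all(df$tau_e[df$class == "terminus"] >= 500))
})

test_that("zero-noise simulation passes forward rates through exactly", {
  scn <- scenario(n_residues = 20, rate_noise = 0, noe_noise = 0, seed = 2)
  tpl <- make_template(scn)
  truth <- assign_dynamics(tpl, scn)
  sim <- simulate_relaxation(truth, tpl, scn)
  expect_equal(sim$records$R1, sim$clean$R1, tolerance = 1e-14)
  expect_equal(sim$records$R2, sim$clean$R2, tolerance = 1e-14)
  expect_equal(sim$records$NOE, sim$clean$NOE, tolerance = 1e-14)
})

test_that("simulated rate noise has the nominal magnitude", {
  devs <- vapply(1:400, function(s) {
    scn <- scenario(n_residues = 2,
                    segments = data.frame(start = 1, end = 2,
                                          class = "core"),
                    seed = 1000 + s)
    tpl <- make_template(scn)
    truth <- assign_dynamics(tpl, scn)
    sim <- simulate_relaxation(truth, tpl, scn)
    sim$records$R1[1] / sim$clean$R1[1] - 1
  }, numeric(1))
  expect_lt(abs(sd(devs) / 0.02 - 1), 0.15)
})

test_that("decay series use the duplicated delay grid and honest noise", {
  scn <- scenario(n_residues = 3, seed = 4)
  tpl <- make_template(scn)
  truth <- assign_dynamics(tpl, scn)
  sim <- simulate_relaxation(truth, tpl, scn)
  d <- sim$decays_r1[sim$decays_r1$residue_id == 1, ]
  expect_equal(length(unique(d$delay_ms)), 12)   # 12 distinct delays
  expect_equal(sum(d$delay_ms == 10), 3)          # triplicated first point
  expect_equal(max(d$delay_ms), 4000)
  # rates refit from the decays agree with the clean rates
  f <- fit_rate_table(sim$decays_r1, n_mc = 0)
  expect_equal(f$rate, sim$clean$R1, tolerance = 0.1)
})

test_that("CSP simulation respects forced and calibrated missingness", {
  scn <- scenario(n_residues = 170, seed = 6)
  tpl <- make_template(scn)

  # forced: every rex-patch residue absent from the apo list
  ef <- default_csp_effects()
  ef$rex_patch$miss_prob <- 1
  sim <- simulate_csp(tpl, ef, seed = 9)
  patch <- which(tpl$classes == "rex_patch")
  expect_true(all(!sim$apo$present[patch]))

  # zero effects: all composite shifts zero, everything small
  ef0 <- lapply(default_csp_effects(), function(e) {
    e$dH_sd <- 0; e$dN_sd <- 0; e$miss_prob <- 0; e
  })
  sim0 <- simulate_csp(tpl, ef0, seed = 9)
  expect_true(all(sim0$truth$delta_comp == 0))
  expect_true(all(sim0$truth$category == "small"))

  # uniform 30% missingness is recovered within 3 points at n = 170
  ef30 <- lapply(default_csp_effects(), function(e) {
    e$miss_prob <- 0.3; e
  })
  frac <- mean(vapply(1:20, function(s) {
    sum(!simulate_csp(tpl, ef30, seed = s)$apo$present) / 170
  }, numeric(1)))
  expect_lt(abs(frac - 0.3), 0.03)
})
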