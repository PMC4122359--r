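# Independent oracles: numerical quadrature for spectral densities, a
# from-scratch evaluation of the relaxation-rate expressions, and a
# brute-force superposition search. Deliberately re-derived here, sharing no
# code with the package internals they check.

# J(omega) by cosine-transform quadrature of the correlation function
# C(t) = (1/5) sum_k A_k [S2 exp(-t/tau_k) + (Sf2 - S2) exp(-t/tau'_k)],
# J = 2 * integral C(t) cos(omega t) dt. Times in seconds. Integration in
# units of the longest correlation time, piecewise to tame oscillation.
oracle_jw <- function(omega, S2, Sf2 = 1, tau_e = 0, taus, A = rep(1, length(taus))) {
  tmax <- max(taus)
  f <- function(x) {
    t <- x * tmax
    ct <- 0
    for (k in seq_along(taus)) {
      tp <- if (tau_e > 0) taus[k] * tau_e / (taus[k] + tau_e) else 0
      ct <- ct + A[k] * (S2 * exp(-t / taus[k]) +
                         if (tp > 0) (Sf2 - S2) * exp(-t / tp) else 0)
    }
    0.2 * ct * cos(omega * t)
  }
  total <- 0
  for (a in seq(0, 59)) {
    total <- total + stats::integrate(f, a, a + 1, subdivisions = 400L,
                                      rel.tol = 1e-10,
                                      abs.tol = 1e-13)$value
  }
  2 * total * tmax
}

# correlation times and amplitudes of the axially symmetric tensor,
# re-derived from (tau_m, ratio, cos_theta)
oracle_axial_lobes <- function(tau_m_ns, ratio, cos_theta) {
  Diso <- 1 / (6 * tau_m_ns * 1e-9)
  Dperp <- 3 * Diso / (2 + ratio)
  Dpar <- ratio * Dperp
  taus <- 1 / c(6 * Dperp, 5 * Dperp + Dpar, 2 * Dperp + 4 * Dpar)
  c2 <- cos_theta^2
  A <- c((3 * c2 - 1)^2 / 4, 3 * (1 - c2) * c2, 0.75 * (1 - c2)^2)
  list(taus = taus, A = A)
}

# Independent spreadsheet-style evaluation of R1/R2/NOE from CODATA
# constants; isotropic tumbling. All numbers re-typed, none imported.
oracle_rates <- function(S2, Sf2 = 1, tau_e_ps = 0, Rex = 0, tau_m_ns,
                         mhz = 800, r_nh = 1.02, dsig = -160) {
  gH <- 2.6752218744e8
  gN <- -2.7126189e7
  h <- 6.62607015e-34
  mu0 <- 4 * pi * 1e-7
  wH <- 2 * pi * mhz * 1e6
  wN <- wH * gN / gH                       # negative
  d2 <- (mu0 * h * gH * abs(gN) / (8 * pi^2 * (r_nh * 1e-10)^3))^2
  c2 <- (wN * dsig * 1e-6)^2 / 3
  tm <- tau_m_ns * 1e-9
  te <- tau_e_ps * 1e-12
  J <- function(w) {
    tp <- if (te > 0) tm * te / (tm + te) else 0
    0.4 * (S2 * tm / (1 + (w * tm)^2) +
           if (tp > 0) (Sf2 - S2) * tp / (1 + (w * tp)^2) else 0)
  }
  # signed combination frequencies, evaluated at their magnitudes
  JmN <- J(abs(wH - wN))  # = wH + |wN|
  JpN <- J(abs(wH + wN))  # = wH - |wN|
  JN <- J(abs(wN))
  JH <- J(wH)
  J0 <- J(0)
  R1 <- d2 / 4 * (JmN + 3 * JN + 6 * JpN) + c2 * JN
  R2 <- d2 / 8 * (4 * J0 + JmN + 3 * JN + 6 * JH + 6 * JpN) +
    c2 / 6 * (4 * J0 + 3 * JN) + Rex
  NOE <- 1 + d2 / (4 * R1) * (gH / gN) * (6 * JpN - JmN)
  list(R1 = R1, R2 = R2, NOE = NOE, d2 = d2, c2 = c2)
}

# Brute-force optimal-superposition RMSD: coarse Euler-angle grid followed
# by Nelder-Mead refinement of (angles, translation).
oracle_superpose_rmsd <- function(P, Q) {
  rotmat <- function(a, b, c) {
    Rz1 <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3, TRUE)
    Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3, TRUE)
    Rz2 <- matrix(c(cos(c), -sin(c), 0, sin(c), cos(c), 0, 0, 0, 1), 3, 3, TRUE)
    Rz1 %*% Ry %*% Rz2
  }
  obj <- function(p) {
    R <- rotmat(p[1], p[2], p[3])
    Pr <- P %*% t(R)
    Pr <- sweep(Pr, 2, p[4:6], "+")
    sqrt(mean(rowSums((Pr - Q)^2)))
  }
  t0 <- colMeans(Q) - colMeans(P)
  best <- NULL
  grid <- seq(0, 2 * pi, length.out = 7)[-7]
  for (a in grid) for (b in seq(0, pi, length.out = 4)) for (c in grid) {
    v <- obj(c(a, b, c, t0))
    if (is.null(best) || v < best$value) best <- list(par = c(a, b, c, t0), value = v)
  }
  for (i in 1:3) {
    fit <- stats::optim(best$par, obj, method = "Nelder-Mead",
                        control = list(maxit = 4000, reltol = 1e-15))
    if (fit$value < best$value) best <- fit
  }
  best$value
}

# forward-modeled noisy relaxation table for n rigid-limit residues under a
# given tensor; used by the diffusion-stage tests
make_rigid_records <- function(n, tensor, constants, nh, noise = 0.02,
                               seed = 1, S2 = 1) {
  ax <- c(sin(tensor$axis_theta) * cos(tensor$axis_phi),
          sin(tensor$axis_theta) * sin(tensor$axis_phi),
          cos(tensor$axis_theta))
  ct <- nh$x * ax[1] + nh$y * ax[2] + nh$z * ax[3]
  r <- relaxfit:::.forward_rates_vec(rep(S2, n), rep(1, n), rep(0, n),
                                     rep(0, n), ct, tensor, constants)
  set.seed(seed)
  R1 <- r$R1 * (1 + rnorm(n, 0, noise))
  R2 <- r$R2 * (1 + rnorm(n, 0, noise))
  NOE <- r$NOE + rnorm(n, 0, 0.02)
  ef <- max(noise, 0.002)
  relax_table(seq_len(n), R1, ef * r$R1, R2, ef * r$R2, NOE,
              rep(max(0.02, ef), n), constants$field)
}

random_unit_vectors <- function(n, seed) {
  set.seed(seed)
  z <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  r <- sqrt(1 - z^2)
  nh_vectors(seq_len(n), cbind(r * cos(phi), r * sin(phi), z))
}

# one-residue relaxation record from known truth plus seeded noise
make_record <- function(id, params, tensor, nh_vec, constants,
                        rate_noise = 0.02, noe_noise = 0.02, seed = 1) {
  r <- forward_rates(params, tensor, nh_vec, constants)
  set.seed(seed)
  list(residue_id = id,
       R1 = r$R1 * (1 + rnorm(1, 0, rate_noise)),
       R1_err = max(rate_noise * r$R1, 1e-9),
       R2 = r$R2 * (1 + rnorm(1, 0, rate_noise)),
       R2_err = max(rate_noise * r$R2, 1e-9),
       NOE = r$NOE + if (noe_noise > 0) rnorm(1, 0, noe_noise) else 0,
       NOE_err = max(noe_noise, 1e-9))
}
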