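## Seeded synthetic-data generator. Emulates the study conditions of a
## monomeric ~150-180 residue flavodoxin-like protein at 800 MHz: overall
## tumbling near 8 ns with mild axial anisotropy, a rigid core
## (S2 ~ 0.85-0.95), flexible termini and loops, and micro-to-millisecond
## exchange confined to binding-loop patches. Every generator is a pure
## function of (scenario, seed).

#' Default residue segmentation
#'
#' Flexible termini, two loops, and one exchange patch placed at fixed
#' fractional positions along the chain; everything else is core.
#'
#' @param n_residues Chain length.
#' @return data.frame with `start`, `end`, `class`.
#' @export
default_segments <- function(n_residues) {
  n <- n_residues
  tl <- max(2L, min(8L, round(0.05 * n)))
  cand <- rbind(
    data.frame(start = 1L, end = tl, class = "terminus"),
    data.frame(start = round(0.20 * n), end = round(0.26 * n), class = "loop"),
    data.frame(start = round(0.36 * n), end = round(0.40 * n), class = "rex_patch"),
    data.frame(start = round(0.56 * n), end = round(0.62 * n), class = "loop"),
    data.frame(start = n - tl + 1L, end = n, class = "terminus"))
  ## short chains: push colliding segments apart, drop what cannot fit
  keep <- logical(nrow(cand))
  prev_end <- 0L
  for (i in seq_len(nrow(cand))) {
    s <- max(cand$start[i], prev_end + 1L)
    e <- min(cand$end[i], n)
    if (s <= e) {
      cand$start[i] <- s
      cand$end[i] <- e
      prev_end <- e
      keep[i] <- TRUE
    }
  }
  cand[keep, , drop = FALSE]
}

#' Synthetic study scenario
#'
#' Bundles everything the generators need: chain length, residue classes,
#' the global diffusion tensor, the field, and the noise model (fractional
#' Gaussian noise on R1/R2, absolute on NOE).
#'
#' @param n_residues Number of residues (default 150).
#' @param segments data.frame(start, end, class) with class in
#'   `{core, loop, terminus, rex_patch}`; unlisted residues are core.
#'   Segments must not overlap.
#' @param tensor A [diffusion_model()]; default axially symmetric with
#'   tau_m = 8 ns and D_par/D_perp = 1.15.
#' @param field A [field_spec()]; default 800 MHz.
#' @param rate_noise Fractional noise on R1 and R2 (default 0.02).
#' @param noe_noise Absolute noise on NOE (default 0.02).
#' @param seed Root seed for all draws (default 1).
#' @return Object of class `scenario`.
#' @export
scenario <- function(n_residues = 150, segments = default_segments(n_residues),
                     tensor = diffusion_model("axial", tau_m = 8, ratio = 1.15,
                                              axis_theta = 0.7, axis_phi = 1.2),
                     field = field_spec(800),
                     rate_noise = 0.02, noe_noise = 0.02, seed = 1) {
  if (rate_noise < 0 || noe_noise < 0) stop("noise must be >= 0")
  classes <- rep("core", n_residues)
  covered <- rep(FALSE, n_residues)
  for (i in seq_len(nrow(segments))) {
    idx <- segments$start[i]:segments$end[i]
    if (any(idx < 1 | idx > n_residues)) stop("segment outside 1..n_residues")
    if (any(covered[idx])) stop("overlapping segments")
    covered[idx] <- TRUE
    classes[idx] <- segments$class[i]
  }
  if (!all(classes %in% c("core", "loop", "terminus", "rex_patch")))
    stop("unknown segment class")
  structure(
    list(n_residues = as.integer(n_residues), classes = classes,
         tensor = tensor, field = field, rate_noise = rate_noise,
         noe_noise = noe_noise, seed = as.integer(seed)),
    class = "scenario")
}

#' Generate the structural template
#'
#' N-H vectors drawn approximately uniformly on the sphere (seeded), or
#' extracted from a supplied structure, with per-residue class labels
#' attached.
#'
#' @param scn A [scenario()].
#' @param structure Optional `structure3d`; its [extract_nh_vectors()]
#'   output replaces the random vectors (chain length must match).
#' @return List with `nh` ([nh_vectors()]) and `classes`.
#' @export
make_template <- function(scn, structure = NULL) {
  stopifnot(inherits(scn, "scenario"))
  if (!is.null(structure)) {
    nh <- extract_nh_vectors(structure)
  } else {
    nh <- .with_seed(scn$seed, {
      z <- stats::runif(scn$n_residues, -1, 1)
      phi <- stats::runif(scn$n_residues, 0, 2 * pi)
      r <- sqrt(1 - z^2)
      nh_vectors(seq_len(scn$n_residues),
                 cbind(r * cos(phi), r * sin(phi), z))
    })
  }
  list(nh = nh, classes = scn$classes)
}

#' Draw ground-truth internal dynamics
#'
#' Class-conditional draws: core residues are M1 with S2 ~ N(0.88, 0.03^2)
#' clipped to \[0.7, 1\]; loops are M2 with S2 ~ N(0.80, 0.05^2) and
#' tau_e ~ U(20, 200) ps; termini are M5 with S2 ~ U(0.3, 0.7),
#' Sf2 ~ U(0.75, 0.9) and tau_e ~ U(0.5, 2) ns; exchange patches are M3 or
#' M4 (even odds) with Rex ~ U(2, 15) s^-1, core-like S2 and, for M4,
#' tau_e ~ U(20, 100) ps. All draws are seeded.
#'
#' @param template Output of [make_template()].
#' @param scn The [scenario()].
#' @return List of [spin_params()], one per residue, in residue order.
#' @export
assign_dynamics <- function(template, scn) {
  stopifnot(inherits(scn, "scenario"))
  .with_seed(scn$seed + 1L, {
    lapply(seq_len(scn$n_residues), function(i) {
      cl <- template$classes[i]
      switch(cl,
        core = spin_params(i, "M1",
                           S2 = min(1, max(0.7, stats::rnorm(1, 0.88, 0.03)))),
        loop = spin_params(i, "M2",
                           S2 = min(0.95, max(0.5, stats::rnorm(1, 0.80, 0.05))),
                           tau_e = stats::runif(1, 20, 200)),
        terminus = {
          S2 <- stats::runif(1, 0.3, 0.7)
          spin_params(i, "M5", S2 = S2, Sf2 = stats::runif(1, 0.75, 0.9),
                      tau_e = stats::runif(1, 500, 2000))
        },
        rex_patch = {
          m <- sample(c("M3", "M4"), 1)
          spin_params(i, m,
                      S2 = min(1, max(0.7, stats::rnorm(1, 0.88, 0.03))),
                      tau_e = if (m == "M4") stats::runif(1, 20, 100) else 0,
                      Rex = stats::runif(1, 2, 15))
        })
    })
  })
}

#' Simulate relaxation data from ground truth
#'
#' Noise-free rates come from [forward_rates()] under the scenario tensor;
#' Gaussian noise is applied per the scenario. Decay series are synthesized
#' on the standard 800-MHz delay grids (the 12-point R1 list with its
#' triplicated first delay, and the matching R2 list) with intensity noise
#' equal to `rate_noise` of the initial amplitude, and NOE
#' saturated/reference intensity pairs are emitted alongside.
#'
#' @param truth List of [spin_params()] from [assign_dynamics()].
#' @param template Output of [make_template()].
#' @param scn The [scenario()].
#' @param delay_r1,delay_r2 Delay grids in ms (defaults: the YqcA grids).
#' @return List with `records` (noisy [relax_table()], nominal errors
#'   attached), `clean` (noise-free rates), `decays_r1`, `decays_r2` (long
#'   data.frames: residue_id, delay_ms, intensity, noise_sigma),
#'   `noe_pairs` (I_sat, I_ref and noise), and `truth` (data.frame of the
#'   generating parameters, a first-class output).
#' @export
simulate_relaxation <- function(truth, template, scn,
                                delay_r1 = delay_grid("r1_yqca"),
                                delay_r2 = delay_grid("r2_yqca")) {
  stopifnot(inherits(scn, "scenario"))
  n <- scn$n_residues
  constants <- dipolar_csa_constants(scn$field)
  S2 <- vapply(truth, `[[`, numeric(1), "S2")
  Sf2 <- vapply(truth, `[[`, numeric(1), "Sf2")
  te <- vapply(truth, `[[`, numeric(1), "tau_e")
  Rex <- vapply(truth, `[[`, numeric(1), "Rex")
  ax <- .axis_vector(scn$tensor)
  ct <- template$nh$x * ax[1] + template$nh$y * ax[2] + template$nh$z * ax[3]
  clean <- .forward_rates_vec(S2, Sf2, te, Rex, ct, scn$tensor, constants)

  out <- .with_seed(scn$seed + 2L, {
    R1 <- clean$R1 * (1 + stats::rnorm(n, 0, scn$rate_noise))
    R2 <- clean$R2 * (1 + stats::rnorm(n, 0, scn$rate_noise))
    NOE <- clean$NOE + stats::rnorm(n, 0, scn$noe_noise)
    I0 <- 1e6
    mk_decay <- function(rates, delays) {
      sig <- scn$rate_noise * I0
      do.call(rbind, lapply(seq_len(n), function(i) {
        I <- I0 * exp(-rates[i] * delays / 1000)
        if (sig > 0) I <- I + stats::rnorm(length(delays), 0, sig)
        data.frame(residue_id = i, delay_ms = delays, intensity = I,
                   noise_sigma = sig)
      }))
    }
    d1 <- mk_decay(clean$R1, delay_r1)
    d2 <- mk_decay(clean$R2, delay_r2)
    sig_pk <- scn$noe_noise * I0 / sqrt(2)
    noe_pairs <- data.frame(
      residue_id = seq_len(n),
      I_ref = I0 + stats::rnorm(n, 0, sig_pk),
      I_sat = clean$NOE * I0 + stats::rnorm(n, 0, sig_pk),
      sigma = sig_pk)
    list(R1 = R1, R2 = R2, NOE = NOE, d1 = d1, d2 = d2, noe_pairs = noe_pairs)
  })

  err_floor <- 1e-6
  records <- relax_table(
    seq_len(n),
    R1 = out$R1, R1_err = pmax(scn$rate_noise * clean$R1, err_floor),
    R2 = out$R2, R2_err = pmax(scn$rate_noise * clean$R2, err_floor),
    NOE = out$NOE, NOE_err = pmax(scn$noe_noise, err_floor),
    field = scn$field)
  truth_df <- data.frame(
    residue_id = seq_len(n), class = template$classes,
    model_id = vapply(truth, `[[`, character(1), "model_id"),
    S2 = S2, Sf2 = Sf2, tau_e = te, Rex = Rex)
  list(records = records, clean = clean, decays_r1 = out$d1,
       decays_r2 = out$d2, noe_pairs = out$noe_pairs, truth = truth_df)
}

#' Default chemical-shift-perturbation effect specification
#'
#' Per-class apo-resonance missing probabilities and shift-change scales
#' (ppm), tuned so missingness concentrates at the exchange patch and
#' binding loops and totals roughly 30 percent of the chain.
#'
#' @return Named list of per-class lists with `miss_prob`, `dH_sd`, `dN_sd`.
#' @export
default_csp_effects <- function() {
  list(core = list(miss_prob = 0.18, dH_sd = 0.02, dN_sd = 0.10),
       loop = list(miss_prob = 0.70, dH_sd = 0.25, dN_sd = 1.20),
       rex_patch = list(miss_prob = 0.90, dH_sd = 0.30, dN_sd = 1.50),
       terminus = list(miss_prob = 0.30, dH_sd = 0.05, dN_sd = 0.25))
}

#' Simulate apo/holo peak lists with perturbations and missingness
#'
#' The holo list is complete, with amide shifts drawn uniformly over the
#' usual 1H/15N ranges. The apo list applies class-dependent Gaussian shift
#' changes and drops residues with the class's missing probability. Truth
#' categories (including `missing_in_apo`) are emitted alongside so
#' downstream classification can be scored.
#'
#' @param template Output of [make_template()].
#' @param effect_spec As [default_csp_effects()].
#' @param seed Seed for all draws.
#' @return List with `apo`, `holo` ([peak_list()]s) and `truth`
#'   (data.frame: residue_id, delta_comp, category).
#' @export
simulate_csp <- function(template, effect_spec = default_csp_effects(),
                         seed = 1) {
  n <- length(template$classes)
  .with_seed(seed, {
    dH_holo <- stats::runif(n, 7, 10)
    dN_holo <- stats::runif(n, 105, 130)
    miss <- dH <- dN <- numeric(n)
    for (i in seq_len(n)) {
      ef <- effect_spec[[template$classes[i]]]
      dH[i] <- stats::rnorm(1, 0, ef$dH_sd)
      dN[i] <- stats::rnorm(1, 0, ef$dN_sd)
      miss[i] <- stats::rbinom(1, 1, ef$miss_prob)
    }
    holo <- peak_list(seq_len(n), dH_holo, dN_holo)
    apo <- peak_list(seq_len(n),
                     ifelse(miss == 1, NA_real_, dH_holo - dH),
                     ifelse(miss == 1, NA_real_, dN_holo - dN))
    dcomp <- composite_shift(dH, dN)
    truth <- data.frame(
      residue_id = seq_len(n), delta_comp = dcomp,
      category = ifelse(miss == 1, "missing_in_apo", classify_csp(dcomp)))
    list(apo = apo, holo = holo, truth = truth)
  })
}

#' Write a synthetic test structure
#'
#' Builds a small synthetic polyalanine chain on a helical curve with N, H,
#' CA, C and O atoms and writes it as a (multi-model) PDB file. Purely a
#' geometric stand-in for exercising coordinate code: bond geometry is
#' idealized, N-H directions vary along the chain, and successive models are
#' Gaussian-perturbed copies of the first.
#'
#' @param path Output path.
#' @param n_residues Chain length (default 12).
#' @param n_models Number of models (default 1).
#' @param perturb Coordinate noise SD (Angstrom) for models beyond the first.
#' @param seed Seed for the perturbations.
#' @return `path`, invisibly.
#' @export
write_synthetic_structure <- function(path, n_residues = 12, n_models = 1,
                                      perturb = 0.3, seed = 1) {
  coords <- .helix_coords(n_residues)
  .with_seed(seed, {
    con <- file(path, "w")
    on.exit(close(con))
    for (m in seq_len(n_models)) {
      xyz <- coords$xyz
      if (m > 1 && perturb > 0)
        xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, perturb),
                            ncol = 3)
      if (n_models > 1) writeLines(sprintf("MODEL     %4d", m), con)
      for (i in seq_len(nrow(xyz))) {
        writeLines(sprintf(
          "ATOM  %5d  %-3s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %s",
          i, coords$name[i], "ALA", coords$resno[i],
          xyz[i, 1], xyz[i, 2], xyz[i, 3], 1.00, 0.00,
          substr(coords$name[i], 1, 1)), con)
      }
      if (n_models > 1) writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  })
  invisible(path)
}

## idealized backbone on a helical curve; N-H directions vary along chain
.helix_coords <- function(n) {
  name <- character(0); resno <- integer(0); xyz <- NULL
  for (i in seq_len(n)) {
    t <- i * 100 * pi / 180
    N <- c(2.3 * cos(t), 2.3 * sin(t), 1.5 * i)
    CA <- N + c(0.9 * cos(t + 0.8), 0.9 * sin(t + 0.8), 0.9)
    C <- CA + c(0.8 * cos(t + 1.8), 0.8 * sin(t + 1.8), 0.9)
    O <- C + c(0.6 * cos(t + 2.6), 0.6 * sin(t + 2.6), -0.7)
    u <- c(cos(0.5 * i), sin(0.5 * i), 0.6)
    H <- N + 1.02 * u / sqrt(sum(u^2))
    name <- c(name, "N", "H", "CA", "C", "O")
    resno <- c(resno, rep(i, 5L))
    xyz <- rbind(xyz, N, H, CA, C, O)
  }
  list(name = name, resno = resno, xyz = unname(xyz))
}
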