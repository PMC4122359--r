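## Gyromagnetic ratios (rad s^-1 T^-1), CODATA values.
.GAMMA_H <- 2.6752218744e8
.GAMMA_N <- -2.7126189e7
## Planck constant (J s) and vacuum permeability (T m A^-1).
.PLANCK_H <- 6.62607015e-34
.MU0 <- 4 * pi * 1e-7

#' Spectrometer field specification
#'
#' Describes the static field through the proton resonance frequency and
#' derives the angular frequencies of 1H and 15N. The 15N frequency carries
#' the sign of its (negative) gyromagnetic ratio, so `omega_N < 0`;
#' magnitudes are taken where spectral densities are evaluated.
#'
#' @param proton_frequency_MHz 1H resonance frequency in MHz (e.g. 800).
#' @return An object of class `field_spec` with components
#'   `proton_frequency_MHz`, `omega_H`, `omega_N` (rad/s, signed) and
#'   `gamma_ratio` (gamma_H / gamma_N, signed, about -9.87).
#' @examples
#' fs <- field_spec(800)
#' fs$omega_N / fs$omega_H   # about -0.1014
#' @export
field_spec <- function(proton_frequency_MHz) {
  if (!is.numeric(proton_frequency_MHz) || length(proton_frequency_MHz) != 1L ||
      !is.finite(proton_frequency_MHz) || proton_frequency_MHz <= 0) {
    stop("'proton_frequency_MHz' must be a single positive number")
  }
  omega_H <- 2 * pi * proton_frequency_MHz * 1e6
  omega_N <- omega_H * (.GAMMA_N / .GAMMA_H)
  structure(
    list(
      proton_frequency_MHz = proton_frequency_MHz,
      omega_H = omega_H,
      omega_N = omega_N,
      gamma_ratio = .GAMMA_H / .GAMMA_N
    ),
    class = "field_spec"
  )
}

#' Dipolar and CSA interaction constants
#'
#' Computes the squared dipolar coupling constant
#' d2 = \[mu0 h gammaH gammaN / (8 pi^2 rNH^3)\]^2 and the squared CSA
#' constant c2 = (omegaN * delta_sigma)^2 / 3, both in s^-2. `d2` uses the
#' magnitude of gammaH * gammaN; the sign of gammaN enters only through the
#' NOE expression (see [forward_rates()]).
#'
#' @param field A [field_spec()].
#' @param r_NH N-H bond length in Angstrom. Default 1.02, the community
#'   standard for backbone amides.
#' @param delta_sigma 15N chemical shift anisotropy in ppm. Default -160.
#' @return Object of class `phys_constants` with `d2`, `c2` (s^-2), and the
#'   inputs echoed for provenance.
#' @export
dipolar_csa_constants <- function(field, r_NH = 1.02, delta_sigma = -160) {
  stopifnot(inherits(field, "field_spec"))
  if (!is.numeric(r_NH) || length(r_NH) != 1L || !is.finite(r_NH) || r_NH <= 0)
    stop("'r_NH' must be a single positive length in Angstrom")
  r_m <- r_NH * 1e-10
  d <- .MU0 * .PLANCK_H * .GAMMA_H * abs(.GAMMA_N) / (8 * pi^2 * r_m^3)
  c2 <- (field$omega_N * delta_sigma * 1e-6)^2 / 3
  structure(
    list(d2 = d^2, c2 = c2, r_NH = r_NH, delta_sigma = delta_sigma,
         field = field),
    class = "phys_constants"
  )
}

#' Per-residue internal motion parameters
#'
#' Container for Lipari-Szabo internal-motion parameters under the standard
#' five-model ladder: M1 (S2), M2 (S2, tau_e), M3 (S2, Rex),
#' M4 (S2, tau_e, Rex), M5 (Sf2, S2, tau_e). Parameters a model does not use
#' are held at exactly zero (Rex) or one (Sf2 for M1-M4).
#'
#' @param residue_id Integer residue number.
#' @param model_id One of `"M1"`..`"M5"`.
#' @param S2 Generalized order parameter in \[0, 1\].
#' @param Sf2 Fast-motion order parameter in \[S2, 1\]; forced to 1 for M1-M4.
#' @param tau_e Effective internal correlation time in ps (>= 0).
#' @param Rex Exchange contribution to R2 in s^-1 (>= 0); forced to 0 for
#'   models that do not carry it.
#' @return Object of class `spin_params`.
#' @export
spin_params <- function(residue_id, model_id = "M1", S2 = 1, Sf2 = 1,
                        tau_e = 0, Rex = 0) {
  model_id <- match.arg(model_id, c("M1", "M2", "M3", "M4", "M5"))
  if (S2 < 0 || S2 > 1) stop("S2 must lie in [0, 1]")
  if (Sf2 < 0 || Sf2 > 1) stop("Sf2 must lie in [0, 1]")
  if (tau_e < 0) stop("tau_e must be >= 0")
  if (Rex < 0) stop("Rex must be >= 0")
  if (model_id %in% c("M1", "M2", "M3", "M4")) Sf2 <- 1
  if (model_id %in% c("M1", "M2", "M5")) Rex <- 0
  if (model_id %in% c("M1", "M3")) tau_e <- 0
  if (model_id == "M5" && Sf2 < S2) stop("Sf2 must be >= S2 for model M5")
  structure(
    list(residue_id = as.integer(residue_id), model_id = model_id,
         S2 = S2, Sf2 = Sf2, tau_e = tau_e, Rex = Rex),
    class = "spin_params"
  )
}

#' Global rotational diffusion model
#'
#' Isotropic or axially symmetric rotational diffusion, parametrized by the
#' overall correlation time tau_m = 1/(6 D_iso) and the anisotropy
#' D_par/D_perp, with the unique-axis orientation given in spherical polar
#' angles in the molecular frame. An axial tensor is directionless, so the
#' axis is canonicalized to the upper hemisphere (theta in \[0, pi/2\]).
#'
#' @param kind `"isotropic"` or `"axial"`.
#' @param tau_m Overall correlation time in ns (> 0).
#' @param ratio D_par / D_perp (> 0); must be 1 for isotropic.
#' @param axis_theta,axis_phi Polar/azimuthal angles (rad) of the unique axis.
#' @return Object of class `diffusion_model` with the derived `D_iso`,
#'   `D_par`, `D_perp` (s^-1) attached.
#' @export
diffusion_model <- function(kind = c("isotropic", "axial"), tau_m,
                            ratio = 1, axis_theta = 0, axis_phi = 0) {
  kind <- match.arg(kind)
  if (!is.finite(tau_m) || tau_m <= 0) stop("tau_m must be > 0 (ns)")
  if (!is.finite(ratio) || ratio <= 0) stop("ratio must be > 0")
  if (kind == "isotropic") {
    ratio <- 1
    axis_theta <- 0
    axis_phi <- 0
  }
  ax <- .canonical_axis(axis_theta, axis_phi)
  D_iso <- 1 / (6 * tau_m * 1e-9)
  D_perp <- 3 * D_iso / (2 + ratio)
  D_par <- ratio * D_perp
  structure(
    list(kind = kind, tau_m = tau_m, ratio = ratio,
         axis_theta = ax[1], axis_phi = ax[2],
         D_iso = D_iso, D_par = D_par, D_perp = D_perp),
    class = "diffusion_model"
  )
}

## Map an axis direction to theta in [0, pi/2] (antipode identification).
.canonical_axis <- function(theta, phi) {
  v <- c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  if (v[3] < 0) v <- -v
  th <- acos(pmin(1, pmax(-1, v[3])))
  ph <- atan2(v[2], v[1])
  if (ph < 0) ph <- ph + 2 * pi
  if (th < 1e-12) ph <- 0
  c(th, ph)
}

#' Unit N-H bond vectors
#'
#' @param residue_id Integer vector of residue numbers.
#' @param v Numeric matrix (n x 3) of N->H direction vectors; normalized to
#'   unit length on construction (a zero vector is an error).
#' @return Object of class `nh_vectors`: a data.frame with columns
#'   `residue_id`, `x`, `y`, `z`.
#' @export
nh_vectors <- function(residue_id, v) {
  v <- matrix(as.numeric(v), ncol = 3)
  if (length(residue_id) != nrow(v)) stop("residue_id / v length mismatch")
  nrm <- sqrt(rowSums(v^2))
  if (any(!is.finite(nrm)) || any(nrm < 1e-12)) stop("NH vectors must be nonzero")
  v <- v / nrm
  out <- data.frame(residue_id = as.integer(residue_id),
                    x = v[, 1], y = v[, 2], z = v[, 3])
  class(out) <- c("nh_vectors", "data.frame")
  out
}
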