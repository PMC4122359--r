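## Rotational diffusion tensor estimation from R2/R1 ratios of rigid
## residues: rigid-subset selection, isotropic and axially symmetric fits,
## and model selection between the two.
##
## The axial fit is two-phase: a coarse hemisphere grid of candidate axes
## scored at fixed (tau_m, ratio), then Nelder-Mead refinement of
## (tau_m, ratio, theta, phi) from the best axes. Model selection uses an
## F statistic whose null distribution is calibrated by parametric
## bootstrap, because the axis orientation is unidentifiable under the
## isotropic null and the analytic F(3, n-4) reference is anticonservative
## there.

#' Select the rigid, exchange-free residue subset
#'
#' Removes residues dominated by fast internal motion or chemical exchange
#' before tensor fitting: first excludes residues with NOE below `noe_min`,
#' then iteratively excludes residues whose R2/R1 deviates from the median
#' by more than `trim_k` times the median absolute deviation (MAD) until
#' stable. R2/R1 of rigid residues is insensitive to S2, so what survives
#' reports on global tumbling only.
#'
#' @param records A [relax_table()] with at least 10 rows.
#' @param noe_min NOE cutoff (default 0.65).
#' @param trim_k MAD multiplier for the iterative trim (default 3).
#' @return The subset `relax_table` (attribute `excluded` lists dropped
#'   residue ids). Fewer than 6 survivors is an error.
#' @export
select_rigid_subset <- function(records, noe_min = 0.65, trim_k = 3.0) {
  stopifnot(inherits(records, "relax_table"))
  if (nrow(records) < 10L) stop("need at least 10 records")
  keep <- records$NOE >= noe_min
  sub <- records[keep, , drop = FALSE]
  repeat {
    if (nrow(sub) < 6L) stop("insufficient data: rigid subset smaller than 6")
    ratio <- sub$R2 / sub$R1
    med <- stats::median(ratio)
    scale <- stats::mad(ratio)
    ## a degenerate MAD (over half the ratios identical) falls back to the
    ## sample SD so isolated exchange outliers are still caught
    if (!is.finite(scale) || scale == 0) scale <- stats::sd(ratio)
    if (!is.finite(scale) || scale == 0) break
    ok <- abs(ratio - med) <= trim_k * scale
    if (all(ok)) break
    sub <- sub[ok, , drop = FALSE]
  }
  if (nrow(sub) < 6L) stop("insufficient data: rigid subset smaller than 6")
  out <- sub
  attr(out, "field") <- attr(records, "field")
  attr(out, "excluded") <- setdiff(records$residue_id, sub$residue_id)
  class(out) <- c("relax_table", "data.frame")
  out
}

## R2/R1 and its error for a subset table.
.ratio_obs <- function(records) {
  rho <- records$R2 / records$R1
  rho_err <- rho * sqrt((records$R1_err / records$R1)^2 +
                        (records$R2_err / records$R2)^2)
  rho_err[rho_err <= 0] <- stats::median(rho_err[rho_err > 0])
  list(rho = rho, rho_err = rho_err)
}

## Predicted R2/R1 for rigid residues (S2 = 1, tau_e = 0, Rex = 0).
.ratio_calc <- function(tensor, cos_theta, constants) {
  n <- length(cos_theta)
  r <- .forward_rates_vec(rep(1, n), rep(1, n), rep(0, n), rep(0, n),
                          cos_theta, tensor, constants)
  r$R2 / r$R1
}

## Fast rigid-limit R2/R1: the single-timescale spectral density reduces to
## one (n x 3) %*% (3 x 5) product over the lobe and frequency grids. The
## hot path of the tensor fits and their bootstrap calibration.
.rigid_ratio_fast <- function(cos_theta, tau_m, ratio, constants) {
  field <- constants$field
  wH <- abs(field$omega_H)
  wN <- abs(field$omega_N)
  freqs <- c(0, wN, wH + wN, wH, wH - wN)
  D_iso <- 1 / (6 * tau_m * 1e-9)
  D_perp <- 3 * D_iso / (2 + ratio)
  D_par <- ratio * D_perp
  taus <- 1 / c(6 * D_perp, 5 * D_perp + D_par, 2 * D_perp + 4 * D_par)
  L <- 0.4 * outer(taus, freqs, function(tk, w) tk / (1 + (w * tk)^2))
  c2t <- cos_theta^2
  s2t <- 1 - c2t
  A <- cbind((3 * c2t - 1)^2 / 4, 3 * s2t * c2t, 0.75 * s2t^2)
  J <- A %*% L
  d2 <- constants$d2
  c2 <- constants$c2
  R1 <- d2 / 4 * (J[, 3] + 3 * J[, 2] + 6 * J[, 5]) + c2 * J[, 2]
  R2 <- d2 / 8 * (4 * J[, 1] + J[, 3] + 3 * J[, 2] + 6 * J[, 4] +
                  6 * J[, 5]) + c2 / 6 * (4 * J[, 1] + 3 * J[, 2])
  R2 / R1
}

## isotropic chi2 minimization on (rho, rho_err) directly
.fit_iso_rho <- function(rho, rho_err, constants, tau_range = c(1, 25)) {
  obj <- function(tm) {
    sum(((rho - .rigid_ratio_fast(0, tm, 1, constants)[1]) / rho_err)^2)
  }
  opt <- stats::optimize(obj, tau_range, tol = 1e-8)
  list(tau_m = opt$minimum, chi2 = opt$objective)
}

## roughly even axis candidates on the upper hemisphere (Fibonacci spiral)
.axis_grid <- function(n) {
  i <- seq_len(n) - 0.5
  z <- i / n                      # cos(theta) in (0, 1): upper hemisphere
  phi <- (pi * (3 - sqrt(5))) * (seq_len(n) - 1)
  cbind(theta = acos(z), phi = phi %% (2 * pi))
}

## axial chi2 minimization on (rho, rho_err, unit vectors); two-phase.
.fit_axial_rho <- function(rho, rho_err, vx, vy, vz, constants,
                           n_axes = 36, refine = 3, maxit = 800,
                           reltol = 1e-11, polish = TRUE) {
  chi2_fun <- function(p) {
    tm <- p[1]; ratio <- p[2]
    if (tm <= 0.3 || tm > 40 || ratio <= 0.3 || ratio > 3) return(1e12)
    st <- sin(p[3])
    u <- c(st * cos(p[4]), st * sin(p[4]), cos(p[3]))
    ct <- vx * u[1] + vy * u[2] + vz * u[3]
    sum(((rho - .rigid_ratio_fast(ct, tm, ratio, constants)) / rho_err)^2)
  }
  iso <- .fit_iso_rho(rho, rho_err, constants)
  axes <- .axis_grid(n_axes)
  scores <- vapply(seq_len(n_axes), function(i) {
    min(chi2_fun(c(iso$tau_m, 0.9, axes[i, 1], axes[i, 2])),
        chi2_fun(c(iso$tau_m, 1.15, axes[i, 1], axes[i, 2])))
  }, numeric(1))
  best <- NULL
  for (i in order(scores)[seq_len(min(refine, n_axes))]) {
    for (r0 in c(0.9, 1.15)) {
      fit <- stats::optim(c(iso$tau_m, r0, axes[i, 1], axes[i, 2]),
                          chi2_fun, method = "Nelder-Mead",
                          control = list(maxit = maxit, reltol = reltol))
      if (is.null(best) || fit$value < best$value) best <- fit
    }
  }
  if (polish) {
    fit <- stats::optim(best$par, chi2_fun, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = reltol))
    if (fit$value < best$value) best <- fit
  }
  list(par = best$par, chi2 = best$value, iso = iso)
}

#' Fit the isotropic rotational correlation time
#'
#' Minimizes chi2 = sum \[(R2/R1)_obs - (R2/R1)_calc(tau_m)\]^2 / sigma^2
#' over tau_m, with the calculated ratio from the rigid-limit forward model
#' (S2 = 1, tau_e = 0, Rex = 0). Uncertainty from Monte-Carlo resampling of
#' the observed ratios within their errors.
#'
#' @param records Rigid-subset [relax_table()].
#' @param constants A [dipolar_csa_constants()].
#' @param tau_range Search interval in ns (default c(1, 25)).
#' @param n_mc Monte-Carlo resamples for the error (default 100; 0 skips).
#' @param seed Seed for the resampling.
#' @return List with `tau_m` (ns), `tau_m_err`, `chi2`, `n`.
#' @export
fit_isotropic_tm <- function(records, constants, tau_range = c(1, 25),
                             n_mc = 100, seed = 1) {
  stopifnot(inherits(records, "relax_table"))
  obs <- .ratio_obs(records)
  fit <- .fit_iso_rho(obs$rho, obs$rho_err, constants, tau_range)
  if (fit$tau_m <= tau_range[1] + 1e-6 || fit$tau_m >= tau_range[2] - 1e-6)
    stop("fit failure: tau_m at search bound; widen tau_range")
  err <- NA_real_
  if (n_mc > 0) {
    sims <- .with_seed(seed, {
      vapply(seq_len(n_mc), function(i) {
        rho_i <- obs$rho + stats::rnorm(length(obs$rho), 0, obs$rho_err)
        .fit_iso_rho(rho_i, obs$rho_err, constants, tau_range)$tau_m
      }, numeric(1))
    })
    err <- stats::sd(sims)
  }
  list(tau_m = fit$tau_m, tau_m_err = err, chi2 = fit$chi2,
       n = nrow(records))
}

#' Fit the axially symmetric diffusion tensor
#'
#' Minimizes the same R2/R1 chi2 as [fit_isotropic_tm()] over
#' (tau_m, D_par/D_perp, axis theta, axis phi), using the axial spectral
#' density and the angle between each N-H vector and the candidate unique
#' axis. A coarse hemisphere grid of starting axes guards against the
#' multimodal axis landscape before local refinement; the fitted axis is
#' reported canonicalized to theta in \[0, pi/2\] (an axial tensor is
#' directionless).
#'
#' @param records Rigid-subset [relax_table()].
#' @param nh An [nh_vectors()] object covering every subset residue.
#' @param constants A [dipolar_csa_constants()].
#' @param n_starts Number of candidate axes scored in the coarse phase
#'   (default 36; the best 3 are refined).
#' @param n_mc Monte-Carlo resamples for parameter errors (default 0).
#' @param seed Seed for the resampling.
#' @return List with `tensor` (a [diffusion_model()]), `chi2`, `n`,
#'   `param_errs` (named vector, NA when `n_mc = 0`), and `degenerate_axes`
#'   (TRUE with a warning when the NH vectors are nearly collinear).
#' @export
fit_axial_tensor <- function(records, nh, constants, n_starts = 36,
                             n_mc = 0, seed = 1) {
  stopifnot(inherits(records, "relax_table"), inherits(nh, "nh_vectors"))
  idx <- match(records$residue_id, nh$residue_id)
  if (anyNA(idx)) stop("NH vectors missing for subset residues: ",
                       paste(records$residue_id[is.na(idx)], collapse = ", "))
  nhv <- nh[idx, , drop = FALSE]
  obs <- .ratio_obs(records)

  ## vector-geometry degeneracy check via the second-moment matrix
  M <- crossprod(as.matrix(nhv[, c("x", "y", "z")])) / nrow(nhv)
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  degenerate <- ev[2] < 0.02
  if (degenerate)
    warning("NH vectors nearly collinear; anisotropy poorly determined")

  fit <- .fit_axial_rho(obs$rho, obs$rho_err, nhv$x, nhv$y, nhv$z,
                        constants, n_axes = n_starts)
  p <- unname(fit$par)
  tensor <- diffusion_model("axial", tau_m = p[1], ratio = p[2],
                            axis_theta = p[3], axis_phi = p[4])
  errs <- c(tau_m = NA_real_, ratio = NA_real_, axis_theta = NA_real_,
            axis_phi = NA_real_)
  if (n_mc > 0) {
    sims <- .with_seed(seed, {
      t(vapply(seq_len(n_mc), function(i) {
        rho_i <- obs$rho + stats::rnorm(length(obs$rho), 0, obs$rho_err)
        .fit_axial_rho(rho_i, obs$rho_err, nhv$x, nhv$y, nhv$z, constants,
                       n_axes = 12, refine = 1, maxit = 400,
                       reltol = 1e-9, polish = FALSE)$par
      }, numeric(4)))
    })
    errs <- c(tau_m = stats::sd(sims[, 1]), ratio = stats::sd(sims[, 2]),
              axis_theta = stats::sd(sims[, 3]),
              axis_phi = stats::sd(sims[, 4]))
  }
  list(tensor = tensor, chi2 = fit$chi2, n = nrow(records),
       param_errs = errs, degenerate_axes = degenerate,
       nh_used = nhv)
}

#' Isotropic vs axially symmetric tensor selection
#'
#' F-test of the axial model (4 parameters) against the nested isotropic
#' model (1 parameter) on identical data:
#' F = \[(chi2_iso - chi2_ax) / 3\] / \[chi2_ax / (n - 4)\].
#' Because the axis orientation exists only under the alternative, the
#' analytic F(3, n-4) null is anticonservative; when the data are supplied
#' the null distribution of F is instead calibrated by parametric bootstrap
#' (ratios simulated from the fitted isotropic model, both models refitted).
#' The axial model is chosen when the bootstrap p-value (or, without
#' calibration data, the analytic p) falls below `alpha`.
#'
#' @param iso_fit Result of [fit_isotropic_tm()].
#' @param axial_fit Result of [fit_axial_tensor()].
#' @param n_data Number of residues both fits used.
#' @param alpha Significance level (default 0.05).
#' @param records,nh,constants The data both fits used; supplying them
#'   enables the bootstrap calibration.
#' @param n_null Bootstrap null samples (default 40; 0 forces the analytic
#'   reference).
#' @param seed Seed for the bootstrap.
#' @return List with `kind`, `tensor` (the chosen [diffusion_model()]),
#'   `F`, `p_value`, and `calibrated` (logical).
#' @export
tensor_model_selection <- function(iso_fit, axial_fit, n_data,
                                   alpha = 0.05, records = NULL, nh = NULL,
                                   constants = NULL, n_null = 40, seed = 1) {
  if (axial_fit$chi2 > iso_fit$chi2 * (1 + 1e-8) + 1e-4)
    stop("axial chi2 exceeds isotropic chi2; optimizer failure - ",
         "re-run fit_axial_tensor with more starts")
  df2 <- n_data - 4
  if (df2 < 1) stop("too few residues for tensor model selection")
  fstat <- function(c_iso, c_ax) ((c_iso - c_ax) / 3) / (c_ax / df2)
  ## chi2 improvements at numerical-noise level count as no improvement
  ## (both fits essentially perfect, e.g. noiseless data)
  Fobs <- if (iso_fit$chi2 - axial_fit$chi2 < 1e-3) 0 else
    max(fstat(iso_fit$chi2, axial_fit$chi2), 0)

  calibrated <- !is.null(records) && !is.null(constants) && n_null > 0
  if (calibrated) {
    nhv <- axial_fit$nh_used
    if (is.null(nhv)) {
      idx <- match(records$residue_id, nh$residue_id)
      nhv <- nh[idx, , drop = FALSE]
    }
    obs <- .ratio_obs(records)
    tens0 <- diffusion_model("isotropic", tau_m = iso_fit$tau_m)
    rho0 <- .ratio_calc(tens0, 0, constants)[1]
    Fnull <- .with_seed(seed, {
      vapply(seq_len(n_null), function(b) {
        rho_b <- rho0 + stats::rnorm(length(obs$rho), 0, obs$rho_err)
        iso_b <- .fit_iso_rho(rho_b, obs$rho_err, constants)
        ax_b <- .fit_axial_rho(rho_b, obs$rho_err, nhv$x, nhv$y, nhv$z,
                               constants, n_axes = 24, refine = 2,
                               maxit = 500, reltol = 1e-9, polish = FALSE)
        max(fstat(iso_b$chi2, min(ax_b$chi2, iso_b$chi2)), 0)
      }, numeric(1))
    })
    p <- (1 + sum(Fnull >= Fobs)) / (1 + n_null)
  } else {
    p <- stats::pf(Fobs, 3, df2, lower.tail = FALSE)
  }
  if (p < alpha) {
    list(kind = "axial", tensor = axial_fit$tensor, F = Fobs, p_value = p,
         calibrated = calibrated)
  } else {
    iso <- diffusion_model("isotropic", tau_m = iso_fit$tau_m)
    list(kind = "isotropic", tensor = iso, F = Fobs, p_value = p,
         calibrated = calibrated)
  }
}
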