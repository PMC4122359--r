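## Conversion of peak-intensity decay series into R1/R2 rates and of
## saturated/reference intensity pairs into heteronuclear NOE values.

#' Standard relaxation delay grids
#'
#' The delay lists (ms) used for the R1 and R2 experiments on the two
#' proteins studied: YqcA (R1: 12 points including a triplicated 10 ms point;
#' R2: 12 points including a duplicated 7.4 ms point) and FldA (R1: 10 points
#' with a duplicated 10 ms point; R2: 10 points with a duplicated 6 ms point).
#' Duplicates are retained as independent points.
#'
#' @param which One of `"r1_yqca"`, `"r2_yqca"`, `"r1_flda"`, `"r2_flda"`.
#' @return Numeric vector of delays in ms.
#' @export
delay_grid <- function(which = c("r1_yqca", "r2_yqca", "r1_flda", "r2_flda")) {
  which <- match.arg(which)
  switch(which,
    r1_yqca = c(10, 10, 10, 100, 300, 450, 600, 800, 1000, 1300, 1600,
                2400, 3200, 4000),
    r2_yqca = c(7.4, 7.4, 14.8, 22.3, 29.7, 37.1, 52.0, 74.2, 89.1, 111.4,
                148.5, 185.6, 222.7),
    r1_flda = c(10, 10, 100, 300, 700, 1200, 1800, 2500, 3200, 3990),
    r2_flda = c(6, 6, 10, 18, 34, 54, 74, 98, 122, 162)
  )
}

#' Peak-intensity decay series
#'
#' @param residue_id Integer residue number.
#' @param delays Relaxation delays in ms (>= 0, duplicates allowed; at least
#'   3 distinct values).
#' @param intensities Peak intensities (arbitrary units), same length.
#' @param noise_sigma Intensity noise (a.u.). If `NA`, it is estimated from
#'   the RMS of replicate-delay intensity differences.
#' @return Object of class `decay_series`.
#' @export
decay_series <- function(residue_id, delays, intensities, noise_sigma = NA) {
  if (length(delays) != length(intensities))
    stop("delays and intensities must have equal length")
  if (any(delays < 0)) stop("delays must be >= 0")
  if (length(unique(delays)) < 3L)
    stop("insufficient data: need at least 3 distinct delays")
  if (is.na(noise_sigma)) {
    dup <- split(intensities, delays)
    dup <- dup[vapply(dup, length, 1L) > 1L]
    if (length(dup) == 0L)
      stop("noise_sigma absent and no replicate delays to estimate it from")
    ss <- sum(vapply(dup, function(x) sum((x - mean(x))^2), numeric(1)))
    df <- sum(vapply(dup, function(x) length(x) - 1L, integer(1)))
    noise_sigma <- sqrt(ss / df)  # pooled replicate variance
  }
  if (!is.finite(noise_sigma) || noise_sigma <= 0)
    stop("noise_sigma must be > 0")
  structure(
    list(residue_id = as.integer(residue_id), delays = as.numeric(delays),
         intensities = as.numeric(intensities), noise_sigma = noise_sigma),
    class = "decay_series"
  )
}

## Profiled least squares for I(t) = I0 exp(-R t): amplitude solved in closed
## form, leaving a 1-D search in R. t in seconds.
.profiled_ssr <- function(R, t, I) {
  e <- exp(-R * t)
  I0 <- sum(I * e) / sum(e * e)
  sum((I - I0 * e)^2)
}

.fit_rate_profiled <- function(t, I, upper = NULL) {
  if (is.null(upper)) upper <- 30 / stats::median(t[t > 0])
  opt <- stats::optimize(.profiled_ssr, c(0, upper), t = t, I = I,
                         tol = 1e-10 * upper)
  opt$minimum
}

#' Fit a single-exponential decay
#'
#' Least-squares fit of I(t) = I0 exp(-R t) to a peak-intensity decay series.
#' The amplitude is profiled out in closed form and the rate found by 1-D
#' minimization, then polished with a Levenberg-Marquardt step. Uncertainty
#' comes from `n_mc` Monte-Carlo refits with Gaussian intensity noise of the
#' series' `noise_sigma`, under the given seed. Duplicate delays are retained
#' as independent points. A fitted rate indistinguishable from zero is
#' reported with `flagged = TRUE`, not as an error.
#'
#' @param series A [decay_series()].
#' @param n_mc Number of Monte-Carlo refits for the uncertainty (default 500;
#'   0 suppresses the error estimate).
#' @param seed Integer seed for the Monte-Carlo perturbations.
#' @return List with `rate` (s^-1), `rate_err` (s^-1, `NA` if `n_mc = 0`),
#'   `I0`, and `flagged` (logical: nonpositive/degenerate rate).
#' @export
fit_exponential <- function(series, n_mc = 500, seed = 1) {
  stopifnot(inherits(series, "decay_series"))
  if (n_mc < 0) stop("n_mc must be >= 0")
  t <- series$delays / 1000  # ms -> s
  I <- series$intensities
  R <- .fit_rate_profiled(t, I)
  e <- exp(-R * t)
  I0 <- sum(I * e) / sum(e * e)
  ## polish with Levenberg-Marquardt for full precision
  fit <- tryCatch(
    minpack.lm::nlsLM(I ~ a * exp(-r * tt),
                      data = list(I = I, tt = t),
                      start = list(a = I0, r = R),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    if (is.finite(cf["r"]) && cf["r"] >= 0) {
      I0 <- unname(cf["a"]); R <- unname(cf["r"])
    }
  }
  rate_err <- NA_real_
  if (n_mc > 0) {
    rng <- .with_seed(seed, {
      matrix(stats::rnorm(n_mc * length(I), 0, series$noise_sigma),
             nrow = n_mc)
    })
    base <- I0 * exp(-R * t)
    rates <- vapply(seq_len(n_mc), function(i) {
      .fit_rate_profiled(t, base + rng[i, ])
    }, numeric(1))
    rate_err <- stats::sd(rates)
  }
  flagged <- R <= .Machine$double.eps^0.25 / max(t)
  list(rate = R, rate_err = rate_err, I0 = I0, flagged = flagged)
}

#' Steady-state heteronuclear NOE from intensity pair
#'
#' NOE = I_sat / I_ref, with uncertainty
#' |NOE| sqrt((sigma_sat/I_sat)^2 + (sigma_ref/I_ref)^2). Negative NOE values
#' (highly mobile residues) pass through unchanged.
#'
#' @param I_sat,I_ref Peak intensities with and without proton presaturation.
#' @param sigma_sat,sigma_ref Intensity noise of the two spectra.
#' @return List with `NOE` and `NOE_err`.
#' @export
compute_noe <- function(I_sat, I_ref, sigma_sat, sigma_ref) {
  if (any(I_ref == 0)) stop("I_ref must be nonzero")
  NOE <- I_sat / I_ref
  NOE_err <- abs(NOE) * sqrt((sigma_sat / I_sat)^2 + (sigma_ref / I_ref)^2)
  list(NOE = NOE, NOE_err = NOE_err)
}

#' Assemble a per-residue relaxation table
#'
#' Combines fitted R1/R2 rates and NOE values into the table consumed by the
#' spectral-density-mapping, diffusion and model-free stages.
#'
#' @param residue_id Integer vector.
#' @param R1,R1_err,R2,R2_err Rates and uncertainties (s^-1).
#' @param NOE,NOE_err Heteronuclear NOE and uncertainty.
#' @param field A [field_spec()].
#' @return A `relax_table`: data.frame with one row per residue and the field
#'   attached as attribute `field`.
#' @export
relax_table <- function(residue_id, R1, R1_err, R2, R2_err, NOE, NOE_err,
                        field) {
  stopifnot(inherits(field, "field_spec"))
  if (any(R1 <= 0) || any(R2 <= 0)) stop("rates must be positive")
  if (any(c(R1_err, R2_err, NOE_err) < 0)) stop("errors must be >= 0")
  out <- data.frame(residue_id = as.integer(residue_id),
                    R1 = R1, R1_err = R1_err, R2 = R2, R2_err = R2_err,
                    NOE = NOE, NOE_err = NOE_err)
  attr(out, "field") <- field
  class(out) <- c("relax_table", "data.frame")
  out
}

#' Fit rates for many residues from a long decay table
#'
#' @param decays data.frame with columns `residue_id`, `delay_ms`,
#'   `intensity` and optionally `noise_sigma` (one value per residue).
#' @param n_mc,seed Passed to [fit_exponential()]; each residue uses a seed
#'   offset by its position for independent Monte-Carlo draws.
#' @return data.frame with `residue_id`, `rate`, `rate_err`, `flagged`.
#' @export
fit_rate_table <- function(decays, n_mc = 500, seed = 1) {
  need <- c("residue_id", "delay_ms", "intensity")
  if (!all(need %in% names(decays))) stop("decays must have columns ",
                                          paste(need, collapse = ", "))
  ids <- sort(unique(decays$residue_id))
  res <- lapply(seq_along(ids), function(i) {
    d <- decays[decays$residue_id == ids[i], ]
    ns <- if ("noise_sigma" %in% names(d)) d$noise_sigma[1] else NA
    s <- decay_series(ids[i], d$delay_ms, d$intensity, ns)
    f <- fit_exponential(s, n_mc = n_mc, seed = seed + i)
    data.frame(residue_id = ids[i], rate = f$rate, rate_err = f$rate_err,
               flagged = f$flagged)
  })
  do.call(rbind, res)
}

## Evaluate expr with a temporary RNG state (restores any prior state).
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
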