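## Per-residue Lipari-Szabo model-free fits (models M1-M5), staged model
## selection against Monte-Carlo critical values, and per-model summaries.
## Two-stage protocol: the diffusion tensor is fixed first, then internal
## parameters are fitted per residue.
##
## Implementation notes:
## - Rex enters R2 linearly and nothing else, so for M3/M4 it is profiled
##   out in closed form (Rex_hat = max(0, R2_obs - R2_calc)), reducing the
##   search dimension by one.
## - Monte-Carlo critical values are computed on dense parameter grids
##   evaluated through a single vectorized forward-model call per grid; the
##   simulated datasets share the grid, so the cost per simulation is a
##   matrix row-minimum.

.MF_MODELS <- c("M1", "M2", "M3", "M4", "M5")

`%||%` <- function(a, b) if (is.null(a)) b else a

## number of free parameters the model reports (Rex counted even though
## profiled)
.mf_npar <- function(model_id) {
  c(M1 = 1L, M2 = 2L, M3 = 2L, M4 = 3L, M5 = 3L)[[model_id]]
}

## search-space parameter names (Rex excluded: profiled)
.mf_search <- function(model_id) {
  switch(model_id,
         M1 = "S2", M2 = c("S2", "tau_e"), M3 = "S2",
         M4 = c("S2", "tau_e"), M5 = c("Sf2", "Ss2", "tau_e"))
}

.mf_has_rex <- function(model_id) model_id %in% c("M3", "M4")

## Forward rates for a set of candidate parameter vectors (matrix columns
## S2, Sf2, tau_e) sharing one residue geometry.
.mf_rates_grid <- function(S2, Sf2, tau_e, cos_theta, tensor, constants) {
  n <- length(S2)
  .forward_rates_vec(S2, Sf2, tau_e, rep(0, n), rep(cos_theta, n),
                     tensor, constants)
}

## chi2 rows = datasets (R1/R2/NOE vectors), cols = grid points; Rex profiled
## when has_rex.
.mf_chi2_grid <- function(rates, R1, R2, NOE, e1, e2, e3, has_rex) {
  n_d <- length(R1)
  t1 <- (outer(R1, rates$R1, "-") / e1)^2
  t3 <- (outer(NOE, rates$NOE, "-") / e3)^2
  d2 <- outer(R2, rates$R2, "-")
  if (has_rex) d2 <- pmin(d2, 0)
  t2 <- (d2 / e2)^2
  t1 + t2 + t3
}

## grid of search parameters per model
.mf_param_grid <- function(model_id, tau_m_ps, fine = FALSE) {
  S2g <- if (fine) seq(0, 1, by = 0.002) else seq(0, 1, by = 0.01)
  teg <- c(0, exp(seq(log(2), log(max(tau_m_ps, 10)),
                      length.out = if (fine) 80 else 40)))
  switch(model_id,
    M1 = data.frame(S2 = S2g, Sf2 = 1, tau_e = 0),
    M3 = data.frame(S2 = S2g, Sf2 = 1, tau_e = 0),
    M2 = {
      g <- expand.grid(S2 = seq(0, 1, by = if (fine) 0.005 else 0.02),
                       tau_e = teg)
      data.frame(S2 = g$S2, Sf2 = 1, tau_e = g$tau_e)
    },
    M4 = {
      g <- expand.grid(S2 = seq(0, 1, by = if (fine) 0.005 else 0.02),
                       tau_e = teg)
      data.frame(S2 = g$S2, Sf2 = 1, tau_e = g$tau_e)
    },
    M5 = {
      g <- expand.grid(Sf2 = seq(0.05, 1, by = 0.05),
                       Ss2 = seq(0.05, 1, by = 0.05),
                       tau_e = teg[teg > 0])
      data.frame(S2 = g$Sf2 * g$Ss2, Sf2 = g$Sf2, tau_e = g$tau_e,
                 Ss2 = g$Ss2)
    })
}

## Full fit of one model to one observed record: grid init + bounded local
## refinement with Rex profiled.
.mf_fit_one <- function(model_id, record, cos_theta, tensor, constants,
                        start = NULL) {
  tau_m_ps <- tensor$tau_m * 1000
  e1 <- record$R1_err; e2 <- record$R2_err; e3 <- record$NOE_err
  has_rex <- .mf_has_rex(model_id)

  chi2_point <- function(S2, Sf2, tau_e) {
    r <- .mf_rates_grid(S2, Sf2, tau_e, cos_theta, tensor, constants)
    d2 <- record$R2 - r$R2
    if (has_rex) d2 <- min(d2, 0)
    ((record$R1 - r$R1) / e1)^2 + (d2 / e2)^2 + ((record$NOE - r$NOE) / e3)^2
  }

  nm <- .mf_search(model_id)
  obj <- function(p) {
    p <- stats::setNames(p, nm)
    if (model_id == "M5") {
      chi2_point(p[["Sf2"]] * p[["Ss2"]], p[["Sf2"]], p[["tau_e"]])
    } else if (length(p) == 1L) {
      chi2_point(p[["S2"]], 1, 0)
    } else {
      chi2_point(p[["S2"]], 1, p[["tau_e"]])
    }
  }

  if (is.null(start)) {
    g <- .mf_param_grid(model_id, tau_m_ps)
    r <- .mf_rates_grid(g$S2, g$Sf2, g$tau_e, cos_theta, tensor, constants)
    chi <- .mf_chi2_grid(r, record$R1, record$R2, record$NOE, e1, e2, e3,
                         has_rex)
    i <- which.min(chi[1, ])
    start <- switch(model_id,
                    M1 = g$S2[i], M3 = g$S2[i],
                    M2 = c(g$S2[i], g$tau_e[i]),
                    M4 = c(g$S2[i], g$tau_e[i]),
                    M5 = c(g$Sf2[i], g$Ss2[i], g$tau_e[i]))
  }
  lo <- c(S2 = 0, Sf2 = 1e-4, Ss2 = 0, tau_e = 0)[nm]
  hi <- c(S2 = 1, Sf2 = 1, Ss2 = 1, tau_e = tau_m_ps)[nm]
  start <- pmin(pmax(as.numeric(start), lo), hi)

  if (length(nm) == 1L) {
    opt <- stats::optimize(function(x) obj(x), c(0, 1), tol = 1e-10)
    if (obj(start) < opt$objective) opt <- list(minimum = start,
                                                objective = obj(start))
    par <- opt$minimum
    val <- opt$objective
  } else {
    fit <- tryCatch(
      stats::optim(start, obj, method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(maxit = 500, factr = 1e3)),
      error = function(e) list(par = start, value = obj(start)))
    pol <- stats::optim(fit$par, function(p) {
      if (any(p < lo - 1e-12) || any(p > hi + 1e-12)) return(1e12)
      obj(p)
    }, method = "Nelder-Mead",
    control = list(maxit = 600, reltol = 1e-14))
    if (pol$value < fit$value) fit <- pol
    par <- pmin(pmax(fit$par, lo), hi)
    val <- obj(par)
  }
  par <- stats::setNames(par, nm)

  ## recover profiled Rex
  Rex <- 0
  if (has_rex) {
    S2v <- par[["S2"]]
    tev <- if ("tau_e" %in% nm) par[["tau_e"]] else 0
    r <- .mf_rates_grid(S2v, 1, tev, cos_theta, tensor, constants)
    Rex <- max(0, record$R2 - r$R2)
  }
  list(par = par, value = val, Rex = Rex)
}

.mf_result <- function(model_id, record, fit, errs) {
  p <- as.list(fit$par)
  S2 <- p$S2 %||% (p$Sf2 * p$Ss2)
  sp <- spin_params(record$residue_id, model_id, S2 = S2,
                    Sf2 = p$Sf2 %||% 1, tau_e = p$tau_e %||% 0,
                    Rex = fit$Rex %||% 0)
  at_bound <- any(abs(unlist(p)[names(p) %in% c("S2", "Sf2", "Ss2")] - 1)
                  < 1e-6)
  structure(
    list(residue_id = as.integer(record$residue_id), model_id = model_id,
         params = sp, param_errs = errs, chi2 = fit$value,
         dof = 3L - .mf_npar(model_id), at_bound = at_bound),
    class = "mf_fit")
}

#' Fit one model-free model to one residue
#'
#' Weighted least squares of the residue's (R1, R2, NOE) against
#' [forward_rates()] with the model's free parameters
#' (M1: S2; M2: S2, tau_e; M3: S2, Rex; M4: S2, tau_e, Rex;
#' M5: Sf2, S2, tau_e). Initialization by coarse grid search, refinement by
#' bounded local optimization. Bounds: 0 <= S2 <= Sf2 <= 1 (M5 is
#' parametrized as S2 = Sf2 * Ss2 so the ordering is structural),
#' 0 <= tau_e <= tau_m, Rex >= 0. Rex is profiled out in closed form.
#' Parameter errors come from seeded Monte-Carlo refits of the record
#' perturbed within its stated uncertainties.
#'
#' @param model_id One of `"M1"`..`"M5"`.
#' @param record One-row [relax_table()] (or list with R1, R1_err, R2,
#'   R2_err, NOE, NOE_err, residue_id).
#' @param tensor A fixed [diffusion_model()].
#' @param nh Unit N-H vector for this residue (ignored when isotropic).
#' @param constants A [dipolar_csa_constants()].
#' @param n_mc Monte-Carlo refits for parameter errors (default 300;
#'   0 skips).
#' @param seed Seed for the Monte-Carlo stage.
#' @return Object of class `mf_fit`: `residue_id`, `model_id`, `params`
#'   (a [spin_params()]), `param_errs` (named, includes Rex for M3/M4),
#'   `chi2`, `dof`, `at_bound`.
#' @export
fit_residue_model <- function(model_id, record, tensor, nh = NULL, constants,
                              n_mc = 300, seed = 1) {
  model_id <- match.arg(model_id, .MF_MODELS)
  ct <- 0
  if (tensor$kind == "axial") ct <- sum(.as_unit_vector(nh) * .axis_vector(tensor))
  fit <- .mf_fit_one(model_id, record, ct, tensor, constants)
  enames <- c(.mf_search(model_id), if (.mf_has_rex(model_id)) "Rex")
  errs <- stats::setNames(rep(NA_real_, length(enames)), enames)
  if (n_mc > 0) {
    sims <- .with_seed(seed, {
      vapply(seq_len(n_mc), function(i) {
        rec_i <- record
        rec_i$R1 <- record$R1 + stats::rnorm(1, 0, record$R1_err)
        rec_i$R2 <- record$R2 + stats::rnorm(1, 0, record$R2_err)
        rec_i$NOE <- record$NOE + stats::rnorm(1, 0, record$NOE_err)
        f <- .mf_fit_one(model_id, rec_i, ct, tensor, constants,
                         start = fit$par)
        c(f$par, if (.mf_has_rex(model_id)) f$Rex)
      }, numeric(length(enames)))
    })
    sims <- if (is.matrix(sims)) t(sims) else matrix(sims, ncol = 1)
    errs <- stats::setNames(apply(sims, 2, stats::sd), enames)
  }
  .mf_result(model_id, record, fit, errs)
}

## Simulated datasets around given true rates (shared across models).
.mf_simulate <- function(truth, record, n_mc, seed) {
  .with_seed(seed, {
    list(R1 = truth$R1 + stats::rnorm(n_mc, 0, record$R1_err),
         R2 = truth$R2 + stats::rnorm(n_mc, 0, record$R2_err),
         NOE = truth$NOE + stats::rnorm(n_mc, 0, record$NOE_err))
  })
}

## Minimum chi2 per simulated dataset for a model, via a fine grid (one
## vectorized forward call for the whole grid).
.mf_chi2_sims <- function(model_id, sims, record, cos_theta, tensor,
                          constants) {
  g <- .mf_param_grid(model_id, tensor$tau_m * 1000, fine = TRUE)
  r <- .mf_rates_grid(g$S2, g$Sf2, g$tau_e, cos_theta, tensor, constants)
  chi <- .mf_chi2_grid(r, sims$R1, sims$R2, sims$NOE,
                       record$R1_err, record$R2_err, record$NOE_err,
                       .mf_has_rex(model_id))
  apply(chi, 1, min)
}

#' Staged model-free model selection for one residue
#'
#' The standard selection ladder at a single field. M1 is accepted if its
#' chi2 passes a goodness-of-fit test at level `alpha`, with the critical
#' value taken from `n_mc_crit` seeded simulations of Gaussian noise around
#' the M1 fit (analytic chi2 quantiles are unreliable at 0-2 degrees of
#' freedom with bounded parameters). Otherwise M2 and M3 are tested by
#' F-statistic improvement over M1, each against its own Monte-Carlo null
#' distribution from the same simulations; among significant candidates the
#' lower chi2 wins. M4 and M5 carry zero degrees of freedom at a single
#' field and are last resorts: accepted only when all simpler models are
#' rejected, lower residual norm breaking the tie, and flagged through
#' `dof = 0`. When even they leave residuals above the noise-derived
#' critical level the residue is reported `"unfit"`.
#'
#' @inheritParams fit_residue_model
#' @param alpha Significance level of the ladder (default 0.05).
#' @param n_mc_crit Simulations for the critical values (default 200).
#' @param n_mc_err Monte-Carlo refits for the selected model's parameter
#'   errors (default 0 = skip).
#' @return The selected `mf_fit`, with `candidates` (chi2 of the fits that
#'   were computed) attached; `model_id = "unfit"` (params NULL) when no
#'   model is acceptable.
#' @export
select_model <- function(record, tensor, nh = NULL, constants, alpha = 0.05,
                         n_mc_crit = 200, n_mc_err = 0, seed = 1) {
  ct <- 0
  if (tensor$kind == "axial") ct <- sum(.as_unit_vector(nh) * .axis_vector(tensor))

  f1 <- .mf_fit_one("M1", record, ct, tensor, constants)
  truth1 <- .mf_rates_grid(f1$par[["S2"]], 1, 0, ct, tensor, constants)
  sims <- .mf_simulate(truth1, record, n_mc_crit, seed)
  chi1_sim <- .mf_chi2_sims("M1", sims, record, ct, tensor, constants)
  crit <- stats::quantile(chi1_sim, 1 - alpha, names = FALSE)

  chi2s <- c(M1 = f1$value)
  fits <- list(M1 = f1)
  chosen <- NULL
  if (f1$value <= crit) {
    chosen <- "M1"
  } else {
    for (m in c("M2", "M3")) {
      fits[[m]] <- .mf_fit_one(m, record, ct, tensor, constants)
      chi2s[m] <- fits[[m]]$value
    }
    fstat <- function(c1, ck) ifelse(ck <= 0, Inf, (c1 - ck) / pmax(ck, 1e-12))
    sig <- character(0)
    for (m in c("M2", "M3")) {
      chik_sim <- .mf_chi2_sims(m, sims, record, ct, tensor, constants)
      f_null <- fstat(chi1_sim, pmin(chik_sim, chi1_sim))
      f_crit <- stats::quantile(f_null, 1 - alpha, names = FALSE)
      if (fstat(chi2s["M1"], min(chi2s[m], chi2s["M1"])) > f_crit)
        sig <- c(sig, m)
    }
    if (length(sig) > 0) {
      chosen <- sig[which.min(chi2s[sig])]
    } else {
      for (m in c("M4", "M5")) {
        fits[[m]] <- .mf_fit_one(m, record, ct, tensor, constants)
        chi2s[m] <- fits[[m]]$value
      }
      best <- c("M4", "M5")[which.min(chi2s[c("M4", "M5")])]
      if (chi2s[best] <= crit) chosen <- best
    }
  }
  if (is.null(chosen)) {
    return(structure(
      list(residue_id = as.integer(record$residue_id), model_id = "unfit",
           params = NULL, param_errs = NULL, chi2 = min(chi2s),
           dof = NA_integer_, at_bound = NA, candidates = chi2s),
      class = "mf_fit"))
  }
  out <- if (n_mc_err > 0) {
    fit_residue_model(chosen, record, tensor, nh, constants,
                      n_mc = n_mc_err, seed = seed + 1)
  } else {
    enames <- c(.mf_search(chosen), if (.mf_has_rex(chosen)) "Rex")
    .mf_result(chosen, record, fits[[chosen]],
               stats::setNames(rep(NA_real_, length(enames)), enames))
  }
  out$candidates <- chi2s
  out
}

#' Model-free fits with selection for a whole table
#'
#' Runs [select_model()] for every residue of a relaxation table.
#'
#' @param records A [relax_table()].
#' @param tensor A fixed [diffusion_model()].
#' @param nh An [nh_vectors()] object (required for an axial tensor).
#' @param constants A [dipolar_csa_constants()].
#' @param ... Passed to [select_model()].
#' @param seed Base seed; each residue's Monte-Carlo stage is offset
#'   deterministically.
#' @return List of `mf_fit` results, one per residue.
#' @export
modelfree_table <- function(records, tensor, nh = NULL, constants, ...,
                            seed = 1) {
  lapply(seq_len(nrow(records)), function(i) {
    rec <- records[i, ]
    v <- NULL
    if (!is.null(nh)) {
      j <- match(rec$residue_id, nh$residue_id)
      if (is.na(j)) stop("no NH vector for residue ", rec$residue_id)
      v <- c(nh$x[j], nh$y[j], nh$z[j])
    }
    select_model(rec, tensor, v, constants, ..., seed = seed + i)
  })
}

#' Summarize model-free results per model
#'
#' Residue counts, residue id lists and mean +/- SD of S2 for each model,
#' computed over selected fits; unfit residues are tallied separately.
#'
#' @param results List of `mf_fit` objects (e.g. from [modelfree_table()]).
#' @return List with `table` (data.frame: model, n, mean_S2, sd_S2),
#'   `residues` (named list of residue ids per model), `n_unfit`.
#' @export
summarize_models <- function(results) {
  ids <- as.integer(vapply(results, function(r) as.numeric(r$residue_id),
                           numeric(1)))
  models <- vapply(results, `[[`, character(1), "model_id")
  S2 <- vapply(results, function(r)
    if (is.null(r$params)) NA_real_ else r$params$S2, numeric(1))
  tab <- do.call(rbind, lapply(.MF_MODELS, function(m) {
    sel <- models == m
    data.frame(model = m, n = sum(sel),
               mean_S2 = if (any(sel)) mean(S2[sel]) else NA_real_,
               sd_S2 = if (sum(sel) > 1) stats::sd(S2[sel]) else NA_real_)
  }))
  residues <- lapply(stats::setNames(.MF_MODELS, .MF_MODELS),
                     function(m) ids[models == m])
  list(table = tab, residues = residues, n_unfit = sum(models == "unfit"))
}
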