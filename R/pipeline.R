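## Stage-driven pipeline: simulate -> fitrates -> jmap -> tensor ->
## modelfree -> csp -> report, with a single resolved configuration, one
## root seed, and artifacts that name their inputs by content hash.

#' Pipeline configuration
#'
#' One resolved bundle of every knob the stages use. All randomness flows
#' from `seed`; identical config and seed give identical outputs.
#'
#' @param n_residues,tau_m,ratio,rate_noise,noe_noise Scenario parameters
#'   (see [scenario()]).
#' @param proton_frequency_MHz Field (default 800).
#' @param r_NH,delta_sigma Physical constants (defaults 1.02 Angstrom,
#'   -160 ppm), recorded in all output headers.
#' @param noe_min,trim_k Rigid-subset rules (see [select_rigid_subset()]).
#' @param alpha Significance level for tensor and model-free selection.
#' @param nitrogen_weight,small_max,large_min CSP settings.
#' @param n_mc_rates Monte-Carlo refits per decay series.
#' @param n_mc_crit Simulations per residue for model-free critical values.
#' @param seed Root seed.
#' @return Named list of class `run_config`.
#' @export
pipeline_config <- function(n_residues = 150, tau_m = 8, ratio = 1.15,
                            rate_noise = 0.02, noe_noise = 0.02,
                            proton_frequency_MHz = 800,
                            r_NH = 1.02, delta_sigma = -160,
                            noe_min = 0.65, trim_k = 3.0, alpha = 0.05,
                            nitrogen_weight = 0.2, small_max = 0.1,
                            large_min = 0.5, n_mc_rates = 50,
                            n_mc_crit = 100, seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

.artifact <- function(out_dir, name) file.path(out_dir, name)

.require_artifact <- function(out_dir, name, producer) {
  p <- .artifact(out_dir, name)
  if (!file.exists(p))
    stop("missing artifact '", name, "': run stage '", producer, "' first")
  p
}

.cfg_header <- function(cfg, inputs = character(0)) {
  h <- cfg[!vapply(cfg, is.list, logical(1))]
  for (f in inputs) h[[paste0("input_md5_", basename(f))]] <-
      unname(tools::md5sum(f))
  h
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order, reading and writing
#' delimited-text artifacts under `out_dir`:
#' \describe{
#'   \item{simulate}{synthetic decay series, NOE pairs, NH vectors, peak
#'     lists and ground truth from the scenario in `config`}
#'   \item{fitrates}{exponential fits and NOE computation ->
#'     `rates.tsv`}
#'   \item{jmap}{reduced spectral density mapping -> `jw.tsv` (plus
#'     exchange indicators `exchange.tsv`)}
#'   \item{tensor}{rigid subset, isotropic + axial fits, F-test selection ->
#'     `tensor.tsv`}
#'   \item{modelfree}{per-residue model selection -> `modelfree.tsv`,
#'     `model_summary.tsv`}
#'   \item{csp}{composite-shift table -> `csp.tsv`}
#'   \item{report}{plain-text run summary -> `report.txt`}
#' }
#' A stage whose upstream artifact is absent fails with an error naming the
#' producing stage. Artifacts embed the resolved config and the md5 of their
#' inputs in their commented headers.
#'
#' @param config A [pipeline_config()].
#' @param stages Character subset of the stage names above, any order.
#' @param out_dir Artifact directory (created if needed).
#' @return Invisible named list of artifact paths.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("simulate", "fitrates", "jmap", "tensor",
                                    "modelfree", "csp", "report"),
                         out_dir = "relaxfit_run") {
  stopifnot(inherits(config, "run_config"))
  order <- c("simulate", "fitrates", "jmap", "tensor", "modelfree", "csp",
             "report")
  stages <- order[order %in% match.arg(stages, order, several.ok = TRUE)]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  field <- field_spec(config$proton_frequency_MHz)
  constants <- dipolar_csa_constants(field, config$r_NH, config$delta_sigma)
  paths <- list()

  if ("simulate" %in% stages) {
    scn <- scenario(n_residues = config$n_residues,
                    tensor = diffusion_model("axial", tau_m = config$tau_m,
                                             ratio = config$ratio,
                                             axis_theta = 0.7, axis_phi = 1.2),
                    field = field, rate_noise = config$rate_noise,
                    noe_noise = config$noe_noise, seed = config$seed)
    tpl <- make_template(scn)
    truth <- assign_dynamics(tpl, scn)
    sim <- simulate_relaxation(truth, tpl, scn)
    hdr <- .cfg_header(config)
    write_decays(sim$decays_r1, .artifact(out_dir, "decays_r1.tsv"), hdr)
    write_decays(sim$decays_r2, .artifact(out_dir, "decays_r2.tsv"), hdr)
    .write_table_with_header(sim$noe_pairs,
                             .artifact(out_dir, "noe_pairs.tsv"), hdr)
    .write_table_with_header(as.data.frame(tpl$nh),
                             .artifact(out_dir, "nh_vectors.tsv"), hdr)
    .write_table_with_header(sim$truth, .artifact(out_dir, "truth.tsv"), hdr)
    csp_sim <- simulate_csp(tpl, seed = config$seed + 10L)
    write_peak_list(csp_sim$apo, .artifact(out_dir, "peaks_apo.tsv"), hdr)
    write_peak_list(csp_sim$holo, .artifact(out_dir, "peaks_holo.tsv"), hdr)
    .write_table_with_header(csp_sim$truth,
                             .artifact(out_dir, "csp_truth.tsv"), hdr)
    paths$simulate <- .artifact(out_dir, "truth.tsv")
  }

  if ("fitrates" %in% stages) {
    p1 <- .require_artifact(out_dir, "decays_r1.tsv", "simulate")
    p2 <- .require_artifact(out_dir, "decays_r2.tsv", "simulate")
    pn <- .require_artifact(out_dir, "noe_pairs.tsv", "simulate")
    f1 <- fit_rate_table(read_decays(p1), n_mc = config$n_mc_rates,
                         seed = config$seed + 20L)
    f2 <- fit_rate_table(read_decays(p2), n_mc = config$n_mc_rates,
                         seed = config$seed + 21L)
    np <- .read_table_with_header(pn)
    noe <- compute_noe(np$I_sat, np$I_ref, np$sigma, np$sigma)
    rec <- relax_table(f1$residue_id, f1$rate, f1$rate_err,
                       f2$rate, f2$rate_err, noe$NOE, noe$NOE_err, field)
    write_relax_table(rec, .artifact(out_dir, "rates.tsv"),
                      .cfg_header(config, c(p1, p2, pn)))
    paths$fitrates <- .artifact(out_dir, "rates.tsv")
  }

  if (any(c("jmap", "tensor", "modelfree") %in% stages)) {
    pr <- .require_artifact(out_dir, "rates.tsv", "fitrates")
    rec <- read_relax_table(pr)
  }

  if ("jmap" %in% stages) {
    jw <- reduced_jw(rec, constants)
    .write_table_with_header(jw, .artifact(out_dir, "jw.tsv"),
                             .cfg_header(config, pr))
    ex <- exchange_indicators(rec)
    .write_table_with_header(ex, .artifact(out_dir, "exchange.tsv"),
                             .cfg_header(config, pr))
    paths$jmap <- .artifact(out_dir, "jw.tsv")
  }

  if (any(c("tensor", "modelfree") %in% stages)) {
    pv <- .require_artifact(out_dir, "nh_vectors.tsv", "simulate")
    nhdf <- .read_table_with_header(pv)
    nh <- nh_vectors(nhdf$residue_id, cbind(nhdf$x, nhdf$y, nhdf$z))
  }

  if ("tensor" %in% stages) {
    sub <- select_rigid_subset(rec, config$noe_min, config$trim_k)
    iso <- fit_isotropic_tm(sub, constants, n_mc = 50,
                            seed = config$seed + 30L)
    axi <- fit_axial_tensor(sub, nh, constants)
    sel <- tensor_model_selection(iso, axi, nrow(sub), config$alpha,
                                  records = sub, constants = constants,
                                  n_null = 40, seed = config$seed + 31L)
    tdf <- data.frame(kind = sel$kind, tau_m = sel$tensor$tau_m,
                      ratio = sel$tensor$ratio,
                      axis_theta = sel$tensor$axis_theta,
                      axis_phi = sel$tensor$axis_phi,
                      F_stat = sel$F, p_value = sel$p_value,
                      n_subset = nrow(sub), chi2_iso = iso$chi2,
                      chi2_axial = axi$chi2)
    .write_table_with_header(tdf, .artifact(out_dir, "tensor.tsv"),
                             .cfg_header(config, c(pr, pv)))
    paths$tensor <- .artifact(out_dir, "tensor.tsv")
  }

  if ("modelfree" %in% stages) {
    pt <- .require_artifact(out_dir, "tensor.tsv", "tensor")
    tdf <- .read_table_with_header(pt)
    tensor <- diffusion_model(tdf$kind, tau_m = tdf$tau_m, ratio = tdf$ratio,
                              axis_theta = tdf$axis_theta,
                              axis_phi = tdf$axis_phi)
    res <- modelfree_table(rec, tensor, nh, constants, alpha = config$alpha,
                           n_mc_crit = config$n_mc_crit,
                           seed = config$seed + 40L)
    mfdf <- do.call(rbind, lapply(res, function(r) {
      data.frame(residue_id = r$residue_id, model = r$model_id,
                 S2 = if (is.null(r$params)) NA else r$params$S2,
                 Sf2 = if (is.null(r$params)) NA else r$params$Sf2,
                 tau_e = if (is.null(r$params)) NA else r$params$tau_e,
                 Rex = if (is.null(r$params)) NA else r$params$Rex,
                 chi2 = r$chi2, dof = r$dof)
    }))
    .write_table_with_header(mfdf, .artifact(out_dir, "modelfree.tsv"),
                             .cfg_header(config, c(pr, pv, pt)))
    sm <- summarize_models(res)
    .write_table_with_header(sm$table,
                             .artifact(out_dir, "model_summary.tsv"),
                             .cfg_header(config))
    paths$modelfree <- .artifact(out_dir, "modelfree.tsv")
  }

  if ("csp" %in% stages) {
    pa <- .require_artifact(out_dir, "peaks_apo.tsv", "simulate")
    ph <- .require_artifact(out_dir, "peaks_holo.tsv", "simulate")
    ct <- csp_table(read_peak_list(pa), read_peak_list(ph),
                    config$nitrogen_weight, config$small_max,
                    config$large_min)
    .write_table_with_header(ct, .artifact(out_dir, "csp.tsv"),
                             .cfg_header(config, c(pa, ph)))
    paths$csp <- .artifact(out_dir, "csp.tsv")
  }

  if ("report" %in% stages) {
    lines <- c("relaxfit run report", "===================")
    for (f in c("rates.tsv", "tensor.tsv", "model_summary.tsv", "csp.tsv")) {
      p <- .artifact(out_dir, f)
      if (file.exists(p)) {
        lines <- c(lines, "", paste0("## ", f),
                   utils::capture.output(print(.read_table_with_header(p))))
      }
    }
    writeLines(lines, .artifact(out_dir, "report.txt"))
    paths$report <- .artifact(out_dir, "report.txt")
  }
  invisible(paths)
}
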