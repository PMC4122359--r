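## Reduced spectral density mapping: direct inversion of (R1, R2, NOE) into
## J(0), J(wN) and J(0.87 wH) without assuming a motional model, plus the
## R2/R1 and R2*R1 exchange indicators.

## High-frequency reduction coefficients. Assuming J(w) ~ 1/w^2 above wH-wN,
## the three proton-frequency terms collapse onto a single effective frequency
## eps*wH (eps ~ 0.870 at the 15N/1H gamma ratio). Coefficients are computed
## exactly from the field's frequencies rather than hard-coding the customary
## rounded constants (5 and 2.72), which they reproduce.
.sdm_coeffs <- function(field) {
  wH <- abs(field$omega_H)
  wN <- abs(field$omega_N)
  u <- 1 / (wH + wN)^2      # J(wH - wN) weight basis (|wN| signed away)
  v <- 6 / (wH - wN)^2
  ## note: with gammaN < 0, |omegaH - omegaN| = wH + wN and
  ## |omegaH + omegaN| = wH - wN in magnitude terms
  sigma_scale <- v - u                      # sigma_NH = (d2 lambda/4)(v - u)
  eps <- sqrt(5 / (sigma_scale * wH^2))     # effective frequency factor
  kN <- (u + v) / (v - u)                   # R1 high-frequency part, sigma units
  k0 <- 18 / (wH^2 * (v - u))               # 6R2 - 3R1 high-frequency part
  list(eps = eps, kN = kN, k0 = k0)
}

#' Reduced spectral density mapping
#'
#' Inverts per-residue (R1, R2, NOE) into J(0), J(wN) and J(0.87 wH):
#' sigma_NH = R1 (NOE - 1) (gammaN/gammaH);
#' J(0.87 wH) = 4 sigma_NH / (5 d2);
#' J(wN) = (4 R1 - 4 kN sigma_NH) / (3 d2 + 4 c2);
#' J(0) = (6 R2 - 3 R1 - k0 sigma_NH) / (3 d2 + 4 c2),
#' where kN (~1.25, i.e. the customary constant 5 after the factor 4) and k0
#' (~2.72) follow from the 1/w^2 high-frequency approximation evaluated at
#' the field's exact frequencies. Errors are propagated linearly. Any Rex
#' contribution to R2 inflates the J(0) estimate; J(wN) and J(0.87 wH) are
#' unaffected by it.
#'
#' @param records A [relax_table()].
#' @param constants A [dipolar_csa_constants()] (field taken from it).
#' @return data.frame with `residue_id`, `J0`, `J0_err`, `JwN`, `JwN_err`,
#'   `JwH`, `JwH_err` (s/rad) and `noe_flag` (TRUE when NOE exceeds 1, the
#'   physical ceiling for 15N; flagged, not fatal).
#' @export
reduced_jw <- function(records, constants) {
  stopifnot(inherits(records, "relax_table"),
            inherits(constants, "phys_constants"))
  if (any(records$R1 <= 0) || any(records$R2 <= 0))
    stop("rates must be positive")
  field <- attr(records, "field")
  cf <- .sdm_coeffs(field)
  d2 <- constants$d2
  c2 <- constants$c2
  g <- 1 / field$gamma_ratio            # gammaN / gammaH (negative)
  D <- 3 * d2 + 4 * c2

  R1 <- records$R1; R2 <- records$R2; NOE <- records$NOE
  sig <- R1 * (NOE - 1) * g
  JwH <- 4 * sig / (5 * d2)
  JwN <- (4 * R1 - 4 * cf$kN * sig) / D
  J0 <- (6 * R2 - 3 * R1 - cf$k0 * sig) / D

  ## linear propagation; sigma_NH depends on R1 and NOE
  dsig_dR1 <- (NOE - 1) * g
  dsig_dNOE <- R1 * g
  e_sig <- sqrt((dsig_dR1 * records$R1_err)^2 + (dsig_dNOE * records$NOE_err)^2)
  JwH_err <- 4 * e_sig / (5 * d2)
  JwN_err <- sqrt(((4 - 4 * cf$kN * dsig_dR1) * records$R1_err)^2 +
                  (4 * cf$kN * dsig_dNOE * records$NOE_err)^2) / D
  J0_err <- sqrt((6 * records$R2_err)^2 +
                 ((3 + cf$k0 * dsig_dR1) * records$R1_err)^2 +
                 (cf$k0 * dsig_dNOE * records$NOE_err)^2) / D

  data.frame(residue_id = records$residue_id,
             J0 = J0, J0_err = J0_err,
             JwN = JwN, JwN_err = JwN_err,
             JwH = JwH, JwH_err = JwH_err,
             noe_flag = NOE > 1)
}

#' Conformational-exchange indicators from R2/R1 and R2*R1
#'
#' Computes per-residue R2/R1 ratios and R2*R1 products and flags residues
#' whose value exceeds the trimmed mean plus `k` trimmed standard deviations.
#' Elevated R2*R1 (and R2/R1) marks micro- to millisecond exchange, since Rex
#' inflates R2 while fast internal motion depresses both rates together. The
#' indicators use only R1 and R2; NOE does not enter.
#'
#' @param records A [relax_table()] with at least 5 rows.
#' @param k Flagging threshold in trimmed SDs above the trimmed mean
#'   (default 1.5).
#' @param trim Fraction trimmed from each tail before computing mean and SD
#'   (default 0.10).
#' @return data.frame with `residue_id`, `ratio` (R2/R1), `product` (R2*R1),
#'   `ratio_flag`, `product_flag`.
#' @export
exchange_indicators <- function(records, k = 1.5, trim = 0.10) {
  stopifnot(inherits(records, "relax_table"))
  if (nrow(records) < 5L) stop("need at least 5 records")
  ratio <- records$R2 / records$R1
  product <- records$R2 * records$R1
  ## centre from the trimmed sample (robust to the outliers being sought);
  ## spread from the full sample, so the threshold stays conservative
  flag <- function(x) {
    m <- mean(x, trim = trim)
    sdv <- stats::sd(x)
    if (!is.finite(sdv) || sdv == 0) return(rep(FALSE, length(x)))
    x > m + k * sdv
  }
  data.frame(residue_id = records$residue_id,
             ratio = ratio, product = product,
             ratio_flag = flag(ratio), product_flag = flag(product))
}
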