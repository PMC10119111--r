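#' PGE2 receptor activation and smooth-muscle cAMP derivatives
#'
#' Binding of astrocytic PGE2 to arteriolar smooth-muscle receptors and the
#' downstream cAMP production:
#' `dR_PG/dt = -R_PG/tau_R + O_R PG (1 - R_PG)` and
#' `dcAMP/dt = -cAMP/tau_cAMP + O_cAMP R_PG`. The activated fraction `R_PG`
#' saturates at 1 for large PGE2; for constant PG the cAMP equilibrium is
#' `tau_cAMP O_cAMP O_R PG tau_R / (O_R PG tau_R + 1)`.
#'
#' @param R_PG Activated receptor fraction in `[0, 1]`.
#' @param cAMP Cyclic-AMP concentration (uM).
#' @param PG PGE2 concentration (uM).
#' @param params An [nvc_params()] object.
#' @return Named vector `c(R_PG, cAMP)` of derivatives (1/s, uM/s).
#' @export
receptor_camp_deriv <- function(R_PG, cAMP, PG, params = nvc_params()) {
  v <- params$vascular
  stopifnot(R_PG >= 0, R_PG <= 1, PG >= 0)
  c(R_PG = -R_PG / v$tau_R + v$O_R * PG * (1 - R_PG),
    cAMP = -cAMP / v$tau_cAMP + v$O_cAMP * R_PG)
}

#' Normalized arteriole volume from cAMP
#'
#' Arteriole dilation is proportional to the cAMP excursion from its basal
#' level through a saturating odd response:
#' `CBV_A = 1 + D_A (cAMP - cAMP_o) / (K_VA^2 + (cAMP - cAMP_o)^2)`.
#' The response is exactly 1 at basal cAMP, maximal (`1 + D_A/(2 K_VA)`) at
#' `cAMP - cAMP_o = K_VA`, and below baseline for `cAMP < cAMP_o` — the
#' constriction branch through which the pathway contributes to basal
#' vascular tone.
#'
#' @param cAMP Cyclic-AMP concentration (uM).
#' @param params An [nvc_params()] object; `cAMP_o` must be resolved (a
#'   number, not `NULL`) — [resting_state()] supplies it.
#' @param cAMP_o Basal cAMP; overrides the value in `params` if given.
#' @return Normalized arteriole volume (baseline 1).
#' @export
arteriole_volume <- function(cAMP, params = nvc_params(), cAMP_o = NULL) {
  v <- params$vascular
  o <- if (!is.null(cAMP_o)) cAMP_o else v$cAMP_o
  if (is.null(o)) {
    stop("cAMP_o is unresolved; compute the resting state first ",
         "(see resting_state())", call. = FALSE)
  }
  dc <- cAMP - o
  1 + v$D_A * dc / (v$K_VA^2 + dc^2)
}

#' Inflow from arteriole volume by power law
#'
#' `CBF_in = CBV_A^(1/alpha_A)`: the standard flow-volume power law, with
#' baseline flow 1 at baseline volume.
#'
#' @param CBV_A Normalized arteriole volume (> 0).
#' @param alpha_A Power-law exponent in `(0, 1]`.
#' @return Normalized inflow.
#' @export
cbf_from_cbv <- function(CBV_A, alpha_A) {
  if (!is.numeric(alpha_A) || alpha_A <= 0) {
    stop("alpha_A must be > 0", call. = FALSE)
  }
  stopifnot(all(CBV_A > 0))
  CBV_A^(1 / alpha_A)
}

#' Balloon model derivatives
#'
#' Venous volume `v` and deoxyhemoglobin content `q` (both normalized to
#' baseline) driven by the normalized inflow:
#' `dv/dt = (CBF_in - CBF_out)/(tau_0 + tau_v)`-type viscoelastic update with
#' `CBF_out = v^(1/alpha_V) + tau_v dv/dt`, and
#' `dq/dt = (CBF_in E(CBF_in)/E_0 - CBF_out q/v)/tau_0` with the
#' flow-extraction coupling `E(f) = 1 - (1 - E_0)^(1/f)`. With `tau_v = 0`
#' the outflow reduces to the pure power law.
#'
#' @param v,q Normalized venous volume and deoxyhemoglobin (> 0).
#' @param CBF_in Normalized inflow (> 0).
#' @param params An [nvc_params()] object.
#' @return Named list with `dv`, `dq` (1/s) and `CBF_out`.
#' @export
balloon_deriv <- function(v, q, CBF_in, params = nvc_params()) {
  b <- params$balloon
  stopifnot(v > 0, q > 0, CBF_in > 0)
  f_out_ss <- v^(1 / b$alpha_V)
  dv <- (CBF_in - f_out_ss) / (b$tau_0 + b$tau_v)
  CBF_out <- f_out_ss + b$tau_v * dv
  E_f <- 1 - (1 - b$E_0)^(1 / CBF_in)
  dq <- (CBF_in * E_f / b$E_0 - CBF_out * q / v) / b$tau_0
  list(dv = dv, dq = dq, CBF_out = CBF_out)
}

#' BOLD signal from Balloon state
#'
#' The static observation equation
#' `BOLD = V_0 (k1 (1 - q) + k2 (1 - q/v) + k3 (1 - v))`, zero at rest.
#' Returned as a fraction; simulation outputs multiply by 100 to report
#' percent signal change.
#'
#' @param v,q Normalized venous volume and deoxyhemoglobin (> 0).
#' @param params An [nvc_params()] object.
#' @return Fractional BOLD signal change.
#' @export
bold_from_balloon <- function(v, q, params = nvc_params()) {
  b <- params$balloon
  stopifnot(all(v > 0), all(q > 0))
  b$V_0 * (b$k1 * (1 - q) + b$k2 * (1 - q / v) + b$k3 * (1 - v))
}

#' Linearized BOLD approximation from inflow
#'
#' The rough linear map `BOLD ~= k1 (CBF_in - 1)` scaled by `V_0`, a
#' first-order approximation of the Balloon output useful as a sanity
#' reference; it misses the post-stimulus undershoot carried by the slow
#' venous volume.
#'
#' @param CBF_in Normalized inflow.
#' @param params An [nvc_params()] object.
#' @return Fractional BOLD approximation.
#' @export
bold_linear <- function(CBF_in, params = nvc_params()) {
  b <- params$balloon
  b$V_0 * b$k1 * (CBF_in - 1)
}
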