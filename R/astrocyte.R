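#' First-order Hill function
#'
#' `hill(x, K) = x / (x + K)`, the saturating occupancy used throughout the
#' astrocyte stage. `hill(x, K, n)` generalises to `x^n / (x^n + K^n)`.
#'
#' @param x Concentration (>= 0).
#' @param K Half-saturation constant (> 0).
#' @param n Hill exponent (default 1).
#' @return Fraction in `[0, 1)`.
#' @export
hill <- function(x, K, n = 1) {
  if (any(K <= 0)) stop("K must be > 0", call. = FALSE)
  if (any(x < 0)) stop("x must be >= 0", call. = FALSE)
  x^n / (x^n + K^n)
}

#' Calcium fluxes of the Li-Rinzel store model
#'
#' The three fluxes exchanging calcium between cytosol and endoplasmic
#' reticulum: IP3-receptor channel release `J_C = Gamma_C m_inf^3 h^3 (C_T -
#' (1+rho_A) Ca)` with open probability `m_inf = hill(IP3, d1) hill(Ca, d5)`,
#' passive leak `J_L = Gamma_L (C_T - (1+rho_A) Ca)`, and SERCA re-uptake
#' `J_P = O_P hill(Ca, K_P, pump_hill)`. Setting `leak_sign = -1` in the
#' parameters reproduces a `(1 - rho_A)` reservoir factor in the leak term
#' only (a printed variant); the default keeps the conserved reservoir
#' consistent between channel and leak.
#'
#' @param state Named vector/list with `Ca`, `h`, `IP3` (uM, -, uM).
#' @param params An [nvc_params()] object.
#' @return Named vector `c(J_C, J_L, J_P)` in uM/s.
#' @export
calcium_fluxes <- function(state, params = nvc_params()) {
  a <- params$astrocyte
  Ca <- state[["Ca"]]; h <- state[["h"]]; IP3 <- state[["IP3"]]
  m_inf <- hill(IP3, a$d1) * hill(Ca, a$d5)
  res_C <- a$C_T - (1 + a$rho_A) * Ca
  res_L <- a$C_T - (1 + a$leak_sign * a$rho_A) * Ca
  c(J_C = a$Gamma_C * m_inf^3 * h^3 * res_C,
    J_L = a$Gamma_L * res_L,
    J_P = a$O_P * hill(Ca, a$K_P, a$pump_hill))
}

#' IP3-receptor inactivation gate kinetics
#'
#' Steady-state value and relaxation time of the IP3R deinactivation gate
#' `h`: `h_inf = d2 (IP3 + d1) / (d2 (IP3 + d1) + (IP3 + d3) Ca)` and
#' `tau_h = (1/O_2) (IP3 + d3) / (d2 (IP3 + d1) + (IP3 + d3) Ca)`. `tau_h`
#' sets the refractory period between calcium spikes and thereby the upper
#' bound of the spike frequency; raising `O_2` shortens it.
#'
#' @inheritParams calcium_fluxes
#' @return List with `h_inf` (in `(0, 1]`) and `tau_h` (s, > 0).
#' @export
ip3r_gating <- function(state, params = nvc_params()) {
  a <- params$astrocyte
  Ca <- state[["Ca"]]; IP3 <- state[["IP3"]]
  den <- a$d2 * (IP3 + a$d1) + (IP3 + a$d3) * Ca
  list(h_inf = a$d2 * (IP3 + a$d1) / den,
       tau_h = (1 / a$O_2) * (IP3 + a$d3) / den)
}

#' Time derivative of cytosolic IP3
#'
#' Agonist-dependent IP3 metabolism: production by glutamate-activated
#' PLC-beta (Hill exponent 0.7 in glutamate, with calcium-dependent shift of
#' the affinity) and by calcium-activated PLC-delta (inhibited by IP3
#' itself), degradation by IP3-3-kinase (calcium-gated) and by a linear
#' 5-phosphatase. Both production terms saturate, so the derivative stays
#' finite as glutamate grows without bound.
#'
#' @param IP3,Ca,Glu Concentrations (uM).
#' @param params An [nvc_params()] object.
#' @return dIP3/dt (uM/s).
#' @export
ip3_deriv <- function(IP3, Ca, Glu, params = nvc_params()) {
  a <- params$astrocyte
  K_gamma <- a$K_R * (1 + (a$K_p / a$K_R) * hill(Ca, a$K_pi))
  J_beta  <- a$v_beta * hill(Glu, K_gamma, 0.7)
  J_delta <- a$v_delta / (1 + IP3 / a$kappa_delta) * hill(Ca, a$K_delta, 2)
  J_3K    <- a$v_3K * hill(Ca, a$K_D, 4) * hill(IP3, a$K_3)
  J_5P    <- a$r_5P * IP3
  J_beta + J_delta - J_3K - J_5P
}

#' Arachidonic acid and prostaglandin-E2 cascade derivatives
#'
#' Michaelis-Menten production driven by cytosolic calcium (AA) and by AA
#' (PGE2), each with first-order decay:
#' `dAA/dt = -AA/tau_AA + O_AA Ca/(K_AA + Ca)` and
#' `dPG/dt = -PG/tau_PG + O_PG AA/(K_PG + AA)`.
#'
#' @param AA,PG,Ca Concentrations (uM).
#' @param params An [nvc_params()] object.
#' @return Named vector `c(AA, PG)` of derivatives (uM/s).
#' @export
aa_pg_deriv <- function(AA, PG, Ca, params = nvc_params()) {
  a <- params$astrocyte
  c(AA = -AA / a$tau_AA + a$O_AA * hill(Ca, a$K_AA),
    PG = -PG / a$tau_PG + a$O_PG * hill(AA, a$K_PG))
}

#' Full astrocyte state derivative
#'
#' Assembles [calcium_fluxes()], [ip3r_gating()], [ip3_deriv()] and
#' [aa_pg_deriv()] into the five-variable astrocyte ODE driven by a
#' glutamate concentration. The optional `ca_clamp` caps the calcium value
#' seen by the AA production term (used by the amplitude-clamp experiment
#' that separates frequency from amplitude coding); the calcium dynamics
#' itself is never clamped.
#'
#' @param state Named vector with `Ca`, `h`, `IP3`, `AA`, `PG`.
#' @param Glu Glutamate concentration (uM).
#' @param params An [nvc_params()] object.
#' @param ca_clamp Upper bound (uM) on calcium as input to AA production.
#' @return Named vector of derivatives.
#' @export
astrocyte_deriv <- function(state, Glu, params = nvc_params(), ca_clamp = Inf) {
  Ca <- max(0, state[["Ca"]]); h <- min(1, max(0, state[["h"]]))
  IP3 <- max(0, state[["IP3"]])
  st <- c(Ca = Ca, h = h, IP3 = IP3)
  J <- calcium_fluxes(st, params)
  g <- ip3r_gating(st, params)
  ap <- aa_pg_deriv(state[["AA"]], state[["PG"]], min(Ca, ca_clamp), params)
  c(Ca  = J[["J_C"]] + J[["J_L"]] - J[["J_P"]],
    h   = (g$h_inf - h) / g$tau_h,
    IP3 = ip3_deriv(IP3, Ca, Glu, params),
    AA  = ap[["AA"]],
    PG  = ap[["PG"]])
}
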