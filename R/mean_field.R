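#' Subthreshold membrane moments of an AdEx population
#'
#' Computes the mean, standard deviation and normalised autocorrelation time
#' of the membrane potential of a conductance-based AdEx neuron bombarded by
#' Poissonian excitatory and inhibitory synaptic input at the given
#' presynaptic rates. These moments feed the semi-analytic transfer function
#' [adex_transfer()]; `mu_V` is also the quantity entering the subthreshold
#' adaptation term when `a != 0`.
#'
#' @param nu_e,nu_i Mean presynaptic excitatory/inhibitory rates (Hz, per
#'   neuron; multiplied internally by the in-degrees `p_conn * N_e` and
#'   `p_conn * N_i`).
#' @param W Mean adaptation current (pA).
#' @param params An [nvc_params()] object (the `neuronal` block is used).
#' @return A list with `mu_V`, `sigma_V` (V), `tau_V` (s) and `tau_V_N`
#'   (dimensionless, normalised by the membrane time at rest).
#' @export
membrane_moments <- function(nu_e, nu_i, W, params = nvc_params()) {
  n <- params$neuronal
  # rate floor keeps the fluctuation moments defined at silent input
  fe <- (nu_e + 1e-6) * n$p_conn * n$N_e
  fi <- (nu_i + 1e-6) * n$p_conn * n$N_i
  muGe <- n$Q_e * n$tau_e * fe
  muGi <- n$Q_i * n$tau_i * fi
  muG  <- n$g_L + muGe + muGi
  muV  <- (muGe * n$E_e + muGi * n$E_i + n$g_L * n$E_L - W * 1e-12) / muG
  Tm   <- n$C_m / muG
  Ue <- n$Q_e / muG * (n$E_e - muV)
  Ui <- n$Q_i / muG * (n$E_i - muV)
  se <- fe * (Ue * n$tau_e)^2
  si <- fi * (Ui * n$tau_i)^2
  sV <- sqrt(se / (2 * (n$tau_e + Tm)) + si / (2 * (n$tau_i + Tm)))
  tV <- (se + si) / (se / (n$tau_e + Tm) + si / (n$tau_i + Tm))
  list(mu_V = muV, sigma_V = sV, tau_V = tV, tau_V_N = tV * n$g_L / n$C_m)
}

#' Semi-analytic AdEx population transfer function
#'
#' Output firing rate of an AdEx neuron receiving excitatory and inhibitory
#' Poisson input at mean rates `nu_e_eff` and `nu_i` with mean adaptation
#' current `W`. The rate is an error-function estimate driven by the
#' subthreshold membrane moments ([membrane_moments()]) with a fitted
#' second-order phenomenological threshold polynomial (coefficients `P_e` for
#' the excitatory, `P_i` for the inhibitory population in [nvc_params()]).
#' A user-supplied tabulated transfer function can be substituted via
#' `table_fn` for exact reproduction of an external fit.
#'
#' @param nu_e_eff Total excitatory presynaptic rate, recurrent plus external
#'   (Hz). Must be finite and non-negative.
#' @param nu_i Inhibitory presynaptic rate (Hz).
#' @param W Mean adaptation current (pA).
#' @param params An [nvc_params()] object.
#' @param pop `"e"` (regular-spiking coefficients) or `"i"` (fast-spiking).
#' @param table_fn Optional function `(nu_e_eff, nu_i, W) -> Hz` overriding
#'   the semi-analytic form.
#' @return Firing rate (Hz), finite and non-negative.
#' @export
adex_transfer <- function(nu_e_eff, nu_i, W, params = nvc_params(),
                          pop = c("e", "i"), table_fn = NULL) {
  pop <- match.arg(pop)
  if (!all(is.finite(nu_e_eff), is.finite(nu_i))) {
    stop("non-finite input rates", call. = FALSE)
  }
  if (any(nu_e_eff < 0) || any(nu_i < 0)) stop("rates must be >= 0", call. = FALSE)
  if (!is.null(table_fn)) return(pmax(0, table_fn(nu_e_eff, nu_i, W)))
  if (is.infinite(W) && W > 0) return(0)
  if (!is.finite(W)) stop("non-finite adaptation current", call. = FALSE)
  n <- params$neuronal
  P <- if (pop == "e") n$P_e else n$P_i
  m <- membrane_moments(nu_e_eff, nu_i, W, params)
  xm <- (m$mu_V - n$muV0) / n$DmuV0
  xs <- (m$sigma_V - n$sV0) / n$DsV0
  xt <- (m$tau_V_N - n$TvN0) / n$DTvN0
  V_thre <- P[1] + P[2] * xm + P[3] * xs + P[4] * xt +
    P[5] * xm^2 + P[6] * xs^2 + P[7] * xt^2 +
    P[8] * xm * xs + P[9] * xm * xt + P[10] * xs * xt
  # erfc((Vthre - muV) / (sqrt(2) sV)) / (2 tauV); far outside the fitted
  # fluctuation regime (mean voltage driven to absurdly hyperpolarised
  # values by extreme adaptation) the neuron is silent and the threshold
  # polynomial must not be extrapolated
  rate <- erfc((V_thre - m$mu_V) / (sqrt(2) * m$sigma_V)) / (2 * m$tau_V)
  rate[m$mu_V < -0.2] <- 0
  pmax(0, rate)
}

erfc <- function(x) 2 * stats::pnorm(-x * sqrt(2))

#' Time derivatives of the mean-field neuronal state
#'
#' First-order mean-field dynamics of the AdEx excitatory/inhibitory
#' population: the rates relax toward the transfer function with time
#' constant `T`, and the adaptation current `W` integrates spike-triggered
#' increments `b * nu_e` (plus a subthreshold term `a * (mu_V - E_L)` when
#' `a != 0`) and decays with `tau_w`.
#'
#' @param state Named numeric vector or list with `nu_e`, `nu_i` (Hz) and
#'   `W` (pA).
#' @param nu_ext External excitatory drive (Hz).
#' @param params An [nvc_params()] object.
#' @return Named numeric vector `c(nu_e, nu_i, W)` of time derivatives
#'   (Hz/s, Hz/s, pA/s).
#' @export
mean_field_deriv <- function(state, nu_ext, params = nvc_params()) {
  n <- params$neuronal
  nu_e <- max(0, state[["nu_e"]]); nu_i <- max(0, state[["nu_i"]])
  W <- state[["W"]]
  nu_bar_e <- nu_e + nu_ext
  Fe <- adex_transfer(nu_bar_e, nu_i, W, params, pop = "e")
  Fi <- adex_transfer(nu_bar_e, nu_i, 0, params, pop = "i")
  dW <- -W / n$tau_w + n$b * nu_e
  if (n$a != 0) {
    m <- membrane_moments(nu_bar_e, nu_i, W, params)
    # a in nS, voltages in V -> nA*V? keep pA/s: a(nS) * dV(mV) = pA
    dW <- dW + n$a * (m$mu_V - n$E_L) * 1e3
  }
  c(nu_e = (Fe - nu_e) / n$T,
    nu_i = (Fi - nu_i) / n$T,
    W = dW)
}

#' Steady state of the neuronal population under constant drive
#'
#' Finds the fixed point of [mean_field_deriv()] by relaxation integration
#' from the quiescent state until the maximum normalised derivative falls
#' below `tol`.
#'
#' @param nu_ext Constant external drive (Hz), `>= 0`.
#' @param params An [nvc_params()] object.
#' @param tol Convergence tolerance on the normalised derivatives (1/s).
#' @param t_max Maximum relaxation time (s) before a convergence error.
#' @param dt Integrator step (s).
#' @return Named vector `c(nu_e, nu_i, W)` at the fixed point.
#' @export
mean_field_steady <- function(nu_ext, params = nvc_params(), tol = 1e-8,
                              t_max = 300, dt = 1e-3) {
  stopifnot(nu_ext >= 0)
  st <- c(nu_e = 0, nu_i = 0, W = 0)
  # scale for the normalised residual: rates ~Hz, W ~ b*tau_w*nu
  scale <- c(1, 1, max(1, params$neuronal$b * params$neuronal$tau_w))
  t <- 0
  check_every <- 50L
  i <- 0L
  repeat {
    st <- rk4_step(function(s) mean_field_deriv(s, nu_ext, params), st, dt)
    st[1:2] <- pmax(st[1:2], 0)
    t <- t + dt
    i <- i + 1L
    if (i %% check_every == 0L) {
      d <- mean_field_deriv(st, nu_ext, params) / scale
      if (max(abs(d)) < tol) break
    }
    if (t > t_max) {
      d <- mean_field_deriv(st, nu_ext, params) / scale
      stop("steady state not reached within ", t_max,
           " s (residual ", signif(max(abs(d)), 3), ")", call. = FALSE)
    }
  }
  st
}

rk4_step <- function(f, y, dt) {
  k1 <- f(y)
  k2 <- f(y + dt / 2 * k1)
  k3 <- f(y + dt / 2 * k2)
  k4 <- f(y + dt * k3)
  y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

#' Synaptic glutamate concentration
#'
#' Mean glutamate concentration in the synaptic cleft, proportional to the
#' mean excitatory synaptic conductance: `[Glu] = (g_r nu_e + g_ext nu_ext) *
#' p_conn * N_e * Q_e * tau_e`, with `Q_e tau_e` expressed in nS s so that
#' `g_r`, `g_ext` carry units of uM per (nS s Hz). Exactly linear in both
#' rates; with the default `g_ext = 0` glutamate release tracks the local
#' recurrent excitatory activity only.
#'
#' @param nu_e Recurrent excitatory rate (Hz).
#' @param nu_ext External drive rate (Hz).
#' @param params An [nvc_params()] object.
#' @return Glutamate concentration (uM).
#' @export
glutamate_release <- function(nu_e, nu_ext, params = nvc_params()) {
  n <- params$neuronal
  stopifnot(all(nu_e >= 0), all(nu_ext >= 0))
  drive <- n$p_conn * n$N_e * (n$Q_e * 1e9) * n$tau_e   # nS s per Hz
  (n$g_r * nu_e + n$g_ext * nu_ext) * drive
}
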