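state_names <- c("nu_e", "nu_i", "W", "Ca", "h", "IP3", "AA", "PG",
                 "R_PG", "cAMP", "v", "q")
result_names <- c("time", state_names, "Glu", "CBV_A", "CBF_in", "CBF_out", "BOLD")

rest_cache <- new.env(parent = emptyenv())

#' Resting state of the coupled system
#'
#' Relaxes the neuronal-astrocyte-vascular chain under zero (or a constant
#' baseline) external drive and returns the resting values of every state
#' variable together with the self-consistent basal cAMP. Because the chain
#' is feed-forward, the Balloon stage is reset to its exact fixed point
#' (`v = q = 1`) and basal cAMP is defined as the relaxed cAMP value, so the
#' returned state is an exact fixed point of the assembled ODEs. Results are
#' cached per parameter set and baseline.
#'
#' @param params An [nvc_params()] object.
#' @param baseline Constant external drive during relaxation (Hz).
#' @param t_relax Relaxation time (s). The astrocytic IP3 turnover is the
#'   slowest process; 400 s leaves all derivatives at numerical zero.
#' @param dt Integrator step (s).
#' @return A list with `state` (named vector of the 12 dynamic variables)
#'   and `cAMP_o` (basal cAMP, uM).
#' @export
resting_state <- function(params = nvc_params(), baseline = 0,
                          t_relax = 400, dt = 2e-4) {
  key <- rlang::hash(list(unclass(params), baseline, t_relax, dt))
  if (!is.null(rest_cache[[key]])) return(rest_cache[[key]])
  pp <- unclass(params)
  pp$vascular$cAMP_o <- 0  # placeholder; CBV/Balloon do not feed back upstream
  init <- c(0, 0, 0, 0.1, 0.8, 0.1, 0, 0, 0, 0, 1, 1)
  n <- round(t_relax / dt)
  m <- .cpp_run_nvc(init, rep(baseline, 2 * n + 1), dt, n, pp, list())
  st <- as.numeric(m[nrow(m), 2:13])
  names(st) <- state_names
  st[["v"]] <- 1; st[["q"]] <- 1
  out <- list(state = st, cAMP_o = st[["cAMP"]])
  rest_cache[[key]] <- out
  out
}

#' Run the coupled neurovascular simulation
#'
#' Integrates the full 12-variable ODE system (mean-field neuronal rates and
#' adaptation; astrocytic calcium, IP3-receptor gate, IP3, arachidonic acid
#' and PGE2; vascular receptor fraction, cAMP, venous volume and
#' deoxyhemoglobin) with a fixed-step 4th-order Runge-Kutta scheme, starting
#' from the computed resting fixed point. The run is fully deterministic:
#' identical inputs give identical outputs.
#'
#' @param protocol An `nvc_protocol` from [stim_event()], [stim_block()],
#'   [stim_sinusoid()] or [stim_custom()].
#' @param params An [nvc_params()] object.
#' @param dt Integrator step (s). The default 0.2 ms resolves the fast
#'   (IP3-receptor gating) dynamics; halving it changes outputs by well
#'   under 1e-4 relative.
#' @param output_dt Output sampling interval (s); must be a multiple of
#'   `dt`. Default 10 ms.
#' @param ca_clamp Optional cap (uM) on the calcium concentration seen by
#'   the arachidonic-acid production term (the spike-amplitude clamp used to
#'   isolate frequency coding). The calcium dynamics itself is untouched.
#' @param glu_floor_time,glu_floor_nu From time `glu_floor_time` (s) on, the
#'   excitatory rate entering the glutamate release is floored at
#'   `glu_floor_nu` (Hz). Used to remove the post-stimulus neuronal
#'   undershoot in the adaptation decomposition.
#' @param rest Optional precomputed [resting_state()] result.
#' @return A tibble of class `nvc_sim` with columns `time`, the 12 state
#'   variables, and the algebraic `Glu`, `CBV_A`, `CBF_in`, `CBF_out` and
#'   `BOLD` (percent signal change). The protocol and parameters are
#'   attached as attributes.
#' @examples
#' \donttest{
#' sim <- simulate_nvc(stim_event(4, 2))
#' max(sim$BOLD)
#' }
#' @export
simulate_nvc <- function(protocol, params = nvc_params(), dt = 2e-4,
                         output_dt = 0.01, ca_clamp = Inf,
                         glu_floor_time = Inf, glu_floor_nu = 0,
                         rest = NULL) {
  stopifnot(inherits(protocol, "nvc_protocol"))
  stride <- round(output_dt / dt)
  if (abs(stride * dt - output_dt) > 1e-12) {
    stop("output_dt must be a multiple of dt", call. = FALSE)
  }
  baseline <- protocol$meta$baseline %||% 0
  if (is.null(rest)) rest <- resting_state(params, baseline = baseline, dt = dt)
  pp <- unclass(params)
  if (is.null(pp$vascular$cAMP_o)) pp$vascular$cAMP_o <- rest$cAMP_o
  n <- round(protocol$t_total / dt)
  # round the evaluation grid to ns so that stimulus edges land on the same
  # side of a step at every resolution (float jitter would otherwise shift
  # edges by half a step and spoil the integrator's convergence order)
  t_half <- round(seq(0, by = dt / 2, length.out = 2 * n + 1), 9)
  nu <- protocol$fn(t_half)
  if (any(nu < 0) || any(!is.finite(nu))) {
    stop("protocol produced invalid nu_ext values", call. = FALSE)
  }
  opts <- list(ca_clamp = ca_clamp, glu_floor_time = glu_floor_time,
               glu_floor_nu = glu_floor_nu)
  m <- .cpp_run_nvc(as.numeric(rest$state), nu, dt, stride, pp, opts)
  colnames(m) <- result_names
  out <- tibble::as_tibble(as.data.frame(m))
  attr(out, "protocol") <- protocol
  attr(out, "params") <- params
  attr(out, "rest") <- rest
  class(out) <- c("nvc_sim", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a simulation result to CSV
#'
#' Plain-text export of every state column with the time grid; the file can
#' be re-imported with any CSV reader.
#'
#' @param sim An `nvc_sim` tibble.
#' @param path Output file.
#' @export
write_nvc_csv <- function(sim, path) {
  utils::write.csv(as.data.frame(sim), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.nvc_sim <- function(x, ...) {
  pr <- attr(x, "protocol")
  cat("<nvc_sim> ", nrow(x), " samples, ",
      if (!is.null(pr)) paste0(pr$kind, " protocol, "),
      "t = [", min(x$time), ", ", max(x$time), "] s\n", sep = "")
  NextMethod()
}
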