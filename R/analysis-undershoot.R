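#' Calcium contribution to the BOLD post-stimulus undershoot
#'
#' Sweeps stimulus conditions (intensity and duration), recording for each
#' run the post-stimulus calcium undershoot amplitude (basal minus the
#' post-offset calcium minimum) and the BOLD undershoot amplitude (minimum
#' BOLD after the response peak). Because the stimulus end falls at
#' different phases of the calcium oscillation, the calcium undershoot
#' varies across conditions and its effect on the BOLD undershoot can be
#' read off the sweep: the summary reports the maximum relative change of
#' the BOLD undershoot across the sweep and the slope of a linear
#' regression of the BOLD undershoot on the calcium undershoot.
#'
#' @param params An [nvc_params()] object.
#' @param amplitudes,durations Stimulus intensities (Hz) and durations (s)
#'   defining the sweep grid.
#' @param dt Integrator step (s).
#' @return An object of class `nvc_ca_undershoot`: list with `sweep`
#'   (tibble: `amplitude`, `duration`, `ca_undershoot`, `bold_undershoot`,
#'   `bold_peak`), `max_rel_change` (percent), `slope` and `r_squared` of
#'   the regression.
#' @export
ca_undershoot_sweep <- function(params = nvc_params(),
                                amplitudes = c(3, 3.5, 4, 5, 6),
                                durations = c(8, 11, 14, 17, 20),
                                dt = 2e-4) {
  rest <- resting_state(params, dt = dt)
  basal <- rest$state[["Ca"]]
  grid <- expand.grid(amplitude = amplitudes, duration = durations)
  rows <- purrr::pmap_dfr(grid, function(amplitude, duration) {
    sim <- simulate_nvc(stim_event(amplitude, duration, onset = 10,
                                   t_total = duration + 55),
                        params, dt = dt, rest = rest)
    offset <- 10 + duration
    post <- sim[sim$time >= offset, ]
    resp <- sim[sim$time >= 10, ]
    pk_t <- resp$time[which.max(resp$BOLD)]
    after_pk <- sim[sim$time > pk_t, ]
    tibble::tibble(
      amplitude = amplitude, duration = duration,
      ca_undershoot = basal - min(post$Ca),
      bold_undershoot = min(after_pk$BOLD),
      bold_peak = max(resp$BOLD)
    )
  })
  u <- abs(rows$bold_undershoot)
  fit <- stats::lm(bold_undershoot ~ ca_undershoot, data = rows)
  structure(list(
    sweep = tibble::as_tibble(rows),
    max_rel_change = 100 * (max(u) - min(u)) / max(u),
    slope = unname(stats::coef(fit)[2]),
    r_squared = summary(fit)$r.squared
  ), class = "nvc_ca_undershoot")
}

#' @export
print.nvc_ca_undershoot <- function(x, ...) {
  cat("<nvc_ca_undershoot> ", nrow(x$sweep), " conditions; max relative",
      " BOLD-undershoot change = ", signif(x$max_rel_change, 3), "%\n", sep = "")
  invisible(x)
}

#' Neuronal-adaptation contribution to the BOLD undershoot
#'
#' With a slow adaptation time constant the post-stimulus dip of the
#' excitatory rate below its pre-stimulus baseline propagates through
#' glutamate and calcium into the BOLD post-stimulus undershoot (PSU). For
#' each spike-adaptation strength `b` this runs the stimulus twice: once
#' normally and once with the neuronal undershoot removed (the rate
#' entering glutamate release is floored at its baseline steady value from
#' stimulus offset on), and reports
#' `dU/U = (min(BOLD) - min(BOLD_Ad)) / min(BOLD)`.
#' The protocol rides on a constant baseline drive so that a below-baseline
#' excursion exists; glutamate is driven by the recurrent activity only
#' (`g_ext = 0`).
#'
#' @param params Base parameters; `tau_w` and `b` are overridden per run.
#' @param b_grid Spike-adaptation strengths to sweep (pA).
#' @param tau_w Adaptation time constant (s, default 5).
#' @param baseline Pre-stimulus external drive (Hz); must be subthreshold
#'   for calcium spiking.
#' @param amplitude Stimulus amplitude above baseline (Hz).
#' @param duration Stimulus duration (s).
#' @param dt Integrator step (s).
#' @return An object of class `nvc_adaptation`: list with `table` (tibble:
#'   `b`, `min_bold`, `min_bold_ad`, `delta_u_over_u` in percent) and
#'   `max_delta_u` (percent).
#' @export
adaptation_undershoot <- function(params = nvc_params(), b_grid = c(0, 20, 40, 60),
                                  tau_w = 5, baseline = 1.5, amplitude = 4,
                                  duration = 30, dt = 2e-4) {
  rows <- purrr::map_dfr(b_grid, function(b) {
    p <- nvc_params(neuronal = utils::modifyList(
      params$neuronal, list(b = b, tau_w = tau_w, g_ext = 0)),
      astrocyte = params$astrocyte, vascular = params$vascular,
      balloon = params$balloon)
    rest <- resting_state(p, baseline = baseline, dt = dt)
    onset <- 10; offset <- onset + duration
    prot <- stim_event(amplitude, duration, onset = onset,
                       t_total = offset + 50, baseline = baseline)
    sim <- simulate_nvc(prot, p, dt = dt, rest = rest)
    sim_ad <- simulate_nvc(prot, p, dt = dt, rest = rest,
                           glu_floor_time = offset,
                           glu_floor_nu = rest$state[["nu_e"]])
    resp <- sim[sim$time >= onset, ]
    pk_t <- resp$time[which.max(resp$BOLD)]
    mb <- min(sim$BOLD[sim$time > pk_t])
    mba <- min(sim_ad$BOLD[sim_ad$time > pk_t])
    tibble::tibble(b = b, min_bold = mb, min_bold_ad = mba,
                   delta_u_over_u = 100 * (mb - mba) / mb)
  })
  structure(list(table = rows, max_delta_u = max(rows$delta_u_over_u)),
            class = "nvc_adaptation")
}

#' @export
print.nvc_adaptation <- function(x, ...) {
  print(x$table)
  cat("max dU/U =", signif(x$max_delta_u, 3), "%\n")
  invisible(x)
}

#' Frequency- versus amplitude-coding contribution to the BOLD response
#'
#' Re-runs the stronger of two sustained stimuli with the calcium spike
#' amplitude clamped (for arachidonic-acid production only) at `clamp` uM
#' and reports which fraction of the BOLD-amplitude change between the two
#' drives survives the clamp — the part attributable to calcium-spike
#' frequency alone.
#'
#' @param params An [nvc_params()] object.
#' @param nu_low,nu_high The two external drives (Hz) compared.
#' @param clamp Spike-amplitude cap (uM) for AA production.
#' @param duration Stimulus duration (s).
#' @param dt Integrator step (s).
#' @return One-row tibble with `amp_low`, `amp_high`, `amp_high_clamped`
#'   (percent BOLD) and `freq_fraction` (percent of the amplitude change
#'   explained by frequency).
#' @export
amplitude_clamp_experiment <- function(params = nvc_params(), nu_low = 3,
                                       nu_high = 6, clamp = 0.65,
                                       duration = 20, dt = 2e-4) {
  rest <- resting_state(params, dt = dt)
  amp_of <- function(nu, ca_clamp = Inf) {
    sim <- simulate_nvc(stim_event(nu, duration, onset = 10,
                                   t_total = duration + 50),
                        params, dt = dt, rest = rest, ca_clamp = ca_clamp)
    max(sim$BOLD[sim$time >= 10])
  }
  a_lo <- amp_of(nu_low)
  a_hi <- amp_of(nu_high)
  a_hi_cl <- amp_of(nu_high, ca_clamp = clamp)
  tibble::tibble(
    amp_low = a_lo, amp_high = a_hi, amp_high_clamped = a_hi_cl,
    freq_fraction = 100 * (a_hi_cl - a_lo) / (a_hi - a_lo)
  )
}

#' Full undershoot decomposition
#'
#' Convenience wrapper running the three decomposition experiments of the
#' pathway: the calcium-undershoot sweep ([ca_undershoot_sweep()]), the
#' adaptation sweep at `tau_w = 5` s ([adaptation_undershoot()]) and the
#' spike-amplitude clamp ([amplitude_clamp_experiment()]).
#'
#' @param params An [nvc_params()] object.
#' @param b_grid Adaptation strengths for the adaptation sweep (pA).
#' @param clamp Spike-amplitude cap (uM).
#' @param dt Integrator step (s).
#' @return List with elements `calcium`, `adaptation`, `clamp`.
#' @export
undershoot_decomposition <- function(params = nvc_params(),
                                     b_grid = c(0, 20, 40, 60),
                                     clamp = 0.65, dt = 2e-4) {
  list(
    calcium = ca_undershoot_sweep(params, dt = dt),
    adaptation = adaptation_undershoot(params, b_grid = b_grid, dt = dt),
    clamp = amplitude_clamp_experiment(params, clamp = clamp, dt = dt)
  )
}
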