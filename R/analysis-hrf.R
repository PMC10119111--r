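#' Extract hemodynamic response features from a BOLD trace
#'
#' Measures the standard HRF descriptors relative to stimulus onset: the
#' onset latency `t_on` (first crossing of a fraction of the eventual peak,
#' 10% by default), the peak latency `t_peak`, the peak amplitude (percent
#' BOLD), the post-stimulus undershoot amplitude (minimum over a post-peak
#' window) and the total response duration (last time the signal exceeds
#' the onset threshold).
#'
#' @param x An `nvc_sim` tibble or data frame with `time` and `BOLD`
#'   (percent) columns.
#' @param stim_onset Stimulus onset time (s). Defaults to the onset recorded
#'   in the protocol attribute, if present.
#' @param onset_frac Fraction of the peak defining `t_on` (default 0.1).
#' @param post_peak_window Length (s) of the window after the peak searched
#'   for the undershoot minimum (default 30).
#' @param min_peak Minimum peak (percent BOLD) below which the trace is
#'   considered flat and an error is raised.
#' @return One-row tibble with `t_on`, `t_peak`, `peak`, `undershoot`,
#'   `t_undershoot` and `duration` (times in s from onset).
#' @export
hrf_features <- function(x, stim_onset = NULL, onset_frac = 0.1,
                         post_peak_window = 30, min_peak = 0.05) {
  df <- as.data.frame(x)
  stopifnot(all(c("time", "BOLD") %in% names(df)))
  if (is.null(stim_onset)) {
    pr <- attr(x, "protocol")
    stim_onset <- if (!is.null(pr)) pr$meta$onset else 0
  }
  if (max(df$time) < stim_onset + 30) {
    stop("trace must extend at least 30 s past stimulus onset", call. = FALSE)
  }
  post <- df[df$time >= stim_onset, ]
  pk <- max(post$BOLD)
  if (!is.finite(pk) || pk < min_peak) {
    stop("no BOLD response detected (flat trace)", call. = FALSE)
  }
  i_pk <- which.max(post$BOLD)
  t_peak <- post$time[i_pk] - stim_onset
  thr <- onset_frac * pk
  t_on <- post$time[which(post$BOLD >= thr)[1]] - stim_onset
  tail_df <- post[post$time > post$time[i_pk] &
                    post$time <= post$time[i_pk] + post_peak_window, ]
  undershoot <- min(tail_df$BOLD)
  t_undershoot <- tail_df$time[which.min(tail_df$BOLD)] - stim_onset
  above <- post$time[post$BOLD >= thr]
  tibble::tibble(t_on = t_on, t_peak = t_peak, peak = pk,
                 undershoot = undershoot, t_undershoot = t_undershoot,
                 duration = max(above) - stim_onset)
}

#' Canonical double-gamma HRF
#'
#' Evaluates `(t/d1)^a1 exp(-(t-d1)/b1) - c (t/d2)^a2 exp(-(t-d2)/b2)`, the
#' standard two-lobe phenomenological HRF with a positive lobe peaking at
#' `d1` and an undershoot lobe peaking at `d2`.
#'
#' @param t Time from stimulus onset (s), `>= 0`.
#' @param d1,a1,b1 Delay (s), shape and scale (s) of the positive lobe.
#' @param c Relative undershoot amplitude, in `(0, 1)`.
#' @param d2,a2,b2 Delay (s), shape and scale (s) of the undershoot lobe.
#' @return Numeric vector; the positive lobe has unit peak at `t = d1` when
#'   `a1 b1 = d1`.
#' @export
canonical_hrf <- function(t, d1 = 6, a1 = 6, b1 = 1, c = 0.07,
                          d2 = 18, a2 = 12, b2 = 1.5) {
  stopifnot(all(t >= 0))
  (t / d1)^a1 * exp(-(t - d1) / b1) - c * (t / d2)^a2 * exp(-(t - d2) / b2)
}

#' Fit the canonical double-gamma HRF to a response trace
#'
#' Nonlinear least squares with multi-start over the lobe delays (`d1` in
#' `[3, 9]` s, `d2` in `[10, 25]` s by default). The trace should be an HRF
#' normalized to unit peak ([extract_hrf()] produces one); time is measured
#' from stimulus onset. Shapes `a1`, `a2` are tied to the delays through
#' `a b = d` during optimisation so each lobe peaks at its delay, matching
#' the conventional parameterisation; all seven coefficients are reported.
#'
#' @param hrf A data frame with columns `time` (s from onset) and `hrf`
#'   (unit-peak response), or an `nvc_hrf` object from [extract_hrf()].
#' @param n_starts Number of multi-start grid points per delay.
#' @param d1_range,d2_range Search ranges for the two lobe delays (s).
#' @return An object of class `nvc_hrf_fit`: list with `coef` (named vector
#'   `d1, a1, b1, c, d2, a2, b2`), `r_squared`, `fitted` tibble and the
#'   winning start. A warning (not an error) is raised when `r_squared`
#'   is below 0.8.
#' @export
fit_canonical_hrf <- function(hrf, n_starts = 4, d1_range = c(3, 9),
                              d2_range = c(10, 25)) {
  df <- as.data.frame(hrf)
  stopifnot(all(c("time", "hrf") %in% names(df)))
  t <- df$time; y <- df$hrf
  keep <- t >= 0
  t <- t[keep]; y <- y[keep]
  model <- function(par) {
    # par: d1, log_b1, c, d2, log_b2 with a = d/b
    d1 <- par[1]; b1 <- exp(par[2]); cc <- par[3]
    d2 <- par[4]; b2 <- exp(par[5])
    canonical_hrf(t, d1, d1 / b1, b1, cc, d2, d2 / b2, b2)
  }
  obj <- function(par) {
    r <- y - model(par)
    sum(r * r)
  }
  starts <- expand.grid(
    d1 = seq(d1_range[1], d1_range[2], length.out = n_starts),
    d2 = seq(d2_range[1], d2_range[2], length.out = n_starts)
  )
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    par0 <- c(starts$d1[i], log(1), 0.1, starts$d2[i], log(1.5))
    fit <- tryCatch(
      stats::optim(par0, obj, method = "L-BFGS-B",
                   lower = c(d1_range[1], log(0.2), 0, d2_range[1], log(0.2)),
                   upper = c(d1_range[2], log(5), 0.95, d2_range[2], log(6)),
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) {
      best <- fit; best$start <- as.numeric(starts[i, ])
    }
  }
  if (is.null(best)) stop("all canonical-HRF fits failed", call. = FALSE)
  par <- best$par
  co <- c(d1 = par[1], a1 = par[1] / exp(par[2]), b1 = exp(par[2]),
          c = par[3], d2 = par[4], a2 = par[4] / exp(par[5]), b2 = exp(par[5]))
  yhat <- model(par)
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  if (r2 < 0.8) warning("canonical HRF fit is poor (R^2 < 0.8)", call. = FALSE)
  structure(list(coef = co, r_squared = r2,
                 fitted = tibble::tibble(time = t, hrf = y, fitted = yhat),
                 start = best$start, rss = best$value),
            class = "nvc_hrf_fit")
}

#' @export
print.nvc_hrf_fit <- function(x, ...) {
  cat("<nvc_hrf_fit> R^2 =", signif(x$r_squared, 4), "\n")
  print(signif(x$coef, 4))
  invisible(x)
}

#' @export
tidy.nvc_hrf_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coef), estimate = unname(x$coef))
}

#' @export
glance.nvc_hrf_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, rss = x$rss)
}

#' Extract a unit-peak HRF from an event simulation
#'
#' Runs (or takes) a single-event simulation and returns the BOLD response
#' re-referenced to stimulus onset and normalized to unit peak — the
#' empirical HRF kernel of the model.
#'
#' @param sim An `nvc_sim` from an event protocol, or `NULL` to run the
#'   reference event (2 s stimulus at `amplitude` Hz).
#' @param amplitude,duration Event parameters used when `sim` is `NULL`.
#' @param params Model parameters for the reference run.
#' @return An `nvc_hrf` tibble with `time` (s from onset) and `hrf`
#'   (unit peak); attribute `peak` stores the raw peak (percent BOLD).
#' @export
extract_hrf <- function(sim = NULL, amplitude = 4, duration = 2,
                        params = nvc_params()) {
  if (is.null(sim)) {
    sim <- simulate_nvc(stim_event(amplitude, duration, onset = 10,
                                   t_total = 70), params)
  }
  onset <- attr(sim, "protocol")$meta$onset
  post <- sim[sim$time >= onset, c("time", "BOLD")]
  pk <- max(post$BOLD)
  if (pk <= 0) stop("no positive BOLD response to normalise", call. = FALSE)
  out <- tibble::tibble(time = post$time - onset, hrf = post$BOLD / pk)
  attr(out, "peak") <- pk
  class(out) <- c("nvc_hrf", class(out))
  out
}

#' Linear BOLD prediction by convolution with an HRF kernel
#'
#' Discrete causal convolution `gain * dt * sum(kernel(t - tau) driver(tau))`
#' implementing the linear-time-invariant approximation of the coupling.
#' The driver is either the neuronal rate or the basal-subtracted calcium
#' trace, on the same time grid as the kernel. The operator is exactly
#' linear and time invariant.
#'
#' @param kernel Numeric vector: HRF samples on a uniform grid (starting at
#'   lag 0), or an `nvc_hrf` object.
#' @param driver Numeric vector: driver samples on the same grid.
#' @param dt Grid spacing (s).
#' @param gain Scalar multiplier (use [calibrate_gain()] to match the
#'   reference simulation).
#' @return Numeric vector of length `length(driver)`.
#' @export
convolve_predict <- function(kernel, driver, dt, gain = 1) {
  if (inherits(kernel, "nvc_hrf")) {
    dtk <- diff(kernel$time[1:2])
    if (abs(dtk - dt) > 1e-9) {
      stop("kernel and driver are on different grids", call. = FALSE)
    }
    kernel <- kernel$hrf
  }
  stopifnot(is.numeric(kernel), is.numeric(driver), dt > 0)
  n <- length(driver)
  # standard causal convolution: out[i] = sum_j kernel[j] * driver[i - j + 1]
  full <- stats::convolve(driver, rev(kernel), type = "open")
  out <- full[seq_len(n)]
  gain * dt * out
}

#' Calibrate the convolution gain against a reference simulation
#'
#' Scales the linear prediction so that its peak matches the simulated BOLD
#' peak for a reference run (by default the standard 2 s, 4 Hz event).
#'
#' @param kernel HRF kernel (vector or `nvc_hrf`).
#' @param driver Driver trace for the reference run, on the same grid.
#' @param reference_bold Simulated BOLD (percent) for the reference run.
#' @param dt Grid spacing (s).
#' @return The scalar gain.
#' @export
calibrate_gain <- function(kernel, driver, reference_bold, dt) {
  pred <- convolve_predict(kernel, driver, dt, gain = 1)
  max(reference_bold) / max(pred)
}
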