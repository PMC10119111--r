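#' Locate the calcium/BOLD activation threshold by bisection
#'
#' Bisects the external drive between `lo` and `hi` using sustained
#' stimulation runs; a grid point is "active" when the calcium trace
#' contains at least `min_spikes` detected spikes. Below the returned
#' threshold no calcium spike (and hence no BOLD activation) occurs.
#'
#' @param params An [nvc_params()] object.
#' @param lo,hi Bracketing external drives (Hz).
#' @param t_stim Sustained stimulation length per probe run (s).
#' @param min_spikes Spike count defining activation (default 1).
#' @param iters Number of bisection steps.
#' @param dt Integrator step (s).
#' @return Threshold drive (Hz).
#' @export
activation_threshold <- function(params = nvc_params(), lo = 1, hi = 4,
                                 t_stim = 60, min_spikes = 1, iters = 9,
                                 dt = 2e-4) {
  rest <- resting_state(params, dt = dt)
  basal <- rest$state[["Ca"]]
  active <- function(nu) {
    sim <- simulate_nvc(stim_event(nu, t_stim, onset = 5, t_total = t_stim + 10),
                        params, dt = dt, rest = rest)
    nrow(detect_ca_spikes(sim, basal = basal, window = c(5, t_stim + 10))) >= min_spikes
  }
  if (active(lo)) stop("lower bracket is already active", call. = FALSE)
  if (!active(hi)) stop("upper bracket is not active", call. = FALSE)
  for (k in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (active(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Fit the logarithmic frequency-coding model
#'
#' Fits `f(x) = A log((x - x_o) / B)` to a frequency-versus-rate curve by
#' nonlinear least squares with a grid of starts over the offset `x_o`.
#'
#' @param x Input values (e.g. steady excitatory rate, Hz).
#' @param f Calcium-spike frequencies (Hz).
#' @return List with `coef` (named `A`, `x_o`, `B`), `r_squared` and
#'   `fitted`.
#' @export
fit_log_curve <- function(x, f) {
  stopifnot(length(x) == length(f), length(x) >= 4)
  obj <- function(par) {
    A <- par[1]; xo <- par[2]; B <- exp(par[3])
    if (any(x - xo <= 0)) return(1e10)
    r <- f - A * log((x - xo) / B)
    sum(r * r)
  }
  best <- NULL
  for (xo0 in seq(min(x) - 1e-3 - 0.5 * diff(range(x)), min(x) - 1e-3,
                  length.out = 8)) {
    fit <- tryCatch(
      stats::optim(c(max(f) / 3, xo0, log(0.05)), obj,
                   control = list(maxit = 2000, reltol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("logarithmic fit failed", call. = FALSE)
  co <- c(A = best$par[1], x_o = best$par[2], B = exp(best$par[3]))
  yhat <- co[1] * log((x - co[2]) / co[3])
  r2 <- 1 - sum((f - yhat)^2) / sum((f - mean(f))^2)
  list(coef = co, r_squared = r2,
       fitted = tibble::tibble(x = x, f = f, fitted = yhat))
}

#' Fit the saturating response model
#'
#' Fits `f(x) = a x^p / (x^p + b)` (the contrast-response form used for
#' BOLD amplitude versus stimulus strength) by multi-start nonlinear least
#' squares over the exponent `p`.
#'
#' @param x Input strengths (> 0).
#' @param y Response amplitudes.
#' @param p_starts Starting values for the exponent.
#' @return List with `coef` (named `a`, `p`, `b`), `r_squared` and `fitted`.
#' @export
fit_saturating <- function(x, y, p_starts = c(0.5, 1, 2, 4)) {
  stopifnot(length(x) == length(y), length(x) >= 4, all(x > 0))
  best <- NULL
  for (p0 in p_starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * x^p / (x^p + b),
                        start = list(a = max(y), p = p0, b = stats::median(x)^p0),
                        lower = c(1e-8, 0.05, 1e-8),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) {
        best <- list(fit = fit, rss = rss)
      }
    }
  }
  if (is.null(best)) stop("saturating fit failed", call. = FALSE)
  co <- stats::coef(best$fit)[c("a", "p", "b")]
  yhat <- stats::predict(best$fit)
  r2 <- 1 - best$rss / sum((y - mean(y))^2)
  list(coef = co, r_squared = r2,
       fitted = tibble::tibble(x = x, y = y, fitted = yhat))
}

#' Stimulus-response coding curve of the full pathway
#'
#' Runs sustained-stimulation simulations over a grid of external drives
#' and collects, per grid point, the steady excitatory rate, the
#' calcium-spike frequency and amplitude over the sustained window, the
#' first-spike latency, and the peak BOLD amplitude and CBF change. The
#' activation threshold is located by bisection, the supra-threshold
#' frequency curve is fitted with the logarithmic model
#' ([fit_log_curve()]) and the BOLD amplitude curve with the saturating
#' model ([fit_saturating()]).
#'
#' @param nu_ext_grid External drives (Hz) spanning sub- and
#'   supra-threshold inputs.
#' @param params An [nvc_params()] object.
#' @param t_stim Sustained stimulation length (s); the spike statistics are
#'   measured over `[t_skip, t_stim]` after onset to avoid the onset
#'   transient.
#' @param t_skip Length of the discarded onset window (s).
#' @param min_fit_points Minimum number of supra-threshold points required
#'   for the fits.
#' @param dt Integrator step (s).
#' @return An object of class `nvc_coding`: list with `curve` (tibble),
#'   `threshold` (Hz), `log_fit`, `sat_fit`.
#' @export
coding_curve <- function(nu_ext_grid = c(1.5, 2, 2.5, 2.75, 3, 3.5, 4, 4.5,
                                         5, 6, 7, 8),
                         params = nvc_params(), t_stim = 90, t_skip = 30,
                         min_fit_points = 4, dt = 2e-4) {
  stopifnot(t_stim > t_skip + 10)
  rest <- resting_state(params, dt = dt)
  basal <- rest$state[["Ca"]]
  rows <- purrr::map_dfr(nu_ext_grid, function(nu) {
    sim <- simulate_nvc(stim_event(nu, t_stim, onset = 5,
                                   t_total = t_stim + 15),
                        params, dt = dt, rest = rest)
    stim_win <- c(5 + t_skip, 5 + t_stim)
    sp <- detect_ca_spikes(sim, basal = basal, window = stim_win)
    first <- detect_ca_spikes(sim, basal = basal, window = c(5, 5 + t_stim))
    st <- sim[sim$time > 5 + t_stim - 5 & sim$time < 5 + t_stim, ]
    tibble::tibble(
      nu_ext = nu,
      nu_e = mean(st$nu_e),
      n_spikes = nrow(sp),
      f_ca = attr(sp, "f_ca"),
      a_ca = attr(sp, "a_ca"),
      latency = if (nrow(first)) first$time[1] - 5 else NA_real_,
      bold_amp = max(sim$BOLD[sim$time >= 5]),
      cbf_peak = max(sim$CBF_in) - 1
    )
  })
  thr <- tryCatch(
    activation_threshold(params, lo = min(nu_ext_grid),
                         hi = max(3.99, min(4, max(nu_ext_grid))), dt = dt),
    error = function(e) NA_real_)
  supra <- rows[rows$n_spikes >= 2, ]
  if (nrow(supra) < min_fit_points) {
    stop("fewer than ", min_fit_points, " supra-threshold grid points",
         call. = FALSE)
  }
  log_fit <- fit_log_curve(supra$nu_e, supra$f_ca)
  sat_fit <- fit_saturating(rows$nu_ext, rows$bold_amp)
  structure(list(curve = rows, threshold = thr,
                 log_fit = log_fit, sat_fit = sat_fit),
            class = "nvc_coding")
}

#' @export
print.nvc_coding <- function(x, ...) {
  cat("<nvc_coding> threshold =", signif(x$threshold, 3), "Hz;",
      nrow(x$curve), "grid points\n")
  cat("  log fit  (A, x_o, B):", signif(x$log_fit$coef, 3),
      " R^2 =", signif(x$log_fit$r_squared, 3), "\n")
  cat("  sat fit  (a, p, b):  ", signif(x$sat_fit$coef, 3),
      " R^2 =", signif(x$sat_fit$r_squared, 3), "\n")
  invisible(x)
}

#' Fraction of the BOLD range described by the linear segment
#'
#' Identifies the linear regime of the BOLD-amplitude-versus-excitatory-rate
#' relation as the initial run of grid points whose straight-line fit has
#' the smallest lack of fit relative to the amplitude span it covers (RMS
#' residual divided by segment span, minimised over prefix length): the
#' segment a line describes best relative to its extent. Reports the
#' fraction of the explored BOLD-amplitude range that this segment covers,
#' together with the R-squared of the linear fit on the segment.
#'
#' @param coding An `nvc_coding` object.
#' @param min_points Minimum prefix length considered.
#' @return One-row tibble with `fraction` (in percent), `r_squared`,
#'   `n_points` of the segment.
#' @export
linear_fraction <- function(coding, min_points = 4) {
  cu <- coding$curve[order(coding$curve$nu_e), ]
  if (nrow(cu) < min_points) stop("not enough grid points", call. = FALSE)
  y <- cu$bold_amp; x <- cu$nu_e
  lof <- vapply(min_points:length(y), function(i) {
    fit <- stats::lm(y[1:i] ~ x[1:i])
    sqrt(mean(stats::resid(fit)^2)) / (max(y[1:i]) - min(y[1:i]))
  }, numeric(1))
  # longest prefix within tolerance of the minimal relative lack of fit
  # (the absolute epsilon settles near-ties between essentially exact fits)
  ok <- lof <= max(1.15 * min(lof), min(lof) + 1e-4)
  end <- (min_points:length(y))[max(which(ok))]
  best <- list(fit = stats::lm(y[1:end] ~ x[1:end]), end = end)
  span_total <- max(y) - min(y)
  span_seg <- max(y[1:best$end]) - min(y[1:best$end])
  tibble::tibble(fraction = 100 * span_seg / span_total,
                 r_squared = summary(best$fit)$r.squared,
                 n_points = best$end)
}
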